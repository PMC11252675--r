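#' Tissue construct
#'
#' A collection of spherical cell agents with centre positions (um),
#' radii and frozen flags, plus an optional contact graph and construct
#' metadata.  Coordinates are Cartesian with the origin at the construct
#' centroid.
#'
#' @param positions numeric matrix (n x 2 or n x 3) of cell centres (um)
#' @param radius cell radius (um), scalar or per-cell
#' @param frozen logical pre-frozen flags, scalar or per-cell
#' @param meta list of construct metadata (kind, build parameters)
#' @param overlap_max maximum allowed fractional radius overlap between any
#'   pair (invariant: centre distance >= (1 - overlap_max) (r_i + r_j))
#' @return an object of class \code{tissue}: list with \code{cells} (a
#'   data.frame id, x, y, z, radius, frozen), \code{graph} (NULL until
#'   [neighbours()] is attached) and \code{meta}
#' @export
tissue <- function(positions, radius, frozen = FALSE, meta = list(),
                   overlap_max = 0.2) {
  positions <- as.matrix(positions)
  if (ncol(positions) == 2) positions <- cbind(positions, 0)
  n <- nrow(positions)
  radius <- rep_len(radius, n)
  frozen <- rep_len(frozen, n)
  if (any(radius <= 0)) stop("cell radii must be positive")
  positions <- sweep(positions, 2, colMeans(positions))  # centroid at origin
  cells <- data.frame(id = seq_len(n), x = positions[, 1], y = positions[, 2],
                      z = positions[, 3], radius = radius, frozen = frozen)
  tis <- structure(list(cells = cells, graph = NULL, meta = meta,
                        overlap_max = overlap_max), class = "tissue")
  if (n > 1) {
    dmin <- min(stats::dist(positions))
    lim <- (1 - overlap_max) * 2 * min(radius)
    if (dmin < lim - 1e-9)
      stop(sprintf(
        "overlap invariant violated: min centre distance %.3f < %.3f um",
        dmin, lim))
  }
  tis
}

#' @export
print.tissue <- function(x, ...) {
  cat(sprintf("Tissue construct '%s': %d cells%s\n",
              if (is.null(x$meta$kind)) "custom" else x$meta$kind,
              nrow(x$cells),
              if (is.null(x$graph)) "" else
                sprintf(", %d contact edges", nrow(x$graph$edges))))
  invisible(x)
}

#' Cell centre coordinates of a tissue
#' @param tissue a [tissue()]
#' @return numeric matrix n x 3 (um)
#' @export
positions <- function(tissue) {
  as.matrix(tissue$cells[, c("x", "y", "z")])
}

#' Hexagonally packed disc monolayer
#'
#' Planar disc filled ring-by-ring from the centre (full hexagonal rings of
#' 6k cells at ring k, partial last ring filled in deterministic angular
#' order) until exactly \code{n_cells} cells.  Centre spacing is
#' \code{spacing_factor * cell_diameter}; the default 0.85 stays within the
#' 20 percent radius-overlap bound of the construct invariant.
#'
#' @param n_cells number of cells (>= 1)
#' @param cell_diameter cell diameter (um)
#' @param spacing_factor centre spacing as a fraction of the diameter
#' @return a [tissue()]
#' @export
build_disc_monolayer <- function(n_cells, cell_diameter = 21,
                                 spacing_factor = 0.85) {
  stopifnot(n_cells >= 1)
  if (spacing_factor < 0.8)
    stop("spacing_factor below 0.8 violates the 20% overlap bound")
  s <- spacing_factor * cell_diameter
  pts <- list(c(0, 0))
  ring <- 1
  while (length(pts) < n_cells) {
    for (k in 0:5) {
      a <- s * ring * c(cos(pi / 3 * k), sin(pi / 3 * k))
      b <- s * ring * c(cos(pi / 3 * (k + 1)), sin(pi / 3 * (k + 1)))
      for (j in 0:(ring - 1))
        pts[[length(pts) + 1L]] <- a + (b - a) * j / ring
    }
    ring <- ring + 1
  }
  xy <- do.call(rbind, pts[seq_len(n_cells)])
  tissue(xy, radius = cell_diameter / 2,
         meta = list(kind = "disc_monolayer", n_cells = n_cells,
                     cell_diameter = cell_diameter,
                     spacing_factor = spacing_factor))
}

#' Close-packed spheroid
#'
#' Cells are placed on a face-centred-cubic lattice and retained in order of
#' distance from the spheroid centre (ties broken lexicographically on
#' coordinates) until exactly \code{target_cells} cells.  The lattice
#' spacing is chosen so that \code{target_cells} cells at FCC packing fill a
#' sphere of the requested diameter; the achieved bounding diameter
#' (twice the largest centre distance) is reported in \code{meta}.
#'
#' @param target_cells number of cells (>= 1)
#' @param spheroid_diameter target construct diameter (um)
#' @param cell_diameter cell diameter (um)
#' @return a [tissue()]
#' @export
build_spheroid <- function(target_cells, spheroid_diameter = 100,
                           cell_diameter = 21) {
  stopifnot(target_cells >= 1)
  # nearest-neighbour spacing for FCC filling: one cell per s^3/sqrt(2)
  s <- (pi / 6 * spheroid_diameter^3 * sqrt(2) / target_cells)^(1 / 3)
  if (s < 0.8 * cell_diameter)
    stop(sprintf(paste0("infeasible: %d cells in %g um need spacing ",
                        "%.1f um < 20%% overlap bound %.1f um"),
                 target_cells, spheroid_diameter, s, 0.8 * cell_diameter))
  a <- s * sqrt(2)  # conventional cubic cell
  half <- ceiling((spheroid_diameter / a) + 2)
  base <- expand.grid(i = -half:half, j = -half:half, k = -half:half)
  offs <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  pts <- do.call(rbind, lapply(seq_len(4), function(b)
    a * (as.matrix(base) + matrix(offs[b, ], nrow(base), 3, byrow = TRUE))))
  d2 <- rowSums(pts^2)
  ord <- order(d2, pts[, 1], pts[, 2], pts[, 3])
  keep <- ord[seq_len(target_cells)]
  sel <- pts[keep, , drop = FALSE]
  tis <- tissue(sel, radius = cell_diameter / 2,
                meta = list(kind = "spheroid", target_cells = target_cells,
                            spheroid_diameter = spheroid_diameter,
                            cell_diameter = cell_diameter, spacing = s,
                            bounding_diameter =
                              2 * sqrt(max(d2[keep])) ))
  tis
}

#' Rectangular lattice slab
#'
#' Cubic lattice of nx x ny x nz cells with spacing equal to the cell
#' diameter (touching cells); extents are counts times diameter.
#'
#' @param nx,ny,nz cell counts along each axis (>= 1)
#' @param cell_diameter cell diameter (um)
#' @return a [tissue()]
#' @export
build_slab <- function(nx, ny, nz, cell_diameter = 21) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1)
  g <- expand.grid(x = seq_len(nx) - 1, y = seq_len(ny) - 1,
                   z = seq_len(nz) - 1)
  # grid order: x fastest, matching cell id = x + nx (y + ny z) + 1
  tissue(as.matrix(g) * cell_diameter, radius = cell_diameter / 2,
         meta = list(kind = "slab", nx = nx, ny = ny, nz = nz,
                     cell_diameter = cell_diameter,
                     extent = c(nx, ny, nz) * cell_diameter))
}

#' Neighbourhood rule
#'
#' Two rules define the contact graph: \code{radius} (cells are neighbours
#' iff their centre distance is strictly below R) and \code{contact} (cells
#' are neighbours iff their membranes touch, i.e. centre distance <=
#' (1 + contact_slack)(r_i + r_j)).
#'
#' @param kind "radius" or "contact"
#' @param R neighbourhood radius (um), required for the radius rule
#' @param contact_slack tolerance fraction for membrane contact
#' @return an object of class \code{neighbour_rule}
#' @export
neighbour_rule <- function(kind = c("radius", "contact"), R = NULL,
                           contact_slack = 0.01) {
  kind <- match.arg(kind)
  if (kind == "radius" && (is.null(R) || R <= 0))
    stop("the radius rule requires R > 0")
  structure(list(kind = kind, R = R, contact_slack = contact_slack),
            class = "neighbour_rule")
}

#' Compute the contact graph of a tissue
#'
#' Applies a [neighbour_rule()] to all cell pairs.  The relation is
#' symmetric and irreflexive by construction.
#'
#' @param tissue a [tissue()]
#' @param rule a [neighbour_rule()]
#' @param symmetry optional symmetry group to attach to the graph
#' @return a [contact_graph()]
#' @export
neighbours <- function(tissue, rule, symmetry = NULL) {
  pos <- positions(tissue)
  n <- nrow(pos)
  if (n == 1) return(contact_graph(1, matrix(integer(0), 0, 2), symmetry))
  D <- as.matrix(stats::dist(pos))
  if (rule$kind == "radius") {
    adj <- D < rule$R
  } else {
    rsum <- outer(tissue$cells$radius, tissue$cells$radius, `+`)
    adj <- D <= (1 + rule$contact_slack) * rsum
  }
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  contact_graph(n, idx, symmetry)
}

#' Attach a contact graph to a tissue
#' @param tissue a [tissue()]
#' @param rule a [neighbour_rule()]
#' @return the tissue with \code{$graph} set
#' @export
set_neighbours <- function(tissue, rule) {
  tissue$graph <- neighbours(tissue, rule)
  tissue
}

#' Read / write tissue tables
#'
#' Delimited-table exchange format: columns cell_id (0-based on disk), x, y,
#' z, radius, frozen0.
#'
#' @param path file path
#' @return \code{read_tissue()} returns a [tissue()]
#' @export
read_tissue <- function(path) {
  d <- utils::read.table(path, header = TRUE)
  tissue(as.matrix(d[, c("x", "y", "z")]), radius = d$radius,
         frozen = as.logical(d$frozen0), meta = list(kind = "imported"))
}

#' @param tis a [tissue()]
#' @rdname read_tissue
#' @export
write_tissue <- function(tis, path) {
  d <- tis$cells
  out <- data.frame(cell_id = d$id - 1L, x = d$x, y = d$y, z = d$z,
                    radius = d$radius, frozen0 = as.integer(d$frozen))
  utils::write.table(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export cell centres as legacy VTK polydata
#'
#' Point-cloud export for 3D viewers; one point per cell with radius and
#' frozen state as point data.
#'
#' @param tis a [tissue()]
#' @param path output file path (.vtk)
#' @export
write_vtk <- function(tis, path) {
  p <- positions(tis)
  n <- nrow(p)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tissue construct", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  writeLines(apply(p, 1, paste, collapse = " "), con)
  writeLines(c(sprintf("POINT_DATA %d", n), "SCALARS radius float 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(tis$cells$radius), con)
  writeLines(c("SCALARS frozen int 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.integer(tis$cells$frozen)), con)
  invisible(path)
}
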