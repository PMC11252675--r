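#' Contact graph of a tissue construct
#'
#' An undirected neighbour relation on cells 1..N, optionally together with a
#' list of symmetry permutations (bijections of cell ids that preserve the
#' edge set) used for state-space reduction of the exact Markov solver.
#'
#' @param n number of cells
#' @param edges two-column integer matrix of unordered cell-id pairs (1-based)
#' @param symmetry optional list of integer permutation vectors of length
#'   \code{n}; each must map the edge set onto itself.  The identity is added
#'   if missing.
#' @return an object of class \code{contact_graph}
#' @export
contact_graph <- function(n, edges, symmetry = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1L) || any(edges > n)) stop("edge ids out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed")
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  g <- structure(list(n = as.integer(n), edges = edges, symmetry = NULL),
                 class = "contact_graph")
  if (!is.null(symmetry)) {
    symmetry <- lapply(symmetry, as.integer)
    ek <- edge_key(g)
    for (p in symmetry) {
      if (length(p) != n || any(sort(p) != seq_len(n)))
        stop("symmetry entries must be permutations of 1..n")
      if (!setequal(edge_key(g, p), ek))
        stop("a supplied permutation does not preserve the edge set")
    }
    idp <- seq_len(n)
    if (!any(vapply(symmetry, identical, TRUE, idp)))
      symmetry <- c(list(idp), symmetry)
  } else {
    symmetry <- list(seq_len(n))
  }
  g$symmetry <- symmetry
  g
}

edge_key <- function(graph, perm = NULL) {
  e <- graph$edges
  if (nrow(e) == 0) return(character(0))
  if (!is.null(perm)) e <- cbind(perm[e[, 1]], perm[e[, 2]])
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("Contact graph: %d cells, %d edges, %d symmetry permutation(s)\n",
              x$n, nrow(x$edges), length(x$symmetry)))
  invisible(x)
}

#' Adjacency list of a contact graph
#' @param graph a [contact_graph()]
#' @return list of integer neighbour vectors, one per cell
#' @export
adjacency_list <- function(graph) {
  adj <- rep(list(integer(0)), graph$n)
  e <- graph$edges
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  adj
}

#' Cell degrees of a contact graph
#' @param graph a [contact_graph()]
#' @return integer vector of neighbour counts
#' @export
graph_degrees <- function(graph) {
  lengths(adjacency_list(graph))
}

#' Breadth-first graph distances from a source cell
#'
#' @param graph a [contact_graph()]
#' @param from source cell id
#' @return integer distances (NA for unreachable cells)
#' @export
graph_distances <- function(graph, from) {
  adj <- adjacency_list(graph)
  d <- rep(NA_integer_, graph$n)
  d[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (v in adj[[u]]) if (is.na(d[v])) {
      d[v] <- d[u] + 1L
      nxt <- c(nxt, v)
    }
    frontier <- nxt
  }
  d
}

#' Automorphism group of a contact graph
#'
#' Computes the full automorphism group of the neighbour relation (optionally
#' fixing a set of distinguished cells, e.g. pre-frozen seeds) by closing the
#' generator set returned by igraph under composition.  Intended for small
#' constructs (n <= 12); beyond that, supply the symmetry group explicitly.
#'
#' @param graph a [contact_graph()]
#' @param fix integer ids of cells that every permutation must fix
#' @param max_order safety cap on the group order
#' @return list of permutation vectors (including the identity)
#' @export
graph_symmetry <- function(graph, fix = integer(0), max_order = 50000) {
  if (graph$n > 12)
    stop("automorphism detection is limited to n <= 12; supply the group")
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, graph$n - igraph::vcount(ig)))
  colors <- rep(0L, graph$n)
  colors[fix] <- seq_along(fix)  # distinct colors pin the fixed cells
  gens <- igraph::automorphism_group(ig, colors = colors)
  gens <- lapply(gens, as.integer)
  # close under composition (BFS over the Cayley graph)
  idp <- seq_len(graph$n)
  seen <- new.env(hash = TRUE)
  keyof <- function(p) paste(p, collapse = ",")
  assign(keyof(idp), TRUE, envir = seen)
  group <- list(idp)
  frontier <- list(idp)
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) for (g in gens) {
      q <- p[g]
      k <- keyof(q)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        group[[length(group) + 1L]] <- q
        nxt[[length(nxt) + 1L]] <- q
        if (length(group) > max_order) stop("symmetry group too large")
      }
    }
    frontier <- nxt
  }
  group
}

#' Symmetry-equivalence classes of cells
#'
#' Partitions cells into orbits under the automorphism group of the contact
#' graph (optionally fixing distinguished cells such as pre-frozen seeds).
#' Works from the generator permutations by union-find, so it scales to any
#' construct size; orbit-equivalent cells are statistically exchangeable in
#' the ice-propagation model started from the fixed seeds.
#'
#' @param graph a [contact_graph()]
#' @param fix integer ids of cells every permutation must fix
#' @return integer orbit membership vector (1-based, contiguous)
#' @export
cell_orbits <- function(graph, fix = integer(0)) {
  ig <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, graph$n - igraph::vcount(ig)))
  colors <- rep(0L, graph$n)
  colors[fix] <- seq_along(fix)
  gens <- igraph::automorphism_group(ig, colors = colors)
  comp <- seq_len(graph$n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (p in gens) for (i in seq_len(graph$n)) {
    a <- find(i); b <- find(as.integer(p[i]))
    if (a != b) comp[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(graph$n), find, integer(1))
  match(roots, sort(unique(roots)))
}

#' The 2 x 2 validation construct
#'
#' Four cells at the corners of a square.  Every pair - including the
#' diagonal - is a contact neighbour (each cell has three neighbours carrying
#' the propagative rate), while the symmetry group used for state-space
#' reduction is the square's dihedral group D4 (8 permutations), which keeps
#' the adjacent-doublet and diagonal-doublet configurations distinct.  Cell
#' order: 1 = (0,0), 2 = (1,0), 3 = (1,1), 4 = (0,1) (scaled by the cell
#' diameter).
#'
#' @param cell_diameter cell diameter (um), default 21
#' @return a list with elements \code{graph} (a [contact_graph()]) and
#'   \code{tissue} (a [tissue()])
#' @export
construct_2x2 <- function(cell_diameter = 21) {
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(1, 3), c(2, 4))
  rot <- c(2, 3, 4, 1)                 # quarter turn
  refl <- c(2, 1, 4, 3)                # mirror
  d4 <- list(rot, rot[rot], rot[rot[rot]], refl,
             refl[rot], refl[rot[rot]], refl[rot[rot[rot]]])
  graph <- contact_graph(4, edges, symmetry = d4)
  pos <- cell_diameter * cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  tis <- tissue(pos, radius = cell_diameter / 2,
                meta = list(kind = "square_2x2", cell_diameter = cell_diameter))
  tis$graph <- graph
  list(graph = graph, tissue = tis)
}

#' Read / write edge-list files
#'
#' Plain-text graph exchange: two integer ids per line, 0-based on disk.
#'
#' @param path file path
#' @param n number of cells (needed on read when isolated cells exist)
#' @return \code{read_edges()} returns a [contact_graph()]
#' @export
read_edges <- function(path, n = NULL) {
  m <- as.matrix(utils::read.table(path, col.names = c("a", "b")))
  m <- m + 1L
  if (is.null(n)) n <- max(m)
  contact_graph(n, m)
}

#' @param graph a [contact_graph()]
#' @rdname read_edges
#' @export
write_edges <- function(graph, path) {
  utils::write.table(graph$edges - 1L, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
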