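#' Mechanics parameters for center-based cell interactions
#'
#' Defaults follow the standard center-based framework: adhesion strength
#' 30 pN, repulsion strength 750 pN, relative maximum adhesion distance 1.25
#' (times the sum of radii; an absolute-distance mode in um is available for
#' sensitivity analysis), mechanics step 0.001 s and an ice expansion factor
#' of 1.09 on the water remaining at the moment of freezing.
#'
#' @param c_adh adhesion strength (pN)
#' @param c_rep repulsion strength (pN)
#' @param adh_reach maximum adhesion distance: relative factor on
#'   (r_i + r_j) in "relative" mode, absolute um in "absolute" mode
#' @param adh_mode "relative" or "absolute"
#' @param dt_mech mechanics time step (s)
#' @param drag translational drag coefficient (pN s / um); forces in pN then
#'   map to velocities in um/s
#' @param expansion water-to-ice volume expansion factor
#' @param frozen_motion "free" (frozen cells remain mobile rigid spheres) or
#'   "pinned" (frozen cells do not translate)
#' @return an object of class \code{mech_params}
#' @export
mech_params <- function(c_adh = 30, c_rep = 750, adh_reach = 1.25,
                        adh_mode = c("relative", "absolute"),
                        dt_mech = 0.001, drag = 1, expansion = 1.09,
                        frozen_motion = c("free", "pinned")) {
  adh_mode <- match.arg(adh_mode)
  frozen_motion <- match.arg(frozen_motion)
  stopifnot(c_adh > 0, c_rep > 0, adh_reach > 0, dt_mech > 0, drag > 0,
            expansion > 0)
  if (adh_mode == "relative" && adh_reach < 1)
    stop("relative adhesion reach must be >= 1")
  structure(list(c_adh = c_adh, c_rep = c_rep, adh_reach = adh_reach,
                 adh_mode = adh_mode, dt_mech = dt_mech, drag = drag,
                 expansion = expansion, frozen_motion = frozen_motion),
            class = "mech_params")
}

reach_distance <- function(ri, rj, params) {
  if (params$adh_mode == "relative") params$adh_reach * (ri + rj)
  else params$adh_reach
}

#' Frozen cell volume after water-to-ice expansion
#'
#' At the moment of freezing the remaining intracellular water turns
#' entirely into ice: the frozen volume is solids plus expansion times the
#' water at freeze, (V - V_w) + expansion * V_w, and is fixed thereafter.
#'
#' @param V cell volume at freeze (um^3)
#' @param V_w water volume at freeze (um^3), 0 <= V_w <= V
#' @param expansion expansion factor (default 1.09)
#' @return frozen volume (um^3)
#' @export
freeze_expand <- function(V, V_w, expansion = 1.09) {
  if (any(V_w < 0) || any(V_w > V))
    stop("invalid state: water volume must lie in [0, V]")
  (V - V_w) + expansion * V_w
}

#' Pairwise center-based force
#'
#' Quadratic-ramp potentials: for centre distance d and membrane span
#' s = r_i + r_j, the repulsion magnitude is c_rep (1 - d/s)^2 for d < s and
#' the adhesion magnitude c_adh (1 - d/reach)^2 for d < reach, with
#' reach the maximum adhesion distance.  The net force on cell i acts along
#' the centre line (repulsion positive away from j), is zero at or beyond
#' reach, and is antisymmetric between the pair.
#'
#' @param xi,xj centre positions of cells i and j (numeric length-3, um)
#' @param ri,rj radii (um)
#' @param params a [mech_params()]
#' @return force vector on cell i (pN)
#' @export
pair_force <- function(xi, xj, ri, rj, params) {
  dvec <- xi - xj
  d <- sqrt(sum(dvec^2))
  if (d == 0) {
    warning("coincident cell centres; repelling along fallback axis")
    dvec <- c(1, 0, 0)
    d <- .Machine$double.eps
  }
  s <- ri + rj
  reach <- reach_distance(ri, rj, params)
  if (d >= reach) return(c(0, 0, 0))
  mag <- -params$c_adh * (1 - d / reach)^2
  if (d < s) mag <- mag + params$c_rep * (1 - d / s)^2
  mag * dvec / d
}

#' Net forces on all cells
#'
#' Vectorised accumulation of [pair_force()] over all interacting pairs.
#'
#' @param pos n x 3 matrix of centre positions (um)
#' @param radii cell radii (um)
#' @param params a [mech_params()]
#' @return n x 3 matrix of net forces (pN)
#' @export
net_forces <- function(pos, radii, params) {
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  if (n < 2) return(F)
  D <- as.matrix(stats::dist(pos))
  rsum <- outer(radii, radii, `+`)
  reach <- if (params$adh_mode == "relative") params$adh_reach * rsum
           else matrix(params$adh_reach, n, n)
  act <- D < reach
  diag(act) <- FALSE
  mag <- matrix(0, n, n)
  mag[act] <- -params$c_adh * (1 - D[act] / reach[act])^2
  ov <- act & (D < rsum)
  mag[ov] <- mag[ov] + params$c_rep * (1 - D[ov] / rsum[ov])^2
  Dsafe <- D
  Dsafe[Dsafe == 0] <- 1
  w <- mag / Dsafe
  for (a in 1:3) {
    diffs <- outer(pos[, a], pos[, a], `-`)   # x_i - x_j
    F[, a] <- rowSums(w * diffs)
  }
  F
}

#' One overdamped position update
#'
#' velocity = net force / drag; position += velocity * dt.  Frozen cells
#' participate in forces identically (solid but interacting); in "pinned"
#' mode their positions are held fixed.
#'
#' @param pos n x 3 matrix of positions (um)
#' @param radii cell radii (um)
#' @param params a [mech_params()]
#' @param frozen logical per-cell frozen flags (used by pinned mode)
#' @return list with updated \code{pos}, \code{vel} (um/s) and
#'   \code{max_disp} (um); a displacement above half the smallest radius
#'   raises a stability error
#' @export
step_positions <- function(pos, radii, params, frozen = NULL) {
  F <- net_forces(pos, radii, params)
  vel <- F / params$drag
  if (!is.null(frozen) && params$frozen_motion == "pinned") vel[frozen, ] <- 0
  disp <- vel * params$dt_mech
  md <- sqrt(max(rowSums(disp^2)))
  if (md > 0.5 * min(radii))
    stop(sprintf("mechanics instability: displacement %.3g um per step; reduce dt_mech", md))
  list(pos = pos + disp, vel = vel, max_disp = md)
}

#' Detect severed adhesive contacts (fissures)
#'
#' A pair from the attachment set is severed when its centre distance
#' exceeds the maximum adhesion distance.  Reports severed pairs, per-cell
#' lost-contact counts and the connected components of the surviving
#' attachment graph; idempotent on repeated calls for a static
#' configuration.
#'
#' @param pos n x 3 matrix of positions (um)
#' @param radii cell radii (um)
#' @param attachments two-column matrix of attached pairs (typically the
#'   initial contact-graph edges)
#' @param params a [mech_params()]
#' @return list of class \code{fissure_report}: \code{severed} (matrix),
#'   \code{lost_contacts} (per-cell counts), \code{surviving} (matrix),
#'   \code{components} (membership vector)
#' @export
detect_detachment <- function(pos, radii, attachments, params) {
  n <- nrow(pos)
  attachments <- matrix(as.integer(attachments), ncol = 2)
  if (nrow(attachments) == 0) {
    return(structure(list(severed = attachments, lost_contacts = integer(n),
                          surviving = attachments,
                          components = seq_len(n)),
                     class = "fissure_report"))
  }
  d <- sqrt(rowSums((pos[attachments[, 1], , drop = FALSE] -
                     pos[attachments[, 2], , drop = FALSE])^2))
  reach <- mapply(function(i, j) reach_distance(radii[i], radii[j], params),
                  attachments[, 1], attachments[, 2])
  cut <- d > reach
  severed <- attachments[cut, , drop = FALSE]
  surviving <- attachments[!cut, , drop = FALSE]
  lost <- tabulate(as.vector(severed), nbins = n)
  # connected components of the surviving attachment graph
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(surviving))) {
      a <- comp[surviving[i, 1]]; b <- comp[surviving[i, 2]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  structure(list(severed = severed, lost_contacts = lost,
                 surviving = surviving,
                 components = match(comp, sort(unique(comp)))),
            class = "fissure_report")
}

#' @export
print.fissure_report <- function(x, ...) {
  cat(sprintf("Fissure report: %d severed pair(s), %d component(s)\n",
              nrow(x$severed), max(x$components)))
  invisible(x)
}

#' Radius of a sphere of given volume
#' @param V volume (um^3)
#' @return radius (um)
#' @export
radius_from_volume <- function(V) (3 * V / (4 * pi))^(1 / 3)
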