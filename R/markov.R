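#' Enumerate symmetry-reduced state classes
#'
#' The raw state space of the ice-propagation Markov chain on N cells is the
#' 2^N frozen-cell subsets.  This partitions the subsets into orbits under
#' the graph's symmetry group; by construction of the per-cell rates
#' (1 + k alpha with k the frozen-neighbour count) the chain is exactly
#' lumpable on these orbits.  Classes are ordered by number of frozen cells,
#' then by canonical (minimal) bitmask representative.
#'
#' @param graph a [contact_graph()] with its symmetry group attached
#' @return a list of class \code{state_classes}; each element has
#'   \code{rep} (integer ids of frozen cells in the representative),
#'   \code{mask} (canonical bitmask), \code{size} (orbit size) and
#'   \code{n_frozen}
#' @export
enumerate_reduced_states <- function(graph) {
  n <- graph$n
  if (n > 20) stop("full state enumeration is limited to n <= 20 cells")
  n_states <- bitwShiftL(1L, n)
  perms <- graph$symmetry
  bit <- bitwShiftL(1L, 0:(n - 1))
  apply_perm <- function(mask, p) {
    # image of the frozen set under p
    frozen <- which(bitwAnd(mask, bit) != 0L)
    sum(bit[p[frozen]])
  }
  orbit_of <- rep(NA_integer_, n_states)
  classes <- list()
  for (mask in 0:(n_states - 1L)) {
    if (!is.na(orbit_of[mask + 1L])) next
    imgs <- unique(vapply(perms, function(p) apply_perm(mask, p), numeric(1)))
    canon <- min(imgs)
    id <- length(classes) + 1L
    orbit_of[imgs + 1L] <- id
    classes[[id]] <- list(rep = which(bitwAnd(canon, bit) != 0L),
                          mask = canon, size = length(imgs),
                          n_frozen = sum(bitwAnd(canon, bit) != 0L))
  }
  ord <- order(vapply(classes, `[[`, 0, "n_frozen"),
               vapply(classes, `[[`, 0, "mask"))
  classes <- classes[ord]
  attr(classes, "orbit_of") <- match(orbit_of, ord)
  attr(classes, "n") <- n
  class(classes) <- "state_classes"
  classes
}

#' @export
print.state_classes <- function(x, ...) {
  cat(sprintf("%d state classes on %d cells (%d raw states)\n",
              length(x), attr(x, "n"), bitwShiftL(1L, attr(x, "n"))))
  for (i in seq_along(x))
    cat(sprintf("  class %d: %d frozen {%s}, orbit size %d\n", i,
                x[[i]]$n_frozen, paste(x[[i]]$rep, collapse = ","),
                x[[i]]$size))
  invisible(x)
}

#' Map frozen-cell subsets to their state class
#'
#' @param classes classes from [enumerate_reduced_states()]
#' @param masks integer bitmask(s) of frozen subsets (bit i-1 = cell i)
#' @return integer class indices
#' @export
class_of_mask <- function(classes, masks) {
  attr(classes, "orbit_of")[masks + 1L]
}

#' Build the symmetry-reduced non-dimensional generator
#'
#' Off-diagonal entry Q[S, S'] aggregates, over all one-cell freezing events
#' leading from the representative of class S into class S', the per-cell
#' rate 1 + k alpha, where k is the cell's frozen-neighbour count in S.
#' Diagonal entries make row sums zero; the all-frozen class is absorbing.
#'
#' @param graph a [contact_graph()]
#' @param classes classes from [enumerate_reduced_states()]
#' @param alpha nonnegative propagation-to-nucleation rate ratio
#' @return dense generator matrix (classes x classes), rates per unit tau
#' @export
build_generator <- function(graph, classes, alpha) {
  if (alpha < 0) stop("alpha must be nonnegative")
  n <- graph$n
  adj <- adjacency_list(graph)
  m <- length(classes)
  Q <- matrix(0, m, m)
  bit <- bitwShiftL(1L, 0:(n - 1))
  for (ci in seq_len(m)) {
    S <- classes[[ci]]$rep
    mask <- classes[[ci]]$mask
    for (j in setdiff(seq_len(n), S)) {
      k <- sum(adj[[j]] %in% S)
      target <- class_of_mask(classes, mask + bit[j])
      Q[ci, target] <- Q[ci, target] + 1 + k * alpha
    }
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Assemble a reduced Markov system
#'
#' @param graph a [contact_graph()]
#' @param alpha propagation ratio
#' @param frozen0 integer ids of pre-frozen seed cells (initial state)
#' @return object of class \code{markov_system} with elements
#'   \code{classes}, \code{Q}, \code{P0}, \code{alpha}
#' @export
markov_system <- function(graph, alpha, frozen0 = integer(0)) {
  classes <- enumerate_reduced_states(graph)
  Q <- build_generator(graph, classes, alpha)
  bit <- bitwShiftL(1L, 0:(graph$n - 1))
  m0 <- sum(bit[frozen0])
  P0 <- numeric(length(classes))
  P0[class_of_mask(classes, m0)] <- 1
  structure(list(classes = classes, Q = Q, P0 = P0, alpha = alpha,
                 n = graph$n),
            class = "markov_system")
}

#' @export
print.markov_system <- function(x, ...) {
  cat(sprintf("Markov system: %d cells, %d classes, alpha = %g\n",
              x$n, length(x$classes), x$alpha))
  invisible(x)
}

#' Solve the master equation on a tau grid
#'
#' Solves dP/dtau = P Q from P0 by the matrix exponential of the reduced
#' generator (exact up to machine precision for these small systems).
#'
#' @param system a [markov_system()]
#' @param tau_grid increasing nonnegative tau values
#' @return matrix (length(tau_grid) x classes) of state-class probabilities,
#'   with the grid attached as attribute \code{tau}
#' @export
solve_master_equation <- function(system, tau_grid) {
  if (any(diff(tau_grid) <= 0) || any(tau_grid < 0))
    stop("tau_grid must be nonnegative and increasing")
  Q <- system$Q
  m <- ncol(Q)
  P <- matrix(NA_real_, length(tau_grid), m)
  # step with expm over grid increments: expm(Q (t1+t2)) = expm(Q t1) expm(Q t2)
  p <- system$P0
  prev <- 0
  for (i in seq_along(tau_grid)) {
    dt <- tau_grid[i] - prev
    if (dt > 0) {
      E <- as.matrix(Matrix::expm(Q * dt))
      p <- as.numeric(p %*% E)
    }
    P[i, ] <- p
    prev <- tau_grid[i]
  }
  if (any(abs(rowSums(P) - 1) > 1e-9))
    stop("master-equation solution lost probability mass")
  colnames(P) <- paste0("class", seq_len(m))
  attr(P, "tau") <- tau_grid
  P
}
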