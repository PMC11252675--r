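#' Monte Carlo configuration
#'
#' @param alpha propagation-to-nucleation rate ratio (>= 0)
#' @param epsilon probability bound per fixed step, in (0, 0.1]
#' @param n_max maximum neighbour count entering the step-size rule; when
#'   NULL it is taken as the maximum degree of the supplied contact graph
#' @param tau_max simulation horizon in non-dimensional time (> 0)
#' @param replicates number of independent replicates (>= 1)
#' @param rng_seed integer seed; identical seed and configuration give
#'   bit-identical event logs
#' @param method "gillespie" (event-driven, exact) or "fixed_step"
#'   (synchronous discretised steps)
#' @return an object of class \code{mc_config}
#' @export
mc_config <- function(alpha, epsilon = 0.05, n_max = NULL, tau_max = 1,
                      replicates = 1, rng_seed = 1,
                      method = c("gillespie", "fixed_step")) {
  method <- match.arg(method)
  if (alpha < 0) stop("alpha must be nonnegative")
  if (epsilon <= 0 || epsilon > 0.1) stop("epsilon must lie in (0, 0.1]")
  if (tau_max <= 0) stop("tau_max must be positive")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(alpha = alpha, epsilon = epsilon, n_max = n_max,
                 tau_max = tau_max, replicates = as.integer(replicates),
                 rng_seed = as.integer(rng_seed), method = method),
            class = "mc_config")
}

#' Fixed time-step size in non-dimensional time
#'
#' Delta tau = epsilon / ((1 + n alpha) N), the step small enough that the
#' per-tissue probability of an ice event per step is bounded by epsilon.
#'
#' @param config an [mc_config()]
#' @param N number of cells
#' @param n maximum neighbour count; defaults to \code{config$n_max}
#' @return step size in tau
#' @export
compute_dtau <- function(config, N, n = config$n_max) {
  stopifnot(N >= 1)
  if (is.null(n)) stop("n (maximum neighbour count) is required")
  config$epsilon / ((1 + n * config$alpha) * N)
}

#' Per-step freezing probability of one cell
#'
#' p = (1 + k alpha) dtau for an unfrozen cell with k frozen neighbours,
#' clamped to [0, 1].  A result at or above 1 before clamping signals a
#' step-size violation.
#'
#' @param k_frozen_neighbours frozen-neighbour count
#' @param alpha propagation ratio
#' @param dtau step size
#' @return probability in [0, 1]
#' @export
step_probability <- function(k_frozen_neighbours, alpha, dtau) {
  p <- (1 + k_frozen_neighbours * alpha) * dtau
  if (any(p >= 1 & dtau > 0))
    stop("step-size violation: (1 + k alpha) dtau >= 1; reduce epsilon")
  pmin(pmax(p, 0), 1)
}

resolve_graph <- function(x) {
  if (inherits(x, "contact_graph")) return(list(graph = x, frozen0 = NULL))
  if (inherits(x, "tissue")) {
    if (is.null(x$graph)) stop("tissue has no contact graph; call set_neighbours()")
    return(list(graph = x$graph, frozen0 = which(x$cells$frozen)))
  }
  stop("expected a tissue or contact_graph")
}

#' Fixed-step Monte Carlo simulation of ice formation and propagation
#'
#' Synchronous discretised sampling: at each step of size dtau every
#' unfrozen cell independently freezes with probability
#' (1 + k alpha) dtau, where k is its frozen-neighbour count at the start of
#' the step (multiple freezes per step are allowed but do not cascade within
#' a step).  Frozen is absorbing.  All replicates are advanced together from
#' a single RNG stream seeded by \code{rng_seed}.
#'
#' @param x a [tissue()] with contact graph (pre-frozen cells taken from its
#'   frozen flags) or a [contact_graph()]
#' @param config an [mc_config()]
#' @param frozen0 integer ids of pre-frozen seed cells (overrides tissue flags)
#' @return a \code{freeze_log}: data.frame (replicate, cell, tau) of freeze
#'   events ordered by replicate then tau, with attributes \code{frozen0},
#'   \code{n_cells}, \code{config}
#' @export
run_fixed_step <- function(x, config, frozen0 = NULL) {
  rg <- resolve_graph(x)
  graph <- rg$graph
  if (is.null(frozen0)) frozen0 <- rg$frozen0
  frozen0 <- as.integer(frozen0)
  N <- graph$n
  n_max <- if (is.null(config$n_max)) max(graph_degrees(graph), 0) else config$n_max
  dtau <- compute_dtau(config, N, n_max)
  n_steps <- ceiling(config$tau_max / dtau)
  R <- config$replicates
  adj <- matrix(0, N, N)
  if (nrow(graph$edges)) {
    adj[graph$edges] <- 1
    adj[graph$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  frozen <- matrix(FALSE, R, N)
  frozen[, frozen0] <- TRUE
  tfreeze <- matrix(NA_real_, R, N)
  tfreeze[, frozen0] <- 0
  set.seed(config$rng_seed)
  for (s in seq_len(n_steps)) {
    if (all(frozen)) break
    k <- frozen %*% adj                       # frozen-neighbour counts
    p <- step_probability(k, config$alpha, dtau)
    hit <- matrix(stats::runif(R * N), R, N) < p & !frozen
    if (any(hit)) {
      tfreeze[hit] <- s * dtau
      frozen <- frozen | hit
    }
  }
  finalize_log(tfreeze, frozen0, N, config)
}

#' Gillespie (event-driven) simulation of ice formation and propagation
#'
#' Exact sampling of the continuous-time chain: with aggregate rate
#' Lambda = sum over unfrozen cells of (1 + k alpha), waiting times are
#' Exponential(Lambda) and the freezing cell is chosen with probability
#' proportional to its rate.  Each replicate runs on its own RNG stream
#' derived from (rng_seed, replicate), so results do not depend on the order
#' in which replicates are executed.
#'
#' @inheritParams run_fixed_step
#' @return a \code{freeze_log}, as for [run_fixed_step()]
#' @export
run_gillespie <- function(x, config, frozen0 = NULL) {
  rg <- resolve_graph(x)
  graph <- rg$graph
  if (is.null(frozen0)) frozen0 <- rg$frozen0
  frozen0 <- as.integer(frozen0)
  N <- graph$n
  adj <- adjacency_list(graph)
  R <- config$replicates
  alpha <- config$alpha
  tfreeze <- matrix(NA_real_, R, N)
  for (rep in seq_len(R)) {
    set.seed((config$rng_seed * 1000003L + rep) %% .Machine$integer.max)
    frozen <- rep(FALSE, N)
    frozen[frozen0] <- TRUE
    tfreeze[rep, frozen0] <- 0
    k <- integer(N)
    for (f in frozen0) for (v in adj[[f]]) k[v] <- k[v] + 1L
    rate <- ifelse(frozen, 0, 1 + k * alpha)
    Lambda <- sum(rate)
    tau <- 0
    while (Lambda > 0) {
      tau <- tau + stats::rexp(1, Lambda)
      if (tau > config$tau_max) break
      j <- sample.int(N, 1, prob = rate)
      frozen[j] <- TRUE
      tfreeze[rep, j] <- tau
      Lambda <- Lambda - rate[j]
      rate[j] <- 0
      for (v in adj[[j]]) if (!frozen[v]) {
        rate[v] <- rate[v] + alpha
        Lambda <- Lambda + alpha
      }
    }
  }
  finalize_log(tfreeze, frozen0, N, config)
}

finalize_log <- function(tfreeze, frozen0, N, config) {
  R <- nrow(tfreeze)
  logs <- do.call(rbind, lapply(seq_len(R), function(r) {
    cells <- setdiff(which(!is.na(tfreeze[r, ])), frozen0)
    if (!length(cells)) return(NULL)
    o <- order(tfreeze[r, cells], cells)
    data.frame(replicate = r, cell = cells[o], tau = tfreeze[r, cells[o]])
  }))
  if (is.null(logs))
    logs <- data.frame(replicate = integer(0), cell = integer(0),
                       tau = numeric(0))
  attr(logs, "frozen0") <- frozen0
  attr(logs, "n_cells") <- N
  attr(logs, "replicates") <- R
  attr(logs, "config") <- config
  class(logs) <- c("freeze_log", "data.frame")
  logs
}

#' Run the configured Monte Carlo method
#' @inheritParams run_fixed_step
#' @return a \code{freeze_log}
#' @export
run_montecarlo <- function(x, config, frozen0 = NULL) {
  if (config$method == "gillespie") run_gillespie(x, config, frozen0)
  else run_fixed_step(x, config, frozen0)
}

#' Per-cell freeze-probability map from an ensemble of replicates
#'
#' For every cell and tau-grid point, the fraction of replicates in which
#' the cell is frozen, with binomial standard errors.
#'
#' @param logs a \code{freeze_log}
#' @param tau_grid nondecreasing tau values
#' @return a list of class \code{freeze_map} with matrices \code{p} and
#'   \code{stderr} (grid x cells) and the grid
#' @export
aggregate_freeze_map <- function(logs, tau_grid) {
  N <- attr(logs, "n_cells")
  R <- attr(logs, "replicates")
  frozen0 <- attr(logs, "frozen0")
  counts <- matrix(0, length(tau_grid), N)
  for (i in seq_len(nrow(logs)))
    counts[, logs$cell[i]] <- counts[, logs$cell[i]] +
      (tau_grid >= logs$tau[i])
  counts[, frozen0] <- R
  p <- counts / R
  structure(list(p = p, stderr = sqrt(p * (1 - p) / R), tau = tau_grid,
                 replicates = R), class = "freeze_map")
}

#' Empirical state-class probabilities from an ensemble of replicates
#'
#' Maps each replicate's frozen subset at every tau-grid point to its
#' symmetry-reduced state class and reports the class frequencies; directly
#' comparable with [solve_master_equation()] output.
#'
#' @param logs a \code{freeze_log}
#' @param classes classes from [enumerate_reduced_states()]
#' @param tau_grid nondecreasing tau values
#' @return matrix (grid x classes) of empirical probabilities with attribute
#'   \code{stderr}
#' @export
aggregate_state_classes <- function(logs, classes, tau_grid) {
  N <- attr(logs, "n_cells")
  R <- attr(logs, "replicates")
  frozen0 <- attr(logs, "frozen0")
  bit <- bitwShiftL(1L, 0:(N - 1))
  base_mask <- sum(bit[frozen0])
  counts <- matrix(0, length(tau_grid), length(classes))
  bylog <- split(logs[, c("cell", "tau")], logs$replicate)
  empty <- !(as.character(seq_len(R)) %in% names(bylog))
  for (r in seq_len(R)) {
    key <- as.character(r)
    if (is.na(match(key, names(bylog)))) {
      cls <- class_of_mask(classes, base_mask)
      counts[, cls] <- counts[, cls] + 1
      next
    }
    ev <- bylog[[key]]
    # frozen mask as a step function of tau
    masks <- base_mask + cumsum(bit[ev$cell])
    idx <- findInterval(tau_grid, ev$tau)
    m <- ifelse(idx == 0, base_mask, masks[pmax(idx, 1)])
    cls <- class_of_mask(classes, m)
    for (i in seq_along(tau_grid))
      counts[i, cls[i]] <- counts[i, cls[i]] + 1
  }
  p <- counts / R
  attr(p, "stderr") <- sqrt(p * (1 - p) / R)
  attr(p, "tau") <- tau_grid
  colnames(p) <- paste0("class", seq_along(classes))
  p
}

#' Probability that the whole construct is frozen, per tau-grid point
#'
#' @param logs a \code{freeze_log}
#' @param tau_grid nondecreasing tau values
#' @return list with \code{p} and binomial \code{stderr} vectors
#' @export
all_frozen_curve <- function(logs, tau_grid) {
  N <- attr(logs, "n_cells")
  R <- attr(logs, "replicates")
  n0 <- length(attr(logs, "frozen0"))
  tall <- vapply(split(logs$tau, logs$replicate), function(tt)
    if (length(tt) == N - n0) max(tt) else Inf, numeric(1))
  tall <- c(tall, rep(if (N - n0 == 0) 0 else Inf,
                      R - length(tall)))
  p <- vapply(tau_grid, function(g) mean(tall <= g), numeric(1))
  list(p = p, stderr = sqrt(p * (1 - p) / R), tau = tau_grid)
}

#' Export a freeze log as a delimited table
#'
#' Columns: replicate, cell_id (0-based), tau, t, T.  The dimensional time
#' and temperature columns are filled through a [tau_map()] when supplied
#' and are NA in pure-tau runs.
#'
#' @param logs a \code{freeze_log}
#' @param path output path
#' @param map optional [tau_map()]
#' @export
write_freeze_log <- function(logs, path, map = NULL) {
  out <- data.frame(replicate = logs$replicate, cell_id = logs$cell - 1L,
                    tau = logs$tau,
                    t = if (is.null(map)) NA else map$t_of_tau(logs$tau),
                    T = if (is.null(map)) NA else map$T_of_tau(logs$tau))
  utils::write.table(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
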