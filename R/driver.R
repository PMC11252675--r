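#' Configuration of a full freezing experiment
#'
#' Bundles the tissue construct, cell parameters, cooling protocol, Monte
#' Carlo settings and mechanics parameters, together with the set of stages
#' to run.  The tissue must carry a contact graph (see [set_neighbours()]).
#'
#' @param tissue a [tissue()] with contact graph attached
#' @param params a [cell_params()]
#' @param protocol a [cooling_protocol()]
#' @param mc an [mc_config()]; its \code{tau_max} is replaced by the horizon
#'   tau(T_end) derived from the dehydration trajectory
#' @param mech a [mech_params()]
#' @param stages character subset of c("propagation", "mechanics");
#'   mechanics implies propagation
#' @param mech_replicate which replicate's freeze schedule drives the
#'   mechanics replay
#' @param snapshots approximate number of mechanics snapshots to keep
#' @return an object of class \code{experiment_config}
#' @export
experiment_config <- function(tissue, params = rat_hepatocyte(), protocol,
                              mc, mech = mech_params(),
                              stages = c("propagation"),
                              mech_replicate = 1, snapshots = 50) {
  if (length(stages) == 0) stop("stage set must be non-empty")
  if (!all(stages %in% c("propagation", "mechanics")))
    stop("stages must be a subset of {propagation, mechanics}")
  if (is.null(tissue$graph))
    stop("tissue has no contact graph; call set_neighbours()")
  structure(list(tissue = tissue, params = params, protocol = protocol,
                 mc = mc, mech = mech, stages = unique(stages),
                 mech_replicate = mech_replicate, snapshots = snapshots),
            class = "experiment_config")
}

#' Run a full freezing experiment
#'
#' Orchestrates the pipeline: (1) integrate the shared dehydration
#' trajectory for the protocol (all cells identical, no thermal gradients);
#' (2) build the invertible tau(t) map; (3) sample stochastic freeze times
#' on the contact graph up to tau(T_end); (4) match freeze events onto the
#' dimensional time grid; (5) when the mechanics stage is requested, replay
#' one replicate in dimensional time - each cell's volume follows the
#' dehydration trajectory until its freeze time, then the remaining water
#' expands into ice and the volume is fixed - stepping the center-based
#' mechanics at dt_mech throughout and reporting detached contacts.
#'
#' @param config an [experiment_config()]
#' @return an object of class \code{sim_result} with elements
#'   \code{dehydration}, \code{map}, \code{logs}, \code{freeze_map},
#'   \code{schedule}, \code{mechanics} (NULL unless run), \code{fissures}
#'   (NULL unless run) and \code{provenance}
#' @export
run_experiment <- function(config) {
  traj <- integrate_dehydration(config$params, config$protocol)
  map <- tau_map(traj)
  mc <- config$mc
  mc$tau_max <- map$tau_end
  logs <- run_montecarlo(config$tissue, mc)
  tau_grid <- seq(0, map$tau_end, length.out = 101)
  fmap <- aggregate_freeze_map(logs, tau_grid)
  schedule <- freeze_time_matching(logs, traj, dt = config$mech$dt_mech)
  mechanics <- NULL
  fissures <- NULL
  if ("mechanics" %in% config$stages) {
    mechanics <- replay_mechanics(config, traj, schedule)
    fissures <- mechanics$fissures
    mechanics$fissures <- NULL
  }
  structure(list(dehydration = traj, map = map, logs = logs,
                 freeze_map = fmap, schedule = schedule,
                 mechanics = mechanics, fissures = fissures,
                 provenance = list(seed = mc$rng_seed, config = config,
                                   package_version =
                                     as.character(utils::packageVersion("iceprop")))),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Freezing experiment result\n")
  print(attr(x$logs, "config"))
  cat(sprintf("  %d freeze events over %d replicate(s); tau horizon %.4g\n",
              nrow(x$logs), attr(x$logs, "replicates"), x$map$tau_end))
  if (!is.null(x$fissures)) print(x$fissures)
  invisible(x)
}

#' @export
print.mc_config <- function(x, ...) {
  cat(sprintf("  MC: method %s, alpha %g, eps %g, tau_max %g, %d replicate(s), seed %d\n",
              x$method, x$alpha, x$epsilon, x$tau_max, x$replicates,
              x$rng_seed))
  invisible(x)
}

#' Match non-dimensional freeze times onto the dimensional time grid
#'
#' Each stochastic freeze time tau_j is assigned the first point of the
#' uniform time grid (step dt) at which the cumulative tau(t) reaches it.
#' Events beyond tau(T_end) cannot occur within the protocol and are
#' reported with NA time and flagged.
#'
#' @param logs a \code{freeze_log} (or numeric vector of tau values)
#' @param traj a dehydration trajectory from [integrate_dehydration()]
#' @param dt time-grid step (s)
#' @return data.frame (replicate, cell, tau, t, T, scheduled)
#' @export
freeze_time_matching <- function(logs, traj, dt = 0.001) {
  if (is.numeric(logs))
    logs <- data.frame(replicate = 1L, cell = seq_along(logs), tau = logs)
  if (any(diff(traj$tau) < 0)) stop("tau map must be nondecreasing")
  t_end <- traj$t[nrow(traj)]
  tgrid <- seq(0, t_end, by = dt)
  tau_at <- stats::approx(traj$t, traj$tau, xout = tgrid, rule = 2)$y
  idx <- findInterval(logs$tau, tau_at, left.open = TRUE) + 1L
  scheduled <- idx <= length(tgrid)
  t <- ifelse(scheduled, tgrid[pmin(idx, length(tgrid))], NA_real_)
  Tmp <- attr(traj, "protocol")$T0 - (attr(traj, "protocol")$B / 60) * t
  data.frame(replicate = logs$replicate, cell = logs$cell, tau = logs$tau,
             t = t, T = Tmp, scheduled = scheduled)
}

replay_mechanics <- function(config, traj, schedule) {
  tis <- config$tissue
  mech <- config$mech
  pos <- positions(tis)
  n <- nrow(pos)
  sched <- schedule[schedule$replicate == config$mech_replicate &
                      schedule$scheduled, ]
  frozen <- tis$cells$frozen
  t_end <- traj$t[nrow(traj)]
  dt <- mech$dt_mech
  n_steps <- ceiling(t_end / dt)
  Vt <- stats::approxfun(traj$t, traj$V, rule = 2)
  Vwt <- stats::approxfun(traj$t, traj$V_w, rule = 2)
  vol <- rep(Vt(0), n)
  vol[frozen] <- freeze_expand(Vt(0), Vwt(0), mech$expansion)
  radii <- radius_from_volume(vol)
  keep <- max(1L, floor(n_steps / config$snapshots))
  snaps <- list()
  attachments <- tis$graph$edges
  ev_t <- sched$t
  ev_cell <- sched$cell
  for (s in seq_len(n_steps)) {
    t_now <- s * dt
    # unfrozen cells follow the shared dehydration trajectory
    vol[!frozen] <- Vt(t_now)
    due <- which(ev_t <= t_now)
    if (length(due)) {
      for (j in ev_cell[due]) {
        if (!frozen[j]) {
          vol[j] <- freeze_expand(Vt(ev_t[match(j, ev_cell)]),
                                  Vwt(ev_t[match(j, ev_cell)]),
                                  mech$expansion)
          frozen[j] <- TRUE
        }
      }
      ev_t <- ev_t[-due]
      ev_cell <- ev_cell[-due]
    }
    radii <- radius_from_volume(vol)
    st <- step_positions(pos, radii, mech, frozen)
    pos <- st$pos
    if (s %% keep == 0 || s == n_steps)
      snaps[[length(snaps) + 1L]] <-
        data.frame(t = t_now, cell = seq_len(n), x = pos[, 1], y = pos[, 2],
                   z = pos[, 3], radius = radii, frozen = frozen)
  }
  fiss <- detect_detachment(pos, radii, attachments, mech)
  list(trajectory = do.call(rbind, snaps), final_pos = pos,
       final_radii = radii, frozen = frozen, fissures = fiss)
}

#' Cumulative single-cell IIF probability along a cooling protocol
#'
#' P_IIF(T) = 1 - exp(-tau(T)), the probability that an isolated cell has
#' nucleated intracellular ice by the time the protocol reaches temperature
#' T; nondecreasing as T falls.
#'
#' @param params a [cell_params()]
#' @param protocol a [cooling_protocol()]
#' @param dT output grid step (K)
#' @return data.frame (t, T, tau, p_iif)
#' @export
single_cell_iif_curve <- function(params, protocol, dT = 0.05) {
  traj <- integrate_dehydration(params, protocol, dT = dT)
  data.frame(t = traj$t, T = traj$T, tau = traj$tau,
             p_iif = 1 - exp(-traj$tau))
}

#' Find the alpha threshold beyond which freezing curves stop changing
#'
#' Runs the event-driven sampler at each alpha of a grid and compares each
#' all-frozen probability curve with the curve at the largest alpha: the
#' threshold is the smallest grid alpha whose curve stays within
#' \code{n_se} pooled binomial standard errors at every tau-grid point.
#'
#' @param x a [tissue()] with graph, or [contact_graph()]
#' @param alphas increasing alpha grid
#' @param replicates Gillespie replicates per alpha
#' @param tau_grid comparison grid (default 51 points on [0, tau_max])
#' @param tau_max horizon
#' @param n_se number of pooled standard errors defining indistinguishable
#' @param rng_seed integer seed
#' @return list with \code{threshold}, per-alpha curves and max deviations
#'   (in pooled standard errors)
#' @export
alpha_threshold <- function(x, alphas = c(10, 50, 100, 200),
                            replicates = 1000, tau_grid = NULL, tau_max = 1,
                            n_se = 3, rng_seed = 1) {
  alphas <- sort(alphas)
  if (is.null(tau_grid)) tau_grid <- seq(0, tau_max, length.out = 51)
  curves <- list()
  for (i in seq_along(alphas)) {
    cfg <- mc_config(alpha = alphas[i], replicates = replicates,
                     tau_max = tau_max, rng_seed = rng_seed + i,
                     method = "gillespie")
    curves[[i]] <- all_frozen_curve(run_gillespie(x, cfg), tau_grid)
  }
  ref <- curves[[length(alphas)]]
  devs <- vapply(seq_along(alphas), function(i) {
    se <- sqrt(curves[[i]]$stderr^2 + ref$stderr^2)
    dif <- abs(curves[[i]]$p - ref$p)
    ok <- se > 0 | dif > 0
    if (!any(ok)) return(0)
    max(dif[ok] / pmax(se[ok], .Machine$double.eps))
  }, numeric(1))
  ok <- devs <= n_se
  list(threshold = alphas[which(ok)[1]], alphas = alphas, curves = curves,
       max_dev_se = devs)
}
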