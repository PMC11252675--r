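#' Read an experiment configuration file
#'
#' Experiment configurations are structured key-value (YAML) files with
#' sections \code{tissue}, \code{params}, \code{protocol}, \code{rule},
#' \code{mc}, \code{mech} and top-level keys \code{stages} and \code{seeds}.
#' The tissue section names a construct kind (\code{square_2x2},
#' \code{disc}, \code{spheroid}, \code{slab}) with its build parameters;
#' \code{seeds} lists pre-frozen cell ids, or one of \code{"centre"} /
#' \code{"corner"}.  Packaged examples live under
#' \code{system.file("extdata", "configs", package = "iceprop")}.
#'
#' @param path path to a YAML configuration file
#' @return an [experiment_config()]
#' @export
read_experiment_config <- function(path) {
  cf <- yaml::read_yaml(path)
  tis <- build_tissue_from_config(cf$tissue)
  rule <- do.call(neighbour_rule, cf$rule)
  tis <- set_neighbours(tis, rule)
  if (!is.null(cf$seeds)) {
    p <- positions(tis)
    ids <- if (identical(cf$seeds, "centre")) {
      which.min(rowSums(p^2))
    } else if (identical(cf$seeds, "corner")) {
      which.min(p %*% c(1, 1, 1))
    } else as.integer(unlist(cf$seeds))
    tis$cells$frozen[ids] <- TRUE
  }
  params <- if (is.null(cf$params)) rat_hepatocyte()
            else do.call(rat_hepatocyte, cf$params)
  protocol <- do.call(cooling_protocol, cf$protocol)
  mc <- do.call(mc_config, cf$mc)
  mech <- if (is.null(cf$mech)) mech_params() else do.call(mech_params, cf$mech)
  stages <- if (is.null(cf$stages)) "propagation" else unlist(cf$stages)
  experiment_config(tissue = tis, params = params, protocol = protocol,
                    mc = mc, mech = mech, stages = stages)
}

build_tissue_from_config <- function(tc) {
  kind <- tc$kind
  tc$kind <- NULL
  switch(kind,
    square_2x2 = do.call(construct_2x2, tc)$tissue,
    disc = do.call(build_disc_monolayer, tc),
    spheroid = do.call(build_spheroid, tc),
    slab = do.call(build_slab, tc),
    stop("unknown tissue kind: ", kind))
}

#' Write the outputs of a simulation result to a directory
#'
#' Writes the dehydration trajectory, freeze log (with dimensional times),
#' per-cell probability map, event schedule, mechanics trajectory and
#' fissure report as delimited text files, plus a provenance block.
#'
#' @param res a \code{sim_result} from [run_experiment()]
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_sim_result <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(res$dehydration),
                     file.path(dir, "dehydration.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_freeze_log(res$logs, file.path(dir, "freeze_log.tsv"), map = res$map)
  fm <- res$freeze_map
  pm <- data.frame(tau = rep(fm$tau, ncol(fm$p)),
                   cell_id = rep(seq_len(ncol(fm$p)) - 1L, each = nrow(fm$p)),
                   p_frozen = as.vector(fm$p),
                   stderr = as.vector(fm$stderr))
  utils::write.table(pm, file.path(dir, "probability_map.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$schedule, file.path(dir, "schedule.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(res$mechanics)) {
    utils::write.table(res$mechanics$trajectory,
                       file.path(dir, "mechanics_trajectory.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    fr <- res$fissures
    writeLines(c(sprintf("severed_pairs\t%d", nrow(fr$severed)),
                 sprintf("components\t%d", max(fr$components)),
                 paste("severed:", paste(apply(fr$severed, 1, paste,
                                               collapse = "-"),
                                         collapse = " "))),
               file.path(dir, "fissures.txt"))
  }
  prov <- res$provenance
  writeLines(c(sprintf("package_version\t%s", prov$package_version),
               sprintf("rng_seed\t%d", prov$seed),
               sprintf("alpha\t%g", prov$config$mc$alpha),
               sprintf("cooling_rate_K_min\t%g", prov$config$protocol$B),
               sprintf("stages\t%s", paste(prov$config$stages,
                                           collapse = ","))),
             file.path(dir, "provenance.txt"))
  invisible(dir)
}
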