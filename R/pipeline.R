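#' Run the full screening pipeline
#'
#' Orchestrates the stages in order -- curves -> growth metrics ->
#' differential screen -> (optional) enrichment -- writing one CSV per
#' stage, each stamped with the configuration hash, and logging record
#' counts at every filter step. The pipeline is a pure function of
#' (inputs, config, seed): rerunning with the same config reproduces
#' identical files.
#'
#' Entry points, in priority order:
#' * `config$curves_csv`: a long curve table (e.g. written by
#'   [as_curve_table()] + [write_pipeline_csv()]).
#' * `config$metrics_csv`: a pre-computed replicate metric table (e.g. a
#'   deposited supplementary table; see [read_supplementary_table()]),
#'   skipping the curve stage.
#' * `config$simulate: yes`: a synthetic experiment generated with
#'   [sim_config()] defaults overridden by any `sim_*` keys.
#'
#' @param config a `run_config` (see [read_run_config()]) or named list
#'   with the same fields; must include `output_dir`.
#' @return invisibly, a list with the `growth_metrics` object (when
#'   computed), the `diff_screen`, the enrichment results (when a GMT was
#'   given) and the paths written.
#' @export
run_pipeline <- function(config) {
  cf <- config
  if (is.null(cf$output_dir)) .gs_stop("config_error", "config lacks output_dir")
  dir.create(cf$output_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("smooth_window", "min_reps", "max_hours", "q_cutoff", "seed", "spatial")) {
    if (is.null(cf[[nm]]))
      cf[[nm]] <- list(smooth_window = 48L, min_reps = 6L, max_hours = 40,
                       q_cutoff = 0.05, seed = 1L, spatial = TRUE)[[nm]]
  }
  paths <- list()
  gm <- NULL

  if (!is.null(cf$curves_csv) || isTRUE(cf$simulate)) {
    if (isTRUE(cf$simulate)) {
      sim_args <- cf[startsWith(names(cf), "sim_")]
      names(sim_args) <- sub("^sim_", "", names(sim_args))
      sim_args$seed <- cf$seed
      sc <- do.call(sim_config, sim_args)
      message("[simulate] ", sc$n_strains, " strains x ", sc$n_replicates,
              " replicates x 2 conditions")
      exper <- simulate_curves(sc)
      gm <- compute_growth_metrics(exper, max_hours = cf$max_hours,
                                   smooth_window = cf$smooth_window,
                                   spatial = cf$spatial)
      paths$labels <- write_pipeline_csv(exper$strains,
                                         file.path(cf$output_dir, "labels.csv"), cf)
    } else {
      message("[curves] reading ", cf$curves_csv)
      curves <- read_pipeline_csv(cf$curves_csv)
      message("[curves] ", nrow(curves), " rows")
      gm <- compute_growth_metrics(curves, max_hours = cf$max_hours,
                                   smooth_window = cf$smooth_window,
                                   spatial = cf$spatial)
    }
    message("[metrics] ", nrow(gm$metrics), " colonies; ",
            sum(gm$metrics$excluded), " excluded (dead/unreferenced)")
    mtab <- gm$metrics[!gm$metrics$excluded, , drop = FALSE]
    paths$metrics <- write_pipeline_csv(mtab, file.path(cf$output_dir, "metrics.csv"), cf)
  } else if (!is.null(cf$metrics_csv)) {
    message("[metrics] reading ", cf$metrics_csv)
    mtab <- if (!is.null(cf$metrics_mapping))
      read_supplementary_table(cf$metrics_csv, mapping = unlist(cf$metrics_mapping))
    else read_pipeline_csv(cf$metrics_csv)
    message("[metrics] ", nrow(mtab), " replicate rows")
  } else {
    .gs_stop("config_error", "config needs curves_csv, metrics_csv or simulate: yes")
  }

  screen <- differential_screen(mtab, q_cutoff = cf$q_cutoff, min_reps = cf$min_reps)
  message("[diffstats] ", screen$n_strains, " strains tested; nominated ",
          length(screen$sets$union), " (union), ",
          paste(vapply(screen$metrics, function(m)
            sprintf("%s: %d", m, length(screen$sets[[m]])), character(1)),
            collapse = ", "))
  paths$diffstats <- write_pipeline_csv(screen$results,
                                        file.path(cf$output_dir, "diffstats.csv"), cf)
  nom_df <- data.frame(strain_id = screen$sets$union,
                       by_lag_v_stall = screen$sets$union %in% screen$sets$lag_v_stall,
                       by_colony_fitness = screen$sets$union %in% screen$sets$colony_fitness)
  paths$nominations <- write_pipeline_csv(nom_df,
                                          file.path(cf$output_dir, "nominations.csv"), cf)

  enr <- NULL
  if (!is.null(cf$gmt)) {
    sets <- read_gmt(cf$gmt)
    universe <- unique(screen$results$strain_id)
    enr <- enrich(screen$sets$union, sets, universe, q_cutoff = cf$q_cutoff)
    message("[enrich] ", nrow(enr), " terms tested; ", sum(enr$significant),
            " significant at q < ", cf$q_cutoff)
    paths$enrichment <- write_pipeline_csv(as.data.frame(enr),
                                           file.path(cf$output_dir, "enrichment.csv"), cf)
  }
  invisible(list(growth_metrics = gm, screen = screen, enrichment = enr,
                 paths = paths))
}
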