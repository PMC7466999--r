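#' Phenotype class parameter sets
#'
#' Default growth parameters for the five simulated colony classes. All
#' classes grow logistically, `I(t) = K / (1 + exp(-r (t - tm)))`, with the
#' reference class saturating well inside the 40-hour analysis window (as
#' colony arrays do before overgrowth):
#'
#' * `reference`: K = 1e5 intensity units, r = 0.008 / min, tm = 1000 min.
#' * `lag`: uniformly slow -- rate halved, midpoint shifted +240 min; grows
#'   below the population for the whole course (negative lagVstall).
#' * `stall`: tracks the reference, then the rate collapses to a fraction
#'   `post_stall_rate_fraction` of itself at `stall_time` (near-plateau;
#'   positive lagVstall).
#' * `uvr_sensitive`: reference growth, but treatment imposes a long pause
#'   (600 min) and a reduced final yield (`uvr_capacity_fraction` 0.6,
#'   the UV-killed cell fraction) -- negative colony-fitness response.
#' * `uvr_resistant_stall`: a stall strain whose post-stall rate fraction
#'   rises under treatment (0.02 -> 0.3): treatment releases the stall,
#'   raising treated colony fitness.
#'
#' Treated colonies pause growth for their class `pause_duration`
#' immediately after the treatment frame. The default is 0 for the
#' non-responder classes -- a strain labeled non-responder must have the
#' same data-generating distribution in both conditions, which is what
#' makes simulator labels usable as statistical ground truth -- and 600 min
#' for `uvr_sensitive`.
#'
#' @return named list of per-class parameter lists.
#' @export
phenotype_specs <- function() {
  base <- list(carrying_capacity = 1e5, max_rate = 0.008, midpoint_time = 1000,
               stall_time = NA_real_, post_stall_rate_fraction = 1,
               treated_post_stall_rate_fraction = 1,
               pause_duration = 0, uvr_capacity_fraction = 1)
  ref <- base
  lag <- base; lag$max_rate <- 0.004; lag$midpoint_time <- 1240
  stall <- base; stall$stall_time <- 1000
  stall$post_stall_rate_fraction <- 0.02
  stall$treated_post_stall_rate_fraction <- 0.02
  sens <- base; sens$pause_duration <- 600; sens$uvr_capacity_fraction <- 0.6
  res <- stall; res$treated_post_stall_rate_fraction <- 0.3
  list(reference = ref, lag = lag, stall = stall,
       uvr_sensitive = sens, uvr_resistant_stall = res)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic experiment. Defaults mirror the
#' screening protocol: 5-minute frames for 48 hours (577 frames), treatment
#' immediately after frame 48 (4 h), 11 replicate plates per condition, and
#' a 16 x 24 plate layout.
#'
#' @param n_strains number of strains (must fit the plate layout).
#' @param n_replicates replicate plates per condition.
#' @param class_probs named class proportions (must sum to 1).
#' @param plate_nrow,plate_ncol grid layout of each plate.
#' @param frame_interval minutes between frames (5).
#' @param total_hours imaging duration.
#' @param treatment_frame treatment applied immediately after this frame.
#' @param gradient_amplitude amplitude of the multiplicative spatial bias
#'   field (0 disables).
#' @param noise_sigma sigma of the per-timepoint multiplicative lognormal
#'   measurement noise.
#' @param strain_tm_sd,strain_logk_sd strain-level biological variation
#'   (midpoint minutes; log carrying capacity).
#' @param rep_tm_sd,rep_logk_sd replicate(colony)-level variation.
#' @param phenotypes per-class parameters; see [phenotype_specs()].
#' @param seed integer seed fixing all randomness end to end.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 384, n_replicates = 11,
                       class_probs = c(reference = 0.83, lag = 0.06, stall = 0.06,
                                       uvr_sensitive = 0.025, uvr_resistant_stall = 0.025),
                       plate_nrow = 16, plate_ncol = 24,
                       frame_interval = 5, total_hours = 48,
                       treatment_frame = 48,
                       gradient_amplitude = 0.10, noise_sigma = 0.05,
                       strain_tm_sd = 30, strain_logk_sd = 0.05,
                       rep_tm_sd = 15, rep_logk_sd = 0.03,
                       phenotypes = phenotype_specs(), seed = 1) {
  if (abs(sum(class_probs) - 1) > 1e-8)
    .gs_stop("config_error", "class proportions must sum to 1")
  if (any(class_probs < 0)) .gs_stop("config_error", "negative class proportion")
  if (!all(names(class_probs) %in% names(phenotypes)))
    .gs_stop("config_error", "class_probs names must match phenotype classes")
  if (n_strains > plate_nrow * plate_ncol)
    .gs_stop("config_error", "n_strains (%d) exceeds plate layout %d x %d",
             n_strains, plate_nrow, plate_ncol)
  structure(as.list(environment()), class = "sim_config")
}

# Piecewise logistic trajectory with growth pauses and a rate collapse.
# Closed form within each constant-rate segment:
#   I(t) = K / (1 + (K/I_a - 1) exp(-r_seg (t - a)))
.sim_colony_curve <- function(times, K, r, tm, stall_time = NA, f_post = 1,
                              pause_start = NA, pause_dur = 0) {
  Tend <- times[length(times)]
  # The stall is intrinsic to colony progress (resource exhaustion), not to
  # wall clock: a growth pause before the stall delays it by the same amount.
  if (is.finite(stall_time) && is.finite(pause_start) &&
      pause_dur > 0 && stall_time >= pause_start)
    stall_time <- stall_time + pause_dur
  bp <- c(0, Tend)
  if (is.finite(stall_time) && stall_time > 0 && stall_time < Tend) bp <- c(bp, stall_time)
  if (is.finite(pause_start) && pause_dur > 0 && pause_start < Tend)
    bp <- c(bp, pause_start, min(pause_start + pause_dur, Tend))
  bp <- sort(unique(bp))
  I0 <- K / (1 + exp(r * tm))
  out <- numeric(length(times))
  out[times <= 0] <- I0
  Ia <- I0
  for (s in seq_len(length(bp) - 1)) {
    a <- bp[s]; b <- bp[s + 1]
    mid <- (a + b) / 2
    rs <- r
    if (is.finite(stall_time) && mid > stall_time) rs <- r * f_post
    if (is.finite(pause_start) && mid > pause_start && mid < pause_start + pause_dur) rs <- 0
    sel <- which(times > a & times <= b)
    if (Ia <= 0) { out[sel] <- 0; next }
    out[sel] <- K / (1 + (K / Ia - 1) * exp(-rs * (times[sel] - a)))
    Ia <- K / (1 + (K / Ia - 1) * exp(-rs * (b - a)))
  }
  out
}

# Smooth low-order polynomial multiplicative bias field for one plate.
.plate_bias_field <- function(nrow, ncol, amplitude, seed) {
  if (amplitude <= 0) return(matrix(1, nrow, ncol))
  set.seed(seed)
  a <- stats::runif(5, -1, 1)
  R <- matrix(if (nrow > 1) seq(-1, 1, length.out = nrow) else 0, nrow, ncol)
  C <- matrix(if (ncol > 1) seq(-1, 1, length.out = ncol) else 0, nrow, ncol, byrow = TRUE)
  f <- a[1] * R + a[2] * C + a[3] * R * C + a[4] * R^2 + a[5] * C^2
  pmax(1 + amplitude * f / max(abs(f), 1e-9), 0.2)
}

#' Simulate a labeled colony-screen experiment
#'
#' Generates per-colony intensity trajectories for `n_strains` strains at
#' `n_replicates` plates per condition (untreated / treated), with the
#' statistical structure the analysis pipeline assumes: logistic growth with
#' class-specific lag/stall/treatment-response phenotypes
#' ([phenotype_specs()]), strain- and replicate-level parameter jitter,
#' a smooth multiplicative spatial bias field per plate, and multiplicative
#' lognormal measurement noise. All randomness derives from `config$seed`
#' through per-strain/per-colony/per-plate substreams (stable under layout
#' changes); the same seed gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_experiment`: list with `times` (minutes),
#'   `colonies` (one row per colony: identity, position, class, bias),
#'   `intensity` (timepoints x colonies observed matrix), `truth`
#'   (noiseless, bias-free matrix), `strains` (strain_id, class,
#'   is_responder), and `config`.
#' @export
simulate_curves <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  times <- seq(0, cf$total_hours * 60, by = cf$frame_interval)
  t_treat <- cf$treatment_frame * cf$frame_interval

  strain_ids <- sprintf("STRAIN_%05d", seq_len(cf$n_strains))
  set.seed(.substream_seed(cf$seed, "classes"))
  classes <- sample(names(cf$class_probs), cf$n_strains, replace = TRUE,
                    prob = cf$class_probs)
  strain_tm <- strain_lk <- numeric(cf$n_strains)
  for (i in seq_len(cf$n_strains)) {
    set.seed(.substream_seed(cf$seed, paste0("strain:", strain_ids[i])))
    strain_tm[i] <- stats::rnorm(1, 0, cf$strain_tm_sd)
    strain_lk[i] <- stats::rnorm(1, 0, cf$strain_logk_sd)
  }

  conditions <- c("untreated", "treated")
  n_col_total <- cf$n_strains * cf$n_replicates * 2
  colonies <- data.frame(
    strain_id = rep(strain_ids, times = cf$n_replicates * 2),
    plate_id = character(n_col_total), condition = character(n_col_total),
    replicate = integer(n_col_total), row = integer(n_col_total),
    col = integer(n_col_total), class = rep(classes, times = cf$n_replicates * 2),
    bias = numeric(n_col_total), stringsAsFactors = FALSE)
  intensity <- matrix(0, length(times), n_col_total)
  truth <- matrix(0, length(times), n_col_total)

  rows <- ((seq_len(cf$n_strains) - 1) %/% cf$plate_ncol) + 1L
  cols <- ((seq_len(cf$n_strains) - 1) %% cf$plate_ncol) + 1L

  k <- 0
  for (cond in conditions) for (rep_i in seq_len(cf$n_replicates)) {
    plate <- sprintf("%s_P%02d", toupper(substr(cond, 1, 2)), rep_i)
    bias <- .plate_bias_field(cf$plate_nrow, cf$plate_ncol, cf$gradient_amplitude,
                              .substream_seed(cf$seed, paste0("plate:", plate)))
    idx <- k + seq_len(cf$n_strains)
    colonies$plate_id[idx] <- plate
    colonies$condition[idx] <- cond
    colonies$replicate[idx] <- rep_i
    colonies$row[idx] <- rows
    colonies$col[idx] <- cols
    colonies$bias[idx] <- bias[cbind(rows, cols)]
    for (i in seq_len(cf$n_strains)) {
      ph <- cf$phenotypes[[classes[i]]]
      set.seed(.substream_seed(cf$seed, paste("colony", plate, rows[i], cols[i], sep = ":")))
      tm <- ph$midpoint_time + strain_tm[i] + stats::rnorm(1, 0, cf$rep_tm_sd)
      K <- ph$carrying_capacity * exp(strain_lk[i] + stats::rnorm(1, 0, cf$rep_logk_sd))
      treated <- cond == "treated"
      if (treated) K <- K * ph$uvr_capacity_fraction
      f_post <- if (treated) ph$treated_post_stall_rate_fraction else ph$post_stall_rate_fraction
      tr <- .sim_colony_curve(times, K, ph$max_rate, tm,
                              stall_time = ph$stall_time, f_post = f_post,
                              pause_start = if (treated) t_treat else NA,
                              pause_dur = if (treated) ph$pause_duration else 0)
      j <- k + i
      truth[, j] <- tr
      noise <- if (cf$noise_sigma > 0)
        exp(stats::rnorm(length(times), 0, cf$noise_sigma)) else 1
      intensity[, j] <- tr * colonies$bias[j] * noise
    }
    k <- k + cf$n_strains
  }

  responder_classes <- c("uvr_sensitive", "uvr_resistant_stall")
  strains <- data.frame(strain_id = strain_ids, class = classes,
                        is_responder = classes %in% responder_classes,
                        stringsAsFactors = FALSE)
  structure(list(times = times, colonies = colonies, intensity = intensity,
                 truth = truth, strains = strains, config = cf),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat("Simulated colony screen:", nrow(x$strains), "strains x",
      x$config$n_replicates, "replicates x 2 conditions =",
      nrow(x$colonies), "colonies,", length(x$times), "frames\n")
  print(table(x$strains$class))
  invisible(x)
}

#' Long curve table from a simulated experiment
#'
#' Emits the CSV schema consumed by [compute_growth_metrics()] and written
#' by the pipeline: one row per colony per timepoint.
#'
#' @param experiment a `sim_experiment`.
#' @return data.frame with columns `strain_id`, `plate_id`, `condition`,
#'   `replicate`, `row`, `col`, `time_min`, `intensity`.
#' @export
as_curve_table <- function(experiment) {
  stopifnot(inherits(experiment, "sim_experiment"))
  n_t <- length(experiment$times); n_c <- nrow(experiment$colonies)
  co <- experiment$colonies[rep(seq_len(n_c), each = n_t),
                            c("strain_id", "plate_id", "condition", "replicate", "row", "col")]
  co$time_min <- rep(experiment$times, times = n_c)
  co$intensity <- as.vector(experiment$intensity)
  rownames(co) <- NULL
  co
}

#' @rdname compute_growth_metrics
#' @export
compute_growth_metrics.sim_experiment <- function(x, ...) {
  .compute_metrics_wide(x$intensity, x$times,
                        x$colonies[c("strain_id", "plate_id", "condition",
                                     "replicate", "row", "col")], ...)
}

#' Evaluate pipeline output against simulator ground truth
#'
#' Scores two things: (i) the sign of untreated per-strain median lagVstall
#' against the programmed lag (negative) / stall (positive) labels, and
#' (ii) nomination of programmed treatment responders (recall and empirical
#' FDR of the nominated union).
#'
#' @param experiment a `sim_experiment`.
#' @param metrics a `growth_metrics` result (or its `metrics` data.frame).
#' @param screen optional `diff_screen` result for nomination scoring.
#' @return list with `lvs_sign_accuracy`, `n_sign_evaluated`, and (when
#'   `screen` is given) `recall`, `fdr`, `n_responders`, `n_nominated`,
#'   `confusion` (TP/FP/FN counts).
#' @export
ground_truth_eval <- function(experiment, metrics, screen = NULL) {
  stopifnot(inherits(experiment, "sim_experiment"))
  mt <- if (inherits(metrics, "growth_metrics")) metrics$metrics else metrics
  mt <- mt[!isTRUE(mt$excluded) & is.finite(mt$lag_v_stall), , drop = FALSE]
  ut <- mt[mt$condition == "untreated", ]
  med <- tapply(ut$lag_v_stall, ut$strain_id, stats::median)
  cls <- stats::setNames(experiment$strains$class, experiment$strains$strain_id)[names(med)]
  lagged <- cls == "lag"
  stalled <- cls %in% c("stall", "uvr_resistant_stall")
  n_eval <- sum(lagged) + sum(stalled)
  acc <- if (n_eval > 0)
    (sum(med[lagged] < 0) + sum(med[stalled] > 0)) / n_eval else NA_real_
  out <- list(lvs_sign_accuracy = acc, n_sign_evaluated = n_eval)
  if (!is.null(screen)) {
    stopifnot(inherits(screen, "diff_screen"))
    analyzed <- unique(screen$results$strain_id)
    resp <- experiment$strains$strain_id[experiment$strains$is_responder]
    resp <- intersect(resp, analyzed)
    score <- function(nom) {
      tp <- length(intersect(nom, resp)); fp <- length(setdiff(nom, resp))
      c(recall = if (length(resp)) tp / length(resp) else NA_real_,
        fdr = if (length(nom)) fp / length(nom) else 0,
        TP = tp, FP = fp, FN = length(setdiff(resp, nom)))
    }
    u <- score(screen$sets$union)
    out$recall <- u[["recall"]]; out$fdr <- u[["fdr"]]
    out$n_responders <- length(resp)
    out$n_nominated <- length(screen$sets$union)
    out$confusion <- u[c("TP", "FP", "FN")]
    # per-metric nominated sets: the families within which the q cutoff
    # controls the false discovery rate
    out$by_metric <- do.call(rbind, lapply(screen$metrics, function(m) {
      data.frame(metric = m, n_nominated = length(screen$sets[[m]]),
                 t(score(screen$sets[[m]])))
    }))
  }
  out
}
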