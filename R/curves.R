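#' Construct a growth curve
#'
#' One colony's intensity trajectory: summed pixel intensity at 5-minute
#' frames, with strain/plate/condition/replicate identity.
#'
#' @param values numeric intensity per timepoint (finite, length >= 2).
#' @param times minutes from the first frame; default uniform 5-minute
#'   spacing starting at 0.
#' @param strain_id,plate_id,condition,replicate identity fields.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(values, times = (seq_along(values) - 1) * 5,
                         strain_id = NA_character_, plate_id = NA_character_,
                         condition = "untreated", replicate = 1L) {
  if (length(values) < 2) .gs_stop("short_curve", "a growth curve needs >= 2 timepoints")
  if (any(!is.finite(values))) .gs_stop("invalid_curve", "curve values must be finite")
  if (any(diff(times) <= 0)) .gs_stop("invalid_curve", "times must be strictly increasing")
  structure(list(strain_id = strain_id, plate_id = plate_id,
                 condition = condition, replicate = replicate,
                 times = as.numeric(times), values = as.numeric(values)),
            class = "growth_curve")
}

.curve_values <- function(x) if (inherits(x, "growth_curve")) x$values else as.numeric(x)
.with_values <- function(x, v) {
  if (inherits(x, "growth_curve")) { x$values <- v; x } else v
}

#' Truncate a growth curve to the analyzed time window
#'
#' Colony overgrowth corrupts late frames, so the analysis is restricted to
#' the first `max_hours` of growth (default 40 h: with 5-minute frames,
#' 481 timepoints including t = 0).
#'
#' @param curve a `growth_curve`.
#' @param max_hours retain timepoints with `time <= max_hours`.
#' @return the truncated `growth_curve`.
#' @export
truncate_curve <- function(curve, max_hours = 40) {
  stopifnot(max_hours > 0)
  keep <- curve$times <= max_hours * 60
  if (sum(keep) < 2) .gs_stop("short_curve", "truncation left fewer than 2 timepoints")
  curve$times <- curve$times[keep]
  curve$values <- curve$values[keep]
  curve
}

# Robust LOWESS on a single vector. stats::lowess implements locally
# weighted linear regression (tricube distance weights) with bisquare
# robustness iterations; the span is the window as a fraction of n.
# Guard: lowess's robustness pass misbehaves when the initial fit is exact
# (zero residual scale), so short-circuit to the non-robust fit then.
.smooth_vec <- function(y, window = 48L, iter = 4L) {
  n <- length(y)
  if (window <= 1 || n < 3) return(y)
  f <- min(window, n) / n
  x <- seq_len(n)
  fit0 <- stats::lowess(x, y, f = f, iter = 0, delta = 0)$y
  scale <- stats::median(abs(y - fit0))
  if (scale <= 1e-9 * max(1, max(abs(y)))) return(fit0)
  stats::lowess(x, y, f = f, iter = iter, delta = 0)$y
}

#' Smooth a growth curve with robust LOWESS
#'
#' Robust locally weighted linear regression over a centered window of
#' `window` timepoints (default 48 = 4 h at 5-minute frames), edge-truncated,
#' with bisquare robustness iterations that down-weight transient imaging
#' artifacts (reflections, condensation spikes). Exact on linear segments;
#' `window = 1` is the identity.
#'
#' @param curve a `growth_curve` or numeric vector.
#' @param window window size in timepoints.
#' @param iter robustness iterations.
#' @return same type as input, smoothed; length unchanged.
#' @export
smooth_curve <- function(curve, window = 48L, iter = 4L) {
  .with_values(curve, .smooth_vec(.curve_values(curve), window = window, iter = iter))
}

#' Zero-normalize a growth curve
#'
#' Subtracts the first-timepoint value so every colony starts at intensity
#' zero; small negative excursions (noise below the starting background) are
#' clipped to 0.
#'
#' @param curve a `growth_curve` or numeric vector (smoothed).
#' @return same type, zero-normalized.
#' @export
zero_normalize <- function(curve) {
  v <- .curve_values(curve)
  .with_values(curve, pmax(v - v[1], 0))
}

#' Endpoint-normalize a growth curve
#'
#' Divides by the final value so the curve expresses progress as a fraction
#' of final colony intensity (final value exactly 1). Colonies whose final
#' intensity is at or below `min_final` never grew ("dead"); they are flagged
#' rather than divided by ~0.
#'
#' @param curve a `growth_curve` or numeric vector.
#' @param min_final dead-colony threshold on the final value (same units as
#'   the curve).
#' @return same type, endpoint-normalized; or, when dead, the input with
#'   attribute/field `dead = TRUE` left unnormalized.
#' @export
endpoint_normalize <- function(curve, min_final = 0) {
  v <- .curve_values(curve)
  fin <- v[length(v)]
  if (fin <= min_final || fin <= 0) {
    if (inherits(curve, "growth_curve")) { curve$dead <- TRUE; return(curve) }
    attr(curve, "dead") <- TRUE
    return(curve)
  }
  .with_values(curve, v / fin)
}

#' Plate reference curve
#'
#' The per-timepoint median of all endpoint-normalized curves on one plate
#' and condition -- the population trend each colony is compared against.
#'
#' @param curves list of `growth_curve`s (endpoint-normalized) or a numeric
#'   matrix with one column per colony.
#' @return numeric vector (final value 1 when members are normalized).
#' @export
reference_curve <- function(curves) {
  if (is.list(curves) && !is.data.frame(curves)) {
    lens <- vapply(curves, function(c) length(.curve_values(c)), integer(1))
    if (length(unique(lens)) != 1) .gs_stop("alignment_error", "curves have unequal lengths")
    if (length(curves) < 3) .gs_stop("alignment_error", "need >= 3 curves for a reference")
    curves <- vapply(curves, .curve_values, numeric(lens[1]))
  }
  apply(curves, 1, stats::median)
}

#' Deviation profile of a curve from the plate reference
#'
#' Pointwise difference (curve minus reference) between an
#' endpoint-normalized curve and the plate reference curve; positive where
#' the colony is ahead of the population in fractional progress.
#'
#' @param curve endpoint-normalized `growth_curve` or numeric vector.
#' @param ref reference curve (numeric vector of equal length).
#' @return same type as `curve`.
#' @export
deviation_profile <- function(curve, ref) {
  v <- .curve_values(curve)
  if (length(v) != length(ref)) .gs_stop("alignment_error", "curve/reference length mismatch")
  .with_values(curve, v - ref)
}

#' lagVstall: signed summed deviation from the plate reference
#'
#' The sum over timepoints of the deviation profile. Negative values mark
#' "lag" colonies (consistently behind the population's fractional
#' progress); positive values mark "stall" colonies (track the population,
#' then plateau early relative to their own final intensity).
#'
#' @param profile a deviation profile (`growth_curve` or numeric vector).
#' @return signed scalar.
#' @export
lag_v_stall <- function(profile) sum(.curve_values(profile))

#' Colony fitness: final intensity of the processed curve
#'
#' The classical static screen metric -- the spatially corrected, smoothed,
#' zero-normalized colony intensity at the last retained timepoint.
#'
#' @param curve processed `growth_curve` or numeric vector.
#' @return scalar >= 0.
#' @export
colony_fitness <- function(curve) {
  v <- .curve_values(curve)
  v[length(v)]
}

#' Growth rate dPI/dT
#'
#' Central finite difference of the (smoothed) intensity values over time,
#' forward/backward at the edges; units: intensity per minute.
#'
#' @param curve a `growth_curve`, or numeric vector with `times`.
#' @param times timepoints in minutes (ignored for `growth_curve` input).
#' @return numeric vector of rates, same length as the curve.
#' @export
growth_rate <- function(curve, times = NULL) {
  v <- .curve_values(curve)
  t <- if (inherits(curve, "growth_curve")) curve$times else
       if (is.null(times)) (seq_along(v) - 1) * 5 else times
  n <- length(v)
  stopifnot(n >= 2)
  r <- numeric(n)
  r[1] <- (v[2] - v[1]) / (t[2] - t[1])
  r[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) r[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  if (inherits(curve, "growth_curve")) { curve$values <- r; curve } else r
}

#' Compute growth metrics for a whole experiment
#'
#' Runs the curve pipeline for every colony, per plate and condition:
#' optional spatial correction of each frame's intensity matrix
#' ([spatial_correct()], when grid positions are available), truncation to
#' `max_hours`, robust LOWESS smoothing, zero-normalization, endpoint
#' normalization, the plate-median reference curve, and finally per-colony
#' lagVstall and colony fitness. Colonies whose final intensity falls below
#' `min_final_frac` times the plate median final intensity are flagged dead
#' and excluded from the reference and the metrics.
#'
#' @param x a long curve table (data.frame with columns `strain_id`,
#'   `plate_id`, `condition`, `replicate`, `time_min`, `intensity`, and
#'   optionally `row`, `col`), or a `sim_experiment` from
#'   [simulate_curves()].
#' @param max_hours analysis window (default 40).
#' @param smooth_window LOWESS window in timepoints (default 48 = 4 h).
#' @param spatial apply [spatial_correct()] per frame when `row`/`col` are
#'   present (default TRUE).
#' @param min_final_frac dead-colony threshold as a fraction of the plate
#'   median final intensity (default 0.01).
#' @param keep_curves retain the normalized curve matrices in the result
#'   (memory-heavy; default FALSE).
#' @param ... passed to methods.
#' @return object of class `growth_metrics`: list with `metrics` (data.frame
#'   of per-colony `lag_v_stall` and `colony_fitness`), `reference` (named
#'   list of plate/condition reference curves), `times`, `n_dead`, and
#'   optionally `normalized`.
#' @export
compute_growth_metrics <- function(x, ...) UseMethod("compute_growth_metrics")

#' @rdname compute_growth_metrics
#' @export
compute_growth_metrics.data.frame <- function(x, max_hours = 40, smooth_window = 48L,
                                              spatial = TRUE, min_final_frac = 0.01,
                                              keep_curves = FALSE, ...) {
  req <- c("strain_id", "plate_id", "condition", "replicate", "time_min", "intensity")
  miss <- setdiff(req, names(x))
  if (length(miss)) .gs_stop("schema_error", "curve table lacks columns: %s",
                             paste(miss, collapse = ", "))
  times <- sort(unique(x$time_min))
  if (length(times) > 2 && max(abs(diff(diff(times)))) > 1e-9)
    .gs_stop("alignment_error", "curves do not share a uniform time grid")
  key <- paste(x$plate_id, x$condition, x$strain_id, x$replicate,
               if (!is.null(x$row)) x$row else "", if (!is.null(x$col)) x$col else "",
               sep = "\r")
  ukey <- unique(key)
  ci <- match(key, ukey)
  ti <- match(x$time_min, times)
  M <- matrix(NA_real_, length(times), length(ukey))
  M[cbind(ti, ci)] <- x$intensity
  if (anyNA(M)) .gs_stop("alignment_error", "curves do not share a common time grid")
  first <- !duplicated(key)
  colonies <- data.frame(strain_id = x$strain_id[first], plate_id = x$plate_id[first],
                         condition = x$condition[first], replicate = x$replicate[first],
                         stringsAsFactors = FALSE)
  if (!is.null(x$row)) { colonies$row <- x$row[first]; colonies$col <- x$col[first] }
  .compute_metrics_wide(M, times, colonies, max_hours = max_hours,
                        smooth_window = smooth_window, spatial = spatial,
                        min_final_frac = min_final_frac, keep_curves = keep_curves)
}

# Core wide-format engine: M is a (timepoints x colonies) intensity matrix.
.compute_metrics_wide <- function(M, times, colonies, max_hours = 40,
                                  smooth_window = 48L, spatial = TRUE,
                                  min_final_frac = 0.01, keep_curves = FALSE) {
  stopifnot(nrow(M) == length(times), ncol(M) == nrow(colonies))
  has_pos <- all(c("row", "col") %in% names(colonies))
  pc <- paste(colonies$plate_id, colonies$condition, sep = "\r")

  # Spatial correction at the curve stage: plate bias fields are static in
  # time, so per-colony multiplicative correction factors are estimated once
  # per plate from the final frame (colonies brightest, bias best resolved)
  # and applied to the whole trajectory. This equals per-frame correction
  # for a static multiplicative field at a fraction of the cost.
  if (spatial && has_pos) {
    for (p in unique(pc)) {
      sel <- which(pc == p)
      nr <- max(colonies$row[sel]); nc <- max(colonies$col[sel])
      pos <- cbind(colonies$row[sel], colonies$col[sel])
      g <- matrix(NA_real_, nr, nc)
      g[pos] <- M[nrow(M), sel]
      cg <- spatial_correct(g)
      fac <- ifelse(g[pos] > 0, cg[pos] / g[pos], 1)
      M[, sel] <- sweep(M[, sel, drop = FALSE], 2, fac, "*")
    }
  }

  keep_t <- times <= max_hours * 60
  if (sum(keep_t) < 2) .gs_stop("short_curve", "truncation left fewer than 2 timepoints")
  times <- times[keep_t]
  M <- M[keep_t, , drop = FALSE]

  for (j in seq_len(ncol(M))) M[, j] <- .smooth_vec(M[, j], window = smooth_window)
  M <- pmax(sweep(M, 2, M[1, ]), 0)  # zero-normalize, clip negatives

  finals <- M[nrow(M), ]
  dead <- logical(ncol(M))
  N <- matrix(NA_real_, nrow(M), ncol(M))
  refs <- list()
  lvs <- rep(NA_real_, ncol(M))
  for (p in unique(pc)) {
    sel <- which(pc == p)
    thr <- min_final_frac * stats::median(finals[sel])
    d <- finals[sel] <= thr | finals[sel] <= 0
    dead[sel[d]] <- TRUE
    live <- sel[!d]
    if (length(live) >= 3) {
      N[, live] <- sweep(M[, live, drop = FALSE], 2, finals[live], "/")
      ref <- apply(N[, live, drop = FALSE], 1, stats::median)
      refs[[gsub("\r", "/", p)]] <- ref
      lvs[live] <- colSums(N[, live, drop = FALSE] - ref)
    }
  }

  metrics <- colonies
  metrics$lag_v_stall <- lvs
  metrics$colony_fitness <- finals
  metrics$excluded <- dead | is.na(lvs)
  out <- list(metrics = metrics, reference = refs, times = times,
              n_dead = sum(dead))
  if (keep_curves) { out$normalized <- N; out$smoothed <- M }
  structure(out, class = "growth_metrics")
}

#' @export
print.growth_metrics <- function(x, ...) {
  m <- x$metrics[!x$metrics$excluded, ]
  cat("Growth metrics:", nrow(x$metrics), "colonies (",
      sum(x$metrics$excluded), "excluded/dead ) over",
      length(x$times), "timepoints\n")
  cat("  plates x conditions:", length(x$reference), "\n")
  if (nrow(m)) {
    cat("  lagVstall range: [", round(min(m$lag_v_stall), 3), ",",
        round(max(m$lag_v_stall), 3), "]\n")
    cat("  median colony fitness:", signif(stats::median(m$colony_fitness), 4), "\n")
  }
  invisible(x)
}
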