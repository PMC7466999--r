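#' Pool duplicate plate positions as extra replicates
#'
#' Strains arrayed at more than one grid position (e.g. edge colonies
#' re-arrayed into the interior) are pooled under one strain id, with
#' replicates re-indexed 1..n within each strain and condition.
#'
#' @param table replicate metric table: data.frame with columns `strain_id`,
#'   `condition`, `replicate` and metric columns (`lag_v_stall`,
#'   `colony_fitness`); optional `row`/`col` distinguish positions.
#' @return the pooled table, replicates re-indexed.
#' @export
merge_duplicates <- function(table) {
  key_cols <- intersect(c("strain_id", "condition", "replicate", "plate_id", "row", "col"),
                        names(table))
  key <- do.call(paste, c(table[key_cols], sep = "\r"))
  if (anyDuplicated(key))
    .gs_stop("key_collision", "duplicate (strain, condition, replicate%s) rows: e.g. %s",
             if (all(c("row", "col") %in% key_cols)) ", position" else "",
             gsub("\r", "/", key[duplicated(key)][1]))
  sc <- paste(table$strain_id, table$condition, sep = "\r")
  ord <- order(sc, table$replicate)
  table <- table[ord, , drop = FALSE]
  sc <- sc[ord]
  table$replicate <- stats::ave(seq_along(sc), sc, FUN = seq_along)
  rownames(table) <- NULL
  table
}

#' Filter strains by replicate depth
#'
#' Strains are retained only when they have at least `min_reps` replicates
#' in *both* conditions; a strain under-replicated in either condition is
#' removed entirely.
#'
#' @param table replicate metric table (see [merge_duplicates()]).
#' @param min_reps minimum replicates per condition (default 6).
#' @return filtered table.
#' @export
filter_replicates <- function(table, min_reps = 6L) {
  stopifnot(min_reps >= 1)
  conds <- unique(table$condition)
  cnt <- table(table$strain_id, table$condition)
  ok_strains <- rownames(cnt)[apply(cnt >= min_reps, 1, all) &
                                apply(cnt > 0, 1, all)]
  out <- table[table$strain_id %in% ok_strains, , drop = FALSE]
  if (!nrow(out)) warning("no strains pass the replicate filter")
  rownames(out) <- NULL
  out
}

#' Robust Z-scores
#'
#' `z = (x - median(x)) / MAD(x)` with the *unscaled* median absolute
#' deviation `MAD = median(|x - median(x)|)` (no 1.4826 normal-consistency
#' factor), so the scored population has median exactly 0 and MAD exactly 1.
#'
#' @param values numeric vector (>= 2 distinct values).
#' @return Z-scored vector.
#' @export
robust_z <- function(values) {
  m <- stats::median(values)
  mad0 <- stats::median(abs(values - m))
  if (mad0 == 0) .gs_stop("degenerate_scale", "MAD is zero; robust Z undefined")
  (values - m) / mad0
}

#' Pooled two-sample t-test
#'
#' Two-sided, unpaired t-test with pooled variance, returning the statistic
#' and p-value. Degenerate zero-variance input is handled explicitly: equal
#' means give p = 1; unequal means give p = 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param x,y numeric vectors (each length >= 2); the statistic is
#'   `(mean(x) - mean(y)) / se`.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df
  dm <- mean(x) - mean(y)
  if (sp2 <= 0) {
    out <- list(t = if (dm == 0) 0 else sign(dm) * Inf,
                p = if (dm == 0) 1 else 0, df = df)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  tt <- dm / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * stats::pt(-abs(tt), df), df = df)
}

#' Storey q-values (positive false discovery rate)
#'
#' Estimates the null proportion `pi0` from the p-value histogram:
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` on
#' `lambda = 0, 0.01, ..., 0.90`, smoothed with a natural cubic smoothing
#' spline (3 effective degrees of freedom, Storey's estimator) and
#' evaluated at the largest lambda, clipped to (0, 1]. Then
#' `q(i) = min over j with p(j) >= p(i) of pi0 * m * p(j) / rank(j)`,
#' clipped to \[0, 1\] -- the step-up construction, monotone in p. With
#' `pi0 = 1` this reduces exactly to the Benjamini-Hochberg adjustment.
#'
#' @param p vector of p-values in \[0, 1\].
#' @param lambda grid for the pi0 estimate.
#' @param pi0 optionally force the null proportion (e.g. 1 for BH).
#' @return vector of q-values in the input order; attribute `pi0` records
#'   the estimate used.
#' @export
storey_qvalues <- function(p, lambda = seq(0, 0.90, by = 0.01), pi0 = NULL) {
  if (!length(p)) .gs_stop("empty_input", "empty p-value vector")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    .gs_stop("invalid_pvalues", "p-values must lie in [0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    pi0 <- min(pi0, 1)
    if (pi0 <= 0) pi0 <- min(1, max(min(pi0_l[pi0_l > 0], na.rm = TRUE), 1 / m))
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  attr(q, "pi0") <- pi0
  q
}

#' Fit the differential screen: nominate treatment-responsive strains
#'
#' The model-fitting entry point of the package. Takes per-replicate metric
#' values (lagVstall and colony fitness) for treated and untreated
#' conditions and, per strain and metric: (i) robust Z-scores every
#' replicate value within its plate x condition population
#' ([robust_z()]; Z-scores absorb plate effects and give each strain a
#' median-Z summary), (ii) runs a pooled two-sample t-test between
#' conditions on the plate-median-centered replicate values
#' ([two_sample_t()]; centering removes additive plate and
#' plate-composition shifts that would otherwise bias every strain's
#' comparison the same way, while avoiding the cross-condition scale
#' mismatch that a per-condition MAD rescale would inject into the test
#' statistic -- the t-test is invariant to any common rescaling anyway),
#' (iii) converts
#' each metric's p-values to Storey q-values ([storey_qvalues()]), and
#' (iv) nominates strains with `q < q_cutoff`, with direction taken from
#' `delta_z` (treated median Z minus untreated median Z).
#'
#' @param table replicate metric table: columns `strain_id`, `condition`
#'   (two levels), `replicate`, `lag_v_stall`, `colony_fitness`, optionally
#'   `plate_id` (Z-scoring population; falls back to the whole condition).
#' @param q_cutoff nomination threshold (default 0.05).
#' @param min_reps replicate filter passed to [filter_replicates()].
#' @param treated,untreated the two condition labels.
#' @param metrics metric columns to analyze.
#' @return object of class `diff_screen`: list with `results` (one row per
#'   strain x metric: `n_ut`, `n_uvr`, `t`, `p`, `q`, `delta_z`,
#'   `direction`, `nominated`), `sets` (per-metric nominated strain sets,
#'   union, intersection), `n_strains`, `q_cutoff`, `call`.
#' @seealso [nominate()], [summary.diff_screen()]
#' @export
differential_screen <- function(table, q_cutoff = 0.05, min_reps = 6L,
                                treated = "treated", untreated = "untreated",
                                metrics = c("lag_v_stall", "colony_fitness")) {
  cl <- match.call()
  stopifnot(all(metrics %in% names(table)))
  if (!all(c(treated, untreated) %in% table$condition))
    .gs_stop("schema_error", "conditions '%s'/'%s' not both present", treated, untreated)
  bad <- !stats::complete.cases(table[metrics]) |
    !apply(sapply(table[metrics], is.finite), 1, all)
  if (any(bad)) {
    message(sum(bad), " replicate rows with missing/non-finite metrics dropped")
    table <- table[!bad, , drop = FALSE]
  }
  if ("excluded" %in% names(table)) table <- table[!table$excluded, , drop = FALSE]

  # Z-score within plate x condition before any pooling/filtering
  zpop <- if ("plate_id" %in% names(table))
    paste(table$plate_id, table$condition, sep = "\r") else table$condition
  ztab <- table
  for (mt in metrics) {
    z <- ctr <- rep(NA_real_, nrow(table))
    for (g in unique(zpop)) {
      sel <- zpop == g
      z[sel] <- robust_z(table[[mt]][sel])
      ctr[sel] <- table[[mt]][sel] - stats::median(table[[mt]][sel])
    }
    ztab[[paste0("z_", mt)]] <- z
    ztab[[paste0("c_", mt)]] <- ctr
  }

  ztab <- merge_duplicates(ztab)
  ztab <- filter_replicates(ztab, min_reps = min_reps)
  strains <- sort(unique(ztab$strain_id))

  res <- vector("list", length(metrics))
  names(res) <- metrics
  idx_uvr <- split(seq_len(nrow(ztab))[ztab$condition == treated],
                   ztab$strain_id[ztab$condition == treated])
  idx_ut <- split(seq_len(nrow(ztab))[ztab$condition == untreated],
                  ztab$strain_id[ztab$condition == untreated])
  for (mt in metrics) {
    v <- ztab[[paste0("c_", mt)]]; zv <- ztab[[paste0("z_", mt)]]
    tt <- pp <- dz <- numeric(length(strains))
    nut <- nuvr <- integer(length(strains))
    # The null hypothesis is "this strain responds like the typical strain":
    # when responders reshape the treated population, every
    # population-relative metric inherits a small common contrast, so the
    # per-strain contrasts are centered at their across-strain median
    # before testing (the usual screen normalization of per-gene effects).
    raw_d <- vapply(strains, function(s)
      mean(v[idx_uvr[[s]]]) - mean(v[idx_ut[[s]]]), numeric(1))
    typical <- stats::median(raw_d)
    for (k in seq_along(strains)) {
      iu <- idx_ut[[strains[k]]]; iv <- idx_uvr[[strains[k]]]
      r <- two_sample_t(v[iv] - typical, v[iu])  # treated - untreated contrast
      tt[k] <- r$t; pp[k] <- r$p
      dz[k] <- stats::median(zv[iv]) - stats::median(zv[iu])
      nut[k] <- length(iu); nuvr[k] <- length(iv)
    }
    qq <- storey_qvalues(pp)
    res[[mt]] <- data.frame(strain_id = strains, metric = mt,
                            n_ut = nut, n_uvr = nuvr, t = tt, p = pp,
                            q = as.numeric(qq), delta_z = dz,
                            direction = ifelse(dz < 0, "sensitive", "resistant"),
                            nominated = as.numeric(qq) < q_cutoff,
                            stringsAsFactors = FALSE)
    attr(res[[mt]], "pi0") <- attr(qq, "pi0")
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  sets <- nominate(results, q_cutoff = q_cutoff, metrics = metrics)
  structure(list(results = results, sets = sets, n_strains = length(strains),
                 q_cutoff = q_cutoff, min_reps = min_reps,
                 metrics = metrics, call = cl),
            class = "diff_screen")
}

#' Build nomination sets from differential results
#'
#' @param results data.frame as in [differential_screen()]'s `results`
#'   (columns `strain_id`, `metric`, `q`, `delta_z`).
#' @param q_cutoff nomination threshold.
#' @param metrics metrics to form sets for.
#' @return list with one strain set per metric, plus `union`,
#'   `intersection`, and exclusive per-metric counts.
#' @export
nominate <- function(results, q_cutoff = 0.05,
                     metrics = c("lag_v_stall", "colony_fitness")) {
  sets <- lapply(metrics, function(mt)
    sort(results$strain_id[results$metric == mt & results$q < q_cutoff]))
  names(sets) <- metrics
  uni <- sort(Reduce(union, sets))
  inter <- sort(Reduce(intersect, sets))
  c(sets, list(union = uni, intersection = inter,
               exclusive = lapply(sets, function(s) setdiff(s, inter))))
}

#' Percentile-tail strain selection
#'
#' Returns the strains at or beyond the lower and upper percentiles of a
#' per-strain metric (e.g. the 5th and 95th percentiles of untreated
#' lagVstall). Tail size is `ceiling(pct/100 * N)`; ties are broken by
#' strain id order, so the selection is deterministic.
#'
#' @param values named numeric vector (names = strain ids) or a data.frame
#'   with columns `strain_id` and `value`.
#' @param lower_pct,upper_pct percentile boundaries (0 < lower < upper < 100).
#' @return list with `lower` and `upper` strain id vectors.
#' @export
tail_select <- function(values, lower_pct = 5, upper_pct = 95) {
  stopifnot(lower_pct > 0, upper_pct < 100, lower_pct < upper_pct)
  if (is.data.frame(values)) values <- stats::setNames(values$value, values$strain_id)
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  n <- length(values)
  k_lo <- ceiling(lower_pct / 100 * n)
  k_hi <- ceiling((100 - upper_pct) / 100 * n)
  o_lo <- order(values, ids)
  o_hi <- order(-values, ids)
  list(lower = ids[o_lo[seq_len(k_lo)]],
       upper = ids[o_hi[seq_len(k_hi)]])
}

#' Replicate-agreement correlation
#'
#' Pearson correlation of per-strain median Z-scored metric values between
#' two replicate subsets or conditions -- the screen's reproducibility
#' check.
#'
#' @param x,y numeric vectors matched by strain (length >= 3).
#' @return correlation scalar.
#' @export
replicate_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .gs_stop("undefined_correlation", "zero variance; correlation undefined")
  stats::cor(x, y)
}

#' @export
print.diff_screen <- function(x, ...) {
  cat("Differential colony screen:", x$n_strains, "strains, q <", x$q_cutoff, "\n")
  for (mt in x$metrics)
    cat(sprintf("  nominated by %-15s %d\n", paste0(mt, ":"), length(x$sets[[mt]])))
  cat("  union:", length(x$sets$union),
      " intersection:", length(x$sets$intersection), "\n")
  invisible(x)
}

#' Summarize a differential screen
#'
#' @param object a `diff_screen`.
#' @param n number of top strains (by q) to display per metric.
#' @param ... unused.
#' @return invisibly, the full results table sorted by q within metric.
#' @export
summary.diff_screen <- function(object, n = 5, ...) {
  print(object)
  res <- object$results[order(object$results$metric, object$results$q), ]
  for (mt in object$metrics) {
    cat("\nTop strains by", mt, ":\n")
    print(utils::head(res[res$metric == mt,
                          c("strain_id", "n_ut", "n_uvr", "t", "p", "q",
                            "delta_z", "direction")], n),
          row.names = FALSE, digits = 3)
  }
  invisible(res)
}

#' Volcano-style plot of a differential screen
#'
#' Plots `delta_z` against `-log10(q)` for one metric, marking nominated
#' strains.
#'
#' @param x a `diff_screen`.
#' @param metric which metric to plot.
#' @param ... passed to `plot()`.
#' @export
plot.diff_screen <- function(x, metric = x$metrics[1], ...) {
  r <- x$results[x$results$metric == metric, ]
  plot(r$delta_z, -log10(pmax(r$q, 1e-300)),
       xlab = expression(Delta * "Z (treated - untreated)"),
       ylab = expression(-log[10] * "(q)"),
       main = paste("Differential screen:", metric),
       col = ifelse(r$nominated, "firebrick", "grey50"), pch = 16, cex = 0.6, ...)
  graphics::abline(h = -log10(x$q_cutoff), lty = 2)
  invisible(x)
}
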