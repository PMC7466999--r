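#' Read a GMT gene-set file
#'
#' Thin wrapper over `fgsea::gmtPathways()`; term descriptions (the second
#' GMT column) are kept as an attribute.
#'
#' @param path GMT file path.
#' @return named list of character vectors (term id -> member genes).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .gs_stop("missing_input", "GMT file not found: %s", path)
  sets <- fgsea::gmtPathways(path)
  lines <- strsplit(readLines(path), "\t")
  attr(sets, "term_name") <- stats::setNames(
    vapply(lines, function(x) x[2], character(1)),
    vapply(lines, function(x) x[1], character(1)))
  sets
}

#' Restrict gene sets to the screen universe
#'
#' Genes not present in the screen carry no information for enrichment;
#' every term is intersected with the universe and empty terms are dropped.
#'
#' @param sets named list of gene-id vectors.
#' @param universe character vector of screened gene ids.
#' @return restricted named list.
#' @export
restrict_to_universe <- function(sets, universe) {
  if (!length(universe)) .gs_stop("empty_input", "empty universe")
  out <- lapply(sets, function(s) intersect(unique(s), universe))
  out[lengths(out) > 0]
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= x)` for X hypergeometric: `N` genes drawn without replacement
#' from a universe of `K` genes of which `M` carry the annotation. This is
#' the enrichment p-value for observing `x` or more annotated genes among
#' the nominated set.
#'
#' @param x overlap count.
#' @param M annotated genes in the universe.
#' @param K universe size.
#' @param N nominated (drawn) genes.
#' @return p-value in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(x, M, K, N) {
  if (M > K || N > K || x < 0 || x > min(N, M) || any(c(x, M, K, N) < 0))
    .gs_stop("parameter_error", "invalid hypergeometric parameters (x=%g M=%g K=%g N=%g)",
             x, M, K, N)
  stats::phyper(x - 1, M, K - M, N, lower.tail = FALSE)
}

#' Fold enrichment
#'
#' Frequency of the term among nominated genes divided by its frequency in
#' the whole screen: `(x / N) / (M / K)`.
#'
#' @inheritParams hypergeom_upper_tail
#' @return ratio >= 0.
#' @export
fold_enrichment <- function(x, M, K, N) {
  stopifnot(N > 0, M > 0, K > 0)
  (x / N) / (M / K)
}

#' Gene-set enrichment of a nominated strain set
#'
#' Per term: hypergeometric upper-tail p-value and fold enrichment of the
#' overlap between the nominated set and the term, after restricting both
#' to the screen universe; Storey q-values across all tested terms; terms
#' with `q < q_cutoff` flagged significant. Results are sorted by p.
#'
#' @param nominated character vector of nominated gene ids.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all screened gene ids.
#' @param q_cutoff significance threshold (default 0.05).
#' @param min_term_size drop terms with fewer in-universe members
#'   (default 1 = no filter).
#' @return object of class `enrichment_result`: data.frame with columns
#'   `term_id`, `term_name`, `x`, `N`, `M`, `K`, `p`, `q`, `fold`,
#'   `significant`.
#' @export
enrich <- function(nominated, sets, universe, q_cutoff = 0.05, min_term_size = 1L) {
  nm <- attr(sets, "term_name")
  universe <- unique(universe)
  nominated <- intersect(unique(nominated), universe)
  sets <- restrict_to_universe(sets, universe)
  sets <- sets[lengths(sets) >= min_term_size]
  K <- length(universe); N <- length(nominated)
  if (N == 0 || !length(sets)) {
    warning("empty nominated set or no testable terms")
    out <- data.frame(term_id = character(), term_name = character(),
                      x = integer(), N = integer(), M = integer(), K = integer(),
                      p = numeric(), q = numeric(), fold = numeric(),
                      significant = logical())
    return(structure(out, class = c("enrichment_result", "data.frame")))
  }
  x <- vapply(sets, function(s) length(intersect(s, nominated)), integer(1))
  M <- lengths(sets)
  p <- vapply(seq_along(sets), function(i) hypergeom_upper_tail(x[i], M[i], K, N),
              numeric(1))
  q <- as.numeric(storey_qvalues(p))
  fold <- (x / N) / (M / K)
  out <- data.frame(term_id = names(sets),
                    term_name = if (!is.null(nm)) unname(nm[names(sets)]) else names(sets),
                    x = x, N = N, M = M, K = K, p = p, q = q, fold = fold,
                    significant = q < q_cutoff, stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), ]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, n = 10, ...) {
  cat("Gene-set enrichment:", nrow(x), "terms tested,",
      sum(x$significant), "significant\n")
  if (nrow(x)) print.data.frame(utils::head(x, n), digits = 3, row.names = FALSE)
  invisible(x)
}
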