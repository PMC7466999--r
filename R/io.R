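#' Write a pipeline CSV with a provenance header
#'
#' All pipeline outputs carry a `# config_hash:` comment line so a result
#' file can be traced to the exact configuration that produced it; readers
#' skip comment lines.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param config optional list; its MD5 hash is recorded in the header.
#' @return invisibly, `path`.
#' @export
write_pipeline_csv <- function(df, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config))
    writeLines(sprintf("# config_hash: %s", .config_hash(config)), con)
  # %.17g guarantees a lossless double round-trip
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_hash <- function(config) {
  config <- config[setdiff(names(config), "output_dir")]  # hash the analysis, not the destination
  tf <- tempfile()
  on.exit(unlink(tf))
  dput(config[order(names(config))], file = tf)
  unname(tools::md5sum(tf))
}

#' Read a pipeline CSV (skipping provenance comments)
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_pipeline_csv <- function(path) {
  if (!file.exists(path)) .gs_stop("missing_input", "file not found: %s", path)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a plate key
#'
#' The mapping from (plate, row, column) grid positions to strain ids, with
#' 1-based row/column as in all written files. Duplicate positions are an
#' error (named in the message); duplicate strains are allowed -- they are
#' extra replicates.
#'
#' @param path CSV with columns `plate_id`, `row`, `col`, `strain_id`.
#' @return validated data.frame.
#' @export
read_plate_key <- function(path) {
  key <- read_pipeline_csv(path)
  req <- c("plate_id", "row", "col", "strain_id")
  miss <- setdiff(req, names(key))
  if (length(miss))
    .gs_stop("schema_error", "plate key lacks columns: %s", paste(miss, collapse = ", "))
  pk <- paste(key$plate_id, key$row, key$col, sep = "/")
  if (anyDuplicated(pk))
    .gs_stop("key_collision", "duplicate (plate,row,col) rows: %s",
             paste(unique(pk[duplicated(pk)]), collapse = ", "))
  key
}

#' Read a deposited replicate metric table
#'
#' Reads pre-processed (spatially corrected, normalized) replicate colony
#' metrics in a deposited-supplementary-file layout and maps its columns
#' onto the replicate table consumed by [differential_screen()]. The column
#' mapping is configurable because deposited layouts vary.
#'
#' @param path CSV/TSV path (delimiter sniffed from the extension).
#' @param mapping named character vector mapping the required fields
#'   (`strain_id`, `condition`, `replicate`, `lag_v_stall`,
#'   `colony_fitness`) to column names in the file.
#' @param condition_levels optional length-2 named vector recoding the
#'   file's condition labels to `untreated` / `treated`.
#' @return replicate table data.frame.
#' @export
read_supplementary_table <- function(path,
                                     mapping = c(strain_id = "strain_id",
                                                 condition = "condition",
                                                 replicate = "replicate",
                                                 lag_v_stall = "lag_v_stall",
                                                 colony_fitness = "colony_fitness"),
                                     condition_levels = NULL) {
  if (!file.exists(path)) .gs_stop("missing_input", "file not found: %s", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- tryCatch(
    utils::read.csv(path, sep = sep, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) .gs_stop("schema_error", "unreadable table %s: %s",
                                 path, conditionMessage(e)))
  if (!nrow(df) || !ncol(df)) .gs_stop("schema_error", "empty table: %s", path)
  miss <- setdiff(unname(mapping), names(df))
  if (length(miss))
    .gs_stop("schema_error",
             "unmapped columns: %s (file has: %s); adjust `mapping`",
             paste(miss, collapse = ", "), paste(names(df), collapse = ", "))
  out <- df[unname(mapping)]
  names(out) <- names(mapping)
  extra <- setdiff(names(df), unname(mapping))
  out <- cbind(out, df[extra])
  if (!is.null(condition_levels))
    out$condition <- unname(condition_levels[as.character(out$condition)])
  out
}

#' Read a pipeline run configuration
#'
#' YAML key-value file holding paths, crop rectangles, grid anchors and all
#' tunables (smoothing window, minimum replicates, analysis hours, q
#' cutoff, seed). Missing tunables take the documented defaults.
#'
#' @param path YAML file.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .gs_stop("missing_input", "config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(smooth_window = 48L, min_reps = 6L, max_hours = 40,
                   q_cutoff = 0.05, seed = 1L, spatial = TRUE)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (cfg$q_cutoff < 0 || cfg$q_cutoff > 1 || cfg$min_reps < 1 || cfg$max_hours <= 0)
    .gs_stop("config_error", "tunable outside documented range")
  structure(cfg, class = "run_config")
}
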