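#' Render a simulated plate as a time-lapse image series
#'
#' Draws each colony as a flat disk (radius `colony_radius` px) centered on
#' its grid position, with uniform pixel values summing exactly to the
#' colony's programmed intensity (noiseless truth times the plate bias
#' field), on a constant background with optional Gaussian pixel noise.
#' Frames align with the experiment's timepoints, so
#' [quantify_plate()] + [compute_growth_metrics()] on the rendered series
#' can be compared against the curve-level pipeline and the programmed
#' ground truth.
#'
#' @param experiment a `sim_experiment`.
#' @param plate_id which plate to render.
#' @param frames integer frame indices (default: all).
#' @param spacing_px center-to-center colony spacing.
#' @param margin_px margin around the outermost centers.
#' @param colony_radius disk radius in px; must satisfy
#'   `2 * colony_radius <= spacing_px` (else a layout error).
#' @param background constant background level.
#' @param noise_sd Gaussian pixel noise sd (0 = noiseless); seeded from the
#'   experiment seed per frame, so rendering is deterministic.
#' @return list of `plate_image` frames; attribute `grid_anchors` gives the
#'   4 x 2 corner-anchor matrix and `centers` the colony centers used.
#' @export
render_plate_images <- function(experiment, plate_id, frames = NULL,
                                spacing_px = 10, margin_px = 20,
                                colony_radius = 3.5, background = 2,
                                noise_sd = 20) {
  stopifnot(inherits(experiment, "sim_experiment"))
  if (2 * colony_radius > spacing_px)
    .gs_stop("layout_error", "colony radius %.1f overlaps spacing %d px",
             colony_radius, spacing_px)
  sel <- which(experiment$colonies$plate_id == plate_id)
  if (!length(sel)) .gs_stop("missing_input", "unknown plate_id: %s", plate_id)
  if (is.null(frames)) frames <- seq_along(experiment$times)
  co <- experiment$colonies[sel, ]
  nr <- max(co$row); nc <- max(co$col)
  h <- 2 * margin_px + (nr - 1) * spacing_px + 1
  w <- 2 * margin_px + (nc - 1) * spacing_px + 1

  off <- expand.grid(dr = -floor(colony_radius):floor(colony_radius),
                     dc = -floor(colony_radius):floor(colony_radius))
  off <- off[off$dr^2 + off$dc^2 <= colony_radius^2, ]
  npx <- nrow(off)

  centers_row <- margin_px + (co$row - 1) * spacing_px  # 0-based px coords
  centers_col <- margin_px + (co$col - 1) * spacing_px
  Q <- experiment$truth[, sel, drop = FALSE] *
    matrix(co$bias, length(experiment$times), length(sel), byrow = TRUE)

  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    px <- matrix(background, h, w)
    for (ci in seq_along(sel)) {
      if (Q[f, ci] <= 0) next
      rr <- centers_row[ci] + off$dr + 1L
      cc <- centers_col[ci] + off$dc + 1L
      px[cbind(rr, cc)] <- px[cbind(rr, cc)] + Q[f, ci] / npx
    }
    if (noise_sd > 0) {
      set.seed(.substream_seed(experiment$config$seed,
                               paste("render", plate_id, f, sep = ":")))
      px <- pmax(px + matrix(stats::rnorm(h * w, 0, noise_sd), h, w), 0)
    }
    out[[fi]] <- plate_image(px, frame_index = f)
  }
  attr(out, "grid_anchors") <- rbind(
    c(margin_px, margin_px),
    c(margin_px, margin_px + (nc - 1) * spacing_px),
    c(margin_px + (nr - 1) * spacing_px, margin_px),
    c(margin_px + (nr - 1) * spacing_px, margin_px + (nc - 1) * spacing_px))
  attr(out, "layout") <- c(nrow = nr, ncol = nc)
  attr(out, "programmed") <- Q[frames, , drop = FALSE]
  out
}

#' Write rendered frames as TIFF files
#'
#' Writes one 16-bit grayscale TIFF per frame (`frame_###.tif`), scaling
#' pixel values by `scale` into \[0, 1\] (the analysis is scale-invariant).
#'
#' @param frames list of `plate_image`s.
#' @param dir output directory (created if needed).
#' @param scale divisor; default the global maximum over all frames.
#' @return invisibly, the file paths written.
#' @export
write_tiff_series <- function(frames, dir, scale = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(scale)) scale <- max(vapply(frames, function(f) max(f$pixels), numeric(1)), 1e-9)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    paths[i] <- file.path(dir, sprintf("frame_%04d.tif", frames[[i]]$frame_index))
    tiff::writeTIFF(pmin(frames[[i]]$pixels / scale, 1), paths[i], bits.per.sample = 16)
  }
  invisible(paths)
}
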