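#' Fit a colony grid from corner anchors
#'
#' Places an `n_rows` x `n_cols` lattice of colony centers by bilinear
#' interpolation between four manually supplied corner anchors, the standard
#' practice for high-density arrays where automatic gridding is unreliable.
#' The returned grid is fitted once per plate and reused for every frame of
#' the series.
#'
#' @param image a `plate_image` (see [plate_image()]), used to validate that
#'   anchors fall inside the crop.
#' @param n_rows,n_cols grid dimensions (e.g. 64 x 96 for 6144 format).
#' @param corner_anchors 4 x 2 numeric matrix of (row, col) pixel coordinates
#'   ordered top-left, top-right, bottom-left, bottom-right (0-based, in crop
#'   coordinates).
#' @param window_radius half-width in pixels of the square measurement window
#'   around each center. Defaults to just under half the minimal center
#'   spacing.
#' @return an object of class `grid_spec` with elements `n_rows`, `n_cols`,
#'   `centers_row`, `centers_col` (n_rows x n_cols matrices of pixel
#'   coordinates) and `window_radius`.
#' @export
fit_grid <- function(image, n_rows, n_cols, corner_anchors, window_radius = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  a <- as.matrix(corner_anchors)
  if (!all(dim(a) == c(4, 2))) .gs_stop("invalid_grid", "corner_anchors must be 4 x 2 (row, col)")
  cr <- image$crop_rect
  h <- cr[2] - cr[1]; w <- cr[4] - cr[3]
  if (any(a[, 1] < 0 | a[, 1] > h - 1 | a[, 2] < 0 | a[, 2] > w - 1))
    .gs_stop("invalid_grid", "corner anchors fall outside the crop rectangle")
  u <- if (n_rows > 1) (seq_len(n_rows) - 1) / (n_rows - 1) else 0
  v <- if (n_cols > 1) (seq_len(n_cols) - 1) / (n_cols - 1) else 0
  U <- matrix(u, n_rows, n_cols)
  V <- matrix(v, n_rows, n_cols, byrow = TRUE)
  bil <- function(k) {
    (1 - U) * (1 - V) * a[1, k] + (1 - U) * V * a[2, k] +
      U * (1 - V) * a[3, k] + U * V * a[4, k]
  }
  centers_row <- bil(1)
  centers_col <- bil(2)
  sp <- Inf
  if (n_cols > 1) sp <- min(sp, min(sqrt(diff(t(centers_row))^2 + diff(t(centers_col))^2)))
  if (n_rows > 1) sp <- min(sp, min(sqrt(diff(centers_row)^2 + diff(centers_col)^2)))
  if (is.finite(sp) && sp < 2) .gs_stop("invalid_grid", "implied center spacing < 2 px")
  if (is.null(window_radius)) window_radius <- max(1L, floor((min(sp, h, w) - 1) / 2))
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 centers_row = centers_row, centers_col = centers_col,
                 window_radius = as.integer(window_radius)),
            class = "grid_spec")
}

#' Construct a plate image
#'
#' Wraps a nonnegative grayscale raster with its frame index (frame 1 at
#' t = 0; frames are 5 minutes apart) and an optional crop rectangle
#' `c(row0, row1, col0, col1)` (half-open, 0-based). Pixels outside the crop
#' are discarded.
#'
#' @param pixels numeric matrix, all values >= 0.
#' @param frame_index integer >= 1.
#' @param crop_rect optional; default is the whole raster.
#' @return object of class `plate_image` with the cropped `pixels`,
#'   `frame_index` and `crop_rect`.
#' @export
plate_image <- function(pixels, frame_index = 1L, crop_rect = NULL) {
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    .gs_stop("invalid_image", "pixel values must be finite and >= 0")
  if (is.null(crop_rect)) crop_rect <- c(0L, nrow(pixels), 0L, ncol(pixels))
  if (crop_rect[1] < 0 || crop_rect[3] < 0 ||
      crop_rect[2] > nrow(pixels) || crop_rect[4] > ncol(pixels) ||
      crop_rect[2] <= crop_rect[1] || crop_rect[4] <= crop_rect[3])
    .gs_stop("invalid_image", "crop_rect must lie inside the raster")
  px <- pixels[(crop_rect[1] + 1):crop_rect[2], (crop_rect[3] + 1):crop_rect[4], drop = FALSE]
  structure(list(pixels = px, frame_index = as.integer(frame_index),
                 crop_rect = crop_rect),
            class = "plate_image")
}

#' Smooth a plate image by Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing: intensity diffuses between 4-neighbors with
#' conductivity `g(d) = exp(-(d / kappa)^2)` on the intensity difference `d`,
#' so colony borders (large gradients) are preserved while background and
#' in-colony noise are averaged out. The update is written in flux form
#' (equal and opposite exchange across each pixel edge, Neumann boundary),
#' so the total image intensity is conserved exactly.
#'
#' @param image a `plate_image` or plain numeric matrix.
#' @param n_iter number of diffusion iterations (0 returns the input).
#' @param conduction gradient scale `kappa`; `NULL` (default) sets it to 10%
#'   of the image's dynamic range (the named-routine default), well below
#'   colony-border gradients and well above pixel-noise gradients.
#' @return same type as the input, smoothed.
#' @export
smooth_image <- function(image, n_iter = 5L, conduction = NULL) {
  is_pi <- inherits(image, "plate_image")
  x <- if (is_pi) image$pixels else as.matrix(image)
  stopifnot(n_iter >= 0)
  if (n_iter > 0 && nrow(x) > 1 && ncol(x) > 1) {
    if (is.null(conduction)) {
      conduction <- 0.1 * (max(x) - min(x))
      if (conduction <= 0) conduction <- 1
    }
    lambda <- 0.25
    for (i in seq_len(n_iter)) {
      dv <- diff(x)                       # x[r+1,] - x[r,]
      dh <- t(diff(t(x)))                 # x[,c+1] - x[,c]
      fv <- lambda * exp(-(dv / conduction)^2) * dv
      fh <- lambda * exp(-(dh / conduction)^2) * dh
      x[-nrow(x), ] <- x[-nrow(x), ] + fv
      x[-1, ]       <- x[-1, ]       - fv
      x[, -ncol(x)] <- x[, -ncol(x)] + fh
      x[, -1]       <- x[, -1]       - fh
    }
  }
  if (is_pi) { image$pixels <- x; image } else x
}

# Mode of the integer-binned intensity histogram (lowest bin on ties).
.background_mode <- function(w) {
  b <- tabulate(floor(w) + 1L)
  which.max(b) - 1L
}

#' Segment a colony in a grid window by half-mode-max thresholding
#'
#' The threshold is the midpoint between the background mode and the window
#' maximum: `T = mode + (max - mode) / 2`, the half-mode-max rule. By
#' default the background mode is the mode of the window's integer-binned
#' intensity histogram; on high-density arrays a mature colony can occupy
#' half the window and its flat plateau then wins the window histogram, so
#' [quantify_plate()] estimates the mode once per *frame* (where background
#' always dominates) and passes it via `background`. Pixels above `T` are
#' candidate colony pixels; the mask is restricted to the 4-connected
#' component containing (or nearest to) the window center, so bright specks
#' elsewhere in the window are excluded. A flat window yields an empty mask
#' (no colony).
#'
#' @param window numeric matrix, the square sub-raster around a grid center.
#' @param background background level; default the window's histogram mode.
#' @return logical matrix of the same shape.
#' @export
segment_colony <- function(window, background = NULL) {
  window <- as.matrix(window)
  bg <- if (is.null(background)) .background_mode(window) else background
  mx <- max(window)
  thr <- bg + (mx - bg) / 2
  if (mx <= bg || !any(window > thr)) return(matrix(FALSE, nrow(window), ncol(window)))
  lab <- EBImage::bwlabel(window > thr)
  lab <- matrix(as.integer(lab), nrow(window), ncol(window))
  cr <- (nrow(window) + 1) / 2; cc <- (ncol(window) + 1) / 2
  ctr_lab <- lab[round(cr), round(cc)]
  if (ctr_lab == 0) {
    idx <- which(lab > 0, arr.ind = TRUE)
    d <- sqrt((idx[, 1] - cr)^2 + (idx[, 2] - cc)^2)
    dmin <- min(d)
    cand <- unique(lab[idx[d <= dmin + 1e-9, , drop = FALSE]])
    if (length(cand) > 1) {  # tie: choose the larger-area component
      areas <- vapply(cand, function(l) sum(lab == l), integer(1))
      cand <- cand[order(-areas, cand)]
    }
    ctr_lab <- cand[1]
  }
  lab == ctr_lab
}

#' Measure a segmented colony
#'
#' @param window numeric matrix (same window passed to [segment_colony()]).
#' @param mask logical matrix of identical shape.
#' @return list with `area` (pixel count) and `intensity` (sum of window
#'   values over the mask).
#' @export
measure_colony <- function(window, mask) {
  stopifnot(all(dim(window) == dim(mask)))
  list(area = sum(mask), intensity = sum(window[mask]))
}

#' Quantify a time-lapse plate series
#'
#' For every frame and grid position: smooth the frame
#' ([smooth_image()]), segment the colony in the window around the grid
#' center ([segment_colony()]) and record its area and summed pixel
#' intensity ([measure_colony()]). Returns raw (spatially uncorrected)
#' matrices; apply [spatial_correct()] per frame afterwards.
#'
#' @param series list of `plate_image` frames sharing one crop.
#' @param grid a `grid_spec` from [fit_grid()].
#' @param smooth logical; apply anisotropic diffusion before segmentation.
#' @param n_iter diffusion iterations passed to [smooth_image()].
#' @param plate_id,condition identity metadata stored on the result.
#' @return object of class `plate_measurement_grid`: list with `intensity`
#'   and `area` (lists of n_rows x n_cols matrices, one per frame),
#'   `frame_index`, `plate_id`, `condition`, `corrected = FALSE`.
#' @export
quantify_plate <- function(series, grid, smooth = TRUE, n_iter = 5L,
                           plate_id = "plate1", condition = "untreated") {
  stopifnot(inherits(grid, "grid_spec"))
  dims <- dim(series[[1]]$pixels)
  r <- grid$window_radius
  n_fr <- length(series)
  intensity <- vector("list", n_fr); area <- vector("list", n_fr)
  for (f in seq_len(n_fr)) {
    im <- series[[f]]
    if (!all(dim(im$pixels) == dims))
      .gs_stop("series_inconsistency", "frame %d has mismatched crop dimensions", f)
    px <- if (smooth) smooth_image(im$pixels, n_iter = n_iter) else im$pixels
    frame_bg <- .background_mode(px)
    I <- matrix(0, grid$n_rows, grid$n_cols)
    A <- matrix(0L, grid$n_rows, grid$n_cols)
    for (i in seq_len(grid$n_rows)) for (j in seq_len(grid$n_cols)) {
      cr0 <- round(grid$centers_row[i, j]) + 1L  # to 1-based matrix index
      cc0 <- round(grid$centers_col[i, j]) + 1L
      rr <- max(1L, cr0 - r):min(nrow(px), cr0 + r)
      cc <- max(1L, cc0 - r):min(ncol(px), cc0 + r)
      w <- px[rr, cc, drop = FALSE]
      m <- segment_colony(w, background = frame_bg)
      meas <- measure_colony(w, m)
      I[i, j] <- meas$intensity
      A[i, j] <- meas$area
    }
    intensity[[f]] <- I; area[[f]] <- A
  }
  structure(list(intensity = intensity, area = area,
                 frame_index = vapply(series, function(s) s$frame_index, integer(1)),
                 plate_id = plate_id, condition = condition, corrected = FALSE),
            class = "plate_measurement_grid")
}

# Moving-window median filter over grid positions, edge-truncated window.
.moving_median <- function(m, half = 4L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    ri <- max(1, i - half):min(nr, i + half)
    for (j in seq_len(nc)) {
      cj <- max(1, j - half):min(nc, j + half)
      out[i, j] <- stats::median(m[ri, cj], na.rm = TRUE)
    }
  }
  out
}

#' Spatially correct a plate intensity matrix
#'
#' Two-stage multiplicative correction of position-dependent artifacts.
#' *Border stage*: colonies in the outermost `border` rows/columns overgrow
#' (more nutrient access); their values are rescaled by
#' `median(interior) / median(border)` so the border median matches the
#' interior. *Spatial stage*: a smooth surface `S` is estimated by a moving
#' `window` x `window` median filter (edge-truncated) over the
#' border-adjusted matrix, and each value `v` becomes
#' `v * median(S) / S[pos]`, removing plate-scale gradients while preserving
#' the plate median.
#'
#' @param grid_values numeric matrix of colony intensities (finite, >= 0;
#'   positions without a colony may be `NA` and are passed through).
#' @param window odd moving-median window size in grid positions.
#' @param border number of outermost rows/columns treated as border.
#' @return corrected matrix; attribute `warning_flag` is `TRUE` when the
#'   input was all zeros and returned unchanged.
#' @export
spatial_correct <- function(grid_values, window = 9L, border = 2L) {
  m <- as.matrix(grid_values)
  ok <- !is.na(m)
  if (any(!is.finite(m[ok])) || any(m[ok] < 0))
    .gs_stop("invalid_matrix", "grid values must be finite and >= 0")
  if (all(m[ok] == 0)) {
    attr(m, "warning_flag") <- TRUE
    return(m)
  }
  nr <- nrow(m); nc <- ncol(m)
  bmask <- matrix(FALSE, nr, nc)
  b <- min(border, floor((min(nr, nc) - 1) / 2))
  if (b > 0) {
    bmask[c(seq_len(b), nr - seq_len(b) + 1L), ] <- TRUE
    bmask[, c(seq_len(b), nc - seq_len(b) + 1L)] <- TRUE
  }
  if (any(bmask & ok) && any(!bmask & ok)) {
    med_b <- stats::median(m[bmask], na.rm = TRUE)
    med_i <- stats::median(m[!bmask], na.rm = TRUE)
    if (med_b > 0) m[bmask] <- m[bmask] * med_i / med_b
  }
  S <- .moving_median(m, half = (window - 1L) %/% 2L)
  medS <- stats::median(S, na.rm = TRUE)
  f <- ifelse(!is.na(S) & S > 0, medS / S, 1)
  out <- m * f
  attr(out, "warning_flag") <- FALSE
  out
}

#' Read a TIFF frame series
#'
#' Accepts either a directory of single-frame grayscale TIFFs (frame order =
#' lexicographic file order) or one multi-page TIFF. Pixel values are used as
#' stored (the `tiff` package returns [0, 1] floats for integer TIFFs; the
#' analysis is scale-invariant).
#'
#' @param path directory or file path.
#' @param crop_rect optional crop passed to [plate_image()].
#' @return list of `plate_image` frames.
#' @export
read_plate_series <- function(path, crop_rect = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE, ignore.case = TRUE))
    if (!length(files)) .gs_stop("missing_input", "no TIFF files found in %s", path)
    imgs <- lapply(files, tiff::readTIFF)
  } else {
    if (!file.exists(path)) .gs_stop("missing_input", "file not found: %s", path)
    imgs <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
  }
  lapply(seq_along(imgs), function(f) {
    px <- imgs[[f]]
    if (length(dim(px)) == 3) px <- px[, , 1]  # collapse channels if present
    plate_image(px, frame_index = f, crop_rect = crop_rect)
  })
}

#' Convert plate measurements to a long table
#'
#' @param pmg a `plate_measurement_grid`.
#' @param corrected optional list of corrected matrices (same shape); when
#'   given, an `intensity_corrected` column is added.
#' @return data.frame with columns plate_id, condition, frame, row, col
#'   (1-based), area, intensity_raw (and intensity_corrected).
#' @export
plate_measurements_table <- function(pmg, corrected = NULL) {
  stopifnot(inherits(pmg, "plate_measurement_grid"))
  nr <- nrow(pmg$intensity[[1]]); nc <- ncol(pmg$intensity[[1]])
  n_fr <- length(pmg$intensity)
  df <- data.frame(
    plate_id = pmg$plate_id, condition = pmg$condition,
    frame = rep(pmg$frame_index, each = nr * nc),
    row = rep(rep(seq_len(nr), nc), n_fr),
    col = rep(rep(seq_len(nc), each = nr), n_fr),
    area = unlist(lapply(pmg$area, as.vector)),
    intensity_raw = unlist(lapply(pmg$intensity, as.vector))
  )
  if (!is.null(corrected))
    df$intensity_corrected <- unlist(lapply(corrected, as.vector))
  df
}
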