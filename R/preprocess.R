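# Slice preprocessing: raw section image -> binary image of isolated tubule
# lumens. Steps: grayscale conversion, background removal, global + local
# adaptive equalisation, thresholding, erode/dilate cycles, size filtering.
# All tunable parameters may vary with depth via a sigmoid schedule anchored at
# the cortico-medullary transition zone.

#' Default preprocessing parameters
#'
#' Lumens are assumed bright against dark-stained tubule walls (toluidine-blue
#' convention after grayscale conversion); set `invert = TRUE` for stains with
#' the opposite polarity. `min_area`/`max_area` follow the standard working
#' range for lumen cross sections (components under 10 or over 100000 px are
#' confidently non-lumen); the remaining values are calibration defaults meant
#' to be tuned per dataset.
#'
#' @param background_threshold intensity above which pixels may belong to the
#'   bright glass background surrounding the tissue.
#' @param bg_close_radius disk radius (px) for morphological closing of the
#'   background mask.
#' @param global_eq_window,local_eq_window window sizes (px) for the two
#'   adaptive equalisation passes; a window at least as large as the image
#'   falls back to whole-image equalisation.
#' @param eq_clip histogram clip limit as a multiple of the uniform bin count
#'   (contrast-limited equalisation).
#' @param binary_threshold lumen/background threshold applied after
#'   equalisation.
#' @param erode_dilate_radius,erode_dilate_cycles disk radius and number of
#'   erode-then-dilate cycles removing thin interstitial cross sections.
#' @param min_area,max_area component area bounds in px^2 (inclusive).
#' @param invert flip intensity polarity before thresholding.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(background_threshold = 0.9, bg_close_radius = 2,
                              global_eq_window = 1e6, local_eq_window = 32,
                              eq_clip = 4, binary_threshold = 0.65,
                              erode_dilate_radius = 1, erode_dilate_cycles = 1,
                              min_area = 10, max_area = 100000,
                              invert = FALSE) {
  p <- list(background_threshold = background_threshold,
            bg_close_radius = bg_close_radius,
            global_eq_window = global_eq_window,
            local_eq_window = local_eq_window, eq_clip = eq_clip,
            binary_threshold = binary_threshold,
            erode_dilate_radius = erode_dilate_radius,
            erode_dilate_cycles = erode_dilate_cycles,
            min_area = min_area, max_area = max_area, invert = invert)
  stopifnot(p$min_area < p$max_area, p$bg_close_radius >= 1,
            p$local_eq_window >= 1, p$global_eq_window >= 1)
  class(p) <- "preprocess_params"
  p
}

#' Convert an image to grayscale
#'
#' Colour input (an `h x w x 3` array) is collapsed with the usual luminance
#' weights (0.299, 0.587, 0.114); grayscale input is returned unchanged.
#'
#' @param image numeric matrix or `h x w x 3` array.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3) {
    if (dim(image)[3] == 1) return(image[, , 1])
    if (dim(image)[3] == 3)
      return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
  }
  stop("image must be 2D grayscale or have 1 or 3 channels")
}

disk_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2 + 1e-9, ]
  g
}

label_components <- function(binary) .cc_label(binary)

#' Remove the bright glass background around the tissue
#'
#' Forms a background mask by thresholding, extracting the largest
#' above-threshold connected component, and morphologically closing it with a
#' disk kernel; the mask is then inverted and multiplied onto the image so
#' background pixels become exactly zero while tissue is untouched.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param threshold background intensity threshold.
#' @param close_radius disk radius for closing the mask.
#' @export
remove_background <- function(image, threshold = 0.9, close_radius = 2) {
  cand <- image >= threshold
  if (!any(cand)) {
    warning("no background component found; image returned unchanged")
    return(image)
  }
  lab <- label_components(cand)
  areas <- tabulate(lab[lab > 0])
  mask <- lab == which.max(areas)
  # pad with foreground before closing so the erosion half of the closing
  # cannot eat the mask inward from the image border
  r <- ceiling(close_radius)
  pm <- matrix(TRUE, nrow(mask) + 2 * r, ncol(mask) + 2 * r)
  pm[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] <- mask
  off <- disk_offsets(close_radius)
  pm <- .morph_op(.morph_op(pm, off$dy, off$dx, FALSE), off$dy, off$dx, TRUE)
  mask <- pm[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))]
  image * !mask
}

# Contrast-limited adaptive histogram equalisation on a tile grid sized by
# `window`, with bilinear interpolation of the per-tile mappings. Exact zeros
# (the removed background) are excluded from the histograms and stay zero, so
# the large background region cannot swamp the intensity ranks of the tissue.
adaptive_equalize <- function(image, window, clip = 4, nbins = 256) {
  nr <- nrow(image); nc <- ncol(image)
  ny <- max(1L, floor(nr / window)); nx <- max(1L, floor(nc / window))
  bin <- pmin(pmax(floor(image * nbins) + 1L, 1L), nbins)
  ybrk <- round(seq(0, nr, length.out = ny + 1))
  xbrk <- round(seq(0, nc, length.out = nx + 1))
  maps <- array(0, c(ny, nx, nbins))
  cy <- numeric(ny); cx <- numeric(nx)
  for (ty in seq_len(ny)) for (tx in seq_len(nx)) {
    rows <- (ybrk[ty] + 1):ybrk[ty + 1]; cols <- (xbrk[tx] + 1):xbrk[tx + 1]
    cy[ty] <- mean(rows); cx[tx] <- mean(cols)
    sub <- image[rows, cols]
    h <- tabulate(bin[rows, cols][sub > 0], nbins)
    if (sum(h) == 0) { maps[ty, tx, ] <- seq(0, 1, length.out = nbins); next }
    lim <- clip * sum(h) / nbins
    excess <- sum(pmax(h - lim, 0))
    h <- pmin(h, lim) + excess / nbins
    maps[ty, tx, ] <- cumsum(h) / sum(h)
  }
  # bilinear blend of the 4 surrounding tile mappings, clamped at the borders
  ri <- row(image); ci <- col(image)
  fy <- if (ny == 1) rep(1, length(ri)) else stats::approx(cy, seq_len(ny), ri, rule = 2)$y
  fx <- if (nx == 1) rep(1, length(ci)) else stats::approx(cx, seq_len(nx), ci, rule = 2)$y
  y0 <- pmin(floor(fy), ny - 1L); y0[ny == 1] <- 1L
  x0 <- pmin(floor(fx), nx - 1L); x0[nx == 1] <- 1L
  y1 <- pmin(y0 + 1L, ny); x1 <- pmin(x0 + 1L, nx)
  wy <- pmin(pmax(fy - y0, 0), 1); wx <- pmin(pmax(fx - x0, 0), 1)
  lk <- function(ty, tx) maps[cbind(ty, tx, as.vector(bin))]
  out <- (1 - wy) * (1 - wx) * lk(y0, x0) + (1 - wy) * wx * lk(y0, x1) +
    wy * (1 - wx) * lk(y1, x0) + wy * wx * lk(y1, x1)
  out[image == 0] <- 0
  matrix(out, nr, nc)
}

#' Global and local adaptive histogram equalisation
#'
#' Applies contrast-limited adaptive equalisation twice: first with a large
#' window (global pass, counteracting slow intensity drift), then with a small
#' window (local pass, sharpening lumen/wall contrast). Windows larger than
#' the image fall back to whole-image equalisation.
#'
#' @param image grayscale matrix in \[0, 1\].
#' @param global_window,local_window window sizes in pixels,
#'   `local_window < global_window`.
#' @param clip histogram clip limit (multiple of the uniform bin count).
#' @export
equalize <- function(image, global_window = 1e6, local_window = 32, clip = 4) {
  stopifnot(global_window >= 1, local_window >= 1)
  out <- adaptive_equalize(image, global_window, clip)
  adaptive_equalize(out, local_window, clip)
}

#' Threshold a grayscale image into a binary lumen mask
#'
#' A pixel is foreground iff it lies on the lumen side of the threshold:
#' intensity `>= threshold` under the bright-lumen convention, `<= threshold`
#' when `invert = TRUE`. The threshold is chosen during calibration so that
#' independent lumens do not merge while small cross sections survive.
#'
#' @param image grayscale matrix.
#' @param threshold intensity threshold.
#' @param invert use dark-lumen polarity.
#' @export
binarize <- function(image, threshold, invert = FALSE) {
  if (invert) image <= threshold else image >= threshold
}

#' Morphological erode/dilate cleaning cycles
#'
#' Each cycle erodes then dilates with a disk kernel (a morphological
#' opening), removing components thinner than about twice the radius — thin
#' interstitial tissue cross sections in practice. `cycles = 0` is the
#' identity.
#'
#' @param binary logical matrix.
#' @param radius disk radius in pixels (>= 1).
#' @param cycles number of erode/dilate cycles (>= 0).
#' @export
morph_clean <- function(binary, radius = 1, cycles = 1) {
  stopifnot(radius >= 1, cycles >= 0)
  if (cycles == 0) return(binary)
  off <- disk_offsets(radius)
  for (i in seq_len(cycles))
    binary <- .morph_op(.morph_op(binary, off$dy, off$dx, TRUE),
                        off$dy, off$dx, FALSE)
  binary
}

#' Remove connected components outside an area range
#'
#' Components (4-connected) with area strictly below `min_area` or strictly
#' above `max_area` are removed; all others are kept bit-identical. Idempotent.
#'
#' @param binary logical matrix.
#' @param min_area,max_area inclusive area bounds in px^2.
#' @export
size_filter <- function(binary, min_area = 10, max_area = 100000) {
  stopifnot(min_area < max_area)
  lab <- label_components(binary)
  if (max(lab) == 0) return(binary)
  areas <- tabulate(lab)
  keep <- areas >= min_area & areas <= max_area
  lab > 0 & keep[pmax(lab, 1)]
}

#' Sigmoid parameter schedule
#'
#' Builds a depth schedule for preprocessing parameters. Each named entry is a
#' list with `cortex_value`, `medulla_value`, `inflection_slice` and
#' `steepness`; unscheduled parameters stay at their configured constant. The
#' inflection is placed at the cortico-medullary transition zone, where tubule
#' diameter drops abruptly (roughly 60 um down to 10-15 um), so parameter
#' values are near-constant within the cortex and within the medulla.
#'
#' @param ... named schedule entries, e.g.
#'   `binary_threshold = list(cortex_value = 0.7, medulla_value = 0.6,
#'   inflection_slice = 120, steepness = 0.1)`.
#' @export
sigmoid_schedule <- function(...) {
  entries <- list(...)
  for (e in entries)
    stopifnot(all(c("cortex_value", "medulla_value", "inflection_slice",
                    "steepness") %in% names(e)), e$steepness > 0)
  structure(entries, class = "sigmoid_schedule")
}

#' Evaluate one sigmoid schedule entry at a slice index
#'
#' `value = medulla + (cortex - medulla) * logistic(-steepness * (z - inflection))`:
#' a monotone interpolation that equals the midpoint at the inflection slice
#' and approaches the cortex value for shallow slices and the medulla value
#' for deep ones.
#'
#' @param entry one schedule entry (see [sigmoid_schedule()]).
#' @param slice_index 0-based slice index.
#' @export
sigmoid_value <- function(entry, slice_index) {
  entry$medulla_value + (entry$cortex_value - entry$medulla_value) *
    stats::plogis(-entry$steepness * (slice_index - entry$inflection_slice))
}

params_at_slice <- function(params, schedule, slice_index) {
  if (is.null(schedule)) return(params)
  for (nm in names(schedule))
    params[[nm]] <- sigmoid_value(schedule[[nm]], slice_index)
  params
}

#' Replace defective slices with their nearest intact neighbour
#'
#' A slice may be listed explicitly or flagged automatically when its mean
#' intensity deviates from the stack median by more than `z_cutoff` robust
#' standard deviations (median absolute deviation scale). Each defective slice
#' is replaced by a copy of the nearest non-defective slice, preferring the
#' slice above (lower index) on ties, so the slice count and numbering are
#' preserved.
#'
#' @param stack a `slice_stack`.
#' @param defective 0-based indices, or `NULL` to auto-detect.
#' @param z_cutoff robust z-score cutoff for auto-detection.
#' @return The repaired stack, with attribute `"replaced"` listing the
#'   0-based indices that were replaced.
#' @export
replace_defective_slices <- function(stack, defective = NULL, z_cutoff = 3) {
  n <- n_slices(stack)
  if (is.null(defective)) {
    m <- vapply(stack$slices, mean, numeric(1))
    s <- stats::mad(m)
    defective <- if (s == 0) integer(0) else which(abs(m - stats::median(m)) / s > z_cutoff) - 1L
  }
  stopifnot(all(defective >= 0 & defective < n))
  if (length(defective) >= n) stop("all slices are defective")
  good <- setdiff(0:(n - 1), defective)
  for (z in defective) {
    d <- abs(good - z)
    src <- good[order(d, good)][1]     # nearest; tie prefers lower index
    stack$slices[[z + 1]] <- stack$slices[[src + 1]]
  }
  attr(stack, "replaced") <- as.integer(sort(defective))
  stack
}

#' Preprocess one slice into a binary lumen image
#'
#' Composition of the full per-slice chain: grayscale conversion, background
#' removal, global + local equalisation, thresholding, erode/dilate cleaning
#' and size filtering, with any scheduled parameter evaluated from the sigmoid
#' schedule at `slice_index`.
#'
#' @param image raw slice (matrix or 3-channel array).
#' @param slice_index 0-based slice index (drives the schedule).
#' @param params a [preprocess_params()] list.
#' @param schedule optional [sigmoid_schedule()].
#' @return Logical matrix of lumen pixels.
#' @export
preprocess_slice <- function(image, slice_index = 0,
                             params = preprocess_params(), schedule = NULL) {
  p <- params_at_slice(params, schedule, slice_index)
  img <- to_grayscale(image)
  img <- remove_background(img, p$background_threshold, round(p$bg_close_radius))
  img <- equalize(img, p$global_eq_window, p$local_eq_window, p$eq_clip)
  bin <- binarize(img, p$binary_threshold, p$invert)
  bin <- morph_clean(bin, round(p$erode_dilate_radius), round(p$erode_dilate_cycles))
  size_filter(bin, p$min_area, p$max_area)
}

#' Preprocess a whole stack
#'
#' Optionally repairs defective slices first, then runs [preprocess_slice()]
#' on every slice.
#'
#' @inheritParams preprocess_slice
#' @param stack a `slice_stack`.
#' @param defective passed to [replace_defective_slices()]; `FALSE` (default)
#'   skips the repair step, `NULL` auto-detects.
#' @return List of binary matrices, one per slice.
#' @export
preprocess_stack <- function(stack, params = preprocess_params(),
                             schedule = NULL, defective = FALSE) {
  if (!isFALSE(defective))
    stack <- replace_defective_slices(stack, defective)
  lapply(seq_len(n_slices(stack)) - 1L, function(z)
    preprocess_slice(get_slice(stack, z), z, params, schedule))
}
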