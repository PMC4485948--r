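#' Slice stack container
#'
#' A `slice_stack` holds an ordered set of serial-section images together with
#' the acquisition geometry. Slice index 0 is the shallowest section (kidney
#' surface / cortex end); the index increases with depth towards the papilla.
#' Images are numeric matrices with intensities in \[0, 1\]; `img[row, col]`
#' corresponds to 0-based image coordinates `x = col - 1`, `y = row - 1`.
#'
#' @param slices list of numeric (or logical) matrices, all the same size.
#' @param pixel_size isotropic pixel size in micrometres.
#' @param slice_thickness section thickness in micrometres.
#' @return An object of class `slice_stack`.
#' @export
slice_stack <- function(slices, pixel_size = 1, slice_thickness = 2.5) {
  stopifnot(is.list(slices), length(slices) >= 1,
            pixel_size > 0, slice_thickness > 0)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must have identical dimensions")
  structure(list(slices = slices, pixel_size = pixel_size,
                 slice_thickness = slice_thickness),
            class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<slice_stack> %d slices of %d x %d px; pixel %.3g um, slice %.3g um\n",
              n_slices(x), d[2], d[1], x$pixel_size, x$slice_thickness))
  invisible(x)
}

#' Number of slices in a stack
#' @param stack a `slice_stack`.
#' @export
n_slices <- function(stack) length(stack$slices)

#' Fetch one slice by 0-based index
#' @param stack a `slice_stack`.
#' @param z 0-based slice index.
#' @export
get_slice <- function(stack, z) {
  stopifnot(z >= 0, z < n_slices(stack))
  stack$slices[[z + 1]]
}

# ---- plain-text PGM slice IO -------------------------------------------------
# The environment provides no TIFF/PNG reader for R, so stacks are exchanged as
# directories of ASCII PGM (P2) files named slice_<index>.pgm plus a JSON
# sidecar (meta.json) carrying pixel_size_um / slice_thickness_um.

write_pgm <- function(img, path, maxval = 255L) {
  v <- round(pmin(pmax(img, 0), 1) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  write(t(v), con, ncolumns = ncol(img))
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("not an ASCII PGM (P2) file: ", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3]); maxval <- as.numeric(toks[4])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) stop("corrupt PGM payload in ", path)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE) / maxval
}

#' Write a slice stack to a directory of PGM files
#'
#' Writes one ASCII PGM per slice (`slice_0000.pgm`, ...) plus a `meta.json`
#' sidecar with the acquisition geometry.
#'
#' @param stack a `slice_stack`.
#' @param dir output directory (created if missing).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stack$slices))
    write_pgm(stack$slices[[i]], file.path(dir, sprintf("slice_%04d.pgm", i - 1)))
  jsonlite::write_json(list(pixel_size_um = stack$pixel_size,
                            slice_thickness_um = stack$slice_thickness,
                            n_slices = n_slices(stack)),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a slice stack from a directory of PGM files
#'
#' Slices are ordered by the numeric index embedded in the file name; a gap in
#' the index sequence is an error (the tracker's slice arithmetic assumes
#' contiguous numbering).
#'
#' @param dir directory holding `slice_*.pgm` files and optionally `meta.json`.
#' @export
read_stack <- function(dir) {
  files <- list.files(dir, pattern = "^slice_[0-9]+\\.pgm$", full.names = TRUE)
  if (length(files) == 0) stop("no slice_*.pgm files in ", dir)
  idx <- as.integer(sub("^slice_([0-9]+)\\.pgm$", "\\1", basename(files)))
  o <- order(idx); files <- files[o]; idx <- idx[o]
  expected <- seq(min(idx), max(idx))
  if (!identical(idx, expected))
    stop("missing slice indices: ", paste(setdiff(expected, idx), collapse = ", "))
  slices <- lapply(files, read_pgm)
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  slice_stack(slices,
              pixel_size = meta$pixel_size_um %||% 1,
              slice_thickness = meta$slice_thickness_um %||% 2.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
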