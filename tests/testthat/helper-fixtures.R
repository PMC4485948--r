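# shared fixture builders: simple rasterised shapes and small phantoms

disk_mask <- function(r, size = 2 * r + 10, cx = size / 2, cy = size / 2) {
  m <- matrix(FALSE, size, size)
  m[(row(m) - 1 - cy)^2 + (col(m) - 1 - cx)^2 <= r^2] <- TRUE
  m
}

rect_mask <- function(w, h, size = max(w, h) + 20, x0 = 10, y0 = 10) {
  m <- matrix(FALSE, size, size)
  m[y0 + seq_len(h), x0 + seq_len(w)] <- TRUE
  m
}

square_mask <- function(side, size = side + 20) {
  rect_mask(side, side, size)
}

# straight-tube phantom used by several tracker tests
straight_tube_phantom <- function(n_slices = 30, blanks = integer(0),
                                  misalignment_sd = 0, seed = 5) {
  generate_phantom(phantom_spec(
    image_size = c(96, 96), n_slices = n_slices,
    tubes = list(tube_spec(cortex_radius = 9, medulla_radius = 9,
                           tortuosity = 0.6)),
    blank_slices = blanks, misalignment_sd = misalignment_sd,
    noise_sd = 0.02, seed = seed))
}

features_of <- function(gen, spacing = 30, seed = 1) {
  extract_features(preprocess_stack(gen$stack), max_mean_spacing = spacing,
                   seed = seed)
}

seed_of <- function(gen, tube = 1, row = 1) {
  p <- gen$truth$paths[[tube]][row, ]
  c(p$x, p$y, p$z)
}

# exhaustive longest-path oracle over a parent vector (0 = root marker)
brute_longest_path <- function(parent) {
  n <- length(parent)
  depth_of <- function(i) {
    d <- 0L
    while (i != 0L && !is.na(i)) { d <- d + 1L; i <- parent[i] }
    d
  }
  max(vapply(which(!is.na(parent)), depth_of, integer(1)))
}
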