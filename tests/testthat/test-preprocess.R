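# preprocessing chain: grayscale, background removal, equalisation,
# thresholding, morphology, size filtering, sigmoid schedule, slice repair

test_that("grayscale conversion handles gray, white and single-channel input", {
  g <- matrix(runif(100), 10, 10)
  expect_identical(to_grayscale(g), g)

  white <- array(1, c(8, 8, 3))
  expect_true(all(abs(to_grayscale(white) - 1) < 1e-12))

  blue <- array(0, c(8, 8, 3))
  blue[, , 3] <- matrix(runif(64), 8, 8)
  expect_equal(to_grayscale(blue), 0.114 * blue[, , 3])

  bad <- array(0, c(8, 8, 4))
  expect_error(to_grayscale(bad), "channels")
})

test_that("background removal zeroes the glass and leaves tissue untouched", {
  # tissue disk on a uniform bright background
  img <- matrix(0.95, 60, 60)
  d <- disk_mask(15, 60, 30, 30)
  img[d] <- 0.4
  out <- remove_background(img, threshold = 0.9, close_radius = 2)
  expect_true(all(out[d] == 0.4))
  # background is exactly zero away from the closing margin
  far_bg <- !d & (row(img) - 31)^2 + (col(img) - 31)^2 > 19^2
  expect_true(all(out[far_bg] == 0))

  # image that is entirely tissue: unchanged, with a warning
  tis <- matrix(0.4, 20, 20)
  expect_warning(out2 <- remove_background(tis, threshold = 0.9), "background")
  expect_identical(out2, tis)

  # all-background image -> all zero
  bg <- matrix(0.95, 20, 20)
  expect_true(all(remove_background(bg, threshold = 0.9) == 0))
})

test_that("equalisation increases contrast and respects the intensity range", {
  const <- matrix(0.5, 40, 40)
  expect_equal(max(equalize(const)) - min(equalize(const)), 0)

  two <- matrix(0.2, 40, 40)
  two[, 21:40] <- 0.4
  out <- equalize(two, local_window = 1e6)   # global pass only
  gap_in <- 0.4 - 0.2
  gap_out <- mean(out[, 21:40]) - mean(out[, 1:20])
  expect_gt(gap_out, gap_in)

  noisy <- matrix(runif(64 * 64), 64, 64)
  out2 <- equalize(noisy, local_window = 16)
  expect_gte(min(out2), 0)
  expect_lte(max(out2), 1)
})

test_that("thresholding separates lumens that share a one-pixel wall", {
  img <- matrix(0, 30, 30)
  img[disk_mask(5, 30, 8, 15)] <- 0.9
  img[disk_mask(5, 30, 20, 15)] <- 0.9
  img[, 15] <- pmin(img[, 15], 0.3)   # wall column between the disks
  b <- binarize(img, 0.6)
  expect_length(segment_components(b, 0), 2)

  expect_true(all(binarize(matrix(0.9, 5, 5), 0.6)))
  expect_true(all(binarize(matrix(0.9, 5, 5), 0.6, invert = TRUE) == FALSE))
})

test_that("morphological cleaning removes thin structures, keeps thick ones", {
  line <- matrix(FALSE, 30, 30); line[15, 5:25] <- TRUE
  expect_identical(morph_clean(line, 1, 0), line)       # cycles = 0 identity
  expect_equal(sum(morph_clean(line, 1, 1)), 0)         # 1-px line vanishes

  d <- disk_mask(10)
  opened <- morph_clean(d, 1, 1)
  expect_gt(sum(opened), 0.9 * sum(d))
  expect_lte(sum(opened), sum(d))
})

test_that("size filter applies the inclusive 10 / 100000 px area bounds", {
  m <- matrix(FALSE, 500, 500)
  m[2:4, 2:4] <- TRUE                          # 9 px: removed
  m[10:14, 10:11] <- TRUE                      # 10 px: kept
  m[100:416, 100:415] <- TRUE                  # 317 x 316 = 100172 px: removed
  out <- size_filter(m, 10, 100000)
  expect_false(any(out[2:4, 2:4]))
  expect_true(all(out[10:14, 10:11]))
  expect_false(any(out[100:416, 100:415]))

  big <- matrix(FALSE, 500, 500)
  big[1:400, 1:250] <- TRUE                    # exactly 100000 px: kept
  expect_true(all(size_filter(big, 10, 100000)[1:400, 1:250]))

  empty <- matrix(FALSE, 10, 10)
  expect_identical(size_filter(empty, 10, 100), empty)
})

test_that("size filter is idempotent", {
  set.seed(1)
  for (i in 1:5) {
    m <- matrix(runif(900) < 0.4, 30, 30)
    once <- size_filter(m, 5, 200)
    expect_identical(size_filter(once, 5, 200), once)
  }
})

test_that("sigmoid schedule interpolates between cortex and medulla values", {
  e <- list(cortex_value = 10, medulla_value = 2, inflection_slice = 120,
            steepness = 0.1)
  expect_equal(sigmoid_value(e, 120), 6)                    # midpoint
  expect_lt(abs(sigmoid_value(e, 0) - 10), 0.1)             # cortex asymptote
  expect_lt(abs(sigmoid_value(e, 240) - 2), 0.02)           # medulla asymptote
  v <- vapply(0:240, function(z) sigmoid_value(e, z), numeric(1))
  expect_true(all(diff(v) < 0))                             # monotone
  expect_true(all(v > 2 & v < 10))                          # bounded
})

test_that("defective slices are replaced by their nearest intact neighbour", {
  set.seed(2)
  slices <- lapply(1:10, function(i) matrix(runif(64, 0.3, 0.6), 8, 8))
  st <- slice_stack(slices)

  expect_identical(replace_defective_slices(st, integer(0))$slices, slices)

  rep5 <- replace_defective_slices(st, 5)
  expect_identical(rep5$slices[[6]], slices[[5]])   # copy of slice above
  expect_equal(n_slices(rep5), 10)

  # mean-intensity detector flags an injected near-black slice
  slices[[4]] <- matrix(0.01, 8, 8)
  auto <- replace_defective_slices(slice_stack(slices), NULL)
  expect_equal(attr(auto, "replaced"), 3L)

  expect_error(replace_defective_slices(st, 0:9), "defective")
})

test_that("the composed slice chain isolates exactly the rendered lumens", {
  gen <- generate_phantom(phantom_spec(
    image_size = c(120, 120), n_slices = 1, noise_sd = 0.02, seed = 3,
    tubes = list(
      tube_spec(start = c(30, 30), cortex_radius = 8, medulla_radius = 8,
                tortuosity = 0),
      tube_spec(start = c(85, 35), cortex_radius = 6, medulla_radius = 6,
                tortuosity = 0),
      tube_spec(start = c(55, 85), cortex_radius = 10, medulla_radius = 10,
                tortuosity = 0))))
  b <- preprocess_slice(get_slice(gen$stack, 0))
  cs <- segment_components(b)
  expect_length(cs, 3)
  centers <- t(vapply(cs, function(x) colMeans(x$pixels), numeric(2)))
  truth <- rbind(c(30, 30), c(85, 35), c(55, 85))
  for (i in 1:3)
    expect_lt(min(sqrt((centers[, 1] - truth[i, 1])^2 +
                       (centers[, 2] - truth[i, 2])^2)), 2)

  blank <- matrix(0.95, 60, 60)
  expect_equal(sum(preprocess_slice(blank)), 0)
})

test_that("medulla schedule settings retain small lumens that cortex removes", {
  img <- matrix(0.95, 60, 60)
  img[7:(60 - 7), 7:(60 - 7)] <- 0.45
  img[disk_mask(2, 60, 30, 30)] <- 0.85        # 4-px-diameter lumen
  sched <- sigmoid_schedule(
    erode_dilate_radius = list(cortex_value = 3, medulla_value = 1,
                               inflection_slice = 50, steepness = 0.5))
  cortex <- preprocess_slice(img, 0, schedule = sched)
  medulla <- preprocess_slice(img, 100, schedule = sched)
  expect_equal(sum(cortex), 0)
  expect_gt(sum(medulla), 0)
})

test_that("preprocessed output is binary with all component areas in range", {
  gen <- straight_tube_phantom(4)
  p <- preprocess_params(min_area = 10, max_area = 100000)
  for (z in 0:3) {
    b <- preprocess_slice(get_slice(gen$stack, z), z, p)
    expect_type(b, "logical")
    areas <- vapply(segment_components(b), function(cs) cs$area, integer(1))
    expect_true(all(areas >= 10 & areas <= 100000))
  }
})
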