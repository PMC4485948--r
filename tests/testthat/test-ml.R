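# machine-learned move validation: features, training, voting, persistence

mk_cs <- function(factors, profile, x = 0, y = 0, z = 0) {
  list(factors = factors, profile = profile, x = x, y = y, z = z)
}

test_that("the move descriptor has the documented 66-feature layout", {
  f <- c(1, 0.1, 0.95, 1.2, 150, 13)
  pr <- seq(8, 12, length.out = 24)
  ctx <- list(n_slices = 100, image_diff = 1, dx = 0, dy = 0)

  # self-move: zero differences, zero distance, correlation 1
  v <- extract_move_features(mk_cs(f, pr), mk_cs(f, pr), ctx)
  expect_length(v, 66)
  expect_equal(unname(v[7:12]), rep(0, 6))
  expect_equal(unname(v[13]), 0)
  expect_equal(unname(v[66]), 1)

  # scaled profile: correlation still 1, area difference nonzero
  f2 <- f; f2[5] <- 300
  v2 <- extract_move_features(mk_cs(f, pr), mk_cs(f2, 2 * pr, x = 3), ctx)
  expect_equal(unname(v2[66]), 1)
  expect_true(v2["diff_area"] != 0)

  expect_error(extract_move_features(mk_cs(f, NULL), mk_cs(f, pr), ctx),
               "profile")
})

test_that("swapping parent and child flips differences, preserves the rest", {
  set.seed(21)
  fa <- runif(6); fb <- runif(6)
  pa <- runif(24, 5, 15); pb <- runif(24, 5, 15)
  ctx <- list(n_slices = 50, image_diff = 2, dx = 1, dy = -2)
  ctx_r <- list(n_slices = 50, image_diff = 2, dx = -1, dy = 2)
  v <- extract_move_features(mk_cs(fa, pa, 3, 4, 10), mk_cs(fb, pb, 7, 1, 11),
                             ctx)
  w <- extract_move_features(mk_cs(fb, pb, 7, 1, 11), mk_cs(fa, pa, 3, 4, 10),
                             ctx_r)
  expect_equal(unname(w[7:12]), unname(-v[7:12]))     # differences flip
  expect_equal(unname(w[1:6]), unname(v[1:6]))        # means preserved
  expect_equal(unname(w[13]), unname(v[13]))          # distance preserved
  expect_equal(unname(w[66]), unname(v[66]))          # correlation preserved
})

# class-conditional Gaussian move data: valid moves have small factor
# differences and high profile correlation, invalid ones the opposite
synthetic_moves <- function(n_per_class, seed = 1) {
  set.seed(seed)
  n <- 5 * n_per_class
  centres <- matrix(rnorm(5 * 66, sd = 3), 5, 66)
  X <- matrix(0, n, 66)
  y <- rep(1:5, each = n_per_class)
  for (i in seq_len(n)) X[i, ] <- centres[y[i], ] + rnorm(66, sd = 0.5)
  list(features = X, labels = y)
}

test_that("both model families learn separable 5-class move data", {
  ds <- synthetic_moves(200, seed = 31)
  clfs <- train_move_classifiers(ds, seed = 31, ann_maxit = 200)
  expect_gte(clfs$ann$report$test$multiclass_accuracy, 0.95)
  expect_gte(clfs$svm$report$test$multiclass_accuracy, 0.95)
})

test_that("the data split honours the 0.7 : 0.15 : 0.15 ratio", {
  ds <- synthetic_moves(200, seed = 32)          # 1000 examples
  clf <- train_move_classifiers(ds, families = "ann", seed = 32,
                                ann_maxit = 30)$ann
  # recompute the split the way training does
  set.seed(32)
  idx <- sample(1000)
  expect_length(idx[1:round(0.7 * 1000)], 700)
  expect_length(idx[700 + 1:round(0.15 * 1000)], 150)
  expect_s3_class(clf, "move_classifier")
})

test_that("a class missing from the training split raises a named error", {
  ds <- synthetic_moves(50, seed = 33)
  ds$labels[ds$labels == 4] <- 3
  expect_error(train_move_classifiers(ds, families = "ann", seed = 33,
                                      ann_maxit = 20),
               "4")
})

test_that("voting maps winning classes onto the four decisions", {
  ds <- synthetic_moves(120, seed = 34)
  clf <- train_move_classifiers(ds, families = "svm", seed = 34)$svm
  # classify one fresh example per class, drawn from the same generator
  set.seed(34)
  centres <- matrix(rnorm(5 * 66, sd = 3), 5, 66)
  finals <- vapply(1:5, function(k)
    classify_move(centres[k, ] + rnorm(66, sd = 0.3), clf)$final,
    character(1))
  expect_equal(finals,
               c("valid", "valid", "invalid", "terminate", "region_signal"))
  expect_error(classify_move(numeric(10), clf), "66")
})

test_that("raising the network threshold never turns invalid into valid", {
  ds <- synthetic_moves(120, seed = 35)
  clf <- train_move_classifiers(ds, families = "ann", seed = 35,
                                ann_maxit = 150)$ann
  set.seed(99)
  probe <- ds$features[sample(nrow(ds$features), 100), ]
  ths <- seq(0.1, 0.9, by = 0.2)
  accepted <- vapply(ths, function(th)
    sum(apply(probe, 1, function(v)
      classify_move(v, clf, th)$final == "valid")), integer(1))
  expect_true(all(diff(accepted) <= 0))
})

test_that("duplicating the training set leaves the fitted network unchanged", {
  set.seed(41)
  X <- matrix(rnorm(60 * 8), 60, 8)
  y <- as.numeric(X[, 1] + X[, 2] > 0)
  m1 <- nephtrack:::fit_ann(X, y, hidden = 4, maxit = 80, seed = 2)
  m2 <- nephtrack:::fit_ann(rbind(X, X), c(y, y), hidden = 4, maxit = 80,
                            seed = 2)
  expect_equal(m1$w, m2$w, tolerance = 1e-5)
})

test_that("classifiers round-trip through the archive bit-identically", {
  ds <- synthetic_moves(60, seed = 36)
  clf <- train_move_classifiers(ds, families = "svm", seed = 36)$svm
  tmp <- tempfile(fileext = ".rds")
  write_move_classifier(clf, tmp)
  back <- read_move_classifier(tmp)
  expect_identical(back$learners, clf$learners)
  v <- ds$features[7, ]
  expect_identical(classify_move(v, back), classify_move(v, clf))
})

test_that("capture on an empty tracking run yields an empty example set", {
  gen <- straight_tube_phantom(4)
  f <- features_of(gen)
  g <- track(NULL, f, seed_of(gen), track_config(tracking_radius = 15),
             capture = TRUE)
  g$attempts <- list()
  cap <- capture_training_examples(g, f, function(p, ch) 1L)
  expect_equal(nrow(cap$features), 0)
  expect_length(cap$labels, 0)
})

test_that("phantom capture labels on-tube moves valid, clutter moves class 3", {
  tube <- tube_spec(cortex_radius = 8, medulla_radius = 8, tortuosity = 0.8)
  ph <- phantom_spec(image_size = c(72, 72), n_slices = 25,
                     tubes = list(tube), noise_sd = 0.015, seed = 44)
  gen <- generate_phantom(ph)
  f <- features_of(gen)
  g <- track(NULL, f, seed_of(gen), track_config(tracking_radius = 24),
             capture = TRUE)
  cap <- capture_training_examples(g, f, phantom_labeller(gen$truth, f))
  expect_gt(nrow(cap$features), 0)
  expect_true(all(cap$labels %in% 1:2))   # clutter-free: all moves on-tube

  ph2 <- ph; ph2$clutter_density <- 6; ph2$clutter_near <- c(12, 22)
  gen2 <- generate_phantom(ph2)
  f2 <- features_of(gen2)
  g2 <- track(NULL, f2, seed_of(gen2), track_config(tracking_radius = 24),
              capture = TRUE)
  cap2 <- capture_training_examples(g2, f2, phantom_labeller(gen2$truth, f2))
  expect_gt(sum(cap2$labels == 3), 0)
})
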