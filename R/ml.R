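# Machine-learned move validation: a 66-feature descriptor of a move between
# two cross sections, classified into 5 classes by one-vs-all learners
# (feed-forward neural network and RBF-kernel SVM), combined by a voting
# scheme into valid / invalid / terminate / region-signal decisions.
#
# Classes: 1 normal move between circular cross sections, 2 normal move
# involving elongated cross sections, 3 abnormal move (interstitial tissue or
# blood vessel), 4 glomerulus move (terminates tracking), 5 inner-medulla
# move (region signal switching the tracking mode, not a validity verdict).

MOVE_CLASSES <- c(normal_circular = 1L, normal_elongated = 2L,
                  abnormal = 3L, glomerulus = 4L, inner_medulla = 5L)

#' Extract the 66-feature descriptor of a move
#'
#' Layout: 6 shape-factor means, 6 shape-factor differences (parent minus
#' child), x-y Euclidean distance (offset-corrected), relative z position in
#' the stack (0 = surface, 1 = deepest slice), image difference (1 normally,
#' 2 or 3 across skips), alignment offset dx and dy, the 24 profile radii of
#' each cross section, and the Pearson correlation of the two profiles.
#'
#' @param parent,child lists with fields `factors` (length-6 shape factors),
#'   `profile` (length-24 radii), `x`, `y`, `z`.
#' @param context list with `n_slices`, `image_diff` (1-3), `dx`, `dy`.
#' @return Named numeric vector of length 66.
#' @export
extract_move_features <- function(parent, child, context) {
  if (is.null(parent$profile) || is.null(child$profile))
    stop("both cross sections must carry a shape profile")
  stopifnot(length(parent$factors) == 6, length(child$factors) == 6,
            length(parent$profile) == 24, length(child$profile) == 24,
            context$image_diff %in% 1:3)
  dist_xy <- sqrt((parent$x - (child$x - context$dx))^2 +
                  (parent$y - (child$y - context$dy))^2)
  zrel <- mean(c(parent$z, child$z)) / max(context$n_slices - 1, 1)
  pc <- profile_correlation(parent$profile, child$profile)
  v <- c((parent$factors + child$factors) / 2,
         parent$factors - child$factors,
         dist_xy, zrel, context$image_diff, context$dx, context$dy,
         parent$profile, child$profile, pc)
  names(v) <- c(paste0("mean_", FACTOR_NAMES), paste0("diff_", FACTOR_NAMES),
                "dist_xy", "z_rel", "image_diff", "offset_dx", "offset_dy",
                paste0("p_r", 0:23), paste0("c_r", 0:23), "profile_cor")
  v
}

FACTOR_NAMES <- c("circularity", "eccentricity", "solidity", "aspect_ratio",
                  "area", "minor_axis")

profile_correlation <- function(a, b) {
  if (stats::sd(a) < 1e-9 || stats::sd(b) < 1e-9)
    return(if (stats::sd(a) < 1e-9 && stats::sd(b) < 1e-9) 1 else 0)
  stats::cor(a, b)
}

# move descriptor for two node ids in a stack_features object
extract_move_features_ids <- function(features, i, j, n_slices, dz_total,
                                      off) {
  nd <- features$nodes
  mk <- function(k) list(factors = features$factors[k, ],
                         profile = features$profiles[k, ],
                         x = nd$x[k], y = nd$y[k], z = nd$z[k])
  extract_move_features(mk(i), mk(j),
                        list(n_slices = n_slices,
                             image_diff = abs(dz_total),
                             dx = off[1], dy = off[2]))
}

# ---- learners ---------------------------------------------------------------

# one-hidden-layer feed-forward network with logistic activations, trained by
# L-BFGS on penalised cross-entropy; returns a predict closure over weights
fit_ann <- function(X, y, hidden = 20, maxit = 300, decay = 1e-4, seed = 1) {
  n <- nrow(X); d <- ncol(X)
  n1 <- (d + 1) * hidden; n2 <- hidden + 1
  unpack <- function(w) list(W1 = matrix(w[1:n1], d + 1, hidden),
                             W2 = w[n1 + 1:n2])
  fwd <- function(w, X) {
    p <- unpack(w)
    H <- stats::plogis(cbind(1, X) %*% p$W1)
    list(H = H, out = stats::plogis(cbind(1, H) %*% p$W2)[, 1], p = p)
  }
  loss <- function(w) {
    f <- fwd(w, X)
    eps <- 1e-12
    -sum(y * log(f$out + eps) + (1 - y) * log(1 - f$out + eps)) / n +
      decay * sum(w^2)
  }
  grad <- function(w) {
    f <- fwd(w, X)
    d_out <- (f$out - y) / n                     # n
    gW2 <- crossprod(cbind(1, f$H), d_out)       # (h+1)
    d_h <- outer(d_out, f$p$W2[-1]) * f$H * (1 - f$H)
    gW1 <- crossprod(cbind(1, X), d_h)           # (d+1) x h
    c(as.vector(gW1), as.vector(gW2)) + 2 * decay * w
  }
  set.seed(seed)
  w0 <- stats::runif(n1 + n2, -0.5, 0.5) / sqrt(d)
  fit <- stats::optim(w0, loss, grad, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  list(type = "ann", w = fit$par, hidden = hidden,
       predict = NULL)  # prediction handled by ann_score to keep it serialisable
}

ann_score <- function(model, X) {
  d <- ncol(X); hidden <- model$hidden
  n1 <- (d + 1) * hidden
  W1 <- matrix(model$w[1:n1], d + 1, hidden)
  W2 <- model$w[n1 + 1:(hidden + 1)]
  H <- stats::plogis(cbind(1, X) %*% W1)
  stats::plogis(cbind(1, H) %*% W2)[, 1]
}

rbf_kernel <- function(A, B, width) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-pmax(d2, 0) / (2 * width^2))
}

# soft-margin SVM with RBF kernel via the SMO solver in src/
fit_svm <- function(X, y, width = 5, C = 10, seed = 1) {
  K <- rbf_kernel(X, X, width)
  yy <- ifelse(y > 0, 1, -1)
  set.seed(seed)
  fit <- .smo_train(K, yy, C, 1e-3, 5L, 200L)
  sv <- which(fit$alpha > 1e-8)
  list(type = "svm", X = X[sv, , drop = FALSE],
       coef = fit$alpha[sv] * yy[sv], b = fit$b, width = width)
}

svm_score <- function(model, X) {
  as.vector(rbf_kernel(X, model$X, model$width) %*% model$coef + model$b)
}

learner_score <- function(model, X) {
  if (model$type == "ann") ann_score(model, X) else svm_score(model, X)
}

# ---- training / classification ---------------------------------------------

#' Train the one-vs-all move classifiers
#'
#' Splits the labelled examples into training/validation/test sets, z-scores
#' every feature on the training split only, and fits five one-vs-all binary
#' learners per requested model family: a feed-forward neural network (one
#' hidden layer) and a support vector machine with radial-basis kernel. The
#' report carries per-split 5-class accuracy plus the condensed valid/invalid
#' confusion matrix, accuracy, precision and sensitivity (classes 1-2 =
#' valid, 3-4 = invalid; class 5 is a region label and is excluded from the
#' valid/invalid tally).
#'
#' @param examples list with `features` (n x 66 matrix) and `labels`
#'   (integers 1-5).
#' @param split length-3 ratios for training/validation/test (sum 1).
#' @param families any of `"ann"`, `"svm"`.
#' @param hidden hidden-layer width of the network.
#' @param ann_maxit optimiser iteration cap.
#' @param ann_threshold default acceptance threshold on the winning
#'   valid-class network score.
#' @param rbf_width RBF kernel width (the SVM's sensitivity analogue of the
#'   network threshold).
#' @param svm_cost soft-margin cost parameter.
#' @param seed split/initialisation seed.
#' @return A list of `move_classifier` objects (one per family), each with a
#'   `$report`.
#' @export
train_move_classifiers <- function(examples, split = c(0.7, 0.15, 0.15),
                                   families = c("ann", "svm"), hidden = 20,
                                   ann_maxit = 300, ann_threshold = 0.3,
                                   rbf_width = 5, svm_cost = 10, seed = 1) {
  X <- examples$features; y <- as.integer(examples$labels)
  stopifnot(ncol(X) == 66, length(y) == nrow(X), abs(sum(split) - 1) < 1e-8)
  n <- nrow(X)
  set.seed(seed)
  idx <- sample(n)
  n_tr <- round(split[1] * n); n_va <- round(split[2] * n)
  sets <- list(train = idx[seq_len(n_tr)],
               validation = idx[n_tr + seq_len(n_va)],
               test = idx[(n_tr + n_va + 1):n])
  missing <- setdiff(1:5, unique(y[sets$train]))
  if (length(missing))
    stop("class(es) absent from training split: ",
         paste(missing, collapse = ", "))
  mu <- colMeans(X[sets$train, , drop = FALSE])
  sd_ <- pmax(apply(X[sets$train, , drop = FALSE], 2, stats::sd), 1e-9)
  Z <- sweep(sweep(X, 2, mu), 2, sd_, "/")
  out <- list()
  for (fam in families) {
    learners <- lapply(1:5, function(k) {
      yk <- as.numeric(y[sets$train] == k)
      if (fam == "ann")
        fit_ann(Z[sets$train, , drop = FALSE], yk, hidden, ann_maxit,
                seed = seed + k)
      else
        fit_svm(Z[sets$train, , drop = FALSE], yk, rbf_width, svm_cost,
                seed = seed + k)
    })
    clf <- structure(list(family = fam, mu = mu, sd = sd_,
                          learners = learners, threshold = ann_threshold,
                          rbf_width = rbf_width, hidden = hidden,
                          feature_names = colnames(X) %||%
                            names(extract_move_features_template())),
                     class = "move_classifier")
    clf$report <- classifier_report(clf, Z, y, sets)
    out[[fam]] <- clf
  }
  out
}

extract_move_features_template <- function() {
  blank <- list(factors = numeric(6), profile = numeric(24), x = 0, y = 0,
                z = 0)
  extract_move_features(blank, blank,
                        list(n_slices = 2, image_diff = 1, dx = 0, dy = 0))
}

score_matrix <- function(clf, Z) {
  vapply(clf$learners, function(m) learner_score(m, Z), numeric(nrow(Z)))
}

classifier_report <- function(clf, Z, y, sets) {
  lapply(sets, function(ii) {
    S <- score_matrix(clf, Z[ii, , drop = FALSE])
    pred <- max.col(S)
    truth <- y[ii]
    keep <- truth != 5 & pred != 5   # class 5 is a region label, not validity
    pv <- pred[keep] <= 2; tv <- truth[keep] <= 2
    cm <- table(predicted = factor(pv, c(TRUE, FALSE), c("valid", "invalid")),
                target = factor(tv, c(TRUE, FALSE), c("valid", "invalid")))
    list(multiclass_accuracy = mean(pred == truth),
         confusion = cm,
         accuracy = mean(pv == tv),
         precision = if (sum(pv)) sum(pv & tv) / sum(pv) else NA_real_,
         sensitivity = if (sum(tv)) sum(pv & tv) / sum(tv) else NA_real_)
  })
}

#' @export
print.move_classifier <- function(x, ...) {
  r <- x$report$test
  cat(sprintf(paste0("<move_classifier> family=%s, 5 one-vs-all learners\n",
                     "  test: valid/invalid accuracy %.1f%%, precision %.1f%%,",
                     " sensitivity %.1f%%\n"),
              x$family, 100 * r$accuracy, 100 * r$precision,
              100 * r$sensitivity))
  invisible(x)
}

#' Classify a move
#'
#' Each one-vs-all learner emits a continuous score; the winning class is the
#' argmax (the voting scheme). Winning class 1 or 2 yields `valid`, 3
#' `invalid`, 4 `terminate` (the glomerulus has been reached), 5
#' `region_signal` (inner medulla; switches the tracking mode). For the
#' neural network, a winning valid class is additionally accepted only if its
#' score reaches `threshold`; raising the threshold monotonically increases
#' the sensitivity of invalid-move rejection.
#'
#' @param features length-66 move descriptor.
#' @param classifier a `move_classifier`.
#' @param threshold network acceptance threshold (defaults to the value
#'   stored in the classifier, 0.3).
#' @return List with `final`, `winning_class` and the 5 `class_scores`.
#' @export
classify_move <- function(features, classifier, threshold = NULL) {
  if (length(features) != 66) stop("move descriptor must have 66 features")
  threshold <- threshold %||% classifier$threshold
  z <- (features - classifier$mu) / classifier$sd
  s <- as.vector(score_matrix(classifier, matrix(z, 1)))
  win <- which.max(s)
  final <- c("valid", "valid", "invalid", "terminate", "region_signal")[win]
  if (classifier$family == "ann" && win <= 2 && s[win] < threshold)
    final <- "invalid"
  list(final = final, winning_class = win, class_scores = s)
}

#' Capture labelled training examples from a tracking run
#'
#' Re-expresses every vertical move attempted during a capture-mode tracking
#' run (see `track(capture = TRUE)`) as a 66-feature descriptor and asks the
#' labeller for its class, realising the feedback loop between tracking and
#' training that keeps all five classes represented. In tests the labeller is
#' driven by phantom ground truth; in production it would be a human.
#'
#' @param graph a `track_graph` produced with `capture = TRUE`.
#' @param features the `stack_features` the run used.
#' @param labeller `function(parent_info, child_info)` returning a class in
#'   1-5 or `NA` to drop the example; each info is a list with `x`, `y`, `z`,
#'   `cs`.
#' @return List with `features` (n x 66), `labels`, `class_counts` and
#'   `accepted` flags.
#' @export
capture_training_examples <- function(graph, features, labeller) {
  att <- graph$attempts
  n_sl <- length(features$cs)
  if (length(att) == 0)
    return(list(features = matrix(numeric(0), 0, 66), labels = integer(0),
                class_counts = integer(5), accepted = logical(0)))
  nd <- features$nodes
  info <- function(i) list(x = nd$x[i], y = nd$y[i], z = nd$z[i],
                           cs = nd$cs[i])
  rows <- list(); labels <- integer(0); acc <- logical(0)
  for (a in att) {
    lab <- labeller(info(a$parent), info(a$child))
    if (is.na(lab)) next
    rows[[length(rows) + 1L]] <-
      extract_move_features_ids(features, a$parent, a$child, n_sl,
                                a$image_diff, a$offset)
    labels <- c(labels, as.integer(lab))
    acc <- c(acc, isTRUE(a$accepted))
  }
  X <- if (length(rows)) do.call(rbind, rows) else matrix(numeric(0), 0, 66)
  list(features = X, labels = labels,
       class_counts = tabulate(labels, 5), accepted = acc)
}

#' Save / load a trained move classifier
#'
#' The archive stores the scaler parameters, per-class learner weights or
#' support data, the acceptance threshold and the feature layout, and
#' round-trips bit-identically.
#'
#' @param classifier a `move_classifier`.
#' @param path file path.
#' @export
write_move_classifier <- function(classifier, path) {
  saveRDS(classifier, path)
  invisible(path)
}

#' @rdname write_move_classifier
#' @export
read_move_classifier <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "move_classifier"))
  x
}
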