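# Synthetic serial-section phantoms with known ground truth: densely packed
# tortuous tubes rendered as wall annuli around bright lumens on a tissue
# background, with interstitial-like clutter, artefacts, per-slice
# translational misalignment and intensity noise. Every stage of the pipeline
# is testable against the recorded centerlines and per-pixel labels.

#' Specify one synthetic tube
#'
#' The lumen radius follows a sigmoid schedule narrowing from `cortex_radius`
#' to `medulla_radius` across `transition_slice`, mimicking the abrupt
#' narrowing of the thick descending limb (about 60 um diameter) into the
#' thin limb (10-15 um) at the outer-medullary transition zone. The
#' centerline is a smoothed random walk whose per-slice step scale sets the
#' tortuosity.
#'
#' @param start `(x, y)` of the centerline on slice 0; `NULL` places it
#'   centrally.
#' @param cortex_radius,medulla_radius lumen radii (px) in the two regimes.
#' @param transition_slice,steepness sigmoid schedule of the radius.
#' @param wall wall thickness (px).
#' @param tortuosity standard deviation of the per-slice centerline step (px).
#' @param smooth moving-average window (slices) applied to the walk.
#' @param elongation x-axis stretch factor of the cross section (1 =
#'   circular; ~3 emulates obliquely cut, elongated cross sections).
#' @param glomerulus render a large high-solidity blob at the tube's origin
#'   to exercise class-4 termination. A crude surrogate: real glomeruli are
#'   highly internally segmented.
#' @param glomerulus_slices number of top slices the blob spans.
#' @param hairpin_slice if not `NULL`, the tube descends to this slice and
#'   then ascends again as a parallel limb (loop-of-Henle-like turn).
#' @param lumen_intensity,wall_intensity rendering intensities.
#' @param bounds optional `(x0, y0, x1, y1)` box (px) confining the
#'   centerline, used to keep tubes pairwise separated; an error is raised
#'   when the box cannot contain the tube.
#' @export
tube_spec <- function(start = NULL, cortex_radius = 12, medulla_radius = 4,
                      transition_slice = 120, steepness = 0.1, wall = 3,
                      tortuosity = 1.2, smooth = 9, elongation = 1,
                      glomerulus = FALSE, glomerulus_slices = 5,
                      hairpin_slice = NULL,
                      lumen_intensity = 0.85, wall_intensity = 0.18,
                      bounds = NULL) {
  stopifnot(cortex_radius > 0, medulla_radius > 0, elongation >= 1)
  structure(as.list(environment()), class = "tube_spec")
}

#' Specify a synthetic phantom stack
#'
#' Defaults state the standard test world: a 160 x 160 px, 200-slice stack
#' holding one tortuous tube narrowing 12 -> 4 px at slice 120, with light
#' Gaussian intensity noise and no clutter, artefacts or misalignment unless
#' requested. Everything is reproducible from `seed`.
#'
#' @param image_size `(width, height)` in px.
#' @param n_slices slice count.
#' @param tubes list of [tube_spec()]s.
#' @param clutter_density interstitial-like clutter components per slice
#'   (thin bright bars of area well below the lumen working range).
#' @param artefact_rate probability per slice of a smeared rectangular
#'   artefact painted over the tissue.
#' @param misalignment_sd standard deviation (px) of the per-slice
#'   translational misalignment; shifts are rounded to whole pixels and
#'   recorded in the ground truth.
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param blank_slices 0-based indices rendered without any tube (defective
#'   slices for skip tests).
#' @param clutter_near if not `NULL`, `(dmin, dmax)` px: clutter is placed at
#'   that distance from tube 1's centerline instead of uniformly.
#' @param seed random seed.
#' @export
phantom_spec <- function(image_size = c(160, 160), n_slices = 200,
                         tubes = list(tube_spec()), clutter_density = 0,
                         artefact_rate = 0, misalignment_sd = 0,
                         noise_sd = 0.02, blank_slices = integer(0),
                         clutter_near = NULL, seed = 1) {
  stopifnot(clutter_density >= 0, artefact_rate >= 0, misalignment_sd >= 0,
            noise_sd >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

BG_INT <- 0.95; TISSUE_INT <- 0.45; CLUTTER_INT <- 0.8; MARGIN <- 6

tube_radius_at <- function(tube, z) {
  sigmoid_value(list(cortex_value = tube$cortex_radius,
                     medulla_value = tube$medulla_radius,
                     inflection_slice = tube$transition_slice,
                     steepness = tube$steepness), z)
}

# smoothed 2D random walk of length n, clamped to [lo, hi] per axis
smoothed_walk <- function(n, start, step_sd, window, lo, hi) {
  w <- cbind(cumsum(stats::rnorm(n, 0, step_sd)),
             cumsum(stats::rnorm(n, 0, step_sd)))
  if (window > 1) {
    k <- rep(1 / window, window)
    pad <- function(v) stats::filter(c(rep(v[1], window), v,
                                       rep(v[n], window)), k, sides = 2)[
                                         window + seq_len(n)]
    w <- cbind(pad(w[, 1]), pad(w[, 2]))
  }
  w <- sweep(w, 2, w[1, ])
  cbind(pmin(pmax(start[1] + w[, 1], lo[1]), hi[1]),
        pmin(pmax(start[2] + w[, 2], lo[2]), hi[2]))
}

# tube centerline as a data frame (t, x, y, z, radius); hairpin tubes revisit
# slices on the ascending limb, laterally offset from the descending one
tube_centerline <- function(tube, spec, which_tube) {
  n <- spec$n_slices
  sz <- spec$image_size
  rmax <- max(tube$cortex_radius, tube$medulla_radius) * tube$elongation +
    tube$wall
  lo <- rep(MARGIN + rmax + 2, 2)
  hi <- c(sz[1], sz[2]) - MARGIN - rmax - 2
  if (!is.null(tube$bounds)) {
    lo <- pmax(lo, tube$bounds[1:2] + rmax)
    hi <- pmin(hi, tube$bounds[3:4] - rmax)
  }
  if (any(lo > hi))
    stop("tube cannot fit: requested bounds too tight for its radius")
  start <- tube$start %||% c(sz[1] / 2, sz[2] / 2)
  if (is.null(tube$hairpin_slice)) {
    zs <- 0:(n - 1)
    xy <- smoothed_walk(n, start, tube$tortuosity, tube$smooth, lo, hi)
  } else {
    h <- tube$hairpin_slice
    zs <- c(0:h, h:0)
    xy <- smoothed_walk(length(zs), start, tube$tortuosity, tube$smooth,
                        lo, hi)
    gap <- 2.5 * (tube_radius_at(tube, h) + tube$wall)
    up <- (h + 2):length(zs)
    xy[up, 1] <- pmin(pmax(xy[up, 1] + gap, lo[1]), hi[1])
  }
  data.frame(t = seq_along(zs) - 1, x = xy[, 1], y = xy[, 2], z = zs,
             radius = tube_radius_at(tube, zs), tube = which_tube)
}

# paint an axis-aligned ellipse (and optional wall annulus) into img/lab
paint_cs <- function(img, lab, cx, cy, r, e, wall, tube, label) {
  h <- nrow(img); w <- ncol(img)
  rx <- r * e + wall; ry <- r + wall
  x0 <- max(1, floor(cx - rx)); x1 <- min(w, ceiling(cx + rx) + 1)
  y0 <- max(1, floor(cy - ry)); y1 <- min(h, ceiling(cy + ry) + 1)
  if (x0 > x1 || y0 > y1) return(list(img = img, lab = lab))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- outer(ys * 0, ((xs - 1 - cx) / e)^2, "+")
  dy2 <- outer((ys - 1 - cy)^2, xs * 0, "+")
  d2 <- dx2 + dy2
  wall_m <- d2 <= (r + wall)^2
  lum_m <- d2 <= r^2
  sub <- img[ys, xs]
  sub[wall_m] <- tube$wall_intensity
  sub[lum_m] <- tube$lumen_intensity
  img[ys, xs] <- sub
  lsub <- lab[ys, xs]
  lsub[lum_m] <- label
  lab[ys, xs] <- lsub
  list(img = img, lab = lab)
}

#' Generate a synthetic phantom stack with ground truth
#'
#' Renders each tube slice by slice as a dark wall annulus around a bright
#' lumen on a mid-intensity tissue background surrounded by bright glass;
#' adds clutter, artefacts, per-slice misalignment and Gaussian noise. The
#' ground truth records every tube centerline in the image frame (i.e. with
#' the injected shift applied), the per-slice shifts themselves, and
#' per-pixel labels (0 background/tissue, k lumen of tube k, -1 clutter, -2
#' glomerulus).
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (a `slice_stack`), and `truth`: `paths` (list of
#'   per-tube data frames `x, y, z, radius` in the image frame),
#'   `paths_aligned` (same, before misalignment), `shifts` (per-slice
#'   `dx, dy`), `labels` (list of integer matrices).
#' @export
generate_phantom <- function(spec) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  w <- spec$image_size[1]; h <- spec$image_size[2]
  n <- spec$n_slices
  cls <- lapply(seq_along(spec$tubes), function(i)
    tube_centerline(spec$tubes[[i]], spec, i))
  shifts <- cbind(dx = as.integer(round(stats::rnorm(n, 0, spec$misalignment_sd))),
                  dy = as.integer(round(stats::rnorm(n, 0, spec$misalignment_sd))))
  slices <- vector("list", n)
  labels <- vector("list", n)
  base <- matrix(BG_INT, h, w)
  base[(MARGIN + 1):(h - MARGIN), (MARGIN + 1):(w - MARGIN)] <- TISSUE_INT
  for (zi in seq_len(n)) {
    z <- zi - 1L
    img <- base
    lab <- matrix(0L, h, w)
    sdx <- shifts[zi, 1]; sdy <- shifts[zi, 2]
    blanked <- z %in% spec$blank_slices
    if (!blanked) for (ti in seq_along(spec$tubes)) {
      tube <- spec$tubes[[ti]]
      pts <- cls[[ti]][cls[[ti]]$z == z, , drop = FALSE]
      for (r in seq_len(nrow(pts))) {
        p <- paint_cs(img, lab, pts$x[r] + sdx, pts$y[r] + sdy,
                      pts$radius[r], tube$elongation, tube$wall, tube, ti)
        img <- p$img; lab <- p$lab
      }
      if (tube$glomerulus && z < tube$glomerulus_slices) {
        p0 <- cls[[ti]][cls[[ti]]$z == 0, , drop = FALSE][1, ]
        p <- paint_cs(img, lab, p0$x + sdx, p0$y + sdy,
                      2.5 * tube$cortex_radius, 1, tube$wall, tube, -2L)
        img <- p$img; lab <- p$lab
      }
    }
    # interstitial-like clutter: thin bright bars, area far below lumen range
    if (spec$clutter_density > 0) {
      p1 <- if (length(cls)) cls[[1]][cls[[1]]$z == z, , drop = FALSE] else NULL
      for (ci in seq_len(round(spec$clutter_density))) {
        if (!is.null(spec$clutter_near) && !is.null(p1) && nrow(p1) > 0) {
          ang0 <- stats::runif(1, 0, 2 * pi)
          dd <- stats::runif(1, spec$clutter_near[1], spec$clutter_near[2])
          cx <- p1$x[1] + sdx + dd * cos(ang0)
          cy <- p1$y[1] + sdy + dd * sin(ang0)
        } else {
          cx <- stats::runif(1, MARGIN + 4, w - MARGIN - 4)
          cy <- stats::runif(1, MARGIN + 4, h - MARGIN - 4)
        }
        len <- stats::runif(1, 8, 18); th <- stats::runif(1, 0.6, 1.2)
        ang <- stats::runif(1, 0, pi)
        tt <- seq(-len / 2, len / 2, by = 0.5)
        px <- round(cx + tt * cos(ang)); py <- round(cy + tt * sin(ang))
        idx <- NULL
        for (o in -ceiling(th):ceiling(th)) {
          xs <- px - round(o * sin(ang)); ys <- py + round(o * cos(ang))
          ok <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
          idx <- rbind(idx, cbind(ys[ok], xs[ok]))
        }
        if (is.null(idx) || nrow(idx) == 0) next
        # drop a bar whose neighbourhood already holds clutter, so separate
        # bars never merge into one oversized component
        ring <- do.call(rbind, lapply(list(c(0, 0), c(1, 0), c(-1, 0),
                                           c(0, 1), c(0, -1)), function(d)
          cbind(pmin(pmax(idx[, 1] + d[1], 1), h),
                pmin(pmax(idx[, 2] + d[2], 1), w))))
        if (any(lab[ring] == -1L)) next
        free <- lab[idx] == 0L & img[idx] == TISSUE_INT
        img[idx[free, , drop = FALSE]] <- CLUTTER_INT
        lab[idx[free, , drop = FALSE]] <- -1L
      }
    }
    if (spec$artefact_rate > 0 && stats::runif(1) < spec$artefact_rate) {
      ax <- sort(round(stats::runif(2, 1, w))); ay <- sort(round(stats::runif(2, 1, h)))
      img[ay[1]:ay[2], ax[1]:ax[2]] <- TISSUE_INT
      lab[ay[1]:ay[2], ax[1]:ax[2]] <- 0L
    }
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    slices[[zi]] <- pmin(pmax(img, 0), 1)
    labels[[zi]] <- lab
  }
  paths <- lapply(cls, function(cl) {
    data.frame(x = cl$x + shifts[cl$z + 1, 1], y = cl$y + shifts[cl$z + 1, 2],
               z = cl$z, radius = cl$radius)
  })
  aligned <- lapply(cls, function(cl)
    data.frame(x = cl$x, y = cl$y, z = cl$z, radius = cl$radius))
  list(stack = slice_stack(slices, pixel_size = 1.16, slice_thickness = 2.5),
       truth = list(paths = paths, paths_aligned = aligned,
                    shifts = as.data.frame(shifts), labels = labels))
}

#' Ground-truth move labeller for phantom runs
#'
#' Returns a labelling closure mapping an attempted move to its class using
#' the phantom's per-pixel labels: moves into the glomerulus blob are class
#' 4, onto clutter class 3, within the narrow regime below the transition
#' slice class 5, between elongated cross sections class 2, and class 1
#' otherwise. Moves landing on unlabelled tissue (spurious components) are
#' class 3.
#'
#' @param truth the `truth` element of [generate_phantom()].
#' @param features the `stack_features` of the run (for elongation checks).
#' @param transition_slice slice index separating classes 1/2 from 5.
#' @param elongation_cutoff aspect ratio above which a move is class 2.
#' @export
phantom_labeller <- function(truth, features, transition_slice = Inf,
                             elongation_cutoff = 2) {
  lab_at <- function(x, y, z) {
    L <- truth$labels[[z + 1]]
    i <- round(y) + 1; j <- round(x) + 1
    if (i < 1 || i > nrow(L) || j < 1 || j > ncol(L)) return(0L)
    L[i, j]
  }
  function(parent, child) {
    lc <- lab_at(child$x, child$y, child$z)
    if (lc == -2L) return(4L)
    if (lc == -1L || lc == 0L) return(3L)
    if (mean(c(parent$z, child$z)) > transition_slice) return(5L)
    ars <- features$factors[c(parent_row(features, parent),
                              parent_row(features, child)), "aspect_ratio"]
    if (any(ars > elongation_cutoff)) return(2L) else 1L
  }
}

parent_row <- function(features, info) {
  nd <- features$nodes
  which(nd$z == info$z & nd$x == info$x & nd$y == info$y)[1]
}

#' Generate a balanced labelled move dataset from phantoms
#'
#' Runs capture-mode tracking on small dedicated phantom stacks per class —
#' circular tubes (class 1), elongated oblique tubes (class 2), tubes with
#' adjacent clutter (class 3), tubes originating in a glomerulus-like blob
#' (class 4) and narrow inner-medulla tubes (class 5) — labelling every
#' attempted move with the ground-truth labeller, and keeps generating new
#' stacks (fresh seeds, never duplication) until each class holds exactly
#' `n_per_class` examples.
#'
#' @param n_per_class examples per class.
#' @param seed base random seed.
#' @param n_slices,image_px size of each per-class phantom stack.
#' @return List with `features` (n x 66 matrix) and `labels` (in 1-5).
#' @export
generate_move_dataset <- function(n_per_class, seed = 1, n_slices = 60,
                                  image_px = 72) {
  stopifnot(n_per_class >= 1)
  sz <- c(image_px, image_px)
  mk_spec <- function(class, s) {
    tube <- switch(class,
      `1` = tube_spec(cortex_radius = 9, medulla_radius = 9, tortuosity = 0.8),
      `2` = tube_spec(cortex_radius = 7, medulla_radius = 7, elongation = 3,
                      tortuosity = 0.8),
      `3` = tube_spec(cortex_radius = 8, medulla_radius = 8, tortuosity = 0.8),
      `4` = tube_spec(cortex_radius = 8, medulla_radius = 8, tortuosity = 0.6,
                      glomerulus = TRUE, glomerulus_slices = 15),
      `5` = tube_spec(cortex_radius = 9, medulla_radius = 4,
                      transition_slice = 5, steepness = 1, tortuosity = 0.6))
    phantom_spec(image_size = sz, n_slices = n_slices, tubes = list(tube),
                 clutter_density = if (class == 3) 6 else 0,
                 clutter_near = if (class == 3) c(12, 22) else NULL,
                 noise_sd = 0.015, seed = s)
  }
  Xs <- vector("list", 5); for (k in 1:5) Xs[[k]] <- list()
  counts <- integer(5)
  for (class in 1:5) {
    tries <- 0
    while (counts[class] < n_per_class) {
      tries <- tries + 1
      if (tries > 100)
        stop("unable to produce enough class-", class, " examples")
      ph <- mk_spec(class, seed * 1000 + class * 50 + tries)
      gen <- generate_phantom(ph)
      bin <- preprocess_stack(gen$stack)
      feats <- extract_features(bin, max_mean_spacing = 30, seed = seed)
      if (nrow(feats$nodes) == 0) next
      p0 <- gen$truth$paths[[1]][1 + (if (class == 4) 17 else 0), ]
      g <- tryCatch(
        track(NULL, feats, c(p0$x, p0$y, p0$z),
              track_config(tracking_radius = 24), capture = TRUE),
        error = function(e) NULL)
      if (is.null(g)) next
      lblr <- phantom_labeller(gen$truth, feats,
                               transition_slice = if (class == 5) 8 else Inf)
      cap <- capture_training_examples(g, feats, lblr)
      sel <- cap$labels == class
      if (!any(sel)) next
      take <- min(sum(sel), n_per_class - counts[class])
      Xs[[class]][[length(Xs[[class]]) + 1L]] <-
        cap$features[which(sel)[seq_len(take)], , drop = FALSE]
      counts[class] <- counts[class] + take
    }
  }
  X <- do.call(rbind, lapply(Xs, function(l) do.call(rbind, l)))
  list(features = X, labels = rep(1:5, each = n_per_class))
}
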