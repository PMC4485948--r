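# Feature extraction: binary slice -> cross sections -> nodes + shape
# descriptors. Coordinates are 0-based with x = column, y = row, z = slice
# index; angles are measured from the +x axis towards +y (the row direction).

#' Segment a binary slice into cross sections
#'
#' One cross section per 4-connected component; labels follow raster-scan
#' order of first occurrence, so segmentation is deterministic.
#'
#' @param binary logical matrix.
#' @param slice_index 0-based slice index stored on each cross section.
#' @return List of `cross_section` objects (shape factors and nodes unfilled).
#' @export
segment_components <- function(binary, slice_index = 0) {
  lab <- label_components(binary)
  k <- max(lab)
  if (k == 0) return(list())
  px <- which(lab > 0, arr.ind = TRUE)
  ord <- lab[lab > 0]
  lapply(seq_len(k), function(l) {
    sel <- ord == l
    structure(list(slice = slice_index, label = l,
                   pixels = cbind(x = px[sel, 2] - 1L, y = px[sel, 1] - 1L),
                   area = sum(sel), shape = NULL, nodes = NULL,
                   profiles = NULL),
              class = "cross_section")
  })
}

# Moore-neighbour boundary tracing on the component's pixel set. Returns the
# ordered closed boundary as a 2-column (x, y) matrix of pixel centres.
trace_boundary <- function(pixels) {
  if (nrow(pixels) == 1) return(pixels)
  x0 <- min(pixels[, 1]) - 2L; y0 <- min(pixels[, 2]) - 2L
  w <- max(pixels[, 1]) - x0 + 2L; h <- max(pixels[, 2]) - y0 + 2L
  mask <- matrix(FALSE, h, w)
  mask[cbind(pixels[, 2] - y0, pixels[, 1] - x0)] <- TRUE
  # clockwise Moore neighbourhood starting east
  dxs <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dys <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  start <- which(mask, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]  # topmost-leftmost
  sy <- start[1]; sx <- start[2]
  bx <- integer(0); by <- integer(0)
  cy <- sy; cx <- sx; dir <- 7L  # came from the west, search from north-east-ish
  repeat {
    bx <- c(bx, cx); by <- c(by, cy)
    found <- FALSE
    for (s in 0:7) {
      d <- (dir + s) %% 8L
      ny <- cy + dys[d + 1L]; nx <- cx + dxs[d + 1L]
      if (mask[ny, nx]) {
        cy <- ny; cx <- nx
        dir <- (d + 6L) %% 8L   # backtrack-relative restart
        found <- TRUE
        break
      }
    }
    if (!found) break                               # isolated pixel
    if (cy == sy && cx == sx) break
    if (length(bx) > 4 * nrow(pixels) + 8) break    # safety
  }
  cbind(x = bx + x0, y = by + y0)
}

# Perimeter estimate. Raw sqrt(2)-weighted chain length biases circularity
# low for smooth shapes, so the chain steps carry the standard corrected
# weights (0.948 axial, 1.343 diagonal); tiny components, where a traced
# chain degenerates, use the exposed-pixel-edge count instead.
estimate_perimeter <- function(pixels) {
  n <- nrow(pixels)
  if (n < 10) {
    key <- paste(pixels[, 1], pixels[, 2])
    nb <- 0L
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
      nb <- nb + sum(!(paste(pixels[, 1] + d[1], pixels[, 2] + d[2]) %in% key))
    return(max(nb, 4))
  }
  b <- trace_boundary(pixels)
  step <- cbind(diff(c(b[, 1], b[1, 1])), diff(c(b[, 2], b[1, 2])))
  diag <- rowSums(abs(step)) == 2
  max(0.948 * sum(!diag) + 1.343 * sum(diag), 4)
}

#' Compute the six shape descriptors of a cross section
#'
#' Four dimensionless shape factors plus two absolute descriptors:
#' circularity `4*pi*area / perimeter^2`, eccentricity and axis lengths from
#' the best-fit ellipse (second central moments of the pixel set, with the
#' 1/12 pixel-extent correction), solidity `area / convex hull area` (hull
#' taken over pixel corners), aspect ratio `major/minor`, area and minor axis
#' length.
#'
#' @param cs a `cross_section`.
#' @return List of class `shape_factors` with fields `circularity`,
#'   `eccentricity`, `solidity`, `aspect_ratio`, `area`, `minor_axis_length`.
#' @export
compute_shape_factors <- function(cs) {
  px <- cs$pixels; n <- nrow(px)
  if (n == 1) {
    sf <- list(circularity = 4 * pi / 16, eccentricity = 0, solidity = 1,
               aspect_ratio = 1, area = 1, minor_axis_length = 1)
    class(sf) <- "shape_factors"
    return(sf)
  }
  mu20 <- stats::var(px[, 1]) * (n - 1) / n + 1 / 12
  mu02 <- stats::var(px[, 2]) * (n - 1) / n + 1 / 12
  mu11 <- stats::cov(px[, 1], px[, 2]) * (n - 1) / n
  tr <- mu20 + mu02
  dt <- sqrt(max((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (tr + dt) / 2; l2 <- max((tr - dt) / 2, 1e-12)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  per <- estimate_perimeter(px)
  # convex hull over pixel corners so thin shapes cannot exceed solidity 1
  corners <- rbind(px + matrix(c(-.5, -.5), n, 2, byrow = TRUE),
                   px + matrix(c(.5, -.5), n, 2, byrow = TRUE),
                   px + matrix(c(-.5, .5), n, 2, byrow = TRUE),
                   px + matrix(c(.5, .5), n, 2, byrow = TRUE))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  hx <- hull[, 1]; hy <- hull[, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  sf <- list(circularity = 4 * pi * n / per^2,
             eccentricity = sqrt(max(1 - l2 / l1, 0)),
             solidity = min(n / max(hull_area, 1e-9), 1),
             aspect_ratio = major / minor,
             area = n,
             minor_axis_length = minor)
  class(sf) <- "shape_factors"
  sf
}

# greedy nearest-neighbour chain ordering of points, starting at start_idx
chain_order <- function(pts, start_idx) {
  n <- nrow(pts)
  ord <- integer(n); used <- logical(n)
  ord[1] <- start_idx; used[start_idx] <- TRUE
  for (i in seq_len(n - 1)) {
    cur <- pts[ord[i], ]
    d <- (pts[, 1] - cur[1])^2 + (pts[, 2] - cur[2])^2
    d[used] <- Inf
    ord[i + 1] <- which.min(d)
    used[ord[i + 1]] <- TRUE
  }
  ord
}

#' Allocate nodes along a cross section by K-means clustering
#'
#' Every foreground pixel is an observation. K starts at 1 and increases until
#' the mean distance between adjacent nodes (adjacent = consecutive along the
#' nearest-neighbour chain started from the node farthest from the centroid)
#' drops below `max_mean_spacing`, so circular cross sections get a single
#' central node while elongated ones get several along their length. K-means
#' runs are seeded deterministically.
#'
#' @param cs a `cross_section`.
#' @param max_mean_spacing target mean spacing between adjacent nodes (px).
#' @param seed integer seed for the clustering restarts.
#' @return Integer matrix of node positions, columns `x`, `y` (pixel-rounded).
#' @export
allocate_nodes <- function(cs, max_mean_spacing = 30, seed = 1) {
  stopifnot(max_mean_spacing > 0, cs$area >= 1)
  px <- cs$pixels
  if (nrow(px) == 1)
    return(cbind(x = px[1, 1], y = px[1, 2]))
  k <- 1L
  repeat {
    if (k == 1L) {
      centers <- matrix(colMeans(px), 1)
    } else {
      old <- .Random.seed_get()
      set.seed(seed + k)
      centers <- tryCatch(
        stats::kmeans(px, centers = k, nstart = 3, iter.max = 50)$centers,
        error = function(e) NULL)
      .Random.seed_set(old)
      if (is.null(centers)) centers <- unique(px)[seq_len(k), , drop = FALSE]
    }
    if (k == 1L) spacing <- 0 else {
      cen <- colMeans(centers)
      start <- which.max((centers[, 1] - cen[1])^2 + (centers[, 2] - cen[2])^2)
      ord <- chain_order(centers, start)
      spacing <- mean(sqrt(rowSums(diff(centers[ord, , drop = FALSE])^2)))
    }
    if ((k == 1L && max_spacing_ok(px, centers, max_mean_spacing)) ||
        (k > 1L && spacing < max_mean_spacing) || k >= nrow(unique(px))) break
    k <- k + 1L
  }
  m <- cbind(x = as.integer(round(centers[, 1])),
             y = as.integer(round(centers[, 2])))
  # a centroid of a bent component can fall outside it: snap to the nearest
  # component pixel so every node lies on (or within 1 px of) the pixel set
  for (i in seq_len(nrow(m))) {
    d2 <- (px[, 1] - m[i, 1])^2 + (px[, 2] - m[i, 2])^2
    if (min(d2) > 2) m[i, ] <- px[which.min(d2), ]
  }
  m <- unique(m)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# With one node there is no adjacent pair; accept K = 1 unless the component
# is so extended that its RMS radius already exceeds the spacing target.
max_spacing_ok <- function(px, center, max_mean_spacing) {
  r <- sqrt(mean((px[, 1] - center[1])^2 + (px[, 2] - center[2])^2))
  2 * r <= max_mean_spacing
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (!is.null(seed)) assign(".Random.seed", seed, envir = globalenv())
}

#' Compute the centroidal shape profile of a cross section from a node
#'
#' The profile samples the distance from the reference node to the component
#' boundary at 24 fixed angles (0, 15, ..., 345 degrees from the +x axis).
#' Multivalued boundary angles are resolved by keeping the first boundary
#' crossing along increasing radius: a ray is marched outward from the node in
#' sub-pixel steps over the component mask and the radius of first exit is
#' recorded, which describes the local lumen outline around the node.
#'
#' @param cs a `cross_section`.
#' @param node numeric length-2 `(x, y)` reference point; must lie inside the
#'   component (within 1 pixel).
#' @param n_angles number of angular samples (24 = 15-degree increments).
#' @return Numeric vector of radii (px), one per angle.
#' @export
compute_shape_profile <- function(cs, node, n_angles = 24) {
  px <- cs$pixels
  x0 <- min(px[, 1]); y0 <- min(px[, 2])
  w <- max(px[, 1]) - x0 + 1L; h <- max(px[, 2]) - y0 + 1L
  mask <- matrix(FALSE, h, w)
  mask[cbind(px[, 2] - y0 + 1L, px[, 1] - x0 + 1L)] <- TRUE
  nx <- node[1] - x0; ny <- node[2] - y0          # 0-based local coords
  inside <- function(xx, yy) {
    i <- round(yy) + 1; j <- round(xx) + 1
    i >= 1 && i <= h && j >= 1 && j <= w && mask[i, j]
  }
  if (!inside(nx, ny)) {
    d2 <- (px[, 1] - node[1])^2 + (px[, 2] - node[2])^2
    if (min(d2) > 2) stop("reference node lies outside the cross section")
    nx <- px[which.min(d2), 1] - x0; ny <- px[which.min(d2), 2] - y0
  }
  ang <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  rmax <- sqrt(w^2 + h^2) + 2
  step <- 0.25
  vapply(ang, function(a) {
    ca <- cos(a); sa <- sin(a)
    r <- 0
    while (r <= rmax && inside(nx + (r + step) * ca, ny + (r + step) * sa))
      r <- r + step
    r + step / 2
  }, numeric(1))
}

#' Extract all features from a preprocessed binary stack
#'
#' Runs segmentation, shape-factor computation, node allocation and per-node
#' shape profiles on every slice, producing the inputs the tracker consumes.
#'
#' @param binary_slices list of logical matrices (from [preprocess_stack()]).
#' @param max_mean_spacing node spacing target for [allocate_nodes()] (px).
#' @param seed clustering seed.
#' @return An object of class `stack_features`: `$cs` is a per-slice list of
#'   `cross_section` objects (with shapes, nodes and profiles filled in);
#'   `$nodes` is a data frame with one row per node (`id`, `z`, `cs`, `k`,
#'   `x`, `y`, `minor_axis`); `$factors` a 6-column matrix of shape factors
#'   per node; `$profiles` a 24-column matrix of profile radii per node.
#' @export
extract_features <- function(binary_slices, max_mean_spacing = 30, seed = 1) {
  factor_names <- c("circularity", "eccentricity", "solidity", "aspect_ratio",
                    "area", "minor_axis_length")
  cs_all <- vector("list", length(binary_slices))
  rows <- list(); fac <- list(); prof <- list(); id <- 0L
  for (zi in seq_along(binary_slices)) {
    z <- zi - 1L
    css <- segment_components(binary_slices[[zi]], z)
    for (ci in seq_along(css)) {
      cs <- css[[ci]]
      cs$shape <- compute_shape_factors(cs)
      cs$nodes <- allocate_nodes(cs, max_mean_spacing, seed)
      cs$profiles <- lapply(seq_len(nrow(cs$nodes)), function(k)
        compute_shape_profile(cs, cs$nodes[k, ]))
      cs$node_ids <- id + seq_len(nrow(cs$nodes))
      for (k in seq_len(nrow(cs$nodes))) {
        id <- id + 1L
        rows[[id]] <- c(id = id, z = z, cs = ci, k = k,
                        x = cs$nodes[k, 1], y = cs$nodes[k, 2],
                        minor_axis = cs$shape$minor_axis_length)
        fac[[id]] <- unlist(cs$shape[factor_names])
        prof[[id]] <- cs$profiles[[k]]
      }
      css[[ci]] <- cs
    }
    cs_all[[zi]] <- css
  }
  nodes <- as.data.frame(do.call(rbind, rows))
  if (id == 0L)
    nodes <- data.frame(id = integer(), z = integer(), cs = integer(),
                        k = integer(), x = integer(), y = integer(),
                        minor_axis = numeric())
  structure(list(cs = cs_all, nodes = nodes,
                 factors = if (id) do.call(rbind, fac) else matrix(0, 0, 6),
                 profiles = if (id) do.call(rbind, prof) else matrix(0, 0, 24)),
            class = "stack_features")
}

#' @export
print.stack_features <- function(x, ...) {
  cat(sprintf("<stack_features> %d slices, %d cross sections, %d nodes\n",
              length(x$cs), sum(lengths(x$cs)), nrow(x$nodes)))
  invisible(x)
}

#' Write a per-node feature table to CSV
#'
#' One row per node: slice, component label, node index, position, the six
#' shape descriptors and the 24 profile radii. Used for debugging and as the
#' capture format for classifier training data.
#'
#' @param features a `stack_features` object.
#' @param path output CSV path.
#' @export
write_features <- function(features, path) {
  df <- cbind(features$nodes,
              as.data.frame(features$factors),
              stats::setNames(as.data.frame(features$profiles),
                              sprintf("r%03d", (0:23) * 15)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
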