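# Graph-based tubule tracking: from a seed node, grow parent/child links
# through the stack via vertical (between-slice) and horizontal (same cross
# section) edges, guarded by local registration, controlled slice skipping,
# a three-rule validation base and an optional machine-learned move
# validator. Open/closed lists manage unexplored/explored nodes, as in
# A*-style search.

#' Tracking configuration
#'
#' @param tracking_radius search radius `r_track` (px) for vertical
#'   candidates; `NULL` derives 1.5x the local mean cross-section spacing
#'   from the feature set (falling back to 25 px when a slice has a single
#'   cross section).
#' @param registration_window half-width (px) of the subimage cropped around
#'   the current node for local cross-correlation registration.
#' @param max_shift largest translational offset (px) searched during
#'   registration.
#' @param max_skip maximum number of consecutive slices that may be skipped
#'   (2, i.e. 5 um of specimen at 2.5 um sections; morphology changes too
#'   much beyond that).
#' @param distance_coefficient multiplier on the radius-sum distance rule.
#' @param shape_change_limit maximum per-factor percentage change allowed
#'   across a skip.
#' @param refractory_period accepted moves required between skip attempts.
#' @param direction_buffer_len number of recent vertical move directions used
#'   to gate skips.
#' @param ml_threshold acceptance threshold on the winning valid-class score
#'   of the neural-network validator.
#' @export
track_config <- function(tracking_radius = NULL, registration_window = 16,
                         max_shift = 8, max_skip = 2,
                         distance_coefficient = 1, shape_change_limit = 30,
                         refractory_period = 10, direction_buffer_len = 5,
                         ml_threshold = 0.3) {
  stopifnot(max_skip <= 2, refractory_period >= 0,
            is.null(tracking_radius) || tracking_radius > 0)
  structure(list(tracking_radius = tracking_radius,
                 registration_window = registration_window,
                 max_shift = max_shift, max_skip = max_skip,
                 distance_coefficient = distance_coefficient,
                 shape_change_limit = shape_change_limit,
                 refractory_period = refractory_period,
                 direction_buffer_len = direction_buffer_len,
                 ml_threshold = ml_threshold),
            class = "track_config")
}

#' Local translational registration of two slices around a point
#'
#' Crops a window around `center` in both slices and finds the integer
#' translation `(dx, dy)` maximising the normalised cross-correlation, so a
#' structure at `(x, y)` in `slice_a` appears near `(x + dx, y + dy)` in
#' `slice_b`. Only translation is estimated (local rotational offsets are
#' assumed minimal). Offsets are applied to candidate positions during
#' linking and reversed afterwards so they never accumulate.
#'
#' @param stack a `slice_stack`.
#' @param slice_a,slice_b 0-based slice indices.
#' @param center `(x, y)` of the crop centre.
#' @param window crop half-width in px.
#' @param max_shift search range in px.
#' @return Integer `c(dx, dy)`, with attribute `confidence` (peak NCC; 0 for
#'   flat subimages, which return `c(0, 0)`).
#' @export
local_register <- function(stack, slice_a, slice_b, center, window = 16,
                           max_shift = 8) {
  A <- get_slice(stack, slice_a); B <- get_slice(stack, slice_b)
  nr <- nrow(A); nc <- ncol(A)
  cx <- round(center[1]) + 1L; cy <- round(center[2]) + 1L
  r0 <- max(1, cy - window); r1 <- min(nr, cy + window)
  c0 <- max(1, cx - window); c1 <- min(nc, cx + window)
  a <- A[r0:r1, c0:c1]
  if (stats::sd(a) == 0)
    return(structure(c(dx = 0L, dy = 0L), confidence = 0))
  best <- -Inf; bdx <- 0L; bdy <- 0L
  av <- as.vector(a); av <- av - mean(av)
  sda <- sqrt(sum(av^2))
  for (dy in -max_shift:max_shift) {
    rr0 <- r0 + dy; rr1 <- r1 + dy
    if (rr0 < 1 || rr1 > nr) next
    for (dx in -max_shift:max_shift) {
      cc0 <- c0 + dx; cc1 <- c1 + dx
      if (cc0 < 1 || cc1 > nc) next
      b <- as.vector(B[rr0:rr1, cc0:cc1])
      b <- b - mean(b)
      sdb <- sqrt(sum(b^2))
      if (sdb == 0) next
      ncc <- sum(av * b) / (sda * sdb)
      if (ncc > best) { best <- ncc; bdx <- dx; bdy <- dy }
    }
  }
  if (!is.finite(best))
    return(structure(c(dx = 0L, dy = 0L), confidence = 0))
  structure(c(dx = as.integer(bdx), dy = as.integer(bdy)), confidence = best)
}

#' Select the vertical-edge candidate for a node
#'
#' Among offset-corrected candidate positions on the neighbouring slice,
#' returns the index of the one minimising the Euclidean distance to the
#' node, provided that minimum is strictly below `r_track`; otherwise `NA`.
#' Only one node may be linked per direction.
#'
#' @param node `(x, y)` of the current node.
#' @param candidates 2-column matrix of candidate `(x, y)` positions.
#' @param r_track tracking radius (px).
#' @return Index into `candidates`, or `NA_integer_`.
#' @export
vertical_candidate <- function(node, candidates, r_track) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NA_integer_)
  d <- sqrt((candidates[, 1] - node[1])^2 + (candidates[, 2] - node[2])^2)
  i <- which.min(d)
  if (d[i] < r_track) i else NA_integer_
}

#' Chain the nodes of a cross section into horizontal edges
#'
#' Builds a nearest-neighbour chain over all nodes of the cross section,
#' starting at the entering node, and returns the consecutive pairs as edges;
#' every node of the cross section is reachable from the entering node.
#'
#' @param entering index (into `nodes`) of the node the tracker entered
#'   the cross section through.
#' @param nodes 2-column matrix of the cross section's node positions.
#' @return 2-column matrix of index pairs (possibly 0 rows).
#' @export
horizontal_links <- function(entering, nodes) {
  n <- nrow(nodes)
  if (n <= 1) return(matrix(integer(0), 0, 2))
  ord <- chain_order(nodes, entering)
  cbind(ord[-n], ord[-1])
}

#' Distance validation rule
#'
#' A parent-child link is plausible only if the x-y distance between the
#' nodes is strictly less than `coefficient` times the sum of their radii
#' (half the minor axis length each): consistency of size and displacement.
#'
#' @param parent,child lists with `x`, `y`, `minor_axis`.
#' @param coefficient rule multiplier (default 1).
#' @export
validate_distance <- function(parent, child, coefficient = 1) {
  d <- sqrt((parent$x - child$x)^2 + (parent$y - child$y)^2)
  d < coefficient * (parent$minor_axis / 2 + child$minor_axis / 2)
}

#' Bidirectional movement validation rule
#'
#' A move A -> B is kept only if the reverse search from B towards A's slice
#' selects A again. `back_candidates` are the offset-corrected positions of
#' the nodes on A's slice and `a_index` the row corresponding to A.
#'
#' @param b `(x, y)` of the proposed child node B.
#' @param back_candidates 2-column matrix of candidate positions on A's slice.
#' @param a_index row index of A within `back_candidates`.
#' @param r_track tracking radius (px).
#' @export
validate_bidirectional <- function(b, back_candidates, a_index, r_track) {
  i <- vertical_candidate(b, back_candidates, r_track)
  !is.na(i) && i == a_index
}

#' Skip validation rule
#'
#' A move that skips slices is allowed only when at most `max_skip` slices
#' are skipped and the cross-section shape stays relatively constant: every
#' one of the six shape descriptors must change by no more than
#' `shape_change_limit` percent of its pre-skip value. The reference value is
#' floored per factor (1 for the dimensionless factors, 10 px^2 for area,
#' 2 px for the minor axis), so factors that sit near zero — eccentricity of
#' an almost circular lumen, say — are judged on their absolute change
#' rather than an exploding relative one. Skips are therefore rejected on
#' turns and bends, where mistracking risk is highest.
#'
#' @param factors_before,factors_after numeric length-6 shape-factor vectors.
#' @param skip_count number of slices skipped (>= 1).
#' @param shape_change_limit maximum percentage change per factor.
#' @param max_skip hard ceiling on skipped slices.
#' @export
validate_skip <- function(factors_before, factors_after, skip_count,
                          shape_change_limit = 30, max_skip = 2) {
  stopifnot(skip_count >= 1)
  if (skip_count > max_skip) return(FALSE)
  ref <- pmax(abs(factors_before), c(1, 1, 1, 1, 10, 2))
  all(abs(factors_after - factors_before) / ref * 100 <= shape_change_limit)
}

# derive r_track = 1.5 x mean nearest-neighbour spacing between cross-section
# centroids, averaged over slices with >= 2 cross sections; fallback 25 px.
default_tracking_radius <- function(features) {
  sp <- unlist(lapply(features$cs, function(css) {
    if (length(css) < 2) return(NULL)
    cen <- t(vapply(css, function(cs) colMeans(cs$pixels), numeric(2)))
    d <- as.matrix(stats::dist(cen)); diag(d) <- Inf
    apply(d, 1, min)
  }))
  if (length(sp) == 0) 25 else 1.5 * mean(sp)
}

#' Track a tubule from a seed point
#'
#' Grows a parent/child node graph from the seed: nodes are popped off the
#' open list; the neighbouring slices are locally registered around the node;
#' the nearest candidate within the tracking radius is proposed per vertical
#' direction and must pass, in order of computational cost, distance
#' validation, skip validation (when skipping), bidirectional validation and
#' machine-learned validation (when a classifier is supplied); nodes on the
#' same cross section are chained through horizontal edges. Dead ends trigger
#' controlled skipping of up to `max_skip` slices, gated by a direction
#' buffer and refractory period. A classifier verdict of class 4
#' (glomerulus) terminates the branch; class 5 (inner medulla) switches
#' tracking to unidirectional mode. When the open list empties, an optional
#' `correction_provider` may supply a manual bridge point past the dead end.
#'
#' @param stack the raw `slice_stack` (used for registration); `NULL`
#'   disables registration (offsets 0).
#' @param features a `stack_features` object.
#' @param seed numeric `(x, y, z)` seed coordinate.
#' @param config a [track_config()].
#' @param classifier optional `move_classifier` for ML validation.
#' @param correction_provider optional `function(dead_end)` returning an
#'   `(x, y, z)` bridge coordinate or `NULL`; `dead_end` is a list with the
#'   terminal node's position.
#' @param rules enable the rule base (disable only for diagnostics/capture).
#' @param capture record every attempted vertical move (for training-example
#'   capture).
#' @param record_all_rules evaluate every validator on each proposed move
#'   (not just until the first failure) so rejection overlap can be reported.
#' @return An object of class `track_graph`.
#' @export
track <- function(stack, features, seed, config = track_config(),
                  classifier = NULL, correction_provider = NULL,
                  rules = TRUE, capture = FALSE, record_all_rules = FALSE) {
  nd <- features$nodes
  if (nrow(nd) == 0) stop("feature set contains no nodes")
  nzs <- length(features$cs)
  r_track <- config$tracking_radius %||% default_tracking_radius(features)

  # locate the seed: nearest node on the seed slice whose cross section
  # contains (or nearly contains) the seed point
  on_z <- which(nd$z == seed[3])
  if (length(on_z) == 0) stop("seed slice contains no cross section")
  d2 <- (nd$x[on_z] - seed[1])^2 + (nd$y[on_z] - seed[2])^2
  seed_id <- on_z[which.min(d2)]
  seed_cs <- features$cs[[nd$z[seed_id] + 1]][[nd$cs[seed_id]]]
  if (min(sqrt((seed_cs$pixels[, 1] - seed[1])^2 +
               (seed_cs$pixels[, 2] - seed[2])^2)) > r_track)
    stop("seed point lies outside every cross section")

  slice_ids <- split(seq_len(nrow(nd)), nd$z)
  n_id <- nrow(nd)
  parent <- rep(NA_integer_, n_id); parent[seed_id] <- 0L
  closed <- logical(n_id)
  open <- c(seed_id)
  counts <- c(distance = 0L, skip = 0L, bidirectional = 0L, ml = 0L)
  overlap <- counts
  skips_used <- 0L; corrections <- list(); terminated_glom <- FALSE
  dir_buf <- integer(0); moves_since_skip <- Inf; accepted_moves <- 0L
  unidir <- 0L  # 0 = bidirectional search; otherwise the forced dz
  attempts <- list()
  reg_cache <- new.env(parent = emptyenv())

  register <- function(za, zb, x, y) {
    if (is.null(stack)) return(c(dx = 0L, dy = 0L))
    key <- paste(za, zb, x %/% 24, y %/% 24)
    if (!is.null(reg_cache[[key]])) return(reg_cache[[key]])
    off <- local_register(stack, za, zb, c(x, y),
                          config$registration_window, config$max_shift)
    reg_cache[[key]] <- off
    off
  }

  node_info <- function(i) list(id = i, x = nd$x[i], y = nd$y[i], z = nd$z[i],
                                minor_axis = nd$minor_axis[i])

  # validate + (maybe) accept a proposed vertical move cur -> cand
  propose <- function(cur, cand, dz_total, off) {
    skip_count <- abs(dz_total) - 1L
    p <- node_info(cur)
    ch <- node_info(cand)
    chx <- ch$x - off[1]; chy <- ch$y - off[2]     # child in parent's frame
    fails <- character(0)
    ok_d <- validate_distance(p, list(x = chx, y = chy,
                                      minor_axis = ch$minor_axis),
                              config$distance_coefficient)
    if (!ok_d) fails <- c(fails, "distance")
    ok_s <- TRUE
    if (skip_count >= 1) {
      ok_s <- validate_skip(features$factors[cur, ], features$factors[cand, ],
                            skip_count, config$shape_change_limit,
                            config$max_skip)
      if (!ok_s) fails <- c(fails, "skip")
    }
    ok_b <- TRUE
    if (rules && (ok_d || record_all_rules) && (ok_s || record_all_rules)) {
      back_ids <- slice_ids[[as.character(p$z)]]
      back <- cbind(nd$x[back_ids] + off[1], nd$y[back_ids] + off[2])
      ok_b <- validate_bidirectional(c(ch$x, ch$y), back,
                                     match(cur, back_ids), r_track)
      if (!ok_b) fails <- c(fails, "bidirectional")
    }
    decision <- NULL
    if (!is.null(classifier) &&
        (record_all_rules || (ok_d && ok_s && ok_b))) {
      fv <- extract_move_features_ids(features, cur, cand, nzs, dz_total, off)
      decision <- classify_move(fv, classifier, config$ml_threshold)
      if (decision$final == "invalid") fails <- c(fails, "ml")
    }
    if (capture)
      attempts[[length(attempts) + 1L]] <<-
        list(parent = cur, child = cand, image_diff = abs(dz_total),
             offset = off, accepted = length(fails) == 0 ||
               (!rules && !any(fails == "ml")))
    if (rules && length(fails) > 0) {
      counts[fails[1]] <<- counts[fails[1]] + 1L
      if (record_all_rules) for (f in fails) overlap[f] <<- overlap[f] + 1L
      return(FALSE)
    }
    if (!rules && !is.null(decision) && decision$final == "invalid") {
      counts["ml"] <<- counts["ml"] + 1L
      return(FALSE)
    }
    if (!is.null(decision)) {
      if (decision$final == "terminate") { terminated_glom <<- TRUE; return(FALSE) }
      if (decision$final == "region_signal" && unidir == 0L)
        unidir <<- sign(dz_total)
    }
    if (!is.na(parent[cand]) || closed[cand]) return(TRUE)  # already in graph
    parent[cand] <<- cur
    open <<- c(open, cand)
    accepted_moves <<- accepted_moves + 1L
    moves_since_skip <<- moves_since_skip + 1L
    dir_buf <<- utils::tail(c(dir_buf, sign(dz_total)),
                            config$direction_buffer_len)
    if (skip_count >= 1) {
      skips_used <<- skips_used + 1L
      moves_since_skip <<- 0L
    }
    TRUE
  }

  skip_allowed <- function(dz) {
    if (moves_since_skip < config$refractory_period) return(FALSE)
    if (length(dir_buf) < 3) return(length(dir_buf) > 0 && all(dir_buf == dz))
    mean(dir_buf == dz) >= 0.6
  }

  expand <- function(cur) {
    z <- nd$z[cur]
    # horizontal edges: chain the remaining nodes of this cross section
    cs <- features$cs[[z + 1]][[nd$cs[cur]]]
    ids <- cs$node_ids
    if (length(ids) > 1) {
      e <- horizontal_links(match(cur, ids), cs$nodes)
      for (r in seq_len(nrow(e))) {
        a <- ids[e[r, 1]]; b <- ids[e[r, 2]]
        if (is.na(parent[b]) && !closed[b]) {
          parent[b] <<- a
          open <<- c(open, b)
        }
      }
    }
    dirs <- if (unidir != 0L) unidir else c(1L, -1L)
    for (dz in dirs) {
      linked <- FALSE
      zt <- z + dz
      if (zt >= 0 && zt < nzs) {
        cand_ids <- slice_ids[[as.character(zt)]]
        if (!is.null(cand_ids)) {
          off <- register(z, zt, nd$x[cur], nd$y[cur])
          cc <- cbind(nd$x[cand_ids] - off[1], nd$y[cand_ids] - off[2])
          i <- vertical_candidate(c(nd$x[cur], nd$y[cur]), cc, r_track)
          if (capture) {
            # capture-mode also records the non-nearest candidates within the
            # tracking radius: the plausible-but-wrong moves the classifier
            # must learn to reject (keeps the invalid classes represented)
            d <- sqrt((cc[, 1] - nd$x[cur])^2 + (cc[, 2] - nd$y[cur])^2)
            for (j in setdiff(which(d < r_track), i))
              attempts[[length(attempts) + 1L]] <<-
                list(parent = cur, child = cand_ids[j], image_diff = 1L,
                     offset = off, accepted = FALSE)
          }
          if (!is.na(i))
            linked <- propose(cur, cand_ids[i], dz, off)
        }
      }
      if (!linked && skip_allowed(dz)) {
        for (sk in seq_len(config$max_skip)) {
          zt <- z + dz * (1L + sk)
          if (zt < 0 || zt >= nzs) break
          cand_ids <- slice_ids[[as.character(zt)]]
          if (is.null(cand_ids)) next
          off <- register(z, zt, nd$x[cur], nd$y[cur])
          cc <- cbind(nd$x[cand_ids] - off[1], nd$y[cand_ids] - off[2])
          i <- vertical_candidate(c(nd$x[cur], nd$y[cur]), cc, r_track)
          if (!is.na(i) && propose(cur, cand_ids[i], dz * (1L + sk), off)) break
        }
      }
    }
  }

  repeat {
    while (length(open) > 0) {
      cur <- open[length(open)]; open <- open[-length(open)]
      if (closed[cur]) next
      closed[cur] <- TRUE
      expand(cur)
    }
    if (is.null(correction_provider)) break
    # ask for a manual bridge past the deepest dead end
    g <- structure(list(parent = parent, closed = closed, nodes = nd,
                        seed_id = seed_id), class = "track_graph")
    leaf <- deepest_leaf(g)
    bridge <- correction_provider(node_info(leaf))
    if (is.null(bridge)) break
    bz <- bridge[3]
    cand_ids <- slice_ids[[as.character(bz)]]
    if (is.null(cand_ids)) break
    d2 <- (nd$x[cand_ids] - bridge[1])^2 + (nd$y[cand_ids] - bridge[2])^2
    b_id <- cand_ids[which.min(d2)]
    if (!is.na(parent[b_id]) || closed[b_id]) break
    parent[b_id] <- leaf
    open <- c(open, b_id)
    corrections[[length(corrections) + 1L]] <-
      c(x = nd$x[b_id], y = nd$y[b_id], z = nd$z[b_id])
  }

  structure(list(parent = parent, closed = closed, nodes = nd,
                 seed_id = seed_id, r_track = r_track,
                 rejections = counts, rejection_overlap = overlap,
                 skips_used = skips_used, corrections = corrections,
                 terminated_at_glomerulus = terminated_glom,
                 unidirectional = unidir != 0L,
                 attempts = attempts),
            class = "track_graph")
}

#' @export
print.track_graph <- function(x, ...) {
  cat(sprintf(paste0("<track_graph> %d nodes linked (of %d), %d skips, ",
                     "%d corrections\n  rejections: %s\n"),
              sum(!is.na(x$parent)), nrow(x$nodes), x$skips_used,
              length(x$corrections),
              paste(names(x$rejections), x$rejections, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

# depth (node count from root) of every linked node; NA when unlinked
node_depths <- function(graph) {
  parent <- graph$parent
  n <- length(parent)
  depth <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(parent[i]) || !is.na(depth[i])) next
    chain <- integer(0); j <- i
    while (is.na(depth[j])) {
      chain <- c(chain, j)
      if (parent[j] == 0L) break
      j <- parent[j]
      if (length(chain) > n) stop("cycle detected in track graph")
    }
    for (k in rev(seq_along(chain))) {
      jj <- chain[k]
      depth[jj] <- if (parent[jj] == 0L) 1 else depth[parent[jj]] + 1
    }
  }
  depth
}

deepest_leaf <- function(graph) {
  depth <- node_depths(graph)
  linked <- which(!is.na(depth))
  # prefer the leaf of the longest chain, tie-break deepest z then lowest id
  o <- order(-depth[linked], -graph$nodes$z[linked], linked)
  linked[o][1]
}

#' Reconstruct the tracked path from the link graph
#'
#' Infers the longest root-to-leaf path through the parent/child pairs (by
#' node count; ties broken towards the deepest terminal slice, then lowest
#' node id); shorter branches are discarded as likely interstitial or
#' ambiguous links. Each point carries the half-minor-axis radius of its
#' cross section, enabling a 3D rendering with varying lumen radius, and a
#' provenance flag (`auto` or `manual` for correction bridge points).
#'
#' @param graph a `track_graph`.
#' @return An object of class `tracked_path`: a data frame with columns `x`,
#'   `y`, `z`, `radius`, `source`.
#' @export
reconstruct_path <- function(graph) {
  linked <- which(!is.na(graph$parent))
  if (length(linked) == 0)
    return(structure(data.frame(x = numeric(0), y = numeric(0),
                                z = numeric(0), radius = numeric(0),
                                source = character(0)),
                     class = c("tracked_path", "data.frame")))
  leaf <- deepest_leaf(graph)
  ids <- integer(0); j <- leaf
  while (j != 0L) { ids <- c(j, ids); j <- graph$parent[j] }
  nd <- graph$nodes
  manual <- if (length(graph$corrections))
    do.call(rbind, graph$corrections) else matrix(numeric(0), 0, 3)
  src <- rep("auto", length(ids))
  if (nrow(manual) > 0)
    src[paste(nd$x[ids], nd$y[ids], nd$z[ids]) %in%
          paste(manual[, 1], manual[, 2], manual[, 3])] <- "manual"
  structure(data.frame(x = nd$x[ids], y = nd$y[ids], z = nd$z[ids],
                       radius = nd$minor_axis[ids] / 2, source = src),
            class = c("tracked_path", "data.frame"))
}

#' @export
print.tracked_path <- function(x, ...) {
  cat(sprintf("<tracked_path> %d points, slices %s, %d manual\n",
              nrow(x),
              if (nrow(x)) paste(range(x$z), collapse = "-") else "-",
              sum(x$source == "manual")))
  invisible(x)
}

#' Plot a tracked path
#'
#' Simple x-z projection coloured by radius; a quick visual check of the
#' reconstruction.
#'
#' @param x a `tracked_path`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tracked_path <- function(x, ...) {
  graphics::plot(x$x, x$z, type = "l", xlab = "x (px)", ylab = "slice",
                 ylim = rev(range(x$z)), ...)
  graphics::points(x$x, x$z, pch = 16, cex = 0.4,
                   col = ifelse(x$source == "manual", "red", "black"))
  invisible(x)
}

#' Compare a tracked path with a ground-truth path
#'
#' Per-slice residuals between automatic and truth coordinates yield the two
#' correctness measures: `alpha` (accuracy) is the percentage of automatic
#' points whose distance to the truth path on the same slice is below the
#' residual threshold; `beta` (extent) is the percentage of truth points
#' matched by some automatic point below the threshold.
#'
#' @param path a `tracked_path` (or data frame with `x`, `y`, `z`).
#' @param truth ground-truth path, same columns.
#' @param threshold residual threshold in px (15 by default: the scale below
#'   which residuals concentrate for correctly tracked tubules).
#' @return List with `alpha`, `beta` (percent) and the per-point residuals.
#' @export
evaluate_against_truth <- function(path, truth, threshold = 15) {
  if (nrow(path) == 0) stop("alpha is undefined for an empty path")
  res_to <- function(a, b) {
    vapply(seq_len(nrow(a)), function(i) {
      j <- which(b$z == a$z[i])
      if (length(j) == 0) return(Inf)
      min(sqrt((b$x[j] - a$x[i])^2 + (b$y[j] - a$y[i])^2))
    }, numeric(1))
  }
  ra <- res_to(path, truth)
  rb <- res_to(truth, path)
  list(alpha = 100 * mean(ra < threshold),
       beta = 100 * mean(rb < threshold),
       residuals_auto = ra, residuals_truth = rb)
}
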