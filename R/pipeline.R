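# Run orchestration: stack in -> preprocess -> features -> track per seed ->
# reconstruct -> export. Every run is reproducible from its resolved
# configuration plus inputs under fixed seeds.

#' Assemble a pipeline run configuration
#'
#' @param stack a `slice_stack`, or a directory readable by [read_stack()].
#' @param seeds list of `(x, y, z)` seed coordinates (one tracked path each).
#' @param params a [preprocess_params()].
#' @param schedule optional [sigmoid_schedule()].
#' @param config a [track_config()].
#' @param classifier optional `move_classifier`, or a path readable by
#'   [read_move_classifier()]; `NULL` disables ML validation.
#' @param correction_provider optional correction callback (see [track()]).
#' @param truth optional ground-truth path (data frame `x, y, z`) or list of
#'   paths, matched to seeds by index, enabling alpha/beta reporting.
#' @param node_spacing node-allocation spacing target (px).
#' @param eval_threshold residual threshold (px) for alpha/beta.
#' @param record_all_rules evaluate all validators per move so the report
#'   can account for rejection overlap between rules.
#' @param out output prefix (directory/base); `NULL` writes nothing.
#' @param seed random seed for clustering.
#' @export
run_config <- function(stack, seeds, params = preprocess_params(),
                       schedule = NULL, config = track_config(),
                       classifier = NULL, correction_provider = NULL,
                       truth = NULL, node_spacing = 30, eval_threshold = 15,
                       record_all_rules = FALSE, out = NULL, seed = 1) {
  structure(list(stack = stack, seeds = seeds, params = params,
                 schedule = schedule, config = config,
                 classifier = classifier,
                 correction_provider = correction_provider, truth = truth,
                 node_spacing = node_spacing,
                 eval_threshold = eval_threshold,
                 record_all_rules = record_all_rules, out = out,
                 seed = seed),
            class = "run_config")
}

#' Execute the full tracking pipeline
#'
#' Preprocesses the stack, extracts features, tracks every seed and
#' reconstructs its path. The report carries, per seed: path length, skips
#' used, per-rule rejection counts (first-firing rule; plus overlap counts
#' when `record_all_rules`), manual corrections, and alpha/beta against the
#' supplied ground truth. With an output prefix, paths are written as CSV
#' and SWC, the report and the resolved configuration as JSON.
#'
#' @param rc a [run_config()].
#' @return List of class `run_report` with elements `paths` (list of
#'   `tracked_path`) and `report`.
#' @export
run_pipeline <- function(rc) {
  stack <- if (is.character(rc$stack)) read_stack(rc$stack) else rc$stack
  classifier <- if (is.character(rc$classifier))
    read_move_classifier(rc$classifier) else rc$classifier
  binary <- preprocess_stack(stack, rc$params, rc$schedule)
  features <- extract_features(binary, max_mean_spacing = rc$node_spacing,
                               seed = rc$seed)
  truths <- if (is.data.frame(rc$truth)) list(rc$truth) else rc$truth
  paths <- list(); per_seed <- list()
  for (si in seq_along(rc$seeds)) {
    g <- track(stack, features, rc$seeds[[si]], rc$config, classifier,
               rc$correction_provider,
               record_all_rules = rc$record_all_rules)
    p <- reconstruct_path(g)
    paths[[si]] <- p
    entry <- list(seed = rc$seeds[[si]], path_length = nrow(p),
                  slices_covered = length(unique(p$z)),
                  skips_used = g$skips_used,
                  rejections = as.list(g$rejections),
                  rejection_overlap = if (rc$record_all_rules)
                    as.list(g$rejection_overlap) else NULL,
                  ml_rejections = unname(g$rejections["ml"]),
                  corrections = length(g$corrections),
                  terminated_at_glomerulus = g$terminated_at_glomerulus)
    if (!is.null(truths) && length(truths) >= si) {
      ev <- evaluate_against_truth(p, truths[[si]], rc$eval_threshold)
      entry$alpha <- ev$alpha; entry$beta <- ev$beta
    }
    per_seed[[si]] <- entry
  }
  report <- list(n_seeds = length(rc$seeds), n_slices = n_slices(stack),
                 n_nodes = nrow(features$nodes), seeds = per_seed)
  if (!is.null(rc$out)) {
    dir.create(dirname(rc$out), showWarnings = FALSE, recursive = TRUE)
    for (si in seq_along(paths)) {
      write_path_csv(paths[[si]], sprintf("%s_path%d.csv", rc$out, si))
      write_path_swc(paths[[si]], sprintf("%s_path%d.swc", rc$out, si))
    }
    jsonlite::write_json(report, paste0(rc$out, "_report.json"),
                         auto_unbox = TRUE, digits = NA)
    resolved <- rc[c("seeds", "node_spacing", "eval_threshold", "seed")]
    resolved$params <- unclass(rc$params)
    resolved$config <- unclass(rc$config)
    resolved$schedule <- if (is.null(rc$schedule)) NULL else unclass(rc$schedule)
    jsonlite::write_json(resolved, paste0(rc$out, "_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(paths = paths, report = report), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d seed(s) over %d slices, %d nodes\n",
              x$report$n_seeds, x$report$n_slices, x$report$n_nodes))
  for (s in x$report$seeds)
    cat(sprintf("  seed (%g,%g,%g): %d points, %d skips, %d corrections%s\n",
                s$seed[1], s$seed[2], s$seed[3], s$path_length, s$skips_used,
                s$corrections,
                if (!is.null(s$alpha))
                  sprintf(", alpha %.1f%%, beta %.1f%%", s$alpha, s$beta)
                else ""))
  invisible(x)
}

#' Write a tracked path as CSV
#'
#' Columns `x, y, z, radius, source` (`source` is `auto` or `manual`).
#'
#' @param path a `tracked_path`.
#' @param file output path.
#' @export
write_path_csv <- function(path, file) {
  utils::write.csv(as.data.frame(path), file, row.names = FALSE)
  invisible(file)
}

#' Write a tracked path in SWC format
#'
#' Standard neuron-morphology tracing format (`id type x y z radius parent`);
#' the type field is repurposed for provenance (2 = automatic, 4 = manual
#' correction bridge). z is expressed in slice units.
#'
#' @param path a `tracked_path`.
#' @param file output path.
#' @export
write_path_swc <- function(path, file) {
  n <- nrow(path)
  df <- data.frame(id = seq_len(n),
                   type = ifelse(path$source == "manual", 4L, 2L),
                   x = path$x, y = path$y, z = path$z, radius = path$radius,
                   parent = c(-1L, seq_len(max(n - 1, 0))))
  utils::write.table(df, file, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
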