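# Accuracy-thresholded learner selection, frequency-based feature ranking,
# feature-count scan and the end-to-end pipeline.

#' Select the significant base learners
#'
#' A learner is significant when its evaluated accuracy is strictly
#' greater than the threshold (0.6 in the reference protocol). Order is
#' preserved.
#'
#' @param cluster An evaluated `nn_cluster` (see [evaluate_learners()]).
#' @param threshold Accuracy threshold (strict inequality).
#' @return List of `base_learner` objects.
#' @export
select_significant_learners <- function(cluster, threshold = 0.6) {
  acc <- learner_accuracies(cluster)
  if (all(is.na(acc))) {
    stop_invalid("cluster has not been evaluated; run evaluate_learners() first")
  }
  cluster$learners[!is.na(acc) & acc > threshold]
}

#' Frequency-based feature ranking over significant learners
#'
#' Counts, for every feature in the universe, how many significant
#' learners drew it, and ranks features by count (descending, ties broken
#' by ascending feature index so the ranking is deterministic).
#'
#' @param significant List of `base_learner` objects (typically from
#'   [select_significant_learners()]).
#' @param universe_size Total number of features.
#' @return An object of class `feature_ranking` with fields `counts`
#'   (length `universe_size`) and `order` (permutation of feature indices,
#'   most frequent first).
#' @export
feature_frequency <- function(significant, universe_size) {
  stopifnot(is_count(universe_size), universe_size >= 1)
  idx <- as.integer(unlist(lapply(significant, `[[`, "feature_indices")))
  if (length(idx) > 0 && max(idx) > universe_size) {
    stop_invalid("learner references feature %d beyond universe of %d",
                 max(idx), universe_size)
  }
  counts <- tabulate(idx, nbins = universe_size)
  structure(list(counts = counts,
                 order = order(-counts, seq_len(universe_size)),
                 n_significant = length(significant)),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  nz <- sum(x$counts > 0)
  cat(sprintf("feature_ranking: %d features, %d with nonzero count over %d significant learners\n",
              length(x$counts), nz, x$n_significant))
  invisible(x)
}

#' Top-ranked features
#'
#' @param ranking A [feature_frequency()] ranking.
#' @param m How many features to take.
#' @return Integer vector: the first `m` entries of the ranked order.
#' @export
top_features <- function(ranking, m) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (!is_count(m) || m < 0 || m > length(ranking$order)) {
    stop_invalid("`m` must be between 0 and the universe size %d",
                 length(ranking$order))
  }
  ranking$order[seq_len(m)]
}

#' Scan candidate feature-set sizes
#'
#' For each candidate count `c`, restricts the feature pool to the top `c`
#' ranked features, builds a fresh cluster drawing `m_features` per
#' learner from that pool, and scores it on the test set. Every candidate
#' reuses the same master-seed-derived learner substreams, so candidates
#' differ only by their feature pool. The optimal count is the candidate
#' with the highest accuracy; ties go to the smallest count (parsimony).
#'
#' @param train,test Training and test [fc_dataset()]s.
#' @param ranking A [feature_frequency()] ranking.
#' @param candidate_counts Candidate pool sizes (default `config$scan_counts`,
#'   i.e. 140..240 by 10).
#' @param config A [cluster_config()]; `scan_k` learners per candidate.
#' @return An object of class `fc_scan` with fields `candidate_counts`,
#'   `accuracy`, `optimal_count`.
#' @export
scan_feature_counts <- function(train, test, ranking,
                                candidate_counts = config$scan_counts,
                                config = cluster_config()) {
  stopifnot(inherits(ranking, "feature_ranking"))
  candidate_counts <- as.integer(candidate_counts)
  if (length(candidate_counts) < 1) stop_invalid("no candidate counts given")
  if (any(config$m_features > candidate_counts)) {
    stop_invalid("m_features = %d exceeds smallest candidate pool %d",
                 config$m_features, min(candidate_counts))
  }
  n_available <- sum(ranking$counts > 0)
  if (max(candidate_counts) > n_available) {
    warning(sprintf("only %d features have nonzero counts; capping candidates at that",
                    n_available), call. = FALSE)
    candidate_counts <- unique(pmin(candidate_counts, n_available))
  }
  scan_seed <- derive_seeds(config$seed, 3)[3]
  accuracy <- vapply(candidate_counts, function(cnt) {
    pool <- top_features(ranking, cnt)
    cl <- build_cluster(train, config, feature_pool = pool,
                        k = config$scan_k, seed = scan_seed)
    cluster_accuracy(cl, test)
  }, numeric(1))
  best <- which(accuracy == max(accuracy))
  optimal <- min(candidate_counts[best])
  structure(list(candidate_counts = candidate_counts, accuracy = accuracy,
                 optimal_count = optimal),
            class = "fc_scan")
}

#' @export
print.fc_scan <- function(x, ...) {
  cat("Feature-count scan:\n")
  print(data.frame(count = x$candidate_counts, accuracy = x$accuracy),
        row.names = FALSE)
  cat(sprintf("optimal count: %d (accuracy %.4f)\n", x$optimal_count,
              x$accuracy[match(x$optimal_count, x$candidate_counts)]))
  invisible(x)
}

#' @export
plot.fc_scan <- function(x, ...) {
  plot(x$candidate_counts, x$accuracy, type = "b", pch = 16,
       xlab = "number of significant features",
       ylab = "cluster accuracy", ylim = c(0, 1), ...)
  abline(v = x$optimal_count, lty = 2)
  invisible(x)
}

#' Run the full ensemble feature-selection pipeline
#'
#' Executes, deterministically given `config$seed`:
#' split -> build cluster -> evaluate learners -> select significant
#' learners -> frequency ranking -> retain top `top_n` -> feature-count
#' scan -> optimal feature set. When an atlas is supplied, per-region
#' weights of the optimal feature set are computed as well.
#'
#' @param D Full [fc_dataset()].
#' @param config A [cluster_config()].
#' @param atlas Optional `region_atlas` for the region-weighting step.
#' @return An object of class `rnn_pipeline`: list with `split`, `cluster`
#'   (evaluated), `cluster_accuracy`, `significant` (learner list),
#'   `ranking`, `scan`, `selected_features` (the top `optimal_count`
#'   features), `region_weights` (or NULL), and `report` (summary list).
#' @export
run_full_pipeline <- function(D, config = cluster_config(), atlas = NULL) {
  stopifnot(inherits(D, "fc_dataset"))
  seeds <- derive_seeds(config$seed, 2)
  sp <- split_dataset(D, config$train_fraction, seed = seeds[1])

  cluster <- build_cluster(sp$train, config, seed = seeds[2])
  eval_set <- if (config$evaluation == "oob") sp$train else sp$test
  cluster <- evaluate_learners(cluster, eval_set, oob = config$evaluation == "oob")
  acc <- cluster_accuracy(cluster, sp$test)

  significant <- select_significant_learners(cluster, config$threshold)
  if (length(significant) == 0) {
    stop_invalid(paste("no learner exceeded the accuracy threshold %.2f;",
                       "lower `threshold` or increase the signal/learner budget"),
                 config$threshold)
  }
  ranking <- feature_frequency(significant, ncol(D$features))
  stopifnot(sum(ranking$counts) == length(significant) * config$m_features)

  top_n <- min(config$top_n, sum(ranking$counts > 0))
  candidates <- config$scan_counts[config$scan_counts <= top_n]
  if (length(candidates) == 0) candidates <- top_n
  scan <- scan_feature_counts(sp$train, sp$test, ranking,
                              candidate_counts = candidates, config = config)
  selected <- top_features(ranking, scan$optimal_count)

  weights <- if (!is.null(atlas)) region_weights(selected, atlas) else NULL
  if (!is.null(weights)) stopifnot(sum(weights$weight) == 2 * length(selected))

  la <- learner_accuracies(cluster)
  report <- list(
    n_subjects = nrow(D$features), n_features = ncol(D$features),
    n_train = nrow(sp$train$features), n_test = nrow(sp$test$features),
    cluster_accuracy = acc,
    learner_accuracy = list(min = min(la), mean = mean(la),
                            max = max(la), sd = sd(la)),
    n_significant = length(significant),
    scan = list(counts = scan$candidate_counts, accuracy = scan$accuracy),
    optimal_count = scan$optimal_count,
    seed = config$seed)
  structure(list(split = sp, cluster = cluster, cluster_accuracy = acc,
                 significant = significant, ranking = ranking, scan = scan,
                 selected_features = selected, region_weights = weights,
                 report = report, config = config),
            class = "rnn_pipeline")
}

#' @export
print.rnn_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "Random neural network cluster pipeline\n",
    "  subjects: %d (%d train / %d test), features: %d\n",
    "  cluster accuracy (majority vote): %.4f\n",
    "  per-learner accuracy: min %.3f / mean %.3f / max %.3f / sd %.3f\n",
    "  significant learners (> %.2f): %d\n",
    "  optimal feature count: %d\n"),
    r$n_subjects, r$n_train, r$n_test, r$n_features, r$cluster_accuracy,
    r$learner_accuracy$min, r$learner_accuracy$mean, r$learner_accuracy$max,
    r$learner_accuracy$sd, x$config$threshold, r$n_significant,
    r$optimal_count))
  invisible(x)
}

#' Export a feature ranking as CSV
#'
#' Columns: `feature_index`, `region_i`, `region_j`, `abbrev_i`,
#' `abbrev_j`, `count`, `rank`. Rows are in rank order.
#'
#' @param ranking A [feature_frequency()] ranking over an edge universe.
#' @param atlas `region_atlas` matching the universe.
#' @param path Output CSV path.
#' @param n_top How many rows to write (default: all with nonzero count).
#' @export
write_ranking_csv <- function(ranking, atlas, path,
                              n_top = sum(ranking$counts > 0)) {
  R <- nrow(atlas)
  stopifnot(length(ranking$counts) == n_edges(R))
  idx <- top_features(ranking, n_top)
  pairs <- index_to_edge(idx, R)
  tab <- data.frame(feature_index = idx,
                    region_i = pairs[, 1], region_j = pairs[, 2],
                    abbrev_i = atlas$abbrev[pairs[, 1]],
                    abbrev_j = atlas$abbrev[pairs[, 2]],
                    count = ranking$counts[idx],
                    rank = seq_along(idx))
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Export a feature-count scan as CSV (and optionally a plot)
#'
#' @param scan An `fc_scan`.
#' @param path Output CSV path (columns `count`, `accuracy`).
#' @param plot_path Optional PNG path for the accuracy-vs-count curve.
#' @export
write_scan_csv <- function(scan, path, plot_path = NULL) {
  stopifnot(inherits(scan, "fc_scan"))
  write.csv(data.frame(count = scan$candidate_counts,
                       accuracy = scan$accuracy),
            path, row.names = FALSE)
  if (!is.null(plot_path)) {
    png(plot_path, width = 800, height = 500)
    plot(scan)
    dev.off()
  }
  invisible(path)
}
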