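# The random neural network cluster: k base learners trained on random
# subject/feature subsets, majority-vote prediction, accuracy C/N2.

#' Configuration for building a random neural network cluster
#'
#' Defaults mirror the reference protocol for a 61-subject, 4005-edge
#' problem: an 8:2 train/test split, 1000 learners each trained on 45 of
#' the 48 training subjects and 120 of the 4005 features, a 0.6 accuracy
#' threshold for significance, retention of the top 240 features, and a
#' feature-count scan over 140..240 in steps of 10.
#'
#' @param k Number of base learners in the cluster.
#' @param n_samples Subjects drawn (without replacement) per learner.
#' @param m_features Features drawn (without replacement) per learner.
#' @param train_fraction Fraction of subjects assigned to the training set.
#' @param threshold Per-learner accuracy must be strictly greater than this
#'   for the learner to count as significant.
#' @param top_n Number of top-ranked features retained before the scan.
#' @param scan_counts Candidate feature-set sizes for the scan.
#' @param scan_k Learners per scan cluster (defaults to `k`; desk-scale
#'   runs typically use 100-200).
#' @param learner_kind Base-learner kind (see [get_learner_kind()]).
#' @param learner_params Hyperparameters handed to the learner kind.
#' @param stratify Draw the per-learner subject subset proportionally by
#'   class instead of uniformly (default FALSE: uniform, unstratified).
#' @param evaluation `"test"` scores each learner on the held-out test set;
#'   `"oob"` scores it on the training subjects it never saw (out-of-bag),
#'   which avoids test-set leakage into feature selection.
#' @param seed Master seed; all randomness (split, subset draws, learner
#'   initialization) derives from it.
#' @return An object of class `cluster_config`.
#' @export
cluster_config <- function(k = 1000, n_samples = 45, m_features = 120,
                           train_fraction = 0.8, threshold = 0.6,
                           top_n = 240, scan_counts = seq(140, 240, by = 10),
                           scan_k = k, learner_kind = "mlp",
                           learner_params = list(), stratify = FALSE,
                           evaluation = c("test", "oob"), seed = 1) {
  stopifnot(is_count(k), k >= 1, is_count(n_samples), n_samples >= 1,
            is_count(m_features), m_features >= 1,
            train_fraction > 0, train_fraction < 1,
            threshold >= 0, threshold <= 1)
  structure(list(k = as.integer(k), n_samples = as.integer(n_samples),
                 m_features = as.integer(m_features),
                 train_fraction = train_fraction, threshold = threshold,
                 top_n = as.integer(top_n),
                 scan_counts = as.integer(scan_counts),
                 scan_k = as.integer(scan_k),
                 learner_kind = learner_kind,
                 learner_params = learner_params,
                 stratify = isTRUE(stratify),
                 evaluation = match.arg(evaluation),
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Split a dataset into training and test sets
#'
#' Subjects are assigned uniformly at random: `floor(train_fraction * n)`
#' go to training, the remainder to test (61 subjects at 8:2 gives 48/13).
#' A draw that leaves the training set without both classes is redrawn, up
#' to 100 times.
#'
#' @param D An [fc_dataset()] with at least 2 subjects per class.
#' @param train_fraction Training proportion in (0, 1).
#' @param seed Seed for the split.
#' @return List with elements `train` and `test` (both [fc_dataset()]),
#'   plus `train_idx` / `test_idx` giving row indices into `D`.
#' @export
split_dataset <- function(D, train_fraction = 0.8, seed = 1) {
  stopifnot(inherits(D, "fc_dataset"))
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("`train_fraction` must be in (0, 1)")
  }
  n <- nrow(D$features)
  n_train <- floor(train_fraction * n)
  if (n_train < 2 || n_train >= n) {
    stop_invalid("split of %d subjects at %.2f leaves an unusable set", n, train_fraction)
  }
  seeds <- derive_seeds(seed, 100)
  for (attempt in seq_along(seeds)) {
    train_idx <- sort(with_seed(seeds[attempt], sample.int(n, n_train)))
    if (length(unique(D$labels[train_idx])) == 2) {
      test_idx <- setdiff(seq_len(n), train_idx)
      return(list(train = subset_rows(D, train_idx),
                  test = subset_rows(D, test_idx),
                  train_idx = train_idx, test_idx = test_idx))
    }
  }
  stop_invalid("could not draw a training set containing both classes in 100 attempts")
}

#' Draw one learner's subject and feature subset
#'
#' Both draws are uniform without replacement. The feature draw comes from
#' `feature_pool`: the full universe when building the initial cluster, or
#' a restricted top-ranked candidate set during the feature-count scan.
#'
#' @param train Training [fc_dataset()].
#' @param n_samples Subjects to draw.
#' @param m_features Features to draw.
#' @param feature_pool Vector of feature indices to draw from.
#' @param seed Seed for this draw.
#' @param stratify Proportional-by-class subject draw instead of uniform.
#' @return List with `sample_indices` and sorted `feature_indices`.
#' @export
draw_subset <- function(train, n_samples, m_features, feature_pool,
                        seed, stratify = FALSE) {
  n <- nrow(train$features)
  if (n_samples > n) {
    stop_invalid("cannot draw %d subjects from %d", n_samples, n)
  }
  if (m_features > length(feature_pool)) {
    stop_invalid("cannot draw %d features from a pool of %d",
                 m_features, length(feature_pool))
  }
  with_seed(seed, {
    if (stratify) {
      pos <- which(train$labels == 1)
      neg <- which(train$labels == -1)
      n_pos <- min(length(pos), max(1, round(n_samples * length(pos) / n)))
      n_neg <- n_samples - n_pos
      if (n_neg > length(neg) || n_neg < 1) {
        stop_invalid("stratified draw of %d subjects is infeasible", n_samples)
      }
      sample_indices <- sort(c(sample(pos, n_pos), sample(neg, n_neg)))
    } else {
      sample_indices <- sort(sample.int(n, n_samples))
    }
    feature_indices <- sort(sample(feature_pool, m_features))
    list(sample_indices = sample_indices, feature_indices = feature_indices)
  })
}

#' Build a random neural network cluster
#'
#' Repeats the draw-and-train step `config$k` times: each learner gets its
#' own RNG substream (derived from the master seed), draws `n_samples`
#' subjects and `m_features` features, and fits the configured classifier.
#' Subject draws yielding a single class are rejected and redrawn (at most
#' 100 times per learner).
#'
#' @param train Training [fc_dataset()].
#' @param config A [cluster_config()].
#' @param feature_pool Feature indices to draw from (default: all columns).
#' @param k Number of learners (default `config$k`).
#' @param seed Master seed for the learner substreams (default
#'   `config$seed`). The scan passes the same seed for every candidate
#'   pool so that candidates differ only by the pool.
#' @return An object of class `nn_cluster`.
#' @export
build_cluster <- function(train, config, feature_pool = NULL,
                          k = config$k, seed = config$seed) {
  stopifnot(inherits(train, "fc_dataset"), inherits(config, "cluster_config"))
  if (is.null(feature_pool)) feature_pool <- seq_len(ncol(train$features))
  if (length(unique(train$labels)) < 2) {
    stop_invalid("training set must contain both classes")
  }
  if (config$n_samples > nrow(train$features)) {
    stop_invalid("n_samples = %d exceeds training size %d",
                 config$n_samples, nrow(train$features))
  }
  learner_seeds <- derive_seeds(seed, k)
  learners <- vector("list", k)
  for (l in seq_len(k)) {
    retry_seeds <- derive_seeds(learner_seeds[l], 101)
    subset <- NULL
    for (s in retry_seeds[-length(retry_seeds)]) {
      cand <- draw_subset(train, config$n_samples, config$m_features,
                          feature_pool, seed = s, stratify = config$stratify)
      if (length(unique(train$labels[cand$sample_indices])) == 2) {
        subset <- cand
        break
      }
    }
    if (is.null(subset)) {
      stop_invalid("learner %d: no two-class subject draw in 100 attempts", l)
    }
    learners[[l]] <- tryCatch(
      with_seed(retry_seeds[length(retry_seeds)],
                train_base_learner(train, subset$sample_indices,
                                   subset$feature_indices,
                                   config$learner_kind, config$learner_params)),
      error = function(e) stop_invalid("learner %d failed: %s", l, conditionMessage(e)))
  }
  structure(list(learners = learners, config = config,
                 feature_universe_size = ncol(train$features),
                 feature_pool = as.integer(feature_pool)),
            class = "nn_cluster")
}

#' @export
print.nn_cluster <- function(x, ...) {
  acc <- learner_accuracies(x)
  cat(sprintf("Random neural network cluster: %d learners (%s), universe %d features\n",
              length(x$learners), x$learners[[1]]$kind_name,
              x$feature_universe_size))
  if (!all(is.na(acc))) {
    cat(sprintf("  per-learner accuracy: min %.3f / mean %.3f / max %.3f\n",
                min(acc), mean(acc), max(acc)))
  }
  invisible(x)
}

#' Majority-vote prediction of a cluster
#'
#' Every learner votes +1 or -1 using its own feature columns; the
#' ensemble prediction is the sign of the vote sum. An exact tie (possible
#' for even `k`) resolves to +1, the control-group label, so that
#' predictions are deterministic.
#'
#' @param cluster An `nn_cluster`.
#' @param X Feature matrix over the full universe (or [fc_dataset()]).
#' @return Vector of +1/-1, one per row of `X`.
#' @export
predict_majority <- function(cluster, X) {
  stopifnot(inherits(cluster, "nn_cluster"))
  if (inherits(X, "fc_dataset")) X <- X$features
  if (ncol(X) != cluster$feature_universe_size) {
    stop_invalid("matrix has %d columns; cluster expects the %d-feature universe",
                 ncol(X), cluster$feature_universe_size)
  }
  votes <- vapply(cluster$learners, function(lr) predict_learner(lr, X),
                  numeric(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  ifelse(rowSums(votes) >= 0, 1, -1)
}

#' Classification accuracy of the cluster on a test set
#'
#' The fraction C/N of test subjects whose majority-vote prediction equals
#' their true label.
#'
#' @param cluster An `nn_cluster`.
#' @param test Nonempty [fc_dataset()].
#' @return Accuracy in \[0, 1\].
#' @export
cluster_accuracy <- function(cluster, test) {
  stopifnot(inherits(test, "fc_dataset"))
  if (nrow(test$features) == 0) stop_invalid("test set is empty")
  mean(predict_majority(cluster, test) == test$labels)
}

#' Evaluate every base learner's own accuracy
#'
#' Fills each learner's `test_accuracy` with its individual accuracy on
#' the evaluation set (each learner predicting from its own feature
#' columns). With `oob = TRUE` each learner is instead scored on the
#' training subjects it never drew (out-of-bag), which keeps the held-out
#' test set out of feature selection.
#'
#' @param cluster An `nn_cluster`.
#' @param eval_set [fc_dataset()] to score on (the held-out test set in
#'   the reference protocol; the training set when `oob = TRUE`).
#' @param oob Score each learner on its own out-of-bag rows of `eval_set`.
#' @return The cluster with per-learner `test_accuracy` filled; learner
#'   order unchanged.
#' @export
evaluate_learners <- function(cluster, eval_set, oob = FALSE) {
  stopifnot(inherits(cluster, "nn_cluster"), inherits(eval_set, "fc_dataset"))
  if (nrow(eval_set$features) == 0) stop_invalid("evaluation set is empty")
  cluster$learners <- lapply(cluster$learners, function(lr) {
    rows <- seq_len(nrow(eval_set$features))
    if (oob) {
      rows <- setdiff(rows, lr$sample_indices)
      if (length(rows) == 0) {
        lr$test_accuracy <- NA_real_
        return(lr)
      }
    }
    pred <- predict_learner(lr, eval_set$features[rows, , drop = FALSE])
    lr$test_accuracy <- mean(pred == eval_set$labels[rows])
    lr
  })
  cluster
}

#' Per-learner accuracies of an evaluated cluster
#'
#' @param cluster An `nn_cluster`.
#' @return Numeric vector of per-learner accuracies (NA if unevaluated).
#' @export
learner_accuracies <- function(cluster) {
  vapply(cluster$learners, `[[`, numeric(1), "test_accuracy")
}

#' Save / load a cluster
#'
#' `save_cluster()` writes a run directory: `manifest.json` (configuration,
#' per-learner feature and subject indices, accuracies, format version) and
#' `models.rds` (the trained models in R's native serialization).
#'
#' @param cluster An `nn_cluster`.
#' @param dir Directory to create/write.
#' @return `save_cluster()` the directory path; `load_cluster()` the
#'   restored `nn_cluster`.
#' @export
save_cluster <- function(cluster, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    format_version = 1L,
    config = unclass(cluster$config),
    feature_universe_size = cluster$feature_universe_size,
    feature_pool = cluster$feature_pool,
    learners = lapply(cluster$learners, function(lr) {
      list(feature_indices = lr$feature_indices,
           sample_indices = lr$sample_indices,
           kind = lr$kind_name, test_accuracy = lr$test_accuracy)
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  saveRDS(lapply(cluster$learners, function(lr) list(model = lr$model, kind = lr$kind)),
          file.path(dir, "models.rds"))
  invisible(dir)
}

#' @rdname save_cluster
#' @export
load_cluster <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  models <- readRDS(file.path(dir, "models.rds"))
  cfg <- manifest$config
  config <- cluster_config(k = cfg$k, n_samples = cfg$n_samples,
                           m_features = cfg$m_features,
                           train_fraction = cfg$train_fraction,
                           threshold = cfg$threshold, top_n = cfg$top_n,
                           scan_counts = cfg$scan_counts, scan_k = cfg$scan_k,
                           learner_kind = cfg$learner_kind,
                           stratify = cfg$stratify,
                           evaluation = cfg$evaluation, seed = cfg$seed)
  learners <- lapply(seq_along(models), function(l) {
    meta <- manifest$learners[l, ]
    structure(list(feature_indices = as.integer(meta$feature_indices[[1]]),
                   sample_indices = as.integer(meta$sample_indices[[1]]),
                   model = models[[l]]$model, kind = models[[l]]$kind,
                   kind_name = meta$kind,
                   test_accuracy = as.numeric(meta$test_accuracy)),
              class = "base_learner")
  })
  structure(list(learners = learners, config = config,
                 feature_universe_size = manifest$feature_universe_size,
                 feature_pool = as.integer(manifest$feature_pool)),
            class = "nn_cluster")
}
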