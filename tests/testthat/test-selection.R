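stub_cluster_with_acc <- function(accs, feature_sets = NULL, universe = 10) {
  preds <- lapply(seq_along(accs), function(i) c(1, -1))
  cl <- make_stub_cluster(preds, universe = universe)
  for (i in seq_along(accs)) {
    cl$learners[[i]]$test_accuracy <- accs[i]
    if (!is.null(feature_sets)) {
      cl$learners[[i]]$feature_indices <- as.integer(feature_sets[[i]])
    }
  }
  cl
}

test_that("significance uses a strict accuracy threshold, order preserved", {
  cl <- stub_cluster_with_acc(c(0.7, 0.6, 0.5))
  sig <- select_significant_learners(cl, 0.6)
  expect_length(sig, 1)
  expect_equal(sig[[1]]$test_accuracy, 0.7)
  expect_length(select_significant_learners(cl, 0), 3)
  expect_length(select_significant_learners(cl, 0.9), 0)
  un <- make_stub_cluster(list(c(1, -1)))
  expect_error(select_significant_learners(un, 0.6), "not been evaluated")
})

test_that("raising the threshold never grows the significant set", {
  set.seed(21)
  cl <- stub_cluster_with_acc(runif(40))
  prev <- select_significant_learners(cl, 0)
  for (thr in seq(0.1, 0.9, by = 0.1)) {
    cur <- select_significant_learners(cl, thr)
    ids_prev <- vapply(prev, function(l) l$test_accuracy, numeric(1))
    ids_cur <- vapply(cur, function(l) l$test_accuracy, numeric(1))
    expect_true(all(ids_cur %in% ids_prev))
    expect_lte(length(cur), length(prev))
    prev <- cur
  }
})

test_that("feature frequencies match a hand tally and conserve draws", {
  cl <- stub_cluster_with_acc(c(0.9, 0.9),
                              feature_sets = list(c(1, 2), c(2, 3)),
                              universe = 3)
  rk <- feature_frequency(cl$learners, 3)
  expect_identical(rk$counts, c(1L, 2L, 1L))
  expect_identical(rk$order, c(2L, 1L, 3L))

  expect_identical(feature_frequency(list(), 5)$counts, integer(5))

  set.seed(4)
  sets <- lapply(1:30, function(i) sample.int(200, 12))
  cl2 <- stub_cluster_with_acc(rep(1, 30), feature_sets = sets, universe = 200)
  rk2 <- feature_frequency(cl2$learners, 200)
  expect_identical(sum(rk2$counts), 30L * 12L)
})

test_that("top features form count-descending prefixes with index tie-breaks", {
  set.seed(31)
  counts <- sample(0:4, 120, replace = TRUE)  # heavy ties
  sets <- unlist(lapply(seq_along(counts), function(f) rep(f, counts[f])))
  # one stub learner per occurrence so tabulated counts reproduce `counts`
  cl <- stub_cluster_with_acc(rep(1, length(sets)),
                              feature_sets = as.list(sets), universe = 120)
  rk <- feature_frequency(cl$learners, 120)
  expect_identical(rk$counts, as.integer(counts))
  expect_identical(rk$order, rank_oracle(counts))
  for (m in c(0, 1, 17, 120)) {
    expect_identical(top_features(rk, m), rank_oracle(counts)[seq_len(m)])
  }
  # prefix property
  expect_identical(top_features(rk, 10), top_features(rk, 50)[1:10])
  expect_error(top_features(rk, 121), "universe size")
})

test_that("the feature-count scan scores each candidate pool and picks the best", {
  cfg <- synthetic_config(R = 10, T = 40, n_pos = 14, n_neg = 12, planted = 4,
                          delta = 0.5, seed = 13)
  D <- simulate_feature_matrix(cfg)
  cc <- cluster_config(k = 25, n_samples = 14, m_features = 6,
                       scan_k = 15, seed = 6, learner_kind = centroid_kind)
  sp <- split_dataset(D, 0.8, seed = 1)
  cl <- evaluate_learners(build_cluster(sp$train, cc), sp$test)
  rk <- feature_frequency(select_significant_learners(cl, 0.6), n_edges(10))

  single <- scan_feature_counts(sp$train, sp$test, rk,
                                candidate_counts = 12, config = cc)
  expect_identical(single$optimal_count, 12L)
  expect_length(single$accuracy, 1)

  multi <- scan_feature_counts(sp$train, sp$test, rk,
                               candidate_counts = c(8, 12, 16), config = cc)
  expect_length(multi$accuracy, 3)
  expect_true(multi$optimal_count %in% c(8L, 12L, 16L))
  expect_equal(multi$accuracy[match(multi$optimal_count, multi$candidate_counts)],
               max(multi$accuracy))
  # ties break to the smallest count: rerun and check the rule directly
  best <- multi$candidate_counts[multi$accuracy == max(multi$accuracy)]
  expect_identical(multi$optimal_count, min(best))

  expect_error(scan_feature_counts(sp$train, sp$test, rk,
                                   candidate_counts = 4, config = cc),
               "m_features")
})

test_that("default scan grid has 11 candidates from 140 to 240", {
  cc <- cluster_config()
  expect_identical(cc$scan_counts, seq(140L, 240L, by = 10L))
  expect_length(cc$scan_counts, 11)
})

test_that("the full pipeline runs, conserves counts, and is reproducible", {
  cfg <- synthetic_config(R = 12, T = 50, n_pos = 16, n_neg = 12, planted = 5,
                          delta = 0.5, seed = 17)
  D <- build_feature_matrix(simulate_cohort(cfg))
  cc <- cluster_config(k = 30, n_samples = 18, m_features = 8, top_n = 40,
                       scan_counts = c(12, 20, 28), scan_k = 15, seed = 23)
  res <- run_full_pipeline(D, cc, atlas = synthetic_atlas(12))

  expect_s3_class(res, "rnn_pipeline")
  expect_identical(sum(res$ranking$counts),
                   length(res$significant) * cc$m_features)
  expect_identical(sum(res$region_weights$weight),
                   2L * length(res$selected_features))
  expect_length(res$selected_features, res$scan$optimal_count)

  res2 <- run_full_pipeline(D, cc, atlas = synthetic_atlas(12))
  expect_identical(
    jsonlite::toJSON(res$report, auto_unbox = TRUE, digits = NA),
    jsonlite::toJSON(res2$report, auto_unbox = TRUE, digits = NA))
  expect_identical(res$selected_features, res2$selected_features)
})

test_that("planted edges dominate the ranking when counting statistics allow", {
  # Frequency counting separates planted from background edges when (a)
  # each planted edge is drawn by enough learners for its count to clear
  # the Poisson tail of the background (k*m/M ~ 18 here) and (b) the
  # accuracy threshold admits few noise-only learners. Recovery should
  # then be essentially perfect.
  fracs <- vapply(1:3, function(seed) {
    cfg <- synthetic_config(R = 30, T = 60, n_pos = 30, n_neg = 30,
                            planted = 5, delta = 0.5, seed = seed)
    D <- simulate_feature_matrix(cfg)
    cc <- cluster_config(k = 400, n_samples = 45, m_features = 20,
                         threshold = 0.7, seed = seed)
    sp <- split_dataset(D, 0.8, seed = seed)
    cl <- evaluate_learners(build_cluster(sp$train, cc), sp$test)
    rk <- feature_frequency(select_significant_learners(cl, cc$threshold),
                            n_edges(30))
    mean(planted_edges(D) %in% top_features(rk, 10))
  }, numeric(1))
  expect_gte(mean(fracs), 0.8)
})
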