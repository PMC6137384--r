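test_that("train/test split follows the floor rule and is a partition", {
  D61 <- make_dataset(n = 61, p = 8, seed = 1)
  sp <- split_dataset(D61, 0.8, seed = 2)
  expect_equal(nrow(sp$train$features), 48)
  expect_equal(nrow(sp$test$features), 13)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)
  expect_setequal(c(sp$train_idx, sp$test_idx), 1:61)
  expect_length(unique(sp$train$labels), 2)

  sp10 <- split_dataset(make_dataset(10, 4), 0.8, seed = 1)
  expect_equal(nrow(sp10$train$features), 8)
  expect_equal(nrow(sp10$test$features), 2)
  sp7 <- split_dataset(make_dataset(7, 4), 0.8, seed = 1)
  expect_equal(nrow(sp7$train$features), 5)
  expect_equal(nrow(sp7$test$features), 2)

  expect_identical(split_dataset(D61, 0.8, seed = 5)$train_idx,
                   split_dataset(D61, 0.8, seed = 5)$train_idx)
  expect_error(split_dataset(D61, 1.2), "in \\(0, 1\\)")
})

test_that("subset draws are without replacement, in range, reproducible", {
  train <- make_dataset(48, 6)
  s1 <- draw_subset(train, 48, 3, 1:6, seed = 1)
  expect_identical(s1$sample_indices, 1:48)        # exhaustive draw
  s2 <- draw_subset(train, 45, 120, 1:4005, seed = 7)
  expect_length(s2$feature_indices, 120)
  expect_false(anyDuplicated(s2$feature_indices) > 0)
  expect_true(all(s2$feature_indices %in% 1:4005))
  expect_length(unique(s2$sample_indices), 45)
  expect_identical(draw_subset(train, 45, 120, 1:4005, seed = 7), s2)
  expect_error(draw_subset(train, 49, 3, 1:6, seed = 1), "cannot draw")
  expect_error(draw_subset(train, 10, 7, 1:6, seed = 1), "cannot draw")
})

test_that("a separable toy problem is learned perfectly", {
  set.seed(11)
  n <- 30
  labels <- rep(c(1, -1), each = n / 2)
  x <- cbind(rnorm(n, mean = 3 * labels), rnorm(n, mean = -3 * labels))
  D <- fc_dataset(x, labels)
  lr <- train_base_learner(D, 1:n, 1:2, "mlp")
  expect_equal(predict_learner(lr, D), labels)
})

test_that("constant features fall back to the majority-class prediction", {
  labels <- c(rep(1, 6), rep(-1, 14))
  D <- fc_dataset(matrix(1, 20, 3), labels)
  lr <- train_base_learner(D, 1:20, 1:3, "mlp")
  majority <- if (sum(labels == 1) >= sum(labels == -1)) 1 else -1
  expect_equal(predict_learner(lr, D), rep(majority, 20))
})

test_that("single-class training subsets are refused", {
  D <- make_dataset(10, 4)
  expect_error(train_base_learner(D, which(D$labels == 1), 1:2, "mlp"),
               "single class")
})

test_that("learners trained on shuffled labels sit at chance on held-out data", {
  accs <- vapply(1:50, function(seed) {
    set.seed(seed)
    x <- matrix(rnorm(60 * 3), 60, 3)
    labels <- sample(rep(c(1, -1), 30))         # permutation destroys signal
    D <- fc_dataset(x, labels)
    lr <- train_base_learner(D, 1:40, 1:3, "mlp")
    mean(predict_learner(lr, D$features[41:60, , drop = FALSE]) == labels[41:60])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.08)
})

test_that("majority vote equals the brute-force tally on stub predictions", {
  # exhaustive over every prediction configuration at small sizes
  for (k in 1:3) {
    for (n in 1:2) {
      grids <- expand.grid(rep(list(c(-1, 1)), k * n))
      for (g in seq_len(nrow(grids))) {
        votes <- matrix(as.numeric(grids[g, ]), nrow = k, ncol = n)
        cl <- make_stub_cluster(lapply(seq_len(k), function(l) votes[l, ]))
        X <- matrix(0, n, 4)
        expect_identical(predict_majority(cl, X), tally_oracle(votes))
      }
    }
  }
  # randomized coverage up to 9 learners x 8 subjects
  set.seed(99)
  for (rep in 1:100) {
    k <- sample(4:9, 1)
    n <- sample(1:8, 1)
    votes <- matrix(sample(c(-1, 1), k * n, replace = TRUE), k, n)
    cl <- make_stub_cluster(lapply(seq_len(k), function(l) votes[l, ]))
    expect_identical(predict_majority(cl, matrix(0, n, 4)), tally_oracle(votes))
  }
})

test_that("tied votes resolve to +1", {
  cl <- make_stub_cluster(list(c(1, 1), c(-1, 1)))
  expect_identical(predict_majority(cl, matrix(0, 2, 4)), c(1, 1))
})

test_that("cluster accuracy is the fraction of consistent test labels", {
  # 13 test subjects, stub votes engineered to get exactly 12 right
  labels <- rep(c(1, -1), length.out = 13)
  pred <- labels
  pred[13] <- -pred[13]
  cl <- make_stub_cluster(list(pred, pred, pred))
  test <- fc_dataset(matrix(0, 13, 4), labels)
  expect_equal(cluster_accuracy(cl, test), 12 / 13)
  expect_equal(cluster_accuracy(cl, test), 0.923077, tolerance = 1e-6)

  all_right <- make_stub_cluster(list(labels))
  expect_equal(cluster_accuracy(all_right, test), 1.0)

  const <- make_stub_cluster(list(rep(1, 12)))
  balanced <- fc_dataset(matrix(0, 12, 4), rep(c(1, -1), 6))
  expect_equal(cluster_accuracy(const, balanced), 0.5)
  expect_error(cluster_accuracy(cl, fc_dataset(matrix(0, 0, 4), numeric(0))),
               "empty")
})

test_that("per-learner evaluation matches hand-tallied confusions", {
  labels <- c(1, 1, -1, -1)
  test <- fc_dataset(matrix(0, 4, 4), labels)
  cl <- make_stub_cluster(list(c(1, 1, -1, -1),    # 4/4
                               c(1, -1, -1, 1),    # 2/4
                               c(-1, -1, 1, 1)))   # 0/4
  cl <- evaluate_learners(cl, test)
  expect_equal(learner_accuracies(cl), c(1, 0.5, 0))
  # order unchanged
  expect_equal(cl$learners[[1]]$model$predictions, c(1, 1, -1, -1))
})

test_that("cluster building is deterministic and respects its config", {
  D <- make_dataset(24, 30, seed = 2)
  cfg <- cluster_config(k = 5, n_samples = 12, m_features = 6, seed = 42,
                        learner_kind = centroid_kind)
  c1 <- build_cluster(D, cfg)
  c2 <- build_cluster(D, cfg)
  expect_length(c1$learners, 5)
  for (l in 1:5) {
    expect_identical(c1$learners[[l]]$feature_indices,
                     c2$learners[[l]]$feature_indices)
    expect_identical(c1$learners[[l]]$sample_indices,
                     c2$learners[[l]]$sample_indices)
    expect_length(c1$learners[[l]]$feature_indices, 6)
    expect_length(c1$learners[[l]]$sample_indices, 12)
    expect_length(unique(D$labels[c1$learners[[l]]$sample_indices]), 2)
  }
  test <- make_dataset(10, 30, seed = 3)
  expect_identical(cluster_accuracy(c1, test), cluster_accuracy(c2, test))
})

test_that("cluster accuracy is invariant to learner order", {
  set.seed(8)
  votes <- lapply(1:7, function(l) sample(c(-1, 1), 6, replace = TRUE))
  test <- fc_dataset(matrix(0, 6, 4), rep(c(1, -1), 3))
  a1 <- cluster_accuracy(make_stub_cluster(votes), test)
  a2 <- cluster_accuracy(make_stub_cluster(rev(votes)), test)
  expect_identical(a1, a2)
})

test_that("learners score at least as well on seen rows as held-out rows, on average", {
  gaps <- vapply(1:20, function(seed) {
    cfg <- synthetic_config(R = 8, T = 40, n_pos = 12, n_neg = 12, planted = 3,
                            delta = 0.3, seed = seed)
    D <- simulate_feature_matrix(cfg)
    set.seed(seed)
    lr <- train_base_learner(D, 1:16, 1:10, "mlp")
    seen <- mean(predict_learner(lr, D$features[1:16, ]) == D$labels[1:16])
    held <- mean(predict_learner(lr, D$features[17:24, ]) == D$labels[17:24])
    seen - held
  }, numeric(1))
  expect_gte(mean(gaps), 0)
})

test_that("a saved cluster reloads with identical structure and votes", {
  D <- make_dataset(20, 12, seed = 4)
  cfg <- cluster_config(k = 3, n_samples = 10, m_features = 4, seed = 5)
  cl <- evaluate_learners(build_cluster(D, cfg), D)
  dir <- withr::local_tempdir()
  save_cluster(cl, dir)
  cl2 <- load_cluster(dir)
  expect_identical(lapply(cl2$learners, `[[`, "feature_indices"),
                   lapply(cl$learners, `[[`, "feature_indices"))
  expect_equal(learner_accuracies(cl2), learner_accuracies(cl))
  expect_identical(predict_majority(cl2, D), predict_majority(cl, D))
})
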