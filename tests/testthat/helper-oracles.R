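# Independent oracles and fixture builders shared across the suite.
# These deliberately use the most naive formulation available so they stay
# independent of the vectorized implementation paths they check.

# Pearson correlation by its definitional formula, scalar arithmetic only.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# Enumerate all (i, j) pairs in row-major upper-triangle order.
enumerate_pairs <- function(R) {
  out <- list()
  for (i in seq_len(R - 1)) for (j in (i + 1):R) out[[length(out) + 1]] <- c(i, j)
  do.call(rbind, out)
}

# Brute-force majority tally: votes is a learners x subjects matrix of +1/-1.
tally_oracle <- function(votes) {
  apply(votes, 2, function(v) {
    pos <- sum(v == 1)
    neg <- sum(v == -1)
    if (pos > neg) 1 else if (neg > pos) -1 else 1  # tie -> +1
  })
}

# Stable count-descending / index-ascending ranking by explicit bucketing.
rank_oracle <- function(counts) {
  out <- integer(0)
  for (cnt in sort(unique(counts), decreasing = TRUE)) {
    out <- c(out, which(counts == cnt))  # which() returns ascending indices
  }
  out
}

# A small labeled dataset with iid noise features.
make_dataset <- function(n = 20, p = 10, seed = 1, labels = NULL) {
  set.seed(seed)
  if (is.null(labels)) labels <- rep(c(1, -1), length.out = n)
  fc_dataset(matrix(rnorm(n * p), n, p), labels)
}

# Wrap fixed-prediction stub learners into a cluster object so that voting
# and scoring logic can be checked against hand tallies.
make_stub_cluster <- function(pred_list, universe = 4L) {
  learners <- lapply(pred_list, stub_learner, feature_indices = 1L)
  structure(list(learners = learners,
                 config = cluster_config(k = length(learners), n_samples = 2,
                                         m_features = 1, seed = 1),
                 feature_universe_size = as.integer(universe),
                 feature_pool = seq_len(universe)),
            class = "nn_cluster")
}

# Fast deterministic learner kind (nearest class centroid) for tests that
# need many fits without neural network training cost.
centroid_kind <- list(
  fit = function(x, y, params) {
    list(mu_pos = colMeans(x[y == 1, , drop = FALSE]),
         mu_neg = colMeans(x[y == -1, , drop = FALSE]))
  },
  predict = function(model, x) {
    d_pos <- rowSums(sweep(x, 2, model$mu_pos)^2)
    d_neg <- rowSums(sweep(x, 2, model$mu_neg)^2)
    ifelse(d_pos <= d_neg, 1, -1)
  })
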