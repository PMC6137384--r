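# Synthetic cohort generator: two groups of ROI time series whose
# correlation structure differs on a chosen ("planted") set of edges.
# The planted edges are the ground truth against which feature selection
# is judged.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the reference cohort geometry: 90 regions, 130
#' retained timepoints per scan, 36 control (+1) and 25 case (-1)
#' subjects, and 20 planted edges whose correlation is `base_r + delta` in
#' the case group against `base_r` everywhere else.
#'
#' @param R Regions (default 90).
#' @param T Timepoints per subject (default 130, a typical resting-state
#'   scan length after discarding initial volumes).
#' @param n_pos,n_neg Subjects in the +1 (control) and -1 (case) groups
#'   (defaults 36 / 25).
#' @param planted Either the number of planted edges to draw at random
#'   (default 20) or a two-column matrix of region pairs (i < j).
#' @param base_r Background correlation between all region pairs
#'   (default 0.1).
#' @param delta Correlation increment on planted edges in the case group
#'   (default 0.4).
#' @param noise_sd Observation noise added on top of the correlated
#'   signal (default 0.1, about the sampling error of a correlation
#'   estimated from ~130 timepoints).
#' @param seed Master seed for the generator.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(R = 90, T = 130, n_pos = 36, n_neg = 25,
                             planted = 20, base_r = 0.1, delta = 0.4,
                             noise_sd = 0.1, seed = 1) {
  stopifnot(is_count(R), R >= 2, is_count(T), T >= 3,
            is_count(n_pos), n_pos >= 1, is_count(n_neg), n_neg >= 1,
            noise_sd >= 0)
  if (base_r < 0 || abs(base_r) >= 1 || abs(base_r + delta) >= 1) {
    stop_invalid("need 0 <= base_r and |base_r + delta| < 1 for a valid correlation")
  }
  cfg <- structure(list(R = as.integer(R), T = as.integer(T),
                        n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                        base_r = base_r, delta = delta, noise_sd = noise_sd,
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  if (is.matrix(planted)) {
    cfg$planted <- sort(edge_to_index(planted[, 1], planted[, 2], R))
  } else {
    stopifnot(is_count(planted), planted >= 0, planted <= n_edges(R))
    cfg$planted <- sort(with_seed(derive_seeds(seed, 1),
                                  sample.int(n_edges(R), planted)))
  }
  # both group targets must admit a PSD correlation matrix
  make_group_correlation(cfg, -1)
  cfg
}

#' Group-specific target correlation matrix
#'
#' Builds the R x R correlation matrix of a group: `base_r` on every
#' off-diagonal entry, with planted entries raised to `base_r + delta` for
#' the case group (-1). If the raw target is not positive semi-definite it
#' is repaired by eigenvalue clipping followed by re-normalization to unit
#' diagonal; a repair that moves any planted entry by more than `delta/4`
#' aborts (the requested signal is too strong to be a correlation).
#'
#' @param config A [synthetic_config()].
#' @param group +1 (control) or -1 (case).
#' @return Symmetric PSD R x R matrix with unit diagonal.
#' @export
make_group_correlation <- function(config, group) {
  stopifnot(inherits(config, "synthetic_config"), group %in% c(-1, 1))
  R <- config$R
  S <- matrix(config$base_r, R, R)
  diag(S) <- 1
  if (group == -1 && length(config$planted) > 0) {
    pairs <- index_to_edge(config$planted, R)
    S[pairs] <- config$base_r + config$delta
    S[pairs[, c(2, 1), drop = FALSE]] <- config$base_r + config$delta
  }
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 1e-8)
    S2 <- ev$vectors %*% (vals * t(ev$vectors))
    S2 <- stats::cov2cor(S2)
    if (group == -1 && length(config$planted) > 0) {
      pairs <- index_to_edge(config$planted, R)
      moved <- max(abs(S2[pairs] - (config$base_r + config$delta)))
      if (config$delta == 0 || moved > abs(config$delta) / 4) {
        stop_invalid("PSD repair moved a planted correlation by %.3f (> delta/4); weaken the signal", moved)
      }
      message(sprintf("PSD repair applied; max planted-entry shift %.4f", moved))
    }
    S <- (S2 + t(S2)) / 2
  }
  S
}

#' Simulate a cohort of ROI time series
#'
#' Each subject's series is `T` independent multivariate-normal draws with
#' the subject's group correlation matrix (no temporal autocorrelation),
#' plus optional iid observation noise. Deterministic given the config
#' seed.
#'
#' @param config A [synthetic_config()].
#' @return List of [roi_ts()] objects (controls first, then cases) with
#'   attributes `planted_edges` (flat ground-truth indices) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_pos + config$n_neg
  labels <- c(rep(1, config$n_pos), rep(-1, config$n_neg))
  ids <- c(sprintf("HC%02d", seq_len(config$n_pos)),
           sprintf("AD%02d", seq_len(config$n_neg)))
  chol_pos <- chol(make_group_correlation(config, 1))
  chol_neg <- chol(make_group_correlation(config, -1))
  subj_seeds <- derive_seeds(config$seed, n + 1)[-1]
  cohort <- lapply(seq_len(n), function(s) {
    ch <- if (labels[s] == 1) chol_pos else chol_neg
    vals <- with_seed(subj_seeds[s], {
      z <- matrix(rnorm(config$T * config$R), config$T, config$R)
      x <- z %*% ch
      if (config$noise_sd > 0) {
        x <- x + matrix(rnorm(length(x), sd = config$noise_sd),
                        nrow(x), ncol(x))
      }
      x
    })
    roi_ts(ids[s], vals, labels[s])
  })
  attr(cohort, "planted_edges") <- config$planted
  attr(cohort, "config") <- config
  cohort
}

#' Simulate a labeled feature matrix directly
#'
#' Shortcut generator for fast tests: skips time series and emits
#' FC-like edge features directly. Every feature is
#' `base_r + noise`, with planted features additionally shifted by
#' `delta` for case (-1) subjects; values are clipped to \[-1, 1\].
#'
#' @param config A [synthetic_config()].
#' @return An [fc_dataset()] with attributes `planted_edges` and `config`.
#' @export
simulate_feature_matrix <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_pos + config$n_neg
  M <- n_edges(config$R)
  labels <- c(rep(1, config$n_pos), rep(-1, config$n_neg))
  feats <- with_seed(derive_seeds(config$seed, 2)[2], {
    x <- matrix(config$base_r + rnorm(n * M, sd = config$noise_sd), n, M)
    x[labels == -1, config$planted] <- x[labels == -1, config$planted] + config$delta
    pmin(pmax(x, -1), 1)
  })
  colnames(feats) <- edge_feature_names(config$R)
  D <- fc_dataset(feats, labels,
                  c(sprintf("HC%02d", seq_len(config$n_pos)),
                    sprintf("AD%02d", seq_len(config$n_neg))))
  attr(D, "planted_edges") <- config$planted
  attr(D, "config") <- config
  D
}

#' Ground-truth planted edges of a simulated object
#'
#' @param x A simulated cohort or dataset.
#' @return Integer vector of flat edge indices.
#' @export
planted_edges <- function(x) attr(x, "planted_edges")

#' Write a simulated cohort to disk
#'
#' Writes one time-series CSV per subject, a `manifest.csv`
#' (subject_id, path, label) and a `planted_edges.txt` ground-truth file,
#' so that the file-based pipeline entry points can be exercised end to
#' end on synthetic data.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_synthetic_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    fn <- paste0(s$subject_id, ".csv")
    write.csv(as.data.frame(s$values), file.path(dir, fn), row.names = FALSE)
    data.frame(subject_id = s$subject_id, path = fn, label = s$label)
  })
  man <- do.call(rbind, rows)
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  writeLines(as.character(planted_edges(cohort)),
             file.path(dir, "planted_edges.txt"))
  invisible(file.path(dir, "manifest.csv"))
}
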