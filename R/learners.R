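# Pluggable base-learner contract.
#
# A learner kind is a list with two functions:
#   fit(x, y, params)  -> opaque model   (x: n x m matrix, y: +1/-1 vector)
#   predict(model, x)  -> vector of +1/-1
# Built-in kinds are resolved by name; users may pass such a list directly
# to use any classifier (the historical ensemble ran five neural network
# variants -- here any learner honouring the contract slots in).

learner_kinds <- new.env(parent = emptyenv())

#' Resolve a base-learner kind
#'
#' @param kind Either the name of a built-in kind (`"mlp"`, `"ridge"`) or a
#'   list with `fit(x, y, params)` and `predict(model, x)` functions.
#' @return The learner-contract list.
#' @export
get_learner_kind <- function(kind) {
  if (is.list(kind)) {
    if (!all(c("fit", "predict") %in% names(kind))) {
      stop_invalid("a custom learner kind needs `fit` and `predict` functions")
    }
    return(kind)
  }
  if (!is.character(kind) || !kind %in% ls(learner_kinds)) {
    stop_invalid("unknown learner kind %s; built-ins: %s",
                 deparse(kind), toString(ls(learner_kinds)))
  }
  get(kind, envir = learner_kinds)
}

# Per-feature standardization fitted on the learner's own training rows;
# zero-variance features get unit scale so they pass through as constants.
fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, x) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

# Default kind: one-hidden-layer feed-forward network (classic multilayer
# perceptron), cross-entropy objective, bounded epochs. Hyperparameters:
#   size  hidden units (default 10)
#   decay weight decay (default 0.1; regularizes the m >> n regime)
#   maxit training epochs (default 100)
learner_kinds$mlp <- list(
  fit = function(x, y, params = list()) {
    size <- params$size %||% 10
    decay <- params$decay %||% 0.1
    maxit <- params$maxit %||% 100
    scaler <- fit_scaler(x)
    xs <- apply_scaler(scaler, x)
    y01 <- as.numeric(y == 1)
    net <- nnet::nnet(xs, y01, size = size, decay = decay, maxit = maxit,
                      entropy = TRUE, trace = FALSE,
                      MaxNWts = (ncol(x) + 1) * size + size + 1 + 10)
    list(net = net, scaler = scaler)
  },
  predict = function(model, x) {
    p <- as.numeric(predict(model$net, apply_scaler(model$scaler, x)))
    ifelse(p >= 0.5, 1, -1)
  }
)

# Second built-in kind: ridge-penalized logistic regression (glmnet,
# alpha = 0). Fast and deterministic; useful as a linear reference learner.
#   lambda penalty (default 0.1)
learner_kinds$ridge <- list(
  fit = function(x, y, params = list()) {
    if (ncol(x) < 2) stop_invalid("ridge learner needs >= 2 features")
    lambda <- params$lambda %||% 0.1
    fit <- glmnet::glmnet(x, factor(y, levels = c(-1, 1)),
                          family = "binomial", alpha = 0, lambda = lambda)
    fit
  },
  predict = function(model, x) {
    p <- as.numeric(predict(model, x, type = "response"))
    ifelse(p >= 0.5, 1, -1)
  }
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train one base learner on a subject/feature subset
#'
#' Fits the configured classifier on the given training rows restricted to
#' the given feature columns. The trained learner remembers its subset so
#' it can later vote on full-universe feature matrices.
#'
#' @param train An [fc_dataset()] (the training set).
#' @param sample_indices Training-row indices to fit on (must contain both
#'   classes).
#' @param feature_indices Feature-column indices for this learner.
#' @param learner_kind Kind name or contract list (see [get_learner_kind()]).
#' @param learner_params List of hyperparameters for the kind.
#' @return An object of class `base_learner` with fields `feature_indices`
#'   (sorted), `sample_indices`, `model`, `kind`, `test_accuracy` (NA until
#'   evaluated).
#' @export
train_base_learner <- function(train, sample_indices, feature_indices,
                               learner_kind = "mlp", learner_params = list()) {
  stopifnot(inherits(train, "fc_dataset"))
  feature_indices <- sort(unique(as.integer(feature_indices)))
  y <- train$labels[sample_indices]
  if (length(unique(y)) < 2) {
    stop_invalid("training subset contains a single class; cannot fit a two-class learner")
  }
  kind <- get_learner_kind(learner_kind)
  x <- train$features[sample_indices, feature_indices, drop = FALSE]
  model <- kind$fit(x, y, learner_params)
  structure(list(feature_indices = feature_indices,
                 sample_indices = as.integer(sample_indices),
                 model = model, kind = kind,
                 kind_name = if (is.character(learner_kind)) learner_kind else "custom",
                 test_accuracy = NA_real_),
            class = "base_learner")
}

#' Predict class labels with one base learner
#'
#' @param learner A `base_learner`.
#' @param X Feature matrix over the full universe (or an [fc_dataset()]);
#'   the learner picks out its own feature columns.
#' @return Vector of +1/-1 predictions.
#' @export
predict_learner <- function(learner, X) {
  if (inherits(X, "fc_dataset")) X <- X$features
  if (max(learner$feature_indices) > ncol(X)) {
    stop_invalid("matrix has %d columns but learner references feature %d",
                 ncol(X), max(learner$feature_indices))
  }
  pred <- learner$kind$predict(learner$model,
                               X[, learner$feature_indices, drop = FALSE])
  if (!all(pred %in% c(-1, 1))) {
    stop_invalid("learner predictions must be +1/-1")
  }
  as.numeric(pred)
}

#' Construct a stub learner with fixed predictions
#'
#' A degenerate base learner that ignores its inputs and replays a fixed
#' prediction vector (recycled per call). Intended for testing voting and
#' evaluation logic against hand tallies.
#'
#' @param predictions Vector of +1/-1 to return from every `predict` call.
#' @param feature_indices Feature columns the stub claims to use.
#' @return A `base_learner`.
#' @export
stub_learner <- function(predictions, feature_indices = 1L) {
  stopifnot(all(predictions %in% c(-1, 1)))
  kind <- list(fit = function(x, y, params) NULL,
               predict = function(model, x) {
                 rep_len(model$predictions, nrow(x))
               })
  structure(list(feature_indices = sort(unique(as.integer(feature_indices))),
                 sample_indices = integer(0),
                 model = list(predictions = as.numeric(predictions)),
                 kind = kind, kind_name = "stub",
                 test_accuracy = NA_real_),
            class = "base_learner")
}
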