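#' Gradient-boosting configuration
#'
#' Hyperparameters of the boosted CART ensemble. The stagewise update is
#' \eqn{f_m(x) = f_{m-1}(x) + \nu \sum_j \gamma_{jm} I(x \in R_{jm})}; with
#' `learning_rate = 1` the update adds each tree's leaf optimum unshrunk,
#' the textbook boosting recursion. The defaults (`n_rounds = 200`,
#' `learning_rate = 0.1`, `max_depth = 3`, `min_leaf = 5`) are conventional
#' shrinkage settings that trade more rounds for better generalization.
#'
#' @param n_rounds number of boosting rounds M.
#' @param learning_rate shrinkage \eqn{\nu} in (0, 1].
#' @param max_depth depth of every tree.
#' @param min_leaf minimum samples per leaf.
#' @param loss `"logistic"` (binomial deviance, the default for binary
#'   labels) or `"squared"`.
#' @return A list of class `gbdt_config`.
#' @export
gbdt_config <- function(n_rounds = 200, learning_rate = 0.1, max_depth = 3,
                        min_leaf = 5, loss = c("logistic", "squared")) {
  loss <- match.arg(loss)
  stopifnot(n_rounds >= 0, learning_rate > 0, learning_rate <= 1,
            max_depth >= 1, min_leaf >= 1)
  structure(list(n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate,
                 max_depth = as.integer(max_depth),
                 min_leaf = as.integer(min_leaf), loss = loss),
            class = "gbdt_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initial constant score of a boosted model
#'
#' The constant \eqn{f_0 = \arg\min_c \sum_i L(y_i, c)}: the label mean under
#' squared loss, the log-odds \eqn{\log(p/(1-p))} of the positive rate under
#' logistic loss.
#'
#' @param labels numeric vector; binary 0/1 for logistic loss.
#' @param loss `"logistic"` or `"squared"`.
#' @export
init_model <- function(labels, loss = c("logistic", "squared")) {
  loss <- match.arg(loss)
  if (loss == "squared") return(mean(labels))
  p <- mean(labels)
  if (p <= 0 || p >= 1) {
    abort("degenerate labels: logistic loss needs both classes present")
  }
  log(p / (1 - p))
}

#' Negative gradient (pseudo-residual) of the loss
#'
#' Squared loss gives the plain residual \eqn{y - f}; logistic loss gives
#' \eqn{y - \sigma(f)}, which always lies in (-1, 1).
#'
#' @param labels observed targets.
#' @param f_current current model scores.
#' @inheritParams init_model
#' @export
negative_gradient <- function(labels, f_current,
                              loss = c("logistic", "squared")) {
  loss <- match.arg(loss)
  stopifnot(length(labels) == length(f_current))
  if (loss == "squared") labels - f_current else labels - sigmoid(f_current)
}

#' Loss-optimal leaf values for a fitted tree
#'
#' Re-optimizes each leaf of a residual-fitted tree for the actual loss:
#' \eqn{\gamma_{jm} = \arg\min_\gamma \sum_{x_i \in R_{jm}} L(y_i,
#' f_{m-1}(x_i) + \gamma)}. Squared loss has the closed form (leaf mean of
#' residuals); logistic loss takes the standard single Newton step
#' \eqn{\sum_i r_i / \sum_i \sigma(f_i)(1 - \sigma(f_i))}, clipped to
#' \eqn{[-4, 4]} for stability. A zero Newton denominator yields a zero leaf
#' with a warning.
#'
#' @param tree a `regression_tree` fitted to the pseudo-residuals.
#' @param features training features (rows as in the fit).
#' @param labels observed 0/1 (or numeric) targets.
#' @param f_prev scores of the model before this tree.
#' @param leaf optional precomputed 0-based leaf index per sample (as
#'   returned by the tree fit); recomputed from `features` when `NULL`.
#' @inheritParams init_model
#' @return Numeric vector of leaf values indexed like `tree$value`
#'   (internal-node entries are 0).
#' @export
fit_leaf_values <- function(tree, features, labels, f_prev,
                            loss = c("logistic", "squared"), leaf = NULL) {
  loss <- match.arg(loss)
  if (is.null(leaf)) leaf <- tree_leaf(tree, features)
  leaf <- leaf + 1L
  nm <- length(tree$value)
  gamma <- numeric(nm)
  if (loss == "squared") {
    r <- labels - f_prev
    num <- vapply(seq_len(nm), function(m) sum(r[leaf == m]), 0)
    cnt <- tabulate(leaf, nbins = nm)
    occ <- cnt > 0
    gamma[occ] <- num[occ] / cnt[occ]
  } else {
    p <- sigmoid(f_prev)
    r <- labels - p
    h <- p * (1 - p)
    for (m in which(tabulate(leaf, nbins = nm) > 0)) {
      den <- sum(h[leaf == m])
      if (den <= 0) {
        warn("zero Newton denominator in a leaf; using value 0")
        gamma[m] <- 0
      } else {
        gamma[m] <- max(-4, min(4, sum(r[leaf == m]) / den))
      }
    }
  }
  gamma
}

#' Fit a gradient-boosted ensemble of CART regression trees
#'
#' Stagewise additive modelling: starting from the constant [init_model()],
#' each round computes the pseudo-residuals [negative_gradient()], fits a
#' regression tree to them (the residual becomes the tree's training
#' target), re-optimizes the leaf values for the loss with
#' [fit_leaf_values()], and adds the shrunken tree to the model. The fit is
#' fully deterministic: no subsampling is used and all tie-breaks are fixed,
#' so identical data yields an identical model regardless of `seed` or
#' sample order.
#'
#' @param features numeric matrix (samples x features); a data frame is
#'   coerced.
#' @param labels per-sample targets, 0/1 for logistic loss.
#' @param config a [gbdt_config()].
#' @param seed kept for interface symmetry with stochastic trainers; the fit
#'   itself draws no random numbers.
#' @return A `gbdt_model` with elements `f0`, `trees` (leaf values already
#'   scaled by the learning rate), `loss`, and per-round `train_loss`
#'   (mean deviance or mean squared error).
#' @examples
#' x <- matrix(rnorm(40), ncol = 2)
#' y <- as.numeric(x[, 1] + x[, 2] > 0)
#' fit <- fit_gbdt(x, y, gbdt_config(n_rounds = 10))
#' head(predict_score(fit, x))
#' @export
fit_gbdt <- function(features, labels, config = gbdt_config(), seed = NULL) {
  features <- as_feature_rows(features)
  labels <- as.numeric(labels)
  stopifnot(nrow(features) == length(labels))
  if (config$loss == "logistic" && !all(labels %in% c(0, 1))) {
    abort("logistic loss requires 0/1 labels")
  }
  f0 <- init_model(labels, config$loss)
  f <- rep(f0, length(labels))
  ord <- presort_features(features)
  trees <- vector("list", config$n_rounds)
  train_loss <- numeric(config$n_rounds)
  for (m in seq_len(config$n_rounds)) {
    r <- negative_gradient(labels, f, config$loss)
    fit <- fit_tree_impl(features, ord, r,
                         max_depth = config$max_depth,
                         min_leaf = config$min_leaf)
    tree <- new_regression_tree(fit, config$max_depth, config$min_leaf)
    gamma <- fit_leaf_values(tree, features, labels, f, config$loss,
                             leaf = fit$leaf_of)
    tree$value <- config$learning_rate * gamma
    f <- f + tree$value[fit$leaf_of + 1L]
    trees[[m]] <- tree
    train_loss[m] <- mean_loss(labels, f, config$loss)
  }
  structure(
    list(f0 = f0, trees = trees, loss = config$loss, config = config,
         n_features = ncol(features), train_loss = train_loss),
    class = "gbdt_model")
}

mean_loss <- function(labels, f, loss) {
  if (loss == "squared") return(mean((labels - f)^2))
  # binomial deviance written on the raw score for numerical stability:
  # -[y f - log(1 + e^f)]
  mean(log1p(exp(-abs(f))) + pmax(f, 0) - labels * f)
}

#' Score samples with a boosted model
#'
#' The raw score is \eqn{f(x) = f_0 + \sum_m \sum_j \gamma_{jm}
#' I(x \in R_{jm})}; under logistic loss the probability is
#' \eqn{\sigma(f(x))}, under squared loss the score is returned as-is.
#'
#' @param model a `gbdt_model`.
#' @param features matrix of samples to score (same feature order as
#'   training).
#' @return A tibble with columns `score` (raw additive score) and
#'   `probability`, one row per sample; row names of `features` are carried
#'   into a `gene` column when present.
#' @export
predict_score <- function(model, features) {
  features <- as_feature_rows(features)
  if (ncol(features) != model$n_features) {
    abort(sprintf("feature dimension mismatch: model has %d, data has %d",
                  model$n_features, ncol(features)))
  }
  f <- rep(model$f0, nrow(features))
  for (tree in model$trees) {
    f <- f + tree$value[tree_leaf(tree, features) + 1L]
  }
  prob <- if (model$loss == "logistic") sigmoid(f) else f
  out <- tibble(score = f, probability = prob)
  if (!is.null(rownames(features))) {
    out <- dplyr::bind_cols(tibble(gene = rownames(features)), out)
  }
  out
}

#' @export
predict.gbdt_model <- function(object, newdata,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  sc <- predict_score(object, newdata)
  if (type == "response") sc$probability else sc$score
}

#' @export
print.gbdt_model <- function(x, ...) {
  cat(sprintf("<gbdt_model: %d trees, %s loss, f0 = %.4f>\n",
              length(x$trees), x$loss, x$f0))
  invisible(x)
}

#' @describeIn fit_gbdt one row per boosting round with that round's tree
#'   size and cumulative training loss.
#' @param x a `gbdt_model`.
#' @method tidy gbdt_model
#' @export
tidy.gbdt_model <- function(x, ...) {
  tibble(
    round = seq_along(x$trees),
    n_leaves = vapply(x$trees, function(t) sum(t$feature == -1L), 0L),
    train_loss = x$train_loss
  )
}

#' @describeIn fit_gbdt one-row model summary.
#' @method glance gbdt_model
#' @export
glance.gbdt_model <- function(x, ...) {
  tibble(
    n_trees = length(x$trees), loss = x$loss, f0 = x$f0,
    learning_rate = x$config$learning_rate,
    max_depth = x$config$max_depth,
    final_train_loss = if (length(x$train_loss)) {
      x$train_loss[length(x$train_loss)]
    } else {
      NA_real_
    }
  )
}
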