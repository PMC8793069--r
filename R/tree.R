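#' Find the best axis-aligned split of a labelled sample
#'
#' Scans every feature and every candidate threshold (midpoints between
#' consecutive distinct sorted values) and returns the split `(j, s)` that
#' minimizes the total within-region squared error
#' \deqn{\sum_{x_i \in R_1}(y_i - c_1)^2 + \sum_{x_i \in R_2}(y_i - c_2)^2,}
#' where \eqn{c_1, c_2} are the region means. Samples with
#' \eqn{x^{(j)} \le s} fall in the left region. Ties in the loss are broken
#' toward the lower feature index, then the lower threshold, so the result
#' is deterministic and invariant to sample order.
#'
#' @param features numeric matrix, samples in rows.
#' @param targets numeric vector of per-sample targets.
#' @param min_leaf minimum number of samples each side of the split must keep.
#' @return A list with elements `feature_index` (1-based column), `threshold`,
#'   `left_value`/`right_value` (region means), and `loss` (post-split total
#'   squared error) — or `NULL` when no candidate split reduces the loss or
#'   satisfies `min_leaf`.
#' @examples
#' best_split(matrix(1:4, ncol = 1), c(0, 0, 1, 1), min_leaf = 1)
#' @export
best_split <- function(features, targets, min_leaf = 1) {
  features <- as_feature_rows(features)
  targets <- as.numeric(targets)
  stopifnot(nrow(features) == length(targets), min_leaf >= 1)
  if (nrow(features) < 2 * min_leaf) return(NULL)
  ord <- presort_features(features)
  fit <- fit_tree_impl(features, ord, targets, max_depth = 1L,
                       min_leaf = as.integer(min_leaf))
  if (fit$feature[1] == -1L) return(NULL)
  go_left <- features[, fit$feature[1] + 1L] <= fit$threshold[1]
  post <- sum((targets[go_left] - mean(targets[go_left]))^2) +
    sum((targets[!go_left] - mean(targets[!go_left]))^2)
  total <- sum((targets - mean(targets))^2)
  if (post >= total - 1e-12 * max(1, total)) return(NULL)
  list(
    feature_index = fit$feature[1] + 1L,
    threshold = fit$threshold[1],
    left_value = mean(targets[go_left]),
    right_value = mean(targets[!go_left]),
    loss = post
  )
}

#' Fit a CART regression tree
#'
#' Recursively partitions the feature space with the squared-error split
#' criterion of [best_split()] until a node is pure, cannot be split
#' without violating `min_leaf`, or `max_depth` is reached. Each leaf
#' predicts the mean target of its region, so the fitted function is
#' \eqn{f(x) = \sum_m \hat c_m I(x \in R_m)}. Unlike the standalone
#' [best_split()], an impure node accepts its best valid split even when
#' the immediate gain is zero — XOR-like targets only become separable one
#' level deeper.
#'
#' @inheritParams best_split
#' @param max_depth maximum tree depth (a depth-1 tree is a stump).
#' @return An object of class `regression_tree`.
#' @examples
#' tr <- fit_regression_tree(matrix(1:4, ncol = 1), c(0, 0, 1, 1),
#'                           max_depth = 1, min_leaf = 1)
#' predict(tr, matrix(c(1.5, 3.7), ncol = 1))
#' @export
fit_regression_tree <- function(features, targets, max_depth = 3,
                                min_leaf = 1) {
  features <- as_feature_rows(features)
  targets <- as.numeric(targets)
  stopifnot(nrow(features) >= 1, nrow(features) == length(targets),
            max_depth >= 1, min_leaf >= 1)
  ord <- presort_features(features)
  fit <- fit_tree_impl(features, ord, targets,
                       max_depth = as.integer(max_depth),
                       min_leaf = as.integer(min_leaf))
  new_regression_tree(fit, max_depth = max_depth, min_leaf = min_leaf)
}

new_regression_tree <- function(fit, max_depth, min_leaf) {
  structure(
    list(feature = fit$feature, threshold = fit$threshold, left = fit$left,
         right = fit$right, value = fit$value, n = fit$n, depth = fit$depth,
         max_depth = max_depth, min_leaf = min_leaf),
    class = "regression_tree")
}

#' @export
print.regression_tree <- function(x, ...) {
  cat(sprintf("<regression_tree: %d nodes, %d leaves, depth <= %d>\n",
              length(x$feature), sum(x$feature == -1L), x$max_depth))
  invisible(x)
}

# 0-based leaf index per row
tree_leaf <- function(tree, features) {
  tree_leaf_impl(tree$feature, tree$threshold, tree$left, tree$right,
                 as_feature_rows(features))
}

#' @export
predict.regression_tree <- function(object, newdata, ...) {
  object$value[tree_leaf(object, newdata) + 1L]
}

#' @describeIn fit_regression_tree one row per tree node: split rule for
#'   internal nodes, fitted value for leaves.
#' @param x a `regression_tree`.
#' @method tidy regression_tree
#' @export
tidy.regression_tree <- function(x, ...) {
  tibble(
    node = seq_along(x$feature) - 1L,
    depth = x$depth,
    is_leaf = x$feature == -1L,
    feature_index = ifelse(x$feature == -1L, NA_integer_, x$feature + 1L),
    threshold = ifelse(x$feature == -1L, NA_real_, x$threshold),
    value = ifelse(x$feature == -1L, x$value, NA_real_),
    n_samples = x$n
  )
}

as_feature_rows <- function(features) {
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, ncol = 1)
  if (storage.mode(features) != "double") storage.mode(features) <- "double"
  features
}

presort_features <- function(features) {
  ord <- apply(features, 2, order) - 1L
  if (!is.matrix(ord)) ord <- matrix(ord, ncol = ncol(features))
  storage.mode(ord) <- "integer"
  ord
}
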