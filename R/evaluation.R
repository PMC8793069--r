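#' Draw balanced negative sets
#'
#' Class-imbalanced training (many more unlabelled than known disease
#' genes) is handled by repeatedly drawing, uniformly without replacement,
#' a negative set the size of the positive set and aggregating metrics
#' across draws.
#'
#' @param positives character vector of positive gene ids.
#' @param negative_pool character vector of candidate negative ids.
#' @param n_repeats number of independent draws.
#' @param negatives_per_draw draw size; defaults to `length(positives)`.
#' @param seed integer seed; the same seed reproduces the same draws.
#' @return List of `n_repeats` character vectors.
#' @export
sample_balanced_negatives <- function(positives, negative_pool,
                                      n_repeats = 10,
                                      negatives_per_draw = length(positives),
                                      seed = 1) {
  stopifnot(n_repeats >= 1, negatives_per_draw >= 1)
  if (negatives_per_draw > length(negative_pool)) {
    abort(sprintf("negative pool (%d) smaller than draw size (%d)",
                  length(negative_pool), negatives_per_draw))
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_repeats), function(r) {
      sample(negative_pool, negatives_per_draw)
    })
  })
}

#' Stratified k-fold assignment
#'
#' Partitions samples into `k` folds so that, within each class, fold sizes
#' differ by at most one.
#'
#' @param labels per-sample class labels (any type; compared by equality).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return Integer vector of fold indices in `1:k`, one per sample.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1) {
  if (k < 2) abort("k must be at least 2: k = 1 leaves no held-out data")
  tab <- table(labels)
  if (any(tab < k)) {
    abort(sprintf("class '%s' has %d members, fewer than k = %d",
                  names(tab)[which.min(tab)], min(tab), k))
  }
  # round-robin over a running counter: fold sizes differ by <= 1 both
  # within every class and in total
  fold <- integer(length(labels))
  withr::with_seed(seed, {
    ctr <- 0L
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((ctr + seq_along(idx) - 1L) %% k) + 1L
      ctr <- ctr + length(idx)
    }
  })
  fold
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability: the fraction of
#' (positive, negative) pairs in which the positive scores higher, with
#' half credit for ties. This equals trapezoidal integration of the ROC
#' curve.
#'
#' @param labels 0/1 vector (both classes present).
#' @param scores finite numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @examples
#' compute_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
compute_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(is.finite(scores))) abort("scores must be finite")
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) abort("both classes must be present")
  r <- rank(scores)  # average ranks give ties half credit
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: sweeping the scores in descending order,
#' each newly recalled positive contributes the precision at its recall
#' point; tied scores are processed as a single group (the precision at the
#' end of the group applies to every positive in it).
#'
#' @inheritParams compute_auc
#' @return AUPR in (0, 1\].
#' @examples
#' compute_aupr(c(0, 0, 0, 1), c(0.9, 0.8, 0.7, 0.1))  # 0.25
#' @export
compute_aupr <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(is.finite(scores))) abort("scores must be finite")
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  if (npos == 0) abort("at least one positive is required")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  grp_end <- cumsum(rle(sc)$lengths)  # last index of each tied group
  tp <- cumsum(lab)[grp_end]
  precision <- tp / grp_end
  dtp <- diff(c(0, tp))
  sum(precision * dtp) / npos
}

#' ROC and precision-recall curve points
#'
#' @inheritParams compute_auc
#' @return Tibble of curve points (`fpr`/`tpr` for ROC; `recall`/
#'   `precision` for PR), tied scores grouped.
#' @export
roc_points <- function(labels, scores) {
  labels <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  grp_end <- cumsum(rle(scores[ord])$lengths)
  tp <- cumsum(lab)[grp_end]
  fp <- grp_end - tp
  tibble(threshold = c(Inf, scores[ord][grp_end]),
         fpr = c(0, fp / max(sum(labels == 0), 1)),
         tpr = c(0, tp / max(sum(labels == 1), 1)))
}

#' @rdname roc_points
#' @export
pr_points <- function(labels, scores) {
  labels <- as.numeric(labels)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  grp_end <- cumsum(rle(scores[ord])$lengths)
  tp <- cumsum(lab)[grp_end]
  tibble(threshold = scores[ord][grp_end],
         recall = tp / max(sum(labels == 1), 1),
         precision = tp / grp_end)
}

#' Classifier plug-ins for cross-validation
#'
#' A classifier is a list with `train(features, labels) -> model` and
#' `score(model, features) -> numeric`. `classifier_gbdt()` wraps
#' [fit_gbdt()]; `classifier_tree()` is a single CART regression tree (a
#' weak-learner baseline); `classifier_oracle()` scores every gene with its
#' true label (upper bound); `classifier_random()` scores uniformly at
#' random (null baseline). External learners (SVMs, other boosting
#' libraries, neural networks) plug in through the same contract.
#'
#' @param config a [gbdt_config()] for the GBDT classifier.
#' @param max_depth,min_leaf tree-baseline hyperparameters.
#' @param labels_by_gene named 0/1 vector for the oracle.
#' @name classifiers
#' @export
classifier_gbdt <- function(config = gbdt_config()) {
  list(
    name = "gbdt",
    train = function(features, labels) fit_gbdt(features, labels, config),
    score = function(model, features) predict_score(model, features)$probability
  )
}

#' @rdname classifiers
#' @export
classifier_tree <- function(max_depth = 3, min_leaf = 5) {
  list(
    name = "cart_tree",
    train = function(features, labels) {
      fit_regression_tree(features, labels, max_depth, min_leaf)
    },
    score = function(model, features) predict(model, features)
  )
}

#' @rdname classifiers
#' @export
classifier_oracle <- function(labels_by_gene) {
  list(
    name = "oracle",
    train = function(features, labels) labels_by_gene,
    score = function(model, features) unname(model[rownames(features)])
  )
}

#' @rdname classifiers
#' @export
classifier_random <- function() {
  list(
    name = "random",
    train = function(features, labels) NULL,
    score = function(model, features) runif(nrow(features))
  )
}

#' Balanced-resampling cross-validation of a gene classifier
#'
#' The balanced-resampling protocol: for each of `n_repeats` balanced negative
#' draws, the positives plus the drawn negatives are split by stratified
#' `k`-fold; the classifier is trained on k-1 folds and scores the held-out
#' fold, and AUC/AUPR are computed per fold. Training and test indices are
#' asserted disjoint on every fold. Features are computed once on the full
#' network beforehand — the diffusion embedding never sees the labels, so
#' this leaks nothing.
#'
#' @param features numeric matrix with gene ids as row names.
#' @param positives character vector of positive gene ids (rows of
#'   `features`).
#' @param negative_pool character vector of negative-candidate ids.
#' @param classifier a plug-in from [classifiers].
#' @param k number of folds.
#' @param n_repeats number of balanced negative draws.
#' @param seed integer seed governing draws, folds and any classifier
#'   randomness.
#' @param keep_predictions keep per-sample held-out scores (needed for
#'   curve plotting).
#' @return A `cv_result`: `metrics` tibble (one row per draw x fold),
#'   `predictions` tibble (if kept), and the configuration. `glance()`
#'   gives mean and population-sd AUC/AUPR; `tidy()` returns the per-fold
#'   metrics.
#' @export
cross_validate <- function(features, positives, negative_pool,
                           classifier = classifier_gbdt(), k = 10,
                           n_repeats = 10, seed = 1,
                           keep_predictions = TRUE) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  missing <- setdiff(c(positives, negative_pool), rownames(features))
  if (length(missing) > 0) {
    abort(sprintf("%d gene id(s) absent from the feature matrix (e.g. '%s')",
                  length(missing), missing[1]))
  }
  draws <- sample_balanced_negatives(positives, negative_pool,
                                     n_repeats = n_repeats, seed = seed)
  metrics <- vector("list", n_repeats)
  preds <- if (keep_predictions) vector("list", n_repeats) else NULL
  withr::with_seed(seed + 1L, {
    for (r in seq_len(n_repeats)) {
      genes <- c(positives, draws[[r]])
      labels <- c(rep(1, length(positives)), rep(0, length(draws[[r]])))
      fold <- stratified_kfold(labels, k = k,
                               seed = sample.int(.Machine$integer.max, 1))
      fold_rows <- vector("list", k)
      for (f in seq_len(k)) {
        test <- which(fold == f)
        train <- which(fold != f)
        stopifnot(length(intersect(train, test)) == 0)  # no leakage
        model <- classifier$train(features[genes[train], , drop = FALSE],
                                  labels[train])
        sc <- classifier$score(model,
                               features[genes[test], , drop = FALSE])
        fold_rows[[f]] <- tibble(
          repeat_id = r, fold = f,
          auc = compute_auc(labels[test], sc),
          aupr = compute_aupr(labels[test], sc))
        if (keep_predictions) {
          preds[[r]][[f]] <- tibble(repeat_id = r, fold = f,
                                    gene = genes[test],
                                    label = labels[test], score = sc)
        }
      }
      metrics[[r]] <- dplyr::bind_rows(fold_rows)
      if (keep_predictions) preds[[r]] <- dplyr::bind_rows(preds[[r]])
    }
  })
  structure(
    list(metrics = dplyr::bind_rows(metrics),
         predictions = if (keep_predictions) dplyr::bind_rows(preds),
         classifier = classifier$name, k = k, n_repeats = n_repeats,
         seed = seed),
    class = "cv_result")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<cv_result: %s, %d-fold x %d draws>\n  AUC  %.3f +/- %.3f\n  AUPR %.3f +/- %.3f\n",
    x$classifier, x$k, x$n_repeats,
    g$mean_auc, g$sd_auc, g$mean_aupr, g$sd_aupr))
  invisible(x)
}

#' @describeIn cross_validate per-fold AUC/AUPR tibble.
#' @param x a `cv_result`.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$metrics

#' @describeIn cross_validate one-row summary; the `+/-` is the population
#'   standard deviation across fold-level metrics (set `se = TRUE` for the
#'   standard error of the mean instead).
#' @param se report the standard error instead of the sd.
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, se = FALSE, ...) {
  denom <- if (se) sqrt(nrow(x$metrics)) else 1
  tibble(
    classifier = x$classifier, k = x$k, n_repeats = x$n_repeats,
    mean_auc = mean(x$metrics$auc),
    sd_auc = pop_sd(x$metrics$auc) / denom,
    mean_aupr = mean(x$metrics$aupr),
    sd_aupr = pop_sd(x$metrics$aupr) / denom)
}
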