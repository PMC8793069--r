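# Independent oracles and small fixture builders used across the suite.

# Exhaustive best-stump search: every feature, every midpoint threshold.
brute_best_stump <- function(X, y, min_leaf = 1) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (s in (head(v, -1) + tail(v, -1)) / 2) {
      left <- X[, j] <= s
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      loss <- sum((y[left] - mean(y[left]))^2) +
        sum((y[!left] - mean(y[!left]))^2)
      if (is.null(best) || loss < best$loss - 1e-12) {
        best <- list(j = j, s = s, loss = loss)
      }
    }
  }
  if (!is.null(best) &&
      best$loss >= sum((y - mean(y))^2) - 1e-12) return(NULL)
  best
}

# Trapezoidal ROC integration from the threshold sweep definition.
auc_trapezoid <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t), 0))
  fpr <- c(0, vapply(th, function(t) mean(scores[labels == 0] >= t), 0))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Random connected-ish undirected weighted graph, column-stochastic kernel.
random_transition <- function(n, p_edge = 0.15, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- ifelse(runif(sum(up)) < p_edge, runif(sum(up), 0.2, 1), 0)
    A <- A + t(A)
    # guarantee no isolated node so the closed form applies
    for (v in which(colSums(A) == 0)) {
      u <- if (v == 1) 2 else v - 1
      A[u, v] <- A[v, u] <- runif(1, 0.2, 1)
    }
    normalize_adjacency(A, "column_stochastic")
  })
}

# Two-class Gaussian toy dataset for boosting tests.
toy_binary <- function(n = 120, p = 4, seed = 1, noise = 0.7) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n)
    y <- as.numeric(X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = noise) > 0)
    list(X = X, y = y)
  })
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
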