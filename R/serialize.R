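#' Serialize a boosted model to JSON
#'
#' Writes `f0`, the loss, the learning rate, and every tree as a nested
#' structure of split rules and leaf values. Doubles are written at full
#' precision so that [read_gbdt()] reproduces the model exactly
#' (bit-identical predictions).
#'
#' @param model a `gbdt_model`.
#' @param path file to write; with `path = NULL` the JSON string is
#'   returned.
#' @return `path` invisibly (or the JSON string).
#' @export
write_gbdt <- function(model, path = NULL) {
  obj <- list(
    format = "walkboost-gbdt",
    f0 = model$f0,
    loss = model$loss,
    learning_rate = model$config$learning_rate,
    max_depth = model$config$max_depth,
    min_leaf = model$config$min_leaf,
    n_features = model$n_features,
    trees = lapply(model$trees, function(t) tree_to_nested(t, 0L))
  )
  # digits = I(17) keeps every double exact under parse (round-trip safe)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

tree_to_nested <- function(tree, m) {
  i <- m + 1L
  if (tree$feature[i] == -1L) {
    list(value = tree$value[i], n = tree$n[i])
  } else {
    list(feature_index = tree$feature[i] + 1L,
         threshold = tree$threshold[i],
         n = tree$n[i],
         left = tree_to_nested(tree, tree$left[i]),
         right = tree_to_nested(tree, tree$right[i]))
  }
}

#' Read a boosted model from JSON
#'
#' @param path file written by [write_gbdt()], or a JSON string.
#' @return A `gbdt_model`.
#' @export
read_gbdt <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$format, "walkboost-gbdt")) {
    abort("not a walkboost model file")
  }
  cfg <- gbdt_config(n_rounds = length(obj$trees),
                     learning_rate = obj$learning_rate,
                     max_depth = obj$max_depth, min_leaf = obj$min_leaf,
                     loss = obj$loss)
  trees <- lapply(obj$trees, nested_to_tree, max_depth = obj$max_depth,
                  min_leaf = obj$min_leaf)
  structure(
    list(f0 = obj$f0, trees = trees, loss = obj$loss, config = cfg,
         n_features = obj$n_features,
         train_loss = numeric(length(trees))),
    class = "gbdt_model")
}

nested_to_tree <- function(node, max_depth, min_leaf) {
  feature <- integer(); threshold <- numeric(); left <- integer()
  right <- integer(); value <- numeric(); nn <- integer(); dep <- integer()
  add <- function(node, depth) {
    i <- length(feature) + 1L
    feature[i] <<- -1L; threshold[i] <<- NA_real_; left[i] <<- -1L
    right[i] <<- -1L; value[i] <<- 0; nn[i] <<- node$n; dep[i] <<- depth
    if (is.null(node$feature_index)) {
      value[i] <<- node$value
    } else {
      feature[i] <<- node$feature_index - 1L
      threshold[i] <<- node$threshold
      left[i] <<- add(node$left, depth + 1L)
      right[i] <<- add(node$right, depth + 1L)
    }
    i - 1L
  }
  add(node, 0L)
  new_regression_tree(
    list(feature = feature, threshold = threshold, left = left,
         right = right, value = value, n = nn, depth = dep),
    max_depth = max_depth, min_leaf = min_leaf)
}
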