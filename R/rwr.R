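#' Random-walk-with-restart configuration
#'
#' The walk iterates \eqn{P_{t+1} = (1-\gamma) W P_t + \gamma P_0} until
#' \eqn{\lVert P_{t+1} - P_t \rVert \le} `tol` or `max_iter` is reached.
#' `gamma` is the restart probability: the fraction of walk mass teleported
#' back to the restart distribution each step, controlling how local the
#' diffusion stays. The default `gamma = 0.5` is the customary
#' middle-ground choice for gene-network propagation.
#'
#' @param gamma restart probability in (0, 1].
#' @param tol convergence threshold (> 0) on the iterate difference.
#' @param max_iter iteration cap.
#' @param norm norm for the difference: `"L1"` (max over columns of the
#'   absolute column-difference sum), `"L2"` (max column Euclidean norm), or
#'   `"Linf"` (max absolute entry).
#' @param dangling `"teleport"` re-injects the walk mass of isolated
#'   (zero-column) genes through the restart distribution so column mass is
#'   conserved; `"strict"` errors on isolated genes.
#' @export
rwr_config <- function(gamma = 0.5, tol = 1e-9, max_iter = 1000,
                       norm = c("L1", "L2", "Linf"),
                       dangling = c("teleport", "strict")) {
  norm <- match.arg(norm)
  dangling <- match.arg(dangling)
  stopifnot(gamma > 0, gamma <= 1, tol > 0, max_iter >= 1)
  structure(list(gamma = gamma, tol = tol, max_iter = as.integer(max_iter),
                 norm = norm, dangling = dangling),
            class = "rwr_config")
}

diff_norm <- function(D, norm) {
  switch(norm,
         L1 = max(colSums(abs(D))),
         L2 = sqrt(max(colSums(D^2))),
         Linf = max(abs(D)))
}

#' Iterate a random walk with restart to its fixed point
#'
#' Runs \eqn{P_{t+1} = (1-\gamma) W P_t + \gamma P_0} from \eqn{P_t = P_0}.
#' Under a column-stochastic `W` each column of the result is a probability
#' distribution (mass is conserved every step). Columns of `W` with no
#' outgoing weight are treated per the config's `dangling` rule.
#'
#' @param W a `transition_matrix` (or square matrix) — the walk kernel.
#' @param P0 restart matrix, one restart distribution per column (each
#'   column nonnegative, summing to 1). Defaults to the identity: every
#'   gene restarts at itself.
#' @param config an [rwr_config()].
#' @return A `diffusion_matrix`: list with `profiles` (dense matrix, one
#'   converged distribution per column), `iterations_used`, `converged`,
#'   and the `gamma` used. Non-convergence at `max_iter` warns and returns
#'   `converged = FALSE`.
#' @export
rwr_iterate <- function(W, P0 = NULL, config = rwr_config()) {
  tw <- as_transition(W)
  W <- tw$weights
  n <- nrow(W)
  if (is.null(P0)) P0 <- Matrix::Diagonal(n)
  if (nrow(P0) != n) abort("dimension mismatch between W and P0")
  P0 <- as.matrix(P0)
  if (any(tw$isolated)) {
    if (identical(config$dangling, "strict")) {
      abort(sprintf("%d isolated gene(s) with no outgoing weight",
                    sum(tw$isolated)))
    }
  }
  gamma <- config$gamma
  P <- P0
  iterations <- 0L
  converged <- FALSE
  dang <- tw$isolated
  while (iterations < config$max_iter) {
    WP <- as.matrix(W %*% P)
    if (any(dang)) {
      # re-inject dangling mass via the restart distribution
      m <- colSums(P[dang, , drop = FALSE])
      WP <- WP + P0 * rep(m, each = n)
    }
    Pnew <- (1 - gamma) * WP + gamma * P0
    iterations <- iterations + 1L
    delta <- diff_norm(Pnew - P, config$norm)
    P <- Pnew
    if (delta <= config$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("random walk did not converge in %d iterations", iterations))
  }
  dimnames(P) <- dimnames(as.matrix(P0)) %||% dimnames(W)
  structure(list(profiles = P, iterations_used = iterations,
                 converged = converged, gamma = gamma),
            class = "diffusion_matrix")
}

#' Closed-form fixed point of the random walk with restart
#'
#' Solves \eqn{P = \gamma (I - (1-\gamma) W)^{-1} P_0} directly — the exact
#' fixed point the iteration converges to whenever the spectral radius of
#' \eqn{(1-\gamma) W} is below 1 (guaranteed for a column-stochastic `W`
#' and \eqn{\gamma > 0}). Intended as the linear-algebra cross-check for
#' [rwr_iterate()]; it does not apply the dangling-mass teleport, so use it
#' on networks without isolated genes.
#'
#' @inheritParams rwr_iterate
#' @param gamma restart probability.
#' @return A `diffusion_matrix` with `iterations_used = 0`,
#'   `converged = TRUE`.
#' @export
rwr_closed_form <- function(W, P0 = NULL, gamma = 0.5) {
  tw <- as_transition(W)
  W <- as.matrix(tw$weights)
  n <- nrow(W)
  if (is.null(P0)) P0 <- diag(n)
  P0 <- as.matrix(P0)
  if (nrow(P0) != n) abort("dimension mismatch between W and P0")
  A <- diag(n) - (1 - gamma) * W
  P <- tryCatch(gamma * solve(A, P0),
                error = function(e) {
                  abort(sprintf(
                    "singular system at gamma=%g (normalization '%s'): %s",
                    gamma, tw$normalization, conditionMessage(e)))
                })
  dimnames(P) <- dimnames(P0) %||% dimnames(W)
  structure(list(profiles = P, iterations_used = 0L, converged = TRUE,
                 gamma = gamma),
            class = "diffusion_matrix")
}

as_transition <- function(W) {
  if (inherits(W, "transition_matrix")) return(W)
  M <- methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix")
  structure(list(weights = M, normalization = "none",
                 isolated = Matrix::colSums(M != 0) == 0),
            class = "transition_matrix")
}

#' Network-association features by random-walk diffusion
#'
#' Embeds every gene by its diffusion profile: with the restart matrix set
#' to the identity, gene g's converged walk distribution measures its
#' network proximity to every other gene, and that n-vector is g's feature
#' row. The adjacency is column-normalized first (per `mode`) so the walk
#' converges for any \eqn{\gamma > 0}.
#'
#' @param net an `interaction_network`.
#' @param config an [rwr_config()].
#' @param mode normalization handed to [normalize_adjacency()].
#' @return A dense numeric matrix, genes in rows and columns (row g is gene
#'   g's profile), with attributes `gamma`, `iterations_used`, `converged`.
#' @examples
#' edges <- tibble::tibble(from = c("s1", "s1"), to = c("a", "b"))
#' net <- build_network(edges, seeds = "s1")
#' extract_features(net, rwr_config(gamma = 0.5))
#' @export
extract_features <- function(net, config = rwr_config(),
                             mode = "column_stochastic") {
  W <- normalize_adjacency(net, mode)
  dm <- rwr_iterate(W, P0 = Matrix::Diagonal(length(net$genes)), config)
  features <- t(dm$profiles)
  dimnames(features) <- list(net$genes, net$genes)
  structure(features, gamma = config$gamma,
            iterations_used = dm$iterations_used, converged = dm$converged)
}

#' Write / read a feature matrix as TSV
#'
#' Header row and row labels carry the gene ids; values are written with 17
#' significant digits so the round trip is lossless.
#'
#' @param features matrix from [extract_features()].
#' @param path TSV path.
#' @return `path` (write) or the feature matrix (read).
#' @export
write_features <- function(features, path) {
  header <- paste(c("gene", colnames(features)), collapse = "\t")
  rows <- vapply(seq_len(nrow(features)), function(i) {
    paste(c(rownames(features)[i],
            sprintf("%.17g", features[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, row.names = 1,
                          comment.char = "")
  as.matrix(df)
}
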