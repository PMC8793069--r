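#' Read a gene list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored. Duplicates are removed (first occurrence kept) and their count
#' reported.
#'
#' @param path path to a plain-text gene list.
#' @return Character vector of unique gene identifiers, in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read gene list '%s'", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("no genes in '%s'", path))
  genes <- unique(lines)
  ndup <- length(lines) - length(genes)
  if (ndup > 0) inform(sprintf("%d duplicate gene id(s) dropped", ndup))
  genes
}

#' Read a gene-interaction edge list
#'
#' Tab- or whitespace-separated rows `geneA geneB [weight]` in the dialect
#' of functional-interaction tables such as HumanNet's. A missing weight
#' defaults to 1. Self-interactions (`geneA == geneB`) are dropped with a
#' reported count; negative weights and rows with fewer than two fields are
#' errors.
#'
#' @param path path to the edge list; `#` lines are comments.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read edge list '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    abort(sprintf("malformed edge row at line %d: fewer than 2 fields",
                  idx[which(nf < 2)[1]]))
  }
  from <- vapply(fields, `[[`, "", 1)
  to <- vapply(fields, `[[`, "", 2)
  weight <- vapply(fields, function(f) {
    if (length(f) >= 3) as.numeric(f[3]) else 1.0
  }, 0)
  if (anyNA(weight)) {
    abort(sprintf("non-numeric weight at line %d", idx[which(is.na(weight))[1]]))
  }
  if (any(weight < 0)) {
    abort(sprintf("negative weight at line %d", idx[which(weight < 0)[1]]))
  }
  self <- from == to
  if (any(self)) {
    inform(sprintf("%d self-loop row(s) dropped", sum(self)))
  }
  tibble(from = from[!self], to = to[!self], weight = weight[!self])
}

#' Assemble a gene-interaction network
#'
#' Builds an undirected weighted network from an edge tibble and a set of
#' seed (known disease) genes. With `restrict = TRUE` only seeds and their
#' direct interactors are kept — the construction that yields a disease
#' neighbourhood subnetwork from a genome-scale interactome. The adjacency
#' is symmetrized by taking the maximum of the two directed weights, and
#' nodes are ordered seeds-first, alphabetically within each group, so
#' downstream feature columns are reproducible.
#'
#' @param edges tibble/data frame with columns `from`, `to` and optionally
#'   `weight` (default 1).
#' @param seeds character vector of known disease gene ids (non-empty).
#' @param restrict keep only seeds and one-hop interactors of a seed.
#' @param binarize map every positive weight to 1.
#' @return An `interaction_network`: list with `genes` (ordered ids),
#'   `adjacency` (symmetric sparse `dgCMatrix`, zero diagonal), and
#'   `seed_flags` (logical).
#' @export
build_network <- function(edges, seeds, restrict = TRUE, binarize = FALSE) {
  stopifnot(is.data.frame(edges), length(seeds) > 0)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  seeds <- unique(as.character(seeds))
  edges <- dplyr::filter(edges, .data$from != .data$to, .data$weight > 0)
  touched <- union(edges$from, edges$to)
  if (!any(seeds %in% touched)) {
    abort("seeds disconnected from interactome: no seed appears in any edge")
  }
  if (restrict) {
    seed_edge <- edges$from %in% seeds | edges$to %in% seeds
    edges <- edges[seed_edge, , drop = FALSE]
    genes_present <- union(edges$from, edges$to)
    keep_genes <- union(seeds, genes_present)
  } else {
    keep_genes <- union(seeds, touched)
  }
  is_seed <- keep_genes %in% seeds
  genes <- c(sort(keep_genes[is_seed]), sort(keep_genes[!is_seed]))
  edges <- edges[edges$from %in% genes & edges$to %in% genes, , drop = FALSE]
  i <- match(edges$from, genes)
  j <- match(edges$to, genes)
  w <- if (binarize) rep(1, nrow(edges)) else edges$weight
  # symmetrize by max of the two directions (and of duplicate rows)
  key <- paste(pmin(i, j), pmax(i, j))
  agg <- tapply(w, key, max)
  ij <- do.call(rbind, strsplit(names(agg), " "))
  ii <- as.integer(ij[, 1]); jj <- as.integer(ij[, 2])
  n <- length(genes)
  adjacency <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(jj, ii), x = c(agg, agg), dims = c(n, n),
    dimnames = list(genes, genes))
  structure(
    list(genes = genes, adjacency = adjacency,
         seed_flags = genes %in% seeds),
    class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network: %d genes (%d seeds), %d undirected edges>\n",
    length(x$genes), sum(x$seed_flags),
    Matrix::nnzero(x$adjacency) / 2))
  invisible(x)
}

#' Normalize an adjacency matrix into a walk transition matrix
#'
#' `column_stochastic` divides every nonzero column by its sum, so each
#' column is a probability distribution over interaction partners and the
#' random walk is a proper Markov chain; `symmetric` applies
#' \eqn{D^{-1/2} A D^{-1/2}}; `none` passes the adjacency through
#' unchanged. Isolated genes (zero columns) are flagged, not fatal — the
#' walk handles them by teleporting their mass back to the restart
#' distribution.
#'
#' @param net an `interaction_network` (or a square nonnegative matrix).
#' @param mode normalization mode.
#' @return A `transition_matrix`: list with `weights` (sparse matrix),
#'   `normalization`, and `isolated` (logical per gene).
#' @export
normalize_adjacency <- function(net,
                                mode = c("column_stochastic", "symmetric",
                                         "none")) {
  mode <- match.arg(mode)
  A <- if (inherits(net, "interaction_network")) net$adjacency else
    methods::as(Matrix::Matrix(net, sparse = TRUE), "generalMatrix")
  stopifnot(nrow(A) == ncol(A), all(A@x >= 0))
  csum <- Matrix::colSums(A)
  isolated <- csum == 0
  W <- switch(mode,
    column_stochastic = {
      d <- ifelse(isolated, 0, 1 / csum)
      A %*% Matrix::Diagonal(x = d)
    },
    symmetric = {
      d <- ifelse(isolated, 0, 1 / sqrt(csum))
      Matrix::Diagonal(x = d) %*% A %*% Matrix::Diagonal(x = d)
    },
    none = A)
  dimnames(W) <- dimnames(A)
  structure(list(weights = W, normalization = mode, isolated = isolated),
            class = "transition_matrix")
}

#' Write a network as an edge-list TSV plus a JSON sidecar
#'
#' The edge list uses the same dialect [read_edge_list()] consumes
#' (`from<TAB>to<TAB>weight`, upper triangle only); the sidecar records the
#' node order and seed flags so the network round-trips exactly.
#'
#' @param net an `interaction_network`.
#' @param edges_path TSV output path.
#' @param sidecar_path JSON output path (default: `edges_path` +
#'   `".json"`).
#' @return `edges_path`, invisibly.
#' @export
write_network <- function(net, edges_path,
                          sidecar_path = paste0(edges_path, ".json")) {
  tri <- Matrix::triu(methods::as(net$adjacency, "TsparseMatrix"))
  tri <- methods::as(tri, "TsparseMatrix")
  ord <- order(tri@i, tri@j)
  lines <- sprintf("%s\t%s\t%.17g", net$genes[tri@i[ord] + 1L],
                   net$genes[tri@j[ord] + 1L], tri@x[ord])
  writeLines(c("# walkboost network edge list", lines), edges_path)
  jsonlite::write_json(
    list(genes = net$genes, seed_flags = net$seed_flags),
    sidecar_path, auto_unbox = FALSE, digits = NA)
  invisible(edges_path)
}

#' Read a network written by [write_network()]
#'
#' @param edges_path TSV edge list.
#' @param sidecar_path JSON sidecar with node order and seed flags.
#' @return An `interaction_network`.
#' @export
read_network <- function(edges_path,
                         sidecar_path = paste0(edges_path, ".json")) {
  edges <- read_edge_list(edges_path)
  meta <- jsonlite::fromJSON(sidecar_path)
  net <- build_network(edges, seeds = meta$genes[meta$seed_flags],
                       restrict = FALSE)
  # restore the recorded node order (covers isolated non-seed genes too)
  missing <- setdiff(meta$genes, net$genes)
  if (length(missing) > 0) {
    n <- length(meta$genes)
    A <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n),
                              dimnames = list(meta$genes, meta$genes))
    A[net$genes, net$genes] <- net$adjacency
    net$adjacency <- methods::as(A, "CsparseMatrix")
    net$genes <- meta$genes
  } else {
    net$adjacency <- net$adjacency[meta$genes, meta$genes]
    net$genes <- meta$genes
  }
  net$seed_flags <- meta$seed_flags
  net
}

#' Edge tibble of a network
#'
#' @param net an `interaction_network`.
#' @return Tibble `from`, `to`, `weight`, one row per undirected edge.
#' @export
network_edges <- function(net) {
  tri <- methods::as(Matrix::triu(net$adjacency), "TsparseMatrix")
  ord <- order(tri@i, tri@j)
  tibble(from = net$genes[tri@i[ord] + 1L],
         to = net$genes[tri@j[ord] + 1L],
         weight = tri@x[ord])
}
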