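#' EIGENSTRAT-style principal components of genotypes
#'
#' Per site, dosages are centred by their mean and scaled by
#' `sqrt(p (1 - p))` with the smoothed frequency
#' `p = (1 + sum dosages) / (2 + 2N)` (the EIGENSTRAT convention, which
#' avoids division by zero at rare sites); monomorphic sites are dropped.
#' The sample-by-sample covariance of the normalized matrix is
#' eigen-decomposed; the variance fraction of an axis is its eigenvalue
#' over the trace.  Coordinates are eigenvectors scaled by the square root
#' of their eigenvalue.  Axis signs are arbitrary.
#'
#' @param gm a `geno_matrix`.
#' @param k number of axes to report (truncated to N - 1 with a warning).
#' @return A `pca_result` object: list with `eigenvalues`,
#'   `variance_fraction`, `scores` (N x k), `sample_ids`, `pops`.
#' @export
pca_eigenstrat <- function(gm, k = 10L) {
  G <- gm$G
  N <- nrow(G)
  if (N < 2L) stop("need at least 2 samples")
  if (k > N - 1L) {
    warning("k truncated to N - 1 = ", N - 1L)
    k <- N - 1L
  }
  mono <- apply(G, 2L, function(x) length(unique(x)) == 1L)
  G <- G[, !mono, drop = FALSE]
  mu <- colMeans(G)
  p_hat <- (1 + colSums(G)) / (2 + 2 * N)
  X <- sweep(sweep(G, 2L, mu), 2L, sqrt(p_hat * (1 - p_hat)), "/")
  M <- tcrossprod(X) / ncol(X)
  eg <- eigen(M, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(k)]), k, k)
  dimnames(scores) <- list(gm$sample_ids, paste0("PC", seq_len(k)))
  structure(list(eigenvalues = ev[seq_len(k)],
                 variance_fraction = ev[seq_len(k)] / sum(ev),
                 scores = scores,
                 sample_ids = gm$sample_ids, pops = gm$pops),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", length(x$sample_ids), "samples;",
      "variance fractions:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$variance_fraction, 4)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration (via ape) on an IBS-derived (or any
#' symmetric, zero-diagonal) distance matrix; negative branch lengths are
#' clipped to zero with a message, the common convention.
#'
#' @param dist symmetric N x N distance matrix with zero diagonal (e.g.
#'   `ibs_matrix(gm)$distance`), N >= 3.
#' @return An ape `phylo` tree with the matrix's row names as tip labels.
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) stop("need at least 3 taxa for neighbor joining")
  if (max(abs(dist - t(dist))) > 1e-8) stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(dist))
  if (any(tree$edge.length < 0)) {
    message(sum(tree$edge.length < 0),
            " negative branch length(s) clipped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Serialize a tree as Newick
#'
#' Branch lengths at 6 significant digits, trailing semicolon; stable
#' output for stable input.
#'
#' @param tree an ape `phylo` object.
#' @param path optional file; if given the string is also written there.
#' @return the Newick string.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 6)
  if (!is.null(path)) writeLines(s, path)
  s
}
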