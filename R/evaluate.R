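#' Construct a bicluster
#'
#' A bicluster is a nonempty set of gene indices crossed with a nonempty set
#' of sample indices; its cell set is the Cartesian product.
#'
#' @param genes Integer vector of gene indices.
#' @param samples Integer vector of sample indices.
#' @return A `"bicluster"` object.
#' @export
bicluster <- function(genes, samples) {
  genes <- sort(unique(as.integer(genes)))
  samples <- sort(unique(as.integer(samples)))
  if (length(genes) == 0 || length(samples) == 0) {
    stop("a bicluster needs at least one gene and one sample")
  }
  structure(list(genes = genes, samples = samples), class = "bicluster")
}

# Jaccard index between the cell sets of two biclusters, computed without
# materializing the products: |A ib B| = |Ag ib Bg| * |As ib Bs|.
.bicluster_jaccard <- function(b1, b2) {
  ig <- length(intersect(b1$genes, b2$genes))
  is <- length(intersect(b1$samples, b2$samples))
  inter <- ig * is
  union <- length(b1$genes) * length(b1$samples) +
    length(b2$genes) * length(b2$samples) - inter
  if (union == 0) 0 else inter / union
}

#' Recovery and relevance scores between bicluster sets
#'
#' Recovery (recall-like) is the mean over true biclusters of the best
#' Jaccard overlap with any estimated bicluster, on cell sets; relevance
#' (precision-like) swaps the roles. An empty estimate gives recovery 0 and
#' relevance 0 with `relevance_defined = FALSE`; an empty truth mirrors this.
#'
#' @param truth,estimate Lists of [bicluster()] objects.
#' @return List with `recovery`, `relevance`, `recovery_defined`,
#'   `relevance_defined`.
#' @export
recovery_relevance <- function(truth, estimate) {
  if (length(truth) == 0 || length(estimate) == 0) {
    return(list(recovery = 0, relevance = 0,
                recovery_defined = length(truth) > 0,
                relevance_defined = length(estimate) > 0))
  }
  J <- outer(seq_along(truth), seq_along(estimate),
             Vectorize(function(i, j) .bicluster_jaccard(truth[[i]], estimate[[j]])))
  J <- matrix(J, length(truth), length(estimate))
  list(recovery = mean(apply(J, 1, max)),
       relevance = mean(apply(J, 2, max)),
       recovery_defined = TRUE, relevance_defined = TRUE)
}

#' Sparse stability index between two matrices
#'
#' Column-matching similarity that is invariant to column permutation, sign
#' flips and scaling, equal to 1 at perfect recovery. Columns of the
#' estimate are greedily matched to columns of the truth on squared Pearson
#' correlation (deterministic index-order tie-breaking); the score is the sum
#' of matched squared correlations divided by `max(K_true, K_est)`, so
#' missing or superfluous columns are penalized. Zero (or constant-column)
#' matrices score 0 on the affected columns.
#'
#' @param M_true,M_est Matrices with the same number of rows; column counts
#'   may differ.
#' @return Scalar in `[0, 1]`.
#' @export
sparse_stability_index <- function(M_true, M_est) {
  M_true <- as.matrix(M_true); M_est <- as.matrix(M_est)
  if (nrow(M_true) != nrow(M_est)) stop("row dimensions must agree")
  K1 <- ncol(M_true); K2 <- ncol(M_est)
  if (K1 == 0 || K2 == 0) return(0)
  sd1 <- apply(M_true, 2, stats::sd)
  sd2 <- apply(M_est, 2, stats::sd)
  C <- matrix(0, K1, K2)
  ok <- outer(sd1 > 0, sd2 > 0, `&`)
  if (any(ok)) {
    R <- suppressWarnings(stats::cor(M_true, M_est))
    R[!is.finite(R)] <- 0
    C[ok] <- R[ok]^2
  }
  total <- 0
  for (step in seq_len(min(K1, K2))) {
    best <- which(C == max(C), arr.ind = TRUE)[1, ]  # first index wins ties
    total <- total + C[best[1], best[2]]
    C[best[1], ] <- -1
    C[, best[2]] <- -1
  }
  total / max(K1, K2)
}

#' Extract estimated biclusters from a fit
#'
#' Converts the components of a fit for which both the loading and the
#' factor side are classified sparse into biclusters, using the non-zero
#' supports at the fit's sparsity threshold.
#'
#' @param fit A `"bc_fit"` object.
#' @param dense_threshold Non-sparse posterior probability at which a side
#'   counts as dense (defaults to the fit's setting).
#' @return List of [bicluster()] objects.
#' @export
fit_biclusters <- function(fit, dense_threshold = fit$dense_threshold) {
  K <- ncol(fit$loading$Lambda)
  if (K == 0) return(list())
  cats <- categorize_components(fit$loading$z, fit$factor$o, dense_threshold)
  thr <- fit$sparsity_threshold
  out <- list()
  for (k in which(cats == "SS")) {
    g <- which(abs(fit$loading$Lambda[, k]) > thr)
    s <- which(abs(fit$factor$X[k, ]) > thr)
    if (length(g) && length(s)) out[[length(out) + 1L]] <- bicluster(g, s)
  }
  out
}
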