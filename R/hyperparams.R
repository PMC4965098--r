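#' Shrinkage hyperparameters for the biclustering model
#'
#' Bundles the three-parameter-beta (TPB) shape/rate settings for the
#' gene-loading side (`a`..`f`, global rate `nu`), the sample-factor side
#' (`aX`..`fX`, global rate `xi`), the beta-Bernoulli priors on the
#' sparse/dense mixture indicators (`alpha`,`beta` for loadings,
#' `alphaX`,`betaX` for factors), and the initial component count `K`.
#'
#' The defaults place a horseshoe prior (`a = b = 0.5`) at the local level,
#' a Strawderman-Berger prior (`c = 1`, `d = 0.5`) at the component level,
#' and a uniform-tailed prior (`e = f = 1`) at the global level, with unit
#' global rates and a uniform beta prior on the mixture proportions.
#'
#' @param a,b,c,d,e,f Positive TPB shape parameters for the loading side.
#' @param nu Positive global rate for the loading hierarchy.
#' @param aX,bX,cX,dX,eX,fX Positive TPB shapes for the factor side.
#' @param xi Positive global rate for the factor hierarchy.
#' @param alpha,beta Beta prior on the loading sparse/dense proportion.
#' @param alphaX,betaX Beta prior on the factor sparse/dense proportion.
#' @param K Initial number of latent components (overestimate; unsupported
#'   components are pruned during fitting).
#' @return An object of class `"bc_hyper"` (a named list).
#' @examples
#' h <- bc_hyper(K = 50)
#' h$a  # 0.5
#' @export
bc_hyper <- function(a = 0.5, b = 0.5, c = 1, d = 0.5, e = 1, f = 1, nu = 1,
                     aX = 0.5, bX = 0.5, cX = 1, dX = 0.5, eX = 1, fX = 1,
                     xi = 1, alpha = 1, beta = 1, alphaX = 1, betaX = 1,
                     K = 10L) {
  h <- list(a = a, b = b, c = c, d = d, e = e, f = f, nu = nu,
            aX = aX, bX = bX, cX = cX, dX = dX, eX = eX, fX = fX, xi = xi,
            alpha = alpha, beta = beta, alphaX = alphaX, betaX = betaX,
            K = as.integer(K))
  bad <- vapply(h[setdiff(names(h), "K")],
                function(x) !is.numeric(x) || length(x) != 1L ||
                  !is.finite(x) || x <= 0, logical(1))
  if (any(bad)) {
    stop("hyperparameters must be strictly positive scalars: ",
         paste(names(h)[c(bad, FALSE)], collapse = ", "))
  }
  if (is.na(h$K) || h$K < 1L) stop("K must be a positive integer")
  structure(h, class = "bc_hyper")
}

#' Default heuristic for the initial component count
#'
#' Rule of thumb: twice the smaller matrix dimension. If a fit does not shed
#' roughly a third of its initial components, `K` should be raised and the
#' model refitted.
#'
#' @param p,n Matrix dimensions (genes, samples).
#' @return Integer `2 * min(n, p)`.
#' @export
default_K <- function(p, n) 2L * as.integer(min(p, n))

# Shared positivity floor for MAP-updated rate/scale parameters.
.bc_floor <- 1e-10
# Much smaller floor for the local variances theta/sigma: their MAP update is
# quadratic in the (shrinking) element, so a floor at 1e-10 would cap the
# prior precision at 1e10 and leave dying elements hovering just above the
# 1e-10 sparsity threshold instead of crossing it.
.bc_local_var_floor <- 1e-30

#' Draw from the gamma-hierarchy representation of a TPB-distributed variance
#'
#' The local variance in the shrinkage hierarchy can be drawn either from the
#' three-parameter-beta distribution on the precision scale or, equivalently,
#' through the two-stage gamma hierarchy `delta ~ Ga(b, nu)`,
#' `theta ~ Ga(a, delta)`. Marginally `theta * nu` follows an inverse-beta
#' (beta-prime) distribution with shapes `(a, b)`; with `a = b = 0.5` this is
#' the horseshoe variance law.
#'
#' @param a,b Positive shape parameters.
#' @param nu Positive rate of the top-level gamma.
#' @param n_draws Number of draws.
#' @param seed Integer seed (RNG state is restored on exit).
#' @return Numeric vector of `n_draws` positive variance draws.
#' @examples
#' th <- sample_tpb_equivalent(0.5, 0.5, 1, 1000, seed = 1)
#' @export
sample_tpb_equivalent <- function(a, b, nu, n_draws, seed = NULL) {
  if (!all(is.finite(c(a, b, nu))) || a <= 0 || b <= 0 || nu <= 0) {
    stop("a, b and nu must be strictly positive")
  }
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.null(seed)) local_seed(seed)
  delta <- stats::rgamma(n_draws, shape = b, rate = nu)
  stats::rgamma(n_draws, shape = a, rate = delta)
}

#' Proportion of variance explained per component
#'
#' For a loading matrix and the second moment of the factors,
#' `PVE_k = Tr(Lambda_k <X_k X_k^T> Lambda_k^T) / Tr(Lambda <X X^T> Lambda^T)`,
#' where the numerator uses the k-th diagonal block of the moment matrix.
#' Without orthogonality constraints components may explain overlapping
#' variance, so the entries only sum to one when `<XX^T>` is diagonal; the
#' quantity treats the per-component PVE as disjoint and normalizes across
#' components.
#'
#' @param Lambda `p x K` loading matrix.
#' @param X_moments `K x K` symmetric PSD second-moment matrix `<XX^T>`.
#' @return Length-`K` nonnegative vector.
#' @export
compute_pve <- function(Lambda, X_moments) {
  Lambda <- as.matrix(Lambda)
  S <- as.matrix(X_moments)
  K <- ncol(Lambda)
  if (nrow(S) != K || ncol(S) != K) stop("dimension mismatch: Lambda is p x K, X_moments must be K x K")
  denom <- sum(diag(Lambda %*% S %*% t(Lambda)))
  if (denom <= 0 || !is.finite(denom)) {
    stop("total explained variance is zero; PVE undefined for an all-zero loading matrix")
  }
  num <- diag(S) * colSums(Lambda^2)
  num / denom
}

#' Categorize components by loading/factor sparsity
#'
#' Each component carries posterior probabilities `z_k` (loading sparse) and
#' `o_k` (factor sparse). A side is classified *dense* when its posterior
#' probability of being non-sparse, `1 - z_k` (resp. `1 - o_k`), reaches
#' `dense_threshold`. Categories are the (loading, factor) pairs:
#' `SS` sparse/sparse, `SD` sparse loading + dense factor, `DS` dense loading
#' + sparse factor, `DD` dense/dense.
#'
#' @param z,o Vectors in `[0,1]`: posterior probabilities that the loading
#'   (resp. factor) side of each component is sparse.
#' @param dense_threshold Probability cutoff for calling a side dense
#'   (default 0.9).
#' @return Character vector of categories (`"SS"`, `"SD"`, `"DS"`, `"DD"`).
#' @export
categorize_components <- function(z, o, dense_threshold = 0.9) {
  if (length(z) != length(o)) stop("z and o must have equal length")
  if (any(z < 0 | z > 1) || any(o < 0 | o > 1)) stop("z and o must lie in [0,1]")
  if (dense_threshold <= 0 || dense_threshold >= 1) stop("dense_threshold must be in (0,1)")
  load_dense <- (1 - z) >= dense_threshold
  fact_dense <- (1 - o) >= dense_threshold
  paste0(ifelse(load_dense, "D", "S"), ifelse(fact_dense, "D", "S"))
}

# Seed the RNG for the duration of the calling function, restoring the
# caller's RNG state when that function exits.
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  restore <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}
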