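#' Simulate expression data with planted sparse and dense components
#'
#' Generates `Y = Lambda X + epsilon` with `n_sparse` sparse and `n_dense`
#' dense components. For each sparse loading and each sparse factor a support
#' size `m` is drawn uniformly from `m_min..m_max` (independently for the
#' loading and the factor of a component), the support positions are drawn
#' uniformly without replacement subject to any two components sharing at
#' most `overlap_max` positions (enforced by rejection resampling), and the
#' supported entries are drawn `N(0, 2)`. Dense loadings/factors are fully
#' `N(0, 2)`. When `shuffle = TRUE` the factor vectors are permuted across
#' components so a sparse loading may pair with a dense factor and vice
#' versa. The residual is i.i.d. `N(0, noise_variance)`.
#'
#' The default dimensions and settings reproduce the low-noise
#' sparse-components-only design used to validate the model (p = 500,
#' n = 300, ten sparse components, supports of 5-20 elements, overlap at
#' most 5, unit noise variance); the companion design adds five dense
#' components and a high-noise variant doubles the residual variance (see
#' [sim_preset()]).
#'
#' @param p,n Numbers of genes and samples.
#' @param n_sparse,n_dense Numbers of sparse and dense components.
#' @param m_min,m_max Range of sparse support sizes (must fit in both `p`
#'   and `n`).
#' @param overlap_max Maximum number of shared support positions between any
#'   two sparse components (per side).
#' @param noise_variance Residual variance (the inverse of the noise
#'   precision).
#' @param shuffle Permute factor vectors across components.
#' @param seed Integer seed.
#' @return A `"bc_sim"` list: `Y`, `Lambda_true`, `X_true`,
#'   `loading_sparse_flags`, `factor_sparse_flags`, `noise_variance`, `seed`.
#' @export
simulate_biclusters <- function(p, n, n_sparse = 10, n_dense = 0,
                                m_min = 5, m_max = 20, overlap_max = 5,
                                noise_variance = 1, shuffle = TRUE,
                                seed = 1) {
  if (m_max > p || m_max > n) stop("m_max must be <= both p and n")
  if (m_min < 1 || m_min > m_max) stop("need 1 <= m_min <= m_max")
  if (overlap_max < 0) stop("overlap_max must be >= 0")
  K <- n_sparse + n_dense
  if (K < 1) stop("need at least one component")
  local_seed(seed)

  draw_side <- function(dim_len, n_sparse, n_dense) {
    vecs <- matrix(0, dim_len, n_sparse + n_dense)
    supports <- list()
    for (k in seq_len(n_sparse)) {
      m <- sample(m_min:m_max, 1)
      ok <- FALSE
      for (attempt in seq_len(10000L)) {
        s <- sample.int(dim_len, m)
        if (all(vapply(supports, function(s0) length(intersect(s0, s)),
                       integer(1)) <= overlap_max)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not satisfy the support-overlap constraint; ",
             "too many sparse components for the dimension")
      }
      supports[[k]] <- s
      vecs[s, k] <- stats::rnorm(m, 0, sqrt(2))
    }
    if (n_dense > 0) {
      vecs[, n_sparse + seq_len(n_dense)] <-
        stats::rnorm(dim_len * n_dense, 0, sqrt(2))
    }
    vecs
  }

  Lambda <- draw_side(p, n_sparse, n_dense)
  Xt <- draw_side(n, n_sparse, n_dense)
  load_sparse <- rep(c(TRUE, FALSE), c(n_sparse, n_dense))
  fact_sparse <- load_sparse
  if (shuffle && K > 1) {
    perm <- sample.int(K)
    Xt <- Xt[, perm, drop = FALSE]
    fact_sparse <- fact_sparse[perm]
  }
  X <- t(Xt)
  eps <- if (noise_variance > 0) {
    matrix(stats::rnorm(p * n, 0, sqrt(noise_variance)), p, n)
  } else {
    matrix(0, p, n)
  }
  structure(list(Y = Lambda %*% X + eps, Lambda_true = Lambda, X_true = X,
                 loading_sparse_flags = load_sparse,
                 factor_sparse_flags = fact_sparse,
                 noise_variance = noise_variance, seed = seed),
            class = "bc_sim")
}

#' Named simulation presets
#'
#' `sim1-ln` / `sim1-hn`: ten sparse components only, at residual variance 1
#' (low noise) or 2 (high noise). `sim2-ln` / `sim2-hn`: ten sparse plus five
#' dense components at the same two noise levels. All presets use p = 500,
#' n = 300, supports of 5-20 elements and pairwise overlap at most 5.
#'
#' @param design One of `"sim1-ln"`, `"sim1-hn"`, `"sim2-ln"`, `"sim2-hn"`.
#' @param ... Overrides passed on to [simulate_biclusters()] (e.g. smaller
#'   `p`, `n` for quick runs); must be fully named.
#' @param seed Integer seed.
#' @return A `"bc_sim"` object.
#' @export
sim_preset <- function(design = c("sim1-ln", "sim1-hn", "sim2-ln", "sim2-hn"),
                       ..., seed = 1) {
  design <- match.arg(design)
  base <- list(p = 500, n = 300, n_sparse = 10,
               n_dense = if (grepl("^sim2", design)) 5 else 0,
               m_min = 5, m_max = 20, overlap_max = 5,
               noise_variance = if (grepl("hn$", design)) 2 else 1,
               shuffle = TRUE, seed = seed)
  args <- utils::modifyList(base, list(...))
  do.call(simulate_biclusters, args)
}

#' Regress out leading principal components
#'
#' Utility reproducing the preprocessing competitors require when dense
#' confounding components are present: removes the rank-`n_pcs`
#' approximation of `Y` (its leading singular triplets) and returns the
#' residual matrix.
#'
#' @param Y `p x n` matrix.
#' @param n_pcs Number of leading principal components to remove.
#' @return Residual matrix of the same dimension.
#' @export
residualize_pcs <- function(Y, n_pcs = 5) {
  if (n_pcs < 1) return(Y)
  s <- svd(Y, nu = n_pcs, nv = n_pcs)
  Y - s$u %*% (diag(s$d[seq_len(n_pcs)], n_pcs) %*% t(s$v))
}

#' Ground-truth biclusters of a simulated dataset
#'
#' Returns the planted biclusters: one per component whose loading *and*
#' factor are both sparse, with the gene set and sample set given by the
#' non-zero supports.
#'
#' @param sim A `"bc_sim"` object.
#' @return List of [bicluster()] objects (possibly empty).
#' @export
true_biclusters <- function(sim) {
  idx <- which(sim$loading_sparse_flags & sim$factor_sparse_flags)
  lapply(idx, function(k) {
    bicluster(which(sim$Lambda_true[, k] != 0), which(sim$X_true[k, ] != 0))
  })
}
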