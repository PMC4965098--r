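#' Fit the biclustering model by variational EM with a Gibbs warm start
#'
#' Runs the Gibbs sampler for `config$warm_start_mcmc_iters` sweeps and uses
#' the final state to initialize the variational EM optimization, then
#' iterates the closed-form updates in a fixed order (loading rows, loading
#' shrinkage, loading mixture, factor columns, factor shrinkage, factor
#' mixture, noise) until the count of non-zero loading entries changes by at
#' most `convergence_fraction * K * p` over `convergence_window` iterations.
#'
#' On output, sparse-classified loading columns and factor rows have elements
#' below `sparsity_threshold` set to zero, and components whose loading
#' column and factor row are both entirely zero are pruned. Components also
#' get pruned during the run as they die, which is how the overestimated
#' initial `K` is reduced to the supported number of components.
#'
#' @param Y `p x n` numeric matrix (genes in rows), complete and finite.
#' @param hyper A [bc_hyper()] object; `hyper$K` is the initial component
#'   count.
#' @param config A [vem_config()] object.
#' @return An object of class `"bc_fit"`: list with `loading` (Lambda and the
#'   loading-side shrinkage state, `z` = posterior probability each loading
#'   is sparse), `factor` (X, accumulated posterior covariance `SigmaX`,
#'   factor-side shrinkage state, `o`), `noise` (`psi`), `converged`,
#'   `trace` (iteration vs. non-zero-loading count), and `seed`.
#' @examples
#' \donttest{
#' sim <- simulate_biclusters(p = 60, n = 40, n_sparse = 3, n_dense = 0,
#'                            m_min = 5, m_max = 10, seed = 1)
#' fit <- fit_vem(sim$Y, bc_hyper(K = 15),
#'                vem_config(max_iter = 300, warm_start_mcmc_iters = 100,
#'                           seed = 1))
#' ncol(fit$loading$Lambda)  # close to 3
#' }
#' @export
fit_vem <- function(Y, hyper, config = vem_config()) {
  Y <- as.matrix(Y)
  if (!all(is.finite(Y))) stop("Y must be finite with no missing values")
  p <- nrow(Y); n <- ncol(Y)
  h <- hyper
  cfg <- config
  K0 <- h$K
  thr <- cfg$sparsity_threshold

  state <- run_warm_start(Y, h, n_iters = cfg$warm_start_mcmc_iters,
                          seed = cfg$seed)
  ld <- state$loading; fc <- state$factor
  psi <- state$noise$psi
  ## the warm start returns averaged indicator draws: posterior sparse
  ## probabilities evaluated on chain samples, used directly as the soft
  ## mixture weights (classifying from hard indicators would let the first
  ## sparse-branch updates zero out part of a dense column and flip its own
  ## evidence)
  ld$z <- as.numeric(ld$z); fc$o <- as.numeric(fc$o)
  lpi <- update_mixing(ld$z, h$alpha, h$beta)
  lpiX <- update_mixing(fc$o, h$alphaX, h$betaX)
  fc$SigmaX <- matrix(0, K0, K0)

  trace_it <- integer(0); trace_count <- integer(0)
  converged <- FALSE

  for (t in seq_len(cfg$max_iter)) {
    K <- ncol(ld$Lambda)
    ## loading rows: ridge solve with the marginalized local precisions
    ## E[1/theta | Lambda, phi] as the sparse-branch prior weights
    S <- fc$X %*% t(fc$X) + fc$SigmaX
    YXt <- Y %*% t(fc$X)
    precL <- matrix(0, p, K)
    for (k in seq_len(K)) {
      precL[, k] <- ld$z[k] *
        tpb_local_precision(ld$Lambda[, k], ld$phi[k], h$a, h$b) +
        (1 - ld$z[k]) / ld$phi[k]
    }
    for (j in seq_len(p)) {
      A <- S / psi[j]
      diag(A) <- diag(A) + precL[j, ]
      ld$Lambda[j, ] <- .ridge_solve(A, YXt[j, ] / psi[j])
    }
    ld$Lambda[abs(ld$Lambda) < thr] <- 0

    ## loading-side shrinkage: component scales by one-dimensional marginal
    ## maximization, then the conjugate global chain and the mixture
    for (k in seq_len(K)) {
      ld$phi[k] <- .update_phi_marginal(ld$Lambda[, k], ld$z[k], ld$tau[k],
                                        h$a, h$b, h$c)
    }
    ld$tau <- pmax((h$c + h$d - 1) / (ld$phi + ld$eta), .bc_floor)
    lsp <- .log_sparse_evidence_marginal(ld$Lambda, ld$phi, h$a, h$b)
    lde <- .log_dense_evidence(ld$Lambda, ld$phi)
    ld$z <- stats::plogis((lpi[1] + lsp) - (lpi[2] + lde))
    ld$eta <- pmax((K * h$d + h$e - 1) / (ld$gamma + sum(ld$tau)), .bc_floor)
    ld$gamma <- pmax((h$e + h$f - 1) / (ld$eta + h$nu), .bc_floor)
    lpi <- update_mixing(ld$z, h$alpha, h$beta)
    ## effective local state for serialization and warm handoff
    ld$theta <- 1 / precL
    ld$delta <- (h$a + h$b) / (ld$theta +
                                 matrix(ld$phi, p, K, byrow = TRUE))

    ## factor columns
    AtA <- t(ld$Lambda) %*% (ld$Lambda / psi)
    B <- t(ld$Lambda / psi) %*% Y
    SigX <- matrix(0, K, K)
    precX <- matrix(0, K, n)
    for (k in seq_len(K)) {
      precX[k, ] <- fc$o[k] *
        tpb_local_precision(fc$X[k, ], fc$omega[k], h$aX, h$bX) +
        (1 - fc$o[k]) / fc$omega[k]
    }
    for (i in seq_len(n)) {
      A <- AtA
      diag(A) <- diag(A) + precX[, i]
      U <- .ridge_chol(A)
      fc$X[, i] <- backsolve(U, forwardsolve(t(U), B[, i]))
      SigX <- SigX + chol2inv(U)
    }
    fc$SigmaX <- SigX
    fc$X[abs(fc$X) < thr] <- 0

    ## factor-side shrinkage (mirror)
    for (k in seq_len(K)) {
      fc$omega[k] <- .update_phi_marginal(fc$X[k, ], fc$o[k], fc$kappa[k],
                                          h$aX, h$bX, h$cX)
    }
    fc$kappa <- pmax((h$cX + h$dX - 1) / (fc$omega + fc$chi), .bc_floor)
    lspo <- .log_sparse_evidence_marginal(t(fc$X), fc$omega, h$aX, h$bX)
    ldeo <- .log_dense_evidence(t(fc$X), fc$omega)
    fc$o <- stats::plogis((lpiX[1] + lspo) - (lpiX[2] + ldeo))
    fc$chi <- pmax((K * h$dX + h$eX - 1) / (fc$phiX + sum(fc$kappa)), .bc_floor)
    fc$phiX <- pmax((h$eX + h$fX - 1) / (fc$chi + h$xi), .bc_floor)
    lpiX <- update_mixing(fc$o, h$alphaX, h$betaX)
    fc$sigma <- 1 / precX
    fc$rho <- (h$aX + h$bX) / (fc$sigma + fc$omega)

    ## noise
    Snew <- fc$X %*% t(fc$X) + fc$SigmaX
    psi <- update_psi(Y, ld$Lambda, fc$X, Snew)

    ## convergence statistic and pruning
    count <- sum(abs(ld$Lambda) > thr)
    trace_it <- c(trace_it, t); trace_count <- c(trace_count, count)
    dead <- .dead_components(ld$Lambda, fc$X, thr)
    if (any(dead)) {
      keep <- !dead
      ld <- .subset_loading(ld, keep)
      fc <- .subset_factor(fc, keep)
      if (!any(keep)) break
    }
    win <- cfg$convergence_window
    if (t > win &&
        abs(trace_count[t] - trace_count[t - win]) <=
          cfg$convergence_fraction * K0 * p) {
      converged <- TRUE
      break
    }
  }

  ## output thresholding: zero out sub-threshold elements of sparse sides
  sparse_load <- (1 - ld$z) < cfg$dense_threshold
  sparse_fact <- (1 - fc$o) < cfg$dense_threshold
  if (ncol(ld$Lambda) > 0) {
    Zl <- abs(ld$Lambda) <= thr &
      matrix(sparse_load, p, ncol(ld$Lambda), byrow = TRUE)
    ld$Lambda[Zl] <- 0
    Zf <- abs(fc$X) <= thr & matrix(sparse_fact, nrow(fc$X), n)
    fc$X[Zf] <- 0
    dead <- .dead_components(ld$Lambda, fc$X, 0)
    if (any(dead)) {
      ld <- .subset_loading(ld, !dead)
      fc <- .subset_factor(fc, !dead)
    }
  }

  structure(list(loading = ld, factor = fc, noise = list(psi = psi),
                 converged = converged,
                 trace = data.frame(iteration = trace_it,
                                    nonzero_loadings = trace_count),
                 seed = cfg$seed, K_init = K0,
                 dense_threshold = cfg$dense_threshold,
                 sparsity_threshold = thr),
            class = "bc_fit")
}

# Cholesky with an escalating ridge for (transiently) rank-deficient systems,
# e.g. duplicated components inherited from the warm-start chain.
.ridge_chol <- function(A) {
  eps <- 0
  base <- max(diag(A), 1)
  for (k in 0:8) {
    U <- tryCatch(chol(A + diag(eps, nrow(A))), error = function(e) NULL)
    if (!is.null(U)) return(U)
    eps <- base * 10^(-12 + 2 * k)
  }
  stop("precision matrix could not be factorized even with ridge")
}

.ridge_solve <- function(A, b) {
  U <- .ridge_chol(A)
  backsolve(U, forwardsolve(t(U), b))
}

.dead_components <- function(Lambda, X, thr) {
  apply(abs(Lambda) <= thr, 2, all) & apply(abs(X) <= thr, 1, all)
}

.subset_loading <- function(ld, keep) {
  ld$Lambda <- ld$Lambda[, keep, drop = FALSE]
  ld$theta <- ld$theta[, keep, drop = FALSE]
  ld$delta <- ld$delta[, keep, drop = FALSE]
  ld$phi <- ld$phi[keep]; ld$tau <- ld$tau[keep]; ld$z <- ld$z[keep]
  ld
}

.subset_factor <- function(fc, keep) {
  fc$X <- fc$X[keep, , drop = FALSE]
  fc$SigmaX <- fc$SigmaX[keep, keep, drop = FALSE]
  fc$sigma <- fc$sigma[keep, , drop = FALSE]
  fc$rho <- fc$rho[keep, , drop = FALSE]
  fc$omega <- fc$omega[keep]; fc$kappa <- fc$kappa[keep]; fc$o <- fc$o[keep]
  fc
}

#' @export
print.bc_fit <- function(x, ...) {
  K <- ncol(x$loading$Lambda)
  cat("Biclustering fit:", K, "surviving components,",
      if (x$converged) "converged" else "NOT converged",
      "after", max(c(0L, x$trace$iteration)), "iterations\n")
  if (K > 0) {
    cat("categories:",
        paste(categorize_components(x$loading$z, x$factor$o,
                                    x$dense_threshold), collapse = " "), "\n")
  }
  invisible(x)
}
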