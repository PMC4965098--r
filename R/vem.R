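#' Configuration for the variational EM fit
#'
#' @param max_iter Maximum number of VEM iterations.
#' @param convergence_window Number of iterations over which the change in
#'   the count of non-zero loading entries is measured.
#' @param convergence_fraction Convergence threshold, as a fraction of
#'   `K * p`: the fit has converged when the non-zero-loading count changes
#'   by at most `convergence_fraction * K * p` over the window.
#' @param sparsity_threshold Magnitude below which an element of a
#'   sparse-classified component is set to zero (default `1e-10`); also the
#'   "non-zero" cutoff used by the convergence statistic and by downstream
#'   support decisions.
#' @param dense_threshold Posterior probability of being non-sparse at which
#'   a component side is classified dense (default 0.9).
#' @param seed Integer seed controlling the warm start and hence the whole
#'   (otherwise deterministic) fit.
#' @param warm_start_mcmc_iters Gibbs sweeps used to initialize the fit
#'   (default 500).
#' @return A `"vem_config"` list.
#' @export
vem_config <- function(max_iter = 1000, convergence_window = 100,
                       convergence_fraction = 0.01,
                       sparsity_threshold = 1e-10, dense_threshold = 0.9,
                       seed = 1, warm_start_mcmc_iters = 500) {
  if (convergence_window < 1 || max_iter < convergence_window) {
    stop("need max_iter >= convergence_window >= 1")
  }
  if (sparsity_threshold <= 0) stop("sparsity_threshold must be > 0")
  structure(list(max_iter = as.integer(max_iter),
                 convergence_window = as.integer(convergence_window),
                 convergence_fraction = convergence_fraction,
                 sparsity_threshold = sparsity_threshold,
                 dense_threshold = dense_threshold,
                 seed = as.integer(seed),
                 warm_start_mcmc_iters = as.integer(warm_start_mcmc_iters)),
            class = "vem_config")
}

#' MAP update of one loading row
#'
#' Solves the ridge-type system for row `j` of the loading matrix:
#' `Lambda_j = Y_j psi^-1 <X>^T (<X psi^-1 X^T> + Z Theta_j^-1 + (I-Z) Phi^-1)^-1`,
#' where `Z` is the diagonal of sparse-branch probabilities, used as convex
#' weights between the local (`theta`) and component-scale (`phi`) prior
#' precisions.
#'
#' @param y_j Length-`n` data row.
#' @param X `K x n` expected factor matrix.
#' @param XpsiXT `K x K` moment `<X psi_j^-1 X^T>` (i.e. `(X X^T + SigmaX)/psi_j`).
#' @param theta_j Length-`K` local variances for this row.
#' @param phi Length-`K` component scales.
#' @param z Length-`K` sparse probabilities in `[0,1]`.
#' @param psi_j Residual variance of gene `j`.
#' @return Length-`K` updated row.
#' @export
update_loading_row <- function(y_j, X, XpsiXT, theta_j, phi, z, psi_j) {
  A <- XpsiXT
  diag(A) <- diag(A) + z / theta_j + (1 - z) / phi
  rhs <- as.numeric(X %*% y_j) / psi_j
  as.numeric(solve(A, rhs))
}

#' MAP update of a local loading variance
#'
#' The local variance has a generalized-inverse-Gaussian-shaped conditional;
#' its mode is `theta = (2a-3 + sqrt((2a-3)^2 + 8 Lambda^2 delta)) / (4 delta)`.
#' When `delta` sits at the positivity floor the analytic `delta -> 0` limit
#' `Lambda^2 / |2a - 3|` is returned (requires `a != 1.5`).
#'
#' @param lambda_jk Loading element.
#' @param delta_jk Nonnegative rate parameter.
#' @param a Local TPB shape.
#' @return Positive scalar (vectorized over inputs), floored at the local-variance floor `1e-30`.
#' @export
update_theta <- function(lambda_jk, delta_jk, a) {
  c1 <- 2 * a - 3
  at_floor <- delta_jk <= .bc_floor
  if (any(at_floor) && abs(c1) < 1e-12) {
    stop("theta update degenerate: a = 1.5 with delta at the positivity floor")
  }
  out <- ifelse(at_floor,
                lambda_jk^2 / abs(c1),
                (c1 + sqrt(c1^2 + 8 * lambda_jk^2 * delta_jk)) / (4 * delta_jk))
  pmax(out, .bc_local_var_floor)
}

#' MAP update of a local factor variance
#'
#' Mirror of [update_theta()] for the factor side, with element `x_ki`,
#' rate `rho_ki` and shape `aX`.
#'
#' @param x_ki Factor element.
#' @param rho_ki Nonnegative rate parameter.
#' @param aX Factor-side local TPB shape.
#' @return Positive scalar (vectorized), floored at the local-variance floor `1e-30`.
#' @export
update_sigma <- function(x_ki, rho_ki, aX) update_theta(x_ki, rho_ki, aX)

#' MAP update of the loading-side local rate
#'
#' `delta = (a + b - 1) / (theta + phi)`, clamped below at the positivity
#' floor. Under the horseshoe default `a = b = 0.5` the numerator is exactly
#' zero, so the update returns the floor and the paired variance update takes
#' its `delta -> 0` limit.
#'
#' @param theta_jk,phi_k Positive variance/scale values.
#' @param a,b Local TPB shapes.
#' @return Nonnegative scalar (vectorized), floored at `1e-10`.
#' @export
update_delta <- function(theta_jk, phi_k, a, b) {
  pmax((a + b - 1) / (theta_jk + phi_k), .bc_floor)
}

#' MAP update of the factor-side local rate
#'
#' Mirror of [update_delta()]: `rho = (aX + bX - 1) / (sigma + omega)`.
#'
#' @param sigma_ki,omega_k Positive variance/scale values.
#' @param aX,bX Factor-side shapes.
#' @return Nonnegative scalar (vectorized), floored at `1e-10`.
#' @export
update_rho <- function(sigma_ki, omega_k, aX, bX) {
  pmax((aX + bX - 1) / (sigma_ki + omega_k), .bc_floor)
}

#' MAP update of a component scale on the loading side
#'
#' The component scale feeds both branches of the sparse/dense mixture: it is
#' the rate of the local rates when the component is sparse and the common
#' loading variance when it is dense. Maximizing the expected complete log
#' likelihood in `phi_k` gives the positive root of
#' `(M/2) phi^2 - H phi - (1 - z) T / 2 = 0`:
#' `phi = (H + sqrt(H^2 + M (1-z) T)) / M` with
#' `H = p b <z> + c - 1 - (p/2)(1 - <z>)`,
#' `M = 2 (<z> sum_j delta_jk + tau_k)` and `T = sum_j Lambda_jk^2`.
#'
#' @param z_k Sparse probability in `[0,1]`.
#' @param delta_col Length-`p` local rates of the component.
#' @param tau_k Component-level rate.
#' @param lambda_col Length-`p` loading column.
#' @param b,c TPB shapes.
#' @param p Number of genes.
#' @return Positive scalar, floored at `1e-10`.
#' @export
update_phi_k <- function(z_k, delta_col, tau_k, lambda_col, b, c, p) {
  H <- p * b * z_k + c - 1 - (p / 2) * (1 - z_k)
  M <- 2 * (z_k * sum(delta_col) + tau_k)
  Tq <- (1 - z_k) * sum(lambda_col^2)
  pmax((H + sqrt(H^2 + M * Tq)) / M, .bc_floor)
}

#' MAP update of a component scale on the factor side
#'
#' Mirror of [update_phi_k()] over the `n` samples, with `o_k`, `rho`,
#' `kappa_k`, the factor row and shapes `bX`, `cX`.
#'
#' @param o_k Sparse probability in `[0,1]`.
#' @param rho_row Length-`n` local rates.
#' @param kappa_k Component-level rate.
#' @param x_row Length-`n` factor row.
#' @param bX,cX TPB shapes.
#' @param n Number of samples.
#' @return Positive scalar, floored at `1e-10`.
#' @export
update_omega_k <- function(o_k, rho_row, kappa_k, x_row, bX, cX, n) {
  update_phi_k(o_k, rho_row, kappa_k, x_row, bX, cX, n)
}

#' MAP updates of the loading-side global shrinkage chain
#'
#' Conjugate-form updates applied cyclically in order:
#' `tau_k = (c+d-1)/(phi_k + eta)`, then `eta = (K d + e - 1)/(gamma + sum tau)`,
#' then `gamma = (e+f-1)/(eta + nu)`.
#'
#' @param phi Length-`K` component scales.
#' @param tau Length-`K` component rates (previous values; unused directly,
#'   kept for signature symmetry).
#' @param eta,gamma Current global values.
#' @param c,d,e,f TPB shapes.
#' @param nu Global rate.
#' @return List with updated `tau`, `eta`, `gamma`.
#' @export
update_global_loading <- function(phi, tau, eta, gamma, c, d, e, f, nu) {
  K <- length(phi)
  tau <- pmax((c + d - 1) / (phi + eta), .bc_floor)
  eta <- pmax((K * d + e - 1) / (gamma + sum(tau)), .bc_floor)
  gamma <- pmax((e + f - 1) / (eta + nu), .bc_floor)
  list(tau = tau, eta = eta, gamma = gamma)
}

#' MAP updates of the factor-side global shrinkage chain
#'
#' Mirror of [update_global_loading()]:
#' `kappa_k = (cX+dX-1)/(omega_k + chi)`,
#' `chi = (K dX + eX - 1)/(phiX + sum kappa)`,
#' `phiX = (eX+fX-1)/(chi + xi)`.
#'
#' @param omega Length-`K` factor-side component scales.
#' @param kappa Length-`K` component rates (previous values).
#' @param chi,phiX Current global values.
#' @param cX,dX,eX,fX TPB shapes.
#' @param xi Global rate.
#' @return List with updated `kappa`, `chi`, `phiX`.
#' @export
update_global_factor <- function(omega, kappa, chi, phiX, cX, dX, eX, fX, xi) {
  out <- update_global_loading(omega, kappa, chi, phiX, cX, dX, eX, fX, xi)
  list(kappa = out$tau, chi = out$eta, phiX = out$gamma)
}

#' Posterior probability that a loading component is sparse
#'
#' Computes, in log space, the two-branch evidence of the mixture for one
#' component: the sparse branch multiplies, over genes, the normal density of
#' the loading under its local variance with the two gamma layers above it;
#' the dense branch is the normal density under the shared component scale.
#' Returns the logistic of the difference of branch log-evidences plus the
#' geometric-mean log mixing weights.
#'
#' @param Lambda_col Length-`p` loading column.
#' @param theta_col,delta_col Length-`p` local variances and rates.
#' @param phi_k Component scale.
#' @param a,b TPB shapes.
#' @param log_pi_geometric Length-2 vector `c(<ln pi>, <ln(1-pi)>)` from
#'   [update_mixing()].
#' @return Probability in `[0,1]`.
#' @export
update_z <- function(Lambda_col, theta_col, delta_col, phi_k, a, b,
                     log_pi_geometric) {
  lsp <- sum(stats::dnorm(Lambda_col, 0, sqrt(theta_col), log = TRUE) +
               stats::dgamma(theta_col, shape = a, rate = delta_col, log = TRUE) +
               stats::dgamma(delta_col, shape = b, rate = phi_k, log = TRUE))
  lde <- sum(stats::dnorm(Lambda_col, 0, sqrt(phi_k), log = TRUE))
  stats::plogis((log_pi_geometric[1] + lsp) - (log_pi_geometric[2] + lde))
}

#' Posterior probability that a factor component is sparse
#'
#' Mirror of [update_z()] over the `n` samples of a factor row.
#'
#' @param x_row,sigma_row,rho_row Length-`n` factor row and its local
#'   variances/rates.
#' @param omega_k Component scale.
#' @param aX,bX Factor-side shapes.
#' @param log_piX_geometric Length-2 vector `c(<ln piX>, <ln(1-piX)>)`.
#' @return Probability in `[0,1]`.
#' @export
update_o <- function(x_row, sigma_row, rho_row, omega_k, aX, bX,
                     log_piX_geometric) {
  update_z(x_row, sigma_row, rho_row, omega_k, aX, bX, log_piX_geometric)
}

#' Geometric-mean log mixing proportions
#'
#' Under the beta posterior for the mixing proportion,
#' `<ln pi> = digamma(sum z + alpha) - digamma(K + alpha + beta)` and
#' `<ln(1 - pi)> = digamma(K - sum z + beta) - digamma(K + alpha + beta)`.
#'
#' @param z_or_o Length-`K` vector of sparse probabilities.
#' @param alpha,beta Beta prior parameters.
#' @return Length-2 vector `c(log_pi, log_1mpi)`.
#' @export
update_mixing <- function(z_or_o, alpha, beta) {
  K <- length(z_or_o)
  s <- sum(z_or_o)
  tot <- digamma(K + alpha + beta)
  c(log_pi = digamma(s + alpha) - tot,
    log_1mpi = digamma(K - s + beta) - tot)
}

#' Posterior mean and covariance of one factor column
#'
#' `mean = (Lambda^T Psi^-1 Lambda + O Sigma_i^-1 + (I-O) Omega^-1)^-1
#'  Lambda^T Psi^-1 y_i`, with the sparse probabilities `o` as convex weights
#' between the local and component-scale prior precisions; the covariance is
#' the inverse of the bracketed precision and is accumulated into the factor
#' second moment.
#'
#' @param y_i Length-`p` data column.
#' @param Lambda `p x K` loading matrix.
#' @param psi Length-`p` residual variances.
#' @param sigma_col Length-`K` local factor variances for this sample.
#' @param omega Length-`K` component scales.
#' @param o Length-`K` sparse probabilities.
#' @return List with `mean` (length `K`) and `cov` (`K x K`).
#' @export
update_factor_column <- function(y_i, Lambda, psi, sigma_col, omega, o) {
  A <- t(Lambda) %*% (Lambda / psi)
  diag(A) <- diag(A) + o / sigma_col + (1 - o) / omega
  cov <- solve(A)
  list(mean = as.numeric(cov %*% (t(Lambda) %*% (y_i / psi))), cov = cov)
}

#' Second moment of the factor matrix
#'
#' `<X X^T> = <X><X>^T + sum_i Cov(X_.,i)`: the outer product of the means
#' plus the per-sample posterior covariances accumulated over samples.
#'
#' @param X_means `K x n` matrix of posterior means.
#' @param X_covariances List of `n` `K x K` covariance matrices, or a single
#'   `K x K` matrix holding their sum.
#' @return `K x K` moment matrix.
#' @export
compute_X_second_moment <- function(X_means, X_covariances) {
  S <- if (is.list(X_covariances)) Reduce(`+`, X_covariances) else X_covariances
  X_means %*% t(X_means) + S
}

#' MAP update of the residual variances
#'
#' With a unit-rate gamma prior on each residual precision,
#' `psi_j = (Y Y^T - 2 Y <X>^T Lambda^T + Lambda <XX^T> Lambda^T + 2 I)_jj
#'  / (n + 2)`; computed diagonally without forming `p x p` matrices.
#'
#' @param Y `p x n` data.
#' @param Lambda `p x K` loadings.
#' @param X_means `K x n` factor means.
#' @param X_second_moment `K x K` moment `<XX^T>`.
#' @return Length-`p` positive vector, floored at `1e-10`.
#' @export
update_psi <- function(Y, Lambda, X_means, X_second_moment) {
  n <- ncol(Y)
  fitted <- Lambda %*% X_means
  quad <- rowSums((Lambda %*% X_second_moment) * Lambda)
  pmax((rowSums(Y^2) - 2 * rowSums(Y * fitted) + quad + 2) / (n + 2), .bc_floor)
}
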