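# Independent oracles used across the suite. Each re-derives the quantity it
# checks from the expected complete log likelihood (or by quadrature /
# simulation) without reusing the closed-form update implementations.

# ---- 1-D argmax oracles over the relevant terms of the expected complete
# log likelihood --------------------------------------------------------------

# theta-dependent terms (sparse branch, one element):
# (a - 3/2) ln theta - lambda^2/(2 theta) - delta * theta
oracle_theta <- function(lambda, delta, a) {
  f <- function(lt) {
    th <- exp(lt)
    (a - 1.5) * lt - lambda^2 / (2 * th) - delta * th
  }
  exp(stats::optimize(f, c(-40, 40), maximum = TRUE, tol = 1e-12)$maximum)
}

# delta terms: (a + b - 1) ln delta - (theta + phi) delta
oracle_delta <- function(theta, phi, a, b) {
  f <- function(ld) (a + b - 1) * ld - (theta + phi) * exp(ld)
  exp(stats::optimize(f, c(-40, 20), maximum = TRUE, tol = 1e-12)$maximum)
}

# phi_k terms with soft z:
# z (p b ln phi - phi sum(delta)) + (1-z)(-p/2 ln phi - T/(2 phi))
#   + (c - 1) ln phi - tau phi
oracle_phi <- function(z, delta_col, tau, lambda_col, b, cc) {
  p <- length(lambda_col)
  Tq <- sum(lambda_col^2)
  f <- function(lp) {
    phi <- exp(lp)
    z * (p * b * lp - phi * sum(delta_col)) +
      (1 - z) * (-p / 2 * lp - Tq / (2 * phi)) +
      (cc - 1) * lp - tau * phi
  }
  exp(stats::optimize(f, c(-40, 30), maximum = TRUE, tol = 1e-12)$maximum)
}

# generic gamma-form argmax: (shape - 1) ln x - rate * x
oracle_gamma_map <- function(shape, rate) {
  f <- function(lx) (shape - 1) * lx - rate * exp(lx)
  exp(stats::optimize(f, c(-40, 20), maximum = TRUE, tol = 1e-12)$maximum)
}

# numeric gradient of the Lambda-row objective at a point:
# -(1/(2 psi)) (Lam S Lam' - 2 y_term Lam') - sum_k prior precision terms
row_objective <- function(lam_row, yXt_row, S, theta_j, phi, z, psi_j) {
  quad <- as.numeric(lam_row %*% S %*% lam_row)
  lin <- sum(yXt_row * lam_row)
  -(quad - 2 * lin) / (2 * psi_j) -
    sum(z * lam_row^2 / (2 * theta_j) + (1 - z) * lam_row^2 / (2 * phi))
}

num_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# x-column objective (Eq-34 terms depending on one factor column)
col_objective <- function(x_col, y_i, Lambda, psi, sigma_col, omega, o) {
  resid <- y_i - as.numeric(Lambda %*% x_col)
  -sum(resid^2 / (2 * psi)) -
    sum(o * x_col^2 / (2 * sigma_col) + (1 - o) * x_col^2 / (2 * omega))
}

# ---- distributional oracles -------------------------------------------------

# CDF of the inverse-beta (beta-prime) distribution by relation to the beta CDF:
# t/(1+t) ~ Beta(a, b) when t ~ Be'(a, b)
pbetaprime <- function(q, a, b) stats::pbeta(q / (1 + q), a, b)

# GIG moments by numerical quadrature of x^k * x^(lam-1) exp(-(ca x + cb/x)/2)
gig_moment_quad <- function(lam, chi_a, chi_b, k = 1) {
  f <- function(x) x^(lam - 1) * exp(-(chi_a * x + chi_b / x) / 2)
  Z <- stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
  stats::integrate(function(x) x^k * f(x), 0, Inf, rel.tol = 1e-10)$value / Z
}

# digamma by asymptotic series with recurrence (independent of base digamma)
digamma_series <- function(x) {
  extra <- 0
  while (x < 8) {
    extra <- extra - 1 / x
    x <- x + 1
  }
  extra + log(x) - 1 / (2 * x) - 1 / (12 * x^2) + 1 / (120 * x^4) -
    1 / (252 * x^6)
}

# two-sample rank-sum test, normal approximation, independent of wilcox.test
ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(rk)
  sig2 <- n1 * n2 / 12 * ((n1 + n2 + 1) -
    sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  2 * stats::pnorm(-abs(W - mu + 0) / sqrt(sig2))
}

# regression-based partial correlations: correlate residuals of j and j2
# after regressing each on all remaining variables of a sample drawn from
# N(0, Omega); here computed analytically from Omega via linear algebra that
# does NOT invert the full matrix: partial covariance of (j, j2) given rest
parcor_regression <- function(Omega) {
  d <- nrow(Omega)
  P <- diag(1, d)
  for (j in 1:(d - 1)) {
    for (j2 in (j + 1):d) {
      rest <- setdiff(1:d, c(j, j2))
      S11 <- Omega[c(j, j2), c(j, j2)]
      S12 <- Omega[c(j, j2), rest, drop = FALSE]
      S22 <- Omega[rest, rest, drop = FALSE]
      Scond <- S11 - S12 %*% solve(S22, t(S12))
      r <- Scond[1, 2] / sqrt(Scond[1, 1] * Scond[2, 2])
      P[j, j2] <- r; P[j2, j] <- r
    }
  }
  P
}

# ---- fixture builders -------------------------------------------------------

# a synthetic converged fit with planted components, for network tests
make_planted_fit <- function(p, n, comps, psi = 0.05, seed = 1) {
  set.seed(seed)
  K <- length(comps)
  Lambda <- matrix(0, p, K)
  X <- matrix(0, K, n)
  for (k in seq_len(K)) {
    cmp <- comps[[k]]
    Lambda[cmp$genes, k] <- cmp$lambda
    X[k, cmp$samples] <- cmp$x
  }
  structure(list(
    loading = list(Lambda = Lambda, z = rep(1, K)),
    factor = list(X = X, SigmaX = diag(1, K), o = rep(1, K)),
    noise = list(psi = rep(psi, p)),
    converged = TRUE, seed = as.integer(seed), K_init = K,
    dense_threshold = 0.9, sparsity_threshold = 1e-10,
    trace = data.frame(iteration = 1L, nonzero_loadings = sum(Lambda != 0))),
    class = "bc_fit")
}

# fresh scratch directory for io tests
withr_dir <- function() {
  d <- tempfile("bicnet-test-")
  dir.create(d)
  d
}
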