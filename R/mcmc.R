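#' @title Gibbs sampler for the sparse/dense-mixture biclustering model
#' @description Systematic-scan Gibbs sampling over the full conditionals of
#'   the model. Its main role in the package is to warm-start the variational
#'   EM fit ([fit_vem()]); it is also available standalone via
#'   [gibbs_sweep()] for posterior exploration.
#' @name mcmc
NULL

# numerical floors keeping the chain inside double range; point-initialization
# use only, no inferential role
.mc_var_floor <- 1e-12
.mc_gig_floor <- 1e-300

#' Initialize a Gibbs chain state
#'
#' Draws the initialization prescribed for the sampler: unit-rate gamma draws
#' for every positive shrinkage parameter and the noise variances, standard
#' normal draws for loadings and factors, and beta/Bernoulli draws for the
#' mixture proportions and sparsity indicators.
#'
#' @param p,n Data dimensions (genes, samples).
#' @param hyper A [bc_hyper()] object (supplies `K` and the mixture priors).
#' @param seed Optional integer seed.
#' @return A model state: list with elements `loading`, `factor`, `noise`.
#' @export
init_gibbs_state <- function(p, n, hyper, seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  K <- hyper$K
  g1 <- function(n) stats::rgamma(n, 1, 1)
  pi0 <- stats::rbeta(1, hyper$alpha, hyper$beta)
  piX0 <- stats::rbeta(1, hyper$alphaX, hyper$betaX)
  list(
    loading = list(
      Lambda = matrix(stats::rnorm(p * K), p, K),
      theta = matrix(g1(p * K), p, K),
      delta = matrix(g1(p * K), p, K),
      phi = g1(K), tau = g1(K),
      eta = g1(1), gamma = g1(1),
      z = stats::rbinom(K, 1, pi0), pi = pi0),
    factor = list(
      X = matrix(stats::rnorm(K * n), K, n),
      SigmaX = matrix(0, K, K),
      sigma = matrix(g1(K * n), K, n),
      rho = matrix(g1(K * n), K, n),
      omega = g1(K), kappa = g1(K),
      chi = g1(1), phiX = g1(1),
      o = stats::rbinom(K, 1, piX0), piX = piX0),
    noise = list(psi = g1(p)))
}

#' One full Gibbs sweep
#'
#' Performs a single systematic scan over all conditionals, in order:
#' loading rows; per-component local/scale shrinkage (generalized inverse
#' Gaussian and gamma conditionals, branching on the sparse/dense indicator);
#' component-scale and global gamma conditionals; sparsity indicators and
#' their beta-distributed mixing proportion; then the mirrored factor-side
#' scan; and finally the inverse-gamma noise variances.
#'
#' @param state A model state as returned by [init_gibbs_state()] or a
#'   previous sweep.
#' @param Y `p x n` data matrix.
#' @param hyper A [bc_hyper()] object.
#' @param seed Optional integer seed.
#' @return The updated state.
#' @export
gibbs_sweep <- function(state, Y, hyper, seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  p <- nrow(Y); n <- ncol(Y)
  ld <- state$loading; fc <- state$factor
  K <- ncol(ld$Lambda)
  psi <- state$noise$psi
  h <- hyper

  ## --- loading rows ------------------------------------------------------
  X <- fc$X
  XXt <- X %*% t(X)
  YXt <- Y %*% t(X)
  V <- ld$theta
  dense <- ld$z == 0
  if (any(dense)) V[, dense] <- matrix(ld$phi[dense], p, sum(dense), byrow = TRUE)
  noise_mat <- matrix(stats::rnorm(p * K), p, K)
  for (j in seq_len(p)) {
    prec <- XXt / psi[j]
    diag(prec) <- diag(prec) + 1 / V[j, ]
    U <- chol(prec)
    mu <- backsolve(U, forwardsolve(t(U), YXt[j, ] / psi[j]))
    ld$Lambda[j, ] <- mu + backsolve(U, noise_mat[j, ])
  }

  ## --- loading-side indicators and shrinkage ------------------------------
  ## The indicator is drawn jointly with the local variances as a blocked
  ## move: z | Lambda, delta, phi, pi uses the sparse evidence with theta
  ## integrated out (a variance-gamma density; the delta layer is common to
  ## both branches and cancels), then theta | z, Lambda, delta is re-imputed
  ## from its exact conditional (GIG under the sparse branch, its prior
  ## under the dense branch). Comparing the two branches' joints at sampled
  ## theta values instead would penalize the sparse branch by the
  ## conditional entropy of the extra layer and freeze the chain in the
  ## dense state.
  lsp <- colSums(matrix(.log_vg(ld$Lambda, ld$delta, h$a), p, K))
  lde <- .log_dense_evidence(ld$Lambda, ld$phi)
  pz <- stats::plogis((log(ld$pi) + lsp) - (log1p(-ld$pi) + lde))
  ld$z <- stats::rbinom(K, 1, pz)
  sp <- which(ld$z == 1)
  de <- which(ld$z == 0)
  if (length(sp)) {
    l2 <- pmax(ld$Lambda[, sp, drop = FALSE]^2, .mc_gig_floor)
    ld$theta[, sp] <- pmax(
      matrix(sample_gig(h$a - 0.5, 2 * ld$delta[, sp, drop = FALSE], l2),
             p, length(sp)), .mc_var_floor)
  }
  if (length(de)) {
    ld$theta[, de] <- pmax(
      matrix(stats::rgamma(p * length(de), shape = h$a,
                           rate = ld$delta[, de, drop = FALSE]),
             p, length(de)), .mc_var_floor)
  }
  ## delta | theta, phi is Ga(a+b, theta+phi) under either branch
  ld$delta <- matrix(
    stats::rgamma(p * K, shape = h$a + h$b,
                  rate = ld$theta + matrix(ld$phi, p, K, byrow = TRUE)),
    p, K)
  ## component scale: gamma under the sparse branch; under the dense branch
  ## both the loading likelihood N(0, phi) and the delta layer Ga(b, phi)
  ## inform phi, giving a GIG conditional
  if (length(sp)) {
    ld$phi[sp] <- stats::rgamma(
      length(sp), shape = p * h$b + h$c,
      rate = colSums(ld$delta[, sp, drop = FALSE]) + ld$tau[sp])
  }
  if (length(de)) {
    t2 <- pmax(colSums(ld$Lambda[, de, drop = FALSE]^2), .mc_gig_floor)
    ld$phi[de] <- pmax(
      sample_gig(p * h$b + h$c - p / 2,
                 2 * (ld$tau[de] + colSums(ld$delta[, de, drop = FALSE])), t2),
      .mc_var_floor)
  }
  ld$tau <- stats::rgamma(K, shape = h$c + h$d, rate = ld$phi + ld$eta)
  ld$eta <- stats::rgamma(1, shape = K * h$d + h$e, rate = ld$gamma + sum(ld$tau))
  ld$gamma <- stats::rgamma(1, shape = h$e + h$f, rate = ld$eta + h$nu)
  n1 <- sum(ld$z)
  ld$pi <- stats::rbeta(1, h$alpha + n1, h$beta + K - n1)

  ## --- factor columns ----------------------------------------------------
  Lam <- ld$Lambda
  AtA <- t(Lam) %*% (Lam / psi)
  B <- t(Lam / psi) %*% Y
  W <- fc$sigma
  denseo <- fc$o == 0
  if (any(denseo)) W[denseo, ] <- matrix(fc$omega[denseo], sum(denseo), n)
  noise_mat <- matrix(stats::rnorm(K * n), K, n)
  for (i in seq_len(n)) {
    prec <- AtA
    diag(prec) <- diag(prec) + 1 / W[, i]
    U <- chol(prec)
    mu <- backsolve(U, forwardsolve(t(U), B[, i]))
    fc$X[, i] <- mu + backsolve(U, noise_mat[, i])
  }

  ## --- factor-side indicators and shrinkage (mirror) ----------------------
  lspo <- rowSums(matrix(.log_vg(fc$X, fc$rho, h$aX), K, n))
  ldeo <- .log_dense_evidence(t(fc$X), fc$omega)
  po <- stats::plogis((log(fc$piX) + lspo) - (log1p(-fc$piX) + ldeo))
  fc$o <- stats::rbinom(K, 1, po)
  spo <- which(fc$o == 1)
  deo <- which(fc$o == 0)
  if (length(spo)) {
    x2 <- pmax(fc$X[spo, , drop = FALSE]^2, .mc_gig_floor)
    fc$sigma[spo, ] <- pmax(
      matrix(sample_gig(h$aX - 0.5, 2 * fc$rho[spo, , drop = FALSE], x2),
             length(spo), n), .mc_var_floor)
  }
  if (length(deo)) {
    fc$sigma[deo, ] <- pmax(
      matrix(stats::rgamma(length(deo) * n, shape = h$aX,
                           rate = fc$rho[deo, , drop = FALSE]),
             length(deo), n), .mc_var_floor)
  }
  fc$rho <- matrix(
    stats::rgamma(K * n, shape = h$aX + h$bX, rate = fc$sigma + fc$omega),
    K, n)
  if (length(spo)) {
    fc$omega[spo] <- stats::rgamma(
      length(spo), shape = n * h$bX + h$cX,
      rate = rowSums(fc$rho[spo, , drop = FALSE]) + fc$kappa[spo])
  }
  if (length(deo)) {
    x2 <- pmax(rowSums(fc$X[deo, , drop = FALSE]^2), .mc_gig_floor)
    fc$omega[deo] <- pmax(
      sample_gig(n * h$bX + h$cX - n / 2,
                 2 * (fc$kappa[deo] + rowSums(fc$rho[deo, , drop = FALSE])), x2),
      .mc_var_floor)
  }
  fc$kappa <- stats::rgamma(K, shape = h$cX + h$dX, rate = fc$omega + fc$chi)
  fc$chi <- stats::rgamma(1, shape = K * h$dX + h$eX, rate = fc$phiX + sum(fc$kappa))
  fc$phiX <- stats::rgamma(1, shape = h$eX + h$fX, rate = fc$chi + h$xi)
  n1 <- sum(fc$o)
  fc$piX <- stats::rbeta(1, h$alphaX + n1, h$betaX + K - n1)

  ## --- noise -------------------------------------------------------------
  ssr <- rowSums((Y - Lam %*% fc$X)^2)
  psi <- 1 / stats::rgamma(p, shape = n / 2 + 1, rate = ssr / 2 + 1)
  list(loading = ld, factor = fc, noise = list(psi = pmax(psi, .mc_var_floor)))
}

# per-component log evidence of the sparse branch:
# sum_j log N(L | 0, theta) + log Ga(theta | a, delta) + log Ga(delta | b, phi)
.log_sparse_evidence <- function(Lambda, theta, delta, phi, a, b) {
  K <- ncol(Lambda); p <- nrow(Lambda)
  phim <- matrix(phi, p, K, byrow = TRUE)
  colSums(stats::dnorm(Lambda, 0, sqrt(theta), log = TRUE) +
            stats::dgamma(theta, shape = a, rate = delta, log = TRUE) +
            stats::dgamma(delta, shape = b, rate = phim, log = TRUE))
}

# log density of an element under the sparse branch with its local variance
# integrated out against Ga(a, delta): the variance-gamma law
#   m(l) = Int N(l | 0, th) Ga(th | a, delta) dth
#        = 2 delta^a / (Gamma(a) sqrt(2 pi)) (l^2/(2 delta))^{(2a-1)/4}
#          K_{a-1/2}(sqrt(2 delta l^2))
# evaluated elementwise with small-argument asymptotics for the Bessel K.
.log_vg <- function(lam, delta, a) {
  nu <- a - 0.5
  l2 <- pmax(as.numeric(lam)^2, 1e-300)
  dl <- pmax(as.numeric(delta), 1e-300)
  zz <- sqrt(2 * dl * l2)
  logK <- numeric(length(zz))
  big <- zz >= 1e-5
  if (any(big)) {
    logK[big] <- log(besselK(zz[big], nu, expon.scaled = TRUE)) - zz[big]
  }
  if (any(!big)) {
    z0 <- zz[!big]
    logK[!big] <- if (abs(nu) > 1e-8) {
      lgamma(abs(nu)) - log(2) + abs(nu) * (log(2) - log(z0))
    } else {
      log(-log(z0 / 2) - 0.57721566490153286)
    }
  }
  a * log(dl) - lgamma(a) - 0.5 * log(2 * pi) + log(2) +
    ((2 * a - 1) / 4) * (log(l2) - log(2 * dl)) + logK
}

# per-component log evidence of the dense branch: sum_j log N(L | 0, phi)
.log_dense_evidence <- function(Lambda, phi) {
  K <- ncol(Lambda); p <- nrow(Lambda)
  colSums(stats::dnorm(Lambda, 0, sqrt(matrix(phi, p, K, byrow = TRUE)), log = TRUE))
}

#' Run the Gibbs sampler as a warm start
#'
#' Runs `n_iters` full sweeps from the stochastic initialization and returns
#' the final state, which [fit_vem()] uses as the starting point of the
#' variational EM optimization (one independent chain per restart seed).
#'
#' By default the warm-start chain holds every sparse/dense indicator in the
#' sparse branch for the first three quarters of the sweeps
#' (`pin_sparse = TRUE`): the heavy-tailed local hierarchy nests dense
#' behavior, so the pinned chain explores support configurations freely,
#' whereas a chain started from an unstructured state with free indicators
#' falls into the all-dense basin and stays there (the sparse basin is
#' separated by a large energy barrier), returning an initialization with no
#' local sparsity information. The final quarter of the sweeps runs with
#' free (collapsed) indicator draws from the structured state; the returned
#' `z` and `o` are the averages of those draws, i.e. posterior sparse/dense
#' probabilities evaluated on honest chain samples rather than on
#' MAP-shrunken values.
#'
#' @inheritParams gibbs_sweep
#' @param n_iters Number of sweeps (default 500).
#' @param seed Integer seed for the chain.
#' @param pin_sparse Hold indicators at the sparse branch during the initial
#'   sweeps (default `TRUE`); `FALSE` runs a plain chain throughout and
#'   returns the final hard indicator draws.
#' @param indicator_tail Fraction of the sweeps run with free indicators at
#'   the end when `pin_sparse = TRUE` (default 0.25).
#' @return The final model state (with averaged `z`, `o` when pinned).
#' @export
run_warm_start <- function(Y, hyper, n_iters = 500, seed = 1,
                           pin_sparse = TRUE, indicator_tail = 0.25) {
  if (n_iters < 1) stop("n_iters must be >= 1")
  if (!all(is.finite(Y))) stop("Y must be finite with no missing values")
  local_seed(seed)
  state <- init_gibbs_state(nrow(Y), ncol(Y), hyper)
  if (!pin_sparse) {
    for (t in seq_len(n_iters)) state <- gibbs_sweep(state, Y, hyper)
    return(state)
  }
  n_tail <- min(n_iters - 1L, max(1L, round(n_iters * indicator_tail)))
  state$loading$z[] <- 1L
  state$factor$o[] <- 1L
  for (t in seq_len(n_iters - n_tail)) {
    state <- gibbs_sweep(state, Y, hyper)
    state$loading$z[] <- 1L
    state$factor$o[] <- 1L
  }
  zacc <- 0; oacc <- 0
  for (t in seq_len(n_tail)) {
    state <- gibbs_sweep(state, Y, hyper)
    zacc <- zacc + state$loading$z
    oacc <- oacc + state$factor$o
  }
  state$loading$z <- zacc / n_tail
  state$factor$o <- oacc / n_tail
  state
}
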