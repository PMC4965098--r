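#' Generalized inverse Gaussian sampling
#'
#' Draws from the generalized inverse Gaussian (GIG) distribution with
#' density proportional to
#' \deqn{x^{lam - 1} \exp\{-(chi_a \, x + chi_b / x)/2\}, \quad x > 0.}
#' This is the conditional family of the local variance parameters in the
#' Gibbs sampler: e.g. a local loading variance is conditionally
#' `GIG(a - 1/2, 2 delta, Lambda^2)`.
#'
#' Valid parameter regions: `chi_a > 0, chi_b >= 0, lam > 0` (gamma limit at
#' `chi_b = 0`); `chi_a > 0, chi_b > 0` (any `lam`); or
#' `chi_a >= 0, chi_b > 0, lam < 0` (inverse-gamma limit at `chi_a = 0`).
#'
#' The sampler reduces to the two-parameter form `GIG(lam, omega)` with
#' `omega = sqrt(chi_a * chi_b)` and uses a mode-shifted ratio-of-uniforms
#' rejection method, except for `|lam| < 1` with small `omega`, where the
#' density is sampled on the log scale through a three-piece
#' (exponential / log-linear / exponential) envelope that exploits the
#' log-concavity of the density in `log x` and remains efficient for
#' `omega` down to the smallest normal doubles.
#'
#' @param lam Power parameter (recycled).
#' @param chi_a Nonnegative coefficient of `x` in the exponent (recycled).
#' @param chi_b Nonnegative coefficient of `1/x` in the exponent (recycled).
#' @param n Number of draws; defaults to the longest parameter vector.
#' @param seed Optional integer seed (RNG state restored on exit).
#' @return Numeric vector of `n` positive draws.
#' @examples
#' x <- sample_gig(0.5, 2, 3, n = 5, seed = 1)
#' @export
sample_gig <- function(lam, chi_a, chi_b, n = NULL, seed = NULL) {
  if (!is.null(seed)) local_seed(seed)
  if (is.null(n)) n <- max(length(lam), length(chi_a), length(chi_b))
  lam <- rep_len(as.numeric(lam), n)
  chi_a <- rep_len(as.numeric(chi_a), n)
  chi_b <- rep_len(as.numeric(chi_b), n)
  if (any(!is.finite(lam)) || any(!is.finite(chi_a)) || any(!is.finite(chi_b)) ||
      any(chi_a < 0) || any(chi_b < 0)) {
    stop("GIG parameters must be finite with chi_a >= 0 and chi_b >= 0")
  }
  bad <- (chi_b == 0 & lam <= 0) | (chi_a == 0 & lam >= 0)
  if (any(bad)) {
    stop("invalid GIG parameter region at index ", which(bad)[1],
         " (lam = ", lam[which(bad)[1]], ", chi_a = ", chi_a[which(bad)[1]],
         ", chi_b = ", chi_b[which(bad)[1]], ")")
  }

  out <- numeric(n)
  ga <- chi_b == 0                       # gamma boundary
  ig <- chi_a == 0                       # inverse-gamma boundary
  if (any(ga)) out[ga] <- stats::rgamma(sum(ga), shape = lam[ga], rate = chi_a[ga] / 2)
  if (any(ig)) out[ig] <- 1 / stats::rgamma(sum(ig), shape = -lam[ig], rate = chi_b[ig] / 2)

  gen <- !(ga | ig)
  if (any(gen)) {
    omega <- sqrt(chi_a[gen] * chi_b[gen])
    scale <- sqrt(chi_b[gen] / chi_a[gen])
    l <- lam[gen]
    flip <- l < 0                        # GIG(-lam, omega) = 1 / GIG(lam, omega)
    al <- abs(l)
    z <- numeric(sum(gen))
    small <- al < 1 & omega <= 0.5
    if (any(small)) z[small] <- .gig2_log_envelope(al[small], omega[small])
    if (any(!small)) z[!small] <- .gig2_rou_shift(al[!small], omega[!small])
    z[flip] <- 1 / z[flip]
    out[gen] <- scale * z
  }
  out
}

# Two-parameter GIG(lam, omega), lam in [0,1), omega <= 0.5 (may be tiny).
# Work with y = log x: log-density l(y) = lam*y - omega*cosh(y), strictly
# concave. Envelope: unit-slope tangent tails beyond Y_l, Y_r (chosen where
# l'(y) = +1 / -1) and exp(lam*y - omega) between them (cosh >= 1 on the
# middle piece, which always brackets 0 since lam < 1).
.gig2_log_envelope <- function(lam, omega) {
  n <- length(lam)
  sr <- (lam + 1) / omega
  sl <- (lam - 1) / omega
  Yr <- asinh(sr)
  Yl <- asinh(sl)
  lfYr <- lam * Yr - omega * sqrt(1 + sr^2)
  lfYl <- lam * Yl - omega * sqrt(1 + sl^2)
  # Middle-piece envelope: exp(lam*y - omega) on [Yl, Yr] in general; when
  # lam*(Yr - Yl) is negligible the flat bound exp(lam*Yr - omega) is used
  # instead so that the within-piece sampler (uniform) matches the envelope
  # exactly.
  tspan <- lam * (Yr - Yl)
  flat <- tspan < 1e-6
  lAm <- ifelse(flat,
                lam * Yr - omega + log(Yr - Yl),
                -omega + lam * Yr + log1p(-exp(-pmax(tspan, 1e-6))) -
                  log(pmax(lam, .Machine$double.xmin)))
  lAr <- lfYr                            # integral of exp(lfYr - (y - Yr))
  lAl <- lfYl
  mx <- pmax(lAm, pmax(lAr, lAl))
  wm <- exp(lAm - mx); wr <- exp(lAr - mx); wl <- exp(lAl - mx)
  tot <- wm + wr + wl

  out <- numeric(n)
  todo <- seq_len(n)
  it <- 0L
  while (length(todo) > 0L) {
    it <- it + 1L
    if (it > 1000L) stop("GIG rejection sampler failed to accept after 1000 rounds")
    i <- todo
    u <- stats::runif(length(i)) * tot[i]
    piece <- ifelse(u < wm[i], 1L, ifelse(u < wm[i] + wr[i], 2L, 3L))
    y <- numeric(length(i))
    # middle: density prop. to exp(lam * y) on [Yl, Yr] (uniform when flat)
    m1 <- piece == 1L
    if (any(m1)) {
      li <- i[m1]
      lz <- lam[li]
      w <- exp(-pmax(lz * (Yr[li] - Yl[li]), 0))
      uu <- stats::runif(length(li), min = w, max = 1)
      y[m1] <- ifelse(flat[li],
                      Yl[li] + stats::runif(length(li)) * (Yr[li] - Yl[li]),
                      Yr[li] + log(uu) / lz)
    }
    m2 <- piece == 2L
    if (any(m2)) y[m2] <- Yr[i[m2]] + stats::rexp(sum(m2))
    m3 <- piece == 3L
    if (any(m3)) y[m3] <- Yl[i[m3]] - stats::rexp(sum(m3))
    # envelope log-density at y
    lenv <- numeric(length(i))
    lenv[m1] <- ifelse(flat[i[m1]],
                       lam[i[m1]] * Yr[i[m1]] - omega[i[m1]],
                       lam[i[m1]] * y[m1] - omega[i[m1]])
    lenv[m2] <- lfYr[i[m2]] - (y[m2] - Yr[i[m2]])
    lenv[m3] <- lfYl[i[m3]] + (y[m3] - Yl[i[m3]])
    ltar <- lam[i] * y - omega[i] * cosh(y)
    acc <- log(stats::runif(length(i))) <= (ltar - lenv)
    acc[is.na(acc)] <- FALSE
    out[i[acc]] <- exp(y[acc])
    todo <- i[!acc]
  }
  out
}

# Two-parameter GIG(lam, omega), lam >= 0, by ratio-of-uniforms with the
# density relocated at its mode (Dagpunar-type). The bounds of the v-region
# are the two positive roots of a cubic obtained from the stationarity of
# (x - m)^2 f(x).
.gig2_rou_shift <- function(lam, omega) {
  n <- length(lam)
  m <- ifelse(lam >= 1,
              ((lam - 1) + sqrt((lam - 1)^2 + omega^2)) / omega,
              omega / ((1 - lam) + sqrt((1 - lam)^2 + omega^2)))
  lf <- function(x, i) (lam[i] - 1) * log(x) - (omega[i] / 2) * (x + 1 / x)
  lfm <- lf(m, seq_len(n))
  a_c <- -(2 * (lam + 1) / omega + m)
  b_c <- 2 * (lam - 1) * m / omega - 1
  c_c <- m
  pp <- b_c - a_c^2 / 3
  qq <- 2 * a_c^3 / 27 - a_c * b_c / 3 + c_c
  arg <- pmin(pmax(-qq / 2 / sqrt(pmax(-pp^3 / 27, .Machine$double.xmin)), -1), 1)
  fi <- acos(arg)
  fak <- 2 * sqrt(pmax(-pp / 3, 0))
  y1 <- fak * cos(fi / 3) - a_c / 3
  y2 <- fak * cos(fi / 3 + 4 * pi / 3) - a_c / 3
  y2 <- pmax(y2, .Machine$double.xmin)
  vp <- (y1 - m) * exp(0.5 * (lf(y1, seq_len(n)) - lfm))
  vm <- (y2 - m) * exp(0.5 * (lf(y2, seq_len(n)) - lfm))

  out <- numeric(n)
  todo <- seq_len(n)
  it <- 0L
  while (length(todo) > 0L) {
    it <- it + 1L
    if (it > 10000L) stop("GIG ratio-of-uniforms sampler failed to accept")
    i <- todo
    u <- stats::runif(length(i))
    v <- stats::runif(length(i), min = vm[i], max = vp[i])
    x <- v / u + m[i]
    ok <- x > 0
    acc <- ok & (2 * log(u) <= lf(pmax(x, .Machine$double.xmin), i) - lfm[i])
    acc[is.na(acc)] <- FALSE
    out[i[acc]] <- x[acc]
    todo <- i[!acc]
  }
  out
}
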