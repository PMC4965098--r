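test_that("run QC applies the product-of-correlations rule", {
  # duplicated component: product 1 -> discard
  fit <- make_planted_fit(
    p = 10, n = 8,
    comps = list(list(genes = 1:4, lambda = c(1, 2, -1, 1),
                      samples = 1:4, x = c(1, -1, 2, 1)),
                 list(genes = 1:4, lambda = c(1, 2, -1, 1),
                      samples = 1:4, x = c(1, -1, 2, 1))))
  expect_false(qc_run(fit))
  # crafted correlations: 0.9 * 0.6 = 0.54 -> discard; 0.9 * 0.5 -> keep
  # (second vectors built from an orthogonalized residual so the pairwise
  # correlations are exact)
  base_l <- c(1, 2, 3, 4, 5); base_x <- c(2, 1, 3, 5, 4)
  with_cor <- function(base, helper, r) {
    u <- as.numeric(scale(base))
    v <- as.numeric(scale(helper))
    v <- v - sum(u * v) / sum(u * u) * u
    v <- v / sqrt(sum(v^2)) * sqrt(sum(u^2))
    r * u + sqrt(1 - r^2) * v
  }
  make_pair <- function(r_l, r_x) {
    make_planted_fit(p = 5, n = 5, comps = list(
      list(genes = 1:5, lambda = base_l, samples = 1:5, x = base_x),
      list(genes = 1:5, lambda = with_cor(base_l, c(3, 1, 4, 1, 5), r_l),
           samples = 1:5, x = with_cor(base_x, c(2, 7, 1, 8, 2), r_x))))
  }
  f_bad <- make_pair(0.9, 0.6)
  prod_bad <- cor(f_bad$loading$Lambda)[1, 2] * cor(t(f_bad$factor$X))[1, 2]
  expect_gt(prod_bad, 0.5)
  expect_false(qc_run(f_bad))
  f_ok <- make_pair(0.9, 0.5)
  prod_ok <- cor(f_ok$loading$Lambda)[1, 2] * cor(t(f_ok$factor$X))[1, 2]
  expect_lt(prod_ok, 0.5)
  expect_true(qc_run(f_ok))
  # orthogonal random components -> keep
  set.seed(41)
  f_r <- make_planted_fit(p = 40, n = 30, comps = list(
    list(genes = 1:20, lambda = rnorm(20), samples = 1:15, x = rnorm(15)),
    list(genes = 21:40, lambda = rnorm(20), samples = 16:30, x = rnorm(15))))
  expect_true(qc_run(f_r))
})

test_that("redundancy groups flag identical supports only", {
  comps <- list(
    list(lambda = c(1, 2, 0, 0), x = c(0, 1, 1)),
    list(lambda = c(3, -1, 0, 0), x = c(0, 2, 5)),   # same supports
    list(lambda = c(1, 0, 2, 0), x = c(0, 1, 1)),    # one gene differs
    list(lambda = c(1, 1, 1, 0), x = c(1, 1, 0)))
  rg <- redundancy_groups(comps)
  expect_identical(rg$group[1], rg$group[2])
  expect_identical(rg$group[1], rg$group[3])  # same (n_g, n_s) sizes
  expect_identical(nrow(rg$redundant_pairs), 1L)
  expect_identical(as.integer(rg$redundant_pairs[1, ]), c(1L, 2L))
  # randomized set against a brute-force pairwise comparison
  set.seed(42)
  comps <- replicate(12, {
    list(lambda = ifelse(runif(6) < 0.5, 0, 1) * rnorm(6),
         x = ifelse(runif(5) < 0.5, 0, 1) * rnorm(5))
  }, simplify = FALSE)
  rg <- redundancy_groups(comps)
  brute <- list()
  for (i in 1:11) for (j in (i + 1):12) {
    si <- comps[[i]]; sj <- comps[[j]]
    if (identical(which(si$lambda != 0), which(sj$lambda != 0)) &&
        identical(which(si$x != 0), which(sj$x != 0))) {
      brute[[length(brute) + 1]] <- c(i, j)
    }
  }
  got <- if (nrow(rg$redundant_pairs)) {
    apply(rg$redundant_pairs, 1, paste, collapse = "-")
  } else character(0)
  want <- vapply(brute, paste, character(1), collapse = "-")
  expect_setequal(got, want)
})

test_that("Bonferroni threshold reproduces the published component count case", {
  expect_equal(signif(bonferroni_threshold(0.05, 53814), 3), 9.29e-7)
})

test_that("component selection by context works in all three modes", {
  labels <- rep(c("female", "male"), each = 5)
  fit <- make_planted_fit(
    p = 12, n = 10,
    comps = list(
      list(genes = 1:3, lambda = c(1, 1, 1), samples = 1:5,
           x = c(1, -1, 2, 1, 1)),                      # female-only
      list(genes = 4:6, lambda = c(1, 1, 1), samples = 1:10,
           x = rep(1, 10)),                             # ubiquitous
      list(genes = 7:9, lambda = c(1, 1, 1), samples = 4:8,
           x = c(1, 1, 1, 1, 1))))                      # straddles contexts
  expect_identical(select_components(fit, mode = "ubiquitous")$A, 2L)
  sel <- select_components(fit, labels, "context_specific", context = "female")
  expect_identical(sel$A, 1L)
  # a female-only component is not ubiquitous
  expect_false(1L %in% select_components(fit, mode = "ubiquitous")$A)

  # differential: identical group values are never selected; a strong shift is
  set.seed(43)
  labels16 <- rep(c("female", "male"), each = 8)
  x_null <- rep(c(1, 2, 3, 4, 5, 6, 7, 8), 2)
  x_diff <- c(rnorm(8, 0, 1), rnorm(8, 6, 1))
  fit2 <- make_planted_fit(
    p = 6, n = 16,
    comps = list(list(genes = 1:3, lambda = c(1, 1, 1), samples = 1:16,
                      x = x_null),
                 list(genes = 4:6, lambda = c(1, 1, 1), samples = 1:16,
                      x = x_diff)))
  sel <- select_components(fit2, labels16, "differential",
                           context = "female", p_threshold = 0.01)
  expect_identical(sel$A, 2L)
  expect_true(all(sel$pvalues <= 0.01))
  expect_error(select_components(fit2, rep("a", 16), "differential"),
               "two label groups|empty")
})

test_that("differential selection agrees with an independent rank-sum test", {
  set.seed(44)
  labels <- rep(c("g1", "g2"), each = 10)
  for (i in 1:20) {
    x <- c(rnorm(10), rnorm(10, sample(c(0, 3), 1)))
    fit <- make_planted_fit(p = 3, n = 20,
                            comps = list(list(genes = 1:3,
                                              lambda = c(1, 1, 1),
                                              samples = 1:20, x = x)))
    sel <- select_components(fit, labels, "differential", context = "g1",
                             p_threshold = 0.01)
    expect_identical(length(sel$A) == 1L, ranksum_p(x[1:10], x[11:20]) <= 0.01)
  }
})

test_that("support covariance matches the direct construction", {
  # single component, support {g1, g2}, values (1, 2), Sigma = 1, psi = 1
  cc <- component_covariance(matrix(c(1, 2, 0), 3, 1), matrix(1, 1, 1),
                             rep(1, 3))
  expect_identical(cc$genes, 1:2)
  expect_equal(cc$Omega, matrix(c(2, 2, 2, 5), 2, 2))
  # all-zero loadings: empty support signals an empty network
  cc0 <- component_covariance(matrix(0, 3, 2), diag(2), rep(1, 3))
  expect_length(cc0$genes, 0)
  # random instance against dense evaluation
  set.seed(45)
  L <- matrix(rnorm(12), 6, 2); L[abs(L) < 0.4] <- 0
  S <- crossprod(matrix(rnorm(4), 2, 2)) + diag(0.1, 2)
  psi <- runif(6, 0.5, 2)
  cc <- component_covariance(L, S, psi)
  sup <- cc$genes
  expect_equal(cc$Omega,
               L[sup, ] %*% S %*% t(L[sup, ]) + diag(psi[sup]),
               tolerance = 1e-12)
})

test_that("partial correlations match a regression-based oracle", {
  # diagonal covariance: all off-diagonal partial correlations are zero
  P <- partial_correlations(diag(c(1, 2, 3)))
  expect_equal(P, diag(3))
  # bivariate case: partial correlation equals the marginal correlation
  Om <- matrix(c(2, 1.2, 1.2, 3), 2, 2)
  P <- partial_correlations(Om)
  expect_equal(P[1, 2], 1.2 / sqrt(6), tolerance = 1e-12)
  # 6-gene sparse covariance vs conditional-covariance oracle
  set.seed(46)
  L <- matrix(rnorm(12), 6, 2); L[abs(L) < 0.5] <- 0
  Om <- L %*% t(L) + diag(runif(6, 0.5, 1.5))
  expect_equal(partial_correlations(Om), parcor_regression(Om),
               tolerance = 1e-8)
  # invariance: symmetric permutation and positive scaling
  perm <- c(3, 1, 6, 2, 5, 4)
  P <- partial_correlations(Om)
  expect_equal(partial_correlations(Om[perm, perm]), P[perm, perm],
               tolerance = 1e-10)
  expect_equal(partial_correlations(7.3 * Om), P, tolerance = 1e-10)
})

test_that("edge testing: null, spiked, and degenerate threshold behavior", {
  # pure null: partial correlations near zero produce no edges at 0.8
  set.seed(47)
  hits <- vapply(1:60, function(i) {
    P <- partial_correlations(cov(t(matrix(rnorm(15 * 200), 15, 200))))
    nrow(test_edges(P, 0.8))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
  # one strong pair among many null pairs is detected
  found <- vapply(1:20, function(i) {
    n_obs <- 300
    Z <- matrix(rnorm(15 * n_obs), 15, n_obs)
    Z[2, ] <- Z[1, ] + rnorm(n_obs, 0, 0.25)   # strong conditional dependence
    P <- partial_correlations(cov(t(Z)))
    ed <- test_edges(P, 0.8)
    any(ed$a == 1 & ed$b == 2)
  }, logical(1))
  expect_gte(mean(found), 0.95)
  # posterior threshold 1 -> empty set regardless of input
  P <- diag(5); P[1, 2] <- P[2, 1] <- 0.99
  expect_identical(nrow(test_edges(P, 1.0)), 0L)
  # too few pairs -> absolute-threshold fallback with warning
  expect_warning(ed <- test_edges(matrix(c(1, .9, .9, 1), 2, 2), 0.8),
                 "fewer than 20")
  expect_identical(nrow(ed), 1L)
})

test_that("ensemble aggregation counts canonical edges across runs", {
  e1 <- data.frame(a = 1, b = 2, parcor = 0.5, posterior = 0.9)
  net <- aggregate_networks(list(e1, e1, e1), r = 3)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$replication_count, 3L)
  # r = 1: union of all edges
  e2 <- data.frame(a = 2, b = 3, parcor = -0.4, posterior = 0.85)
  net <- aggregate_networks(list(e1, e2), r = 1)
  expect_identical(nrow(net$edges), 2L)
  # randomized edge sets against brute-force counting
  set.seed(48)
  sets <- replicate(6, {
    k <- sample(0:5, 1)
    if (k == 0) return(NULL)
    pairs <- t(replicate(k, sort(sample(8, 2))))
    data.frame(a = pairs[, 1], b = pairs[, 2], parcor = runif(k),
               posterior = runif(k))
  }, simplify = FALSE)
  for (r in 1:3) {
    net <- aggregate_networks(sets, r = r)
    tab <- table(unlist(lapply(sets, function(e) {
      if (is.null(e)) return(character(0))
      paste(pmin(e$a, e$b), pmax(e$a, e$b))
    })))
    expect_identical(sort(paste(net$edges$a, net$edges$b)),
                     sort(names(tab)[tab >= r]))
  }
})

test_that("expected replicated edges: closed forms, Monte Carlo, monotonicity", {
  # r = 1 reduces to the complement of never occurring
  expect_equal(expected_replicated_edges(20, 1, 1000, 50),
               1000 * (1 - (1 - 0.05)^20))
  # every run contains every edge
  expect_equal(expected_replicated_edges(7, 4, 300, 300), 300)
  # printed (uncorrected) variant differs by the j = 0 term
  expect_equal(expected_replicated_edges(20, 3, 1000, 50, corrected = FALSE) -
                 expected_replicated_edges(20, 3, 1000, 50),
               1000 * dbinom(0, 20, 0.05))
  # Monte-Carlo oracle: runs draw e_hat distinct edges uniformly
  set.seed(49)
  R <- 20; E <- 1000; e_hat <- 50
  reps <- 2000
  counts <- matrix(0, reps, 3)
  for (i in seq_len(reps)) {
    occ <- tabulate(unlist(lapply(seq_len(R), function(j) sample.int(E, e_hat))),
                    nbins = E)
    counts[i, ] <- c(sum(occ >= 1), sum(occ >= 2), sum(occ >= 3))
  }
  for (r in 1:3) {
    mc <- mean(counts[, r])
    se <- sd(counts[, r]) / sqrt(reps)
    expect_lt(abs(expected_replicated_edges(R, r, E, e_hat) - mc),
              3 * se + 0.02 * mc)
  }
  # monotone decreasing in r, increasing in e_hat
  grid_r <- vapply(1:6, function(r) expected_replicated_edges(10, r, 500, 40),
                   numeric(1))
  expect_true(all(diff(grid_r) < 0))
  grid_e <- vapply(c(10, 20, 40, 80), function(e)
    expected_replicated_edges(10, 2, 500, e), numeric(1))
  expect_true(all(diff(grid_e) > 0))
  expect_error(expected_replicated_edges(10, 2, 100, 200), "e_hat")
})

test_that("planted context-specific networks are recovered end to end", {
  prec <- c(); rec <- c()
  for (sd in 1:10) {
    set.seed(sd)
    labels <- rep(c("ctx1", "ctx2"), each = 10)
    mk_fit <- function(jitter_seed) {
      set.seed(jitter_seed)
      comps <- list(
        # two planted context-1-only components with disjoint gene sets
        list(genes = 1:6, lambda = c(2, -2, 1.5, 2, -1.5, 2) + rnorm(6, 0, .1),
             samples = 1:10, x = c(1, -1, 1, 1, -1, 1, 1, -1, 1, 1)),
        list(genes = 7:12, lambda = c(2, 2, -2, 1.5, 2, -2) + rnorm(6, 0, .1),
             samples = 1:10, x = c(1, 1, -1, 1, 1, -1, 1, 1, -1, 1)),
        # background component spanning both contexts
        list(genes = 13:18, lambda = rep(1.5, 6) + rnorm(6, 0, .1),
             samples = 1:20, x = rnorm(20)))
      make_planted_fit(p = 20, n = 20, comps = comps, psi = 0.05,
                       seed = jitter_seed)
    }
    fits <- lapply(sd * 100 + 1:3, mk_fit)
    net <- build_network(fits, labels, mode = "context_specific",
                         context = "ctx1", r = 2)
    got <- paste(net$edges$a, net$edges$b)
    want <- c(apply(t(combn(1:6, 2)), 1, paste, collapse = " "),
              apply(t(combn(7:12, 2)), 1, paste, collapse = " "))
    prec <- c(prec, if (length(got)) mean(got %in% want) else 0)
    rec <- c(rec, mean(want %in% got))
  }
  expect_gte(mean(prec), 0.9)
  expect_gte(mean(rec), 0.9)
})

test_that("selection misses produce an empty network without error", {
  fit <- make_planted_fit(
    p = 8, n = 6,
    comps = list(list(genes = 1:3, lambda = c(1, 1, 1), samples = 1:6,
                      x = rep(1, 6))))
  labels <- rep(c("a", "b"), each = 3)
  net <- build_network(list(fit), labels, mode = "context_specific",
                       context = "a", r = 1)
  expect_identical(nrow(net$edges), 0L)
  expect_length(net$nodes, 0)
})

test_that("precision matrices are only formed on the selected support", {
  # a gene outside the selected component's support never gains an edge
  fit <- make_planted_fit(
    p = 10, n = 8,
    comps = list(
      list(genes = 1:4, lambda = c(2, 2, -2, 2), samples = 1:4,
           x = c(1, 1, -1, 1)),
      list(genes = 5:8, lambda = c(2, -2, 2, 2), samples = 5:8,
           x = c(1, 1, 1, -1))))
  labels <- rep(c("u", "v"), each = 4)
  net <- build_network(list(fit), labels, mode = "context_specific",
                       context = "u", r = 1)
  expect_true(all(c(net$edges$a, net$edges$b) %in% 1:4))
})
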