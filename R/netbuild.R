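#' @title Gene co-expression networks from fitted biclusters
#' @description
#' A fitted sparse factorization implies a regularized gene-by-gene
#' covariance `Omega_A = Lambda_A Sigma_AA Lambda_A^T + Psi` for any subset
#' `A` of components. Restricting to the genes loaded on `A`, inverting, and
#' transforming the precision matrix to partial correlations yields a
#' Gaussian graphical model. Components are selected by how their factor
#' rows relate to sample contexts (ubiquitous, context-specific, or
#' rank-differential), candidate edges are tested against an empirical-null
#' mixture, and edges are aggregated across independent restarts (bagging),
#' keeping those replicated in at least `r` runs.
#' @name netbuild
NULL

#' Run-level quality control
#'
#' A run is discarded when any pair of components is redundant in the sense
#' that the product of the loading-column correlation and the factor-row
#' correlation exceeds `redundancy_cutoff` (signed product; constant columns
#' count as correlation 0).
#'
#' @param fit A `"bc_fit"` object.
#' @param redundancy_cutoff Product-of-correlations threshold (default 0.5).
#' @return `TRUE` to keep the run, `FALSE` to discard it.
#' @export
qc_run <- function(fit, redundancy_cutoff = 0.5) {
  K <- ncol(fit$loading$Lambda)
  if (K < 2) return(TRUE)
  safe_cor <- function(M) {
    C <- suppressWarnings(stats::cor(M))
    C[!is.finite(C)] <- 0
    C
  }
  cl <- safe_cor(fit$loading$Lambda)
  cx <- safe_cor(t(fit$factor$X))
  prod <- cl * cx
  diag(prod) <- 0
  all(prod <= redundancy_cutoff)
}

#' Group components by support and flag redundant pairs
#'
#' Components (from any number of runs) are grouped by their pair of support
#' sizes (number of genes, number of samples with non-zero values); within a
#' group, two components are redundant when their supports are identical on
#' both sides (zero Manhattan distance between support indicators).
#'
#' @param components List where each element has `lambda` (loading vector)
#'   and `x` (factor vector); all loading vectors must share length, as must
#'   factor vectors.
#' @param threshold Non-zero cutoff (default `1e-10`).
#' @return List with `group` (integer group id per component) and
#'   `redundant_pairs` (two-column matrix of component indices).
#' @export
redundancy_groups <- function(components, threshold = 1e-10) {
  n <- length(components)
  supp <- lapply(components, function(cmp) {
    list(g = which(abs(cmp$lambda) > threshold),
         s = which(abs(cmp$x) > threshold))
  })
  sizes <- vapply(supp, function(s) c(length(s$g), length(s$s)), numeric(2))
  key <- paste(sizes[1, ], sizes[2, ])
  group <- as.integer(factor(key, levels = unique(key)))
  pairs <- matrix(integer(0), 0, 2)
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < 2) next
    for (i in seq_along(idx)[-length(idx)]) {
      for (j in seq(i + 1, length(idx))) {
        a <- supp[[idx[i]]]; b <- supp[[idx[j]]]
        if (identical(a$g, b$g) && identical(a$s, b$s)) {
          pairs <- rbind(pairs, c(idx[i], idx[j]))
        }
      }
    }
  }
  list(group = group, redundant_pairs = pairs)
}

#' Bonferroni threshold for differential component selection
#'
#' `alpha / n_components`; with the 53,814 components recovered across the
#' breast-cancer restarts this gives 9.29e-7.
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_components Total number of components tested.
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_components) {
  if (n_components < 1) stop("n_components must be >= 1")
  alpha / n_components
}

#' Select components for a network type
#'
#' * `ubiquitous`: factor row non-zero for every sample.
#' * `context_specific`: non-zero factor values occur only at samples
#'   carrying the given context label (and at least one of them).
#' * `differential`: two-sided rank-sum (Mann-Whitney) test of the factor
#'   values between the two label groups; selected when `p <= p_threshold`.
#'   The default threshold is the Bonferroni rule `0.05 / K`; a fixed
#'   `1e-10` preset matches the stricter variant.
#'
#' @param fit A `"bc_fit"` object.
#' @param labels Per-sample context labels (binary for the context and
#'   differential modes).
#' @param mode One of `"ubiquitous"`, `"context_specific"`, `"differential"`.
#' @param context The label value defining the context (context mode) or the
#'   first group (differential mode; defaults to the first level).
#' @param p_threshold Differential p-value cutoff; `NULL` (default) uses
#'   `bonferroni_threshold(0.05, K)`.
#' @param threshold Non-zero cutoff for factor support (default `1e-10`).
#' @return A `"component_selection"` list: `A` (selected indices), `mode`,
#'   `context`, `pvalues` (differential mode).
#' @export
select_components <- function(fit, labels = NULL,
                              mode = c("ubiquitous", "context_specific",
                                       "differential"),
                              context = NULL, p_threshold = NULL,
                              threshold = 1e-10) {
  mode <- match.arg(mode)
  X <- fit$factor$X
  K <- nrow(X); n <- ncol(X)
  nz <- abs(X) > threshold
  pvals <- NULL
  if (mode == "ubiquitous") {
    A <- which(rowSums(nz) == n)
  } else {
    if (is.null(labels) || length(labels) != n) {
      stop("per-sample labels are required for this mode")
    }
    labels <- as.character(labels)
    lev <- unique(labels)
    if (is.null(context)) context <- lev[1]
    if (mode == "context_specific") {
      inside <- labels == context
      A <- which(vapply(seq_len(K), function(k) {
        any(nz[k, inside]) && !any(nz[k, !inside])
      }, logical(1)))
    } else {
      if (length(lev) != 2) stop("differential mode needs exactly two label groups")
      g1 <- labels == context
      if (!any(g1) || all(g1)) stop("one label group is empty")
      if (is.null(p_threshold)) p_threshold <- bonferroni_threshold(0.05, K)
      pvals <- vapply(seq_len(K), function(k) {
        x1 <- X[k, g1]; x2 <- X[k, !g1]
        if (stats::sd(c(x1, x2)) == 0) return(1)
        suppressWarnings(stats::wilcox.test(x1, x2, exact = FALSE)$p.value)
      }, numeric(1))
      pvals[!is.finite(pvals)] <- 1
      A <- which(pvals <= p_threshold)
    }
  }
  structure(list(A = A, mode = mode, context = context,
                 pvalues = if (!is.null(pvals)) pvals[A] else NULL,
                 p_threshold = if (mode == "differential") p_threshold else NULL),
            class = "component_selection")
}

#' Gene covariance implied by a component subset
#'
#' `Omega_A = Lambda_A Sigma_AA Lambda_A^T + Psi`, restricted to the genes
#' with a non-zero loading in at least one selected component (the full gene
#' set is never inverted, so genes that never share a bicluster cannot gain
#' an edge).
#'
#' @param Lambda_A `p x |A|` loading submatrix.
#' @param Sigma_AA `|A| x |A|` factor covariance (e.g.
#'   `<XX^T> - <X><X>^T = SigmaX` restricted to `A`).
#' @param psi Length-`p` residual variances.
#' @param threshold Non-zero cutoff for the gene support (default `1e-10`).
#' @return List with `genes` (support indices) and `Omega` (covariance on
#'   the support); `genes` empty signals an empty network.
#' @export
component_covariance <- function(Lambda_A, Sigma_AA, psi, threshold = 1e-10) {
  Lambda_A <- as.matrix(Lambda_A)
  Sigma_AA <- as.matrix(Sigma_AA)
  genes <- which(apply(abs(Lambda_A) > threshold, 1, any))
  if (length(genes) == 0) return(list(genes = integer(0), Omega = NULL))
  L <- Lambda_A[genes, , drop = FALSE]
  Omega <- L %*% Sigma_AA %*% t(L) + diag(psi[genes], length(genes))
  list(genes = genes, Omega = Omega)
}

#' Partial correlations from a covariance matrix
#'
#' Inverts the covariance and maps the precision `delta_{jj'}` to
#' `-delta_{jj'} / sqrt(delta_jj delta_j'j')`; the diagonal is set to 1.
#'
#' @param Omega Symmetric positive-definite covariance matrix.
#' @return Symmetric matrix of partial correlations.
#' @export
partial_correlations <- function(Omega) {
  Omega <- as.matrix(Omega)
  Delta <- tryCatch(chol2inv(chol(Omega)), error = function(e) {
    stop("covariance numerically singular (condition number ~ ",
         format(kappa(Omega), digits = 3), "); cannot form partial correlations")
  })
  d <- sqrt(diag(Delta))
  P <- -Delta / tcrossprod(d)
  diag(P) <- 1
  P
}

#' Test edges against an empirical-null mixture
#'
#' Off-diagonal partial correlations are Fisher-transformed and modeled as a
#' two-component mixture `eta0 f0 + (1-eta0) f1`: a Gaussian null with scale
#' `sd0` (an effective-degrees-of-freedom parameter) and a flat alternative
#' on (-1, 1). `eta0` and `sd0` are fitted by EM; each pair's posterior
#' probability of coming from the alternative is returned and pairs above
#' `posterior_threshold` become edges. With fewer than 20 pairs the mixture
#' cannot be fitted and an absolute-threshold rule `|parcor| >= 0.8` is used
#' with a warning.
#'
#' @param parcor Symmetric partial-correlation matrix.
#' @param posterior_threshold Posterior probability cutoff (default 0.8).
#' @return Data frame with `a`, `b` (indices, `a < b`), `parcor`,
#'   `posterior` for the retained edges; attribute `"mixture"` carries the
#'   fitted `eta0`, `sd0`.
#' @export
test_edges <- function(parcor, posterior_threshold = 0.8) {
  P <- as.matrix(parcor)
  ut <- upper.tri(P)
  idx <- which(ut, arr.ind = TRUE)
  r <- P[ut]
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  if (posterior_threshold >= 1) {
    out <- data.frame(a = integer(0), b = integer(0),
                      parcor = numeric(0), posterior = numeric(0))
    return(out)
  }
  if (length(r) < 20) {
    warning("fewer than 20 gene pairs; falling back to |parcor| >= 0.8 rule")
    keep <- abs(r) >= 0.8
    out <- data.frame(a = idx[keep, 1], b = idx[keep, 2],
                      parcor = r[keep], posterior = as.numeric(keep[keep]))
    return(out[order(out$a, out$b), , drop = FALSE])
  }
  z <- atanh(r)
  sd0 <- max(stats::mad(z), 1e-3)
  eta0 <- 0.9
  f1 <- 0.5 * (1 - r^2)          # flat on r, transformed to the z scale
  for (it in 1:200) {
    f0 <- stats::dnorm(z, 0, sd0)
    w0 <- eta0 * f0 / (eta0 * f0 + (1 - eta0) * f1)
    w0[!is.finite(w0)] <- 1
    eta0_new <- max(min(mean(w0), 1 - 1e-6), 1e-6)
    sd0_new <- max(sqrt(sum(w0 * z^2) / sum(w0)), 1e-4)
    if (abs(eta0_new - eta0) < 1e-8 && abs(sd0_new - sd0) < 1e-8) {
      eta0 <- eta0_new; sd0 <- sd0_new
      break
    }
    eta0 <- eta0_new; sd0 <- sd0_new
  }
  f0 <- stats::dnorm(z, 0, sd0)
  post1 <- (1 - eta0) * f1 / (eta0 * f0 + (1 - eta0) * f1)
  keep <- post1 > posterior_threshold
  out <- data.frame(a = idx[keep, 1], b = idx[keep, 2],
                    parcor = r[keep], posterior = post1[keep])
  out <- out[order(out$a, out$b), , drop = FALSE]
  attr(out, "mixture") <- c(eta0 = eta0, sd0 = sd0)
  out
}

#' Aggregate edge sets across runs
#'
#' Counts each canonical (gene_a < gene_b) edge across the per-run edge
#' sets and keeps edges found in at least `r` runs.
#'
#' @param per_run_edge_sets List of data frames with columns `a`, `b` (and
#'   optionally `parcor`, `posterior`).
#' @param r Replication threshold (>= 1).
#' @return A `"gene_network"` list: `edges` (data frame `a`, `b`,
#'   `replication_count`, mean `parcor` and `posterior` across supporting
#'   runs), `nodes` (sorted endpoint indices), `n_runs`, `r`.
#' @export
aggregate_networks <- function(per_run_edge_sets, r = 1) {
  if (r < 1) stop("replication threshold must be >= 1")
  all_edges <- do.call(rbind, lapply(per_run_edge_sets, function(e) {
    if (is.null(e) || nrow(e) == 0) return(NULL)
    data.frame(a = pmin(e$a, e$b), b = pmax(e$a, e$b),
               parcor = if ("parcor" %in% names(e)) e$parcor else NA_real_,
               posterior = if ("posterior" %in% names(e)) e$posterior else NA_real_)
  }))
  if (is.null(all_edges) || nrow(all_edges) == 0) {
    edges <- data.frame(a = integer(0), b = integer(0),
                        replication_count = integer(0),
                        parcor = numeric(0), posterior = numeric(0))
  } else {
    key <- paste(all_edges$a, all_edges$b)
    cnt <- table(key)
    keep_keys <- names(cnt)[cnt >= r]
    sel <- all_edges[key %in% keep_keys, , drop = FALSE]
    sk <- paste(sel$a, sel$b)
    agg <- do.call(rbind, lapply(split(seq_len(nrow(sel)), sk), function(ii) {
      data.frame(a = sel$a[ii[1]], b = sel$b[ii[1]],
                 replication_count = length(ii),
                 parcor = mean(sel$parcor[ii]),
                 posterior = mean(sel$posterior[ii]))
    }))
    edges <- agg[order(agg$a, agg$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$a, edges$b))),
                 n_runs = length(per_run_edge_sets), r = r),
            class = "gene_network")
}

#' Expected number of edges replicated at least r times under the null
#'
#' With `R` independent runs each containing on average `e_hat` of `E`
#' possible edges chosen at random, an edge appears in a run with
#' probability `e_hat / E` and the number of runs containing it is
#' binomial. The expected count of edges appearing in `>= r` runs is
#' `E * Pr(Bin(R, e_hat/E) >= r)`. The corrected form computes the tail
#' with the complete complement sum (`j = 0, ..., r-1`); the printed
#' variant, which omits the `j = 0` term of the complement and can go
#' negative, is available for comparison.
#'
#' @param R Number of runs.
#' @param r Replication threshold (`1 <= r <= R`).
#' @param E Total number of possible edges.
#' @param e_hat Average number of edges per run (`0 <= e_hat <= E`).
#' @param corrected Use the complete complement sum (default `TRUE`).
#' @return Expected number of replicated edges.
#' @export
expected_replicated_edges <- function(R, r, E, e_hat, corrected = TRUE) {
  if (e_hat < 0 || e_hat > E) stop("need 0 <= e_hat <= E")
  if (r < 1 || r > R) stop("need 1 <= r <= R")
  pr <- e_hat / E
  jmin <- if (corrected) 0 else 1
  tail <- 1 - sum(stats::dbinom(jmin:(r - 1), R, pr))
  E * tail
}

#' Build a gene co-expression network from fitted runs
#'
#' End-to-end composition: per run, QC ([qc_run()]), component selection
#' ([select_components()]), support covariance ([component_covariance()]),
#' partial correlations, and edge testing ([test_edges()]); then ensemble
#' aggregation across runs ([aggregate_networks()]). Non-converged fits are
#' skipped unless `include_nonconverged`. Betweenness centrality per node is
#' attached as a report attribute.
#'
#' @param fits List of `"bc_fit"` objects (independent restarts).
#' @param labels Per-sample context labels (as in [select_components()]).
#' @param mode Network type passed to [select_components()].
#' @param context Context label (see [select_components()]).
#' @param r Replication threshold for the ensemble (default 1).
#' @param redundancy_cutoff QC threshold (default 0.5).
#' @param posterior_threshold Edge posterior cutoff (default 0.8).
#' @param p_threshold Differential p-value cutoff (default Bonferroni).
#' @param include_nonconverged Keep runs with `converged = FALSE` (default
#'   `FALSE`).
#' @return A `"gene_network"` (see [aggregate_networks()]) with a
#'   `betweenness` attribute (named numeric vector).
#' @export
build_network <- function(fits, labels = NULL, mode = "ubiquitous",
                          context = NULL, r = 1, redundancy_cutoff = 0.5,
                          posterior_threshold = 0.8, p_threshold = NULL,
                          include_nonconverged = FALSE) {
  edge_sets <- lapply(fits, function(fit) {
    if (!include_nonconverged && !isTRUE(fit$converged)) return(NULL)
    if (!qc_run(fit, redundancy_cutoff)) return(NULL)
    sel <- select_components(fit, labels, mode, context, p_threshold)
    if (length(sel$A) == 0) return(NULL)
    cc <- component_covariance(
      fit$loading$Lambda[, sel$A, drop = FALSE],
      fit$factor$SigmaX[sel$A, sel$A, drop = FALSE],
      fit$noise$psi)
    if (length(cc$genes) < 2) return(NULL)
    pc <- partial_correlations(cc$Omega)
    ed <- suppressWarnings(test_edges(pc, posterior_threshold))
    if (nrow(ed) == 0) return(NULL)
    ed$a <- cc$genes[ed$a]
    ed$b <- cc$genes[ed$b]
    ed
  })
  net <- aggregate_networks(edge_sets, r)
  if (nrow(net$edges) > 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = net$edges$a, to = net$edges$b), directed = FALSE)
    bw <- igraph::betweenness(g)
    attr(net, "betweenness") <- stats::setNames(as.numeric(bw),
                                                names(bw))
  } else {
    attr(net, "betweenness") <- stats::setNames(numeric(0), character(0))
  }
  net$mode <- mode
  net$context <- context
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene co-expression network (", x$mode %||% "?", "): ",
      length(x$nodes), " nodes, ", nrow(x$edges),
      " edges replicated >= ", x$r, " of ", x$n_runs, " runs\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
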