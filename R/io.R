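#' Load an expression matrix from TSV/CSV
#'
#' Expects a header row and identifiers in the first column. The canonical
#' orientation is genes in rows; `orientation = "samples"` transposes the
#' parsed matrix. `NA` tokens populate the missing mask.
#'
#' @param path File path (TSV or CSV; the separator is sniffed).
#' @param orientation `"genes"` (rows are genes, default) or `"samples"`.
#' @return An `"expression_matrix"` list: `values` (p x n), `gene_ids`,
#'   `sample_ids`, `missing_mask`.
#' @export
load_expression <- function(path, orientation = c("genes", "samples")) {
  orientation <- match.arg(orientation)
  dt <- data.table::fread(path, header = TRUE, sep = "auto",
                          na.strings = c("NA", "NaN", ""))
  ids <- as.character(dt[[1]])
  M <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric cells found in ", path)
  rownames(M) <- ids
  if (orientation == "samples") M <- t(M)
  if (anyDuplicated(rownames(M))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(M)[duplicated(rownames(M))])[1:3], collapse = ", "))
  }
  if (anyDuplicated(colnames(M))) {
    stop("duplicate sample identifiers")
  }
  structure(list(values = M, gene_ids = rownames(M),
                 sample_ids = colnames(M), missing_mask = is.na(M)),
            class = "expression_matrix")
}

#' Drop genes with too many missing values
#'
#' Removes genes whose fraction of missing entries strictly exceeds
#' `max_missing_fraction` (default 0.10, i.e. "> 10% missing").
#'
#' @param m An `"expression_matrix"`.
#' @param max_missing_fraction Highest tolerated missing fraction.
#' @return Filtered `"expression_matrix"`.
#' @export
filter_missing_genes <- function(m, max_missing_fraction = 0.10) {
  frac <- rowMeans(m$missing_mask)
  keep <- frac <= max_missing_fraction
  structure(list(values = m$values[keep, , drop = FALSE],
                 gene_ids = m$gene_ids[keep],
                 sample_ids = m$sample_ids,
                 missing_mask = m$missing_mask[keep, , drop = FALSE]),
            class = "expression_matrix")
}

#' Project each gene to standard-normal quantiles
#'
#' Per gene, values are replaced by `qnorm((rank - 0.5) / n)` with average
#' ranks for ties, preserving each row's rank order exactly and giving every
#' gene the same marginal distribution. Missing values must be removed or
#' imputed beforehand.
#'
#' @param m An `"expression_matrix"` with no missing values.
#' @return Quantile-normalized `"expression_matrix"`.
#' @export
quantile_normalize_to_normal <- function(m) {
  if (any(m$missing_mask)) {
    stop("missing values present; filter or impute before quantile normalization")
  }
  n <- ncol(m$values)
  vals <- t(apply(m$values, 1, function(x) {
    stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  }))
  dimnames(vals) <- dimnames(m$values)
  structure(list(values = vals, gene_ids = m$gene_ids,
                 sample_ids = m$sample_ids,
                 missing_mask = m$missing_mask),
            class = "expression_matrix")
}

# fixed formatting for deterministic TSV output
.fmt <- function(x) formatC(x, digits = 12, format = "g")

#' Write a fit to a directory of TSV files
#'
#' Layout: `Lambda.tsv` (genes x components, header = component ids),
#' `X.tsv` (components x samples), `SigmaX.tsv`, `z.tsv`, `o.tsv`,
#' `psi.tsv` (single-column), and `meta.json` (converged flag, seed,
#' thresholds, trace). Numbers are written with 12 significant digits, so
#' identical fits serialize bit-identically.
#'
#' @param fit A `"bc_fit"` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  K <- ncol(fit$loading$Lambda)
  comp_ids <- if (K > 0) paste0("comp", seq_len(K)) else character(0)
  wt <- function(M, file, col_names) {
    df <- as.data.frame(apply(M, c(1, 2), .fmt), stringsAsFactors = FALSE)
    colnames(df) <- col_names
    data.table::fwrite(df, file.path(dir, file), sep = "\t", quote = FALSE)
  }
  wt(fit$loading$Lambda, "Lambda.tsv", comp_ids)
  wt(fit$factor$X, "X.tsv", paste0("s", seq_len(ncol(fit$factor$X))))
  wt(fit$factor$SigmaX, "SigmaX.tsv", comp_ids)
  wv <- function(v, file) {
    writeLines(c(sub("\\.tsv$", "", file), .fmt(v)), file.path(dir, file))
  }
  wv(fit$loading$z, "z.tsv")
  wv(fit$factor$o, "o.tsv")
  wv(fit$noise$psi, "psi.tsv")
  meta <- list(converged = fit$converged, seed = fit$seed,
               K_init = fit$K_init, K = K,
               dense_threshold = fit$dense_threshold,
               sparsity_threshold = fit$sparsity_threshold,
               trace_iteration = fit$trace$iteration,
               trace_nonzero = fit$trace$nonzero_loadings)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a fit written by [write_fit()]
#'
#' Restores the matrices, indicators, noise variances and metadata needed by
#' the network-construction functions (the full shrinkage state is not
#' serialized).
#'
#' @param dir Directory created by [write_fit()].
#' @return A `"bc_fit"`-compatible list.
#' @export
read_fit <- function(dir) {
  rd <- function(file) {
    as.matrix(data.table::fread(file.path(dir, file), header = TRUE, sep = "\t"))
  }
  Lambda <- rd("Lambda.tsv")
  X <- rd("X.tsv")
  SigmaX <- rd("SigmaX.tsv")
  rv <- function(file) as.numeric(readLines(file.path(dir, file))[-1])
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  structure(list(
    loading = list(Lambda = Lambda, z = rv("z.tsv")),
    factor = list(X = X, SigmaX = SigmaX, o = rv("o.tsv")),
    noise = list(psi = rv("psi.tsv")),
    converged = isTRUE(meta$converged), seed = meta$seed,
    K_init = meta$K_init, dense_threshold = meta$dense_threshold,
    sparsity_threshold = meta$sparsity_threshold,
    trace = data.frame(iteration = meta$trace_iteration %||% integer(0),
                       nonzero_loadings = meta$trace_nonzero %||% integer(0))),
    class = "bc_fit")
}

#' Write a network's edge list as TSV (and optionally GraphML)
#'
#' Edge list columns: `gene_a`, `gene_b`, `parcor`, `posterior`,
#' `replication_count`. When `graphml` is given, the same network is written
#' in GraphML for network tools.
#'
#' @param net A `"gene_network"`.
#' @param path TSV output path.
#' @param graphml Optional GraphML output path.
#' @param gene_ids Optional identifier vector indexed by node id.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, graphml = NULL, gene_ids = NULL) {
  e <- net$edges
  name_of <- function(i) if (is.null(gene_ids)) as.character(i) else gene_ids[i]
  df <- data.frame(gene_a = name_of(e$a), gene_b = name_of(e$b),
                   parcor = .fmt(e$parcor), posterior = .fmt(e$posterior),
                   replication_count = e$replication_count)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::make_empty_graph(directed = FALSE)
    if (nrow(e) > 0) {
      g <- igraph::graph_from_data_frame(
        data.frame(from = name_of(e$a), to = name_of(e$b),
                   parcor = e$parcor, posterior = e$posterior,
                   replication_count = e$replication_count),
        directed = FALSE)
    }
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}
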