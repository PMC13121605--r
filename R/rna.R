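#' Normalize a count matrix
#'
#' Per-cell total-count scaling to the median library size, then
#' `log(1 + x)`. The raw matrix is never modified; re-running from raw is
#' bit-identical.
#'
#' @param counts Cells x genes matrix (dense or `Matrix` sparse) of
#'   non-negative integer counts.
#' @return Dense cells x genes matrix of log-normalized values. The target
#'   library size is attached as attribute `"target_sum"`.
#' @export
normalize_counts <- function(counts) {
  m <- as.matrix(counts)
  if (min(m) < 0) abort("counts must be non-negative")
  totals <- rowSums(m)
  if (any(totals == 0))
    warn(sprintf("%d cell(s) with zero total counts left all-zero",
                 sum(totals == 0)))
  target <- median(totals[totals > 0])
  scale <- ifelse(totals > 0, target / totals, 0)
  out <- log1p(m * scale)
  attr(out, "target_sum") <- target
  out
}

#' Binned-control gene-module score
#'
#' Per-cell score of a gene set relative to expression-matched controls:
#' all genes are binned by their dataset-mean normalized expression into
#' `n_bins` equal-size bins; for every module gene, `n_ctrl` control genes
#' are drawn (seeded) from the same bin; the score is the mean normalized
#' expression of the module genes minus the mean over the drawn control
#' genes. Under the null (module genes exchangeable with their bins) the
#' score is centered at zero.
#'
#' @param norm Normalized cells x genes matrix ([normalize_counts()]).
#' @param genes Character vector of module genes (case-sensitive); genes
#'   absent from the matrix are skipped with a warning.
#' @param n_bins Number of mean-expression bins.
#' @param n_ctrl Control genes drawn per module gene (capped at bin size;
#'   drawn without replacement within a bin).
#' @param seed Integer seed for the control draw.
#' @return Numeric per-cell score vector.
#' @export
module_score <- function(norm, genes, n_bins = 25, n_ctrl = 50, seed = 0) {
  all_genes <- colnames(norm)
  if (is.null(all_genes)) abort("`norm` must have gene column names")
  hit <- genes %in% all_genes
  if (!any(hit)) abort("no module gene matches the matrix")
  if (any(!hit))
    warn(paste0("module gene(s) absent, skipped: ",
                paste(genes[!hit], collapse = ", ")))
  genes <- genes[hit]
  gene_mean <- colMeans(norm)
  # equal-size bins by rank of mean expression
  bins <- dplyr::ntile(rank(gene_mean, ties.method = "first"), n_bins)
  names(bins) <- all_genes
  ctrl <- withr::with_seed(seed, {
    unlist(lapply(genes, function(g) {
      pool <- all_genes[bins == bins[[g]]]
      pool <- setdiff(pool, g)
      if (!length(pool)) return(character())
      sample(pool, size = min(n_ctrl, length(pool)))
    }), use.names = FALSE)
  })
  if (!length(ctrl)) abort("no control genes available")
  rowMeans(norm[, genes, drop = FALSE]) - rowMeans(norm[, ctrl, drop = FALSE])
}

#' Rank-based marker statistics between two cell groups
#'
#' For each gene: `log2FC = log2((mean(expm1(A)) + eps) / (mean(expm1(B)) +
#' eps))` on the normalized scale, the Wilcoxon rank-sum p-value on
#' normalized values, and BH-adjusted p-values across the tested genes.
#'
#' @param norm Normalized cells x genes matrix.
#' @param cells_a,cells_b Row indices (or logical masks) of the two groups.
#' @param genes Genes to test (default: all). A named gene absent from the
#'   matrix is an error.
#' @param eps Pseudocount guarding the ratio.
#' @return Tibble with `gene`, `log2_fc`, `p_value`, `p_adj`, sorted by
#'   decreasing `log2_fc`.
#' @export
rank_markers <- function(norm, cells_a, cells_b, genes = NULL, eps = 1e-9) {
  genes <- genes %||% colnames(norm)
  missing <- setdiff(genes, colnames(norm))
  if (length(missing))
    abort(paste0("gene(s) not in matrix: ", paste(missing, collapse = ", ")))
  a <- norm[cells_a, genes, drop = FALSE]
  b <- norm[cells_b, genes, drop = FALSE]
  lfc <- log2((colMeans(expm1(a)) + eps) / (colMeans(expm1(b)) + eps))
  p <- vapply(seq_along(genes), function(j) {
    suppressWarnings(wilcox.test(a[, j], b[, j])$p.value)
  }, 0.0)
  p[is.nan(p)] <- 1  # all values tied across both groups
  out <- tibble(gene = genes, log2_fc = unname(lfc), p_value = p,
                p_adj = bh_adjust(p))
  dplyr::arrange(out, dplyr::desc(.data$log2_fc))
}

#' Compare module scores between two clusters
#'
#' Two-sided Welch t-test on per-cell module scores of two clusters.
#'
#' @param scores Per-cell score vector ([module_score()]).
#' @param labels Cluster label per cell.
#' @param cluster_a,cluster_b Labels to compare.
#' @return An `imc_test` (see [run_test()]).
#' @export
score_compare <- function(scores, labels, cluster_a, cluster_b) {
  run_test(scores[labels == cluster_a], scores[labels == cluster_b],
           test = "t_two_sample", alternative = "two_sided")
}

#' Read / write a cells x genes count matrix in MatrixMarket format
#'
#' `path` is the `.mtx` file; gene and cell names are stored alongside as
#' `<stem>.genes.txt` and `<stem>.cells.txt` (one name per line).
#'
#' @param counts Cells x genes matrix.
#' @param path `.mtx` path.
#' @return `write_counts_mtx`: the path, invisibly; `read_counts_mtx`: a
#'   dense cells x genes matrix with dimnames.
#' @export
write_counts_mtx <- function(counts, path) {
  stem <- sub("\\.mtx$", "", path)
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE), path)
  writeLines(colnames(counts), paste0(stem, ".genes.txt"))
  writeLines(rownames(counts) %||% as.character(seq_len(nrow(counts))),
             paste0(stem, ".cells.txt"))
  invisible(path)
}

#' @rdname write_counts_mtx
#' @param path `.mtx` path written by `write_counts_mtx`.
#' @export
read_counts_mtx <- function(path) {
  stem <- sub("\\.mtx$", "", path)
  m <- as.matrix(Matrix::readMM(path))
  colnames(m) <- readLines(paste0(stem, ".genes.txt"))
  rownames(m) <- readLines(paste0(stem, ".cells.txt"))
  m
}
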