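#' Pairwise Pearson correlation between U-stretch-length columns
#'
#' Correlates every pair of the 17 U-stretch-length columns across genes of a
#' normalized U-count matrix.  Genuine tagging produces U stretches of
#' different lengths on the same set of genes, so the 4-13 block of this
#' matrix is highly correlated for a working sample and flat for a dead-enzyme
#' control; that contrast is the basis of the tagging-reliability QC.
#'
#' @param mat a normalized [ucount_matrix()] with at least 3 genes.
#' @return A 17x17 symmetric correlation matrix (dimnames `u0`..`u16`);
#'   zero-variance columns yield `NA` entries.
#' @export
stretch_correlations <- function(mat) {
  stopifnot_normalized(mat)
  if (nrow(mat) < 3) stop("need at least 3 genes to correlate U stretches")
  suppressWarnings(stats::cor(unclass(mat)))
}

#' Median tagging reliability of a sample
#'
#' For each U-stretch length in 4..13, takes the best Pearson correlation with
#' any *other* stretch in the 4..13 block (self excluded, missing entries
#' skipped), and returns the ten per-stretch values and their median.  High
#' values mean long U stretches co-occur on the same genes — the signature of
#' genuine enzymatic tagging rather than sequencing error.
#'
#' @param cor_matrix a 17x17 correlation matrix from [stretch_correlations()].
#' @return List with `per_stretch` (named numeric, u4..u13) and `median`.
#' @export
median_reliability <- function(cor_matrix) {
  stopifnot(is.matrix(cor_matrix), all(dim(cor_matrix) == c(17L, 17L)))
  block <- 5:14  # columns u4..u13
  best <- vapply(seq_along(block), function(i) {
    r <- cor_matrix[block[i], block[-i]]
    if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }, numeric(1))
  names(best) <- paste0("u", 4:13)
  if (all(is.na(best)))
    stop("reliability undefined: no correlations available in the 4..13 block")
  list(per_stretch = best, median = stats::median(best, na.rm = TRUE))
}

#' Per-gene expression from a U-count matrix
#'
#' Expression of a gene is the sum of its RPM over all U-stretch lengths
#' 0..16, i.e. its total 3'-end read abundance; expression sums to one
#' million over genes.
#'
#' @param mat a normalized [ucount_matrix()].
#' @return Named numeric vector of per-gene expression.
#' @export
expression_vector <- function(mat) {
  stopifnot_normalized(mat)
  rowSums(unclass(mat))
}

#' Per-gene binding score
#'
#' The binding score is the length-weighted sum of U counts over stretch
#' lengths 4..13: `bs(gene) = sum_{u=4}^{13} u * RPM(u, gene)`, i.e. the
#' total number of enzymatically added uridines associated with the gene.
#' Short stretches (1-3, dominated by sequencing error) and over-long
#' stretches (14-16) contribute nothing.
#'
#' @param mat a normalized [ucount_matrix()].
#' @return Named numeric vector of per-gene binding scores.
#' @export
binding_score <- function(mat) {
  stopifnot_normalized(mat)
  bs <- as.numeric(unclass(mat)[, 5:14, drop = FALSE] %*% (4:13))
  names(bs) <- rownames(mat)
  bs
}

#' Per-gene modification level
#'
#' The modification level is the ratio of binding score to expression, the
#' average number of enzymatically added uridines per transcript molecule.
#' Genes with zero expression are undefined (`NA`) and excluded downstream.
#'
#' @param bs,expr aligned per-gene binding-score and expression vectors.
#' @return Named numeric vector `bs/expr`, `NA` where `expr == 0`.
#' @export
modification_level <- function(bs, expr) {
  if (length(bs) != length(expr))
    stop("binding score and expression vectors differ in length")
  m <- ifelse(expr > 0, bs / expr, NA_real_)
  names(m) <- names(bs)
  m
}

#' Correlation of each U-stretch-length column with expression
#'
#' Across genes, correlates each of the 17 columns with total expression.
#' Error-driven short stretches (1-3) track expression tightly; genuine tails
#' (4-13) do not, because they follow target identity instead.
#'
#' @param mat a normalized [ucount_matrix()] with at least 3 genes.
#' @return Named numeric vector of length 17 (`NA` for zero-variance columns).
#' @export
expression_correlation <- function(mat) {
  stopifnot_normalized(mat)
  if (nrow(mat) < 3) stop("need at least 3 genes")
  expr <- rowSums(unclass(mat))
  r <- suppressWarnings(as.numeric(stats::cor(unclass(mat), expr)))
  names(r) <- u_colnames()
  r
}

#' Full binding profile of a sample
#'
#' Convenience wrapper computing expression, binding score, modification level
#' and its log2 transform for every gene.  Raw input is RPM-normalized first.
#'
#' @param mat a [ucount_matrix()] (raw or normalized).
#' @return A data.frame with columns `gene_id`, `exp`, `bs`, `m`, `log2_m`
#'   (`NA` where undefined).
#' @export
binding_profile <- function(mat) {
  mat <- normalize_rpm(mat)
  expr <- expression_vector(mat)
  bs <- binding_score(mat)
  m <- modification_level(bs, expr)
  data.frame(gene_id = rownames(mat), exp = expr, bs = bs, m = m,
             log2_m = ifelse(!is.na(m) & m > 0, log2(m), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call targets from modification levels
#'
#' A gene is a target when its modification level exceeds (strictly) the
#' background threshold derived from the dead-enzyme control: -2.7 on the
#' log2 scale (`2^-2.7 = 0.1539` linear).  Genes with zero or undefined
#' modification level are never targets.
#'
#' @param m named numeric vector of modification levels, or a
#'   [binding_profile()] data.frame.
#' @param threshold_log2 log2-scale threshold; ignored when
#'   `threshold_linear` is given.
#' @param threshold_linear optional linear-scale threshold (`m >
#'   threshold_linear`); equivalent to `threshold_log2 = log2(threshold_linear)`.
#' @param sample_id label stored on the result.
#' @return An object of class `target_set`: list with `gene_ids` (members),
#'   `m` (members' modification levels), `threshold_log2`, `threshold_linear`
#'   and `sample_id`.
#' @export
call_targets <- function(m, threshold_log2 = -2.7, threshold_linear = NULL,
                         sample_id = "sample") {
  if (is.data.frame(m)) m <- stats::setNames(m$m, m$gene_id)
  if (is.null(names(m))) stop("modification levels must be named by gene_id")
  if (!is.null(threshold_linear)) threshold_log2 <- log2(threshold_linear)
  defined <- !is.na(m) & m > 0
  member <- defined
  member[defined] <- log2(m[defined]) > threshold_log2  # strict
  structure(list(gene_ids = names(m)[member],
                 m = m[member],
                 threshold_log2 = threshold_log2,
                 threshold_linear = 2^threshold_log2,
                 sample_id = sample_id),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("target_set '%s': %d targets (m > %.4f, log2 m > %.2f)\n",
              x$sample_id, length(x$gene_ids), x$threshold_linear,
              x$threshold_log2))
  invisible(x)
}

target_ids <- function(x) {
  if (inherits(x, "target_set")) x$gene_ids else as.character(x)
}
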