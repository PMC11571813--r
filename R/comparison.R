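#' Correlate the binding profiles of two samples
#'
#' Pearson correlation of log2 modification level across genes, typically a
#' deletion mutant against the wild type.  By default only genes with `m > 0`
#' in both samples enter (log2 of zero is undefined); alternatively a
#' pseudocount can be added so all co-expressed genes are used.
#'
#' @param profile_a,profile_b [binding_profile()] data.frames sharing a gene
#'   universe.
#' @param pseudocount if `> 0`, correlate `log2(m + pseudocount)` over genes
#'   with defined `m` in both samples instead of restricting to `m > 0`.
#' @return List with `r` (Pearson correlation) and `n` (genes used).
#' @export
profile_correlation <- function(profile_a, profile_b, pseudocount = 0) {
  common <- intersect(profile_a$gene_id, profile_b$gene_id)
  ma <- profile_a$m[match(common, profile_a$gene_id)]
  mb <- profile_b$m[match(common, profile_b$gene_id)]
  if (pseudocount > 0) {
    keep <- !is.na(ma) & !is.na(mb)
    xa <- log2(ma[keep] + pseudocount)
    xb <- log2(mb[keep] + pseudocount)
  } else {
    keep <- !is.na(ma) & !is.na(mb) & ma > 0 & mb > 0
    xa <- log2(ma[keep])
    xb <- log2(mb[keep])
  }
  if (sum(keep) < 3)
    stop("fewer than 3 genes with defined modification level in both samples")
  list(r = stats::cor(xa, xb), n = sum(keep))
}

#' Classify mutant targets as retained ("old") or gained ("new")
#'
#' Set algebra between a mutant's and the wild type's target sets:
#' `n_old = |mut & wt|`, `n_new = |mut \ wt|`, `n_lost = |wt \ mut|`, so
#' `n_old + n_new` is the mutant target count and `n_old + n_lost` the WT
#' count.
#'
#' @param targets_mut,targets_wt [call_targets()] results or character
#'   vectors of gene ids.
#' @return List with counts `n_old`, `n_new`, `n_lost` and the corresponding
#'   gene-id vectors `old`, `new`, `lost`.
#' @export
classify_old_new <- function(targets_mut, targets_wt) {
  mut <- unique(target_ids(targets_mut))
  wt <- unique(target_ids(targets_wt))
  old <- intersect(mut, wt)
  new <- setdiff(mut, wt)
  lost <- setdiff(wt, mut)
  list(n_old = length(old), n_new = length(new), n_lost = length(lost),
       old = old, new = new, lost = lost)
}

#' Significance of the overlap between two target sets
#'
#' Upper-tail hypergeometric test of `|A & B|` given `|A|`, `|B|` and a
#' shared background, e.g. whether two deletion strains lose overlapping
#' target sets.
#'
#' @param set_a,set_b target sets (character vectors or [call_targets()]
#'   results), both subsets of `background`.
#' @param background the shared gene universe.
#' @return The hypergeometric p-value.
#' @export
overlap_significance <- function(set_a, set_b, background) {
  a <- unique(target_ids(set_a))
  b <- unique(target_ids(set_b))
  background <- unique(as.character(background))
  if (length(setdiff(a, background)) || length(setdiff(b, background)))
    stop("both sets must be subsets of the background")
  hyper_pvalue(length(intersect(a, b)), length(a), length(b),
               length(background))
}
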