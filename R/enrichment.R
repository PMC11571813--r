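#' Upper-tail hypergeometric p-value
#'
#' Probability of observing `k` or more successes when drawing `n` items
#' without replacement from a population of `N` containing `K` successes:
#' `P(X >= k) = 1 - CDF(k - 1)`.  Vectorized over all arguments.
#'
#' @param k observed overlap.
#' @param K number of successes in the population (term size in background).
#' @param n number of draws (targets in background).
#' @param N population size (background).
#' @return p-value(s) in `(0, 1]`.
#' @export
hyper_pvalue <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | K > N | n > N | k > pmin(K, n)
  if (any(bad)) stop("inconsistent hypergeometric counts")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set enrichment of a target set by the hypergeometric test
#'
#' Tests each gene set for over-representation among targets against the
#' expressed-gene background.  Targets outside the background are dropped
#' with a warning; set members outside the background do not count.  Results
#' are ordered by p-value, ties broken by term name, so the output is
#' deterministic.
#'
#' @param targets character vector (or [call_targets()] result) of target
#'   gene ids.
#' @param background character vector of expressed genes (the gene universe).
#' @param collection named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param alpha significance level for the `significant` flag (raw p-values
#'   are compared; see `adjust`).
#' @param adjust if `TRUE`, adds a Benjamini-Hochberg `q` column and flags
#'   significance on `q` instead of `p`.
#' @return A data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`
#'   (optionally `q`) and `significant`; terms with no member in the
#'   background are excluded.
#' @export
enrich <- function(targets, background, collection, alpha = 0.05,
                   adjust = FALSE) {
  targets <- unique(target_ids(targets))
  background <- unique(as.character(background))
  if (!length(background)) stop("empty background")
  outside <- setdiff(targets, background)
  if (length(outside)) {
    warning(length(outside), " target(s) outside the background were dropped")
    targets <- intersect(targets, background)
  }
  n <- length(targets)
  N <- length(background)
  rows <- lapply(names(collection), function(term) {
    members <- intersect(unique(collection[[term]]), background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(targets, members))
    data.frame(term = term, k = k, K = K, n = n, N = N,
               p = hyper_pvalue(k, K, n, N), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      significant = logical()))
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  if (adjust) {
    res$q <- stats::p.adjust(res$p, method = "BH")
    res$significant <- res$q < alpha
  } else {
    res$significant <- res$p < alpha
  }
  res
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (tab-separated: set name, description, member genes).
#' @return Named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write enrichment results as TSV
#'
#' @param results data.frame from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
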