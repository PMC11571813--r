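#' Gene-by-U-stretch-length count matrices
#'
#' The central object of the tagging pipeline is a matrix of read counts with
#' one row per gene and 17 columns `u0` ... `u16`, giving the number of reads
#' whose post-poly(A) U stretch had the given length (stretches longer than 16
#' are binned at 16).  Raw matrices hold integer read counts; normalized
#' matrices hold reads-per-million (RPM), i.e. the matrix total is scaled to
#' one million.
#'
#' @param counts numeric matrix with 17 columns (`u0`..`u16`) and one row per
#'   gene; rownames are gene identifiers.
#' @param sample_id character scalar naming the sample.
#' @param enzyme_active logical; `FALSE` marks a catalytically-dead-enzyme
#'   control sample.
#' @param normalized logical; `TRUE` if the matrix is RPM-scaled.
#' @param total_reads raw read total before any normalization.  Defaults to
#'   `sum(counts)` for raw matrices.
#'
#' @return An object of class `ucount_matrix`: the numeric matrix with
#'   attributes `sample_id`, `enzyme_active`, `normalized` and `total_reads`.
#' @seealso [normalize_rpm()], [binding_profile()], [read_ucount_matrix()]
#' @export
ucount_matrix <- function(counts, sample_id = "sample", enzyme_active = TRUE,
                          normalized = FALSE, total_reads = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 17L)
    stop("a U-count matrix must have 17 columns (u0..u16), got ", ncol(counts))
  if (is.null(rownames(counts)))
    stop("U-count matrix rows must be named by gene_id")
  if (any(counts < 0) || anyNA(counts))
    stop("U-count matrix entries must be non-negative and non-missing")
  if (!normalized && any(counts != round(counts)))
    stop("raw U-count matrix entries must be integers")
  colnames(counts) <- u_colnames()
  if (is.null(total_reads)) {
    if (normalized)
      stop("total_reads must be supplied for a normalized matrix")
    total_reads <- sum(counts)
  }
  structure(counts,
            class = c("ucount_matrix", "matrix", "array"),
            sample_id = sample_id,
            enzyme_active = isTRUE(enzyme_active),
            normalized = isTRUE(normalized),
            total_reads = as.numeric(total_reads))
}

u_colnames <- function() paste0("u", 0:16)

#' @export
print.ucount_matrix <- function(x, ...) {
  cat(sprintf("ucount_matrix: %d genes x 17 U-stretch lengths (u0..u16)\n",
              nrow(x)))
  cat(sprintf("  sample_id: %s | enzyme_active: %s | %s | total_reads: %s\n",
              attr(x, "sample_id"), attr(x, "enzyme_active"),
              if (attr(x, "normalized")) "RPM-normalized" else "raw counts",
              format(attr(x, "total_reads"), big.mark = ",",
                     scientific = FALSE)))
  invisible(x)
}

is_normalized <- function(mat) isTRUE(attr(mat, "normalized"))

stopifnot_normalized <- function(mat) {
  if (!inherits(mat, "ucount_matrix"))
    stop("expected a ucount_matrix")
  if (!is_normalized(mat))
    stop("expected an RPM-normalized matrix; call normalize_rpm() first")
  invisible(mat)
}

#' Scale a U-count matrix to reads per million
#'
#' Every entry is multiplied by `10^6 / total` so the matrix total becomes one
#' million counts.  Normalization is idempotent: a matrix already flagged as
#' normalized is returned unchanged.
#'
#' @param mat a [ucount_matrix()].
#' @return The RPM-normalized `ucount_matrix`.
#' @export
normalize_rpm <- function(mat) {
  if (!inherits(mat, "ucount_matrix")) stop("expected a ucount_matrix")
  if (is_normalized(mat)) return(mat)
  total <- sum(mat)
  if (total <= 0) stop("cannot normalize a matrix with zero total counts")
  ucount_matrix(unclass(mat) * (1e6 / total),
                sample_id = attr(mat, "sample_id"),
                enzyme_active = attr(mat, "enzyme_active"),
                normalized = TRUE,
                total_reads = attr(mat, "total_reads"))
}

#' Write / read a U-count matrix as TSV with a JSON metadata sidecar
#'
#' The TSV has a `gene_id` column followed by the 17 count columns `u0`..`u16`.
#' Sample metadata (`sample_id`, `enzyme_active`, `normalized`, `total_reads`)
#' travels in `<path>.meta.json`.
#'
#' @param mat a [ucount_matrix()].
#' @param path output TSV path.
#' @return `write_ucount_matrix` returns `path` invisibly;
#'   `read_ucount_matrix` returns the `ucount_matrix`.
#' @export
write_ucount_matrix <- function(mat, path) {
  if (!inherits(mat, "ucount_matrix")) stop("expected a ucount_matrix")
  df <- data.frame(gene_id = rownames(mat), unclass(mat),
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(sample_id = attr(mat, "sample_id"),
               enzyme_active = attr(mat, "enzyme_active"),
               normalized = attr(mat, "normalized"),
               total_reads = attr(mat, "total_reads"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ucount_matrix
#' @export
read_ucount_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (!identical(colnames(df), c("gene_id", u_colnames())))
    stop("malformed U-count matrix TSV: ", path)
  m <- as.matrix(df[, u_colnames()])
  rownames(m) <- df$gene_id
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(sample_id = basename(path), enzyme_active = TRUE,
         normalized = FALSE, total_reads = sum(m))
  }
  ucount_matrix(m, sample_id = meta$sample_id,
                enzyme_active = meta$enzyme_active,
                normalized = meta$normalized,
                total_reads = meta$total_reads)
}
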