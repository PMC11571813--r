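#' Orient a read-2 sequence to the sense strand
#'
#' In 3'-end tagging libraries read 2 is sequenced from the 3' adapter, so its
#' sequence is the reverse complement of the transcript's sense 3' end.  This
#' returns the reverse complement (an involution: applying it twice restores
#' the input).
#'
#' @param seqs character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of sense-oriented sequences.
#' @export
orient_tail <- function(seqs) {
  if (any(!nzchar(seqs))) stop("empty sequence")
  if (any(grepl("[^ACGTN]", seqs)))
    stop("non-DNA characters in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Count post-poly(A) uridines in a sense-oriented 3' sequence
#'
#' Locates the last A-run of length `>= min_polya_run` (the poly(A) tail) and
#' returns the length of the contiguous T-run (poly(U) in the RNA) that starts
#' immediately after it, capped at `cap`.  Reads without a qualifying poly(A)
#' run are rejected and reported as `NA` (reason `"no_polya"`).
#'
#' @param seqs character vector of sense-oriented sequences (poly(A) appears
#'   as an A-run, poly(U) as the T-run following it).
#' @param min_polya_run minimum A-run length that qualifies as a poly(A) tail.
#' @param cap longest stretch recorded; longer runs are binned at `cap`.
#' @return Integer vector of U counts in `0..cap`, `NA` for rejected reads.
#' @export
count_post_polya_us <- function(seqs, min_polya_run = 5, cap = 16) {
  if (any(!nzchar(seqs))) stop("empty sequence")
  if (min_polya_run < 1) stop("min_polya_run must be >= 1")
  pat <- sprintf("A{%d,}", min_polya_run)
  hits <- gregexpr(pat, seqs)
  vapply(seq_along(seqs), function(i) {
    h <- hits[[i]]
    if (h[1] == -1L) return(NA_integer_)
    last <- length(h)
    after <- h[last] + attr(h, "match.length")[last]
    rest <- substr(seqs[i], after, nchar(seqs[i]))
    t_run <- regexpr("^T+", rest)
    u <- if (t_run == -1L) 0L else attr(t_run, "match.length")
    min(u, as.integer(cap))
  }, integer(1))
}

#' Gene annotations with strand-aware TTS counting windows
#'
#' Builds the per-gene sense counting window `[TTS-300, TTS+100)` (coordinates
#' 0-based half-open along the direction of transcription) used to assign
#' 3'-end reads to genes.
#'
#' @param gene_id,chrom,strand,tts equal-length vectors; `tts` is the 0-based
#'   transcription-termination-site coordinate and `strand` is `"+"`/`"-"`.
#' @param upstream,downstream window extent upstream/downstream of the TTS.
#' @return A data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, strand, tts,
                            upstream = 300L, downstream = 100L) {
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(tts < 0)) stop("TTS coordinates must be non-negative")
  if (anyDuplicated(gene_id)) stop("duplicated gene_id in annotation")
  structure(data.frame(gene_id = as.character(gene_id),
                       chrom = as.character(chrom),
                       strand = as.character(strand),
                       tts = as.integer(tts),
                       stringsAsFactors = FALSE),
            upstream = as.integer(upstream),
            downstream = as.integer(downstream),
            class = c("gene_annotation", "data.frame"))
}

# genomic (strand-resolved) windows as GRanges, 1-based inclusive
annotation_windows <- function(ann) {
  up <- attr(ann, "upstream"); dn <- attr(ann, "downstream")
  plus <- ann$strand == "+"
  start1 <- ifelse(plus, ann$tts - up + 1L, ann$tts - dn + 2L)
  end1   <- ifelse(plus, ann$tts + dn,      ann$tts + up + 1L)
  GenomicRanges::GRanges(ann$chrom,
                         IRanges::IRanges(pmax(start1, 1L), end1),
                         strand = ann$strand)
}

#' Assign reads to genes by their TTS counting window
#'
#' A read is assigned to the gene whose sense window `[TTS-300, TTS+100)`
#' (along the direction of transcription) contains its position on the same
#' strand; antisense and out-of-window reads get `NA`.  When windows of
#' several genes overlap, the gene with the nearest TTS wins; exact distance
#' ties go to the lexicographically smaller `gene_id`.
#'
#' @param chrom,pos,strand equal-length vectors describing read alignments
#'   (`pos` 0-based).
#' @param annotations a [gene_annotation()].
#' @return Character vector of gene ids (`NA` for unassigned reads).
#' @export
assign_to_gene <- function(chrom, pos, strand, annotations) {
  stopifnot(inherits(annotations, "gene_annotation"))
  if (!all(chrom %in% annotations$chrom))
    stop("read on chromosome absent from the annotation: ",
         paste(unique(setdiff(chrom, annotations$chrom)), collapse = ", "))
  win <- annotation_windows(annotations)
  reads <- GenomicRanges::GRanges(chrom,
                                  IRanges::IRanges(pos + 1L, width = 1L),
                                  strand = strand)
  hits <- GenomicRanges::findOverlaps(reads, win, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  out <- rep(NA_character_, length(pos))
  if (length(q)) {
    dist <- abs(pos[q] - annotations$tts[s])
    gid <- annotations$gene_id[s]
    ord <- order(q, dist, gid)
    keep <- ord[!duplicated(q[ord])]
    out[q[keep]] <- gid[keep]
  }
  out
}

#' Collapse duplicate reads by (gene, UMI)
#'
#' Keeps one record per `(gene_id, umi)` key: the one with the largest
#' `u_count` (ties resolved to the first encountered).  Records without a gene
#' assignment pass through untouched.
#'
#' @param records data.frame with columns `gene_id`, `umi`, `u_count`.
#' @return The deduplicated data.frame.
#' @export
dedup_umis <- function(records) {
  stopifnot(all(c("gene_id", "umi", "u_count") %in% colnames(records)))
  assigned <- !is.na(records$gene_id)
  rec <- records[assigned, , drop = FALSE]
  if (nrow(rec)) {
    key <- paste(rec$gene_id, rec$umi, sep = "\r")
    ord <- order(key, -rec$u_count, seq_len(nrow(rec)))
    keep <- ord[!duplicated(key[ord])]
    rec <- rec[sort(keep), , drop = FALSE]
  }
  out <- rbind(rec, records[!assigned, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Tabulate assigned reads into a raw U-count matrix
#'
#' @param records deduplicated, gene-assigned read records (columns `gene_id`,
#'   `u_count`); unassigned or rejected (`NA`) records are dropped.
#' @param annotations a [gene_annotation()]; every annotated gene appears as a
#'   row even with zero counts.
#' @param sample_id,enzyme_active metadata stored on the matrix.
#' @return A raw [ucount_matrix()] whose total equals the number of assigned,
#'   deduplicated records.
#' @export
build_matrix <- function(records, annotations, sample_id = "sample",
                         enzyme_active = TRUE) {
  stopifnot(inherits(annotations, "gene_annotation"))
  ok <- !is.na(records$gene_id) & !is.na(records$u_count)
  rec <- records[ok, , drop = FALSE]
  counts <- table(factor(rec$gene_id, levels = annotations$gene_id),
                  factor(pmin(rec$u_count, 16L), levels = 0:16))
  m <- matrix(as.integer(counts), nrow = nrow(annotations), ncol = 17L,
              dimnames = list(annotations$gene_id, u_colnames()))
  ucount_matrix(m, sample_id = sample_id, enzyme_active = enzyme_active)
}

#' Quantify a tagging sample from reads into a raw U-count matrix
#'
#' End-to-end read processing: extract the UMI and tail from each read-2
#' sequence (or take pre-extracted sense tails from a read table), orient to
#' the sense strand, count post-poly(A) Us, assign reads to TTS windows,
#' deduplicate by (gene, UMI), and tabulate.
#'
#' @param fastq2 path to the read-2 FASTQ (each read: UMI prefix followed by
#'   the reverse-complemented 3' fragment).  Mutually exclusive with
#'   `read_table`.
#' @param alignment_table path to (or data.frame of) read alignments with
#'   columns `read_id`, `umi`, `chrom`, `pos`, `strand` (and `tail_seq` when
#'   used as `read_table`).
#' @param read_table path/data.frame with pre-extracted sense tails
#'   (`tail_seq` column) instead of FASTQ input.
#' @param annotations a [gene_annotation()].
#' @param umi_len length of the UMI prefix on read 2.
#' @param min_polya_run,cap see [count_post_polya_us()].
#' @param sample_id,enzyme_active metadata stored on the matrix.
#' @return A raw [ucount_matrix()].
#' @export
count_tagging_reads <- function(fastq2 = NULL, alignment_table = NULL,
                                read_table = NULL, annotations,
                                umi_len = 8L, min_polya_run = 5, cap = 16,
                                sample_id = "sample", enzyme_active = TRUE) {
  if (is.character(alignment_table))
    alignment_table <- utils::read.delim(alignment_table,
                                         stringsAsFactors = FALSE)
  if (!is.null(fastq2)) {
    seqs <- read_fastq(fastq2)
    aln <- alignment_table[match(names(seqs), alignment_table$read_id), ]
    umi <- substr(seqs, 1L, umi_len)
    sense <- orient_tail(substr(seqs, umi_len + 1L, nchar(seqs)))
    u <- count_post_polya_us(sense, min_polya_run, cap)
  } else if (!is.null(read_table)) {
    if (is.character(read_table))
      read_table <- utils::read.delim(read_table, stringsAsFactors = FALSE)
    aln <- read_table
    umi <- aln$umi
    u <- count_post_polya_us(aln$tail_seq, min_polya_run, cap)
  } else stop("supply either fastq2 + alignment_table or read_table")
  gene <- assign_to_gene(aln$chrom, aln$pos, aln$strand, annotations)
  records <- data.frame(gene_id = gene, umi = umi, u_count = u,
                        stringsAsFactors = FALSE)
  records <- dedup_umis(records)
  build_matrix(records, annotations, sample_id = sample_id,
               enzyme_active = enzyme_active)
}

#' Combine replicate U-count matrices after quality control
#'
#' A replicate passes QC when its raw read total exceeds `min_reads` or its
#' median tagging reliability (see [median_reliability()]) reaches
#' `min_reliability`.  Passing replicates are RPM-normalized, averaged
#' entry-wise, and the average is re-normalized to one million counts.
#'
#' @param matrices list of [ucount_matrix()] objects sharing the same gene
#'   rows.
#' @param min_reads raw-read-total threshold (a replicate passes with
#'   strictly more reads).
#' @param min_reliability median-reliability threshold (the assay's replicate
#'   quality score; passed with `reliability >= min_reliability`).
#' @return The merged, normalized [ucount_matrix()].
#' @export
merge_replicates <- function(matrices, min_reads = 200000,
                             min_reliability = 0.8) {
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, logical(1), "ucount_matrix")))
  genes <- rownames(matrices[[1]])
  if (!all(vapply(matrices, function(m) identical(rownames(m), genes),
                  logical(1))))
    stop("replicates must share the same gene rows")
  totals <- vapply(matrices, function(m) attr(m, "total_reads"), numeric(1))
  norm <- lapply(matrices, normalize_rpm)
  rel <- vapply(norm, function(m) {
    tryCatch(median_reliability(stretch_correlations(m))$median,
             error = function(e) NA_real_)
  }, numeric(1))
  pass <- totals > min_reads | (!is.na(rel) & rel >= min_reliability)
  if (!any(pass))
    stop("no replicate passed QC; totals = ",
         paste(round(totals), collapse = ", "), "; reliabilities = ",
         paste(signif(rel, 3), collapse = ", "))
  kept <- norm[pass]
  avg <- Reduce(`+`, lapply(kept, unclass)) / length(kept)
  merged <- ucount_matrix(avg,
                          sample_id = attr(matrices[[1]], "sample_id"),
                          enzyme_active = attr(matrices[[1]], "enzyme_active"),
                          normalized = TRUE,
                          total_reads = sum(totals[pass]))
  # averaging 1e6-total matrices already gives 1e6; rescale exactly anyway
  ucount_matrix(unclass(merged) * (1e6 / sum(merged)),
                sample_id = attr(merged, "sample_id"),
                enzyme_active = attr(merged, "enzyme_active"),
                normalized = TRUE, total_reads = attr(merged, "total_reads"))
}

#' Read gene annotations from BED6 or GFF3
#'
#' The transcription termination site is taken as the strand-aware 3' end of
#' each feature (the last transcribed base, 0-based).
#'
#' @param path BED or GFF3 file.
#' @param format `"bed"` or `"gff3"` (guessed from the extension by default).
#' @param id_attribute GFF3 attribute holding the gene id (default `"ID"`).
#' @return A [gene_annotation()].
#' @export
read_annotation <- function(path, format = NULL, id_attribute = "ID") {
  if (is.null(format)) {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
              else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*")) stop("annotation features must be stranded")
  # 3' end, back to 0-based
  tts <- ifelse(strand == "+", BiocGenerics::end(gr) - 1L,
                BiocGenerics::start(gr) - 1L)
  ids <- if (format == "bed") gr$name else {
    v <- S4Vectors::mcols(gr)[[id_attribute]]
    if (is.null(v)) stop("GFF3 attribute not found: ", id_attribute)
    as.character(v)
  }
  gene_annotation(ids, as.character(GenomicRanges::seqnames(gr)), strand, tts)
}
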