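#' Parameters of a synthetic RNA-tagging experiment
#'
#' Describes the generative model used throughout the package to emulate an
#' RNA-tagging experiment: a heavy-tailed (log-normal) transcript abundance
#' distribution; a subset of target genes whose molecules carry bona fide
#' poly(U) tails with probability `tailed_fraction`, with tail lengths drawn
#' from `tail_length_dist` (support 4..16); and spurious short U stretches of
#' length 1-3 that arise on any untailed molecule with probability
#' `error_stretch_rate`, so that their counts scale with transcript abundance
#' (the sequencing-error signature of the assay).  A catalytically dead enzyme
#' (`enzyme_active = FALSE`) produces error stretches only.
#'
#' @param n_genes number of genes.
#' @param n_targets number of true target genes (`<= n_genes`).
#' @param expression_meanlog,expression_sdlog log-normal location and scale of
#'   relative transcript abundance.
#' @param tailed_fraction probability that a target-gene molecule carries a
#'   genuine poly(U) tail.  Forced to 0 when `enzyme_active` is `FALSE`.
#' @param tail_length_dist probability vector over tail lengths 4..16 (length
#'   13, sums to 1).  Default: uniform over 4..13, zero at 14..16.
#' @param error_stretch_rate probability that an untailed molecule records a
#'   spurious U stretch.
#' @param error_length_dist probability vector over error-stretch lengths 1..3.
#' @param total_reads number of sequenced molecules.
#' @param enzyme_active logical; `FALSE` emulates the dead-enzyme control.
#' @param seed integer seed; every simulator entry point is deterministic
#'   given (`params`, `seed`).
#' @return An object of class `simulation_params` (a validated list).
#' @export
simulation_params <- function(n_genes = 2000, n_targets = 200,
                              expression_meanlog = 0, expression_sdlog = 1.5,
                              tailed_fraction = 0.2,
                              tail_length_dist = NULL,
                              error_stretch_rate = 0.05,
                              error_length_dist = c(0.5, 0.3, 0.2),
                              total_reads = 1e6,
                              enzyme_active = TRUE,
                              seed) {
  if (missing(seed)) stop("a seed is required; there is no hidden randomness")
  if (is.null(tail_length_dist))
    tail_length_dist <- c(rep(0.1, 10), 0, 0, 0)  # uniform on 4..13
  if (n_genes < 1) stop("n_genes must be positive")
  if (n_targets < 0 || n_targets > n_genes)
    stop("n_targets must be between 0 and n_genes")
  if (total_reads < 1) stop("total_reads must be positive")
  if (tailed_fraction < 0 || tailed_fraction > 1)
    stop("tailed_fraction must be in [0,1]")
  if (error_stretch_rate < 0 || error_stretch_rate > 1)
    stop("error_stretch_rate must be in [0,1]")
  if (length(tail_length_dist) != 13L ||
      abs(sum(tail_length_dist) - 1) > 1e-8 || any(tail_length_dist < 0))
    stop("tail_length_dist must be 13 non-negative probabilities (lengths 4..16) summing to 1")
  if (length(error_length_dist) != 3L ||
      abs(sum(error_length_dist) - 1) > 1e-8 || any(error_length_dist < 0))
    stop("error_length_dist must be 3 non-negative probabilities (lengths 1..3) summing to 1")
  if (!enzyme_active) tailed_fraction <- 0
  structure(list(n_genes = as.integer(n_genes),
                 n_targets = as.integer(n_targets),
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 tailed_fraction = tailed_fraction,
                 tail_length_dist = tail_length_dist,
                 error_stretch_rate = error_stretch_rate,
                 error_length_dist = error_length_dist,
                 total_reads = as.integer(total_reads),
                 enzyme_active = isTRUE(enzyme_active),
                 seed = as.integer(seed)),
            class = "simulation_params")
}

#' Draw the ground truth of a synthetic tagging experiment
#'
#' Samples per-gene expression weights from the log-normal abundance model and
#' picks `n_targets` target genes without replacement.  Deterministic for a
#' fixed seed.
#'
#' @param params a [simulation_params()] object.
#' @return An object of class `simulation_truth` with fields `gene_ids`,
#'   `expression_weights` (non-negative, summing to 1), `target_flags`
#'   (logical), `tailed_fraction` (per gene: `params$tailed_fraction` for
#'   targets, 0 otherwise), `params` and `seed`.
#' @export
simulate_truth <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  n <- params$n_genes
  w <- stats::rlnorm(n, params$expression_meanlog, params$expression_sdlog)
  w <- w / sum(w)
  flags <- logical(n)
  if (params$n_targets > 0)
    flags[sample.int(n, params$n_targets)] <- TRUE
  f <- ifelse(flags, params$tailed_fraction, 0)
  structure(list(gene_ids = sprintf("g%04d", seq_len(n)),
                 expression_weights = w,
                 target_flags = flags,
                 tailed_fraction = f,
                 params = params,
                 seed = params$seed),
            class = "simulation_truth")
}

# One molecule per sequenced read: gene assignment proportional to expression
# weights; genuine tails only on target genes of an active enzyme; spurious
# stretches (1-3) only on untailed molecules.  The RNG draw order here is the
# contract that makes the count-level and read-level simulators agree exactly.
simulate_molecules <- function(truth, params) {
  set.seed(params$seed + 1L)
  n_reads <- params$total_reads
  gene <- sample.int(params$n_genes, n_reads, replace = TRUE,
                     prob = truth$expression_weights)
  f_gene <- truth$tailed_fraction[gene]
  if (!params$enzyme_active) f_gene[] <- 0
  tailed <- stats::runif(n_reads) < f_gene
  u <- integer(n_reads)
  if (any(tailed))
    u[tailed] <- sample(4:16, sum(tailed), replace = TRUE,
                        prob = params$tail_length_dist)
  err <- !tailed & (stats::runif(n_reads) < params$error_stretch_rate)
  if (any(err))
    u[err] <- sample(1:3, sum(err), replace = TRUE,
                     prob = params$error_length_dist)
  data.frame(gene = gene, u = u)
}

#' Simulate a raw U-count matrix directly at the count level
#'
#' Assigns each of `total_reads` molecules to a gene in proportion to its
#' expression weight, draws tail / error-stretch lengths per the generative
#' model, and tabulates the gene-by-length matrix.  Raw counts sum exactly to
#' `total_reads`.
#'
#' @param truth a [simulate_truth()] object.
#' @param params the matching [simulation_params()].
#' @return A raw [ucount_matrix()].
#' @export
simulate_ucount_matrix <- function(truth, params = truth$params) {
  stopifnot(inherits(truth, "simulation_truth"))
  mol <- simulate_molecules(truth, params)
  tabulate_molecules(mol, truth, params)
}

tabulate_molecules <- function(mol, truth, params) {
  counts <- table(factor(mol$gene, levels = seq_len(params$n_genes)),
                  factor(mol$u, levels = 0:16))
  m <- matrix(as.integer(counts), nrow = params$n_genes, ncol = 17L,
              dimnames = list(truth$gene_ids, u_colnames()))
  ucount_matrix(m,
                sample_id = if (params$enzyme_active) "synthetic_active"
                            else "synthetic_dead",
                enzyme_active = params$enzyme_active)
}

#' Simulate the catalytically-dead-enzyme control
#'
#' Identical to [simulate_ucount_matrix()] with the enzyme switched off: no
#' genuine tails are laid down, so columns 4-16 are identically zero and the
#' short (1-3) error-stretch counts remain proportional to expression across
#' genes.
#'
#' @inheritParams simulate_ucount_matrix
#' @return A raw [ucount_matrix()] with `enzyme_active = FALSE`.
#' @export
simulate_dead_control <- function(truth, params = truth$params) {
  dead <- params
  dead$enzyme_active <- FALSE
  simulate_ucount_matrix(truth, dead)
}

#' Build a toy transcriptome for read-level simulation
#'
#' Lays `n_genes` genes on a single chromosome with transcription termination
#' sites (TTS) spaced `spacing` bases apart (far enough that the -300/+100
#' sense counting windows never overlap) on alternating strands, each with a
#' random 3'-end body sequence.
#'
#' @param truth a [simulate_truth()] object (supplies gene ids and the seed).
#' @param body_length length of the stored 3'-end body sequence per gene.
#' @param spacing distance between consecutive TTS coordinates.
#' @return A data.frame of class `toy_transcriptome` with columns `gene_id`,
#'   `chrom`, `strand`, `tts` (0-based) and `body` (sense DNA).
#' @export
toy_transcriptome <- function(truth, body_length = 60, spacing = 1000L) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (body_length < 50) stop("body_length must be >= 50")
  set.seed(truth$seed + 3L)
  n <- length(truth$gene_ids)
  bodies <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), body_length, replace = TRUE),
          collapse = ""), character(1))
  structure(data.frame(gene_id = truth$gene_ids,
                       chrom = "chrS",
                       strand = rep(c("+", "-"), length.out = n),
                       tts = 400L + (seq_len(n) - 1L) * as.integer(spacing),
                       body = bodies,
                       stringsAsFactors = FALSE),
            class = c("toy_transcriptome", "data.frame"))
}

#' Simulate paired 3'-end sequencing reads of a tagging experiment
#'
#' Generates the same molecule stream as [simulate_ucount_matrix()] (identical
#' seed arithmetic, so the two simulators agree exactly) and renders each
#' molecule as a read pair: read 1 is a sense fragment whose 5' end falls
#' inside the `[TTS-300, TTS+100)` counting window of its gene, and read 2 is
#' sequenced from the 3' adapter, i.e. an 8-mer UMI followed by the reverse
#' complement of `body suffix + poly(A) run (10-30 nt) + poly(U)-as-T run +
#' adapter stub`.  UMIs are drawn without replacement within each gene so the
#' read stream survives UMI deduplication intact.
#'
#' @inheritParams simulate_ucount_matrix
#' @param transcriptome a [toy_transcriptome()] covering all genes.
#' @param out_dir optional directory; when given, `reads_2.fastq`, and
#'   `alignments.tsv` (read_id, umi, chrom, pos, strand, tail_seq) are written
#'   there.
#' @return A list with `reads` (data.frame: read_id, umi, chrom, pos, strand,
#'   read2_seq, tail_seq, gene, u), `truth`, and when `out_dir` is given,
#'   `fastq2` and `alignment_table` file paths.
#' @export
simulate_reads <- function(truth, params = truth$params, transcriptome,
                           out_dir = NULL) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(transcriptome, "toy_transcriptome"))
  if (!all(truth$gene_ids %in% transcriptome$gene_id))
    stop("transcriptome does not cover all simulated genes")
  mol <- simulate_molecules(truth, params)
  n_reads <- nrow(mol)
  tx <- transcriptome[match(truth$gene_ids, transcriptome$gene_id), ]

  set.seed(params$seed + 2L)
  # read 1 placement: sense offset in [-300, 100) from the TTS
  offset <- sample(-300:99, n_reads, replace = TRUE)
  strand <- tx$strand[mol$gene]
  tts <- tx$tts[mol$gene]
  pos <- ifelse(strand == "+", tts + offset, tts - offset)
  polya <- sample(10:30, n_reads, replace = TRUE)
  umi <- draw_umis_per_gene(mol$gene)

  body <- tx$body[mol$gene]
  suffix <- substr(body, nchar(body) - 19L, nchar(body))
  sense_frag <- paste0(suffix,
                       strrep("A", polya),
                       strrep("T", mol$u),
                       ADAPTER_STUB)
  read2 <- paste0(umi, as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(sense_frag))))

  reads <- data.frame(read_id = sprintf("r%07d", seq_len(n_reads)),
                      umi = umi,
                      chrom = tx$chrom[mol$gene],
                      pos = pos,
                      strand = strand,
                      read2_seq = read2,
                      tail_seq = paste0(strrep("A", polya), strrep("T", mol$u),
                                        ADAPTER_STUB),
                      gene = mol$gene,
                      u = mol$u,
                      stringsAsFactors = FALSE)
  out <- list(reads = reads, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fq2 <- file.path(out_dir, "reads_2.fastq")
    write_fastq(stats::setNames(reads$read2_seq, reads$read_id), fq2)
    aln <- file.path(out_dir, "alignments.tsv")
    utils::write.table(
      reads[, c("read_id", "umi", "chrom", "pos", "strand", "tail_seq")],
      aln, sep = "\t", quote = FALSE, row.names = FALSE)
    out$fastq2 <- fq2
    out$alignment_table <- aln
  }
  out
}

ADAPTER_STUB <- "CTGTCTCTTATACACATCT"

# Distinct 8-mer UMIs within each gene (cross-gene reuse allowed); keeps the
# simulated read stream identical before and after (gene, UMI) deduplication.
draw_umis_per_gene <- function(gene) {
  umi_int <- integer(length(gene))
  for (g in unique(gene)) {
    idx <- which(gene == g)
    if (length(idx) > 65536L)
      stop("more than 4^8 reads for one gene; cannot draw distinct UMIs")
    umi_int[idx] <- sample.int(65536L, length(idx)) - 1L
  }
  encode_umi(umi_int)
}

encode_umi <- function(x) {
  alpha <- c("A", "C", "G", "T")
  out <- character(length(x))
  chars <- matrix("", nrow = length(x), ncol = 8L)
  for (p in 1:8) {
    chars[, p] <- alpha[x %% 4L + 1L]
    x <- x %/% 4L
  }
  apply(chars, 1L, paste, collapse = "")
}

#' Write sequences as a 4-line FASTQ with constant Phred+33 quality
#'
#' @param seqs named character vector (names become read ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Write the ground-truth table of a synthetic experiment
#'
#' @param truth a [simulate_truth()] object.
#' @param path output TSV path (columns gene_id, expression_weight, is_target,
#'   tailed_fraction).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "simulation_truth"))
  utils::write.table(
    data.frame(gene_id = truth$gene_ids,
               expression_weight = truth$expression_weights,
               is_target = truth$target_flags,
               tailed_fraction = truth$tailed_fraction),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the sequences of a FASTQ file
#'
#' @param path FASTQ path.
#' @return Named character vector of read sequences (names are the read ids,
#'   truncated at the first whitespace).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), ids)
}
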