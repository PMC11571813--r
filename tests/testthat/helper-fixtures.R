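# Small shared fixtures, built in code.

tiny_params <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_genes = 200, n_targets = 20, total_reads = 50000, seed = seed),
    list(...))
  do.call(simulation_params, args)
}

# hand-buildable raw matrix: rows named, 17 columns
hand_matrix <- function(rows, gene_ids = names(rows), ...) {
  m <- do.call(rbind, rows)
  rownames(m) <- gene_ids
  colnames(m) <- paste0("u", 0:16)
  ucount_matrix(m, ...)
}

u_row <- function(...) {
  r <- numeric(17)
  vals <- list(...)
  for (u in names(vals)) r[as.integer(u) + 1L] <- vals[[u]]
  r
}

# protein with explicit disorder/domains; sequence defaults to poly-A residues
make_protein <- function(id, L, domains = NULL, disorder = rep(0.9, L),
                         sequence = strrep("A", L), species = NA) {
  protein_architecture(id, sequence, domains, disorder, species = species)
}

two_domain_template <- function(seed = 42) {
  set.seed(seed)
  L <- 300
  seqc <- paste(sample(AA_letters(), L, replace = TRUE), collapse = "")
  dom <- data.frame(family = "RRM", start = c(61, 181), end = c(120, 240))
  dis <- ifelse(seq_len(L) %in% c(61:120, 181:240), 0.2, 0.85)
  protein_architecture("TMPL", seqc, dom, dis)
}

AA_letters <- function() c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# independent brute-force oracle for post-poly(A) U counting: run-length scan
brute_count_us <- function(s, min_polya_run = 5, cap = 16) {
  r <- rle(strsplit(s, "")[[1]])
  ends <- cumsum(r$lengths)
  polya <- which(r$values == "A" & r$lengths >= min_polya_run)
  if (!length(polya)) return(NA_integer_)
  i <- max(polya)
  if (i == length(r$lengths) || r$values[i + 1] != "T") return(0L)
  as.integer(min(r$lengths[i + 1], cap))
}

# exhaustive interval-enumeration oracle for read-to-gene assignment
brute_assign <- function(chrom, pos, strand, ann) {
  vapply(seq_along(pos), function(i) {
    best <- NA_character_; best_d <- Inf
    for (j in seq_len(nrow(ann))) {
      if (ann$chrom[j] != chrom[i] || ann$strand[j] != strand[i]) next
      d <- if (ann$strand[j] == "+") pos[i] - ann$tts[j]
           else ann$tts[j] - pos[i]
      if (d < -300 || d >= 100) next
      dist <- abs(pos[i] - ann$tts[j])
      if (dist < best_d ||
          (dist == best_d && !is.na(best) && ann$gene_id[j] < best)) {
        best <- ann$gene_id[j]; best_d <- dist
      }
    }
    best
  }, character(1))
}

# textbook Pearson correlation, written out
pearson_direct <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

truth_targets <- function(truth) truth$gene_ids[truth$target_flags]

# strip sample metadata so count matrices compare on values alone
bare_counts <- function(m) {
  x <- unclass(m)
  attributes(x) <- list(dim = dim(x), dimnames = dimnames(x))
  x
}
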