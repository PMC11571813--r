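AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' A protein's domain/disorder architecture
#'
#' Bundles a protein sequence with its annotated binding domains (1-based
#' inclusive residue coordinates, Pfam convention) and a per-residue disorder
#' score in `[0, 1]` (e.g. IUPred output; scores are inputs, never predicted
#' here).  Overlapping annotations of the same family are merged; domains are
#' stored ordered by start position.
#'
#' @param protein_id identifier.
#' @param sequence amino-acid sequence (20-letter alphabet; other letters are
#'   tolerated but dropped from compositions).
#' @param domains data.frame with columns `family`, `start`, `end`; may be
#'   empty.
#' @param disorder numeric vector, one score per residue.
#' @param species optional species label.
#' @return An object of class `protein_architecture`.
#' @export
protein_architecture <- function(protein_id, sequence, domains, disorder,
                                 species = NA_character_) {
  L <- nchar(sequence)
  if (length(disorder) != L)
    stop("disorder track length (", length(disorder),
         ") does not match sequence length (", L, ")")
  if (any(disorder < 0 | disorder > 1, na.rm = TRUE))
    stop("disorder scores must lie in [0, 1]")
  if (is.null(domains) || nrow(domains) == 0) {
    domains <- data.frame(family = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("family", "start", "end") %in% colnames(domains)))
    if (any(domains$start < 1 | domains$end > L | domains$start > domains$end))
      stop("domain coordinates out of range for ", protein_id)
    domains <- merge_same_family(domains[order(domains$start, domains$end), ])
  }
  structure(list(protein_id = protein_id, species = species,
                 length = L, sequence = sequence,
                 domains = domains, disorder = as.numeric(disorder)),
            class = "protein_architecture")
}

merge_same_family <- function(domains) {
  out <- domains[0, ]
  for (i in seq_len(nrow(domains))) {
    j <- nrow(out)
    if (j > 0 && out$family[j] == domains$family[i] &&
        domains$start[i] <= out$end[j] + 1L) {
      out$end[j] <- max(out$end[j], domains$end[i])
    } else {
      out <- rbind(out, domains[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.protein_architecture <- function(x, ...) {
  cat(sprintf("protein_architecture %s (%s): %d aa, %d domain(s) [%s]\n",
              x$protein_id, x$species, x$length, nrow(x$domains),
              paste(x$domains$family, collapse = ", ")))
  invisible(x)
}

domain_coverage <- function(protein) {
  covered <- logical(protein$length)
  for (i in seq_len(nrow(protein$domains)))
    covered[protein$domains$start[i]:protein$domains$end[i]] <- TRUE
  covered
}

#' Per-residue IDR mask
#'
#' A residue belongs to an intrinsically disordered region when it lies
#' outside every annotated domain and its disorder score strictly exceeds
#' the cutoff (a score of exactly 0.5 is not disordered).
#'
#' @param protein a [protein_architecture()].
#' @param cutoff disorder-score cutoff (strict `>`).
#' @return Logical vector of length `protein$length`.
#' @export
idr_mask <- function(protein, cutoff = 0.5) {
  stopifnot(inherits(protein, "protein_architecture"))
  !domain_coverage(protein) & protein$disorder > cutoff
}

#' Fractions of a protein in domains, IDRs, and the rest
#'
#' Residues covered by any domain (counted once under overlaps), residues in
#' IDRs ([idr_mask()]), and the remainder, each as a fraction of protein
#' length; the three fractions sum to 1.
#'
#' @inheritParams idr_mask
#' @return Named numeric vector `c(domain, idr, other)`.
#' @export
region_fractions <- function(protein, cutoff = 0.5) {
  covered <- domain_coverage(protein)
  idr <- !covered & protein$disorder > cutoff
  c(domain = mean(covered), idr = mean(idr), other = mean(!covered & !idr))
}

#' Fraction of the sequence spanned by the domain region
#'
#' Extent from the first domain's start to the last domain's end, as a
#' fraction of protein length — a measure of how dispersed the binding
#' domains are along the sequence.
#'
#' @param protein a [protein_architecture()].
#' @return `(max(end) - min(start) + 1) / L`, or `NA` without domains.
#' @export
domain_span_fraction <- function(protein) {
  d <- protein$domains
  if (nrow(d) == 0) return(NA_real_)
  (max(d$end) - min(d$start) + 1) / protein$length
}

#' Amino-acid composition of masked residues
#'
#' Frequency of each of the 20 canonical amino acids among the residues
#' selected by `mask` (by default the protein's IDR residues); non-canonical
#' letters are dropped with a warning.
#'
#' @param protein a [protein_architecture()].
#' @param mask logical per-residue mask; defaults to [idr_mask()].
#' @return Named numeric 20-vector summing to 1.
#' @export
aa_composition <- function(protein, mask = idr_mask(protein)) {
  if (!any(mask)) stop("composition undefined: empty residue mask for ",
                       protein$protein_id)
  res <- strsplit(protein$sequence, "")[[1]][mask]
  bad <- !(res %in% AA20)
  if (any(bad)) {
    warning("dropping ", sum(bad), " non-canonical residue(s) in ",
            protein$protein_id)
    res <- res[!bad]
    if (!length(res)) stop("no canonical residues left in mask")
  }
  counts <- table(factor(res, levels = AA20))
  stats::setNames(as.numeric(counts) / length(res), AA20)
}

#' Pairwise IDR-composition correlation, ordered by TF similarity
#'
#' Computes the IDR amino-acid composition of every protein, the pairwise
#' Pearson correlation matrix between those 20-vectors, and a display order:
#' descending correlation with the average composition of the proteins
#' labeled `"TF"` (transcription factors); without TF labels the input order
#' is kept with a warning.
#'
#' @param proteins list of [protein_architecture()] objects with non-empty
#'   IDRs (at least 2).
#' @param group_labels character vector of group labels per protein (e.g.
#'   `"mRBP"`, `"genRBP"`, `"TF"`).
#' @return List with `compositions` (proteins x 20 matrix), `correlation`
#'   (symmetric matrix in display order), `order` (protein ids) and
#'   `group_labels` (reordered).
#' @export
composition_correlation <- function(proteins, group_labels) {
  stopifnot(length(proteins) >= 2, length(group_labels) == length(proteins))
  comp <- t(vapply(proteins, aa_composition, numeric(20)))
  rownames(comp) <- vapply(proteins, `[[`, character(1), "protein_id")
  cors <- stats::cor(t(comp))
  if (any(group_labels == "TF")) {
    ref <- colMeans(comp[group_labels == "TF", , drop = FALSE])
    sim <- as.numeric(stats::cor(t(comp), ref))
    ord <- order(-sim)
  } else {
    warning("no TF-labeled proteins; keeping input order")
    ord <- seq_along(proteins)
  }
  list(compositions = comp[ord, , drop = FALSE],
       correlation = cors[ord, ord, drop = FALSE],
       order = rownames(comp)[ord],
       group_labels = group_labels[ord])
}

#' A group of orthologous protein architectures
#'
#' @param members list of [protein_architecture()] objects (>= 2), one per
#'   species.
#' @param group_id identifier.
#' @return An object of class `ortholog_group`.
#' @export
ortholog_group <- function(members, group_id = "group") {
  stopifnot(length(members) >= 1,
            all(vapply(members, inherits, logical(1),
                       "protein_architecture")))
  structure(list(group_id = group_id, members = members),
            class = "ortholog_group")
}

#' @export
print.ortholog_group <- function(x, ...) {
  cat(sprintf("ortholog_group '%s': %d orthologs\n", x$group_id,
              length(x$members)))
  invisible(x)
}

# (family, rank-within-family) keys of a member's domains, in start order
domain_keys <- function(protein) {
  d <- protein$domains
  if (nrow(d) == 0)
    return(data.frame(family = character(), rank = integer(),
                      start = integer()))
  rank <- stats::ave(seq_len(nrow(d)), d$family, FUN = seq_along)
  data.frame(family = d$family, rank = rank, start = d$start)
}

#' Ancestral domain composition of an ortholog group
#'
#' Domains are matched across orthologs by (family, rank-within-family) after
#' sorting by position; a domain belongs to the ancestral composition when it
#' is present in strictly more than `presence_fraction` of the orthologs
#' (exactly 30% is excluded at the default).  The consensus order is by mean
#' start position across the orthologs that carry the domain.
#'
#' @param group an [ortholog_group()].
#' @param presence_fraction presence cutoff (strict `>`).
#' @return A data.frame with columns `family`, `rank`, `presence` (fraction
#'   of orthologs), ordered by consensus position; zero rows when nothing
#'   qualifies.
#' @export
ancestral_composition <- function(group, presence_fraction = 0.30) {
  stopifnot(inherits(group, "ortholog_group"))
  n <- length(group$members)
  if (n == 0) stop("empty ortholog group")
  keys <- lapply(group$members, domain_keys)
  all_keys <- do.call(rbind, keys)
  if (nrow(all_keys) == 0)
    return(data.frame(family = character(), rank = integer(),
                      presence = numeric()))
  key_str <- paste(all_keys$family, all_keys$rank, sep = "\r")
  presence <- tapply(key_str, key_str, length) / n
  mean_start <- tapply(all_keys$start, key_str, mean)
  keep <- names(presence)[presence > presence_fraction]
  if (!length(keep))
    return(data.frame(family = character(), rank = integer(),
                      presence = numeric()))
  ord <- keep[order(mean_start[keep], keep)]
  parts <- strsplit(ord, "\r", fixed = TRUE)
  data.frame(family = vapply(parts, `[`, character(1), 1),
             rank = as.integer(vapply(parts, `[`, character(1), 2)),
             presence = as.numeric(presence[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# does `families` contain `ancestral_families` as an in-order subsequence?
contains_in_order <- function(families, ancestral_families) {
  if (!length(ancestral_families)) return(TRUE)
  i <- 1L
  for (fam in families) {
    if (fam == ancestral_families[i]) {
      i <- i + 1L
      if (i > length(ancestral_families)) return(TRUE)
    }
  }
  FALSE
}

#' Fraction of orthologs with conserved domain organization
#'
#' An ortholog conserves the ancestral organization when its domain family
#' sequence (by position) contains the ancestral family list as an in-order
#' subsequence; swapped domains do not count.  An empty ancestral composition
#' (every domain lost group-wide) yields 0 — there is no architecture left to
#' conserve.
#'
#' @param group an [ortholog_group()].
#' @param ancestral optional precomputed [ancestral_composition()].
#' @return List with `fraction`, per-member logical `conserved` (named by
#'   protein id) and the `ancestral` table used.
#' @export
conserved_fraction <- function(group, ancestral = NULL) {
  stopifnot(inherits(group, "ortholog_group"))
  if (is.null(ancestral)) ancestral <- ancestral_composition(group)
  ids <- vapply(group$members, `[[`, character(1), "protein_id")
  if (nrow(ancestral) == 0) {
    conserved <- stats::setNames(rep(FALSE, length(ids)), ids)
    return(list(fraction = 0, conserved = conserved, ancestral = ancestral))
  }
  conserved <- vapply(group$members, function(p)
    contains_in_order(p$domains$family, ancestral$family), logical(1))
  names(conserved) <- ids
  list(fraction = mean(conserved), conserved = conserved,
       ancestral = ancestral)
}

# Greedy left-to-right match of the ancestral family list within a member's
# domains; returns the matched domain rows (start/end), or NULL if no match.
match_ancestral_domains <- function(protein, ancestral_families) {
  d <- protein$domains
  idx <- integer(0)
  i <- 1L
  for (j in seq_len(nrow(d))) {
    if (i <= length(ancestral_families) &&
        d$family[j] == ancestral_families[i]) {
      idx <- c(idx, j)
      i <- i + 1L
    }
  }
  if (i <= length(ancestral_families)) return(NULL)
  d[idx, , drop = FALSE]
}

#' IDR-segment conservation within an ortholog group
#'
#' Considering only orthologs with the conserved domain organization, the
#' inter-domain sequence is cut into segments keyed by position relative to
#' the ancestral domain order (N-terminal, between ancestral domains i and
#' i+1, C-terminal).  A segment qualifies as a conserved IDR segment when its
#' across-ortholog average disorder tendency exceeds 0.5 and its average
#' length is at least `min_avg_length` residues.  For each qualifying segment
#' the mean and sample standard deviation (n-1 denominator) of the number of
#' disordered residues across orthologs are computed; `mean_ratio` averages
#' the per-segment `std/mean` ratios — small values mean the IDR sizes are
#' conserved.
#'
#' @param group an [ortholog_group()].
#' @param cutoff per-residue disorder cutoff (strict `>`).
#' @param min_avg_length minimum across-ortholog average segment length.
#' @return List with `segments` (data.frame: `segment`, `mean_length`,
#'   `mean_disorder`, `is_idr`, `mean_count`, `sd_count`, `ratio`),
#'   `mean_ratio` (`NA` when no segment qualifies), `n_conserved`, and the
#'   `ancestral` table.
#' @export
idr_segment_conservation <- function(group, cutoff = 0.5,
                                     min_avg_length = 15) {
  cf <- conserved_fraction(group)
  members <- group$members[cf$conserved]
  if (length(members) < 2)
    stop("need at least 2 orthologs with conserved domain organization")
  anc <- cf$ancestral
  seg_names <- c("N", if (nrow(anc) > 1)
    paste0("between_", seq_len(nrow(anc) - 1)), "C")
  per_member <- lapply(members, function(p) {
    dom <- match_ancestral_domains(p, anc$family)
    bounds <- rbind(c(1L, if (nrow(dom)) dom$start[1] - 1L else p$length),
                    if (nrow(dom) > 1)
                      cbind(dom$end[-nrow(dom)] + 1L, dom$start[-1] - 1L),
                    c(if (nrow(dom)) dom$end[nrow(dom)] + 1L else 1L,
                      p$length))
    t(apply(bounds, 1, function(b) {
      if (b[1] > b[2]) return(c(len = 0, n_dis = 0, mean_dis = NA_real_))
      d <- p$disorder[b[1]:b[2]]
      c(len = length(d), n_dis = sum(d > cutoff), mean_dis = mean(d))
    }))
  })
  stats_df <- do.call(rbind, lapply(seq_along(seg_names), function(s) {
    len <- vapply(per_member, function(m) m[s, "len"], numeric(1))
    n_dis <- vapply(per_member, function(m) m[s, "n_dis"], numeric(1))
    mean_dis <- vapply(per_member, function(m) m[s, "mean_dis"], numeric(1))
    avg_dis <- if (all(is.na(mean_dis))) NA_real_
               else mean(mean_dis, na.rm = TRUE)
    is_idr <- !is.na(avg_dis) && avg_dis > 0.5 &&
      mean(len) >= min_avg_length
    mu <- mean(n_dis); sdev <- stats::sd(n_dis)
    data.frame(segment = seg_names[s], mean_length = mean(len),
               mean_disorder = avg_dis, is_idr = is_idr,
               mean_count = mu, sd_count = sdev,
               ratio = if (is_idr && mu > 0) sdev / mu else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(stats_df) <- NULL
  idr_rows <- stats_df[stats_df$is_idr, , drop = FALSE]
  mean_ratio <- if (nrow(idr_rows) == 0 || all(is.na(idr_rows$ratio)))
    NA_real_ else mean(idr_rows$ratio, na.rm = TRUE)
  list(segments = stats_df, mean_ratio = mean_ratio,
       n_conserved = length(members), ancestral = anc)
}

#' Simulate an ortholog group from a template architecture
#'
#' Derives `n_orthologs` architectures from a template by per-residue point
#' substitutions, indels restricted to non-domain (IDR) residues, and
#' whole-domain loss with probability `domain_loss_prob` per domain per
#' ortholog.  The disorder profile is regenerated consistently: low inside
#' domains, high outside.  The returned group carries a `truth` attribute
#' recording which orthologs retained every template domain.
#'
#' @param template a [protein_architecture()].
#' @param n_orthologs number of orthologs to derive.
#' @param substitution_rate per-residue substitution probability.
#' @param idr_indel_rate per-residue indel probability outside domains (half
#'   deletions, half single-residue insertions).
#' @param domain_loss_prob probability that a domain is deleted wholesale.
#' @param seed integer seed.
#' @return An [ortholog_group()] with attribute `truth` (data.frame:
#'   `protein_id`, `n_domains_lost`, `retains_all_domains`).
#' @export
simulate_ortholog_group <- function(template, n_orthologs,
                                    substitution_rate = 0.05,
                                    idr_indel_rate = 0.02,
                                    domain_loss_prob = 0, seed) {
  stopifnot(inherits(template, "protein_architecture"))
  rates <- c(substitution_rate, idr_indel_rate, domain_loss_prob)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  n_dom <- nrow(template$domains)
  res <- strsplit(template$sequence, "")[[1]]
  in_dom <- domain_coverage(template)
  dom_of <- rep(0L, template$length)
  for (i in seq_len(n_dom))
    dom_of[template$domains$start[i]:template$domains$end[i]] <- i

  members <- vector("list", n_orthologs)
  lost_count <- integer(n_orthologs)
  for (j in seq_len(n_orthologs)) {
    lost <- stats::runif(n_dom) < domain_loss_prob
    keep_res <- dom_of == 0L | !lost[pmax(dom_of, 1L)]
    seq_j <- res
    sub <- stats::runif(template$length) < substitution_rate
    seq_j[sub] <- sample(AA20, sum(sub), replace = TRUE)
    # indels only outside domains: delete or insert one residue
    op <- stats::runif(template$length)
    del <- !in_dom & op < idr_indel_rate / 2
    ins <- !in_dom & op >= idr_indel_rate / 2 & op < idr_indel_rate
    pieces <- character(template$length)
    pieces[keep_res & !del] <- seq_j[keep_res & !del]
    if (any(ins & keep_res)) {
      extra <- sample(AA20, sum(ins & keep_res), replace = TRUE)
      pieces[ins & keep_res] <- paste0(pieces[ins & keep_res], extra)
    }
    # rebuild coordinates: residue lengths per template position
    lens <- nchar(pieces)
    ends <- cumsum(lens)
    new_dom <- template$domains[!lost, , drop = FALSE]
    if (nrow(new_dom)) {
      new_dom$start <- ends[new_dom$start] - lens[new_dom$start] + 1L
      new_dom$end <- ends[new_dom$end]
    }
    seq_out <- paste(pieces, collapse = "")
    L_out <- nchar(seq_out)
    in_dom_out <- logical(L_out)
    for (i in seq_len(nrow(new_dom)))
      in_dom_out[new_dom$start[i]:new_dom$end[i]] <- TRUE
    disorder <- ifelse(in_dom_out, stats::runif(L_out, 0.05, 0.35),
                       stats::runif(L_out, 0.60, 0.95))
    members[[j]] <- protein_architecture(
      protein_id = sprintf("%s_sp%02d", template$protein_id, j),
      sequence = seq_out, domains = new_dom, disorder = disorder,
      species = sprintf("sp%02d", j))
    lost_count[j] <- sum(lost)
  }
  grp <- ortholog_group(members, group_id = paste0(template$protein_id,
                                                   "_orthologs"))
  attr(grp, "truth") <- data.frame(
    protein_id = vapply(members, `[[`, character(1), "protein_id"),
    n_domains_lost = lost_count,
    retains_all_domains = lost_count == 0L,
    stringsAsFactors = FALSE)
  grp
}
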