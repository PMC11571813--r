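test_that("idr_mask is strict at the disorder cutoff", {
  p1 <- make_protein("p1", 10, disorder = rep(0.9, 10))
  expect_true(all(idr_mask(p1)))
  p2 <- make_protein("p2", 10,
                     domains = data.frame(family = "RRM", start = 1, end = 10))
  expect_false(any(idr_mask(p2)))
  p3 <- make_protein("p3", 4, disorder = c(0.5, 0.5001, 0.4999, 0.5))
  expect_identical(idr_mask(p3), c(FALSE, TRUE, FALSE, FALSE))
  expect_error(protein_architecture("bad", "AAAA", NULL, rep(0.5, 3)),
               "length")
})

test_that("region fractions sum to one and count overlap residues once", {
  p <- make_protein("p", 100,
                    domains = data.frame(family = "KH", start = 1, end = 27),
                    disorder = rep(1, 100))
  expect_equal(region_fractions(p),
               c(domain = 0.27, idr = 0.73, other = 0), tolerance = 1e-12)

  # overlapping same-family annotations merge: residues counted once
  po <- make_protein("po", 100,
                     domains = data.frame(family = "KH", start = c(1, 20),
                                          end = c(30, 40)),
                     disorder = rep(0, 100))
  expect_equal(region_fractions(po)[["domain"]], 0.40)

  # hand-built 20-residue protein, residue-by-residue enumeration
  ph <- make_protein("ph", 20,
                     domains = data.frame(family = "RRM", start = 6, end = 10),
                     disorder = c(rep(0.8, 5), rep(0.9, 5), rep(0.3, 5),
                                  rep(0.7, 5)))
  by_hand <- c(domain = 5 / 20, idr = (5 + 5) / 20, other = 5 / 20)
  expect_equal(region_fractions(ph), by_hand)

  set.seed(6)
  for (i in 1:5) {
    L <- sample(50:150, 1)
    s <- sort(sample(L, 2))
    pr <- make_protein(paste0("r", i), L,
                       domains = data.frame(family = "X", start = s[1],
                                            end = s[2]),
                       disorder = runif(L))
    expect_equal(sum(region_fractions(pr)), 1)
  }
})

test_that("domain_span_fraction measures first-to-last domain extent", {
  full <- make_protein("f", 80,
                       domains = data.frame(family = "D", start = 1, end = 80))
  expect_equal(domain_span_fraction(full), 1)
  two <- make_protein("t", 100,
                      domains = data.frame(family = "D", start = c(10, 90),
                                           end = c(19, 99)))
  expect_equal(domain_span_fraction(two), 0.90)
  one <- make_protein("o", 100,
                      domains = data.frame(family = "D", start = 40, end = 49))
  expect_equal(domain_span_fraction(one), 0.10)
  expect_true(is.na(domain_span_fraction(make_protein("n", 60))))
})

test_that("aa_composition returns a unit-sum frequency vector", {
  pa <- make_protein("pa", 4, sequence = "AAAA")
  ca <- aa_composition(pa, rep(TRUE, 4))
  expect_equal(ca[["A"]], 1)
  expect_equal(sum(ca), 1)
  pm <- make_protein("pm", 4, sequence = "ACDE")
  expect_equal(unname(aa_composition(pm, rep(TRUE, 4))[c("A", "C", "D", "E")]),
               rep(0.25, 4))
  px <- make_protein("px", 4, sequence = "ACDX")
  expect_warning(cx <- aa_composition(px, rep(TRUE, 4)), "non-canonical")
  expect_equal(sum(cx), 1)
  expect_error(aa_composition(pa, rep(FALSE, 4)), "empty")
})

test_that("composition_correlation orders by similarity to the TF average", {
  mk <- function(id, seqs) make_protein(id, nchar(seqs), sequence = seqs)
  prots <- list(mk("tf1", strrep("KR", 20)),    # charged
                mk("rbp1", strrep("KR", 20)),   # identical to tf1
                mk("rbp2", strrep("GS", 20)))   # distinct
  cc <- composition_correlation(prots, c("TF", "mRBP", "mRBP"))
  expect_equal(cc$correlation["tf1", "rbp1"], 1)
  expect_equal(diag(cc$correlation), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cc$correlation, t(cc$correlation))
  expect_identical(cc$order[3], "rbp2")  # least TF-like last

  # 3 hand compositions against the direct formula
  set.seed(9)
  rnd <- lapply(1:3, function(i)
    make_protein(paste0("h", i), 60,
                 sequence = paste(sample(AA_letters(), 60, TRUE),
                                  collapse = "")))
  ccr <- composition_correlation(rnd, c("TF", "A", "B"))
  comp <- ccr$compositions
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(ccr$correlation[i, j],
                 pearson_direct(comp[i, ], comp[j, ]))

  expect_warning(composition_correlation(rnd[1:2], c("A", "B")), "no TF")
})

test_that("ancestral_composition applies the strict >30% presence rule", {
  dom1 <- data.frame(family = "RRM", start = 10, end = 30)
  with_dom <- lapply(1:3, function(i) make_protein(paste0("w", i), 100,
                                                   domains = dom1))
  without <- lapply(4:10, function(i) make_protein(paste0("w", i), 100))
  # 3 of 10 = exactly 30%: excluded
  grp30 <- ortholog_group(c(with_dom, without))
  expect_identical(nrow(ancestral_composition(grp30)), 0L)
  # 4 of 10 = 40%: included
  grp40 <- ortholog_group(c(with_dom,
                            list(make_protein("w11", 100, domains = dom1)),
                            without[1:6]))
  anc <- ancestral_composition(grp40)
  expect_identical(anc$family, "RRM")
  expect_equal(anc$presence, 0.4)
})

test_that("second-rank domains join the ancestral set at 75% presence", {
  two <- data.frame(family = "RRM", start = c(10, 60), end = c(30, 80))
  one <- data.frame(family = "RRM", start = 10, end = 30)
  grp <- ortholog_group(list(make_protein("a", 100, domains = two),
                             make_protein("b", 100, domains = two),
                             make_protein("c", 100, domains = two),
                             make_protein("d", 100, domains = one)))
  anc <- ancestral_composition(grp)
  expect_identical(anc$rank, 1:2)
  expect_equal(anc$presence, c(1, 0.75))
  cf <- conserved_fraction(grp)
  expect_equal(cf$fraction, 0.75)  # "d" lacks the second RRM
  expect_false(cf$conserved[["d"]])
})

test_that("conserved organization requires the ancestral order", {
  fwd <- data.frame(family = c("RRM", "KH"), start = c(10, 60),
                    end = c(30, 80))
  rev <- data.frame(family = c("KH", "RRM"), start = c(10, 60),
                    end = c(30, 80))
  grp <- ortholog_group(list(make_protein("a", 100, domains = fwd),
                             make_protein("b", 100, domains = fwd),
                             make_protein("c", 100, domains = fwd),
                             make_protein("d", 100, domains = rev)))
  cf <- conserved_fraction(grp)
  expect_identical(cf$ancestral$family, c("RRM", "KH"))
  expect_false(cf$conserved[["d"]])   # swapped order does not count
  expect_equal(cf$fraction, 0.75)

  ident <- ortholog_group(lapply(1:4, function(i)
    make_protein(paste0("i", i), 100, domains = fwd)))
  expect_equal(conserved_fraction(ident)$fraction, 1)
})

test_that("identical orthologs give zero IDR variability", {
  dom <- data.frame(family = "RRM", start = 41, end = 60)
  grp <- ortholog_group(lapply(1:4, function(i)
    make_protein(paste0("i", i), 100, domains = dom,
                 disorder = c(rep(0.9, 40), rep(0.2, 20), rep(0.9, 40)))))
  res <- idr_segment_conservation(grp)
  expect_true(all(res$segments$ratio[res$segments$is_idr] == 0))
  expect_equal(res$mean_ratio, 0)
})

test_that("IDR segment statistics match a hand computation", {
  # N-terminal segment: 20 vs 40 disordered residues across two orthologs
  a <- make_protein("a", 100,
                    domains = data.frame(family = "RRM", start = 41, end = 60),
                    disorder = c(rep(0.9, 20), rep(0.45, 20), rep(0.2, 20),
                                 rep(0.3, 40)))
  b <- make_protein("b", 140,
                    domains = data.frame(family = "RRM", start = 61, end = 80),
                    disorder = c(rep(0.9, 40), rep(0.45, 20), rep(0.2, 20),
                                 rep(0.3, 60)))
  res <- idr_segment_conservation(ortholog_group(list(a, b)))
  nseg <- res$segments[res$segments$segment == "N", ]
  expect_true(nseg$is_idr)
  expect_equal(nseg$mean_count, 30)
  expect_equal(nseg$sd_count, sqrt((20 - 30)^2 + (40 - 30)^2), tolerance = 1e-4)
  expect_equal(nseg$ratio, 14.14214 / 30, tolerance = 1e-4)
  # C-terminal segment: average disorder 0.3 < 0.5, excluded
  cseg <- res$segments[res$segments$segment == "C", ]
  expect_false(cseg$is_idr)
  expect_equal(res$mean_ratio, nseg$ratio)
})

test_that("low-average-disorder or short segments are excluded", {
  dom <- data.frame(family = "RRM", start = 21, end = 90)
  # N segment length 20 >= 15 but disorder 0.4; C segment length 10 < 15
  grp <- ortholog_group(lapply(1:3, function(i)
    make_protein(paste0("s", i), 100, domains = dom,
                 disorder = c(rep(0.4, 20), rep(0.2, 70), rep(0.9, 10)))))
  res <- idr_segment_conservation(grp)
  expect_false(any(res$segments$is_idr))
  expect_true(is.na(res$mean_ratio))
})

test_that("std/mean ratio is invariant under count scaling", {
  mk <- function(id, n_dis, n_ord) {
    L <- n_dis + n_ord + 20
    make_protein(id, L,
                 domains = data.frame(family = "RRM", start = n_dis + n_ord + 1,
                                      end = L),
                 disorder = c(rep(0.9, n_dis), rep(0.55, n_ord), rep(0.2, 20)))
  }
  base <- idr_segment_conservation(ortholog_group(list(mk("a", 20, 10),
                                                       mk("b", 40, 10))))
  scaled <- idr_segment_conservation(ortholog_group(list(mk("a", 60, 30),
                                                         mk("b", 120, 30))))
  expect_equal(base$mean_ratio, scaled$mean_ratio)
})

test_that("conserved_fraction decreases with simulated domain loss", {
  tmpl <- two_domain_template()
  mean_cf <- vapply(c(0, 0.3, 0.7, 1), function(p) {
    mean(vapply(1:12, function(s)
      conserved_fraction(simulate_ortholog_group(tmpl, 10,
                                                 domain_loss_prob = p,
                                                 seed = 100 + s))$fraction,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_cf) < 0))
  expect_equal(mean_cf[1], 1)
  expect_equal(mean_cf[4], 0)
})
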