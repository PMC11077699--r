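counts_of <- function(...) codon_counts(paste(c(...), collapse = ""))

test_that("RSCU follows its definition on hand-computed counts", {
  r <- rscu(counts_of(rep("GCT", 3), "GCC"))
  expect_equal(unname(r[c("GCT", "GCC", "GCA", "GCG")]), c(3, 1, 0, 0))
  # every synonym equally used -> all RSCU 1 among used amino acids
  r2 <- rscu(counts_of("GCT", "GCC", "GCA", "GCG", "AAA", "AAG"))
  expect_true(all(abs(r2[c("GCT", "GCC", "GCA", "GCG", "AAA", "AAG")] - 1) < 1e-12))
  # single-codon amino acids always have RSCU 1 when present
  r3 <- rscu(counts_of("ATG", "TGG"))
  expect_equal(unname(r3[c("ATG", "TGG")]), c(1, 1))
})

test_that("RSCU sums per synonym family equal the degeneracy", {
  aa <- Biostrings::GENETIC_CODE
  fam <- split(names(aa)[aa != "*"], aa[aa != "*"])
  set.seed(77)
  for (rep_i in 1:50) {
    counts <- setNames(rpois(61, 3), names(aa)[aa != "*"])
    r <- rscu(counts)
    for (a in names(fam)) {
      if (sum(counts[fam[[a]]]) == 0) next
      expect_equal(sum(r[fam[[a]]]), length(fam[[a]]), tolerance = 1e-9)
    }
  }
})

test_that("ENC reaches its limits and handles missing information", {
  aa <- Biostrings::GENETIC_CODE
  one_per <- tapply(names(aa)[aa != "*"], aa[aa != "*"], `[`, 1)
  gene20 <- paste(rep(one_per, 10), collapse = "")
  expect_equal(enc(codon_counts(gene20)), 20)
  expect_true(is.na(enc(counts_of(rep("ATG", 5), rep("TGG", 5)))))
  # uniform synonym usage on a long gene approaches the 61 asymptote
  set.seed(123)
  unif <- paste(sample(names(aa)[aa != "*"], 3000, TRUE), collapse = "")
  e <- enc(codon_counts(unif))
  expect_gte(e, 59); expect_lte(e, 61)
})

test_that("ENC equals an independent transcription of Wright's formula", {
  for (seed in 1:10) {
    counts <- codon_counts(random_cds(120, seed))
    expect_equal(enc(counts), oracle_enc(counts), tolerance = 1e-12)
  }
})

test_that("CAI is the geometric mean of reference weights", {
  w <- cai_weights(setNames(rep(1L, 61), names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]))
  expect_true(all(w == 1))
  counts <- counts_of("GCT", "AAA")
  expect_equal(cai(counts, w), 1)
  w2 <- w; w2[c("GCT", "AAA")] <- 0.5
  expect_equal(cai(counts, w2), 0.5)
  w3 <- w; w3["GCT"] <- 1; w3["AAA"] <- 0.25
  expect_equal(cai(counts, w3), 0.5)  # sqrt(1 * 0.25)
  w4 <- w; w4["GCT"] <- 0
  expect_error(cai(counts, w4), "smoothing")
})

test_that("CBI and Fop match the closed forms", {
  opt <- "GCT"
  counts <- counts_of(rep("GCT", 6), rep("GCC", 2))
  r <- cbi_fop(counts, opt)
  expect_equal(r$fop, 0.75)
  expect_equal(r$cbi, (6 - 2) / (8 - 2))
  all_opt <- cbi_fop(counts_of(rep("GCT", 10)), opt)
  expect_equal(all_opt$fop, 1)
  expect_equal(all_opt$cbi, 1)
  # uniform usage with one optimal codon per family: CBI near 0
  unif <- counts_of(rep(c("GCT", "GCC", "GCA", "GCG"), 50))
  expect_lt(abs(cbi_fop(unif, opt)$cbi), 1e-9)
})

test_that("third-position composition excludes Met, Trp and stops", {
  r <- third_position_composition(counts_of(rep("GCC", 5)))
  expect_equal(r$c3s, 1); expect_equal(r$gc3s, 1)
  r2 <- third_position_composition(counts_of(rep("GCA", 5)))
  expect_equal(r2$a3s, 1); expect_equal(r2$gc3s, 0)
  r3 <- third_position_composition(counts_of("ATG", "TGG"))
  expect_true(is.na(r3$a3s) && is.na(r3$gc3s))
  expect_equal(r3$gc, 3 / 6)
  r4 <- third_position_composition(counts_of("GCA", "GCC", "GCG", "GCT"))
  expect_equal(r4$a3s + r4$t3s + r4$g3s + r4$c3s, 1, tolerance = 1e-9)
})

test_that("optimal codons are the pooled RSCU > 1 set", {
  unif <- rep(list(counts_of(rep(c("GCT", "GCC", "GCA", "GCG"), 3))), 2)
  expect_length(optimal_codons(unif), 0L)
  skew <- list(counts_of(rep("GCT", 9), "GCC"))
  expect_identical(optimal_codons(skew), "GCT")
})

test_that("a strongly biased synthetic family recovers the designated codon set", {
  set.seed(31)
  cds_set <- setNames(lapply(1:12, function(i) {
    reverse_translate(random_protein(300, i), bias = 0.8)
  }), paste0("g", 1:12))
  opt <- optimal_codons(unlist(cds_set))
  designated <- pcfam:::PC_DESIGNATED_CODON
  multi <- designated[!names(designated) %in% c("M", "W")]
  expect_true(all(multi %in% opt))
  expect_true(all(opt %in% designated))
})

test_that("index correlations reproduce the expected directionality", {
  set.seed(47)
  biases <- seq(0.02, 0.92, length.out = 30)
  cds_set <- setNames(lapply(seq_along(biases), function(i) {
    reverse_translate(random_protein(400, 1000 + i), bias = biases[i])
  }), paste0("g", seq_along(biases)))
  prof <- codon_usage_profiles(cds_set)
  m <- index_correlations(prof)
  expect_true(all(abs(diag(m) - 1) < 1e-12))
  expect_gt(m["gc3s", "g3s"], 0)
  expect_gt(m["gc3s", "c3s"], 0)
  expect_lt(m["gc3s", "a3s"], 0)
  expect_lt(m["gc3s", "t3s"], 0)
  expect_gt(m["fop", "cai"], 0)
  expect_gt(m["fop", "cbi"], 0)
})

test_that("zero-variance columns give NA correlations, not errors", {
  prof <- tibble::tibble(a3s = c(1, 1, 1), t3s = c(0.2, 0.4, 0.3),
                         g3s = c(0.1, 0.2, 0.3), c3s = c(0.3, 0.1, 0.2),
                         gc3s = c(0.4, 0.3, 0.5), gc = c(0.5, 0.5, 0.6),
                         cai = c(0.7, 0.8, 0.9), cbi = c(0.1, 0.2, 0.3),
                         fop = c(0.5, 0.6, 0.7), enc = c(45, 50, 55))
  m <- index_correlations(prof)
  expect_true(all(is.na(m["a3s", setdiff(colnames(m), "a3s")])))
})

test_that("codon rendering can switch to RNA spelling", {
  x <- c(GCT = 1.2, TTT = 0.8)
  expect_identical(names(render_codons(x)), c("GCU", "UUU"))
})
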