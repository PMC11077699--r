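test_that("NG86 site counts match per-codon enumeration", {
  s <- ng86_sites("TTT")
  expect_equal(s[["S"]], 1 / 3, tolerance = 1e-12)
  expect_equal(s[["N"]], 8 / 3, tolerance = 1e-12)
  g <- ng86_sites("GGG")
  expect_equal(g[["S"]], 1); expect_equal(g[["N"]], 2)
  m <- ng86_sites("ATG")
  expect_equal(m[["S"]], 0); expect_equal(m[["N"]], 3)
})

test_that("S + N always totals three sites per compared codon", {
  for (seed in 1:10) {
    cds <- random_cds(40, seed)
    s <- ng86_sites(cds)
    expect_equal(s[["S"]] + s[["N"]], 3 * 40, tolerance = 1e-6)
  }
})

test_that("codons with ambiguous bases are excluded and logged", {
  s <- ng86_sites("ATGNNNGGG")
  expect_equal(attr(s, "n_excluded"), 1L)
  expect_equal(s[["S"]] + s[["N"]], 6)
})

test_that("difference counting matches simple single-step cases", {
  expect_equal(as.numeric(ng86_differences("GGG", "GGG")), c(0, 0))
  d <- ng86_differences("GGG", "GGC")
  expect_equal(d[["Sd"]], 1); expect_equal(d[["Nd"]], 0)
  d2 <- ng86_differences("TTT", "GTA")
  o2 <- oracle_ng86_differences("TTT", "GTA")
  expect_equal(d2[["Sd"]], o2[["Sd"]], tolerance = 1e-12)
  expect_equal(d2[["Nd"]], o2[["Nd"]], tolerance = 1e-12)
})

test_that("pathway averaging equals the exhaustive enumeration oracle", {
  set.seed(55)
  for (rep_i in 1:60) {
    a <- random_cds(30)
    b <- mutate_pair(a, sample(0:4, 1), sample(0:4, 1),
                     seed = sample.int(1e6, 1))$cds
    # add a couple of raw substitutions so multi-step codons occur
    pos <- sample(4:nchar(b), 3)
    for (p in pos) substr(b, p, p) <- sample(c("A", "C", "G", "T"), 1)
    if (grepl("TAA|TAG|TGA", paste0(substring(b, seq(1, nchar(b), 3),
                                              seq(3, nchar(b), 3)),
                                    collapse = "|"))) next
    d <- ng86_differences(a, b)
    o <- oracle_ng86_differences(a, b)
    expect_equal(d[["Sd"]], o[["Sd"]], tolerance = 1e-9)
    expect_equal(d[["Nd"]], o[["Nd"]], tolerance = 1e-9)
    s <- ng86_sites(a); os <- oracle_ng86_sites(a)
    expect_equal(s[["S"]], os[["S"]], tolerance = 1e-9)
  }
})

test_that("Ka/Ks reproduces the fourfold-site closed form", {
  a <- strrep("GGG", 10)
  b <- paste0(strrep("GGG", 9), "GGC")
  r <- kaks(a, b)
  expect_equal(r$ps, 0.1, tolerance = 1e-12)
  expect_equal(r$Ks, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(r$Ka, 0)
  expect_identical(r$selection_class, "purifying")
})

test_that("identical sequences give zero distances and an undefined class", {
  a <- random_cds(100, seed = 8)
  r <- kaks(a, a)
  expect_equal(r$Ks, 0); expect_equal(r$Ka, 0)
  expect_true(is.na(r$ratio))
  expect_identical(r$selection_class, "undefined")
})

test_that("kaks is symmetric in argument order", {
  a <- random_cds(60, seed = 13)
  b <- mutate_pair(a, 8, 4, seed = 99)$cds
  r1 <- kaks(a, b); r2 <- kaks(b, a)
  for (col in c("S", "N", "Sd", "Nd", "ps", "pn", "Ks", "Ka", "ratio")) {
    expect_equal(r1[[col]], r2[[col]], tolerance = 1e-12)
  }
})

test_that("mutation regimes order the Ka/Ks ratio as expected", {
  a <- random_cds(300, seed = 17)
  pur <- kaks(a, mutate_pair(a, 5, 1, seed = 1)$cds)
  expect_lt(pur$ratio, 1)
  expect_identical(pur$selection_class, "purifying")
  pos <- kaks(a, mutate_pair(a, 1, 15, seed = 2)$cds)
  expect_gt(pos$ratio, 1)
  expect_identical(pos$selection_class, "positive")
})

test_that("mean Ka/Ks orders correctly across divergence regimes", {
  a <- random_cds(120, seed = 23)
  ratios <- function(syn, nonsyn) {
    vapply(1:15, function(s) {
      kaks(a, mutate_pair(a, syn, nonsyn, seed = 3000 + s)$cds)$ratio
    }, numeric(1))
  }
  low <- mean(ratios(8, 1))
  mid <- mean(ratios(4, 4))
  high <- mean(ratios(1, 12))
  expect_lt(low, mid)
  expect_lt(mid, high)
})

test_that("saturated proportions give missing distances", {
  expect_true(is.na(pcfam:::jukes_cantor(0.8)))
})

test_that("tandem clusters follow the distance and intervening-gene rules", {
  genes <- tibble::tibble(
    gene_id = c("f1", "f2"), chromosome = "chr1",
    start = c(1000L, 11000L), end = c(2000L, 12000L), strand = "+")
  cl <- tandem_clusters(genes, c("f1", "f2"))
  expect_equal(nrow(cl), 1L)
  expect_identical(cl$members, "f1;f2")

  far <- tibble::tibble(
    gene_id = c("f1", "f2"), chromosome = c("chr1", "chr2"),
    start = c(1000L, 2000L), end = c(1500L, 2500L), strand = "+")
  expect_equal(nrow(tandem_clusters(far, c("f1", "f2"))), 0L)

  three <- tibble::tibble(
    gene_id = c("f1", "f2", "f3"), chromosome = "chr1",
    start = c(0L, 100000L, 600000L), end = c(500L, 100500L, 600500L),
    strand = "+")
  cl3 <- tandem_clusters(three, c("f1", "f2", "f3"))
  expect_equal(nrow(cl3), 1L)
  expect_equal(cl3$n_members, 2L)
  expect_identical(cl3$members, "f1;f2")
})

test_that("too many intervening non-family genes break a chain", {
  fam_genes <- tibble::tibble(
    gene_id = c("f1", paste0("x", 1:6), "f2"), chromosome = "chr1",
    start = seq(1000L, by = 1000L, length.out = 8L),
    end = seq(1400L, by = 1000L, length.out = 8L), strand = "+")
  expect_equal(nrow(tandem_clusters(fam_genes, c("f1", "f2"))), 0L)
  expect_equal(nrow(tandem_clusters(fam_genes, c("f1", "f2"),
                                    max_intervening = 6L)), 1L)
})

test_that("the generated duplicate pairs are the only tandem clusters", {
  fam <- small_family()
  members <- fam$truth$gene_id
  cl <- tandem_clusters(fam$genes, members)
  expect_equal(nrow(cl), nrow(fam$pairs))
  expect_setequal(
    cl$members,
    paste(fam$pairs$gene_a, fam$pairs$gene_b, sep = ";"))
})
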