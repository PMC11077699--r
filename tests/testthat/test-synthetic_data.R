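test_that("generate_family is byte-identical under a fixed seed", {
  cfg <- family_sim_config(n_genes = 12L, n_chromosomes = 3L, seed = 7L,
                           pair_divergence = list(c(0.05, 0.01)))
  a <- generate_family(cfg)
  b <- generate_family(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$genes, b$genes)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth, b$truth)
  expect_identical(a$elements, b$elements)
})

test_that("a pure-SCL family plants Gln at every fourth ligand slot", {
  cfg <- family_sim_config(
    n_genes = 10L, n_chromosomes = 2L, seed = 3L,
    subfamily_mix = c(SCL = 1, UCL = 0, PLCL = 0, ENODL = 0),
    pair_divergence = list())
  fam <- generate_family(cfg)
  expect_true(all(fam$truth$subfamily == "SCL"))
  expect_true(all(grepl("Q:\\d+$", fam$truth$ligands)))
  z <- vapply(seq_len(nrow(fam$truth)), function(i) {
    pos <- as.integer(sub(".*Q:(\\d+)$", "\\1", fam$truth$ligands[i]))
    substr(fam$proteins[[fam$truth$gene_id[i]]], pos, pos)
  }, character(1))
  expect_true(all(z == "Q"))
})

test_that("an incompatible subfamily/type mix is a config error", {
  cfg <- family_sim_config(
    n_genes = 10L, n_chromosomes = 2L,
    subfamily_mix = c(PLCL = 1, UCL = 0, SCL = 0, ENODL = 0),
    type_mix = c(I = 0, II = 1, III = 0, IV = 0, V = 0, VI = 0, VII = 0,
                 VIII = 0),
    pair_divergence = list())
  expect_error(generate_family(cfg), "ALR-free")
})

test_that("planted promoter elements appear exactly at truth positions", {
  cfg <- family_sim_config(n_genes = 6L, n_chromosomes = 2L, seed = 5L,
                           planted_elements = c("G-box" = 3L),
                           pair_divergence = list())
  fam <- generate_family(cfg)
  dict <- default_element_dictionary()
  for (i in seq_len(nrow(fam$genes))) {
    g <- fam$genes[i, ]
    prom <- extract_promoter(g, fam$genome, 2000L)$sequence
    hits <- scan_promoter(prom, dict[dict$name == "G-box", ])
    expect_equal(nrow(hits), 3L)
    truth <- fam$elements[fam$elements$gene_id == g$gene_id, ]
    expect_setequal(hits$start, truth$start)
    expect_true(all(hits$match == "CACGTG"))
  }
})

test_that("domain truth spans stay inside the protein and ligands inside the PLCD", {
  fam <- small_family()
  for (i in seq_len(nrow(fam$truth))) {
    row <- fam$truth[i, ]
    L <- row$protein_length
    spans <- strsplit(row$plcd_spans, ";")[[1]]
    ligs <- strsplit(row$ligands, ";")[[1]]
    for (j in seq_along(spans)) {
      se <- as.integer(strsplit(spans[j], "-")[[1]])
      expect_true(se[1] >= 1 && se[2] <= L)
      pos <- suppressWarnings(as.integer(
        sub(".*:", "", strsplit(ligs[j], ",")[[1]])))
      pos <- pos[!is.na(pos)]
      expect_true(all(pos >= se[1] & pos <= se[2]))
      expect_true(all(diff(pos) > 0))
    }
  }
})

test_that("mutate_pair with zero requests is the identity", {
  cds <- random_cds(50, seed = 9)
  out <- mutate_pair(cds, 0, 0, seed = 1)
  expect_identical(out$cds, cds)
  expect_equal(nrow(out$log), 0L)
})

test_that("mutate_pair makes one third-position change in a fourfold codon run", {
  cds <- strrep("GGG", 10)
  out <- mutate_pair(cds, 1, 0, seed = 4)
  expect_equal(nrow(out$log), 1L)
  expect_equal(out$log$category, "synonymous")
  expect_equal(out$log$position %% 3, 0)
  expect_equal(sum(strsplit(cds, "")[[1]] != strsplit(out$cds, "")[[1]]), 1L)
})

test_that("mutate_pair logs recount as codon-by-codon differences vs the code", {
  for (seed in 1:5) {
    cds <- random_cds(80, seed = seed)
    out <- mutate_pair(cds, 6, 3, seed = seed + 100)
    expect_equal(nrow(out$log), 9L)
    ca <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    cb <- substring(out$cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    changed <- which(ca != cb)
    expect_setequal(changed, out$log$codon_index)
    syn <- vapply(changed, function(i) {
      oracle_aa(ca[i]) == oracle_aa(cb[i])
    }, logical(1))
    expect_equal(sum(syn), 6L)
    expect_equal(sum(!syn), 3L)
    expect_false(any(cb %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("mutate_pair reports infeasible requests with the shortfall", {
  expect_error(mutate_pair("ATGTGGATG", 2, 0, seed = 1),
               "short by 2 synonymous")
})

test_that("noise-free Ct tables recover the planted folds exactly", {
  folds <- matrix(c(1, 4, 0.5), nrow = 2, ncol = 3, byrow = TRUE)
  sim <- generate_ct_table(2, 3, folds, noise_sd = 0, replicates = 2,
                           seed = 11)
  rec <- delta_delta_ct(sim$ct, calibrator = "DAF1")
  expect_equal(rec$DAF1, c(1, 1))
  expect_equal(rec$DAF5, c(4, 4))
  expect_equal(rec$DAF9, c(0.5, 0.5))
})

test_that("mean recovered fold over many noisy genes is within 10% of truth", {
  sim <- generate_ct_table(200, 2, matrix(c(1, 4), 200, 2, byrow = TRUE),
                           noise_sd = 0.2, replicates = 3, seed = 21)
  rec <- delta_delta_ct(sim$ct, calibrator = "DAF1")
  expect_lt(abs(mean(rec$DAF5) - 4) / 4, 0.10)
})

test_that("non-positive fold changes are rejected", {
  expect_error(generate_ct_table(2, 2, matrix(c(1, -2), 2, 2), seed = 1),
               "positive")
})

test_that("the family bundle writes and reads back consistently", {
  fam <- small_family()
  dir <- withr::local_tempdir()
  write_family_bundle(fam, dir)
  genome <- read_fasta(file.path(dir, "genome.fna"))
  expect_identical(genome, fam$genome)
  genes <- read_gff3(file.path(dir, "genes.gff3"))
  expect_equal(genes$gene_id, fam$genes$gene_id)
  prot <- read_fasta(file.path(dir, "proteins.faa"))
  expect_identical(prot, fam$proteins)
})
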