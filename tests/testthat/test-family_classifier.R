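# hand-built protein fragments for the detectors
plcd_fragment <- function(z, filler = "E") {
  paste0("H", strrep(filler, 30), "C", strrep(filler, 9), "C",
         strrep(filler, 5), "H", strrep(filler, 5), z)
}

test_that("signal peptides need a Met start and a hydrophobic core", {
  with_sp <- paste0("M", strrep("L", 8), strrep("D", 30))
  expect_false(is.null(detect_signal_peptide(with_sp)))
  no_core <- paste0("M", strrep("D", 40))
  expect_null(detect_signal_peptide(no_core))
  no_met <- paste0("A", strrep("L", 8), strrep("D", 30))
  expect_null(detect_signal_peptide(no_met))
})

test_that("complete PLCD sites report ordered ligand sets ending in M or Q", {
  for (z in c("M", "Q")) {
    p <- paste0(strrep("E", 10), plcd_fragment(z), strrep("D", 30))
    sites <- detect_plcd(p)
    expect_equal(length(sites), 1L)
    expect_true(sites[[1]]$complete)
    lig <- sites[[1]]$ligands
    expect_identical(lig$residue[lig$slot == "Z"], z)
    expect_true(all(diff(lig$position) > 0))
    expect_identical(lig$residue[1:3][order(lig$position[1:3])][1], "H")
  }
})

test_that("an ENODL block with a non-ligand fourth slot is an incomplete site", {
  p <- paste0(strrep("E", 10), plcd_fragment("A"), strrep("D", 30))
  sites <- detect_plcd(p)
  expect_equal(length(sites), 1L)
  expect_false(sites[[1]]$complete)
  lig <- sites[[1]]$ligands
  expect_true(sum(!is.na(lig$position)) >= 2L)
})

test_that("two planted blocks give two ordered PLCD sites", {
  p <- paste0(strrep("E", 6), plcd_fragment("M"), strrep("E", 8),
              plcd_fragment("M"), strrep("D", 10))
  sites <- detect_plcd(p)
  expect_equal(length(sites), 2L)
  expect_lt(sites[[1]]$span[2], sites[[2]]$span[1])
})

test_that("ALR detection needs a PAST-rich run outside excluded spans", {
  alr <- paste(rep(c("P", "A", "S", "D", "T"), 6), collapse = "")  # 80% PAST
  p <- paste0(strrep("E", 30), alr, strrep("D", 30))
  span <- detect_alr(p)
  expect_false(is.null(span))
  expect_gte(span[2] - span[1] + 1L, 20L)
  expect_null(detect_alr(strrep("L", 80)))
  expect_null(detect_alr(p, excluded = list(c(25L, 70L))))
})

test_that("GAS detection requires a hydrophobic tail and a small omega residue", {
  good <- paste0(strrep("D", 40), "EKG", strrep("E", 8), strrep("L", 12))
  span <- detect_gas(good)
  expect_false(is.null(span))
  expect_identical(substr(good, span[1], span[1]), "G")
  hydrophilic_tail <- paste0(strrep("D", 40), "G", strrep("E", 22))
  expect_null(detect_gas(hydrophilic_tail))
  no_omega <- paste0(strrep("D", 20), strrep("L", 40))
  expect_null(detect_gas(no_omega))
})

test_that("N-glycosylation sequons follow the N-X-S/T with X != P rule", {
  expect_equal(find_nglyc_sites("NGS"), 1L)
  expect_equal(find_nglyc_sites("NPS"), integer(0))
  expect_equal(find_nglyc_sites("NGSNGT"), c(1L, 4L))
})

dom <- function(sp = NULL, plcds = list(), alr = NULL, gas = NULL) {
  list(protein_id = "p", sp = sp, plcds = plcds, alr = alr, gas = gas,
       nglyc_sites = integer(0))
}
site <- function(z, complete = !is.na(z)) {
  list(span = c(10L, 63L),
       ligands = tibble::tibble(slot = c("H1", "C", "H2", "Z"),
                                residue = c("H", "C", "H", z),
                                position = c(10L, 51L, 57L,
                                             if (is.na(z)) NA_integer_ else 63L)),
       complete = complete)
}

test_that("subfamily assignment follows the copper-ligand rules", {
  expect_identical(assign_subfamily(dom(plcds = list(site("M")),
                                        alr = c(70L, 99L))), "UCL")
  expect_identical(assign_subfamily(dom(plcds = list(site("M")))), "PLCL")
  expect_identical(assign_subfamily(dom(plcds = list(site("Q")))), "SCL")
  expect_identical(assign_subfamily(dom(plcds = list(site(NA_character_)))),
                   "ENODL")
  expect_error(assign_subfamily(dom()), "not a phytocyanin")
})

test_that("type assignment matches the canonical table exhaustively", {
  expected <- function(sp, n, alr, gas) {
    key <- paste(sp, n, alr, gas)
    switch(key,
           "TRUE 2 TRUE TRUE" = "I", "TRUE 1 TRUE TRUE" = "II",
           "TRUE 1 TRUE FALSE" = "III", "TRUE 1 FALSE FALSE" = "IV",
           "TRUE 1 FALSE TRUE" = "V", "FALSE 1 TRUE TRUE" = "VI",
           "FALSE 2 TRUE TRUE" = "VII", "FALSE 1 FALSE FALSE" = "VIII",
           "UNCLASSIFIED")
  }
  for (sp in c(TRUE, FALSE)) {
    for (n in 1:2) {
      for (alr in c(TRUE, FALSE)) {
        for (gas in c(TRUE, FALSE)) {
          d <- dom(sp = if (sp) c(1L, 15L) else NULL,
                   plcds = rep(list(site("M")), n),
                   alr = if (alr) c(70L, 99L) else NULL,
                   gas = if (gas) c(120L, 142L) else NULL)
          expect_identical(assign_type(d), expected(sp, n, alr, gas),
                           info = paste(sp, n, alr, gas))
        }
      }
    }
  }
})

test_that("AGP classes follow the type-based rules", {
  d2 <- dom(sp = c(1L, 15L), plcds = list(site("M")), alr = c(70L, 99L),
            gas = c(120L, 142L))
  r <- assign_agp_class(d2, "II")
  expect_identical(r$agp_class, "typical_AGP")
  expect_true(r$chimeric_agp)
  d6 <- dom(plcds = list(site("M")), alr = c(70L, 99L), gas = c(120L, 142L))
  r <- assign_agp_class(d6, "VI")
  expect_identical(r$agp_class, "atypical_AGP")
  expect_false(r$chimeric_agp)
  d4 <- dom(sp = c(1L, 15L), plcds = list(site("M")))
  expect_identical(assign_agp_class(d4, "IV")$agp_class, "non_AGP")
})

test_that("members are named by subfamily in chromosome order", {
  ucl <- paste0("M", strrep("L", 9), strrep("N", 5), strrep("E", 5),
                plcd_fragment("M"),
                paste(rep(c("P", "A", "S", "T", "D"), 6), collapse = ""),
                strrep("D", 20))
  proteins <- c(gB = ucl, gA = ucl)
  genes <- tibble::tibble(gene_id = c("gB", "gA"),
                          chromosome = c("chr3", "chr1"),
                          start = c(100L, 100L), end = c(700L, 700L),
                          strand = c("+", "+"))
  out <- classify(proteins, genes, mode = "heuristic_scan")
  expect_identical(out$assigned_name[out$protein_id == "gA"], "UCL1")
  expect_identical(out$assigned_name[out$protein_id == "gB"], "UCL2")
})

test_that("truth mode recovers every planted subfamily and type", {
  fam <- small_family()
  out <- classify(fam$proteins, fam$genes, mode = "truth_annotation",
                  annotations = fam$truth)
  tr <- fam$truth[match(out$protein_id, fam$truth$gene_id), ]
  expect_true(all(out$member))
  expect_identical(out$subfamily, tr$subfamily)
  expect_identical(out$type, tr$type)
})

test_that("heuristic mode agrees with the planted truth on a generated family", {
  fam <- small_family()
  out <- classify(fam$proteins, fam$genes, mode = "heuristic_scan")
  tr <- fam$truth[match(out$protein_id, fam$truth$gene_id), ]
  agree <- mean(out$subfamily == tr$subfamily & out$type == tr$type)
  expect_gte(agree, 0.99)
})

test_that("subfamily counts partition the PLCD-bearing proteins", {
  fam <- small_family()
  out <- classify(fam$proteins, fam$genes, mode = "heuristic_scan")
  mem <- out[out$member, ]
  expect_equal(sum(mem$subfamily == "UCL") + sum(mem$subfamily == "SCL") +
                 sum(mem$subfamily == "PLCL") + sum(mem$subfamily == "ENODL"),
               nrow(mem))
})

test_that("proteins without a PLCD are reported as non-members", {
  junk <- strrep("DEKRG", 40)
  genes <- tibble::tibble(gene_id = "x", chromosome = "chr1", start = 1L,
                          end = 600L, strand = "+")
  out <- classify(c(x = junk), genes, mode = "heuristic_scan")
  expect_equal(nrow(out), 1L)
  expect_false(out$member)
  expect_true(is.na(out$subfamily))
})
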