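# Synthetic phytocyanin families with planted ground truth: multi-chromosome
# genomes, proteins built from domain templates, promoters with planted
# cis-elements, duplicate gene pairs with controlled synonymous /
# nonsynonymous divergence, and qPCR Ct tables with known fold changes.
#
# All randomness flows from one integer seed through a named substream per
# output unit, so adding genes never perturbs existing ones.

# Deterministic substream seed (< 2^31) from a master seed and unit ids.
substream <- function(seed, ...) {
  x <- as.double(seed %% 1000003L)
  for (i in c(...)) {
    x <- (x * 7919 + as.double(i) * 104729 + 12345) %% 2147483629
  }
  as.integer(x)
}

# residue pools used by the protein templates
PC_FILLER   <- c("D", "E", "N", "K", "R", "G")   # hydrophilic, ligand-free
PC_SP_HYD   <- c("L", "V", "I", "F")
PC_SP_POLAR <- c("N", "S", "T")
PC_PAST     <- c("P", "A", "S", "T")
PC_GAS_MID  <- c("E", "K", "R", "T")
PC_GAS_TAIL <- c("L", "V", "I", "F")
PC_OMEGA    <- c("G", "A", "S", "N")

# A/T-leaning designated codon per amino acid for biased reverse translation.
PC_DESIGNATED_CODON <- c(
  F = "TTT", L = "TTG", I = "ATT", V = "GTT", S = "TCA", P = "CCA",
  T = "ACT", A = "GCT", Y = "TAT", H = "CAT", Q = "CAG", N = "AAT",
  K = "AAG", E = "GAA", R = "AGA", D = "GAT", C = "TGT", G = "GGA",
  M = "ATG", W = "TGG"
)

codons_by_aa <- function() {
  gc <- genetic_code()
  split(names(gc), gc)[setdiff(unique(gc), "*")]
}

ALR_FREE_TYPES <- c("IV", "V", "VIII")
ALR_TYPES <- c("I", "II", "III", "VI", "VII")

#' Configuration for a synthetic phytocyanin family
#'
#' Defaults emulate the organisation reported for the apple family: 59
#' genes over 12 chromosomes, subfamily sizes 33/13/9/4
#' (ENODL/UCL/SCL/PLCL), 50 signal peptides, 42 GPI anchors, 34 typical
#' and 17 atypical AGPs, moderate codon bias, and a few tandem duplicate
#' pairs under predominantly synonymous divergence.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of chromosomes.
#' @param subfamily_mix Named proportions over UCL, SCL, PLCL, ENODL
#'   (must sum to 1).
#' @param type_mix Named proportions over types I-VIII (must sum to 1).
#' @param cds_length_range Integer pair, protein length range in codons
#'   (>= 120 so planted domains fit).
#' @param codon_bias_strength Probability mass placed on the designated
#'   codon of each amino acid, in [0, 1].
#' @param planted_elements Named integer vector: cis-element copies planted
#'   per promoter.
#' @param pair_divergence List of numeric pairs (target proportion of
#'   synonymous sites mutated, target proportion of nonsynonymous sites
#'   mutated); each entry creates one duplicate gene pair.
#' @param gene_spacing Intergenic spacing in bp between unrelated genes.
#' @param pair_spacing Spacing in bp within a duplicate pair (tandem).
#' @param seed Master integer seed.
#' @return Validated config list.
#' @export
family_sim_config <- function(
    n_genes = 59L,
    n_chromosomes = 12L,
    subfamily_mix = c(ENODL = 33, UCL = 13, SCL = 9, PLCL = 4) / 59,
    type_mix = c(I = 4, II = 30, III = 9, IV = 7, V = 0, VI = 4, VII = 4,
                 VIII = 1) / 59,
    cds_length_range = c(160L, 260L),
    codon_bias_strength = 0.55,
    planted_elements = c("G-box" = 2L, "TGACG-motif" = 1L, "MBS" = 1L,
                         "LTR" = 1L),
    pair_divergence = list(c(0.10, 0.01), c(0.15, 0.02), c(0.05, 0.005)),
    gene_spacing = 300000L,
    pair_spacing = 10000L,
    seed = 1L) {
  stopifnot(n_genes >= 1L, n_chromosomes >= 1L)
  stopifnot(setequal(names(subfamily_mix), c("UCL", "SCL", "PLCL", "ENODL")))
  stopifnot(setequal(names(type_mix),
                     c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")))
  if (abs(sum(subfamily_mix) - 1) > 1e-9) stop("subfamily_mix must sum to 1")
  if (abs(sum(type_mix) - 1) > 1e-9) stop("type_mix must sum to 1")
  if (cds_length_range[1] < 120L) stop("cds lengths must be >= 120 codons")
  stopifnot(cds_length_range[1] <= cds_length_range[2])
  stopifnot(codon_bias_strength >= 0, codon_bias_strength <= 1)
  if (2L * length(pair_divergence) > n_genes) {
    stop("too many duplicate pairs for n_genes")
  }
  list(n_genes = as.integer(n_genes),
       n_chromosomes = as.integer(n_chromosomes),
       subfamily_mix = subfamily_mix, type_mix = type_mix,
       cds_length_range = as.integer(cds_length_range),
       codon_bias_strength = codon_bias_strength,
       planted_elements = planted_elements,
       pair_divergence = pair_divergence,
       gene_spacing = as.integer(gene_spacing),
       pair_spacing = as.integer(pair_spacing),
       seed = as.integer(seed))
}

# Largest-remainder rounding of proportions to integer counts summing to n.
round_counts <- function(props, n) {
  raw <- props * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  stats::setNames(as.integer(cnt), names(props))
}

# Jointly assign subfamilies and types under the structural constraints:
# PLCL members need an ALR-free type, UCL members an ALR-bearing type.
assign_subfamily_types <- function(config) {
  sub_cnt <- round_counts(config$subfamily_mix, config$n_genes)
  type_cnt <- round_counts(config$type_mix, config$n_genes)
  avail <- type_cnt
  take <- function(pool, k) {
    got <- character(0)
    for (t in pool) {
      m <- min(avail[[t]], k - length(got))
      if (m > 0) {
        got <- c(got, rep(t, m))
        avail[[t]] <<- avail[[t]] - m
      }
      if (length(got) == k) break
    }
    got
  }
  plcl <- take(ALR_FREE_TYPES, sub_cnt[["PLCL"]])
  if (length(plcl) < sub_cnt[["PLCL"]]) {
    stop("config error: type_mix incompatible with subfamily_mix ",
         "(PLCL requires an ALR-free type; short by ",
         sub_cnt[["PLCL"]] - length(plcl), ")")
  }
  ucl <- take(ALR_TYPES, sub_cnt[["UCL"]])
  if (length(ucl) < sub_cnt[["UCL"]]) {
    stop("config error: type_mix incompatible with subfamily_mix ",
         "(UCL requires an ALR-bearing type; short by ",
         sub_cnt[["UCL"]] - length(ucl), ")")
  }
  scl <- take(c(ALR_TYPES, ALR_FREE_TYPES), sub_cnt[["SCL"]])
  enodl <- take(c(ALR_TYPES, ALR_FREE_TYPES), sub_cnt[["ENODL"]])
  tibble::tibble(
    subfamily = rep(c("PLCL", "UCL", "SCL", "ENODL"),
                    c(length(plcl), length(ucl), length(scl), length(enodl))),
    type = c(plcl, ucl, scl, enodl)
  )
}

type_features <- function(type) {
  row <- TYPE_TABLE[TYPE_TABLE$type == type, ]
  list(sp = row$sp, n_plcd = row$n_plcd, alr = row$alr, gas = row$gas)
}

# Build one protein from the domain templates. Returns the residue vector
# plus truth spans, ligand positions and protected (mutation-critical)
# residue positions.
build_protein <- function(subfamily, type, target_len) {
  feat <- type_features(type)
  z_res <- switch(subfamily,
                  UCL = "M", PLCL = "M", SCL = "Q",
                  ENODL = sample(PC_OMEGA[PC_OMEGA != "N"], 1))
  res <- character(0)
  protected <- integer(0)
  sp_span <- c(NA_integer_, NA_integer_)
  if (feat$sp) {
    res <- c("M", sample(PC_SP_HYD, 10, TRUE), sample(PC_SP_POLAR, 4, TRUE))
    sp_span <- c(1L, 15L)
  } else {
    res <- c("M", sample(PC_FILLER, 5, TRUE))
  }
  res <- c(res, sample(PC_FILLER, 5, TRUE))
  plcd_spans <- list()
  ligands <- list()
  for (b in seq_len(feat$n_plcd)) {
    if (b > 1L) res <- c(res, sample(PC_FILLER, 8, TRUE))
    s <- length(res) + 1L
    block <- c("H", sample(PC_FILLER, 30, TRUE), "C",
               sample(PC_FILLER, 9, TRUE), "C", sample(PC_FILLER, 5, TRUE),
               "H", sample(PC_FILLER, 5, TRUE), z_res)
    res <- c(res, block)
    plcd_spans[[b]] <- c(s, s + 53L)
    lig_pos <- c(H1 = s, C = s + 41L, H2 = s + 47L, Z = s + 53L)
    ligands[[b]] <- lig_pos
    # whole ligand block plus the window where a mutant M/Q could complete
    # (or rewrite) the copper site is treated as conserved
    protected <- c(protected, s:(s + 68L))
  }
  res <- c(res, sample(PC_FILLER, 3, TRUE))
  alr_span <- c(NA_integer_, NA_integer_)
  if (feat$alr) {
    s <- length(res) + 1L
    res <- c(res, sample(c(sample(PC_PAST, 21, TRUE),
                           sample(PC_FILLER, 9, TRUE))))
    alr_span <- c(s, s + 29L)
  }
  tail_len <- if (feat$gas) 25L else 0L
  pad <- max(0L, target_len - length(res) - tail_len)
  res <- c(res, sample(PC_FILLER, pad, TRUE))
  gas_span <- c(NA_integer_, NA_integer_)
  if (feat$gas) {
    res <- c(res, sample(c("E", "K"), 2, TRUE), sample(PC_OMEGA, 1),
             sample(PC_GAS_MID, 10, TRUE), sample(PC_GAS_TAIL, 12, TRUE))
    gas_span <- c(length(res) - 22L, length(res))
    protected <- c(protected, length(res) - 22L)
  }
  protected <- c(1L, protected)  # never mutate the start codon
  list(residues = res, z = if (subfamily == "ENODL") NA_character_ else z_res,
       sp = sp_span, plcd_spans = plcd_spans, ligands = ligands,
       alr = alr_span, gas = gas_span,
       complete = subfamily != "ENODL", protected = protected)
}

#' Reverse-translate a protein with a controlled codon bias
#'
#' Per residue, the designated codon of its amino acid is drawn with
#' probability `bias + (1 - bias)/k` (k = degeneracy) and each other
#' synonym with probability `(1 - bias)/k`.
#'
#' @param protein Amino-acid string or residue vector.
#' @param bias Codon bias strength in [0, 1].
#' @return CDS string (no stop codon).
#' @export
reverse_translate <- function(protein, bias = 0.5) {
  if (length(protein) == 1L) protein <- aa_chars(protein)
  byaa <- codons_by_aa()
  out <- vapply(protein, function(aa) {
    syn <- byaa[[aa]]
    k <- length(syn)
    pr <- rep((1 - bias) / k, k)
    pr[syn == PC_DESIGNATED_CODON[[aa]]] <- bias + (1 - bias) / k
    sample(syn, 1, prob = pr)
  }, character(1))
  paste(out, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

instantiate_iupac <- function(consensus) {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_DNA[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1)
  }, character(1)), collapse = "")
}

`substr<-` <- base::`substr<-`

# Remove every dictionary-element occurrence (both strands) from a random
# background by rerandomizing hit windows until the sequence is clean.
scrub_elements <- function(seq, elements, max_iter = 200L) {
  for (i in seq_len(max_iter)) {
    hits <- scan_promoter(seq, elements)
    if (nrow(hits) == 0L) return(seq)
    for (j in seq_len(nrow(hits))) {
      w <- hits$start[j]:hits$end[j]
      substr(seq, min(w), max(w)) <- random_dna(length(w))
    }
  }
  stop("could not scrub promoter background of dictionary elements")
}

# Build one promoter with `planted` (named counts) element copies at
# recorded positions; the background contains no dictionary element and
# junction artifacts of planted element names are repaired.
plant_promoter <- function(len, planted, elements) {
  seq <- scrub_elements(random_dna(len), elements)
  truth <- list()
  occupied <- integer(0)
  for (name in names(planted)) {
    cons <- elements$consensus[elements$name == name]
    if (length(cons) != 1L) stop("planted element not in dictionary: ", name)
    w <- nchar(cons)
    for (k in seq_len(planted[[name]])) {
      for (try in 1:500) {
        s <- sample.int(len - w + 1L, 1)
        win <- (s - 1L):(s + w)        # one base of margin each side
        win <- win[win >= 1L & win <= len]
        if (!any(win %in% occupied)) break
        if (try == 500) stop("could not place planted elements")
      }
      substr(seq, s, s + w - 1L) <- instantiate_iupac(cons)
      occupied <- c(occupied, (s - 1L):(s + w))
      truth[[length(truth) + 1L]] <- tibble::tibble(
        element = name, start = s, end = s + w - 1L)
    }
  }
  truth <- dplyr::bind_rows(truth)
  # repair junction hits of planted element names at non-truth positions
  core <- unlist(lapply(seq_len(nrow(truth)),
                        function(i) truth$start[i]:truth$end[i]))
  planted_el <- elements[elements$name %in% names(planted), ]
  for (i in 1:100) {
    hits <- scan_promoter(seq, planted_el)
    keyh <- paste(hits$element, hits$start, hits$end)
    keyt <- paste(truth$element, truth$start, truth$end)
    extra <- hits[!(keyh %in% keyt), ]
    if (nrow(extra) == 0L) break
    for (j in seq_len(nrow(extra))) {
      w <- setdiff(extra$start[j]:extra$end[j], core)
      if (length(w) == 0L) next  # fully inside a planted copy: cannot occur
      pos <- w[1]
      old <- substr(seq, pos, pos)
      substr(seq, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  list(sequence = seq, truth = truth)
}

span_str <- function(spans) {
  paste(vapply(spans, function(s) paste0(s[1], "-", s[2]), character(1)),
        collapse = ";")
}

#' Generate a synthetic phytocyanin family with planted ground truth
#'
#' Builds proteins back-to-front from domain templates (optional signal
#' peptide; one or two plastocyanin-like blocks carrying the ligand
#' pattern H-x40-C-x5-H-x5-Z with Z = M for UCL/PLCL, Q for SCL and a
#' small non-ligand residue for ENODL, plus a second Cys ten residues
#' before the ligand Cys; optional PAST-rich ALR; optional GPI tail),
#' reverse-translates them under the configured codon bias, places the
#' genes on chromosomes with wide spacing (duplicate pairs adjacent), and
#' plants cis-elements into otherwise element-free 2 kb promoters.
#'
#' @param config Output of [family_sim_config()].
#' @return List with genome (named chromosome sequences), genes (gene-model
#'   tibble with a cds column), proteins (named vector), truth (annotation
#'   tibble), elements (planted-element truth tibble), pairs (duplicate
#'   pair tibble) and config.
#' @export
generate_family <- function(config = family_sim_config()) {
  n <- config$n_genes
  dict <- default_element_dictionary()
  set.seed(substream(config$seed, 1L))
  assign_tab <- assign_subfamily_types(config)
  assign_tab <- assign_tab[sample.int(nrow(assign_tab)), ]
  npairs <- length(config$pair_divergence)

  gene_ids <- sprintf("g%03d", seq_len(n))
  built <- vector("list", n)
  cds_list <- character(n)
  pair_partner <- rep(NA_character_, n)
  pair_syn <- rep(NA_integer_, n)
  pair_nonsyn <- rep(NA_integer_, n)
  pair_rows <- list()

  for (i in seq_len(n)) {
    is_partner <- npairs > 0L && i %% 2L == 0L && i <= 2L * npairs
    if (is_partner) {
      src <- i - 1L
      div <- config$pair_divergence[[i / 2L]]
      sn <- ng86_sites(cds_list[src])
      syn_n <- max(0L, round(div[1] * sn[["S"]]))
      nonsyn_n <- max(0L, round(div[2] * sn[["N"]]))
      mut <- mutate_pair(cds_list[src], syn_n, nonsyn_n,
                         seed = substream(config$seed, 2L, i),
                         protect = built[[src]]$protected)
      cds_list[i] <- mut$cds
      b <- built[[src]]
      b$residues <- aa_chars(translate(mut$cds))
      built[[i]] <- b
      pair_partner[c(src, i)] <- gene_ids[c(i, src)]
      pair_syn[c(src, i)] <- syn_n
      pair_nonsyn[c(src, i)] <- nonsyn_n
      pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
        gene_a = gene_ids[src], gene_b = gene_ids[i],
        syn_changes = syn_n, nonsyn_changes = nonsyn_n)
    } else {
      set.seed(substream(config$seed, 3L, i))
      target_len <- sample(config$cds_length_range[1]:config$cds_length_range[2], 1)
      b <- build_protein(assign_tab$subfamily[i], assign_tab$type[i], target_len)
      built[[i]] <- b
      cds_list[i] <- reverse_translate(b$residues, config$codon_bias_strength)
    }
  }
  # partners inherit subfamily/type truth from their source gene
  subfam <- assign_tab$subfamily
  types <- assign_tab$type
  if (npairs > 0L) {
    for (j in seq_len(npairs)) {
      subfam[2L * j] <- subfam[2L * j - 1L]
      types[2L * j] <- types[2L * j - 1L]
    }
  }

  # promoters with planted elements
  promoters <- character(n)
  el_truth <- list()
  for (i in seq_len(n)) {
    set.seed(substream(config$seed, 4L, i))
    pp <- plant_promoter(2000L, config$planted_elements, dict)
    promoters[i] <- pp$sequence
    if (nrow(pp$truth) > 0L) {
      pp$truth$gene_id <- gene_ids[i]
      el_truth[[length(el_truth) + 1L]] <- pp$truth
    }
  }

  # chromosome placement: units (pairs stay together) dealt round-robin
  unit_of <- integer(n)
  units <- list()
  i <- 1L
  while (i <= n) {
    if (npairs > 0L && i %% 2L == 1L && i < 2L * npairs) {
      units[[length(units) + 1L]] <- c(i, i + 1L)
      i <- i + 2L
    } else {
      units[[length(units) + 1L]] <- i
      i <- i + 1L
    }
  }
  chrom_of_unit <- rep(seq_len(config$n_chromosomes), length.out = length(units))
  set.seed(substream(config$seed, 5L))
  strand <- sample(c("+", "-"), n, TRUE)

  chrom_names <- sprintf("chr%02d", seq_len(config$n_chromosomes))
  segments <- stats::setNames(vector("list", config$n_chromosomes), chrom_names)
  cursor <- stats::setNames(rep(0L, config$n_chromosomes), chrom_names)
  start <- integer(n); end <- integer(n); chromosome <- character(n)

  for (u in seq_along(units)) {
    chr <- chrom_names[chrom_of_unit[u]]
    members <- units[[u]]
    for (k in seq_along(members)) {
      i <- members[k]
      spacer <- if (k == 1L) config$gene_spacing else config$pair_spacing
      gene_seq <- paste0(cds_list[i], "TAA")
      block <- if (strand[i] == "+") {
        paste0(promoters[i], gene_seq)
      } else {
        paste0(reverse_complement(gene_seq), reverse_complement(promoters[i]))
      }
      gstart <- cursor[[chr]] + spacer +
        (if (strand[i] == "+") 2000L else 0L) + 1L
      gend <- gstart + nchar(gene_seq) - 1L
      segments[[chr]] <- c(segments[[chr]], strrep("N", spacer), block)
      cursor[[chr]] <- cursor[[chr]] + spacer + nchar(block)
      chromosome[i] <- chr; start[i] <- gstart; end[i] <- gend
    }
  }
  genome <- vapply(segments, function(s) {
    paste(c(s, strrep("N", 200L)), collapse = "")
  }, character(1))
  empty <- !nzchar(genome)
  genome[empty] <- strrep("N", 200L)

  proteins <- stats::setNames(
    vapply(built, function(b) paste(b$residues, collapse = ""), character(1)),
    gene_ids)

  lig_field <- vapply(seq_len(n), function(i) {
    b <- built[[i]]
    paste(vapply(seq_along(b$ligands), function(j) {
      lp <- b$ligands[[j]]
      slots <- c("H", "C", "H", if (b$complete) b$z else "-")
      pos <- unname(lp)
      if (!b$complete) pos[4] <- NA_integer_
      paste(paste0(slots, ":", ifelse(is.na(pos), "NA", pos)), collapse = ",")
    }, character(1)), collapse = ";")
  }, character(1))

  truth <- tibble::tibble(
    gene_id = gene_ids,
    chromosome = chromosome, start = start, end = end, strand = strand,
    subfamily = subfam, type = types,
    protein_length = nchar(proteins),
    sp_start = vapply(built, function(b) b$sp[1], integer(1)),
    sp_end = vapply(built, function(b) b$sp[2], integer(1)),
    plcd_spans = vapply(built, function(b) span_str(b$plcd_spans), character(1)),
    ligands = lig_field,
    plcd_complete = vapply(built, function(b) {
      paste(rep(as.integer(b$complete), length(b$plcd_spans)), collapse = ";")
    }, character(1)),
    alr_start = vapply(built, function(b) b$alr[1], integer(1)),
    alr_end = vapply(built, function(b) b$alr[2], integer(1)),
    gas_start = vapply(built, function(b) b$gas[1], integer(1)),
    gas_end = vapply(built, function(b) b$gas[2], integer(1)),
    pair_partner = pair_partner, pair_syn = pair_syn,
    pair_nonsyn = pair_nonsyn
  )

  genes <- tibble::tibble(
    gene_id = gene_ids, chromosome = chromosome, start = start, end = end,
    strand = strand, cds = cds_list
  )
  genes <- genes[order(genes$chromosome, genes$start), ]

  elements <- if (length(el_truth) > 0L) {
    dplyr::relocate(dplyr::bind_rows(el_truth), "gene_id")
  } else {
    tibble::tibble(gene_id = character(), element = character(),
                   start = integer(), end = integer())
  }

  list(genome = genome, genes = genes, proteins = proteins, truth = truth,
       elements = elements,
       pairs = dplyr::bind_rows(pair_rows), config = config)
}

#' Write a generated family bundle to disk
#'
#' Emits genome.fna, genes.gff3, cds.fna, proteins.faa, truth.tsv,
#' elements.tsv and pairs.tsv under `dir`.
#'
#' @param fam Output of [generate_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family_bundle <- function(fam, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fam$genome, file.path(dir, "genome.fna"))
  write_gff3(fam$genes, file.path(dir, "genes.gff3"))
  write_fasta(stats::setNames(fam$genes$cds, fam$genes$gene_id),
              file.path(dir, "cds.fna"))
  write_fasta(fam$proteins, file.path(dir, "proteins.faa"))
  utils::write.table(fam$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fam$elements, file.path(dir, "elements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fam$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Introduce exact numbers of synonymous and nonsynonymous changes
#'
#' Each change is a single-nucleotide substitution verified against the
#' standard genetic code, at most one change per codon, never creating a
#' stop codon.
#'
#' @param cds Coding nucleotide string.
#' @param syn_changes Number of synonymous changes.
#' @param nonsyn_changes Number of nonsynonymous changes.
#' @param seed Integer seed.
#' @param protect Codon indices excluded from mutation.
#' @return List with `cds` (mutated) and `log` (tibble: codon_index,
#'   position, from_base, to_base, from_codon, to_codon, category).
#' @export
mutate_pair <- function(cds, syn_changes, nonsyn_changes, seed = 1L,
                        protect = integer(0)) {
  cds <- toupper(cds)
  gc <- genetic_code()
  codons <- split_codons(cds)
  bases <- c("A", "C", "G", "T")
  cand <- list()
  for (ci in seq_along(codons)) {
    if (ci %in% protect) next
    cod <- codons[ci]
    if (cod %in% STOP_CODONS || grepl("N", cod)) next
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        new <- cod
        substr(new, pos, pos) <- b
        if (new %in% STOP_CODONS) next
        cand[[length(cand) + 1L]] <- list(
          ci = ci, pos = pos, b = b, new = new,
          syn = gc[[new]] == gc[[cod]])
      }
    }
  }
  syn_flag <- vapply(cand, `[[`, logical(1), "syn")
  ci_all <- vapply(cand, `[[`, integer(1), "ci")
  set.seed(seed)
  ord <- sample.int(length(cand))
  used <- integer(0)
  picks <- list()
  pick_n <- function(want_syn, k) {
    got <- 0L
    for (j in ord) {
      if (got == k) break
      if (syn_flag[j] != want_syn) next
      if (ci_all[j] %in% used) next
      picks[[length(picks) + 1L]] <<- cand[[j]]
      used <<- c(used, ci_all[j])
      got <- got + 1L
    }
    got
  }
  got_s <- pick_n(TRUE, syn_changes)
  got_n <- pick_n(FALSE, nonsyn_changes)
  if (got_s < syn_changes || got_n < nonsyn_changes) {
    stop("infeasible mutation request: short by ",
         syn_changes - got_s, " synonymous and ",
         nonsyn_changes - got_n, " nonsynonymous changes")
  }
  log <- list()
  for (p in picks) {
    ntpos <- (p$ci - 1L) * 3L + p$pos
    old <- substr(cds, ntpos, ntpos)
    oldcod <- codons[p$ci]
    substr(cds, ntpos, ntpos) <- p$b
    log[[length(log) + 1L]] <- tibble::tibble(
      codon_index = p$ci, position = ntpos, from_base = old, to_base = p$b,
      from_codon = oldcod, to_codon = p$new,
      category = if (p$syn) "synonymous" else "nonsynonymous")
  }
  log <- if (length(log) > 0L) {
    dplyr::arrange(dplyr::bind_rows(log), .data$position)
  } else {
    tibble::tibble(codon_index = integer(), position = integer(),
                   from_base = character(), to_base = character(),
                   from_codon = character(), to_codon = character(),
                   category = character())
  }
  list(cds = cds, log = log)
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Target Ct = calibrator target Ct - log2(fold) + Gaussian noise; the
#' reference-gene Ct is constant at `ref_ct` plus noise; stage 1 is the
#' calibrator and its fold is fixed to 1.
#'
#' @param n_genes Number of target genes.
#' @param n_stages Number of sample stages (stage 1 = calibrator; stages
#'   are labelled DAF1, DAF5, ... like a fruit de-bagging series when
#'   `n_stages` <= 6).
#' @param fold_changes Matrix (n_genes x n_stages) of true fold changes
#'   (positive; column 1 coerced to 1).
#' @param ref_ct Reference-gene Ct level.
#' @param noise_sd Gaussian noise SD on the Ct scale.
#' @param replicates Biological replicates per (gene, stage).
#' @param seed Integer seed.
#' @return List with `ct` (tibble: gene_id, sample_id, replicate,
#'   ct_target, ct_reference) and `truth` (tibble of true folds).
#' @export
generate_ct_table <- function(n_genes, n_stages, fold_changes, ref_ct = 20,
                              noise_sd = 0.2, replicates = 3L, seed = 1L) {
  stopifnot(replicates >= 1L, n_stages >= 1L)
  fold_changes <- matrix(fold_changes, nrow = n_genes, ncol = n_stages)
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  fold_changes[, 1] <- 1
  stage_names <- if (n_stages <= 6L) {
    paste0("DAF", c(1L, 5L, 9L, 13L, 17L, 21L))[seq_len(n_stages)]
  } else {
    paste0("S", seq_len(n_stages))
  }
  gene_ids <- sprintf("t%03d", seq_len(n_genes))
  rows <- list()
  for (g in seq_len(n_genes)) {
    set.seed(substream(seed, 7L, g))
    base_ct <- stats::runif(1, 22, 28)
    for (s in seq_len(n_stages)) {
      tgt <- base_ct - log2(fold_changes[g, s]) +
        stats::rnorm(replicates, 0, noise_sd)
      ref <- ref_ct + stats::rnorm(replicates, 0, noise_sd)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene_id = gene_ids[g], sample_id = stage_names[s],
        replicate = seq_len(replicates), ct_target = tgt,
        ct_reference = ref)
    }
  }
  truth <- tibble::as_tibble(fold_changes, .name_repair = ~stage_names)
  truth <- dplyr::mutate(truth, gene_id = gene_ids, .before = 1L)
  list(ct = dplyr::bind_rows(rows), truth = truth)
}
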