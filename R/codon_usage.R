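# Codon-usage-bias battery: RSCU, Wright's effective number of codons,
# CAI, CBI, Fop, GC/GC3s and third-position base composition, pooled
# optimal-codon calling and index correlations.
#
# Codons are spelled with T internally; set `rna = TRUE` on the renderers
# to report U.

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

# amino acid of each sense codon and synonym families
codon_aa <- function() {
  gc <- genetic_code()
  gc[gc != "*"]
}

#' Count sense codons of a CDS
#'
#' Stop codons and codons containing N are excluded (the latter counted in
#' the `n_excluded` attribute).
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Named integer vector over the 61 sense codons.
#' @export
codon_counts <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  codons <- split_codons(cds)
  has_n <- grepl("[^ACGT]", codons)
  codons <- codons[!has_n]
  codons <- codons[!codons %in% STOP_CODONS]
  out <- table(factor(codons, levels = sense_codons()))
  res <- stats::setNames(as.integer(out), names(out))
  attr(res, "n_excluded") <- sum(has_n)
  res
}

#' Relative synonymous codon usage
#'
#' RSCU(c) = count(c) / mean count over the codon's synonym family.
#' Codons of unused amino acids are 0 by convention and flagged in the
#' `unused_aa` attribute.
#'
#' @param counts Named counts over sense codons (see [codon_counts()]).
#' @return Named numeric vector of RSCU values.
#' @export
rscu <- function(counts) {
  aa <- codon_aa()
  out <- stats::setNames(rep(0, length(aa)), names(aa))
  unused <- character(0)
  for (a in unique(aa)) {
    syn <- names(aa)[aa == a]
    tot <- sum(counts[syn])
    if (tot == 0L) {
      unused <- c(unused, a)
      next
    }
    out[syn] <- counts[syn] / (tot / length(syn))
  }
  attr(out, "unused_aa") <- unused
  out
}

#' Wright's effective number of codons (ENC)
#'
#' Per amino acid with n > 1 codon observations, the codon homozygosity is
#' F = (n * sum p^2 - 1) / (n - 1); class averages over degeneracy classes
#' 2, 3, 4, 6 use amino acids with F > 0, the missing 3-fold class is
#' interpolated as (F2 + F4)/2, and
#' ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6, clipped at 61. `NA` when a
#' required class average is unavailable.
#'
#' @param counts Named counts over sense codons.
#' @return ENC in [20, 61], or `NA`.
#' @export
enc <- function(counts) {
  aa <- codon_aa()
  deg <- table(aa)
  fhat <- list(`2` = numeric(0), `3` = numeric(0), `4` = numeric(0),
               `6` = numeric(0))
  for (a in unique(aa)) {
    k <- deg[[a]]
    if (k == 1L) next
    syn <- names(aa)[aa == a]
    n <- sum(counts[syn])
    if (n <= 1L) next
    p <- counts[syn] / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (f > 0) fhat[[as.character(k)]] <- c(fhat[[as.character(k)]], f)
  }
  fbar <- vapply(fhat, function(x) if (length(x)) mean(x) else NA_real_,
                 numeric(1))
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  if (anyNA(fbar)) return(NA_real_)
  min(61, 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
        3 / fbar[["6"]])
}

#' Relative adaptiveness weights for CAI from a reference gene set
#'
#' w(c) = RSCU(c) / max RSCU over the codon's synonym family, computed on
#' pooled reference counts; codons absent from the reference can be
#' smoothed with a pseudo-count.
#'
#' @param reference_counts Pooled named counts over sense codons.
#' @param smooth Pseudo-count added to every sense codon (default 0, the
#'   conventional choice is 0.5 when the reference has absent codons).
#' @return Named weight vector in (0, 1].
#' @export
cai_weights <- function(reference_counts, smooth = 0) {
  counts <- reference_counts + smooth
  aa <- codon_aa()
  w <- stats::setNames(rep(NA_real_, length(aa)), names(aa))
  for (a in unique(aa)) {
    syn <- names(aa)[aa == a]
    mx <- max(counts[syn])
    w[syn] <- if (mx > 0) counts[syn] / mx else 0
  }
  w
}

#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness weights over the gene's
#' codons, excluding Met, Trp and stops.
#'
#' @param counts Named counts over sense codons.
#' @param reference_weights Named weight vector in (0, 1] with w = 1 for
#'   each amino acid's best codon (see [cai_weights()]).
#' @return CAI in (0, 1].
#' @export
cai <- function(counts, reference_weights) {
  aa <- codon_aa()
  keep <- !(aa %in% c("M", "W"))
  syn <- names(aa)[keep]
  used <- syn[counts[syn] > 0]
  if (length(used) == 0L) return(NA_real_)
  w <- reference_weights[used]
  if (any(is.na(w) | w <= 0)) {
    stop("zero or missing CAI weight for codon(s) ",
         paste(used[is.na(w) | w <= 0], collapse = ", "),
         "; recompute the reference weights with smoothing ",
         "(cai_weights(..., smooth = 0.5))")
  }
  exp(sum(counts[used] * log(w)) / sum(counts[used]))
}

#' Codon bias index and frequency of optimal codons
#'
#' Over degenerate amino acids only: Fop = N_opt / N_tot and
#' CBI = (N_opt - N_ran) / (N_tot - N_ran) where N_ran is the count
#' expected under uniform synonym usage.
#'
#' @param counts Named counts over sense codons.
#' @param optimal_set Character vector of optimal codons (at least one per
#'   represented degenerate amino acid class).
#' @return List with `fop` and `cbi` (either may be `NA` when degenerate).
#' @export
cbi_fop <- function(counts, optimal_set) {
  aa <- codon_aa()
  deg <- table(aa)
  n_tot <- 0; n_opt <- 0; n_ran <- 0
  for (a in unique(aa)) {
    k <- deg[[a]]
    if (k == 1L) next
    syn <- names(aa)[aa == a]
    n <- sum(counts[syn])
    if (n == 0L) next
    k_opt <- sum(syn %in% optimal_set)
    n_tot <- n_tot + n
    n_opt <- n_opt + sum(counts[intersect(syn, optimal_set)])
    n_ran <- n_ran + n * k_opt / k
  }
  if (n_tot == 0) return(list(fop = NA_real_, cbi = NA_real_))
  fop <- n_opt / n_tot
  cbi <- if (abs(n_tot - n_ran) < 1e-12) NA_real_ else {
    (n_opt - n_ran) / (n_tot - n_ran)
  }
  list(fop = fop, cbi = cbi)
}

#' Base composition at synonymous third positions, GC3s and GC
#'
#' Third-position shares are computed over synonymously variable codons
#' only (Met, Trp and stops excluded); `gc` is computed over all positions
#' of all sense codons.
#'
#' @param counts Named counts over sense codons.
#' @return List with a3s, t3s, g3s, c3s, gc3s (NA when no synonymous third
#'   position exists) and gc.
#' @export
third_position_composition <- function(counts) {
  aa <- codon_aa()
  all_syn <- names(aa)[!(aa %in% c("M", "W"))]
  third <- substr(all_syn, 3, 3)
  n3 <- sum(counts[all_syn])
  shares <- if (n3 > 0) {
    vapply(c("A", "T", "G", "C"), function(b) {
      sum(counts[all_syn[third == b]]) / n3
    }, numeric(1))
  } else {
    stats::setNames(rep(NA_real_, 4), c("A", "T", "G", "C"))
  }
  total <- sum(counts)
  gc <- if (total > 0) {
    gc_per <- vapply(names(counts), function(cod) {
      sum(strsplit(cod, "")[[1]] %in% c("G", "C"))
    }, numeric(1))
    sum(counts * gc_per) / (3 * total)
  } else {
    NA_real_
  }
  list(a3s = shares[["A"]], t3s = shares[["T"]], g3s = shares[["G"]],
       c3s = shares[["C"]],
       gc3s = if (n3 > 0) shares[["G"]] + shares[["C"]] else NA_real_,
       gc = gc)
}

#' Full codon-usage profile of one gene
#'
#' @param cds Coding sequence.
#' @param gene_id Identifier.
#' @param reference_weights CAI weights; `NULL` leaves CAI `NA`.
#' @param optimal_set Optimal codon set for CBI/Fop; `NULL` leaves both `NA`.
#' @return One-row tibble with enc, cai, cbi, fop, gc, gc3s, a3s/t3s/g3s/c3s
#'   and the codon counts as an attribute-free list column `counts`.
#' @export
codon_usage_profile <- function(cds, gene_id = "gene",
                                reference_weights = NULL,
                                optimal_set = NULL) {
  counts <- codon_counts(cds)
  comp <- third_position_composition(counts)
  cf <- if (is.null(optimal_set)) {
    list(fop = NA_real_, cbi = NA_real_)
  } else {
    cbi_fop(counts, optimal_set)
  }
  tibble::tibble(
    gene_id = gene_id,
    n_codons = sum(counts),
    enc = enc(counts),
    cai = if (is.null(reference_weights)) NA_real_ else cai(counts, reference_weights),
    cbi = cf$cbi, fop = cf$fop,
    gc = comp$gc, gc3s = comp$gc3s,
    a3s = comp$a3s, t3s = comp$t3s, g3s = comp$g3s, c3s = comp$c3s,
    counts = list(counts)
  )
}

#' Codon-usage profiles for a gene set
#'
#' The optimal-codon set defaults to the pooled RSCU > 1 codons of the
#' analyzed family itself, and the CAI reference weights to the pooled
#' counts (with 0.5 smoothing), unless supplied.
#'
#' @param cds_set Named character vector of coding sequences.
#' @param reference_weights Optional CAI weight vector.
#' @param optimal_set Optional optimal codon set.
#' @return Tibble with one profile row per gene.
#' @export
codon_usage_profiles <- function(cds_set, reference_weights = NULL,
                                 optimal_set = NULL) {
  counts_list <- lapply(cds_set, codon_counts)
  pooled <- Reduce(`+`, lapply(counts_list, as.integer))
  pooled <- stats::setNames(pooled, sense_codons())
  if (is.null(optimal_set)) {
    pooled_rscu <- rscu(pooled)
    optimal_set <- names(pooled_rscu)[pooled_rscu > 1]
  }
  if (is.null(reference_weights)) {
    reference_weights <- cai_weights(pooled, smooth = 0.5)
  }
  dplyr::bind_rows(lapply(names(cds_set), function(id) {
    codon_usage_profile(cds_set[[id]], id, reference_weights, optimal_set)
  }))
}

#' Optimal codons of a gene family (pooled RSCU > 1)
#'
#' @param cds_set Named character vector of coding sequences (or a list of
#'   codon count vectors).
#' @return Character vector of codons with pooled RSCU > 1.
#' @export
optimal_codons <- function(cds_set) {
  counts_list <- if (is.character(cds_set)) {
    lapply(cds_set, codon_counts)
  } else {
    cds_set
  }
  stopifnot(length(counts_list) >= 1L)
  pooled <- Reduce(`+`, lapply(counts_list, as.integer))
  pooled <- stats::setNames(pooled, sense_codons())
  r <- rscu(pooled)
  names(r)[r > 1]
}

#' Pairwise Pearson correlations among codon-usage indices
#'
#' @param profiles Profile tibble from [codon_usage_profiles()].
#' @param indices Columns to correlate.
#' @return Correlation matrix (pairwise-complete; zero-variance columns
#'   give NA entries).
#' @export
index_correlations <- function(profiles,
                               indices = c("a3s", "t3s", "g3s", "c3s",
                                           "gc3s", "gc", "cai", "cbi",
                                           "fop", "enc")) {
  stopifnot(nrow(profiles) >= 3L)
  m <- as.matrix(profiles[, indices])
  suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
}

#' Render a codon table with RNA spelling
#'
#' @param x Named vector keyed by DNA codons.
#' @param rna Render T as U in the names.
#' @return The vector with renamed codons.
#' @export
render_codons <- function(x, rna = TRUE) {
  if (rna) names(x) <- chartr("T", "U", names(x))
  x
}
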