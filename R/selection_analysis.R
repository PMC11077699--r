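# Pairwise Ka/Ks by the Nei-Gojobori (1986) counting method with
# Jukes-Cantor correction, plus tandem-cluster detection from gene
# positions.

BASES <- c("A", "C", "G", "T")

#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' Each codon position contributes (number of synonymous single-nucleotide
#' changes)/3 to S and the complement to N; changes creating stop codons
#' count as nonsynonymous. Codons containing N (or gaps) are excluded and
#' tallied in the `n_excluded` attribute.
#'
#' @param cds Coding nucleotide string (no internal stops).
#' @return Named numeric vector c(S, N); S + N = 3 x compared codons.
#' @export
ng86_sites <- function(cds) {
  gc <- genetic_code()
  codons <- split_codons(toupper(cds))
  skip <- grepl("[^ACGT]", codons) | codons %in% STOP_CODONS
  S <- 0
  for (cod in codons[!skip]) {
    aa <- gc[[cod]]
    for (pos in 1:3) {
      alts <- setdiff(BASES, substr(cod, pos, pos))
      syn <- 0L
      for (b in alts) {
        new <- cod
        substr(new, pos, pos) <- b
        if (gc[[new]] == aa) syn <- syn + 1L  # changes to stops: nonsyn
      }
      S <- S + syn / 3
    }
  }
  n_codons <- sum(!skip)
  out <- c(S = S, N = 3 * n_codons - S)
  attr(out, "n_excluded") <- sum(skip)
  out
}

# Average synonymous/nonsynonymous step counts between two codons over all
# orderings of the differing positions. Pathways through stop codons are
# excluded with renormalization unless count_stop_paths is TRUE.
codon_path_diffs <- function(a, b, count_stop_paths = FALSE) {
  gc <- genetic_code()
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  d <- length(diff_pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) {
    list(diff_pos)
  } else if (d == 2L) {
    list(diff_pos, rev(diff_pos))
  } else {
    lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1)), function(o) diff_pos[o])
  }
  sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
  for (ord in perms) {
    cur <- a
    sd <- 0L; nd <- 0L; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      if (!count_stop_paths && gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(NULL)  # all pathways cross a stop
  c(sd = sd_tot / n_ok, nd = nd_tot / n_ok)
}

#' Nei-Gojobori synonymous and nonsynonymous difference counts
#'
#' Per codon pair with d differing positions, step categories are averaged
#' over all d! orderings of the minimal mutational pathway; pathways
#' passing through a stop codon are excluded with renormalization over the
#' remaining ones (`count_stop_paths = TRUE` restores naive averaging).
#' Codon pairs whose pathways all cross stops, or containing N, are
#' excluded and tallied in the `n_excluded` attribute.
#'
#' @param a,b Aligned coding sequences of equal length.
#' @param count_stop_paths Include stop-crossing pathways.
#' @return Named numeric vector c(Sd, Nd).
#' @export
ng86_differences <- function(a, b, count_stop_paths = FALSE) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  if (nchar(a) %% 3L != 0L) stop("length not a multiple of 3")
  ca <- split_codons(a); cb <- split_codons(b)
  skip <- grepl("[^ACGT]", ca) | grepl("[^ACGT]", cb) |
    ca %in% STOP_CODONS | cb %in% STOP_CODONS
  Sd <- 0; Nd <- 0; n_excl <- sum(skip)
  for (i in which(!skip)) {
    r <- codon_path_diffs(ca[i], cb[i], count_stop_paths)
    if (is.null(r)) { n_excl <- n_excl + 1L; next }
    Sd <- Sd + r[["sd"]]; Nd <- Nd + r[["nd"]]
  }
  out <- c(Sd = Sd, Nd = Nd)
  attr(out, "n_excluded") <- n_excl
  out
}

jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, 0 + -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise Ka/Ks by Nei-Gojobori with Jukes-Cantor correction
#'
#' Site counts are averaged over the two sequences; ps = Sd/S and pn =
#' Nd/N are corrected as d = -(3/4) ln(1 - 4p/3). The result is symmetric
#' in argument order. Saturation (p >= 3/4) gives missing distances;
#' Ks = 0 gives a missing ratio and an undefined selection class.
#'
#' @param a,b Aligned coding sequences.
#' @param pair Identifier pair (character vector of 2).
#' @param count_stop_paths Passed to [ng86_differences()].
#' @return One-row tibble (class KaKsResult layout): pair ids, S, N, Sd,
#'   Nd, ps, pn, Ks, Ka, ratio, selection_class.
#' @export
kaks <- function(a, b, pair = c("a", "b"), count_stop_paths = FALSE) {
  sa <- ng86_sites(a); sb <- ng86_sites(b)
  S <- (sa[["S"]] + sb[["S"]]) / 2
  N <- (sa[["N"]] + sb[["N"]]) / 2
  d <- ng86_differences(a, b, count_stop_paths)
  ps <- if (S > 0) d[["Sd"]] / S else NA_real_
  pn <- if (N > 0) d[["Nd"]] / N else NA_real_
  Ks <- jukes_cantor(ps)
  Ka <- jukes_cantor(pn)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  cls <- if (is.na(ratio)) {
    "undefined"
  } else if (abs(ratio - 1) <= 1e-9) {
    "neutral"
  } else if (ratio < 1) {
    "purifying"
  } else {
    "positive"
  }
  tibble::tibble(
    gene_a = pair[1], gene_b = pair[2],
    S = S, N = N, Sd = d[["Sd"]], Nd = d[["Nd"]],
    ps = ps, pn = pn, Ks = Ks, Ka = Ka, ratio = ratio,
    selection_class = cls
  )
}

#' Ka/Ks for a table of gene pairs
#'
#' @param pairs Tibble with columns gene_a, gene_b.
#' @param cds_set Named character vector of coding sequences.
#' @param ... Passed to [kaks()].
#' @return Tibble with one KaKsResult row per pair.
#' @export
kaks_pairs <- function(pairs, cds_set, ...) {
  dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    if (!ga %in% names(cds_set) || !gb %in% names(cds_set)) {
      stop("pair references unknown gene: ", ga, " / ", gb)
    }
    kaks(cds_set[[ga]], cds_set[[gb]], pair = c(ga, gb), ...)
  }))
}

#' Detect tandem duplication clusters
#'
#' Maximal chains of family genes on one chromosome where consecutive
#' family members lie within `max_separation` bp (start to start) and are
#' separated by at most `max_intervening` non-family genes.
#'
#' @param genes Gene-model tibble (all genes, any order).
#' @param family_ids Ids of the family members.
#' @param max_separation Maximum start-to-start distance in bp.
#' @param max_intervening Maximum intervening non-family genes.
#' @return Tibble with one row per cluster: chromosome, members
#'   (";"-joined in positional order), n_members, span_bp.
#' @export
tandem_clusters <- function(genes, family_ids, max_separation = 250000L,
                            max_intervening = 5L) {
  genes <- genes[order(genes$chromosome, genes$start), ]
  out <- list()
  for (chr in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chr, ]
    fam_idx <- which(g$gene_id %in% family_ids)
    if (length(fam_idx) < 2L) next
    cur <- fam_idx[1]
    flush <- function(idx) {
      if (length(idx) >= 2L) {
        out[[length(out) + 1L]] <<- tibble::tibble(
          chromosome = chr,
          members = paste(g$gene_id[idx], collapse = ";"),
          n_members = length(idx),
          span_bp = max(g$end[idx]) - min(g$start[idx]) + 1L
        )
      }
    }
    for (k in fam_idx[-1]) {
      prev <- cur[length(cur)]
      close_enough <- (g$start[k] - g$start[prev]) <= max_separation
      intervening <- k - prev - 1L
      if (close_enough && intervening <= max_intervening) {
        cur <- c(cur, k)
      } else {
        flush(cur)
        cur <- k
      }
    }
    flush(cur)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chromosome = character(), members = character(),
                          n_members = integer(), span_bp = integer()))
  }
  dplyr::bind_rows(out)
}
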