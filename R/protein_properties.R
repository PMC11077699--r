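# Physicochemical profiling: molecular weight, pI, GRAVY, aliphatic index,
# instability index, and the acidity / hydropathy dichotomies.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_residues <- function(p, allow_unknown = FALSE) {
  p <- toupper(p)
  if (nchar(p) == 0L) stop("empty protein sequence")
  alphabet <- paste(AA20, collapse = "")
  if (allow_unknown) alphabet <- paste0(alphabet, "X")
  if (grepl(sprintf("[^%s]", alphabet), p)) {
    stop("protein contains residues outside the 20-letter alphabet")
  }
  p
}

residue_counts <- function(p, allow_unknown = FALSE) {
  p <- check_residues(p, allow_unknown)
  chars <- strsplit(p, "", fixed = TRUE)[[1]]
  chars <- chars[chars != "X"]   # X never enters index computations
  table(factor(chars, levels = AA20))
}

#' Average molecular weight of a protein (Da)
#'
#' Sum of average residue masses plus one water.
#'
#' @param p Amino-acid string.
#' @param allow_unknown Permit `X` (excluded from the sum).
#' @return Molecular weight in daltons.
#' @export
molecular_weight <- function(p, allow_unknown = FALSE) {
  cnt <- residue_counts(p, allow_unknown)
  sum(cnt * (PC_AA_MASS[names(cnt)] - PC_WATER_MASS)) + PC_WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch over D, E, C, Y, H, K, R and the termini, using the
#' Bjellqvist pKa set (residue-specific terminal pKa where tabulated).
#'
#' @param p Amino-acid string.
#' @param pH pH value.
#' @param pka pKa table (list with positive, negative, nterm_residue,
#'   cterm_residue components); default the shipped Bjellqvist set.
#' @return Net charge (elementary charges).
#' @export
protein_charge <- function(p, pH, pka = PC_PKA) {
  p <- check_residues(p, allow_unknown = TRUE)
  cnt <- residue_counts(p, allow_unknown = TRUE)
  first <- substr(p, 1L, 1L)
  last <- substr(p, nchar(p), nchar(p))
  pos_pk <- pka$positive
  neg_pk <- pka$negative
  nterm_pk <- if (first %in% names(pka$nterm_residue)) {
    pka$nterm_residue[[first]]
  } else {
    pos_pk[["Nterm"]]
  }
  cterm_pk <- if (last %in% names(pka$cterm_residue)) {
    pka$cterm_residue[[last]]
  } else {
    neg_pk[["Cterm"]]
  }
  pos <- 1 / (1 + 10^(pH - nterm_pk))
  for (aa in c("K", "R", "H")) {
    pos <- pos + cnt[[aa]] / (1 + 10^(pH - pos_pk[[aa]]))
  }
  neg <- 1 / (1 + 10^(cterm_pk - pH))
  for (aa in c("D", "E", "C", "Y")) {
    neg <- neg + cnt[[aa]] / (1 + 10^(neg_pk[[aa]] - pH))
  }
  pos - neg
}

#' Theoretical isoelectric point
#'
#' Bisection on pH in [0, 14] for the zero of the net-charge curve, which is
#' monotone decreasing in pH, to |charge| < 1e-4.
#'
#' @inheritParams protein_charge
#' @return pI in pH units.
#' @export
isoelectric_point <- function(p, pka = PC_PKA) {
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- protein_charge(p, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle value over residues.
#'
#' @param p Amino-acid string.
#' @param allow_unknown Permit `X` (excluded from the mean).
#' @return GRAVY value in [-4.5, 4.5].
#' @export
gravy <- function(p, allow_unknown = FALSE) {
  cnt <- residue_counts(p, allow_unknown)
  sum(cnt * PC_KD[names(cnt)]) / sum(cnt)
}

#' Aliphatic index
#'
#' AI = X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu)) with X in mole percent.
#'
#' @inheritParams gravy
#' @return Aliphatic index (>= 0).
#' @export
aliphatic_index <- function(p, allow_unknown = FALSE) {
  cnt <- residue_counts(p, allow_unknown)
  x <- 100 * cnt / sum(cnt)
  unname(x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]]))
}

#' Instability index
#'
#' II = (10 / L) * sum of Guruprasad dipeptide weights over consecutive
#' residue pairs.
#'
#' @inheritParams gravy
#' @return Instability index.
#' @export
instability_index <- function(p, allow_unknown = FALSE) {
  p <- check_residues(p, allow_unknown)
  chars <- strsplit(p, "", fixed = TRUE)[[1]]
  if (length(chars) < 2L) stop("instability index requires length >= 2")
  a <- chars[-length(chars)]
  b <- chars[-1]
  keep <- a != "X" & b != "X"
  (10 / length(chars)) * sum(PC_DIWV[cbind(a[keep], b[keep])])
}

#' Acidity class from pI
#'
#' basic if pI > 7.5, neutral if 6.5 <= pI <= 7.5, acidic if pI < 6.5
#' (boundaries belong to neutral).
#'
#' @param pI Isoelectric point in (0, 14).
#' @return One of "acidic", "neutral", "basic".
#' @export
acidity_class <- function(pI) {
  stopifnot(all(pI > 0 & pI < 14))
  ifelse(pI > 7.5, "basic", ifelse(pI >= 6.5, "neutral", "acidic"))
}

#' Hydropathy class from GRAVY
#'
#' @param gravy GRAVY value.
#' @return "hydropathic" if gravy > 0, else "hydrophilic".
#' @export
hydropathy_class <- function(gravy) {
  ifelse(gravy > 0, "hydropathic", "hydrophilic")
}

#' Physicochemical profile of a set of proteins
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param allow_unknown Permit `X` residues.
#' @return Tibble with one row per protein: length, molecular_weight, pI,
#'   gravy, aliphatic_index, instability_index, acidity_class,
#'   hydropathy_class.
#' @export
protein_profiles <- function(proteins, allow_unknown = FALSE) {
  stopifnot(length(proteins) > 0L, !is.null(names(proteins)))
  rows <- lapply(names(proteins), function(id) {
    p <- proteins[[id]]
    g <- gravy(p, allow_unknown)
    pi_ <- isoelectric_point(p)
    tibble::tibble(
      protein_id = id,
      length = nchar(p),
      molecular_weight = molecular_weight(p, allow_unknown),
      pI = pi_,
      gravy = g,
      aliphatic_index = aliphatic_index(p, allow_unknown),
      instability_index = instability_index(p, allow_unknown),
      acidity_class = acidity_class(pi_),
      hydropathy_class = hydropathy_class(g)
    )
  })
  dplyr::bind_rows(rows)
}
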