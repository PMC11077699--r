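# Domain detection and rule-based classification of phytocyanin proteins.
#
# Subfamilies are keyed on the copper-ligand set of the plastocyanin-like
# domain (PLCD): two His, one Cys and a fourth axial ligand that is Met in
# UCL/PLCL and Gln in SCL; ENODLs carry an incomplete site. Types I-VIII
# are keyed on the presence/absence of SP, ALR, GAS and the PLCD count.

#' Detector parameter set for heuristic domain scanning
#'
#' The heuristics approximate the external predictors a practitioner would
#' use (SignalP-like hydrophobic-core rule, GPI omega-site rule, PAST-rich
#' glycomodule rule, ligand-pattern scan); parity with those servers is not
#' claimed.
#'
#' @param sp_hydropathy Minimum mean Kyte-Doolittle over the best 8-residue
#'   window of the signal-peptide core (default 1.6).
#' @param gas_hydropathy Minimum mean Kyte-Doolittle of the final 12
#'   residues for a GPI anchor signal (default 1.5).
#' @param past_fraction Minimum P/A/S/T fraction per 20-residue ALR window
#'   (default 0.5).
#' @param plcd_gap1,plcd_gap2,plcd_gap3 Integer pairs: allowed spacer ranges
#'   between ligand H..C, C..H and H..(M|Q).
#' @return Named list of parameters.
#' @export
detector_params <- function(sp_hydropathy = 1.6, gas_hydropathy = 1.5,
                            past_fraction = 0.5,
                            plcd_gap1 = c(20L, 90L),
                            plcd_gap2 = c(2L, 20L),
                            plcd_gap3 = c(2L, 20L)) {
  list(sp_hydropathy = sp_hydropathy, gas_hydropathy = gas_hydropathy,
       past_fraction = past_fraction, plcd_gap1 = plcd_gap1,
       plcd_gap2 = plcd_gap2, plcd_gap3 = plcd_gap3)
}

aa_chars <- function(p) strsplit(toupper(p), "", fixed = TRUE)[[1]]

#' Detect an N-terminal signal peptide (heuristic)
#'
#' Reported iff residue 1 is Met and some 8-residue window starting within
#' residues 2-25 has mean Kyte-Doolittle hydropathy above the threshold.
#' The span runs from residue 1 to the end of the best window plus 5
#' residues (nominal cleavage region).
#'
#' @param p Amino-acid string (length >= 30).
#' @param params Output of [detector_params()].
#' @return Integer span `c(start, end)` or `NULL`.
#' @export
detect_signal_peptide <- function(p, params = detector_params()) {
  chars <- aa_chars(p)
  if (length(chars) < 30L) return(NULL)
  if (chars[1] != "M") return(NULL)
  kdv <- PC_KD[chars]
  kdv[is.na(kdv)] <- 0
  starts <- 2:min(25L, length(chars) - 7L)
  means <- vapply(starts, function(s) mean(kdv[s:(s + 7L)]), numeric(1))
  if (max(means) < params$sp_hydropathy) return(NULL)
  best <- starts[which.max(means)]
  c(1L, min(length(chars), best + 7L + 5L))
}

plcd_pattern <- function(params) {
  sprintf("(H).{%d,%d}?(C).{%d,%d}?(H).{%d,%d}?([MQ])",
          params$plcd_gap1[1], params$plcd_gap1[2],
          params$plcd_gap2[1], params$plcd_gap2[2],
          params$plcd_gap3[1], params$plcd_gap3[2])
}

ligand_tibble <- function(slots, residues, positions) {
  tibble::tibble(slot = slots, residue = residues, position = positions)
}

#' Detect plastocyanin-like domains and their copper-ligand residues
#'
#' Complete sites match H - x(20,90) - C - x(2,20) - H - x(2,20) - (M|Q)
#' (leftmost, non-overlapping). Incomplete (ENODL-type) sites carry the
#' disulfide Cys scaffold C - x(2,60) - C plus at least two of the four
#' ligand slots without completing the full pattern.
#'
#' @inheritParams detect_signal_peptide
#' @return List of sites, each `list(span, ligands, complete)`; ligand
#'   tibbles have slots H1, C, H2, Z with NA positions for missing slots.
#' @export
detect_plcd <- function(p, params = detector_params()) {
  p <- toupper(p)
  L <- nchar(p)
  if (L < 90L) return(list())
  sites <- list()
  m <- gregexpr(plcd_pattern(params), p, perl = TRUE)[[1]]
  occupied <- integer(0)
  if (m[1] != -1L) {
    cs <- attr(m, "capture.start")
    for (i in seq_along(m)) {
      span <- c(as.integer(m[i]), as.integer(m[i]) + attr(m, "match.length")[i] - 1L)
      pos <- as.integer(cs[i, ])
      res <- vapply(pos, function(j) substr(p, j, j), character(1))
      sites[[length(sites) + 1L]] <- list(
        span = span,
        ligands = ligand_tibble(c("H1", "C", "H2", "Z"), res, pos),
        complete = TRUE
      )
      occupied <- c(occupied, span[1]:span[2])
    }
  }
  # incomplete sites: Cys scaffold outside complete spans
  chars <- aa_chars(p)
  cpos <- which(chars == "C")
  cpos <- setdiff(cpos, occupied)
  used <- integer(0)
  for (c2 in cpos) {
    c1 <- cpos[cpos < c2 & (c2 - cpos - 1L) >= 2L & (c2 - cpos - 1L) <= 60L]
    if (length(c1) == 0L) next
    c1 <- max(c1)
    if (c1 %in% used || c2 %in% used) next
    # ligand slots relative to c2 acting as the ligand Cys
    h1 <- which(chars == "H" &
                  seq_along(chars) >= c2 - params$plcd_gap1[2] - 1L &
                  seq_along(chars) <= c2 - params$plcd_gap1[1] - 1L)
    h2 <- which(chars == "H" &
                  seq_along(chars) >= c2 + params$plcd_gap2[1] + 1L &
                  seq_along(chars) <= c2 + params$plcd_gap2[2] + 1L)
    zpos <- NA_integer_
    if (length(h2) > 0L) {
      h2 <- h2[1]
      z <- which(chars %in% c("M", "Q") &
                   seq_along(chars) >= h2 + params$plcd_gap3[1] + 1L &
                   seq_along(chars) <= h2 + params$plcd_gap3[2] + 1L)
      if (length(z) > 0L) zpos <- z[1]
    } else {
      h2 <- NA_integer_
    }
    h1 <- if (length(h1) > 0L) h1[1] else NA_integer_
    n_slots <- 1L + sum(!is.na(c(h1, h2, zpos)))
    if (n_slots < 2L) next
    span <- c(max(1L, c1 - 5L, if (!is.na(h1)) h1 - 1L else c1 - 5L),
              min(L, max(c2, h2, zpos, na.rm = TRUE) + 5L))
    if (any(span[1]:span[2] %in% occupied)) next
    slots_pos <- c(h1, c2, h2, zpos)
    sites[[length(sites) + 1L]] <- list(
      span = as.integer(span),
      ligands = ligand_tibble(
        c("H1", "C", "H2", "Z"),
        ifelse(is.na(slots_pos), NA_character_, chars[pmax(slots_pos, 1L)]),
        as.integer(slots_pos)
      ),
      complete = FALSE
    )
    occupied <- c(occupied, span[1]:span[2])
    used <- c(used, c1, c2)
  }
  sites[order(vapply(sites, function(s) s$span[1], numeric(1)))]
}

#' Detect an arabinogalactan protein-like region (ALR)
#'
#' Maximal run of merged 20-residue windows each with at least
#' `past_fraction` of residues in {P, A, S, T}, length >= 20, not
#' overlapping excluded spans; the longest run wins.
#'
#' @inheritParams detect_signal_peptide
#' @param excluded List of integer spans (PLCD/SP/GAS) the ALR may not
#'   overlap.
#' @return Integer span or `NULL`.
#' @export
detect_alr <- function(p, excluded = list(), params = detector_params()) {
  chars <- aa_chars(p)
  L <- length(chars)
  if (L < 20L) return(NULL)
  past <- as.integer(chars %in% c("P", "A", "S", "T"))
  csum <- cumsum(c(0L, past))
  excl_mask <- rep(FALSE, L)
  for (sp in excluded) {
    if (!is.null(sp)) excl_mask[sp[1]:sp[2]] <- TRUE
  }
  ok <- rep(FALSE, L)
  for (s in 1:(L - 19L)) {
    e <- s + 19L
    if (any(excl_mask[s:e])) next
    if ((csum[e + 1L] - csum[s]) / 20 >= params$past_fraction) ok[s:e] <- TRUE
  }
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 20L)
  if (length(runs) == 0L) return(NULL)
  best <- runs[which.max(r$lengths[runs])]
  c(starts[best], ends[best])
}

#' Detect a C-terminal GPI anchor signal (GAS, heuristic)
#'
#' Reported iff the mean Kyte-Doolittle hydropathy of the final 12 residues
#' meets the threshold and a small omega-site candidate residue
#' ({G, A, S, N, D, C}) lies 15-30 residues from the C-terminus. The span
#' runs from the most C-terminal such candidate to the terminus.
#'
#' @inheritParams detect_signal_peptide
#' @return Integer span or `NULL`.
#' @export
detect_gas <- function(p, params = detector_params()) {
  chars <- aa_chars(p)
  L <- length(chars)
  if (L < 40L) return(NULL)
  kdv <- PC_KD[chars]
  kdv[is.na(kdv)] <- 0
  if (mean(kdv[(L - 11L):L]) < params$gas_hydropathy) return(NULL)
  dist <- L - seq_along(chars)  # 0 for the terminal residue
  cand <- which(chars %in% c("G", "A", "S", "N", "D", "C") &
                  dist >= 15L & dist <= 30L)
  if (length(cand) == 0L) return(NULL)
  c(max(cand), L)
}

#' Find N-glycosylation sequons (N-X-S/T, X != P)
#'
#' @param p Amino-acid string.
#' @return Integer vector of 1-based Asn positions.
#' @export
find_nglyc_sites <- function(p) {
  chars <- aa_chars(p)
  L <- length(chars)
  if (L < 3L) return(integer(0))
  i <- seq_len(L - 2L)
  i[chars[i] == "N" & chars[i + 1L] != "P" & chars[i + 2L] %in% c("S", "T")]
}

#' Annotate the domains of one protein (heuristic scan)
#'
#' @param protein_id Identifier.
#' @param p Amino-acid string.
#' @param params Output of [detector_params()].
#' @return A domain annotation: list with protein_id, sp, plcds, alr, gas,
#'   nglyc_sites.
#' @export
annotate_domains <- function(protein_id, p, params = detector_params()) {
  sp <- detect_signal_peptide(p, params)
  plcds <- detect_plcd(p, params)
  gas <- detect_gas(p, params)
  excl <- c(list(sp, gas), lapply(plcds, `[[`, "span"))
  excl <- excl[!vapply(excl, is.null, logical(1))]
  alr <- detect_alr(p, excluded = excl, params = params)
  list(protein_id = protein_id, sp = sp, plcds = plcds, alr = alr,
       gas = gas, nglyc_sites = find_nglyc_sites(p))
}

#' Assign a phytocyanin subfamily from a domain annotation
#'
#' No complete copper-ligand set: ENODL. A complete set ending in Gln: SCL.
#' A complete set ending in Met: UCL when an ALR is present (chimeric
#' glycoprotein), PLCL otherwise.
#'
#' @param d Domain annotation (see [annotate_domains()]).
#' @return One of "UCL", "SCL", "PLCL", "ENODL".
#' @export
assign_subfamily <- function(d) {
  if (length(d$plcds) == 0L) {
    stop("not a phytocyanin: no plastocyanin-like domain in ", d$protein_id)
  }
  complete <- Filter(function(s) isTRUE(s$complete), d$plcds)
  if (length(complete) == 0L) return("ENODL")
  z <- vapply(complete, function(s) s$ligands$residue[s$ligands$slot == "Z"],
              character(1))
  if (any(z == "Q")) return("SCL")
  if (!is.null(d$alr)) "UCL" else "PLCL"
}

TYPE_TABLE <- tibble::tibble(
  type   = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
  sp     = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
  n_plcd = c(2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L),
  alr    = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
  gas    = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
)

#' Assign the structural type (I-VIII)
#'
#' Pure function of the SP/ALR/GAS booleans and the PLCD count (complete or
#' incomplete sites both count): I SP+2xPLCD+ALR+GAS; II SP+PLCD+ALR+GAS;
#' III SP+PLCD+ALR; IV SP+PLCD; V SP+PLCD+GAS; VI PLCD+ALR+GAS;
#' VII 2xPLCD+ALR+GAS; VIII PLCD only. Anything else is UNCLASSIFIED.
#'
#' @param d Domain annotation.
#' @return Type string.
#' @export
assign_type <- function(d) {
  if (length(d$plcds) == 0L) stop("no PLCD in ", d$protein_id)
  key <- TYPE_TABLE$sp == !is.null(d$sp) &
    TYPE_TABLE$n_plcd == length(d$plcds) &
    TYPE_TABLE$alr == !is.null(d$alr) &
    TYPE_TABLE$gas == !is.null(d$gas)
  if (any(key)) TYPE_TABLE$type[key][1] else "UNCLASSIFIED"
}

#' Assign the arabinogalactan-protein class
#'
#' ALR absent: non_AGP. Types I and II: typical AGP; types III, VI and VII:
#' atypical AGP; an ALR-bearing protein of any other type is reported as
#' atypical. Chimeric AGP means SP and ALR are both present.
#'
#' @param d Domain annotation.
#' @param type Type string from [assign_type()].
#' @return List with `agp_class` and `chimeric_agp`.
#' @export
assign_agp_class <- function(d, type) {
  chimeric <- !is.null(d$sp) && !is.null(d$alr)
  cls <- if (is.null(d$alr)) {
    "non_AGP"
  } else if (type %in% c("I", "II")) {
    "typical_AGP"
  } else {
    "atypical_AGP"
  }
  list(agp_class = cls, chimeric_agp = chimeric)
}

parse_span_field <- function(s, e) {
  if (is.na(s) || is.na(e)) NULL else c(as.integer(s), as.integer(e))
}

# Parse a truth/annotation row into a domain annotation. plcd_spans is
# "s1-e1;s2-e2"; ligands is per-PLCD "H:12,C:53,H:59,M:65" (missing slot
# "-:NA"), blocks joined by ";". complete_flags like "1;0".
annotation_row_to_domains <- function(row) {
  plcds <- list()
  if (!is.na(row$plcd_spans) && nzchar(row$plcd_spans)) {
    spans <- strsplit(row$plcd_spans, ";", fixed = TRUE)[[1]]
    ligs <- strsplit(row$ligands, ";", fixed = TRUE)[[1]]
    comp <- as.logical(as.integer(strsplit(as.character(row$plcd_complete),
                                           ";", fixed = TRUE)[[1]]))
    for (i in seq_along(spans)) {
      se <- as.integer(strsplit(spans[i], "-", fixed = TRUE)[[1]])
      parts <- strsplit(strsplit(ligs[i], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
      res <- vapply(parts, `[[`, character(1), 1L)
      pos <- suppressWarnings(as.integer(vapply(parts, `[[`, character(1), 2L)))
      res[res == "-"] <- NA_character_
      plcds[[i]] <- list(span = se,
                         ligands = ligand_tibble(c("H1", "C", "H2", "Z"), res, pos),
                         complete = comp[i])
    }
  }
  list(protein_id = row$gene_id,
       sp = parse_span_field(row$sp_start, row$sp_end),
       plcds = plcds,
       alr = parse_span_field(row$alr_start, row$alr_end),
       gas = parse_span_field(row$gas_start, row$gas_end),
       nglyc_sites = integer(0))
}

#' Classify a phytocyanin protein set
#'
#' Runs the domain detectors (`heuristic_scan` mode) or consumes a
#' domain-annotation table (`truth_annotation` mode), applies the
#' subfamily/type/AGP rules, and names members Subfamily+counter in order
#' of chromosome position within each subfamily. Proteins without a PLCD
#' are reported as non-members (`member = FALSE`), never dropped.
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param genes Tibble of gene models (gene_id, chromosome, start, ...)
#'   whose ids match the protein ids.
#' @param mode "heuristic_scan" or "truth_annotation".
#' @param annotations Domain-annotation tibble (required in truth mode);
#'   same layout as the generator's truth table.
#' @param params Detector parameters (heuristic mode).
#' @param prefix Name prefix (e.g. "Md"), default "".
#' @return Tibble with one row per protein: protein_id, member, subfamily,
#'   type, agp_class, chimeric_agp, assigned_name, n_plcd, sp, alr, gas,
#'   ligand_z, chromosome, start.
#' @export
classify <- function(proteins, genes, mode = c("heuristic_scan", "truth_annotation"),
                     annotations = NULL, params = detector_params(),
                     prefix = "") {
  mode <- match.arg(mode)
  stopifnot(all(names(proteins) %in% genes$gene_id))
  if (mode == "truth_annotation" && is.null(annotations)) {
    stop("truth_annotation mode requires an annotation table")
  }
  rows <- lapply(names(proteins), function(id) {
    d <- if (mode == "heuristic_scan") {
      annotate_domains(id, proteins[[id]], params)
    } else {
      row <- annotations[annotations$gene_id == id, ]
      if (nrow(row) != 1L) stop("no annotation row for ", id)
      annotation_row_to_domains(as.list(row[1, ]))
    }
    g <- genes[genes$gene_id == id, ]
    if (length(d$plcds) == 0L) {
      return(tibble::tibble(
        protein_id = id, member = FALSE, subfamily = NA_character_,
        type = NA_character_, agp_class = NA_character_,
        chimeric_agp = NA, n_plcd = 0L,
        sp = !is.null(d$sp), alr = !is.null(d$alr), gas = !is.null(d$gas),
        ligand_z = NA_character_,
        chromosome = g$chromosome[1], start = g$start[1]
      ))
    }
    subfam <- assign_subfamily(d)
    type <- assign_type(d)
    agp <- assign_agp_class(d, type)
    complete <- Filter(function(s) isTRUE(s$complete), d$plcds)
    z <- if (length(complete) > 0L) {
      complete[[1]]$ligands$residue[complete[[1]]$ligands$slot == "Z"]
    } else {
      NA_character_
    }
    tibble::tibble(
      protein_id = id, member = TRUE, subfamily = subfam, type = type,
      agp_class = agp$agp_class, chimeric_agp = agp$chimeric_agp,
      n_plcd = length(d$plcds),
      sp = !is.null(d$sp), alr = !is.null(d$alr), gas = !is.null(d$gas),
      ligand_z = z,
      chromosome = g$chromosome[1], start = g$start[1]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$assigned_name <- NA_character_
  for (sf in unique(stats::na.omit(out$subfamily))) {
    idx <- which(out$member & out$subfamily == sf)
    ord <- idx[order(out$chromosome[idx], out$start[idx])]
    out$assigned_name[ord] <- paste0(prefix, sf, seq_along(ord))
  }
  out
}
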