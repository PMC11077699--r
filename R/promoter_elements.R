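# Promoter cis-element scanning against a dictionary of IUPAC consensi.
# The shipped dictionary uses standard published plant consensi and is
# fully user-replaceable; overlapping occurrences are all counted.

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N"
)

iupac_regex <- function(consensus) {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_DNA[[ch]]
    if (is.null(opts)) stop("invalid IUPAC code '", ch, "'")
    if (length(opts) == 1L) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

iupac_reverse_complement <- function(consensus) {
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Built-in plant cis-element dictionary
#'
#' Standard consensi for the light-, hormone-, stress- and
#' flavonoid-regulation elements commonly scanned in plant promoter work.
#'
#' @return Tibble with columns name, consensus, category.
#' @export
default_element_dictionary <- function() {
  tibble::tribble(
    ~name,          ~consensus,     ~category,
    "G-box",        "CACGTG",       "light",
    "I-box",        "GATAAG",       "light",
    "GT1-motif",    "GGTTAA",       "light",
    "ABRE",         "ACGTG",        "hormone",
    "TGACG-motif",  "TGACG",        "hormone",
    "CGTCA-motif",  "CGTCA",        "hormone",
    "TCA-element",  "CCATCTTTTT",   "hormone",
    "GARE-motif",   "TCTGTTG",      "hormone",
    "P-box",        "CCTTTTG",      "hormone",
    "AuxRE",        "TGTCTC",       "hormone",
    "as-1",         "TGACG",        "hormone",
    "ARE",          "AAACCA",       "stress",
    "LTR",          "CCGAAA",       "stress",
    "MBS",          "CAACTG",       "stress",
    "DRE",          "RCCGAC",       "stress",
    "MBSI",         "AAAAAACSGTTA", "flavonoid"
  )
}

#' Load a cis-element dictionary
#'
#' @param path Optional TSV with columns name, consensus, category; `NULL`
#'   loads the built-in dictionary.
#' @return Validated tibble with columns name, consensus, category.
#' @export
load_element_dictionary <- function(path = NULL) {
  el <- if (is.null(path)) {
    default_element_dictionary()
  } else {
    tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  }
  stopifnot(all(c("name", "consensus", "category") %in% names(el)))
  el$consensus <- toupper(el$consensus)
  for (i in seq_len(nrow(el))) {
    if (nchar(el$consensus[i]) < 4L) {
      stop("consensus of element '", el$name[i], "' is shorter than 4")
    }
    bad <- grepl(sprintf("[^%s]", paste(names(IUPAC_DNA), collapse = "")),
                 el$consensus[i])
    if (bad) stop("invalid IUPAC consensus for element '", el$name[i], "'")
    cat_ok <- el$category[i] %in% c("light", "hormone", "stress", "flavonoid", "other")
    if (!cat_ok) stop("invalid category for element '", el$name[i], "'")
  }
  el
}

overlapping_matches <- function(seq, regex) {
  m <- gregexpr(sprintf("(?=(%s))", regex), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  start <- as.vector(attr(m, "capture.start")[, 1], mode = "integer")
  len <- as.vector(attr(m, "capture.length")[, 1], mode = "integer")
  cbind(start = unname(start), end = unname(start + len - 1L))
}

#' Scan one promoter for cis-element hits
#'
#' Exhaustive IUPAC matching (all overlapping occurrences) on both strands;
#' positions are reported on the forward coordinate system and palindromic
#' double hits are deduplicated by (element, start, end).
#'
#' @param promoter Nucleotide string.
#' @param elements Element dictionary tibble (see
#'   [load_element_dictionary()]).
#' @return Tibble with columns element, start, end, strand, match.
#' @export
scan_promoter <- function(promoter, elements) {
  stopifnot(nchar(promoter) > 0L)
  promoter <- toupper(promoter)
  out <- list()
  for (i in seq_len(nrow(elements))) {
    name <- elements$name[i]
    cons <- elements$consensus[i]
    fwd <- overlapping_matches(promoter, iupac_regex(cons))
    if (!is.null(fwd)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        element = name, start = unname(fwd[, 1]), end = unname(fwd[, 2]),
        strand = "+",
        match = unname(substring(promoter, fwd[, 1], fwd[, 2]))
      )
    }
    rev <- overlapping_matches(promoter, iupac_regex(iupac_reverse_complement(cons)))
    if (!is.null(rev)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        element = name, start = unname(rev[, 1]), end = unname(rev[, 2]),
        strand = "-",
        match = unname(substring(promoter, rev[, 1], rev[, 2]))
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(element = character(), start = integer(),
                          end = integer(), strand = character(),
                          match = character()))
  }
  hits <- dplyr::bind_rows(out)
  hits <- hits[order(hits$element, hits$start, hits$strand), ]
  hits[!duplicated(hits[, c("element", "start", "end")]), ]
}

#' Scan a set of promoters
#'
#' @param promoters Named character vector of promoter sequences.
#' @param elements Element dictionary tibble.
#' @return Tibble of hits with a gene_id column.
#' @export
scan_promoters <- function(promoters, elements) {
  rows <- lapply(names(promoters), function(id) {
    h <- scan_promoter(promoters[[id]], elements)
    if (nrow(h) > 0L) h$gene_id <- id
    h
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(element = character(), start = integer(),
                          end = integer(), strand = character(),
                          match = character(), gene_id = character())
  }
  dplyr::relocate(out, "gene_id")
}

#' Summarize cis-element hits per gene
#'
#' @param hits Hit tibble from [scan_promoters()].
#' @param elements Element dictionary tibble.
#' @param gene_ids All gene ids (genes without hits get zero rows).
#' @return Tibble gene_id x element counts, plus one `cat_<category>`
#'   total column per category.
#' @export
summarize_counts <- function(hits, elements, gene_ids) {
  counts <- matrix(0L, nrow = length(gene_ids), ncol = nrow(elements),
                   dimnames = list(gene_ids, elements$name))
  if (nrow(hits) > 0L) {
    tab <- table(factor(hits$gene_id, levels = gene_ids),
                 factor(hits$element, levels = elements$name))
    counts[] <- as.integer(tab)
  }
  out <- tibble::as_tibble(counts)
  out <- dplyr::mutate(out, gene_id = gene_ids, .before = 1L)
  for (cat in unique(elements$category)) {
    members <- elements$name[elements$category == cat]
    out[[paste0("cat_", cat)]] <- as.integer(rowSums(counts[, members, drop = FALSE]))
  }
  out
}
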