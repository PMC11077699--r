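# Sequence and gene-model I/O: FASTA, GFF3, translation, promoter windows.
# Coordinates are 1-based inclusive throughout (GFF3 convention); slicing
# converts at the call site, never in stored objects.

#' Read a FASTA file into a named character vector
#'
#' Record ids are the first whitespace-delimited token of each header;
#' sequences are uppercased and record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path)
  }
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)), !anyNA(seqs))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Returns one row per record of the requested feature type, with 1-based
#' inclusive coordinates as printed in the file, sorted by
#' (chromosome, start). The `ID` attribute becomes `gene_id`.
#'
#' @param path Path to a GFF3 file (9 tab-separated columns).
#' @param feature Feature type to keep (column 3), default `"gene"`.
#' @return Tibble with columns gene_id, chromosome, start, end, strand.
#' @export
read_gff3 <- function(path, feature = "gene") {
  stopifnot(file.exists(path))
  raw <- readLines(path)
  keep <- !grepl("^#", raw) & nzchar(raw)
  lineno <- which(keep)
  if (length(lineno) == 0L) stop("no records in GFF3 file: ", path)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    stop("GFF3 line ", lineno[bad[1]], " does not have 9 columns")
  }
  m <- do.call(rbind, fields)
  sel <- m[, 3] == feature
  if (!any(sel)) {
    return(tibble::tibble(
      gene_id = character(), chromosome = character(),
      start = integer(), end = integer(), strand = character()
    ))
  }
  m <- m[sel, , drop = FALSE]
  lineno <- lineno[sel]
  start <- as.integer(m[, 4])
  end <- as.integer(m[, 5])
  bad <- which(is.na(start) | is.na(end) | start > end | start < 1L)
  if (length(bad) > 0L) {
    stop("invalid coordinates (start > end or non-positive) at GFF3 line ",
         lineno[bad[1]])
  }
  id <- sub(".*ID=([^;]+).*", "\\1", m[, 9])
  noid <- !grepl("(^|;)ID=", m[, 9])
  if (any(noid)) {
    stop("missing ID attribute at GFF3 line ", lineno[which(noid)[1]])
  }
  out <- tibble::tibble(
    gene_id = id, chromosome = m[, 1],
    start = start, end = end, strand = m[, 7]
  )
  out[order(out$chromosome, out$start), ]
}

#' Write gene models to GFF3
#'
#' @param genes Tibble with gene_id, chromosome, start, end, strand.
#' @param path Output path.
#' @param feature Feature type for column 3 (default `"gene"`).
#' @param source Source tag for column 2.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, feature = "gene", source = "pcfam") {
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                   genes$chromosome, source, feature,
                   genes$start, genes$end, genes$strand, genes$gene_id)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# Standard genetic code keyed on DNA codons, taken from Biostrings.
genetic_code <- function() Biostrings::GENETIC_CODE

STOP_CODONS <- c("TAA", "TAG", "TGA")

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Validate a coding sequence
#'
#' Checks the alphabet, length divisibility by 3, the ATG start (optional)
#' and the absence of internal stop codons.
#'
#' @param cds Nucleotide string.
#' @param require_atg Require an ATG start codon.
#' @param allow_unknown Permit `N` bases.
#' @return `cds` (uppercased), invisibly; errors otherwise.
#' @export
validate_cds <- function(cds, require_atg = TRUE, allow_unknown = TRUE) {
  cds <- toupper(cds)
  alphabet <- if (allow_unknown) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), cds)) {
    stop("CDS contains characters outside {", alphabet, "}")
  }
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  }
  if (require_atg && substr(cds, 1L, 3L) != "ATG") {
    stop("CDS does not begin with ATG")
  }
  codons <- split_codons(cds)
  internal <- codons[-length(codons)]
  if (any(internal %in% STOP_CODONS)) {
    stop("CDS contains an internal stop codon")
  }
  invisible(cds)
}

#' Translate a coding sequence with the standard genetic code
#'
#' A trailing stop codon is dropped; an internal stop is an error. Codons
#' containing `N` translate to `X` when `allow_unknown` is on, and are an
#' error otherwise.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @param allow_unknown Permit ambiguous bases (translated as `X`).
#' @return Amino-acid string.
#' @export
translate <- function(cds, allow_unknown = FALSE) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length ", nchar(cds), " is not a multiple of 3")
  }
  alphabet <- if (allow_unknown) "ACGTN" else "ACGT"
  if (grepl(sprintf("[^%s]", alphabet), cds)) {
    stop("CDS contains characters outside {", alphabet, "}")
  }
  codons <- split_codons(cds)
  if (length(codons) == 0L) return("")
  if (codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  if (any(codons %in% STOP_CODONS)) {
    stop("internal stop codon at codon ",
         which(codons %in% STOP_CODONS)[1])
  }
  gc <- genetic_code()
  aa <- gc[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param x Nucleotide string over A, C, G, T, N (case preserved as upper).
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(x) {
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the upstream promoter window of a gene
#'
#' The window is anchored at the 5' end of the gene feature: for `+` strand
#' genes the `length` bases immediately before `start`, for `-` strand genes
#' the reverse complement of the `length` bases immediately after `end`.
#' Windows clipped by the chromosome boundary return the available portion
#' with `truncated = TRUE`.
#'
#' @param gene List or one-row data frame with chromosome, start, end, strand.
#' @param genome Named character vector of chromosome sequences.
#' @param length Window length in bp (default 2000).
#' @return List with `sequence` (string) and `truncated` (logical).
#' @export
extract_promoter <- function(gene, genome, length = 2000L) {
  chrom <- as.character(gene$chromosome)
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome: ", chrom)
  }
  chrseq <- genome[[chrom]]
  clen <- nchar(chrseq)
  if (gene$strand == "+") {
    from <- max(1L, gene$start - length)
    to <- gene$start - 1L
    truncated <- (gene$start - length) < 1L
    seq <- if (to >= from) substr(chrseq, from, to) else ""
  } else {
    from <- gene$end + 1L
    to <- min(clen, gene$end + length)
    truncated <- (gene$end + length) > clen
    seq <- if (to >= from) reverse_complement(substr(chrseq, from, to)) else ""
  }
  list(sequence = seq, truncated = truncated)
}

#' Extract the coding sequence of a gene from a genome
#'
#' Takes the gene span from the chromosome, reverse complements on the `-`
#' strand, and drops a trailing stop codon if present.
#'
#' @inheritParams extract_promoter
#' @param drop_stop Drop a trailing stop codon (default TRUE).
#' @return Nucleotide string.
#' @export
extract_cds <- function(gene, genome, drop_stop = TRUE) {
  chrom <- as.character(gene$chromosome)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  s <- substr(genome[[chrom]], gene$start, gene$end)
  if (gene$strand == "-") s <- reverse_complement(s)
  if (drop_stop && nchar(s) %% 3L == 0L && nchar(s) >= 3L) {
    last <- substr(s, nchar(s) - 2L, nchar(s))
    if (last %in% STOP_CODONS) s <- substr(s, 1L, nchar(s) - 3L)
  }
  s
}
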