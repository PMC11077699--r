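# Independent oracles, deliberately written against different primitives
# than the implementation they check.

GC_TABLE <- Biostrings::GENETIC_CODE

oracle_aa <- function(codon) unname(GC_TABLE[codon])

# NG86 site oracle: enumerate all nine single-base mutations per codon.
oracle_ng86_sites <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  S <- 0; n_used <- 0
  for (cod in codons) {
    if (grepl("[^ACGT]", cod) || oracle_aa(cod) == "*") next
    n_used <- n_used + 1
    for (pos in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(cod, pos, pos)) next
        mut <- paste0(substr(cod, 1, pos - 1), b, substr(cod, pos + 1, 3))
        if (oracle_aa(mut) != "*" && oracle_aa(mut) == oracle_aa(cod)) {
          S <- S + 1 / 3
        }
      }
    }
  }
  c(S = S, N = 3 * n_used - S)
}

# Exhaustive pathway-enumeration oracle for NG86 differences.
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

oracle_ng86_differences <- function(a, b, count_stop_paths = FALSE) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    x <- strsplit(ca[i], "")[[1]]; y <- strsplit(cb[i], "")[[1]]
    if (any(!c(x, y) %in% c("A", "C", "G", "T"))) next
    if (oracle_aa(ca[i]) == "*" || oracle_aa(cb[i]) == "*") next
    dpos <- which(x != y)
    if (length(dpos) == 0) next
    tot_s <- 0; tot_n <- 0; n_ok <- 0
    for (ord in perms_of(dpos)) {
      cur <- x; s <- 0; n <- 0; ok <- TRUE
      for (p in ord) {
        nxt <- cur; nxt[p] <- y[p]
        a1 <- oracle_aa(paste(cur, collapse = ""))
        a2 <- oracle_aa(paste(nxt, collapse = ""))
        if (!count_stop_paths && a2 == "*") { ok <- FALSE; break }
        if (a1 == a2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n; n_ok <- n_ok + 1 }
    }
    if (n_ok > 0) { Sd <- Sd + tot_s / n_ok; Nd <- Nd + tot_n / n_ok }
  }
  c(Sd = Sd, Nd = Nd)
}

# Grid-search pI oracle on the same pKa table, independent charge formula.
oracle_pi <- function(p, step = 0.001) {
  tab <- c(table(factor(strsplit(p, "")[[1]],
                        levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])))
  first <- substr(p, 1, 1); last <- substr(p, nchar(p), nchar(p))
  nt <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
  ct <- c(D = 4.55, E = 4.75)
  pk_nt <- if (first %in% names(nt)) nt[[first]] else 7.5
  pk_ct <- if (last %in% names(ct)) ct[[last]] else 3.55
  pHs <- seq(0, 14, by = step)
  q <- 1 / (1 + 10^(pHs - pk_nt)) +
    tab[["K"]] / (1 + 10^(pHs - 10.0)) +
    tab[["R"]] / (1 + 10^(pHs - 12.0)) +
    tab[["H"]] / (1 + 10^(pHs - 5.98)) -
    1 / (1 + 10^(pk_ct - pHs)) -
    tab[["D"]] / (1 + 10^(4.05 - pHs)) -
    tab[["E"]] / (1 + 10^(4.45 - pHs)) -
    tab[["C"]] / (1 + 10^(9.0 - pHs)) -
    tab[["Y"]] / (1 + 10^(10.0 - pHs))
  pHs[which.min(abs(q))]
}

# Naive character-by-character IUPAC sliding-window scanner.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

# character-level sliding-window match: per consensus offset, test set
# membership of the shifted sequence characters (no regular expressions)
oracle_scan_starts <- function(seq_chars, cons) {
  cc <- strsplit(cons, "")[[1]]
  w <- length(cc)
  n <- length(seq_chars)
  if (n < w) return(integer(0))
  ok <- rep(TRUE, n - w + 1)
  for (k in seq_len(w)) {
    ok <- ok & seq_chars[(k):(n - w + k)] %in% IUPAC_SETS[[cc[k]]]
  }
  which(ok)
}

oracle_scan <- function(promoter, name, consensus) {
  sc <- strsplit(toupper(promoter), "")[[1]]
  rc_cons <- paste(rev(unname(
    c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
      W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
      N = "N")[strsplit(toupper(consensus), "")[[1]]])), collapse = "")
  w <- nchar(consensus)
  hits <- list()
  for (cons in unique(c(toupper(consensus), rc_cons))) {
    strand <- if (cons == toupper(consensus)) "+" else "-"
    for (s in oracle_scan_starts(sc, cons)) {
      hits[[length(hits) + 1]] <- data.frame(
        element = name, start = s, end = s + w - 1, strand = strand)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(element = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  out <- do.call(rbind, hits)
  out[!duplicated(out[, c("element", "start", "end")]), ]
}

# Direct transcription of Wright's ENC formula as an independent check.
oracle_enc <- function(counts) {
  aa <- GC_TABLE[GC_TABLE != "*"]
  fam <- split(names(aa), aa)
  fbar <- list()
  for (k in c(2, 3, 4, 6)) {
    fs <- c()
    for (a in names(fam)[lengths(fam) == k]) {
      n <- sum(counts[fam[[a]]])
      if (n < 2) next
      f <- (n * sum((counts[fam[[a]]] / n)^2) - 1) / (n - 1)
      if (f > 0) fs <- c(fs, f)
    }
    fbar[[as.character(k)]] <- if (length(fs)) mean(fs) else NA
  }
  if (is.na(fbar[["3"]])) fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  if (any(vapply(fbar, is.na, logical(1)))) return(NA_real_)
  min(61, 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
        3 / fbar[["6"]])
}

# Random sequence helpers for property tests.
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  paste(c("ATG", sample(sense, n_codons - 1, TRUE)), collapse = "")
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, TRUE),
        collapse = "")
}

small_family <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_family(family_sim_config(
        n_genes = 24L, n_chromosomes = 4L, seed = 42L,
        pair_divergence = list(c(0.08, 0.01))))
    }
    cache
  }
})
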