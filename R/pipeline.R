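# End-to-end characterization pipeline: identify/classify -> properties ->
# codon bias -> Ka/Ks + tandem clusters -> promoters -> expression ->
# summary, with TSV outputs and a JSON manifest per run.

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Pipeline run configuration
#'
#' @param genome Path to the genome FASTA.
#' @param gff3 Path to the gene-model GFF3.
#' @param annotations Optional domain-annotation TSV (enables
#'   truth_annotation mode).
#' @param pairs Optional TSV of aligned duplicate pairs (gene_a, gene_b).
#' @param ct Optional qPCR Ct TSV.
#' @param anthocyanin Optional anthocyanin TSV (sample_id, od530, od600,
#'   mass_g).
#' @param mode Classification mode.
#' @param promoter_length Promoter window in bp (default 2000).
#' @param max_separation,max_intervening Tandem-cluster parameters.
#' @param dictionary Optional cis-element dictionary TSV.
#' @param calibrator Calibrator sample for expression.
#' @param prefix Member name prefix.
#' @param seed Integer seed recorded in the manifest.
#' @param out_dir Output directory.
#' @return Validated config list.
#' @export
pipeline_config <- function(genome, gff3, annotations = NULL, pairs = NULL,
                            ct = NULL, anthocyanin = NULL,
                            mode = c("heuristic_scan", "truth_annotation"),
                            promoter_length = 2000L,
                            max_separation = 250000L, max_intervening = 5L,
                            dictionary = NULL, calibrator = "DAF1",
                            prefix = "", seed = 1L, out_dir = "pcfam_run") {
  mode <- match.arg(mode)
  stopifnot(promoter_length > 0L)
  for (p in c(genome, gff3, annotations, pairs, ct, anthocyanin, dictionary)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  if (mode == "truth_annotation" && is.null(annotations)) {
    stop("truth_annotation mode requires an annotations table")
  }
  list(genome = genome, gff3 = gff3, annotations = annotations,
       pairs = pairs, ct = ct, anthocyanin = anthocyanin, mode = mode,
       promoter_length = as.integer(promoter_length),
       max_separation = as.integer(max_separation),
       max_intervening = as.integer(max_intervening),
       dictionary = dictionary, calibrator = calibrator, prefix = prefix,
       seed = as.integer(seed), out_dir = out_dir)
}

read_tsv_in <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Run the full family-characterization pipeline
#'
#' Executes the stages in dependency order, writes one TSV per stage under
#' `config$out_dir` plus a `manifest.json` with tool version, config hash
#' and per-stage row counts and output hashes. Optional stages without
#' inputs are skipped with a notice.
#'
#' @param config Output of [pipeline_config()].
#' @param quiet Suppress stage messages.
#' @return List of stage results (invisibly includes the manifest).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[pcfam] ", ...)
  manifest <- list(
    tool = "pcfam",
    version = as.character(utils::packageVersion("pcfam")),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    stages = list()
  )
  note <- function(name, rows, file) {
    manifest$stages[[name]] <<- list(
      rows = rows, file = basename(file),
      hash = rlang::hash(readLines(file)))
  }

  say("loading inputs")
  genome <- read_fasta(config$genome)
  genes <- read_gff3(config$gff3)
  cds_set <- stats::setNames(
    vapply(seq_len(nrow(genes)), function(i) {
      extract_cds(genes[i, ], genome)
    }, character(1)), genes$gene_id)
  proteins <- vapply(cds_set, translate, character(1))

  say("classifying ", length(proteins), " proteins (", config$mode, ")")
  annotations <- if (!is.null(config$annotations)) {
    read_tsv_in(config$annotations)
  }
  classification <- classify(proteins, genes, mode = config$mode,
                             annotations = annotations,
                             prefix = config$prefix)
  f <- write_tsv(classification, file.path(config$out_dir, "classification.tsv"))
  note("classification", nrow(classification), f)
  members <- classification$protein_id[classification$member]

  say("computing physicochemical profiles")
  props <- protein_profiles(proteins[members])
  f <- write_tsv(props, file.path(config$out_dir, "protein_properties.tsv"))
  note("protein_properties", nrow(props), f)

  say("computing codon-usage profiles")
  profiles <- codon_usage_profiles(cds_set[members])
  prof_out <- profiles[, setdiff(names(profiles), "counts")]
  f <- write_tsv(prof_out, file.path(config$out_dir, "codon_usage.tsv"))
  note("codon_usage", nrow(prof_out), f)
  pooled <- optimal_codons(cds_set[members])
  opt_tbl <- tibble::tibble(codon = pooled)
  f <- write_tsv(opt_tbl, file.path(config$out_dir, "optimal_codons.tsv"))
  note("optimal_codons", nrow(opt_tbl), f)
  corr <- index_correlations(profiles)
  corr_tbl <- tibble::as_tibble(corr, rownames = "index")
  f <- write_tsv(corr_tbl, file.path(config$out_dir, "index_correlations.tsv"))
  note("index_correlations", nrow(corr_tbl), f)

  kaks_tbl <- NULL
  if (!is.null(config$pairs)) {
    say("computing Ka/Ks for duplicate pairs")
    pairs <- read_tsv_in(config$pairs)
    kaks_tbl <- kaks_pairs(pairs, cds_set)
    f <- write_tsv(kaks_tbl, file.path(config$out_dir, "kaks.tsv"))
    note("kaks", nrow(kaks_tbl), f)
  } else {
    say("no pairs table; skipping Ka/Ks stage")
  }

  say("detecting tandem clusters")
  clusters <- tandem_clusters(genes, members,
                              max_separation = config$max_separation,
                              max_intervening = config$max_intervening)
  f <- write_tsv(clusters, file.path(config$out_dir, "tandem_clusters.tsv"))
  note("tandem_clusters", nrow(clusters), f)

  say("scanning promoters (", config$promoter_length, " bp)")
  dict <- load_element_dictionary(config$dictionary)
  promoters <- stats::setNames(
    vapply(seq_len(nrow(genes)), function(i) {
      extract_promoter(genes[i, ], genome, config$promoter_length)$sequence
    }, character(1)), genes$gene_id)
  promoters <- promoters[members]
  hits <- scan_promoters(promoters, dict)
  f <- write_tsv(hits, file.path(config$out_dir, "promoter_hits.tsv"))
  note("promoter_hits", nrow(hits), f)
  counts <- summarize_counts(hits, dict, members)
  f <- write_tsv(counts, file.path(config$out_dir, "promoter_counts.tsv"))
  note("promoter_counts", nrow(counts), f)

  folds <- NULL
  if (!is.null(config$ct)) {
    say("quantifying expression (2^-ddCt)")
    ct <- read_tsv_in(config$ct)
    folds <- delta_delta_ct(ct, calibrator = config$calibrator)
    f <- write_tsv(folds, file.path(config$out_dir, "expression_folds.tsv"))
    note("expression_folds", nrow(folds), f)
  } else {
    say("no Ct table; skipping expression stage")
  }
  antho <- NULL
  if (!is.null(config$anthocyanin)) {
    tab <- read_tsv_in(config$anthocyanin)
    antho <- dplyr::bind_cols(
      tab["sample_id"],
      anthocyanin_units(tab$od530, tab$od600, tab$mass_g))
    f <- write_tsv(antho, file.path(config$out_dir, "anthocyanin.tsv"))
    note("anthocyanin", nrow(antho), f)
  }

  say("summarizing family")
  summary_tbl <- summarize_family(classification, clusters, counts, dict)
  f <- write_tsv(summary_tbl, file.path(config$out_dir, "summary.tsv"))
  note("summary", nrow(summary_tbl), f)

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(classification = classification, properties = props,
                 codon_usage = prof_out, optimal_codons = pooled,
                 correlations = corr, kaks = kaks_tbl, clusters = clusters,
                 promoter_hits = hits, promoter_counts = counts,
                 expression = folds, anthocyanin = antho,
                 summary = summary_tbl, manifest = manifest))
}

#' Summarize a classified family
#'
#' Counts per subfamily, type and chromosome, AGP tallies, tandem-cluster
#' count and the number of genes with at least one promoter element per
#' category.
#'
#' @param classification Output of [classify()].
#' @param clusters Output of [tandem_clusters()].
#' @param promoter_counts Output of [summarize_counts()] (optional).
#' @param elements Element dictionary used for the scan (optional).
#' @return Long tibble with columns section, key, count.
#' @export
summarize_family <- function(classification, clusters = NULL,
                             promoter_counts = NULL, elements = NULL) {
  mem <- classification[classification$member, ]
  row <- function(section, key, count) {
    tibble::tibble(section = section, key = as.character(key),
                   count = as.integer(count))
  }
  out <- list(row("total", "members", nrow(mem)))
  for (sf in sort(unique(mem$subfamily))) {
    out[[length(out) + 1L]] <- row("subfamily", sf, sum(mem$subfamily == sf))
  }
  for (tp in sort(unique(mem$type))) {
    out[[length(out) + 1L]] <- row("type", tp, sum(mem$type == tp))
  }
  for (ch in sort(unique(mem$chromosome))) {
    out[[length(out) + 1L]] <- row("chromosome", ch, sum(mem$chromosome == ch))
  }
  for (ac in sort(unique(mem$agp_class))) {
    out[[length(out) + 1L]] <- row("agp_class", ac, sum(mem$agp_class == ac))
  }
  out[[length(out) + 1L]] <- row("agp_class", "chimeric_AGP",
                                 sum(mem$chimeric_agp))
  if (!is.null(clusters)) {
    out[[length(out) + 1L]] <- row("tandem", "clusters", nrow(clusters))
    out[[length(out) + 1L]] <- row(
      "tandem", "genes_in_clusters",
      if (nrow(clusters)) sum(clusters$n_members) else 0L)
  }
  if (!is.null(promoter_counts) && !is.null(elements)) {
    for (cat in unique(elements$category)) {
      col <- paste0("cat_", cat)
      if (col %in% names(promoter_counts)) {
        out[[length(out) + 1L]] <- row(
          "promoter_category", cat, sum(promoter_counts[[col]] > 0))
      }
    }
  }
  dplyr::bind_rows(out)
}
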