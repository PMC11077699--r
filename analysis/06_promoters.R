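#!/usr/bin/env Rscript
# Stage 6: scan the 2 kb upstream promoter of every family gene for the
# plant cis-element dictionary and summarize counts per category (light,
# hormone, stress, flavonoid regulation).

library(pcfam)

dat <- "results/data"
genome <- read_fasta(file.path(dat, "genome.fna"))
genes <- read_gff3(file.path(dat, "genes.gff3"))
cl <- read.delim("results/classification.tsv")

dict <- load_element_dictionary()
members <- cl$protein_id[cl$member]
proms <- setNames(vapply(seq_len(nrow(genes)), function(i) {
  extract_promoter(genes[i, ], genome, 2000L)$sequence
}, character(1)), genes$gene_id)[members]

hits <- scan_promoters(proms, dict)
counts <- summarize_counts(hits, dict, members)
write.table(hits, "results/promoter_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(counts, "results/promoter_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Scanned", length(proms), "promoters;", nrow(hits), "element hits.\n")
for (cat_name in unique(dict$category)) {
  col <- paste0("cat_", cat_name)
  cat(sprintf("genes with >=1 %s element: %d\n", cat_name,
              sum(counts[[col]] > 0)))
}
cat("genes with >=1 MeJA (TGACG/CGTCA) element:",
    sum(counts[["TGACG-motif"]] + counts[["CGTCA-motif"]] > 0), "\n")
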