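#!/usr/bin/env Rscript
# Stage 5: selection pressure on the duplicate pairs (NG86 Ka/Ks with
# Jukes-Cantor correction) and tandem-duplication clusters from the gene
# positions.

library(pcfam)

dat <- "results/data"
genome <- read_fasta(file.path(dat, "genome.fna"))
genes <- read_gff3(file.path(dat, "genes.gff3"))
pairs <- read.delim(file.path(dat, "pairs.tsv"))
cl <- read.delim("results/classification.tsv")

cds <- setNames(vapply(seq_len(nrow(genes)), function(i) {
  extract_cds(genes[i, ], genome)
}, character(1)), genes$gene_id)

kk <- kaks_pairs(pairs, cds)
write.table(kk, "results/kaks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("Ka/Ks for", nrow(kk), "duplicate pairs:\n")
print(as.data.frame(kk[, c("gene_a", "gene_b", "Ka", "Ks", "ratio",
                           "selection_class")]))

clusters <- tandem_clusters(genes, cl$protein_id[cl$member])
write.table(clusters, "results/tandem_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(nrow(clusters), "tandem clusters detected:\n")
print(as.data.frame(clusters))
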