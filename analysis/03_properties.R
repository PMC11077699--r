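#!/usr/bin/env Rscript
# Stage 3: physicochemical profiles of the classified proteins — length,
# molecular weight, pI (with the acidic/neutral/basic split at 6.5/7.5),
# GRAVY, aliphatic and instability indices.

library(pcfam)

dat <- "results/data"
genome <- read_fasta(file.path(dat, "genome.fna"))
genes <- read_gff3(file.path(dat, "genes.gff3"))
cl <- read.delim("results/classification.tsv")

cds <- setNames(vapply(seq_len(nrow(genes)), function(i) {
  extract_cds(genes[i, ], genome)
}, character(1)), genes$gene_id)
proteins <- vapply(cds, translate, character(1))

prof <- protein_profiles(proteins[cl$protein_id[cl$member]])
write.table(prof, "results/protein_properties.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Lengths %d-%d aa; MW %.2f-%.2f kDa; pI %.2f-%.2f\n",
            min(prof$length), max(prof$length),
            min(prof$molecular_weight) / 1000,
            max(prof$molecular_weight) / 1000,
            min(prof$pI), max(prof$pI)))
cat("Acidity classes:\n"); print(table(prof$acidity_class))
cat("Hydropathy classes:\n"); print(table(prof$hydropathy_class))
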