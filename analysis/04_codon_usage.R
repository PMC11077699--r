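#!/usr/bin/env Rscript
# Stage 4: codon-usage bias of the family — per-gene ENC/CAI/CBI/Fop and
# base composition, pooled RSCU with the RSCU>1 optimal-codon set, and
# the correlation structure among indices.

library(pcfam)

dat <- "results/data"
genome <- read_fasta(file.path(dat, "genome.fna"))
genes <- read_gff3(file.path(dat, "genes.gff3"))
cl <- read.delim("results/classification.tsv")

cds <- setNames(vapply(seq_len(nrow(genes)), function(i) {
  extract_cds(genes[i, ], genome)
}, character(1)), genes$gene_id)
cds <- cds[cl$protein_id[cl$member]]

prof <- codon_usage_profiles(cds)
write.table(prof[, setdiff(names(prof), "counts")],
            "results/codon_usage.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

opt <- optimal_codons(cds)
pooled <- Reduce(`+`, lapply(lapply(cds, codon_counts), as.integer))
pooled_rscu <- rscu(setNames(pooled, names(codon_counts(cds[[1]]))))
rscu_tbl <- data.frame(codon = names(render_codons(pooled_rscu)),
                       rscu = as.numeric(pooled_rscu))
write.table(rscu_tbl, "results/pooled_rscu.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

corr <- index_correlations(prof)
write.table(data.frame(index = rownames(corr), corr, check.names = FALSE),
            "results/index_correlations.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("ENC range %.2f-%.2f; GC range %.2f-%.2f\n",
            min(prof$enc, na.rm = TRUE), max(prof$enc, na.rm = TRUE),
            min(prof$gc), max(prof$gc)))
cat("Optimal (pooled RSCU>1) codons:",
    paste(names(render_codons(setNames(seq_along(opt), opt))),
          collapse = " "), "\n")
cat(sprintf("cor(GC3s, C3s) = %.3f; cor(GC3s, T3s) = %.3f; cor(Fop, CAI) = %.3f\n",
            corr["gc3s", "c3s"], corr["gc3s", "t3s"], corr["fop", "cai"]))
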