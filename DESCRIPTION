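Package: pcfam
Title: Genome-Wide Characterization of Plant Phytocyanin Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genome-wide identification and characterization of
    plant phytocyanin (blue copper cupredoxin) gene families. Detects the
    four diagnostic structural modules (signal peptide, plastocyanin-like
    domain with its copper-ligand residues, arabinogalactan-like region,
    GPI anchor signal), applies rule-based subfamily (UCL/SCL/PLCL/ENODL),
    type (I-VIII) and arabinogalactan-protein class assignment, and computes
    protein physicochemical profiles, codon-usage-bias statistics (RSCU,
    ENC, CAI, CBI, Fop), pairwise Ka/Ks by the Nei-Gojobori method, tandem
    duplication clusters, promoter cis-element scans, anthocyanin units and
    qPCR relative expression with ANOVA/Tukey grouping. A synthetic-genome
    generator with planted ground truth makes every stage testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
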