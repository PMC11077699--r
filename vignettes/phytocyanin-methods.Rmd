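---
title: "Methods: rule-based phytocyanin family characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based phytocyanin family characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfam)
```

# Scope and model

`pcfam` characterizes a plant phytocyanin (blue copper cupredoxin) gene
family from a genome FASTA and gene-model GFF3. The scientific content is
a set of explicit decision rules and classical statistics; there is no
fitted model. This vignette records how each rule is defined, which
parameters matter, what the synthetic benchmark does and does not
demonstrate, and where genuinely open design choices were resolved.

## Domain detection

Published family surveys delegate domain calls to external predictors
(signal-peptide, GPI and N-glycosylation servers, domain databases).
Those services are not scriptable offline, so `pcfam` ships transparent
heuristics with the same *shape* of output; parity with any particular
server is explicitly not claimed, and every threshold is a visible
parameter of `detector_params()`:

* **Signal peptide** — residue 1 must be Met and some 8-residue window
  starting in residues 2–25 must average Kyte–Doolittle hydropathy
  ≥ 1.6 (`sp_hydropathy`). This is the classical n/h-region picture:
  a charged N-terminus followed by a hydrophobic core.
* **PLCD** — a complete copper site matches
  `H x(20,90) C x(2,20) H x(2,20) [MQ]` (`plcd_gap*`), scanned
  left-to-right without overlap; the spacer windows are deliberately much
  wider than any single family's spacing. An *incomplete* (ENODL-type)
  site requires the disulfide Cys scaffold `C x(2,60) C` plus at least
  two of the four ligand slots while failing the full pattern.
* **ALR** — merged 20-residue windows with ≥ 50 % Pro/Ala/Ser/Thr
  (`past_fraction`), total run ≥ 20 residues, outside SP/PLCD/GAS spans.
  PAST-richness is the defining property of arabinogalactan
  glycomodules.
* **GAS** — mean hydropathy of the final 12 residues ≥ 1.5
  (`gas_hydropathy`) plus a small omega-site candidate
  ({G,A,S,N,D,C}) 15–30 residues from the C-terminus; when several
  candidates qualify the most C-terminal one is taken, matching the
  omega–spacer–hydrophobic-tail architecture of GPI signals.
* **N-glycosylation** — the sequon N-X-S/T with X ≠ P.

## Classification rules

Subfamily is a function of the copper-ligand set: no complete set →
ENODL; fourth ligand Gln → SCL; fourth ligand Met with an ALR → UCL,
without → PLCL. The published verbal rule for SCLs is ambiguous in
isolation; the conserved-site notation H-C-(C)-H-Q for stellacyanins
fixes Gln as the SCL axial ligand, and that is what the code implements.

Type I–VIII is a pure lookup on (SP, ALR, GAS, PLCD count):

| type | SP | PLCD | ALR | GAS |
|------|----|------|-----|-----|
| I    | +  | 2    | +   | +   |
| II   | +  | 1    | +   | +   |
| III  | +  | 1    | +   | −   |
| IV   | +  | 1    | −   | −   |
| V    | +  | 1    | −   | +   |
| VI   | −  | 1    | +   | +   |
| VII  | −  | 2    | +   | +   |
| VIII | −  | 1    | −   | −   |

Any other combination returns `UNCLASSIFIED` rather than a forced call.
Types VI and VII are distinguished by PLCD count — the only assignment
consistent with all the textual constraints the type system carries (SP
absent from VI/VII/VIII, ALR absent from IV/V/VIII, GAS on I/II/V/VI/VII,
two PLCDs in I). The PLCD count includes incomplete sites, so an ENODL
with two incomplete domains can be type I. AGP classes: no ALR →
`non_AGP`; types I–II → `typical_AGP`; III/VI/VII → `atypical_AGP`; an
ALR-bearing protein of any other (unclassified) type is reported
atypical. SP together with ALR flags a chimeric AGP.

Members are renamed `<Subfamily><counter>` in (chromosome, start) order
within each subfamily, mirroring the positional renaming convention of
genome-wide surveys.

## Physicochemical profile

Molecular weight is the sum of average residue masses plus one water.
pI solves the Henderson–Hasselbalch net-charge equation over
D, E, C, Y, H, K, R and both termini on the Bjellqvist pKa set
(residue-specific terminal pKa where tabulated; the table is shipped as
data and swappable). The charge is monotone decreasing in pH, so
bisection on [0, 14] to |charge| < 1e−4 has a unique answer; tests
compare it with a 0.001-step grid search on the same table. GRAVY is the
mean Kyte–Doolittle value; the aliphatic index is
X(A) + 2.9·X(V) + 3.9·(X(I)+X(L)) in mole percent; the instability index
is (10/L)·Σ of Guruprasad dipeptide weights. Acidity classes follow the
printed convention basic > 7.5, neutral 6.5–7.5 (boundaries inclusive to
neutral, since the source prints a closed interval), acidic < 6.5;
hydropathic vs hydrophilic is keyed on the GRAVY sign because no other
threshold is stated anywhere.

## Codon usage

Counts are over the 61 sense codons; codons containing N are excluded
rather than guessed; internal spelling is DNA (T), with a renderer flag
for RNA reports. ENC follows Wright: per amino acid with n > 1,
F̂ = (n·Σp̂² − 1)/(n − 1); class means over degeneracy classes 2/3/4/6 use
amino acids with F̂ > 0; a missing 3-fold class is interpolated as
(F̄₂+F̄₄)/2 (Wright's own prescription — the source papers are silent);
any other missing class makes ENC undefined rather than extrapolated,
and values are clipped at 61. CAI needs an explicit reference weight
table because published family papers rarely state their reference set;
`cai_weights()` derives weights from any pooled count vector with
optional 0.5 pseudo-counts, and `codon_usage_profiles()` defaults to the
analyzed family itself. The optimal-codon set for CBI/Fop defaults to
the pooled RSCU > 1 codons of the family, matching the common "RSCU > 1
defines the optimal codons" language, and is overridable. Correlations
are pairwise-complete Pearson; zero-variance columns yield NA entries,
not errors.

## Ka/Ks

The estimator is Nei–Gojobori (1986) with equal weighting of minimal
mutational pathways and Jukes–Cantor correction — the simple counting
method that desktop synteny tools default to; codon-model ML estimators
are out of scope. Two conventions required a decision:

* mutations *to* stop codons count as nonsynonymous in the site counts;
* pathways *through* stop codons are excluded with renormalization over
  the remaining orderings (`count_stop_paths = TRUE` restores naive
  averaging for oracle comparisons); a codon pair whose pathways all
  cross stops is excluded and tallied.

Gap/ambiguity handling is whole-codon exclusion, never position-wise
patching. Saturation (p ≥ 3/4) yields missing distances; Ks = 0 yields a
missing ratio and an `undefined` class. Tests verify (S, N, Sd, Nd)
against an exhaustive pathway-enumeration oracle to 1e−9 and symmetry in
argument order.

Tandem clusters are not defined in most source surveys; the defaults here
— consecutive family members within 250 kb (start-to-start) with at most
5 intervening non-family genes — are stated, configurable parameters, not
biology-free magic numbers: they bracket the common "adjacent or
near-adjacent paralogs" usage.

## Promoter scanning

Promoters are the 2 kb (configurable) upstream of the gene feature's 5′
end — translation vs transcription start is not distinguishable in a
gene-level GFF, and the choice is recorded here rather than guessed per
genome. Scanning is exhaustive IUPAC matching on both strands with all
overlapping occurrences counted (PLACE-like behavior); palindromic double
hits are deduplicated by (element, start, end). The shipped dictionary
uses standard published consensi (G-box CACGTG, ABRE ACGTG, MeJA
TGACG/CGTCA pair, LTR CCGAAA, MBS CAACTG, DRE RCCGAC, MBSI, …) and is
fully user-replaceable; parity with the PLACE/PlantCARE output for any
given genome is not claimed.

## Expression and pigment

2^−ΔΔCT averages replicates on the Ct scale first (the estimator the
method's originators describe); a `per_replicate` flag computes
per-replicate folds with mean ± SE for error bars instead. The
calibrator sample's fold is exactly 1 by construction. Anthocyanin units
are U = (OD530 − OD600)/gFW; negative values are legal (blank
subtraction) but flagged. Group comparisons use one-way ANOVA with
Tukey HSD (Tukey–Kramer under imbalance, via R's `TukeyHSD`) and a
compact letter display assigned greedily from the largest mean with
containment absorption; zero within-group variance is an error, not an
NaN.

# The synthetic benchmark

`generate_family()` builds proteins from domain templates: optional SP
(Met + 10 hydrophobic + polar residues), one or two 54-residue PLCD
blocks carrying H·x40·C·x5·H·x5·Z with the scaffold Cys 10 before the
ligand Cys (Z = M/Q for complete sites, a small non-ligand residue for
ENODLs), an optional 30-residue ALR at 70 % PAST, an optional 25-residue
GPI tail with the omega site 22 residues from the terminus. Planted
spacings are fixed while detector windows are much wider, so detection
has a deterministic target. CDSs are reverse-translated under a
categorical codon model placing probability mass `codon_bias_strength`
on one designated (A/T-leaning) codon per amino acid — a tunable
ENC/CAI gradient. Promoters are element-free random backgrounds
(scrubbed against the whole dictionary on both strands) with planted
element copies at recorded positions and junction repair, so planted
counts are exact ground truth. Genes sit on chromosomes with 300 kb
N-gaps between unrelated genes and 10 kb within duplicate pairs: the
spec-level tandem truth is exactly the planted pairs. Duplicate partners
receive exact numbers of verified synonymous/nonsynonymous changes
(`mutate_pair`), with the copper-site block, omega site and start codon
treated as conserved — mutating a ligand slot would silently change the
planted class. All randomness flows from one seed through per-unit
substreams, so adding genes never perturbs existing ones.

Defaults emulate the apple-family study design: 59 genes on 12
chromosomes, subfamily proportions 33/13/9/4 (ENODL/UCL/SCL/PLCL), a
type mix chosen as the unique allocation satisfying every printed tally
(50 signal peptides, 42 GPI anchors, 34 typical + 17 atypical AGPs,
4 two-PLCD members), moderate bias 0.55, three pairs at
(ps, pn) ≈ (0.10, 0.01), (0.15, 0.02), (0.05, 0.005). Because duplicate
partners inherit their source gene's subfamily, realized subfamily
counts can deviate from the requested mix by up to the number of pairs.

What passing on this benchmark shows: the decision rules, counting
statistics and bookkeeping are implemented exactly as stated, at scale,
deterministically. What it does not show: performance on real proteomes,
where domain boundaries are fuzzy, ligand spacings vary, glycomodules
grade into background composition, and the heuristics would need
per-genome calibration against curated members. The generator also omits
introns/UTRs, indels, and interspecies synteny by design.

# Numerical choices and problem sizes

* pI bisection: 100 iterations max, tolerance 1e−4 charge units; ties
  impossible by monotonicity.
* ENC clipping at 61; all class-mean edge cases return NA rather than
  inventing information.
* Compact letters: greedy insert-and-absorb from the largest mean;
  studentized-range quantiles come from R's `ptukey` machinery inside
  `TukeyHSD` (accurate far beyond the 1e−6 needed).
* Test and acceptance scales, chosen to exercise every rule while
  keeping a single-CPU run comfortable: 500-gene family for classifier
  recovery; 1,000 random 30-codon pairs against the NG86 oracle; 1,000
  random count tables for RSCU identities; 200 random 2 kb promoters for
  scanner/oracle agreement; 100 random peptides for the pI oracle;
  a 60-gene end-to-end pipeline run repeated for determinism.

# Known limitations

* Heuristic detectors are not the external predictors they stand in for;
  on real data their thresholds are starting points, not conclusions.
* CAI is only as meaningful as its reference set; the family-internal
  default measures within-family bias, not adaptation to the host's
  highly expressed genes.
* NG86 underestimates divergence at high saturation and ignores
  transition/transversion and codon-frequency biases by construction.
* The promoter scanner counts consensus occurrences; it says nothing
  about occupancy or orientation effects beyond strand bookkeeping.
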