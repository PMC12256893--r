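---
title: "Methods: missense-variant burden around chemoproteomic-detected residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: missense-variant burden around chemoproteomic-detected residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckyburden)
```

## The problem

Broad-spectrum covalent probes (iodoacetamide-, sulfonyl-triazole- and
sulfonyl-fluoride-type chemistries) label intrinsically reactive cysteine,
lysine and tyrosine side chains across the proteome; mass spectrometry then
identifies the labelled residue positions. These chemoproteomic-detected
amino acids (CpDAAs) mark nucleophilic, often functional, sites — catalytic
residues, metal- and ligand-binding positions, interface residues. Clinical
genetics, meanwhile, accumulates protein-level missense variation: ClinVar
assertions (pathogenic, benign, uncertain) and population allele frequencies
(gnomAD). `ckyburden` integrates the two resources at residue resolution: it
asks whether detected residues sit closer to pathogenic missense variation
than undetected residues of the same chemical type, both along the linear
sequence and in the folded structure, and uses that proximity — together
with variant-effect predictions — to prioritise proteins and residues whose
variants of uncertain significance (VUS) deserve functional follow-up.

## Pipeline stages and their contracts

1. **Chemoproteomics ingest** (`filter_peptides`, `require_replication`,
   `build_cpdaa_table`). Peptide-level records are kept only when the
   peptide carries exactly one modified residue and is 6–45 residues long
   (unmodified length, inclusive bounds), and the residue is observed at
   least twice across experimental replicates (counting unit: one
   (experiment, peptide) occurrence). Every surviving residue is verified
   against the canonical sequence (`verify_residue`) before any cross-table
   join; failures are dropped with a reason code, never silently. Rejection
   is data: each stage partitions its input into kept and rejected with
   exhaustive reason codes, so count bookkeeping is auditable.
2. **Reactivity categories** (`categorize_reactivity`). Isotopic reactivity
   ratios R10:1 compare labelling at a 10-fold concentration difference; a
   residue that saturates at low concentration is hyper-reactive and has a
   low ratio. Categories are high (R10:1 ≤ 2), medium (2 < R10:1 ≤ 5), low
   (R10:1 > 5); the boundaries are closed exactly as written. Residues
   detected only by coverage experiments keep an `undetermined` category
   rather than being discarded. Ratios are averaged with a plain arithmetic
   mean, pooled across probes, with per-probe means available because
   whether pooling precedes averaging is an open choice; both are emitted.
3. **Variant curation** (`classify_variants`). Classes are mutually
   exclusive with precedence pathogenic > benign/common > VUS > allele-
   frequency bins: a clinical assertion outranks a frequency observation.
   The *background* comparator set pools clinically benign variants with
   common population variants (allele frequency strictly > 0.05), because
   benign assertions alone are too sparse to anchor enrichment. The rare
   (AF < 1e-3) and rarest (AF < 1e-5) bins are configurable; they label
   alleles, they never enter the background set. Likely-pathogenic pools
   with pathogenic by default (`pool_likely = FALSE` separates them), and a
   predicate hook allows confidence filtering of clinical assertions.
   Conflicting assertions (pathogenic and benign for one allele) are
   excluded and reported, not resolved.
4. **Gene-level layer** (`set_enrichment`, `overlap_summary`,
   `composition_comparison`, `ppi_comparison`). All enrichment universes
   are explicit inputs — never inferred from set unions — because published
   panels use different protein-coding universes. Composition comparisons
   correct for protein length by working on per-protein residue fractions.
5. **1D proximity** (`enumerate_sites`, `window_burden`,
   `window_enrichment`, `distance_comparison`). Every C/K/Y position of
   every analysis protein is a site, detected or not. A window of
   half-width 6 (3 and 15 supported) is centred on each site; burden counts
   unique (position, alt-amino-acid) alleles at distance 1..half-width.
   Direct overlaps (distance 0) are excluded from window counts and from
   nearest-distance statistics, so proximity is measured without
   conflating it with direct hits; windows at protein termini are
   truncated, not discarded, to avoid biasing against short proteins.
   Sites whose protein carries no variant of the tested class remain in
   containment tables — absence is the informative complement.
6. **3D proximity** (`parse_structure`, `residue_environment`,
   `environment_burden`). Distances anchor at the reactive terminal atom:
   SG (cysteine sulfhydryl), NZ (lysine amine), OH (tyrosine hydroxyl).
   For each mapped neighbour residue the minimum over its atoms of the
   Euclidean distance to the terminal atom is stored; environments are
   computed once at 10 Å and sliced to 8 (the primary cutoff, the
   conventional residue-contact range) and 6. Neighbours from every chain
   of the assembly are included — interface biology requires inter-chain
   contacts — with chain provenance recorded. Across multiple structures
   of one protein, neighbour positions are unioned keeping per-position
   minima. Hydrogens are excluded (crystal structures rarely resolve them;
   including them would make results resolution-dependent), as are waters
   and hetero groups; the first alternate location wins; model 1 of
   multi-model files is used. Structure-map rows whose residue identity
   disagrees with the canonical sequence are dropped — engineered
   constructs must not anchor joins.
7. **Stratification and prioritisation** (`mean_cadd_per_codon`,
   `rank_by_vus`, `cluster_burden`, `candidate_filter`). Per-codon CADD
   means average over all *missense* single-nucleotide substitutions of the
   codon (stop-gaining substitutions excluded; the flag is configurable)
   and require a complete score set — a codon with any missing substitution
   is excluded rather than averaged optimistically. Deleterious is a strict
   mean > 25 on the phred scale. VUS ranking sorts by 8 Å VUS burden with a
   deterministic (accession, position) tie-break. Burden clustering
   row-centres the residue × class count matrix (no unit-variance scaling),
   applies average-linkage hierarchical clustering on Euclidean distances,
   and cuts at two groups, labelling the larger-mean-total group "high";
   the linkage choice is this package's decision — the preprocessing is
   prescribed, the linkage is not — and degenerate (all-identical) inputs
   are flagged rather than over-interpreted. The candidate filter is the
   conjunction of five booleans: pathogenic *and* background variants
   present; a solved structure; length < 1,000 residues; a missense variant
   inside a detected residue's 8 Å environment; at least one detected
   residue.

## Statistical machinery

All 2×2 enrichment uses `fisher_exact`: the two-sided p-value is the
conditional hypergeometric sum of tables (at the observed margins) whose
probability does not exceed the observed table's, with a relative tolerance
of 1e-7 guarding probability ties against floating-point noise. The
reported effect is the *sample* odds ratio ad/bc — the estimate enrichment
panels in this field conventionally draw — not the conditional-MLE that
`stats::fisher.test` reports; the two p-values agree (the test suite checks
this), the estimates deliberately differ. When any cell is zero the
Haldane–Anscombe correction adds 0.5 to every cell and sets a flag; the 95%
interval is the Woolf logit interval on the (possibly corrected) cells.
Bonferroni adjustment uses the explicit family size of the panel (e.g. a
six-test window panel tests at 0.05/6). Rank-sum comparisons call
`stats::wilcox.test`, which enumerates exactly for small untied samples and
otherwise uses the tie-corrected normal approximation — reproducible
p-values at fixture scale. Distance-distribution families use FDR
adjustment, mirroring the convention for those panels.

## The synthetic-data generator

`sim_config` defaults define the study conditions. Protein sequences are
drawn residue-wise from average human-proteome amino-acid frequencies;
coding sequences are back-translated with uniform codon choice, so codon
arithmetic is exercised without an evolutionary model. Detection rates per
residue type (C 0.14, K 0.042, Y 0.027) sit at the detected fractions
observed in curated chemoproteomics compendia. Peptide evidence gives every
planted site 2–3 replicate records with its planted R10:1 value, plus decoy
records violating each ingest filter (5% each of two-mark, too-short and
singleton records) so that filters are tested against known contamination.
Structures are ideal α-helices (rise 1.5 Å per residue, twist 100°, radius
2.3 Å) with one backbone CA and one side-chain pseudo-atom per residue
(the terminal atom for C/K/Y): inter-residue distances then have closed
forms, giving the 3D layer an analytic oracle. A configurable fraction of
structures is a homodimer whose second chain is translated by 8 Å,
creating genuine inter-chain contacts.

Variant placement is the core of the plant. Background, rare and rarest
alleles fall uniformly over residue positions. Pathogenic alleles are drawn
with `planted_window_or` times the baseline odds of landing at linear
distance 1–6 from a detected site; VUS alleles analogously with
`planted_env_or` for the 8 Å structural zone. Because the plant acts on
placement *odds* over an explicitly enumerated zone, the planted odds ratio
is exact by construction rather than asymptotic, and the matching
estimator — the variant-level 2×2 of {pathogenic vs background} ×
{inside vs outside the zone} (`proximity_class_enrichment`,
`env_class_enrichment`) — recovers it without attenuation. The
window-*containment* odds ratio (`window_enrichment`, detected vs
undetected windows holding ≥ 1 variant) is a different functional of the
same plant: binary containment saturates, and overlapping windows leak
planted variants into undetected windows, so its expectation sits below the
placement odds. Both statistics are reported; parameter-recovery claims are
made for the estimator that estimates the planted parameter.

What the generator does **not** emulate: realistic folds (helices only),
linkage between variants, transcript-level annotation ambiguity, realistic
allele-frequency spectra (parametric class-wise draws only), probe-specific
sequence biases, and missing-data structure beyond the configured decoys.
Passing recovery tests therefore demonstrates the statistical machinery and
bookkeeping are correct under known truth — not that real chemoproteomics
or ClinVar data satisfy the generator's assumptions.

## Numerical choices and test scale

Distances are stored in Å to 3 decimals; environment membership is decided
before rounding at the 10 Å horizon. Seeds make every bundle a pure
function of its configuration: the test suite checks byte-identical
regeneration of written fixtures. Verification suites run at deliberate
sizes: the exact-test oracle enumerates all 2×2 tables with margins ≤ 12
(agreement to 1e-9); the 3D oracle compares 50 seeded structures of 25–35
residues against a quadratic all-atom scan (1e-6 Å); parameter recovery
uses 100 replicates of ~5,000-site proteomes (100 proteins × ~500
residues, 1,500 pathogenic and 1,500 background alleles) at planted odds
2.0 and 1.0, requiring ≥ 90/100 interval coverage — sizes chosen so the
whole suite completes in minutes on a single core while keeping every
assertion at its stated tolerance.

## Known limitations

The pipeline consumes pre-extracted tables (ClinVar/gnomAD-shaped variant
rows, OMIM counts, interaction counts, pre-built sequence↔structure maps);
it performs no live retrieval, transcript lifting or consequence calling.
PDB-format input only (no mmCIF); no solvent accessibility, secondary
structure or disulfide detection. One-to-many gene↔protein mappings are
accepted as an explicit mapping table and never guessed. Phenotype-count
bins (1, 2, 3, 4, ≥5) and the constraint threshold for "missense
intolerant" are configuration, not derived values.
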