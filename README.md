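# ckyburden

Missense-variant burden analysis around chemoproteomic-detected cysteine,
lysine, and tyrosine residues.

## What it is for

Covalent chemical probes label intrinsically reactive Cys/Lys/Tyr side
chains proteome-wide; mass spectrometry pinpoints the labelled positions
(chemoproteomic-detected amino acids, **CpDAAs**). Clinical genetics
supplies protein-level missense variation: ClinVar assertions and gnomAD
allele frequencies. `ckyburden` is for computational biologists who want to
integrate the two at residue resolution: quality-control peptide-level
chemoproteomics into a verified CpDAA table with reactivity categories,
curate mutually exclusive variant classes, and quantify how pathogenic,
benign/common, and uncertain (VUS) missense alleles distribute around
detected residues — in the linear sequence and in the 3D structure — to
prioritise proteins and residues for functional follow-up.

## The statistics at its core

* **Variant classes** (mutually exclusive, precedence pathogenic >
  benign/common > VUS > frequency bins). The *background* comparator is
  ClinVar-benign ∪ {gnomAD AF > 0.05}.
* **1D windows.** For every C/K/Y site *s* (detected or not) and
  half-width *w* (default ±6 residues), the burden is the number of unique
  (position, alt-aa) alleles at distance 1 ≤ |Δ| ≤ *w*; direct overlaps
  (Δ = 0) are excluded. Detected-vs-undetected containment is tested with
  Fisher's exact test.
* **3D environments.** From the terminal side-chain atom (Cys SG, Lys NZ,
  Tyr OH) to the nearest atom of every other mapped residue of the
  biological assembly (all chains); neighbours within 6/8/10 Å form nested
  environments (8 Å primary), unioned across structures with per-position
  minimum distances.
* **Enrichment.** For a 2×2 table (a, b; c, d): two-sided exact p by the
  conditional hypergeometric rule; sample odds ratio OR = ad/bc
  (Haldane–Anscombe +0.5 when a cell is zero); Woolf logit 95% CI
  exp(log OR ± 1.96·√(1/a+1/b+1/c+1/d)); Bonferroni over the explicit
  panel family.
* **CADD stratification.** Per codon, the mean phred over all possible
  missense single-nucleotide substitutions (complete score set required);
  deleterious ⇔ mean > 25.
* **Prioritisation.** VUS-burden ranking of CpDAAs, row-centred
  average-linkage clustering of burden matrices into high/low groups, and
  a five-criterion candidate filter (pathogenic *and* background variants;
  structure available; length < 1,000 aa; variant inside a CpDAA 8 Å
  environment; CpDAA-detected).

A seeded synthetic-data module generates complete fixture bundles
(proteome + coding sequences, replicate peptide records with decoys,
classified variants with *planted* proximity odds, ideal-helix PDB
structures with residue maps, CADD scores) so every stage is testable
against known ground truth without downloads.

## Worked example

```r
library(ckyburden)

bundle     <- simulate_bundle(sim_config(seed = 1))
ing        <- ingest_chemoproteomics(bundle$peptides, bundle$proteins)
classified <- classify_variants(bundle$variants)$variants
sites      <- enumerate_sites(bundle$proteins, ing$cpdaa)

site_detection_summary(sites)
#> # A tibble: 4 × 4
#>   residue_type n_detected n_total pct_detected
#>   <chr>             <int>   <int>        <dbl>
#> 1 C                    59     387        15.2
#> 2 K                    39    1019         3.83
#> 3 Y                    15     482         3.11
#> 4 all                 113    1888         5.99

proximity_class_enrichment(sites, classified)
#> 2x2 enrichment: OR = 2.209 [1.362, 3.582], p = 0.001064

window_enrichment(window_burden(sites, classified, 6), "pathogenic")
#> # A tibble: 4 × 11
#>   residue_type     a     b     c     d odds_ratio ci_low ci_high   p_value
#> 1 C               24    35    67   261       2.67  1.49     4.79 0.00137
#> 2 K               15    24   229   751       2.05  1.06     3.97 0.0359
#> 3 Y                7     8   113   354       2.74  0.973    7.73 0.0653
#> 4 all             46    67   409  1366       2.29  1.55     3.39 0.0000577
```

The detection fractions mirror the configured per-type rates (Cys
detection runs ~3–4× that of Lys/Tyr). `proximity_class_enrichment` is the
parameter-recovery statistic: the bundle plants pathogenic alleles with 2×
the baseline odds of landing within ±6 residues of a detected site, and the
sample OR of 2.21 [1.36, 3.58] recovers that multiplier. The window panel
shows the same signal as containment odds per residue type; values above 1
mean detected-residue windows hold pathogenic alleles more often than
undetected ones.

The same functions consume real data from TSV/FASTA/PDB inputs
(`read_peptides`, `read_fasta`, `read_variants`, `parse_structure`,
`read_structure_map`); a thin command-line front end lives at
`inst/cli/ckyburden.R`.

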