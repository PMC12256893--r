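vrow <- function(acc = "P1", pos = 1L, alt = "R", label = "none",
                 af = NA_real_, ref = "G", ref_codon = "GGA",
                 alt_codon = "AGA") {
  tibble::tibble(accession = acc, position = as.integer(pos), ref_aa = ref,
                 alt_aa = alt, ref_codon = ref_codon, alt_codon = alt_codon,
                 clinical_label = label, allele_frequency = af)
}

test_that("classification precedence and the common-frequency boundary", {
  rows <- dplyr::bind_rows(
    vrow(pos = 1, label = "pathogenic", af = 1e-4),
    vrow(pos = 2, label = "none", af = 0.06),
    vrow(pos = 3, label = "none", af = 0.05),        # exactly at threshold
    vrow(pos = 4, label = "likely_benign", af = 0.2),
    vrow(pos = 5, label = "vus", af = 1e-4),
    vrow(pos = 6, label = "none", af = 5e-4),
    vrow(pos = 7, label = "none", af = 5e-6))
  out <- classify_variants(rows)
  cls <- setNames(out$variants$variant_class, out$variants$position)
  expect_equal(unname(cls[as.character(1:7)]),
               c("pathogenic", "background", "rare", "benign_common",
                 "vus", "rare", "rarest"))
})

test_that("conflicting assertions are excluded and reported", {
  rows <- dplyr::bind_rows(
    vrow(pos = 1, label = "pathogenic"),
    vrow(pos = 1, label = "benign", af = 0.1),
    vrow(pos = 2, label = "pathogenic"))
  out <- classify_variants(rows)
  expect_equal(nrow(out$conflicts), 1)
  expect_equal(out$conflicts$position, 1L)
  expect_equal(out$variants$position, 2L)
})

test_that("each variant lands in exactly one class (partition)", {
  b <- test_bundle()
  out <- classify_variants(b$variants)
  expect_equal(nrow(out$variants) + nrow(out$conflicts), nrow(b$variants))
  expect_true(all(out$variants$variant_class %in%
                    c("pathogenic", "benign_common", "background", "vus",
                      "rare", "rarest")))
  # planted classes are reproduced exactly
  joined <- dplyr::inner_join(out$variants, b$truth$variants,
                              by = c("accession", "position", "alt_aa"))
  expect_equal(joined$variant_class, joined$planted_class)
})

test_that("analysis-gene filter requires OMIM, CpDAA, and both variant kinds", {
  cpdaa <- tibble::tibble(accession = c("G1", "G2", "G4"))
  variants <- dplyr::bind_rows(
    vrow("G1", 1, label = "pathogenic"),
    vrow("G1", 2, label = "benign", af = 0.2),
    vrow("G2", 1, label = "pathogenic"),
    vrow("G2", 2, label = "pathogenic"),
    vrow("G3", 1, label = "pathogenic"),
    vrow("G3", 2, label = "benign", af = 0.2),
    vrow("G4", 1, label = "pathogenic"),
    vrow("G4", 2, label = "benign", af = 0.2))
  cl <- classify_variants(variants)$variants
  omim <- c("G1", "G2", "G3")
  # G2 lacks a background variant, G3 lacks a CpDAA, G4 is not in OMIM
  expect_equal(filter_analysis_genes(cl, cpdaa, omim), "G1")
})

test_that("substitution spectrum normalises within class", {
  variants <- dplyr::bind_rows(
    vrow(pos = 1:3, label = "pathogenic", ref = "G", alt = "R"),
    vrow(pos = 4, label = "none", af = 0.1, ref = "G", alt = "R"),
    vrow(pos = 5, label = "none", af = 0.1, ref = "A", alt = "T",
         ref_codon = "GCA", alt_codon = "ACA"))
  cl <- classify_variants(variants)$variants
  spec <- substitution_spectrum(cl)
  gr <- spec[spec$ref_aa == "G" & spec$alt_aa == "R", ]
  expect_equal(gr$freq_a, 1.0)
  expect_equal(gr$freq_b, 0.5)
  expect_equal(gr$freq_diff, 0.5)
  # no diagonal cells; marginals reproduce loss totals per amino acid
  expect_true(all(spec$ref_aa != spec$alt_aa))
  expect_equal(sum(spec$n_a[spec$ref_aa == "G"]), 3)
  # an empty pathogenic set yields all-zero frequencies
  spec0 <- substitution_spectrum(dplyr::filter(cl,
                                               variant_class != "pathogenic"))
  expect_true(all(spec0$freq_a == 0))
})

test_that("codon-exchange enrichment reproduces hand-built tables", {
  mk <- function(n, ref_codon, alt_codon, label, af = NA_real_) {
    snv <- enumerate_codon_snvs(ref_codon)
    snv <- snv[snv$alt_codon == alt_codon, ]
    vrow(pos = seq_len(n) + 1000L * (label == "none"), label = label,
         af = af, ref = snv$ref_aa, alt = snv$alt_aa,
         ref_codon = ref_codon, alt_codon = alt_codon)
  }
  # balanced: 10/10 vs 100/100 on the rest
  rows <- dplyr::bind_rows(
    mk(10, "TGC", "TTC", "pathogenic"),
    mk(10, "TGC", "TTC", "none", af = 0.1) |>
      dplyr::mutate(position = position + 50L),
    mk(100, "GGA", "AGA", "pathogenic") |>
      dplyr::mutate(accession = "P2"),
    mk(100, "GGA", "AGA", "none", af = 0.1) |>
      dplyr::mutate(accession = "P2", position = position + 500L))
  enr <- codon_exchange_enrichment(classify_variants(rows)$variants)
  cell <- enr[enr$ref_codon == "TGC", ]
  expect_equal(cell$odds_ratio, 1.0)
  expect_equal(cell$p_value, 1.0)
  # imbalanced: [[20,5],[100,100]] with the exact hypergeometric oracle
  rows2 <- dplyr::bind_rows(
    mk(20, "TGC", "TTC", "pathogenic"),
    mk(5, "TGC", "TTC", "none", af = 0.1) |>
      dplyr::mutate(position = position + 50L),
    mk(100, "GGA", "AGA", "pathogenic") |>
      dplyr::mutate(accession = "P2"),
    mk(100, "GGA", "AGA", "none", af = 0.1) |>
      dplyr::mutate(accession = "P2", position = position + 500L))
  enr2 <- codon_exchange_enrichment(classify_variants(rows2)$variants)
  cell2 <- enr2[enr2$ref_codon == "TGC", ]
  expect_equal(cell2$odds_ratio, (20 * 100) / (5 * 100))
  expect_equal(cell2$p_value, oracle_fisher_p(20, 100, 5, 100),
               tolerance = 1e-12)
  # the planted excess carries the minimal p among enriched exchanges
  enriched <- enr2[enr2$odds_ratio > 1, ]
  expect_equal(enriched$ref_codon[which.min(enriched$p_value)], "TGC")
})

test_that("per-codon CADD means require completeness and use strict > 25", {
  tgc_mis <- dplyr::filter(enumerate_codon_snvs("TGC"), kind == "missense")
  cadd <- tibble::tibble(accession = "P1", position = 10L,
                         ref_codon = "TGC", alt_codon = tgc_mis$alt_codon,
                         phred = 30)
  out <- mean_cadd_per_codon(cadd)
  expect_equal(out$scores$mean_phred, 30)
  expect_true(out$scores$deleterious)

  cadd25 <- dplyr::mutate(cadd, phred = 25)
  expect_false(mean_cadd_per_codon(cadd25)$scores$deleterious)

  incomplete <- cadd[-1, ]
  out2 <- mean_cadd_per_codon(incomplete)
  expect_equal(nrow(out2$scores), 0)
  expect_equal(out2$excluded$reason, "incomplete")
})

test_that("TGG means average over its missense substitutions only", {
  # independent enumeration of TGG's single-nucleotide outcomes
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  alts <- character(0)
  for (i in 1:3) for (b in bases) {
    alt <- strsplit("TGG", "")[[1]]
    if (alt[i] == b) next
    alt[i] <- b
    alts <- c(alts, paste(alt, collapse = ""))
  }
  mis_alts <- alts[code[alts] != "*" & code[alts] != code[["TGG"]]]
  phreds <- seq(10, by = 2, length.out = length(mis_alts))
  cadd <- tibble::tibble(accession = "P1", position = 3L,
                         ref_codon = "TGG", alt_codon = mis_alts,
                         phred = phreds)
  out <- mean_cadd_per_codon(cadd)
  expect_equal(out$scores$n_substitutions, length(mis_alts))
  expect_equal(out$scores$mean_phred, mean(phreds))
})

test_that("planted deleterious flags are recovered from simulated scores", {
  b <- test_bundle()
  out <- mean_cadd_per_codon(b$cadd)
  truth <- b$truth$cadd
  joined <- dplyr::inner_join(out$scores, truth,
                              by = c("accession", "position"))
  expect_true(all(joined$complete))
  expect_equal(joined$deleterious.x, joined$deleterious.y)
  expect_equal(nrow(out$scores) + nrow(out$excluded),
               sum(truth$complete) + sum(!truth$complete))
})
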