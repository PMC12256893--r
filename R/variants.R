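# Variant curation: mutually exclusive missense classes built from clinical
# assertions and population allele frequencies, amino-acid and codon-exchange
# spectra, and per-codon CADD deleteriousness flags.

#' Read a protein-level missense variant table
#'
#' Expected columns: `accession`, `position`, `ref_aa`, `alt_aa`,
#' `ref_codon`, `alt_codon`, `clinical_label` (pathogenic, likely_pathogenic,
#' benign, likely_benign, vus, or none), `allele_frequency` (empty =
#' missing).
#'
#' @param path Path to a TSV file.
#' @return A tibble of variant rows.
#' @export
read_variants <- function(path) {
  x <- read_table_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    position = readr::col_integer(),
    ref_aa = readr::col_character(),
    alt_aa = readr::col_character(),
    ref_codon = readr::col_character(),
    alt_codon = readr::col_character(),
    clinical_label = readr::col_character(),
    allele_frequency = readr::col_double()
  ))
  assert_columns(x, c("accession", "position", "ref_aa", "alt_aa",
                      "clinical_label", "allele_frequency"), "variant table")
  x
}

#' Assign mutually exclusive variant classes
#'
#' Builds the mutually exclusive class partition used throughout the
#' analyses, with precedence pathogenic > benign/common > VUS > allele
#' frequency bins (a clinical assertion outranks a frequency observation):
#' * `pathogenic`: ClinVar pathogenic (and, by default, likely pathogenic);
#' * `benign_common`: ClinVar benign / likely benign;
#' * `background`: unlabeled with allele frequency strictly > `common_af`
#'   (the analysis-level background set is `benign_common` plus
#'   `background`, see [background_classes()]);
#' * `vus`: ClinVar uncertain significance;
#' * `rare` / `rarest`: remaining variants binned by allele frequency.
#'
#' Alleles asserted both pathogenic and benign are excluded and reported as
#' conflicts. One row per (accession, position, alt_aa) is enforced.
#'
#' @param clinvar_rows Variant rows carrying `clinical_label`.
#' @param gnomad_rows Variant rows carrying `allele_frequency` (may be the
#'   same table; rows are combined and de-duplicated).
#' @param common_af Background allele-frequency threshold (strict >).
#' @param rare_af,rarest_af Upper bounds of the rare bins: `rarest` is
#'   AF < `rarest_af`, `rare` is AF < `rare_af`.
#' @param pool_likely Pool likely_pathogenic with pathogenic and
#'   likely_benign with benign.
#' @param clinvar_predicate Optional function(rows) -> logical keep-mask,
#'   hook for confidence filtering of clinical assertions; default accepts
#'   all.
#' @return List with `variants` (input columns plus `variant_class`) and
#'   `conflicts`.
#' @export
classify_variants <- function(clinvar_rows, gnomad_rows = NULL,
                              common_af = 0.05, rare_af = 1e-3,
                              rarest_af = 1e-5, pool_likely = TRUE,
                              clinvar_predicate = NULL) {
  x <- bind_rows(clinvar_rows, gnomad_rows)
  assert_columns(x, c("accession", "position", "alt_aa", "clinical_label",
                      "allele_frequency"))
  x$clinical_label[is.na(x$clinical_label)] <- "none"
  if (!is.null(clinvar_predicate)) {
    keep <- clinvar_predicate(x)
    drop_label <- x$clinical_label != "none" & !keep
    x$clinical_label[drop_label] <- "none"
  }
  path_labels <- if (pool_likely) c("pathogenic", "likely_pathogenic")
                 else "pathogenic"
  ben_labels <- if (pool_likely) c("benign", "likely_benign") else "benign"

  # collapse to one row per allele; collect label/AF evidence across sources
  key <- x %>%
    group_by(.data$accession, .data$position, .data$alt_aa) %>%
    summarise(
      is_path = any(.data$clinical_label %in% path_labels),
      is_ben = any(.data$clinical_label %in% ben_labels),
      is_vus = any(.data$clinical_label == "vus"),
      allele_frequency = if (all(is.na(.data$allele_frequency))) NA_real_
                         else max(.data$allele_frequency, na.rm = TRUE),
      across(dplyr::any_of(c("ref_aa", "ref_codon", "alt_codon")), first),
      .groups = "drop"
    )
  conflicts <- filter(key, .data$is_path & .data$is_ben)
  key <- filter(key, !(.data$is_path & .data$is_ben))
  key$variant_class <- dplyr::case_when(
    key$is_path ~ "pathogenic",
    key$is_ben ~ "benign_common",
    !is.na(key$allele_frequency) & key$allele_frequency > common_af ~
      "background",
    key$is_vus ~ "vus",
    !is.na(key$allele_frequency) & key$allele_frequency < rarest_af ~
      "rarest",
    !is.na(key$allele_frequency) & key$allele_frequency < rare_af ~ "rare",
    TRUE ~ "rare"
  )
  list(variants = select(key, -"is_path", -"is_ben", -"is_vus"),
       conflicts = conflicts)
}

#' Classes forming the non-pathogenic background set
#'
#' The background comparator pools clinically benign variants with common
#' population variants, because benign assertions alone are too few to
#' anchor enrichment comparisons.
#'
#' @return Character vector of class labels.
#' @export
background_classes <- function() c("benign_common", "background")

#' Genes eligible for residue-level burden analysis
#'
#' The analysis set: genes that are disease-associated (OMIM-listed), carry
#' at least one detected residue, and have at least one pathogenic and one
#' background (common/benign) missense variant.
#'
#' @param variants Classified variant tibble.
#' @param cpdaa CpDAA table.
#' @param omim_genes Character vector of OMIM gene/protein accessions
#'   (same id space as `accession`).
#' @return Character vector of accessions.
#' @export
filter_analysis_genes <- function(variants, cpdaa, omim_genes) {
  assert_columns(variants, c("accession", "variant_class"))
  assert_columns(cpdaa, "accession")
  per_gene <- variants %>%
    group_by(.data$accession) %>%
    summarise(
      n_path = sum(.data$variant_class == "pathogenic"),
      n_bg = sum(.data$variant_class %in% background_classes()),
      .groups = "drop"
    )
  eligible <- per_gene$accession[per_gene$n_path >= 1 & per_gene$n_bg >= 1]
  sort(intersect(intersect(eligible, unique(cpdaa$accession)),
                 unique(omim_genes)))
}

#' Amino-acid substitution spectrum between two variant classes
#'
#' For every ordered (ref_aa, alt_aa) pair, the count and class-normalised
#' frequency in each class and their difference. The diagonal is undefined
#' for missense data and is not emitted.
#'
#' @param variants Classified variant tibble with `ref_aa`, `alt_aa`.
#' @param classes Length-2 character vector of class labels to compare; the
#'   second may be a vector (e.g. [background_classes()]).
#' @return Tibble with `ref_aa`, `alt_aa`, `n_a`, `n_b`, `freq_a`, `freq_b`,
#'   `freq_diff`.
#' @export
substitution_spectrum <- function(variants,
                                  classes = list("pathogenic",
                                                 background_classes())) {
  assert_columns(variants, c("ref_aa", "alt_aa", "variant_class"))
  grid <- tidyr::expand_grid(ref_aa = AA_LETTERS, alt_aa = AA_LETTERS) %>%
    filter(.data$ref_aa != .data$alt_aa)
  count_class <- function(cls) {
    v <- filter(variants, .data$variant_class %in% cls)
    v %>%
      dplyr::count(.data$ref_aa, .data$alt_aa, name = "n") %>%
      dplyr::right_join(grid, by = c("ref_aa", "alt_aa")) %>%
      mutate(n = tidyr::replace_na(.data$n, 0L)) %>%
      arrange(.data$ref_aa, .data$alt_aa)
  }
  a <- count_class(classes[[1]])
  b <- count_class(classes[[2]])
  tot_a <- sum(a$n); tot_b <- sum(b$n)
  tibble(
    ref_aa = a$ref_aa, alt_aa = a$alt_aa, n_a = a$n, n_b = b$n,
    freq_a = if (tot_a > 0) a$n / tot_a else 0 * a$n,
    freq_b = if (tot_b > 0) b$n / tot_b else 0 * b$n
  ) %>%
    mutate(freq_diff = .data$freq_a - .data$freq_b)
}

#' Per-codon-exchange enrichment of pathogenic over background variants
#'
#' For every observed single-nucleotide codon exchange, a 2x2 exact test of
#' {this exchange vs all other exchanges} x {pathogenic vs background}.
#' Results can be partitioned into loss-of / gain-of panels for a given
#' amino acid via `ref_aa` / `alt_aa`.
#'
#' @param variants Classified variant tibble with `ref_codon`, `alt_codon`.
#' @return Tibble, one row per exchange, with counts, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `or_undefined`.
#' @export
codon_exchange_enrichment <- function(variants) {
  assert_columns(variants, c("ref_codon", "alt_codon", "variant_class"))
  v <- filter(variants,
              .data$variant_class %in%
                c("pathogenic", background_classes())) %>%
    mutate(group = ifelse(.data$variant_class == "pathogenic",
                          "pathogenic", "background"))
  if (nrow(v) == 0) stop("no pathogenic or background variants", call. = FALSE)
  counts <- v %>%
    dplyr::count(.data$ref_codon, .data$alt_codon, .data$group) %>%
    tidyr::pivot_wider(names_from = "group", values_from = "n",
                       values_fill = 0L)
  for (col in c("pathogenic", "background")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  tot_p <- sum(counts$pathogenic); tot_b <- sum(counts$background)
  snvs <- codon_snv_table()
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$pathogenic[i]; c_ <- counts$background[i]
    b <- tot_p - a; d <- tot_b - c_
    res <- fisher_exact(rbind(c(a, c_), c(b, d)))
    aa <- snvs[snvs$ref_codon == counts$ref_codon[i] &
                 snvs$alt_codon == counts$alt_codon[i], ]
    tibble(ref_codon = counts$ref_codon[i],
           alt_codon = counts$alt_codon[i],
           ref_aa = if (nrow(aa)) aa$ref_aa else NA_character_,
           alt_aa = if (nrow(aa)) aa$alt_aa else NA_character_,
           n_pathogenic = a, n_background = c_,
           odds_ratio = res$odds_ratio, ci_low = res$ci_low,
           ci_high = res$ci_high, p_value = res$p_value,
           or_undefined = res$or_undefined | (a + c_ == 0))
  })
  dplyr::bind_rows(rows) %>% arrange(.data$p_value)
}

#' Mean CADD phred score per codon
#'
#' Averages CADD phred scores over all possible missense (amino-acid
#' changing, stop-excluded) single-nucleotide substitutions of each codon.
#' A codon is scored only when every one of its missense substitutions has a
#' phred value; incomplete codons are excluded with reason `incomplete`.
#' `deleterious` is a strict mean > `threshold`.
#'
#' @param cadd Tibble with `accession`, `position`, `ref_codon`,
#'   `alt_codon`, `phred` (one row per scored substitution).
#' @param threshold Deleteriousness threshold on the mean phred.
#' @return List with `scores` (accession, position, ref_codon, mean_phred,
#'   n_substitutions, deleterious) and `excluded`.
#' @export
mean_cadd_per_codon <- function(cadd, threshold = 25) {
  assert_columns(cadd, c("accession", "position", "ref_codon", "alt_codon",
                         "phred"))
  snvs <- codon_snv_table()
  required <- snvs %>%
    filter(.data$kind == "missense") %>%
    dplyr::count(.data$ref_codon, name = "n_required")
  missense_keys <- paste(snvs$ref_codon[snvs$kind == "missense"],
                         snvs$alt_codon[snvs$kind == "missense"])
  scored <- cadd %>%
    filter(!is.na(.data$phred),
           paste(.data$ref_codon, .data$alt_codon) %in% missense_keys) %>%
    dplyr::distinct(.data$accession, .data$position, .data$ref_codon,
                    .data$alt_codon, .keep_all = TRUE) %>%
    group_by(.data$accession, .data$position, .data$ref_codon) %>%
    summarise(mean_phred = mean(.data$phred), n_substitutions = n(),
              .groups = "drop") %>%
    left_join(required, by = "ref_codon")
  complete <- scored$n_substitutions == scored$n_required
  scores <- scored[complete, , drop = FALSE] %>%
    select(-"n_required") %>%
    mutate(deleterious = .data$mean_phred > threshold)
  excluded <- scored[!complete, , drop = FALSE] %>%
    select(-"n_required") %>%
    mutate(reason = "incomplete")
  list(scores = scores, excluded = excluded)
}
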