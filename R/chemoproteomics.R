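# Peptide-level chemoproteomics QC: filter, replicate-check, aggregate into a
# verified table of chemoproteomic-detected amino acids (CpDAAs) with
# reactivity categories derived from isotopic R10:1 ratios.

PEPTIDE_MIN_LEN <- 6L
PEPTIDE_MAX_LEN <- 45L

#' Read a peptide-level chemoproteomics table
#'
#' Expected columns: `accession`, `peptide` (modified residues marked with a
#' trailing asterisk, e.g. `MAC*ALRCY`), `position` (1-based protein position
#' of the modified residue), `residue_type` (C/K/Y), `probe_id`,
#' `experiment_id`, `r10_1` (reactivity ratio; empty = not a
#' reactivity-profiling record).
#'
#' @param path Path to a TSV file.
#' @return A tibble of peptide records.
#' @export
read_peptides <- function(path) {
  x <- read_table_tsv(path, col_types = readr::cols(
    accession = readr::col_character(),
    peptide = readr::col_character(),
    position = readr::col_integer(),
    residue_type = readr::col_character(),
    probe_id = readr::col_character(),
    experiment_id = readr::col_character(),
    r10_1 = readr::col_double()
  ))
  assert_columns(x, c("accession", "peptide", "position", "residue_type",
                      "probe_id", "experiment_id", "r10_1"), "peptide table")
  x
}

#' Number of modification marks in a peptide string
#' @param peptide Peptide string(s) with asterisk marks.
#' @return Integer vector of mark counts.
#' @export
count_modification_marks <- function(peptide) {
  stringr::str_count(peptide, stringr::fixed("*"))
}

#' Filter peptide records on modification count and length
#'
#' Keeps records with exactly one modified residue and an unmodified peptide
#' length of 6-45 residues inclusive. Rejection is data, not failure: every
#' input record lands in exactly one of `kept` or `rejected`, the latter with
#' a reason code in `multi_modified`, `too_short`, `too_long`, `unmapped`
#' (`unmapped` also covers records with no modification mark, whose modified
#' residue cannot be located).
#'
#' @param records Peptide record tibble (see [read_peptides()]).
#' @return A list with tibbles `kept` and `rejected` (extra column `reason`).
#' @export
filter_peptides <- function(records) {
  assert_columns(records, c("accession", "peptide"))
  marks <- count_modification_marks(records$peptide)
  len <- nchar(gsub("*", "", records$peptide, fixed = TRUE))
  reason <- dplyr::case_when(
    marks == 0 ~ "unmapped",
    marks > 1 ~ "multi_modified",
    len < PEPTIDE_MIN_LEN ~ "too_short",
    len > PEPTIDE_MAX_LEN ~ "too_long",
    TRUE ~ NA_character_
  )
  list(
    kept = records[is.na(reason), , drop = FALSE],
    rejected = dplyr::mutate(records[!is.na(reason), , drop = FALSE],
                             reason = reason[!is.na(reason)])
  )
}

#' Require replicated observation of each modified residue
#'
#' A residue must appear at least twice across all experimental replicates;
#' the counting unit is one (experiment_id, peptide) occurrence. Residues
#' observed once are dropped with reason `singleton`.
#'
#' @param records Records that already passed [filter_peptides()].
#' @return List with `kept` (extra column `n_observations`) and `rejected`.
#' @export
require_replication <- function(records) {
  assert_columns(records, c("accession", "position", "peptide",
                            "experiment_id"))
  counts <- records %>%
    dplyr::distinct(.data$accession, .data$position, .data$experiment_id,
                    .data$peptide) %>%
    dplyr::count(.data$accession, .data$position, name = "n_observations")
  tagged <- dplyr::left_join(records, counts,
                             by = c("accession", "position"))
  list(
    kept = filter(tagged, .data$n_observations >= 2),
    rejected = tagged %>%
      filter(.data$n_observations < 2) %>%
      select(-"n_observations") %>%
      mutate(reason = "singleton")
  )
}

#' Mean reactivity ratio across replicates
#'
#' Plain arithmetic mean of the non-missing R10:1 values of one residue's
#' replicate records; `NA` when no record carries a ratio (e.g. residues
#' detected only by coverage experiments).
#'
#' @param r10_1 Numeric vector of replicate ratios, possibly with `NA`.
#' @return Scalar mean or `NA_real_`.
#' @export
aggregate_reactivity <- function(r10_1) {
  v <- r10_1[!is.na(r10_1)]
  if (length(v) == 0) return(NA_real_)
  mean(v)
}

#' Categorise a mean reactivity ratio
#'
#' Intrinsically hyper-reactive residues saturate labeling already at low
#' probe concentration, giving low isotopic ratios: high reactivity is
#' R10:1 <= 2, medium is 2 < R10:1 <= 5, low is R10:1 > 5. Missing ratios
#' map to `undetermined`.
#'
#' @param mean_r10_1 Numeric vector of mean ratios (> 0 or `NA`).
#' @return Character vector in `low`/`medium`/`high`/`undetermined`.
#' @export
categorize_reactivity <- function(mean_r10_1) {
  if (any(!is.na(mean_r10_1) & mean_r10_1 <= 0)) {
    stop("reactivity ratios must be positive", call. = FALSE)
  }
  dplyr::case_when(
    is.na(mean_r10_1) ~ "undetermined",
    mean_r10_1 <= 2 ~ "high",
    mean_r10_1 <= 5 ~ "medium",
    TRUE ~ "low"
  )
}

#' Build the verified CpDAA table
#'
#' Aggregates filtered, replicated peptide records to one row per detected
#' residue, verifying each (accession, position, residue_type) against the
#' canonical sequence; records failing verification are dropped with reason
#' `mismatch`. Pooled means are reported across probes; per-probe means are
#' available via `per_probe = TRUE`.
#'
#' @param records Kept records from [require_replication()].
#' @param proteins Protein table from [read_fasta()].
#' @param per_probe Also return per-probe mean ratios.
#' @return A list with `cpdaa` (accession, position, residue_type,
#'   mean_r10_1, reactivity_category, n_observations), `rejected`, and
#'   optionally `per_probe`.
#' @export
build_cpdaa_table <- function(records, proteins, per_probe = FALSE) {
  assert_columns(records, c("accession", "position", "residue_type",
                            "experiment_id", "peptide", "r10_1"))
  assert_columns(proteins, c("accession", "sequence"))
  x <- dplyr::left_join(records,
                        select(proteins, "accession", "sequence"),
                        by = "accession")
  ok <- !is.na(x$sequence) &
    verify_residue(x$sequence, x$position, x$residue_type)
  rejected <- x[!ok, , drop = FALSE] %>%
    select(-"sequence") %>%
    mutate(reason = "mismatch")
  kept <- x[ok, , drop = FALSE]
  cpdaa <- kept %>%
    group_by(.data$accession, .data$position, .data$residue_type) %>%
    summarise(
      mean_r10_1 = aggregate_reactivity(.data$r10_1),
      n_observations = dplyr::n_distinct(
        paste(.data$experiment_id, .data$peptide, sep = "\r")),
      .groups = "drop"
    ) %>%
    mutate(reactivity_category = categorize_reactivity(.data$mean_r10_1)) %>%
    arrange(.data$accession, .data$position)
  out <- list(cpdaa = cpdaa, rejected = rejected)
  if (per_probe) {
    out$per_probe <- kept %>%
      group_by(.data$accession, .data$position, .data$residue_type,
               .data$probe_id) %>%
      summarise(mean_r10_1 = aggregate_reactivity(.data$r10_1),
                n_observations = n(), .groups = "drop")
  }
  out
}

#' Per-protein CpDAA summary
#'
#' Counts detected C/K/Y sites per protein and flags proteins carrying two or
#' more residue types and all three types; also returns the overall fractions
#' of proteins with multi-type detection.
#'
#' @param cpdaa CpDAA table from [build_cpdaa_table()].
#' @return List with `per_protein` tibble and `overall` one-row tibble.
#' @export
cpdaa_protein_summary <- function(cpdaa) {
  assert_columns(cpdaa, c("accession", "position", "residue_type"))
  per_protein <- cpdaa %>%
    group_by(.data$accession) %>%
    summarise(
      n_sites = n(),
      n_cys = sum(.data$residue_type == "C"),
      n_lys = sum(.data$residue_type == "K"),
      n_tyr = sum(.data$residue_type == "Y"),
      n_types = dplyr::n_distinct(.data$residue_type),
      .groups = "drop"
    ) %>%
    mutate(two_or_more_types = .data$n_types >= 2,
           all_three_types = .data$n_types == 3)
  overall <- tibble(
    n_proteins = nrow(per_protein),
    n_sites = sum(per_protein$n_sites),
    n_two_or_more = sum(per_protein$two_or_more_types),
    n_all_three = sum(per_protein$all_three_types),
    pct_two_or_more = 100 * mean(per_protein$two_or_more_types),
    pct_all_three = 100 * mean(per_protein$all_three_types)
  )
  list(per_protein = per_protein, overall = overall)
}

#' Run the full chemoproteomics ingest
#'
#' Convenience wrapper chaining [filter_peptides()], [require_replication()]
#' and [build_cpdaa_table()]; keeps every rejected record with its reason so
#' the kept + rejected partition can be audited.
#'
#' @param records Raw peptide record tibble.
#' @param proteins Protein table.
#' @return List with `cpdaa`, `rejected` (all stages, with `reason`), and
#'   `summary` from [cpdaa_protein_summary()].
#' @export
ingest_chemoproteomics <- function(records, proteins) {
  f <- filter_peptides(records)
  r <- require_replication(f$kept)
  b <- build_cpdaa_table(select(r$kept, -"n_observations"), proteins)
  rejected <- bind_rows(f$rejected, r$rejected, b$rejected)
  list(cpdaa = b$cpdaa, rejected = rejected,
       summary = cpdaa_protein_summary(b$cpdaa))
}
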