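# Sequence ingest, residue identity verification, and genetic-code utilities
# shared by every downstream stage. Positions are 1-based and inclusive
# throughout the package, matching residue naming such as Cys333.

#' Read canonical protein sequences from FASTA
#'
#' Reads a FASTA file of canonical protein sequences into a protein table.
#' The first whitespace-delimited token of each header is the accession; a
#' second token, when present, is kept as a gene identifier. Sequences are
#' uppercased. Selenocysteine (`U`) and ambiguity codes are rejected because
#' no probe chemistry is defined for them; `X` is permitted but flagged with
#' a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession`, `gene_id`, `sequence`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0) {
    return(tibble(accession = character(), gene_id = character(),
                  sequence = character(), length = integer()))
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA at line ", nonempty[1],
         ": expected a '>' header before sequence data", call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  tokens <- strsplit(headers, "\\s+")
  accession <- vapply(tokens, function(t) t[[1]], character(1))
  gene_id <- vapply(tokens, function(t) {
    if (length(t) >= 2) t[[2]] else NA_character_
  }, character(1))
  if (anyDuplicated(accession)) {
    dup <- unique(accession[duplicated(accession)])
    stop("duplicate accession(s) in FASTA: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sequence <- unname(toupper(as.character(seqs)))
  bad <- grepl("[UBZJO]", sequence)
  if (any(bad)) {
    stop("unsupported residue letters (selenocysteine/ambiguity codes) in: ",
         paste(accession[bad], collapse = ", "), call. = FALSE)
  }
  if (any(grepl("X", sequence, fixed = TRUE))) {
    warning("sequence(s) contain 'X' residues: ",
            paste(accession[grepl("X", sequence, fixed = TRUE)],
                  collapse = ", "), call. = FALSE)
  }
  other <- grepl(paste0("[^", paste(c(AA_LETTERS, "X"), collapse = ""), "]"),
                 sequence)
  if (any(other)) {
    stop("non-amino-acid characters in sequence(s): ",
         paste(accession[other], collapse = ", "), call. = FALSE)
  }
  tibble(accession = accession, gene_id = gene_id,
         sequence = sequence, length = nchar(sequence))
}

#' Verify a residue identity at a protein position
#'
#' Hard gate applied before any residue-level join across tables: `TRUE` only
#' when `position` lies inside the sequence and the residue letter there
#' equals `expected_aa`. Out-of-range positions return `FALSE` rather than
#' erroring, so callers can drop unverifiable records with a reason code.
#'
#' @param sequence Amino-acid string (or vector, recycled).
#' @param position 1-based residue position (vectorised).
#' @param expected_aa Expected single-letter residue (vectorised).
#' @return Logical vector.
#' @export
verify_residue <- function(sequence, position, expected_aa) {
  n <- max(length(sequence), length(position), length(expected_aa))
  sequence <- rep_len(sequence, n)
  position <- rep_len(as.integer(position), n)
  expected_aa <- rep_len(expected_aa, n)
  ok <- !is.na(position) & position >= 1L & position <= nchar(sequence)
  out <- rep(FALSE, n)
  out[ok] <- substr(sequence[ok], position[ok], position[ok]) ==
    expected_aa[ok]
  out
}

#' Translate DNA codons with the standard genetic code
#'
#' @param codon Character vector of 3-letter DNA codons.
#' @return Single-letter amino acids; `*` for stop codons.
#' @export
translate_codon <- function(codon) {
  codon <- toupper(codon)
  bad <- !grepl("^[ACGT]{3}$", codon)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(codon[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(Biostrings::GENETIC_CODE[codon])
}

# All 9 single-nucleotide substitutions of one codon, classified.
.codon_snvs_one <- function(ref_codon) {
  bases <- c("A", "C", "G", "T")
  ref_split <- strsplit(ref_codon, "")[[1]]
  alts <- character(9)
  k <- 0
  for (pos in 1:3) {
    for (b in setdiff(bases, ref_split[pos])) {
      alt <- ref_split
      alt[pos] <- b
      k <- k + 1
      alts[k] <- paste(alt, collapse = "")
    }
  }
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alts)
  kind <- ifelse(alt_aa == ref_aa, "synonymous",
                 ifelse(alt_aa == "*", "nonsense", "missense"))
  tibble(ref_codon = ref_codon, alt_codon = alts,
         ref_aa = ref_aa, alt_aa = alt_aa, kind = kind)
}

.codon_snv_cache <- new.env(parent = emptyenv())

#' Enumerate all single-nucleotide substitutions of a codon
#'
#' Each sense codon has exactly 9 single-nucleotide neighbours (3 positions x
#' 3 alternative bases), each classified as synonymous, missense, or nonsense
#' under the standard genetic code. Used for per-codon CADD completeness
#' checks and the codon-exchange spectrum.
#'
#' @param ref_codon A 3-letter DNA codon (not a stop codon).
#' @return A 9-row tibble with columns `ref_codon`, `alt_codon`, `ref_aa`,
#'   `alt_aa`, `kind`.
#' @export
enumerate_codon_snvs <- function(ref_codon) {
  ref_codon <- toupper(ref_codon)
  if (!grepl("^[ACGT]{3}$", ref_codon)) {
    stop("invalid codon: ", ref_codon, call. = FALSE)
  }
  if (translate_codon(ref_codon) == "*") {
    stop("ref_codon is a stop codon: ", ref_codon, call. = FALSE)
  }
  if (is.null(.codon_snv_cache[[ref_codon]])) {
    .codon_snv_cache[[ref_codon]] <- .codon_snvs_one(ref_codon)
  }
  .codon_snv_cache[[ref_codon]]
}

#' Single-nucleotide substitution table for all sense codons
#'
#' @return A tibble of the 9 single-nucleotide substitutions of each of the
#'   61 sense codons, classified by kind.
#' @export
codon_snv_table <- function() {
  if (is.null(.codon_snv_cache[["__all__"]])) {
    codons <- names(Biostrings::GENETIC_CODE)
    sense <- codons[Biostrings::GENETIC_CODE != "*"]
    .codon_snv_cache[["__all__"]] <-
      dplyr::bind_rows(lapply(sense, .codon_snvs_one))
  }
  .codon_snv_cache[["__all__"]]
}

#' Standardise gene symbols with a synonym map
#'
#' Replaces every symbol by its approved symbol and collapses exact duplicate
#' rows that the replacement creates. Unmapped symbols are retained and
#' reported with a message rather than dropped: absence from the synonym map
#' is not evidence the symbol is wrong.
#'
#' @param table A data frame with a `gene_id` column.
#' @param synonym_map Two-column data frame (`symbol`, `approved`).
#' @return The table with standardised `gene_id`, duplicates collapsed.
#' @export
normalize_gene_ids <- function(table, synonym_map) {
  assert_columns(table, "gene_id")
  if (nrow(synonym_map) == 0) {
    return(dplyr::distinct(as_tibble(table)))
  }
  names(synonym_map)[1:2] <- c("symbol", "approved")
  conflicts <- synonym_map %>%
    dplyr::distinct(.data$symbol, .data$approved) %>%
    dplyr::count(.data$symbol) %>%
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    stop("synonym map has conflicting targets for symbol(s): ",
         paste(conflicts$symbol, collapse = ", "), call. = FALSE)
  }
  map <- setNames(synonym_map$approved, synonym_map$symbol)
  hit <- table$gene_id %in% names(map)
  if (any(!hit)) {
    message(sum(!hit), " gene symbol(s) not in synonym map; retained as-is")
  }
  table$gene_id[hit] <- unname(map[table$gene_id[hit]])
  dplyr::distinct(as_tibble(table))
}
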