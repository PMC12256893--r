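# Shared fixtures built in code. The default bundle and its derived objects
# are computed once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

test_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    .fixtures$bundle <- simulate_bundle(sim_config(seed = 42))
  }
  .fixtures$bundle
}

test_ingest <- function() {
  if (is.null(.fixtures$ingest)) {
    b <- test_bundle()
    .fixtures$ingest <- ingest_chemoproteomics(b$peptides, b$proteins)
  }
  .fixtures$ingest
}

test_classified <- function() {
  if (is.null(.fixtures$classified)) {
    .fixtures$classified <- classify_variants(test_bundle()$variants)$variants
  }
  .fixtures$classified
}

# Parsed structure models of the default bundle, written to PDB and read
# back, so tests exercise the real file round-trip.
test_models <- function() {
  if (is.null(.fixtures$models)) {
    b <- test_bundle()
    td <- file.path(tempdir(), "ckyburden-structs")
    dir.create(td, showWarnings = FALSE)
    .fixtures$models <- lapply(seq_len(nrow(b$structures)), function(i) {
      p <- file.path(td, paste0(b$structures$structure_id[i], ".pdb"))
      write_structure_pdb(b$structures[i, ], p)
      parse_structure(p)
    })
    .fixtures$map <- verify_structure_map(
      dplyr::bind_rows(b$structures$map), b$proteins)
  }
  .fixtures$models
}

test_structure_map <- function() {
  test_models()
  .fixtures$map
}

test_environments <- function() {
  if (is.null(.fixtures$envs)) {
    .fixtures$envs <- compute_environments(test_models(),
                                           test_structure_map(),
                                           test_ingest()$cpdaa)
  }
  .fixtures$envs
}

# A tiny single-structure model/map pair given directly as tibbles, for
# geometric examples with hand-checkable distances.
toy_model <- function(atoms) {
  tibble::tibble(structure_id = "TOY1", chain = atoms$chain %||% "A",
                 resno = atoms$resno, resid = "ALA",
                 elety = atoms$elety, x = atoms$x, y = atoms$y, z = atoms$z)
}

toy_map <- function(accession, positions, chain = "A") {
  tibble::tibble(accession = accession, position = positions,
                 structure_id = "TOY1", chain = chain,
                 structure_residue_number = positions,
                 structure_aa = "A", aa_match = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a FASTA file from named sequences; returns the path.
write_test_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}

# Independent exact two-sided p for a 2x2 table by explicit enumeration of
# all tables with the observed margins, using binomial coefficients only.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n_ <- b + d; k <- a + b
  lo <- max(0, k - n_); hi <- min(k, m)
  logp <- vapply(lo:hi, function(x) {
    lchoose(m, x) + lchoose(n_, k - x) - lchoose(m + n_, k)
  }, numeric(1))
  p <- exp(logp)
  p_obs <- p[a - lo + 1]
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}
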