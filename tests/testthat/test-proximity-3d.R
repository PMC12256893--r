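test_that("terminal atoms map C/K/Y to SG/NZ/OH", {
  expect_equal(terminal_atom_name("C"), "SG")
  expect_equal(terminal_atom_name("K"), "NZ")
  expect_equal(terminal_atom_name("Y"), "OH")
  expect_equal(terminal_atom_name(c("C", "Y")), c("SG", "OH"))
  expect_error(terminal_atom_name("W"), "unsupported")
})

test_that("parse_structure reads ATOM records and honours altloc", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       3.200   0.000   0.000  0.50  0.00           C",
    "ATOM      5  O   GLY A   2       4.000   1.000   0.000  1.00  0.00           O",
    "HETATM    6  O   HOH A 101       9.000   9.000   9.000  1.00  0.00           O",
    "TER", "END"), path)
  m <- parse_structure(path)
  expect_equal(nrow(m), 4)                      # altloc B and water dropped
  expect_equal(sum(m$resno == 2 & m$elety == "CA"), 1)
  expect_equal(m$x[m$resno == 2 & m$elety == "CA"], 3.0)
  expect_false(any(m$resid == "HOH"))
})

test_that("simulated structures round-trip through PDB to 3 decimals", {
  b <- test_bundle()
  st <- b$structures[1, ]
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(st, path)
  m <- parse_structure(path)
  atoms <- st$atoms[[1]]
  joined <- dplyr::inner_join(
    atoms, m, by = c("chain", "resno", "elety"))
  expect_equal(nrow(joined), nrow(atoms))
  expect_equal(joined$x.x, joined$x.y, tolerance = 1e-3)
  expect_equal(joined$y.x, joined$y.y, tolerance = 1e-3)
  expect_equal(joined$z.x, joined$z.y, tolerance = 1e-3)
})

test_that("helix backbone spacing matches the closed-form chord", {
  b <- test_bundle()
  cfg <- b$config
  atoms <- b$structures$atoms[[1]]
  ca <- atoms[atoms$elety == "CA" & atoms$chain == "A", ]
  d_obs <- sqrt(diff(ca$x)^2 + diff(ca$y)^2 + diff(ca$z)^2)
  chord <- sqrt((2 * cfg$helix_radius *
                   sin(cfg$helix_twist * pi / 360))^2 + cfg$helix_rise^2)
  expect_equal(d_obs, rep(chord, nrow(ca) - 1), tolerance = 1e-6)
})

test_that("residue_environment resolves the 3-4-5 toy geometry", {
  model <- toy_model(tibble::tibble(
    chain = "A", resno = c(1L, 2L, 2L, 3L),
    elety = c("SG", "CB", "CA", "CB"),
    x = c(0, 3, 6, 0), y = c(0, 4, 8, 0), z = c(0, 0, 0, 10.5)))
  map <- toy_map("P1", 1:3)
  env <- residue_environment(model, map, "P1", 1L, "C")
  expect_equal(env$min_distance[env$neighbor_position == 2], 5.0)
  expect_false(3 %in% env$neighbor_position)     # 10.5 A is out of range
  expect_false(1 %in% env$neighbor_position)     # own residue excluded
})

test_that("environments are skipped with a reason when unanchorable", {
  model <- toy_model(tibble::tibble(chain = "A", resno = 1:2,
                                    elety = c("CA", "CA"),
                                    x = c(0, 1), y = 0, z = 0))
  map <- toy_map("P1", 1:2)
  e1 <- residue_environment(model, map, "P1", 1L, "C")
  expect_equal(attr(e1, "skip_reason"), "missing_atom")
  e2 <- residue_environment(model, map, "P1", 9L, "C")
  expect_equal(attr(e2, "skip_reason"), "unmapped")
})

test_that("environment neighbour sets are nested across cutoffs", {
  envs <- test_environments()$environments
  key <- function(x) paste(x$accession, x$position, x$neighbor_position)
  k6 <- key(slice_environment(envs, 6))
  k8 <- key(slice_environment(envs, 8))
  k10 <- key(slice_environment(envs, 10))
  expect_true(all(k6 %in% k8))
  expect_true(all(k8 %in% k10))
})

test_that("environment burden counts unique alleles and unions structures", {
  env <- tibble::tibble(
    accession = "P1", position = 50L, residue_type = "C",
    structure_id = c("S1", "S1", "S2"),
    neighbor_position = c(100L, 104L, 104L),
    neighbor_chain = "A", min_distance = c(4, 6, 5))
  variants <- tibble::tibble(
    accession = "P1", position = c(100L, 100L, 104L),
    alt_aa = c("R", "Q", "W"), variant_class = "pathogenic")
  out <- environment_burden(env, variants, cutoff = 8)
  expect_equal(out$n_alleles[out$variant_class == "pathogenic"], 3L)
  # two structures with disjoint neighbour sets union to one environment
  env2 <- dplyr::mutate(env, neighbor_position = c(100L, 100L, 104L))
  out2 <- environment_burden(env2, variants, cutoff = 8)
  expect_equal(out2$n_alleles[out2$variant_class == "pathogenic"], 3L)
})

test_that("union across structures keeps per-position minimum distances", {
  envs <- test_environments()$environments
  merged <- slice_environment(envs, 10) |>
    dplyr::group_by(accession, position, neighbor_position) |>
    dplyr::summarise(min_distance = min(min_distance), .groups = "drop")
  per_struct <- slice_environment(envs, 10)
  j <- dplyr::inner_join(
    merged, per_struct,
    by = c("accession", "position", "neighbor_position"),
    suffix = c("_merged", "_struct"), relationship = "many-to-many")
  expect_true(all(j$min_distance_merged <= j$min_distance_struct + 1e-9))
})

test_that("per-type 3D enrichment reproduces the toy table", {
  burdens <- tibble::tibble(
    accession = "P1",
    position = 1:12, residue_type = c(rep("C", 4), rep("K", 8)),
    variant_class = "pathogenic",
    n_alleles = as.integer(c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0, 0, 0)),
    contains = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, rep(FALSE, 6)),
    cutoff = 8)
  out <- type_enrichment_3d(burdens, "pathogenic")
  cys <- out[out$residue_type == "C", ]
  expect_equal(unlist(cys[c("a", "b", "c", "d")], use.names = FALSE),
               c(3, 1, 2, 6))
  expect_equal(cys$odds_ratio, 9.0)
  # all environments containing leaves a zero column, flagged and corrected
  all_in <- dplyr::mutate(burdens, contains = TRUE, n_alleles = 1L)
  out2 <- type_enrichment_3d(all_in, "pathogenic")
  expect_true(all(out2$or_undefined))
  expect_true(all(out2$zero_corrected))
})

test_that("VUS ranking orders by burden with deterministic tie-break", {
  burdens <- tibble::tibble(
    accession = c("b", "a", "c", "a"),
    position = c(10L, 20L, 30L, 5L),
    residue_type = "C",
    variant_class = "vus",
    n_alleles = c(3L, 10L, 7L, 10L),
    contains = TRUE, cutoff = 8)
  out <- rank_by_vus(burdens, NULL, k = 4)
  expect_equal(out$ranked$accession, c("a", "a", "c", "b"))
  expect_equal(out$ranked$position, c(5L, 20L, 30L, 10L))
  cadd <- tibble::tibble(accession = "a", position = c(5L, 20L),
                         mean_phred = c(30, 10),
                         deleterious = c(TRUE, FALSE))
  out2 <- rank_by_vus(burdens, cadd, k = 2)
  expect_true(out2$ranked$deleterious[1])
  expect_equal(out2$frac_deleterious, 0.5)
})

test_that("burden clustering separates a planted high group", {
  m <- rbind(matrix(c(25, 3, 30, 2, 28, 4), 3, 2, byrow = TRUE),
             matrix(rep(c(2, 1), 13), 13, 2, byrow = TRUE))
  rownames(m) <- paste0("r", 1:16)
  out <- cluster_burden(m)
  expect_equal(out$high_group_size, 3)
  expect_equal(out$groups$group[1:3], rep("high", 3))
  expect_false(out$degenerate)
  same <- matrix(1, 4, 3)
  expect_true(cluster_burden(same)$degenerate)
  expect_error(cluster_burden(m[1, , drop = FALSE]), "at least 2")
})

test_that("a hand-linked 5-row toy matrix splits on totals", {
  # row totals 25, 30, 4, 5, 6; centred profiles of the first two rows sit
  # far from the rest under Euclidean average linkage
  m <- matrix(c(20, 5, 24, 6, 2, 2, 3, 2, 2, 4), 5, 2, byrow = TRUE)
  rownames(m) <- paste0("s", 1:5)
  out <- cluster_burden(m)
  expect_equal(sort(out$groups$row[out$groups$group == "high"]),
               c("s1", "s2"))
  expect_equal(out$groups$total_burden, c(25, 30, 4, 5, 6))
})

test_that("sphere composition reports the variant-involved fraction", {
  env <- tibble::tibble(
    accession = "FHX", position = 333L, residue_type = "C",
    structure_id = "S1", neighbor_position = 1:44,
    neighbor_chain = "A", min_distance = 6)
  variants <- tibble::tibble(
    accession = "FHX", position = 1:34,
    alt_aa = "R",
    variant_class = rep(c("pathogenic", "vus"), c(4, 30)))
  out <- environment_composition(env, variants)
  expect_equal(out$n_neighbors, 44L)
  expect_equal(out$n_with_variant, 34L)
  expect_equal(round(out$pct_with_variant), 77)
})

test_that("candidate filter applies all five criteria", {
  proteins <- tibble::tibble(
    accession = c("FHX", "LONG", "NOSTRUCT"),
    length = c(510L, 1200L, 300L))
  variants <- dplyr::bind_rows(lapply(proteins$accession, function(a) {
    tibble::tibble(accession = a, position = c(10L, 20L), alt_aa = "R",
                   variant_class = c("pathogenic", "benign_common"))
  }))
  cpdaa <- tibble::tibble(accession = proteins$accession,
                          position = 5L, residue_type = "C")
  burdens <- tibble::tibble(
    accession = proteins$accession, position = 5L, residue_type = "C",
    variant_class = "pathogenic", n_alleles = 1L, contains = TRUE,
    cutoff = 8)
  out <- candidate_filter(proteins, variants,
                          structure_accessions = c("FHX", "LONG"),
                          cpdaa, burdens)
  expect_true(out$passes[out$accession == "FHX"])
  expect_false(out$passes[out$accession == "LONG"])       # too long
  expect_false(out$passes[out$accession == "NOSTRUCT"])   # no structure
  expect_false(out$length_lt_1000[out$accession == "LONG"])
  expect_false(out$has_structure[out$accession == "NOSTRUCT"])
})

test_that("3D zone enrichment recovers the planted multiplier", {
  b <- test_bundle()
  envs <- test_environments()$environments
  res <- env_class_enrichment(envs, test_classified())
  expect_true(res$ci_low <= b$truth$planted_env_or)
  expect_true(res$ci_high >= b$truth$planted_env_or)
})

test_that("planted VUS clustering puts the burdened residue first", {
  # one residue given an artificially VUS-rich neighbourhood
  env <- dplyr::bind_rows(lapply(1:5, function(i) {
    tibble::tibble(accession = "P1", position = i * 100L,
                   residue_type = "C", structure_id = "S1",
                   neighbor_position = i * 100L + 1:6,
                   neighbor_chain = "A", min_distance = 5)
  }))
  variants <- dplyr::bind_rows(
    tibble::tibble(accession = "P1", position = 301L + 0:5, alt_aa = "R",
                   variant_class = "vus"),
    tibble::tibble(accession = "P1", position = 101L, alt_aa = "R",
                   variant_class = "vus"))
  bur <- environment_burden(env, variants, cutoff = 8)
  out <- rank_by_vus(bur, NULL, k = 5)
  expect_equal(out$ranked$position[1], 300L)
})
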