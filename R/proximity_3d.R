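# Structure-based (3D) proximity layer: terminal side-chain atom distances,
# residue environments at 6/8/10 angstrom cutoffs, missense burden and
# enrichment by residue type, VUS ranking, burden clustering, and the
# five-criterion candidate filter.

#' Terminal side-chain atom for a probed residue type
#'
#' All 3D distances are anchored at the reactive side-chain atom: the
#' cysteine sulfhydryl sulfur (SG), the lysine side-chain amine nitrogen
#' (NZ), or the tyrosine phenolic hydroxyl oxygen (OH).
#'
#' @param residue_type `"C"`, `"K"`, or `"Y"` (vectorised).
#' @return Atom name(s).
#' @export
terminal_atom_name <- function(residue_type) {
  bad <- !residue_type %in% CKY_TYPES
  if (any(bad)) {
    stop("unsupported residue type(s): ",
         paste(unique(residue_type[bad]), collapse = ", "), call. = FALSE)
  }
  unname(TERMINAL_ATOMS[residue_type])
}

#' Parse a PDB-format structure into an atom table
#'
#' Reads model 1 of a PDB file, keeps the first alternate location of each
#' atom, and drops waters, hetero groups, and hydrogens. Neighbour residues
#' from every chain of the assembly are retained.
#'
#' @param path Path to a PDB-format file.
#' @param structure_id Identifier stored with the atoms; defaults to the
#'   file name without extension.
#' @return Tibble with `structure_id`, `chain`, `resno`, `resid`, `elety`,
#'   `x`, `y`, `z`.
#' @export
parse_structure <- function(path, structure_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  structure_id <- structure_id %||%
    sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) {
      stop("failed to parse PDB file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  at <- pdb$atom
  keep <- at$type == "ATOM" &
    (is.na(at$alt) | at$alt %in% c("", "A")) &
    at$resid != "HOH" &
    !(toupper(substr(trimws(at$elety), 1, 1)) == "H")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no usable ATOM records in ", path, call. = FALSE)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  # first altloc only: one row per (chain, resno, atom name)
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  tibble(structure_id = structure_id, chain = at$chain,
         resno = as.integer(at$resno), resid = at$resid,
         elety = trimws(at$elety), x = at$x, y = at$y, z = at$z)
}

#' Read a sequence-to-structure residue mapping table
#'
#' Columns: `accession`, `position` (1-based sequence position),
#' `structure_id`, `chain`, `structure_residue_number`, `structure_aa`
#' (single letter). Rows whose structure residue identity disagrees with the
#' canonical sequence (`aa_match` false) are dropped with a message, since
#' engineered or mutated constructs must not anchor residue joins.
#'
#' @param path Path to the mapping TSV.
#' @param proteins Optional protein table; when given, `aa_match` is
#'   verified against the canonical sequences.
#' @return Tibble of verified mapping rows with an `aa_match` column (all
#'   `TRUE` after filtering).
#' @export
read_structure_map <- function(path, proteins = NULL) {
  map <- read_table_tsv(path)
  assert_columns(map, c("accession", "position", "structure_id", "chain",
                        "structure_residue_number", "structure_aa"),
                 "structure map")
  verify_structure_map(map, proteins)
}

#' Verify a structure map against canonical sequences
#' @param map Mapping tibble (see [read_structure_map()]).
#' @param proteins Optional protein table for sequence verification.
#' @return Verified mapping tibble (`aa_match` all `TRUE`).
#' @export
verify_structure_map <- function(map, proteins = NULL) {
  if (!is.null(proteins)) {
    seqs <- proteins$sequence[match(map$accession, proteins$accession)]
    map$aa_match <- !is.na(seqs) &
      verify_residue(seqs, map$position, map$structure_aa)
  } else if (!"aa_match" %in% names(map)) {
    map$aa_match <- TRUE
  }
  n_bad <- sum(!map$aa_match)
  if (n_bad > 0) {
    message(n_bad, " structure-map row(s) dropped: residue identity ",
            "mismatch with canonical sequence")
  }
  filter(map, .data$aa_match)
}

#' 3D residue environment of one detected residue
#'
#' From the terminal side-chain atom of the detected residue, the minimum
#' atomic distance to every other mapped residue of the assembly (all
#' chains); residues with minimum distance at or below `max_radius` form the
#' environment. Computed once at 10 angstrom and sliceable to 6/8 via
#' [slice_environment()]. Skipped (with a reason) when the residue is not
#' mapped or its terminal atom is absent.
#'
#' @param model Atom table from [parse_structure()].
#' @param map Verified structure map restricted to this structure.
#' @param accession,position,residue_type Identity of the detected residue.
#' @param max_radius Maximum stored neighbour distance in angstrom.
#' @return Tibble with `accession`, `position`, `residue_type`,
#'   `structure_id`, `neighbor_position`, `neighbor_chain`, `min_distance`;
#'   or a zero-row tibble with attribute `skip_reason` set.
#' @export
residue_environment <- function(model, map, accession, position,
                                residue_type, max_radius = 10) {
  empty <- tibble(accession = character(), position = integer(),
                  residue_type = character(), structure_id = character(),
                  neighbor_position = integer(),
                  neighbor_chain = character(), min_distance = numeric())
  map <- filter(map, .data$accession == !!accession,
                .data$structure_id %in% unique(model$structure_id))
  self <- filter(map, .data$position == !!position)
  if (nrow(self) == 0) {
    attr(empty, "skip_reason") <- "unmapped"
    return(empty)
  }
  term <- terminal_atom_name(residue_type)
  # a residue mapped to several chains (homo-oligomer): anchor at each copy,
  # keep per-neighbour minima
  anchors <- inner_join(
    self, model,
    by = c("structure_id", "chain",
           "structure_residue_number" = "resno")) %>%
    filter(.data$elety == term)
  if (nrow(anchors) == 0) {
    attr(empty, "skip_reason") <- "missing_atom"
    return(empty)
  }
  neigh_map <- filter(map, .data$position != !!position)
  atoms <- inner_join(
    neigh_map, model,
    by = c("structure_id", "chain", "structure_residue_number" = "resno"))
  if (nrow(atoms) == 0) {
    attr(empty, "skip_reason") <- "no_neighbors"
    return(empty)
  }
  out <- lapply(seq_len(nrow(anchors)), function(i) {
    dx <- atoms$x - anchors$x[i]
    dy <- atoms$y - anchors$y[i]
    dz <- atoms$z - anchors$z[i]
    d <- sqrt(dx * dx + dy * dy + dz * dz)
    tibble(neighbor_position = atoms$position,
           neighbor_chain = atoms$chain, d = d)
  })
  dplyr::bind_rows(out) %>%
    group_by(.data$neighbor_position) %>%
    summarise(neighbor_chain = .data$neighbor_chain[which.min(.data$d)],
              min_distance = min(.data$d), .groups = "drop") %>%
    filter(.data$min_distance <= max_radius) %>%
    mutate(accession = accession, position = as.integer(position),
           residue_type = residue_type,
           structure_id = model$structure_id[1],
           min_distance = round(.data$min_distance, 3)) %>%
    select("accession", "position", "residue_type", "structure_id",
           "neighbor_position", "neighbor_chain", "min_distance")
}

#' Compute environments for every detected residue across structures
#'
#' @param models List of atom tables (one per structure).
#' @param map Verified structure map covering the structures.
#' @param cpdaa CpDAA table.
#' @param max_radius Maximum neighbour distance in angstrom.
#' @return List with `environments` (row-bound neighbour records) and
#'   `skipped` (accession, position, structure_id, reason).
#' @export
compute_environments <- function(models, map, cpdaa, max_radius = 10) {
  envs <- list()
  skipped <- list()
  for (model in models) {
    sid <- model$structure_id[1]
    m <- filter(map, .data$structure_id == sid)
    cp <- semi_join(cpdaa, m, by = "accession")
    for (i in seq_len(nrow(cp))) {
      e <- residue_environment(model, m, cp$accession[i], cp$position[i],
                               cp$residue_type[i], max_radius)
      reason <- attr(e, "skip_reason")
      if (!is.null(reason)) {
        skipped[[length(skipped) + 1]] <-
          tibble(accession = cp$accession[i], position = cp$position[i],
                 structure_id = sid, reason = reason)
      } else {
        envs[[length(envs) + 1]] <- e
      }
    }
  }
  list(environments = dplyr::bind_rows(envs),
       skipped = dplyr::bind_rows(skipped))
}

#' Restrict environments to a tighter cutoff
#'
#' Environments are nested: the 6 angstrom environment is a subset of the 8,
#' which is a subset of the 10.
#'
#' @param environments Environment tibble.
#' @param cutoff Cutoff in angstrom (6, 8, or 10).
#' @return Filtered environment tibble.
#' @export
slice_environment <- function(environments, cutoff) {
  filter(environments, .data$min_distance <= cutoff)
}

#' Missense burden of each detected residue's 3D environment
#'
#' Neighbour sequence positions are unioned across structures (keeping each
#' position's minimum distance over structures), then unique (position,
#' alt_aa) alleles of each variant class among the neighbours are counted.
#'
#' @param environments Environment tibble from [compute_environments()].
#' @param variants Classified variant tibble.
#' @param cutoff Cutoff in angstrom.
#' @return Tibble, one row per detected residue x variant class, with
#'   `n_alleles` and `contains`; every residue with an environment appears
#'   for every class present in `variants`.
#' @export
environment_burden <- function(environments, variants, cutoff = 8) {
  assert_columns(environments, c("accession", "position", "residue_type",
                                 "neighbor_position", "min_distance"))
  assert_columns(variants, c("accession", "position", "alt_aa",
                             "variant_class"))
  env <- slice_environment(environments, cutoff) %>%
    group_by(.data$accession, .data$position, .data$residue_type,
             .data$neighbor_position) %>%
    summarise(min_distance = min(.data$min_distance), .groups = "drop")
  hits <- inner_join(
    env,
    variants %>% select("accession", neighbor_position = "position",
                        "alt_aa", "variant_class"),
    by = c("accession", "neighbor_position"),
    relationship = "many-to-many") %>%
    dplyr::distinct(.data$accession, .data$position, .data$residue_type,
                    .data$neighbor_position, .data$alt_aa,
                    .data$variant_class) %>%
    dplyr::count(.data$accession, .data$position, .data$residue_type,
                 .data$variant_class, name = "n_alleles")
  grid <- tidyr::expand_grid(
    dplyr::distinct(env, .data$accession, .data$position,
                    .data$residue_type),
    variant_class = intersect(VARIANT_CLASSES,
                              unique(variants$variant_class)))
  grid %>%
    left_join(hits, by = c("accession", "position", "residue_type",
                           "variant_class")) %>%
    mutate(n_alleles = tidyr::replace_na(.data$n_alleles, 0L),
           contains = .data$n_alleles > 0, cutoff = cutoff)
}

#' Containment proportions of 3D environments by residue type
#'
#' The fraction of detected residues of each type whose environment contains
#' at least one variant of the class (and pooled over types).
#'
#' @param burdens Output of [environment_burden()].
#' @param class Variant class label(s).
#' @return Tibble with `residue_type`, `n_containing`, `n_total`,
#'   `pct_containing`.
#' @export
env_containment_summary <- function(burdens, class = "pathogenic") {
  b <- burdens %>%
    filter(.data$variant_class %in% class) %>%
    group_by(.data$accession, .data$position, .data$residue_type) %>%
    summarise(contains = any(.data$contains), .groups = "drop")
  per <- b %>%
    group_by(.data$residue_type) %>%
    summarise(n_containing = sum(.data$contains), n_total = n(),
              .groups = "drop")
  bind_rows(per, tibble(residue_type = "all",
                        n_containing = sum(per$n_containing),
                        n_total = sum(per$n_total))) %>%
    mutate(pct_containing = 100 * .data$n_containing / .data$n_total)
}

#' Per-type 3D proximity enrichment
#'
#' For each residue type, a 2x2 exact test of {this type vs all other types}
#' x {environment contains >= 1 proximal variant of the class vs not}, over
#' de-duplicated detected residues.
#'
#' @param burdens Output of [environment_burden()] (one cutoff).
#' @param class Variant class label(s).
#' @param family_size Bonferroni family size for the panel.
#' @return Tibble, one row per residue type.
#' @export
type_enrichment_3d <- function(burdens, class = "pathogenic",
                               family_size = NULL) {
  b <- burdens %>%
    filter(.data$variant_class %in% class) %>%
    group_by(.data$accession, .data$position, .data$residue_type) %>%
    summarise(contains = any(.data$contains), .groups = "drop")
  types <- intersect(CKY_TYPES, unique(b$residue_type))
  if (length(types) < 2) {
    stop("need environments for at least two residue types", call. = FALSE)
  }
  rows <- lapply(types, function(tt) {
    this <- b$residue_type == tt
    a <- sum(this & b$contains); bb <- sum(this & !b$contains)
    c_ <- sum(!this & b$contains); d <- sum(!this & !b$contains)
    res <- fisher_exact(rbind(c(a, bb), c(c_, d)))
    tibble(residue_type = tt, a = a, b = bb, c = c_, d = d,
           odds_ratio = res$odds_ratio, ci_low = res$ci_low,
           ci_high = res$ci_high, p_value = res$p_value,
           zero_corrected = res$zero_corrected,
           or_undefined = res$or_undefined)
  })
  out <- dplyr::bind_rows(rows)
  fs <- family_size %||% nrow(out)
  out$p_adjusted <- pmin(1, out$p_value * fs)
  out
}

#' Rank detected residues by local VUS burden
#'
#' Sorts detected residues by the number of unique VUS alleles in their 3D
#' environment (descending; ties broken by accession then position,
#' ascending), joins per-codon mean CADD scores where available, and reports
#' the fraction of the top `k` flagged deleterious.
#'
#' @param burdens Output of [environment_burden()].
#' @param cadd_scores `scores` tibble from [mean_cadd_per_codon()], or
#'   `NULL`.
#' @param k Number of top rows to report.
#' @return List with `ranked` (top-k tibble with `rank`, `n_vus`,
#'   `mean_phred`, `deleterious`) and `frac_deleterious` (among scored
#'   top-k rows).
#' @export
rank_by_vus <- function(burdens, cadd_scores = NULL, k = 50) {
  vus <- burdens %>%
    filter(.data$variant_class == "vus") %>%
    group_by(.data$accession, .data$position, .data$residue_type) %>%
    summarise(n_vus = sum(.data$n_alleles), .groups = "drop") %>%
    arrange(dplyr::desc(.data$n_vus), .data$accession, .data$position) %>%
    mutate(rank = row_number())
  top <- head(vus, k)
  if (!is.null(cadd_scores)) {
    top <- left_join(top,
                     select(cadd_scores, "accession", "position",
                            "mean_phred", "deleterious"),
                     by = c("accession", "position"))
  } else {
    top$mean_phred <- NA_real_
    top$deleterious <- NA
  }
  scored <- !is.na(top$deleterious)
  list(ranked = top,
       frac_deleterious = if (any(scored)) mean(top$deleterious[scored])
                          else NA_real_)
}

#' Cluster detected residues by local missense burden
#'
#' Rows (detected residues) of a residue x class count matrix are centred by
#' subtracting the row mean (no unit-variance scaling), clustered
#' hierarchically (Euclidean distance, average linkage), and cut into two
#' groups; the group with the larger mean total burden is labelled
#' `"high"`. Degenerate inputs (all rows identical) are flagged.
#'
#' @param burden_matrix Numeric matrix of non-negative counts, residues as
#'   rows (named), classes as columns.
#' @return List with `groups` (tibble: row, group, total_burden),
#'   `high_group_size`, `degenerate`, and the `hclust` object.
#' @export
cluster_burden <- function(burden_matrix) {
  burden_matrix <- as.matrix(burden_matrix)
  if (nrow(burden_matrix) < 2) {
    stop("need at least 2 rows to cluster", call. = FALSE)
  }
  centred <- burden_matrix - rowMeans(burden_matrix)
  degenerate <- all(dist(centred) < .Machine$double.eps^0.5)
  hc <- hclust(dist(centred, method = "euclidean"), method = "average")
  cut <- unname(cutree(hc, k = 2))
  totals <- rowSums(burden_matrix)
  mean1 <- mean(totals[cut == 1]); mean2 <- mean(totals[cut == 2])
  high <- if (mean1 >= mean2) 1 else 2
  groups <- tibble(
    row = rownames(burden_matrix) %||% as.character(seq_len(nrow(burden_matrix))),
    group = ifelse(cut == high, "high", "low"),
    total_burden = unname(totals))
  list(groups = groups, high_group_size = sum(cut == high),
       degenerate = degenerate, hclust = hc)
}

#' Composition of one residue's 3D sphere by variant involvement
#'
#' Among the neighbour residues of one environment, the count and fraction
#' of positions carrying at least one variant of the given classes
#' (pathogenic, likely pathogenic and VUS by default, i.e. clinically
#' flagged or unresolved alleles).
#'
#' @param environment Environment tibble for a single detected residue.
#' @param variants Classified variant tibble.
#' @param classes Variant class labels counted as involved.
#' @param cutoff Cutoff in angstrom.
#' @return One-row tibble with `n_neighbors`, `n_with_variant`,
#'   `pct_with_variant`.
#' @export
environment_composition <- function(environment, variants,
                                    classes = c("pathogenic", "vus"),
                                    cutoff = 8) {
  env <- slice_environment(environment, cutoff) %>%
    dplyr::distinct(.data$accession, .data$neighbor_position)
  v <- filter(variants, .data$variant_class %in% classes)
  vkey <- unique(paste(v$accession, v$position))
  hit <- paste(env$accession, env$neighbor_position) %in% vkey
  tibble(n_neighbors = nrow(env), n_with_variant = sum(hit),
         pct_with_variant = if (nrow(env) > 0) 100 * mean(hit) else NA_real_)
}

#' Class enrichment inside detected residues' 3D environments
#'
#' Variant-level 2x2 exact test of {class A vs class B} x {position inside
#' the union of detected residues' environments at the cutoff vs not},
#' restricted to proteins with at least one computed environment. When
#' class A is placed with an odds multiplier for the 3D zone relative to a
#' uniformly placed comparator class, the sample odds ratio estimates that
#' multiplier directly — the 3D analogue of
#' [proximity_class_enrichment()].
#'
#' @param environments Environment tibble from [compute_environments()].
#' @param variants Classified variant tibble.
#' @param classes Length-2 list: class label(s) A (tested) and B
#'   (comparator).
#' @param cutoff Cutoff in angstrom.
#' @return An `enrichment_result`.
#' @export
env_class_enrichment <- function(environments, variants,
                                 classes = list("vus",
                                                background_classes()),
                                 cutoff = 8) {
  env <- slice_environment(environments, cutoff)
  zone <- unique(paste(env$accession, env$neighbor_position))
  covered <- unique(env$accession)
  v <- filter(variants, .data$variant_class %in% unlist(classes),
              .data$accession %in% covered)
  in_zone <- paste(v$accession, v$position) %in% zone
  is_a <- v$variant_class %in% classes[[1]]
  fisher_exact(rbind(c(sum(is_a & in_zone), sum(is_a & !in_zone)),
                     c(sum(!is_a & in_zone), sum(!is_a & !in_zone))))
}

#' Five-criterion candidate filter
#'
#' A protein passes when it (1) has both pathogenic and common/benign
#' missense variants, (2) has a solved structure, (3) is shorter than 1,000
#' residues, (4) has a missense variant inside a detected residue's 8
#' angstrom environment, and (5) carries at least one chemoproteomic-
#' detected residue.
#'
#' @param proteins Protein table.
#' @param variants Classified variant tibble.
#' @param structure_accessions Accessions with at least one structure.
#' @param cpdaa CpDAA table.
#' @param burdens Output of [environment_burden()] at 8 angstrom.
#' @param max_length Length threshold (strictly less than).
#' @return Tibble of per-protein criterion flags and `passes`.
#' @export
candidate_filter <- function(proteins, variants, structure_accessions,
                             cpdaa, burdens, max_length = 1000) {
  per_gene <- variants %>%
    group_by(.data$accession) %>%
    summarise(
      has_path = any(.data$variant_class == "pathogenic"),
      has_bg = any(.data$variant_class %in% background_classes()),
      .groups = "drop")
  env_hit <- burdens %>%
    group_by(.data$accession) %>%
    summarise(variant_in_env = any(.data$contains), .groups = "drop")
  proteins %>%
    select("accession", "length") %>%
    left_join(per_gene, by = "accession") %>%
    left_join(env_hit, by = "accession") %>%
    mutate(
      has_path_and_benign = tidyr::replace_na(.data$has_path &
                                                .data$has_bg, FALSE),
      has_structure = .data$accession %in% structure_accessions,
      length_lt_1000 = .data$length < max_length,
      variant_in_cpdaa_env = tidyr::replace_na(.data$variant_in_env, FALSE),
      is_cky_detected = .data$accession %in% unique(cpdaa$accession),
      passes = .data$has_path_and_benign & .data$has_structure &
        .data$length_lt_1000 & .data$variant_in_cpdaa_env &
        .data$is_cky_detected) %>%
    select("accession", "has_path_and_benign", "has_structure",
           "length_lt_1000", "variant_in_cpdaa_env", "is_cky_detected",
           "passes")
}
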