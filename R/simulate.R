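# Seeded synthetic-data generator. Produces a complete fixture bundle
# (proteome + coding sequences, peptide-level chemoproteomics records with
# deliberate decoys, classified-variant tables with planted proximity
# enrichment, gene annotations, ideal-helix structures with a residue map,
# per-substitution CADD scores) together with the ground truth needed to
# verify every planted quantity. The whole bundle is a pure function of the
# configuration, including its seed.

# Average amino-acid frequencies of the human proteome (UniProt statistics,
# rounded); the baseline composition the proteome sampler draws from.
HUMAN_AA_FREQ <- c(
  A = 0.0702, C = 0.0230, D = 0.0474, E = 0.0710, F = 0.0365,
  G = 0.0658, H = 0.0263, I = 0.0433, K = 0.0573, L = 0.0996,
  M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
  S = 0.0833, T = 0.0536, V = 0.0597, W = 0.0122, Y = 0.0266
)
HUMAN_AA_FREQ <- HUMAN_AA_FREQ / sum(HUMAN_AA_FREQ)

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' residue-type detection rates near the observed detected fractions of
#' cysteine (14%), lysine (4.2%) and tyrosine (2.7%); a planted odds
#' multiplier of 2 for pathogenic placement within 6 residues of a detected
#' site (and the 3D analogue for VUS placement within 8 angstrom); peptide
#' evidence with at least two replicates per site and a small spike of decoy
#' records violating each ingest filter; ideal alpha-helix geometry (rise
#' 1.5 angstrom, twist 100 degrees per residue) so inter-residue distances
#' have closed forms.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Integer min/max protein length (residues).
#' @param aa_frequencies Named 20-vector of amino-acid frequencies (sums
#'   to 1).
#' @param cpdaa_rate Named per-type detection probability for C, K, Y sites.
#' @param planted_window_or Odds multiplier for pathogenic placement at
#'   linear distance 1-6 from a detected site.
#' @param planted_env_or Odds multiplier for VUS placement within 8 angstrom
#'   of a detected site (proteins with structures).
#' @param n_pathogenic,n_background,n_vus,n_rare,n_rarest Variant counts per
#'   class.
#' @param reactivity_mix Named probabilities of planted reactivity
#'   categories (high/medium/low).
#' @param decoy_fraction Named fractions (relative to the number of detected
#'   sites) of decoy peptide records per violation:
#'   `multi_modified`, `too_short`, `singleton`.
#' @param structure_fraction Fraction of proteins given a structure.
#' @param two_chain_fraction Fraction of structures built as homodimers
#'   (second chain translated by `chain_offset`).
#' @param helix_rise,helix_twist,helix_radius Helix geometry: rise per
#'   residue (angstrom), twist per residue (degrees), backbone radius
#'   (angstrom).
#' @param terminal_offset Radial offset of the side-chain terminal
#'   pseudo-atom from the backbone radius (angstrom).
#' @param chain_offset Translation (x, y, z, angstrom) of the second chain.
#' @param seed Integer seed; identical configurations produce byte-identical
#'   bundles.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_proteins = 60,
                       length_range = c(200L, 400L),
                       aa_frequencies = HUMAN_AA_FREQ,
                       cpdaa_rate = c(C = 0.14, K = 0.042, Y = 0.027),
                       planted_window_or = 2,
                       planted_env_or = 2,
                       n_pathogenic = 400, n_background = 400,
                       n_vus = 400, n_rare = 150, n_rarest = 150,
                       reactivity_mix = c(high = 0.10, medium = 0.45,
                                          low = 0.45),
                       decoy_fraction = c(multi_modified = 0.05,
                                          too_short = 0.05,
                                          singleton = 0.05),
                       structure_fraction = 0.5,
                       two_chain_fraction = 0.3,
                       helix_rise = 1.5, helix_twist = 100,
                       helix_radius = 2.3, terminal_offset = 1.5,
                       chain_offset = c(8, 0, 0),
                       seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              length_range = as.integer(length_range),
              aa_frequencies = aa_frequencies, cpdaa_rate = cpdaa_rate,
              planted_window_or = planted_window_or,
              planted_env_or = planted_env_or,
              n_pathogenic = n_pathogenic, n_background = n_background,
              n_vus = n_vus, n_rare = n_rare, n_rarest = n_rarest,
              reactivity_mix = reactivity_mix,
              decoy_fraction = decoy_fraction,
              structure_fraction = structure_fraction,
              two_chain_fraction = two_chain_fraction,
              helix_rise = helix_rise, helix_twist = helix_twist,
              helix_radius = helix_radius,
              terminal_offset = terminal_offset,
              chain_offset = chain_offset, seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_proteins >= 1,
            length(cfg$length_range) == 2,
            cfg$length_range[1] >= 12,
            cfg$length_range[2] >= cfg$length_range[1])
  if (abs(sum(cfg$aa_frequencies) - 1) > 1e-6) {
    stop("aa_frequencies must sum to 1", call. = FALSE)
  }
  if (any(cfg$aa_frequencies < 0)) {
    stop("aa_frequencies must be non-negative", call. = FALSE)
  }
  if (!all(CKY_TYPES %in% names(cfg$cpdaa_rate)) ||
      any(cfg$cpdaa_rate < 0 | cfg$cpdaa_rate > 1)) {
    stop("cpdaa_rate must be probabilities named C, K, Y", call. = FALSE)
  }
  if (cfg$planted_window_or <= 0 || cfg$planted_env_or <= 0) {
    stop("planted odds multipliers must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a proteome with coding sequences
#'
#' Sequences are drawn residue-wise from the configured amino-acid
#' frequencies; coding sequences are back-translated with a uniform choice
#' among each residue's codons.
#'
#' @param config A [sim_config()]. The caller controls the RNG state;
#'   [simulate_bundle()] seeds it once from `config$seed`.
#' @return Protein table with columns `accession`, `gene_id`, `sequence`,
#'   `length`, `cds`.
#' @export
simulate_proteome <- function(config) {
  rng <- config$length_range[1]:config$length_range[2]
  lens <- rng[sample.int(length(rng), config$n_proteins, replace = TRUE)]
  aa <- names(config$aa_frequencies)
  code <- Biostrings::GENETIC_CODE
  codons_by_aa <- split(names(code), unname(code))
  # codon lookup matrix for vectorised uniform back-translation
  max_syn <- max(lengths(codons_by_aa))
  codon_mat <- t(vapply(codons_by_aa, function(x) {
    c(x, rep(NA_character_, max_syn - length(x)))
  }, character(max_syn)))
  n_syn <- lengths(codons_by_aa)
  seqs <- character(config$n_proteins)
  cds <- character(config$n_proteins)
  for (i in seq_len(config$n_proteins)) {
    s <- sample(aa, lens[i], replace = TRUE, prob = config$aa_frequencies)
    seqs[i] <- paste(s, collapse = "")
    row <- match(s, rownames(codon_mat))
    pick <- floor(runif(lens[i]) * n_syn[row]) + 1L
    cds[i] <- paste(codon_mat[cbind(row, pick)], collapse = "")
  }
  tibble(accession = sprintf("SP%04d", seq_len(config$n_proteins)),
         gene_id = sprintf("GENE%04d", seq_len(config$n_proteins)),
         sequence = seqs, length = lens, cds = cds)
}

#' Plant detected residues
#'
#' Each C/K/Y position is detected independently with its type's rate; a
#' reactivity category is planted per detected site from the configured
#' mixture, with a concrete R10:1 value drawn inside the category's range.
#'
#' @param proteins Output of [simulate_proteome()].
#' @param config A [sim_config()].
#' @return Truth tibble: `accession`, `position`, `residue_type`,
#'   `category`, `r10_1`.
#' @export
simulate_detected_sites <- function(proteins, config) {
  chars <- strsplit(proteins$sequence, "")
  out <- lapply(seq_len(nrow(proteins)), function(i) {
    hit <- which(chars[[i]] %in% CKY_TYPES)
    if (length(hit) == 0) return(NULL)
    tt <- chars[[i]][hit]
    det <- runif(length(hit)) < config$cpdaa_rate[tt]
    if (!any(det)) return(NULL)
    tibble(accession = proteins$accession[i], position = hit[det],
           residue_type = tt[det])
  })
  truth <- dplyr::bind_rows(out)
  if (nrow(truth) == 0) {
    stop("no detected sites planted; raise cpdaa_rate or proteome size",
         call. = FALSE)
  }
  cat_names <- names(config$reactivity_mix)
  truth$category <- sample(cat_names, nrow(truth), replace = TRUE,
                           prob = config$reactivity_mix)
  truth$r10_1 <- round(dplyr::case_when(
    truth$category == "high" ~ runif(nrow(truth), 0.5, 2),
    truth$category == "medium" ~ runif(nrow(truth), 2 + 1e-6, 5),
    TRUE ~ runif(nrow(truth), 5 + 1e-6, 15)
  ), 4)
  truth
}

# One marked replicate peptide covering a planted site.
.make_peptide <- function(sequence, position, width = 12) {
  len <- nchar(sequence)
  start <- max(1, min(position - sample(2:6, 1), len - width + 1))
  end <- min(len, start + width - 1)
  pep <- substr(sequence, start, end)
  mark_at <- position - start + 1
  paste0(substr(pep, 1, mark_at), "*",
         substr(pep, mark_at + 1, nchar(pep)))
}

#' Simulate peptide-level chemoproteomics records
#'
#' Every planted detected site is emitted as 2-3 replicate records from
#' distinct experiments, each a 6-45-residue single-marked peptide carrying
#' the site's planted R10:1 value. Decoy records that violate each ingest
#' filter (two marks, 5-residue peptides, singleton observations at
#' otherwise undetected sites) are spiked in at the configured fractions so
#' filter behaviour is testable.
#'
#' @param proteins Output of [simulate_proteome()].
#' @param config A [sim_config()].
#' @param truth Optional precomputed [simulate_detected_sites()] truth.
#' @return List with `peptides` (record tibble) and `truth`.
#' @export
simulate_cpdaa <- function(proteins, config, truth = NULL) {
  truth <- truth %||% simulate_detected_sites(proteins, config)
  seqs <- setNames(proteins$sequence, proteins$accession)
  probe_of <- c(C = "IA-alkyne", K = "STP-alkyne", Y = "HHS-465")
  recs <- lapply(seq_len(nrow(truth)), function(i) {
    n_rep <- sample(2:3, 1)
    exps <- paste0("EXP", sample(1:6, n_rep))
    pep <- .make_peptide(seqs[[truth$accession[i]]], truth$position[i])
    tibble(accession = truth$accession[i], peptide = pep,
           position = truth$position[i],
           residue_type = truth$residue_type[i],
           probe_id = unname(probe_of[truth$residue_type[i]]),
           experiment_id = exps,
           r10_1 = truth$r10_1[i])
  })
  peptides <- dplyr::bind_rows(recs)
  n_sites <- nrow(truth)
  decoys <- list()
  n_multi <- round(config$decoy_fraction[["multi_modified"]] * n_sites)
  if (n_multi > 0) {
    idx <- sample(nrow(truth), n_multi, replace = TRUE)
    decoys$multi <- tibble(
      accession = truth$accession[idx],
      peptide = vapply(idx, function(i) {
        p <- .make_peptide(seqs[[truth$accession[i]]], truth$position[i])
        sub("([CKY])([^*])", "\\1*\\2", paste0(p, ""), perl = TRUE)
      }, character(1)),
      position = truth$position[idx],
      residue_type = truth$residue_type[idx],
      probe_id = unname(probe_of[truth$residue_type[idx]]),
      experiment_id = "EXP1", r10_1 = truth$r10_1[idx])
    # guarantee two marks even if the regex found no second C/K/Y
    one_mark <- count_modification_marks(decoys$multi$peptide) < 2
    decoys$multi$peptide[one_mark] <-
      paste0(decoys$multi$peptide[one_mark], "C*")
  }
  n_short <- round(config$decoy_fraction[["too_short"]] * n_sites)
  if (n_short > 0) {
    idx <- sample(nrow(truth), n_short, replace = TRUE)
    decoys$short <- tibble(
      accession = truth$accession[idx],
      peptide = paste0(substr(seqs[truth$accession[idx]], 1, 4), "C*"),
      position = truth$position[idx],
      residue_type = truth$residue_type[idx],
      probe_id = unname(probe_of[truth$residue_type[idx]]),
      experiment_id = "EXP1", r10_1 = truth$r10_1[idx])
  }
  n_single <- round(config$decoy_fraction[["singleton"]] * n_sites)
  if (n_single > 0) {
    # undetected C/K/Y sites observed exactly once
    sites <- enumerate_sites(select(proteins, "accession", "sequence"),
                             truth)
    undet <- filter(sites, !.data$detected)
    if (nrow(undet) > 0) {
      idx <- sample(nrow(undet), min(n_single, nrow(undet)))
      decoys$single <- tibble(
        accession = undet$accession[idx],
        peptide = vapply(idx, function(i) {
          .make_peptide(seqs[[undet$accession[i]]], undet$position[i])
        }, character(1)),
        position = undet$position[idx],
        residue_type = undet$residue_type[idx],
        probe_id = unname(probe_of[undet$residue_type[idx]]),
        experiment_id = "EXP1",
        r10_1 = round(runif(length(idx), 0.5, 15), 4))
    }
  }
  list(peptides = bind_rows(peptides, dplyr::bind_rows(decoys)),
       truth = truth)
}

# Positions within linear distance 1..half_width of a detected site, per
# protein, as a keyed character vector for fast membership tests.
.window_zone_keys <- function(truth, proteins, half_width = 6) {
  lens <- setNames(proteins$length, proteins$accession)
  zones <- lapply(split(truth$position, truth$accession), function(pos) pos)
  keys <- character(0)
  for (acc in names(zones)) {
    pos <- zones[[acc]]
    cand <- unique(unlist(lapply(pos, function(p) {
      (p - half_width):(p + half_width)
    })))
    cand <- cand[cand >= 1 & cand <= lens[[acc]]]
    # the site positions themselves are direct overlaps, not zone members
    cand <- setdiff(cand, pos)
    keys <- c(keys, paste(acc, cand))
  }
  keys
}

# Closed-form ideal-helix atom coordinates for one chain.
.helix_atoms <- function(sequence, config, shift = c(0, 0, 0)) {
  n <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  theta <- (seq_len(n) - 1) * config$helix_twist * pi / 180
  z <- (seq_len(n) - 1) * config$helix_rise
  r <- config$helix_radius
  ca <- tibble(resno = seq_len(n), aa = chars, elety = "CA",
               x = r * cos(theta) + shift[1],
               y = r * sin(theta) + shift[2], z = z + shift[3])
  r2 <- r + config$terminal_offset
  side <- tibble(resno = seq_len(n), aa = chars,
                 elety = ifelse(chars %in% CKY_TYPES,
                                unname(TERMINAL_ATOMS[
                                  match(chars, CKY_TYPES)]), "CB"),
                 x = r2 * cos(theta) + shift[1],
                 y = r2 * sin(theta) + shift[2], z = z + shift[3])
  bind_rows(ca, side) %>% arrange(.data$resno)
}

# Generator-internal 3D proximity zone: positions whose nearest atom lies
# within `cutoff` of any detected site's terminal atom (any chain pairing),
# computed directly from the closed-form helix geometry.
.env_zone_keys <- function(truth, proteins, structures, cutoff = 8) {
  keys <- character(0)
  for (acc in unique(structures$accession)) {
    det <- filter(truth, .data$accession == acc)
    if (nrow(det) == 0) next
    st <- filter(structures, .data$accession == acc)
    atoms <- st$atoms[[1]]
    term <- atoms[atoms$resno %in% det$position &
                    atoms$elety %in% TERMINAL_ATOMS, , drop = FALSE]
    in_zone <- logical(max(atoms$resno))
    for (i in seq_len(nrow(term))) {
      d2 <- (atoms$x - term$x[i])^2 + (atoms$y - term$y[i])^2 +
        (atoms$z - term$z[i])^2
      hit <- unique(atoms$resno[d2 <= cutoff^2 & atoms$resno != term$resno[i]])
      in_zone[hit] <- TRUE
    }
    zone <- setdiff(which(in_zone), det$position)
    keys <- c(keys, paste(acc, zone))
  }
  keys
}

# Weighted allele draw: n variants over all proteome positions, zone
# positions carrying `or` times the baseline odds; alt amino acid sampled
# among the ref codon's missense single-nucleotide substitutions.
.draw_variants <- function(n, proteins, zone_keys, or) {
  pool <- tibble(accession = rep(proteins$accession, proteins$length),
                 position = sequence(proteins$length))
  w <- ifelse(paste(pool$accession, pool$position) %in% zone_keys, or, 1)
  idx <- sample(nrow(pool), n, replace = TRUE, prob = w)
  drawn <- pool[idx, , drop = FALSE]
  drawn$in_zone <- w[idx] > 1
  seqs <- setNames(proteins$sequence, proteins$accession)
  cds <- setNames(proteins$cds, proteins$accession)
  drawn$ref_aa <- substr(seqs[drawn$accession], drawn$position,
                         drawn$position)
  drawn$ref_codon <- substr(cds[drawn$accession], 3 * drawn$position - 2,
                            3 * drawn$position)
  snvs <- codon_snv_table()
  mis <- filter(snvs, .data$kind == "missense")
  mis_by_codon <- split(seq_len(nrow(mis)), mis$ref_codon)
  pick <- vapply(drawn$ref_codon, function(cd) {
    opts <- mis_by_codon[[cd]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, integer(1))
  drawn$alt_codon <- mis$alt_codon[pick]
  drawn$alt_aa <- mis$alt_aa[pick]
  as_tibble(drawn)
}

#' Simulate classified missense variants with planted proximity enrichment
#'
#' Background, rare and rarest variants are placed uniformly over all
#' residue positions. Pathogenic variants are placed with
#' `planted_window_or` times the baseline odds of landing at linear distance
#' 1-6 from a detected site; VUS variants with `planted_env_or` times the
#' baseline odds of landing within 8 angstrom of a detected site (for
#' proteins with structures). Clinical labels and allele frequencies are
#' emitted so that [classify_variants()] reproduces the planted classes
#' exactly.
#'
#' @param proteins Output of [simulate_proteome()].
#' @param truth Detected-site truth from [simulate_detected_sites()].
#' @param config A [sim_config()].
#' @param structures Optional structure list from [simulate_structures()];
#'   when `NULL`, VUS placement is uniform.
#' @return List with `variants` (raw rows for [classify_variants()]) and
#'   `truth` (per-allele planted class and zone flags).
#' @export
simulate_variants <- function(proteins, truth, config, structures = NULL) {
  if (nrow(truth) == 0) stop("no detected sites to plant around",
                             call. = FALSE)
  window_zone <- .window_zone_keys(truth, proteins, 6)
  env_zone <- if (!is.null(structures) && nrow(structures) > 0) {
    .env_zone_keys(truth, proteins, structures, 8)
  } else character(0)
  draw_class <- function(n, zone, or, class) {
    if (n == 0) return(NULL)
    mutate(.draw_variants(n, proteins, zone, or), planted_class = class)
  }
  all <- bind_rows(
    draw_class(config$n_pathogenic, window_zone,
               config$planted_window_or, "pathogenic"),
    draw_class(config$n_background, character(0), 1, "background"),
    draw_class(config$n_vus, env_zone,
               if (length(env_zone)) config$planted_env_or else 1, "vus"),
    draw_class(config$n_rare, character(0), 1, "rare"),
    draw_class(config$n_rarest, character(0), 1, "rarest")
  ) %>%
    dplyr::distinct(.data$accession, .data$position, .data$alt_aa,
                    .keep_all = TRUE)
  n <- nrow(all)
  label <- character(n)
  af <- numeric(n)
  cls <- all$planted_class
  label[cls == "pathogenic"] <- sample(
    c("pathogenic", "likely_pathogenic"), sum(cls == "pathogenic"),
    replace = TRUE)
  af[cls == "pathogenic"] <- runif(sum(cls == "pathogenic"), 0, 1e-6)
  label[cls == "background"] <- "none"
  af[cls == "background"] <- runif(sum(cls == "background"), 0.051, 0.5)
  label[cls == "vus"] <- "vus"
  af[cls == "vus"] <- runif(sum(cls == "vus"), 0, 1e-6)
  label[cls == "rare"] <- "none"
  af[cls == "rare"] <- runif(sum(cls == "rare"), 2e-5, 9e-4)
  label[cls == "rarest"] <- "none"
  af[cls == "rarest"] <- runif(sum(cls == "rarest"), 1e-8, 9e-6)
  variants <- tibble(
    accession = all$accession, position = all$position,
    ref_aa = all$ref_aa, alt_aa = all$alt_aa,
    ref_codon = all$ref_codon, alt_codon = all$alt_codon,
    clinical_label = label, allele_frequency = round(af, 10))
  list(variants = variants,
       truth = select(all, "accession", "position", "alt_aa",
                      "planted_class", "in_zone"))
}

#' Simulate ideal-helix structures with a residue map
#'
#' Each selected protein is laid on an ideal alpha helix (closed-form
#' coordinates), with a backbone CA per residue and one side-chain
#' pseudo-atom: the terminal atom (SG/NZ/OH) for C/K/Y residues, CB
#' otherwise. A configurable fraction of structures is a homodimer whose
#' second chain is the first translated by `chain_offset`, creating
#' inter-chain contacts. The map covers every residue of every chain with
#' matching identities.
#'
#' @param proteins Output of [simulate_proteome()].
#' @param config A [sim_config()].
#' @return Tibble with one row per structure: `accession`, `structure_id`,
#'   `n_chains`, and list-columns `atoms` (chain, resno, aa, elety, x, y,
#'   z), `map` (structure-map rows).
#' @export
simulate_structures <- function(proteins, config) {
  n_struct <- round(config$structure_fraction * nrow(proteins))
  if (n_struct == 0) {
    return(tibble(accession = character(), structure_id = character(),
                  n_chains = integer(), atoms = list(), map = list()))
  }
  chosen <- sort(sample(nrow(proteins), n_struct))
  rows <- lapply(seq_along(chosen), function(j) {
    i <- chosen[j]
    sid <- sprintf("SYN%04d", j)
    two <- runif(1) < config$two_chain_fraction
    a1 <- mutate(.helix_atoms(proteins$sequence[i], config), chain = "A")
    atoms <- if (two) {
      bind_rows(a1, mutate(.helix_atoms(proteins$sequence[i], config,
                                        config$chain_offset),
                           chain = "B"))
    } else a1
    map <- atoms %>%
      dplyr::distinct(.data$chain, .data$resno, .data$aa) %>%
      mutate(accession = proteins$accession[i], structure_id = sid,
             position = .data$resno,
             structure_residue_number = .data$resno) %>%
      select("accession", "position", "structure_id", "chain",
             "structure_residue_number", structure_aa = "aa")
    tibble(accession = proteins$accession[i], structure_id = sid,
           n_chains = if (two) 2L else 1L,
           atoms = list(atoms), map = list(map))
  })
  dplyr::bind_rows(rows)
}

#' Write a simulated structure as a PDB file
#'
#' @param structure One row of [simulate_structures()] output.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  atoms <- structure$atoms[[1]]
  resid3 <- bio3d::aa123(atoms$aa)
  n <- nrow(atoms)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   resno = atoms$resno, resid = resid3,
                   elety = atoms$elety, chain = atoms$chain,
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Simulate per-substitution CADD phred scores for detected residues
#'
#' Emits one phred value per missense single-nucleotide substitution of each
#' detected residue's codon. Sites planted `deleterious` draw phreds above
#' the threshold, others below, so per-codon means recover the plant; a
#' small fraction of codons is left with one score missing to exercise the
#' completeness rule.
#'
#' @param proteins Output of [simulate_proteome()].
#' @param truth Detected-site truth.
#' @param deleterious_fraction Fraction of detected sites planted
#'   deleterious.
#' @param incomplete_fraction Fraction of codons emitted with a missing
#'   substitution score.
#' @return List with `cadd` (accession, position, ref_codon, alt_codon,
#'   phred) and `truth` (per-site `deleterious`, `complete`).
#' @export
simulate_cadd <- function(proteins, truth, deleterious_fraction = 0.3,
                          incomplete_fraction = 0.05) {
  cds <- setNames(proteins$cds, proteins$accession)
  truth$deleterious <- runif(nrow(truth)) < deleterious_fraction
  truth$complete <- runif(nrow(truth)) >= incomplete_fraction
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    ref_codon <- substr(cds[truth$accession[i]], 3 * truth$position[i] - 2,
                        3 * truth$position[i])
    mis <- filter(enumerate_codon_snvs(ref_codon),
                  .data$kind == "missense")
    phred <- if (truth$deleterious[i]) runif(nrow(mis), 26, 37)
             else runif(nrow(mis), 5, 24)
    out <- tibble(accession = truth$accession[i],
                  position = truth$position[i],
                  ref_codon = ref_codon, alt_codon = mis$alt_codon,
                  phred = round(phred, 2))
    if (!truth$complete[i]) out <- out[-1, , drop = FALSE]
    out
  })
  list(cadd = dplyr::bind_rows(rows),
       truth = select(truth, "accession", "position", "deleterious",
                      "complete"))
}

#' Simulate gene annotations
#'
#' OMIM phenotype counts, FDA-target flags, constraint metric, LoF
#' tolerance, and protein-protein-interaction counts with a planted
#' location shift (higher interaction counts for detected proteins).
#'
#' @param proteins Output of [simulate_proteome()].
#' @param truth Detected-site truth (defines which genes are detected).
#' @param omim_fraction Fraction of genes given at least one phenotype.
#' @param ppi_shift Multiplier on the mean interaction count of detected
#'   genes.
#' @return Gene annotation tibble.
#' @export
simulate_gene_annotations <- function(proteins, truth,
                                      omim_fraction = 0.6,
                                      ppi_shift = 2) {
  n <- nrow(proteins)
  is_cpd <- proteins$accession %in% unique(truth$accession)
  has_omim <- runif(n) < omim_fraction
  tibble(
    gene_id = proteins$gene_id, accession = proteins$accession,
    omim_phenotype_count = ifelse(has_omim, 1L + stats::rpois(n, 0.8), 0L),
    is_fda_target = runif(n) < 0.1,
    is_cpd = is_cpd,
    constraint_metric = round(runif(n, 0.2, 1.4), 3),
    is_lof_tolerant = runif(n) < 0.05,
    ppi_count = stats::rpois(n, ifelse(is_cpd, 15 * ppi_shift, 15)),
    protein_length = proteins$length)
}

#' Simulate the complete fixture bundle in memory
#'
#' Seeds the RNG once from `config$seed` and generates every component in a
#' fixed order, making the bundle a pure function of the configuration.
#'
#' @param config A [sim_config()].
#' @return List: `config`, `proteins`, `peptides`, `variants`,
#'   `structures`, `cadd`, `genes`, and `truth` (detected sites, variant
#'   placements, CADD plants).
#' @export
simulate_bundle <- function(config = sim_config()) {
  set.seed(config$seed)
  proteins <- simulate_proteome(config)
  detected <- simulate_detected_sites(proteins, config)
  cp <- simulate_cpdaa(proteins, config, truth = detected)
  structures <- simulate_structures(proteins, config)
  v <- simulate_variants(proteins, detected, config, structures)
  cadd <- simulate_cadd(proteins, detected)
  genes <- simulate_gene_annotations(proteins, detected)
  list(config = config, proteins = proteins, peptides = cp$peptides,
       variants = v$variants, structures = structures, cadd = cadd$cadd,
       genes = genes,
       truth = list(detected = detected, variants = v$truth,
                    cadd = cadd$truth,
                    planted_window_or = config$planted_window_or,
                    planted_env_or = config$planted_env_or))
}

#' Write a fixture bundle to disk
#'
#' Writes the FASTA proteome, coding sequences, peptide records, variant
#' rows, gene annotations, CADD scores, PDB structures with their
#' sequence-structure map, the ground truth (JSON), and a manifest of MD5
#' checksums. Regeneration under the same configuration reproduces the
#' checksums byte for byte.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return The manifest tibble (`file`, `md5`), invisibly; the bundle is
#'   returned in attribute `bundle`.
#' @export
write_fixture_bundle <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundle <- simulate_bundle(config)
  fa <- file.path(outdir, "proteome.fa")
  writeLines(paste0(">", bundle$proteins$accession, " ",
                    bundle$proteins$gene_id, "\n",
                    bundle$proteins$sequence), fa)
  write_table_tsv(select(bundle$proteins, "accession", "cds"),
                  file.path(outdir, "cds.tsv"))
  write_table_tsv(bundle$peptides, file.path(outdir, "peptides.tsv"))
  write_table_tsv(bundle$variants, file.path(outdir, "variants.tsv"))
  write_table_tsv(bundle$genes, file.path(outdir, "genes.tsv"))
  write_table_tsv(bundle$cadd, file.path(outdir, "cadd.tsv"))
  st_dir <- file.path(outdir, "structures")
  dir.create(st_dir, showWarnings = FALSE)
  maps <- list()
  for (i in seq_len(nrow(bundle$structures))) {
    st <- bundle$structures[i, ]
    write_structure_pdb(st, file.path(st_dir,
                                      paste0(st$structure_id, ".pdb")))
    maps[[i]] <- st$map[[1]]
  }
  if (length(maps)) {
    write_table_tsv(dplyr::bind_rows(maps), file.path(outdir, "map.tsv"))
  }
  jsonlite::write_json(
    list(detected = bundle$truth$detected,
         variants = bundle$truth$variants,
         cadd = bundle$truth$cadd,
         planted_window_or = bundle$truth$planted_window_or,
         planted_env_or = bundle$truth$planted_env_or),
    file.path(outdir, "truth.json"), dataframe = "columns", digits = NA)
  files <- sort(setdiff(list.files(outdir, recursive = TRUE),
                        "manifest.tsv"))
  manifest <- tibble(file = files,
                     md5 = unname(tools::md5sum(file.path(outdir, files))))
  write_table_tsv(manifest, file.path(outdir, "manifest.tsv"))
  attr(manifest, "bundle") <- bundle
  invisible(manifest)
}
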