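# Linear-sequence (1D) proximity layer: every Cys/Lys/Tyr position of each
# analysis protein, detected or not, its distances to missense variants,
# window burden around it, and detected-vs-undetected enrichment.

#' Enumerate all Cys/Lys/Tyr positions with detection flags
#'
#' Lists every C, K, and Y residue of each protein exactly once, flagging the
#' ones present in the CpDAA table.
#'
#' @param proteins Protein table (`accession`, `sequence`).
#' @param cpdaa CpDAA table (`accession`, `position`, `residue_type`).
#' @return Tibble with `accession`, `position`, `residue_type`, `detected`.
#' @export
enumerate_sites <- function(proteins, cpdaa) {
  assert_columns(proteins, c("accession", "sequence"))
  assert_columns(cpdaa, c("accession", "position", "residue_type"))
  chars <- strsplit(proteins$sequence, "")
  sites <- dplyr::bind_rows(lapply(seq_len(nrow(proteins)), function(i) {
    hit <- which(chars[[i]] %in% CKY_TYPES)
    tibble(accession = proteins$accession[i], position = hit,
           residue_type = chars[[i]][hit])
  }))
  if (nrow(sites) == 0) {
    return(mutate(sites, detected = logical(0)))
  }
  det_key <- paste(cpdaa$accession, cpdaa$position)
  bad <- !verify_residue(
    proteins$sequence[match(cpdaa$accession, proteins$accession)],
    cpdaa$position, cpdaa$residue_type)
  if (any(bad, na.rm = TRUE)) {
    stop("CpDAA rows at non-C/K/Y or mismatched positions reached ",
         "enumerate_sites; run build_cpdaa_table first", call. = FALSE)
  }
  mutate(sites, detected = paste(.data$accession, .data$position) %in%
           det_key)
}

#' Per-type detection summary of Cys/Lys/Tyr sites
#'
#' @param sites Site table from [enumerate_sites()].
#' @return Tibble with `residue_type`, `n_detected`, `n_total`,
#'   `pct_detected`, plus a pooled row (`residue_type = "all"`).
#' @export
site_detection_summary <- function(sites) {
  assert_columns(sites, c("residue_type", "detected"))
  per <- sites %>%
    group_by(.data$residue_type) %>%
    summarise(n_detected = sum(.data$detected), n_total = n(),
              .groups = "drop")
  all_row <- tibble(residue_type = "all",
                    n_detected = sum(per$n_detected),
                    n_total = sum(per$n_total))
  bind_rows(per, all_row) %>%
    mutate(pct_detected = 100 * .data$n_detected / .data$n_total)
}

#' Direct-overlap enrichment at detected versus undetected sites
#'
#' For each residue type (and pooled), tests whether detected sites are more
#' likely than undetected sites to coincide exactly (distance 0) with a
#' missense variant of the given class.
#'
#' @param sites Site table from [enumerate_sites()].
#' @param variants Classified variant tibble.
#' @param class Variant class label(s) tested.
#' @param family_size Bonferroni family size for the panel.
#' @return Tibble (one row per residue type plus `"all"`) of 2x2 cells and
#'   exact-test statistics.
#' @export
direct_overlap_enrichment <- function(sites, variants, class = "pathogenic",
                                      family_size = NULL) {
  assert_columns(variants, c("accession", "position", "variant_class"))
  v <- filter(variants, .data$variant_class %in% class)
  vkey <- unique(paste(v$accession, v$position))
  s <- mutate(sites, overlapped = paste(.data$accession, .data$position)
              %in% vkey)
  groups <- c(as.list(CKY_TYPES), list(CKY_TYPES))
  names(groups) <- c(CKY_TYPES, "all")
  rows <- lapply(names(groups), function(g) {
    si <- filter(s, .data$residue_type %in% groups[[g]])
    a <- sum(si$detected & si$overlapped)
    b <- sum(si$detected & !si$overlapped)
    c_ <- sum(!si$detected & si$overlapped)
    d <- sum(!si$detected & !si$overlapped)
    if (a + c_ == 0) {
      return(tibble(residue_type = g, a = a, b = b, c = c_, d = d,
                    odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_,
                    or_undefined = TRUE, p_adjusted = NA_real_))
    }
    res <- fisher_exact(rbind(c(a, b), c(c_, d)))
    tibble(residue_type = g, a = a, b = b, c = c_, d = d,
           odds_ratio = res$odds_ratio, ci_low = res$ci_low,
           ci_high = res$ci_high, p_value = res$p_value,
           or_undefined = res$or_undefined, p_adjusted = NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  fs <- family_size %||% sum(!is.na(out$p_value))
  out$p_adjusted <- pmin(1, out$p_value * fs)
  out
}

#' All site-variant linear distances within proteins
#'
#' One row per (variant, site) pair sharing an accession; distance is the
#' absolute difference of positions, with distance 0 flagged as a direct
#' overlap.
#'
#' @param sites Site table.
#' @param variants Classified variant tibble.
#' @return Tibble with site and variant identifiers, `distance`, `overlap`.
#' @export
linear_distances <- function(sites, variants) {
  assert_columns(sites, c("accession", "position"))
  assert_columns(variants, c("accession", "position"))
  pairs <- inner_join(
    rename(sites, site_position = "position"),
    rename(variants, variant_position = "position"),
    by = "accession", relationship = "many-to-many")
  mutate(pairs,
         distance = abs(.data$site_position - .data$variant_position),
         overlap = .data$distance == 0L)
}

#' Nearest-target distance per anchor
#'
#' Minimum absolute linear distance from each anchor position to any target
#' position within the same protein. Direct overlaps (distance 0) are
#' excluded by default, mirroring the nearest-variant rule; anchors with no
#' eligible target are skipped (returned with `NA`).
#'
#' @param anchors Tibble with `accession`, `position` (plus any id columns).
#' @param targets Tibble with `accession`, `position`.
#' @param exclude_overlap Drop distance-0 pairs before taking the minimum.
#' @return `anchors` with an added `nearest_distance` column (`NA` when no
#'   eligible target exists in the protein).
#' @export
nearest_distance <- function(anchors, targets, exclude_overlap = TRUE) {
  assert_columns(anchors, c("accession", "position"))
  assert_columns(targets, c("accession", "position"))
  tl <- split(targets$position, targets$accession)
  nd <- vapply(seq_len(nrow(anchors)), function(i) {
    tp <- tl[[anchors$accession[i]]]
    if (is.null(tp)) return(NA_real_)
    d <- abs(tp - anchors$position[i])
    if (exclude_overlap) d <- d[d > 0]
    if (length(d) == 0) NA_real_ else min(d)
  }, numeric(1))
  mutate(anchors, nearest_distance = nd)
}

#' Window burden of missense variants around each site
#'
#' Counts, for every site and variant class, the unique (position, alt_aa)
#' alleles at linear distance 1..`half_width`; direct overlaps are excluded.
#' Windows are truncated at protein termini rather than discarded.
#'
#' @param sites Site table.
#' @param variants Classified variant tibble with `alt_aa`.
#' @param half_width Window half-width in residues (3, 6, or 15 are the
#'   conventional choices; 6 is the default).
#' @return Tibble: one row per site x class with `n_alleles` and `contains`;
#'   classes with zero alleles are present with `n_alleles = 0`.
#' @export
window_burden <- function(sites, variants, half_width = 6) {
  assert_columns(variants, c("accession", "position", "alt_aa",
                             "variant_class"))
  pairs <- linear_distances(sites, variants) %>%
    filter(.data$distance >= 1, .data$distance <= half_width)
  counts <- pairs %>%
    dplyr::distinct(.data$accession, .data$site_position,
                    .data$variant_position, .data$alt_aa,
                    .data$variant_class) %>%
    dplyr::count(.data$accession, .data$site_position, .data$variant_class,
                 name = "n_alleles")
  grid <- tidyr::expand_grid(
    sites %>% select("accession", site_position = "position",
                     "residue_type", "detected"),
    variant_class = intersect(VARIANT_CLASSES,
                              unique(variants$variant_class)))
  grid %>%
    left_join(counts, by = c("accession", "site_position", "variant_class")) %>%
    mutate(n_alleles = tidyr::replace_na(.data$n_alleles, 0L),
           contains = .data$n_alleles > 0,
           half_width = half_width)
}

#' Window containment enrichment, detected versus undetected sites
#'
#' 2x2 exact test of {detected vs undetected site} x {window contains >= 1
#' variant of the class vs not}, per residue type and pooled. Sites whose
#' protein carries no variant of the class still contribute "not
#' containing": that absence is information.
#'
#' @param burdens Output of [window_burden()].
#' @param class Variant class label(s).
#' @param family_size Bonferroni family size (e.g. 6 for a two-class,
#'   three-type panel).
#' @return Tibble, one row per residue type plus `"all"`.
#' @export
window_enrichment <- function(burdens, class = "pathogenic",
                              family_size = NULL) {
  assert_columns(burdens, c("residue_type", "detected", "variant_class",
                            "contains"))
  b <- burdens %>%
    filter(.data$variant_class %in% class) %>%
    group_by(.data$accession, .data$site_position, .data$residue_type,
             .data$detected) %>%
    summarise(contains = any(.data$contains), .groups = "drop")
  groups <- c(as.list(CKY_TYPES), list(CKY_TYPES))
  names(groups) <- c(CKY_TYPES, "all")
  rows <- lapply(names(groups), function(g) {
    bi <- filter(b, .data$residue_type %in% groups[[g]])
    a <- sum(bi$detected & bi$contains)
    bb <- sum(bi$detected & !bi$contains)
    c_ <- sum(!bi$detected & bi$contains)
    d <- sum(!bi$detected & !bi$contains)
    if (a + c_ == 0 || nrow(bi) == 0) {
      return(tibble(residue_type = g, a = a, b = bb, c = c_, d = d,
                    odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p_value = NA_real_,
                    or_undefined = TRUE, p_adjusted = NA_real_))
    }
    res <- fisher_exact(rbind(c(a, bb), c(c_, d)))
    tibble(residue_type = g, a = a, b = bb, c = c_, d = d,
           odds_ratio = res$odds_ratio, ci_low = res$ci_low,
           ci_high = res$ci_high, p_value = res$p_value,
           or_undefined = res$or_undefined, p_adjusted = NA_real_)
  })
  out <- dplyr::bind_rows(rows)
  fs <- family_size %||% sum(!is.na(out$p_value))
  out$p_adjusted <- pmin(1, out$p_value * fs)
  out
}

#' Class enrichment inside the detected-site proximity zone
#'
#' Variant-level 2x2 exact test of {class A vs class B} x {position within
#' linear distance 1..`half_width` of any detected site vs not}. When one
#' class is placed with an odds multiplier for the zone relative to a
#' uniformly placed comparator class, the sample odds ratio of this table
#' estimates that multiplier directly, which makes this the
#' parameter-recovery statistic for planted simulations.
#'
#' @param sites Site table ([enumerate_sites()]).
#' @param variants Classified variant tibble.
#' @param classes Length-2 list: class label(s) A (tested) and B
#'   (comparator).
#' @param half_width Zone half-width in residues.
#' @return An `enrichment_result`.
#' @export
proximity_class_enrichment <- function(sites, variants,
                                       classes = list("pathogenic",
                                                      background_classes()),
                                       half_width = 6) {
  det <- filter(sites, .data$detected)
  v <- filter(variants, .data$variant_class %in% unlist(classes))
  v <- nearest_distance(v, select(det, "accession", "position"),
                        exclude_overlap = FALSE)
  in_zone <- !is.na(v$nearest_distance) &
    v$nearest_distance >= 1 & v$nearest_distance <= half_width
  is_a <- v$variant_class %in% classes[[1]]
  fisher_exact(rbind(c(sum(is_a & in_zone), sum(is_a & !in_zone)),
                     c(sum(!is_a & in_zone), sum(!is_a & !in_zone))))
}

#' Compare nearest-distance distributions, detected versus undetected
#'
#' Two-sided rank-sum comparison of nearest-variant distances for detected
#' versus undetected sites (anchor mode `"site"`), or of nearest-site
#' distances anchored on variants against detected versus undetected site
#' populations (anchor mode `"variant"`), per residue type, with FDR
#' adjustment across types.
#'
#' @param sites Site table.
#' @param variants Classified variant tibble.
#' @param class Variant class label(s).
#' @param anchor `"site"` or `"variant"`.
#' @return Tibble, one row per residue type, with medians, `p_value`,
#'   `p_adjusted` (FDR).
#' @export
distance_comparison <- function(sites, variants, class = "pathogenic",
                                anchor = c("site", "variant")) {
  anchor <- match.arg(anchor)
  v <- filter(variants, .data$variant_class %in% class)
  rows <- lapply(CKY_TYPES, function(tt) {
    st <- filter(sites, .data$residue_type == tt)
    if (anchor == "site") {
      nd <- nearest_distance(st, select(v, "accession", "position"))
      da <- nd$nearest_distance[nd$detected]
      db <- nd$nearest_distance[!nd$detected]
    } else {
      nda <- nearest_distance(v, filter(st, .data$detected) %>%
                                select("accession", "position"))
      ndb <- nearest_distance(v, filter(st, !.data$detected) %>%
                                select("accession", "position"))
      da <- nda$nearest_distance
      db <- ndb$nearest_distance
    }
    da <- da[!is.na(da)]; db <- db[!is.na(db)]
    p <- if (length(da) > 0 && length(db) > 0) {
      suppressWarnings(wilcox.test(da, db)$p.value)
    } else NA_real_
    tibble(residue_type = tt, n_detected = length(da),
           n_undetected = length(db),
           median_detected = if (length(da)) median(da) else NA_real_,
           median_undetected = if (length(db)) median(db) else NA_real_,
           p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "fdr")
  out
}
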