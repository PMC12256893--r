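toy_sites <- function() {
  proteins <- tibble::tibble(accession = "P1", sequence = "CAKY")
  cpdaa <- tibble::tibble(accession = "P1", position = 1L,
                          residue_type = "C")
  enumerate_sites(proteins, cpdaa)
}

toy_variants <- function(positions, class = "pathogenic", acc = "P1") {
  tibble::tibble(accession = acc, position = as.integer(positions),
                 alt_aa = "R", variant_class = class)
}

test_that("enumerate_sites lists every C/K/Y once with detection flags", {
  sites <- toy_sites()
  expect_equal(nrow(sites), 3)
  expect_equal(sites$position, c(1L, 3L, 4L))
  expect_equal(sites$residue_type, c("C", "K", "Y"))
  expect_equal(sites$detected, c(TRUE, FALSE, FALSE))
  s <- site_detection_summary(sites)
  expect_equal(s$pct_detected[s$residue_type == "C"], 100)
  expect_equal(s$pct_detected[s$residue_type == "K"], 0)
})

test_that("site enumeration matches the planted detection truth", {
  b <- test_bundle()
  sites <- enumerate_sites(b$proteins, test_ingest()$cpdaa)
  expect_equal(sum(sites$detected), nrow(b$truth$detected))
  expect_equal(anyDuplicated(paste(sites$accession, sites$position)), 0)
  # every C/K/Y of a sampled protein is present
  i <- 7
  expect_equal(sum(sites$accession == b$proteins$accession[i]),
               sum(strsplit(b$proteins$sequence[i], "")[[1]] %in%
                     c("C", "K", "Y")))
})

test_that("direct-overlap enrichment reproduces the toy table", {
  sites <- tibble::tibble(
    accession = "P1", position = 1:10, residue_type = "C",
    detected = c(TRUE, TRUE, rep(FALSE, 8)))
  variants <- toy_variants(c(1, 3))
  out <- direct_overlap_enrichment(sites, variants, "pathogenic")
  cys <- out[out$residue_type == "C", ]
  expect_equal(unlist(cys[c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 1, 1, 7))
  expect_equal(cys$odds_ratio, 7.0)
  none <- direct_overlap_enrichment(sites, toy_variants(integer(0)),
                                    "pathogenic")
  expect_true(all(none$or_undefined))
})

test_that("linear distances and overlap flags", {
  sites <- tibble::tibble(accession = "P1", position = c(10L, 20L, 60L),
                          residue_type = "C", detected = TRUE)
  d <- linear_distances(sites, toy_variants(c(15, 60, 63)))
  expect_equal(sort(d$distance[d$site_position == 10]), c(5, 50, 53))
  expect_equal(sort(d$distance[d$site_position == 20]), c(5, 40, 43))
  expect_true(d$overlap[d$site_position == 60 & d$variant_position == 60])
  expect_equal(d$distance[d$site_position == 60 &
                            d$variant_position == 63], 3)
})

test_that("nearest distance excludes direct overlaps when asked", {
  anchors <- tibble::tibble(accession = "P1", position = 10L)
  expect_equal(
    nearest_distance(anchors, toy_variants(c(10, 14)))$nearest_distance, 4)
  expect_true(is.na(
    nearest_distance(anchors, toy_variants(10))$nearest_distance))
  expect_equal(
    nearest_distance(anchors, toy_variants(c(3, 12)))$nearest_distance, 2)
  expect_equal(
    nearest_distance(anchors, toy_variants(10),
                     exclude_overlap = FALSE)$nearest_distance, 0)
})

test_that("nearest distance with overlap exclusion is never zero", {
  b <- test_bundle()
  sites <- enumerate_sites(b$proteins, test_ingest()$cpdaa)
  v <- test_classified()
  nd <- nearest_distance(sites[sites$detected, ],
                         dplyr::select(v, accession, position))
  expect_true(all(nd$nearest_distance > 0, na.rm = TRUE))
})

test_that("window burden counts unique alleles at distance 1..half_width", {
  sites <- tibble::tibble(accession = "P1", position = 60L,
                          residue_type = "K", detected = TRUE)
  variants <- toy_variants(c(58, 66, 60))
  w6 <- window_burden(sites, variants, half_width = 6)
  expect_equal(w6$n_alleles[w6$variant_class == "pathogenic"], 2L)
  w3 <- window_burden(sites, variants, half_width = 3)
  expect_equal(w3$n_alleles[w3$variant_class == "pathogenic"], 1L)
  # two alleles at one position are both counted; the overlap never is
  two_alt <- dplyr::bind_rows(
    toy_variants(58), dplyr::mutate(toy_variants(58), alt_aa = "Q"),
    toy_variants(60))
  w <- window_burden(sites, two_alt, half_width = 6)
  expect_equal(w$n_alleles[w$variant_class == "pathogenic"], 2L)
})

test_that("window counts are monotone in half-width", {
  b <- test_bundle()
  sites <- enumerate_sites(b$proteins, test_ingest()$cpdaa)
  sites <- sites[sites$accession %in% b$proteins$accession[1:15], ]
  v <- test_classified()
  key <- function(w) paste(w$accession, w$site_position, w$variant_class)
  w3 <- window_burden(sites, v, 3)
  w6 <- window_burden(sites, v, 6)
  w15 <- window_burden(sites, v, 15)
  expect_equal(key(w3), key(w6))
  expect_true(all(w3$n_alleles <= w6$n_alleles))
  expect_true(all(w6$n_alleles <= w15$n_alleles))
})

test_that("containment fraction agrees when recomputed from raw pairs", {
  b <- test_bundle()
  sites <- enumerate_sites(b$proteins, test_ingest()$cpdaa)
  v <- test_classified()
  w <- window_burden(sites, v, 6)
  wp <- w[w$variant_class == "pathogenic", ]
  frac_from_burdens <- mean(wp$contains)
  pairs <- linear_distances(sites, v[v$variant_class == "pathogenic", ])
  hit_keys <- unique(paste(pairs$accession, pairs$site_position)[
    pairs$distance >= 1 & pairs$distance <= 6])
  frac_from_pairs <- mean(paste(sites$accession, sites$position) %in%
                            hit_keys)
  expect_equal(frac_from_burdens, frac_from_pairs)
})

test_that("window enrichment reproduces the toy containment table", {
  burdens <- tibble::tibble(
    accession = "P1", site_position = 1:50, residue_type = "C",
    detected = c(rep(TRUE, 10), rep(FALSE, 40)),
    variant_class = "pathogenic",
    n_alleles = 0L,
    contains = c(rep(TRUE, 4), rep(FALSE, 6), rep(TRUE, 4),
                 rep(FALSE, 36)),
    half_width = 6)
  out <- window_enrichment(burdens, "pathogenic")
  cys <- out[out$residue_type == "C", ]
  expect_equal(unlist(cys[c("a", "b", "c", "d")], use.names = FALSE),
               c(4, 6, 4, 36))
  expect_equal(cys$odds_ratio, 6.0)
  # equal containment rates give an odds ratio of 1
  eq <- dplyr::mutate(burdens,
                      contains = rep(c(TRUE, FALSE), 25))
  out_eq <- window_enrichment(eq, "pathogenic")
  expect_equal(out_eq$odds_ratio[out_eq$residue_type == "C"], 1.0,
               tolerance = 0.2)
})

test_that("rank-sum distance comparison matches exact enumeration", {
  # 3-vs-3 with complete separation: two-sided exact p = 2 * 1/choose(6,3)
  sites <- tibble::tibble(
    accession = paste0("P", 1:6), position = 50L, residue_type = "C",
    detected = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  variants <- dplyr::bind_rows(lapply(1:6, function(i) {
    toy_variants(50 + c(1, 2, 3, 10, 11, 12)[i], acc = paste0("P", i))
  }))
  out <- distance_comparison(sites, variants, "pathogenic")
  cys <- out[out$residue_type == "C", ]
  expect_equal(cys$p_value, 0.1)
  expect_lt(cys$median_detected, cys$median_undetected)
})

test_that("planted proximity shortens detected-site distances", {
  b <- test_bundle()
  sites <- enumerate_sites(b$proteins, test_ingest()$cpdaa)
  out <- distance_comparison(sites, test_classified(), "pathogenic")
  pooled_med <- stats::weighted.mean(out$median_detected, out$n_detected) -
    stats::weighted.mean(out$median_undetected, out$n_undetected)
  expect_lt(pooled_med, 0)
})

test_that("zone enrichment estimates the planted odds multiplier", {
  b <- test_bundle()
  sites <- enumerate_sites(b$proteins, test_ingest()$cpdaa)
  res <- proximity_class_enrichment(sites, test_classified())
  expect_true(res$ci_low <= b$truth$planted_window_or)
  expect_true(res$ci_high >= b$truth$planted_window_or)
})
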