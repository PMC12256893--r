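# Exact 2x2 enrichment machinery and the gene-level comparison layer:
# set overlaps, phenotype-level distributions, constraint/composition and
# protein-protein-interaction comparisons.

#' Fisher's exact test with sample odds ratio and Woolf interval
#'
#' Two-sided p-value by the conditional hypergeometric rule (sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table). The odds ratio is the sample
#' cross-product `ad/bc`; when any cell is zero the Haldane-Anscombe
#' correction (+0.5 to every cell) is applied and flagged. The 95% CI is the
#' Woolf logit interval on the (possibly corrected) cells. The sample OR is
#' reported (rather than the conditional-MLE of [stats::fisher.test()])
#' because enrichment panels in this field are conventionally drawn with the
#' cross-product estimate.
#'
#' @param table 2x2 matrix of non-negative integer counts `rbind(c(a,b),
#'   c(c,d))`, where rows are the attribute and columns the grouping; OR > 1
#'   means the row-1 attribute is enriched in column-1.
#' @param conf_level Confidence level for the Woolf interval.
#' @return An object of class `enrichment_result`: a list with `table`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `zero_corrected`,
#'   `or_undefined` (a margin of the uncorrected table is zero),
#'   `p_adjusted` (initially `NA`), `family`, `family_size`.
#' @export
fisher_exact <- function(table, conf_level = 0.95) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2", call. = FALSE)
  if (any(table < 0) || any(table != round(table)) || any(!is.finite(table))) {
    stop("table cells must be non-negative integers", call. = FALSE)
  }
  if (sum(table) == 0) stop("all-zero table", call. = FALSE)
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  p <- fisher_p_two_sided(a, b, c, d)
  zero <- any(table == 0)
  cells <- if (zero) table + 0.5 else table
  or <- (cells[1, 1] * cells[2, 2]) / (cells[1, 2] * cells[2, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  structure(
    list(table = table, odds_ratio = or,
         ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
         p_value = p, zero_corrected = zero,
         or_undefined = any(rowSums(table) == 0) || any(colSums(table) == 0),
         p_adjusted = NA_real_, family = NA_character_,
         family_size = NA_integer_),
    class = "enrichment_result"
  )
}

#' Two-sided exact p-value of a 2x2 table
#'
#' Conditional hypergeometric two-sided p used by [fisher_exact()], exposed
#' for batch computations.
#'
#' @param a,b,c,d Cell counts, row-wise.
#' @return Two-sided p-value.
#' @export
fisher_p_two_sided <- function(a, b, c, d) {
  m <- a + c        # column-1 total
  n_ <- b + d       # column-2 total
  k <- a + b        # row-1 total
  if (m + n_ == 0) stop("all-zero table", call. = FALSE)
  support <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  # relative tolerance guards against ties lost to floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("2x2 enrichment:",
      sprintf("OR = %.4g [%.4g, %.4g], p = %.4g", x$odds_ratio,
              x$ci_low, x$ci_high, x$p_value), "\n")
  if (x$zero_corrected) cat("  (Haldane-Anscombe 0.5 correction applied)\n")
  if (!is.na(x$p_adjusted)) {
    cat(sprintf("  Bonferroni (family %s, size %d): p_adj = %.4g\n",
                x$family, x$family_size, x$p_adjusted))
  }
  invisible(x)
}

#' @export
as_tibble.enrichment_result <- function(x, ...) {
  tibble(a = x$table[1, 1], b = x$table[1, 2], c = x$table[2, 1],
         d = x$table[2, 2], odds_ratio = x$odds_ratio, ci_low = x$ci_low,
         ci_high = x$ci_high, p_value = x$p_value,
         zero_corrected = x$zero_corrected, or_undefined = x$or_undefined,
         p_adjusted = x$p_adjusted, family = x$family,
         family_size = x$family_size)
}

#' Bonferroni-adjust a family of enrichment results
#'
#' @param results List of `enrichment_result` objects or a tibble with a
#'   `p_value` column.
#' @param family Family label.
#' @param family_size Number of tests in the family; defaults to the number
#'   of results supplied.
#' @return Same shape as input with `p_adjusted`, `family`, `family_size`
#'   filled in (`p_adjusted = min(1, p * family_size)`).
#' @export
adjust_family <- function(results, family = "family",
                          family_size = NULL) {
  if (is.data.frame(results)) {
    family_size <- family_size %||% nrow(results)
    results$p_adjusted <- pmin(1, results$p_value * family_size)
    results$family <- family
    results$family_size <- family_size
    return(results)
  }
  family_size <- family_size %||% length(results)
  lapply(results, function(r) {
    r$p_adjusted <- min(1, r$p_value * family_size)
    r$family <- family
    r$family_size <- family_size
    r
  })
}

#' Three-set overlap summary
#'
#' All seven disjoint regions of a (up to) three-set Venn decomposition, plus
#' pairwise intersection sizes and the fraction of each set shared with each
#' other set.
#'
#' @param gene_sets Named list of 2 or 3 character vectors (normalised ids).
#' @return List with `regions` (disjoint region sizes), `pairwise` tibble
#'   (set_a, set_b, n_intersect, frac_of_a), and `union_size`.
#' @export
overlap_summary <- function(gene_sets) {
  stopifnot(is.list(gene_sets), length(gene_sets) %in% c(2, 3))
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be named", call. = FALSE)
  }
  sets <- lapply(gene_sets, unique)
  nm <- names(sets)
  if (length(sets) == 2) sets[["__empty__"]] <- character(0)
  A <- sets[[1]]; B <- sets[[2]]; C <- sets[[3]]
  inA <- function(x) x %in% A
  universe <- unique(c(A, B, C))
  memb <- cbind(universe %in% A, universe %in% B, universe %in% C)
  code <- memb[, 1] * 4 + memb[, 2] * 2 + memb[, 3]
  region_names <- c("100", "010", "001", "110", "101", "011", "111")
  region_codes <- c(4, 2, 1, 6, 5, 3, 7)
  regions <- setNames(vapply(region_codes,
                             function(cd) sum(code == cd), numeric(1)),
                      region_names)
  pairs <- utils::combn(seq_along(gene_sets), 2)
  pairwise <- dplyr::bind_rows(apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    n_int <- length(intersect(sets[[i]], sets[[j]]))
    tibble(set_a = nm[i], set_b = nm[j], n_a = length(sets[[i]]),
           n_b = length(sets[[j]]), n_intersect = n_int,
           frac_of_a = if (length(sets[[i]]) > 0)
             n_int / length(sets[[i]]) else NA_real_,
           frac_of_b = if (length(sets[[j]]) > 0)
             n_int / length(sets[[j]]) else NA_real_)
  }))
  list(regions = regions, pairwise = pairwise,
       union_size = length(universe))
}

#' Distribution of genes over phenotype-count levels
#'
#' Bins genes of a set by their count of monogenic-disorder phenotypes into
#' five levels (default 1, 2, 3, 4, >=5) and reports the fraction of a
#' stated reference universe that each level represents.
#'
#' @param annotations Gene annotation tibble with `gene_id`,
#'   `omim_phenotype_count`.
#' @param gene_set Character vector of gene ids.
#' @param breaks Lower bounds of the first four levels; counts at or above
#'   the last break + 1 form level five.
#' @param reference_n Denominator for fractions; defaults to the set size.
#' @return Tibble with `level`, `n`, `fraction`.
#' @export
phenotype_level_distribution <- function(annotations, gene_set,
                                         breaks = c(1, 2, 3, 4),
                                         reference_n = NULL) {
  assert_columns(annotations, c("gene_id", "omim_phenotype_count"))
  counts <- annotations$omim_phenotype_count[
    annotations$gene_id %in% gene_set]
  counts <- counts[!is.na(counts) & counts >= 1]
  reference_n <- reference_n %||% length(gene_set)
  labels <- c(as.character(breaks), paste0(">=", breaks[length(breaks)] + 1))
  level <- cut(counts, c(breaks - 0.5, breaks[length(breaks)] + 0.5, Inf),
               labels = labels)
  n <- as.numeric(table(level))
  tibble(level = labels, n = n,
         fraction = if (reference_n > 0) n / reference_n else 0 * n)
}

#' Compare phenotype counts between two gene sets
#'
#' Two-sided rank-sum comparison of per-gene phenotype counts.
#'
#' @inheritParams phenotype_level_distribution
#' @param set_a,set_b Character vectors of gene ids.
#' @return Tibble with means, medians, and the rank-sum p-value.
#' @export
phenotype_level_compare <- function(annotations, set_a, set_b) {
  assert_columns(annotations, c("gene_id", "omim_phenotype_count"))
  xa <- annotations$omim_phenotype_count[annotations$gene_id %in% set_a]
  xb <- annotations$omim_phenotype_count[annotations$gene_id %in% set_b]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
  tibble(mean_a = mean(xa), mean_b = mean(xb),
         median_a = median(xa), median_b = median(xb), p_value = p)
}

#' Gene-set attribute enrichment over an explicit universe
#'
#' 2x2 test of membership in a target set against possession of an attribute
#' over a stated universe; the universe is always an explicit input, never
#' inferred from the union of the sets.
#'
#' @param target_set,attribute_set Character vectors, subsets of `universe`.
#' @param universe Character vector defining the tested population.
#' @param family,family_size Bonferroni family annotation (e.g. the number
#'   of gene sets in a forest-plot panel).
#' @return An `enrichment_result` (table rows: in/out of target; columns:
#'   with/without attribute).
#' @export
set_enrichment <- function(target_set, attribute_set, universe,
                           family = "set_enrichment", family_size = 1) {
  target_set <- unique(target_set)
  attribute_set <- unique(attribute_set)
  universe <- unique(universe)
  if (!all(target_set %in% universe)) {
    stop("target_set is not a subset of universe", call. = FALSE)
  }
  attribute_set <- intersect(attribute_set, universe)
  a <- length(intersect(target_set, attribute_set))
  b <- length(target_set) - a
  c_ <- length(attribute_set) - a
  d <- length(universe) - length(target_set) - c_
  res <- fisher_exact(rbind(c(a, b), c(c_, d)))
  res$p_adjusted <- min(1, res$p_value * family_size)
  res$family <- family
  res$family_size <- as.integer(family_size)
  res
}

#' Per-amino-acid composition comparison between protein sets
#'
#' Protein length is corrected for by working on per-protein composition
#' fractions (residue count / length); each amino acid is compared between
#' the two sets with a two-sided rank-sum test, adjusted across the 20
#' features.
#'
#' @param proteins Protein table with `accession`, `sequence`, `length`.
#' @param set_a,set_b Character vectors of accessions.
#' @param adjust Multiple-testing method passed to [stats::p.adjust()].
#' @return Tibble with per-amino-acid mean fractions, direction, `p_value`
#'   and `p_adjusted`.
#' @export
composition_comparison <- function(proteins, set_a, set_b,
                                   adjust = "bonferroni") {
  assert_columns(proteins, c("accession", "sequence", "length"))
  frac <- function(accs) {
    seqs <- proteins$sequence[proteins$accession %in% accs]
    lens <- nchar(seqs)
    sapply(AA_LETTERS, function(aa) {
      stringr::str_count(seqs, stringr::fixed(aa)) / lens
    }, simplify = FALSE)
  }
  fa <- frac(set_a); fb <- frac(set_b)
  rows <- lapply(AA_LETTERS, function(aa) {
    xa <- fa[[aa]]; xb <- fb[[aa]]
    p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
    tibble(aa = aa, mean_frac_a = mean(xa), mean_frac_b = mean(xb),
           direction = dplyr::case_when(
             mean(xa) > mean(xb) ~ "enriched_in_a",
             mean(xa) < mean(xb) ~ "depleted_in_a",
             TRUE ~ "equal"),
           p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out
}

#' Compare protein-protein-interaction counts between two sets
#'
#' @param annotations Gene annotation tibble with `gene_id`, `ppi_count`.
#' @param set_a,set_b Character vectors of gene ids.
#' @return Tibble with medians and a two-sided rank-sum p-value.
#' @export
ppi_comparison <- function(annotations, set_a, set_b) {
  assert_columns(annotations, c("gene_id", "ppi_count"))
  xa <- annotations$ppi_count[annotations$gene_id %in% set_a]
  xb <- annotations$ppi_count[annotations$gene_id %in% set_b]
  xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
  p <- suppressWarnings(wilcox.test(xa, xb)$p.value)
  tibble(median_a = median(xa), median_b = median(xb),
         n_a = length(xa), n_b = length(xb),
         greater_set = dplyr::case_when(
           median(xa) > median(xb) ~ "a",
           median(xa) < median(xb) ~ "b",
           TRUE ~ "tie"),
         p_value = p)
}
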