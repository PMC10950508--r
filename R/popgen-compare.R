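## Cross-population comparison. Allele-frequency differences are tested
## per variant with a two-sided Fisher exact test on the 2x2 alt/ref x
## population allele-count table (minimum-likelihood rule: sum of
## hypergeometric point probabilities no larger than the observed one,
## with a 1e-7 relative tolerance for ties). Population differentiation
## is the Weir & Cockerham (1984) Fst with ratio-of-sums ("weighted")
## aggregation across sites, the estimator behind PLINK's --fst. Negative
## per-site components are kept as computed; sites monomorphic across
## both populations are excluded.

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Wraps the exact conditional test on fixed margins. A table with a zero
#' margin carries no information about association; by convention it gets
#' p = 1 (logged).
#'
#' @param table 2x2 non-negative integer matrix (allele count x
#'   population).
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    log_info("fisher_exact_2x2: zero margin, p = 1 by convention")
    return(1)
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Compare allele frequencies between two populations
#'
#' For every allele shared by the two frequency tables, builds the 2x2
#' table (alt_count, ref_count) x population and tests it with
#' [fisher_exact_2x2()]. Alleles present in only one table are reported
#' as unmatched and skipped.
#'
#' @param af_table_a,af_table_b allele-frequency tables (see
#'   [allele_frequencies()]); counts must be integral.
#' @param alpha significance threshold on the raw p-value (the pipeline's
#'   convention is a bare p < alpha with no multiplicity correction).
#' @param p_adjust if `TRUE`, apply Benjamini-Hochberg and flag on the
#'   adjusted values instead.
#' @return data frame sorted by `allele_id`: `allele_id`, `pop_a`,
#'   `pop_b`, `alt_a`, `ref_a`, `alt_b`, `ref_b`, `af_a`, `af_b`,
#'   `p_value`, `significant`. Attribute `"unmatched"` lists skipped
#'   allele ids.
#' @export
compare_allele_frequencies <- function(af_table_a, af_table_b,
                                       alpha = 0.05, p_adjust = FALSE) {
  shared <- intersect(af_table_a$allele_id, af_table_b$allele_id)
  unmatched <- c(setdiff(af_table_a$allele_id, shared),
                 setdiff(af_table_b$allele_id, shared))
  if (length(unmatched)) {
    log_info("compare_allele_frequencies: ", length(unmatched),
             " allele(s) present in only one table, skipped")
  }
  shared <- sort(shared)
  ia <- match(shared, af_table_a$allele_id)
  ib <- match(shared, af_table_b$allele_id)
  alt_a <- af_table_a$alt_count[ia]
  ref_a <- af_table_a$total_count[ia] - alt_a
  alt_b <- af_table_b$alt_count[ib]
  ref_b <- af_table_b$total_count[ib] - alt_b
  p <- vapply(seq_along(shared), function(i) {
    fisher_exact_2x2(matrix(c(alt_a[i], ref_a[i], alt_b[i], ref_b[i]), 2L))
  }, numeric(1))
  p_flag <- if (p_adjust) stats::p.adjust(p, method = "BH") else p
  out <- data.frame(allele_id = shared,
                    pop_a = af_table_a$population[ia],
                    pop_b = af_table_b$population[ib],
                    alt_a = alt_a, ref_a = ref_a,
                    alt_b = alt_b, ref_b = ref_b,
                    af_a = af_table_a$af[ia], af_b = af_table_b$af[ib],
                    p_value = p, significant = p_flag < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "unmatched") <- unmatched
  out
}

#' Weir-Cockerham (1984) variance components for one biallelic site
#'
#' Two-population case. Inputs are per-population observed (non-missing)
#' diploid sample sizes, alt-allele counts and heterozygote counts. The
#' returned components partition the allelic variance: `a` among
#' populations, `b` among individuals within populations, `c` within
#' individuals; each may be negative. The per-site Fst estimate is
#' `a / (a + b + c)`.
#'
#' @param alt_count_a,alt_count_b alt-allele counts (0..2n).
#' @param het_count_a,het_count_b heterozygous-individual counts.
#' @param n_a,n_b observed diploid sample sizes (>= 1 each, n_a + n_b > 2).
#' @return named numeric vector `c(a = , b = , c = )`.
#' @export
wc_fst_components <- function(alt_count_a, het_count_a, n_a,
                              alt_count_b, het_count_b, n_b) {
  stopifnot(n_a >= 1, n_b >= 1,
            alt_count_a <= 2 * n_a, alt_count_b <= 2 * n_b,
            het_count_a <= n_a, het_count_b <= n_b)
  r <- 2
  p_a <- alt_count_a / (2 * n_a)
  p_b <- alt_count_b / (2 * n_b)
  h_a <- het_count_a / n_a
  h_b <- het_count_b / n_b
  n_bar <- (n_a + n_b) / r
  if (n_bar <= 1) stop("Weir-Cockerham components need n_bar > 1",
                       call. = FALSE)
  n_c <- (r * n_bar - (n_a^2 + n_b^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n_a * p_a + n_b * p_b) / (r * n_bar)
  s2 <- (n_a * (p_a - p_bar)^2 + n_b * (p_b - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n_a * h_a + n_b * h_b) / (r * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) /
       (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
       (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  c(a = a, b = b, c = cc)
}

## Per-variant observed counts needed by the estimator.
site_counts <- function(cohort) {
  d <- cohort$dosage
  list(n = colSums(!is.na(d)),
       alt = colSums(d, na.rm = TRUE),
       het = colSums(d == 1L, na.rm = TRUE))
}

#' Weighted Weir-Cockerham Fst between two cohorts
#'
#' Components are computed per shared variant and aggregated as a ratio
#' of sums, `sum(a) / sum(a + b + c)` (the "weighted" Fst); the unweighted
#' average of per-site ratios is also reported. Sites monomorphic across
#' both populations, and sites without at least one observed genotype in
#' each population, are excluded with a logged count. The result is
#' symmetric in the two cohorts.
#'
#' @param cohort_a,cohort_b [cohort_genotypes] objects sharing variants.
#' @param variant_subset optional character vector of variant ids to
#'   restrict to.
#' @return list of class `"fst_result"`: `pop_a`, `pop_b`,
#'   `n_variants_used`, `weighted_fst`, `mean_fst`, `components` (data
#'   frame `allele_id`, `a`, `b`, `c`, `fst`).
#' @export
weighted_fst <- function(cohort_a, cohort_b, variant_subset = NULL) {
  ids_a <- variant_ids(cohort_a$variants)
  ids_b <- variant_ids(cohort_b$variants)
  shared <- intersect(ids_a, ids_b)
  if (!is.null(variant_subset)) shared <- intersect(shared, variant_subset)
  if (length(shared) == 0) {
    stop("no shared variants between cohorts '", cohort_a$population,
         "' and '", cohort_b$population, "'",
         if (!is.null(variant_subset)) " after subsetting" else "",
         call. = FALSE)
  }
  sa <- site_counts(subset_cohort(cohort_a, variants = shared))
  sb <- site_counts(subset_cohort(cohort_b, variants = shared))
  ok_n <- sa$n >= 1 & sb$n >= 1 & (sa$n + sb$n) > 2
  pooled_alt <- sa$alt + sb$alt
  pooled_tot <- 2 * (sa$n + sb$n)
  poly <- pooled_alt > 0 & pooled_alt < pooled_tot
  keep <- ok_n & poly
  n_mono <- sum(ok_n & !poly)
  if (n_mono) {
    log_info("weighted_fst: excluded ", n_mono,
             " site(s) monomorphic across both populations")
  }
  if (any(!ok_n)) {
    log_info("weighted_fst: excluded ", sum(!ok_n),
             " site(s) with insufficient observed genotypes")
  }
  if (!any(keep)) {
    stop("weighted_fst: zero retained variants (all monomorphic or ",
         "unobserved)", call. = FALSE)
  }
  comp <- vapply(which(keep), function(i) {
    wc_fst_components(sa$alt[i], sa$het[i], sa$n[i],
                      sb$alt[i], sb$het[i], sb$n[i])
  }, numeric(3))
  a <- comp[1, ]; b <- comp[2, ]; cc <- comp[3, ]
  denom <- a + b + cc
  per_site <- ifelse(denom != 0, a / denom, NA_real_)
  structure(list(
    pop_a = cohort_a$population, pop_b = cohort_b$population,
    n_variants_used = sum(keep),
    weighted_fst = sum(a) / sum(denom),
    mean_fst = mean(per_site, na.rm = TRUE),
    components = data.frame(allele_id = shared[keep], a = a, b = b,
                            c = cc, fst = per_site,
                            stringsAsFactors = FALSE, row.names = NULL)),
    class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("fst_result: %s vs %s, %d variants, weighted Fst = %.4f (mean %.4f)\n",
              x$pop_a, x$pop_b, x$n_variants_used, x$weighted_fst,
              x$mean_fst))
  invisible(x)
}

#' Pairwise weighted-Fst matrix over several cohorts
#'
#' @param cohorts named list of [cohort_genotypes] (>= 2).
#' @param variant_subset optional variant-id restriction.
#' @return list: `matrix` (symmetric, zero diagonal, labelled by
#'   population) and `pairs` (long-format data frame `pop_a`, `pop_b`,
#'   `n_variants_used`, `weighted_fst`, `mean_fst`).
#' @export
fst_matrix <- function(cohorts, variant_subset = NULL) {
  stopifnot(length(cohorts) >= 2)
  pops <- unname(vapply(cohorts, function(x) x$population, character(1)))
  k <- length(cohorts)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  pairs <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq.int(i + 1, k)) {
      r <- weighted_fst(cohorts[[i]], cohorts[[j]], variant_subset)
      m[i, j] <- m[j, i] <- r$weighted_fst
      pairs[[length(pairs) + 1L]] <- data.frame(
        pop_a = pops[i], pop_b = pops[j],
        n_variants_used = r$n_variants_used,
        weighted_fst = r$weighted_fst, mean_fst = r$mean_fst,
        stringsAsFactors = FALSE)
    }
  }
  list(matrix = m, pairs = do.call(rbind, pairs))
}
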