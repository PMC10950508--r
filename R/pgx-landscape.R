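## Per-drug risk-variant landscape: for every drug, the distribution over
## cohort individuals of the number of annotated risk variants/alleles
## carried, summarised as median, range, quartiles and carrier fraction.
## Counting is carrier-based: a variant counts once whether the sample
## carries one or two risk alleles ("carry at least one risk variant");
## allele-dosage weighting is available behind `dosage_weighted`.

#' Per-sample carrier status for one annotation
#'
#' A sample carries a SNP annotation if its dosage of the risk allele is
#' at least 1 (missing genotype counts as non-carrier and is logged by the
#' caller); it carries a star/HLA annotation if either diplotype allele
#' equals the risk allele.
#'
#' @param annotation one row of a `clinical_annotations` table.
#' @param cohort a [cohort_genotypes].
#' @param diplotypes optional `diplotype_calls` table.
#' @return named logical vector over cohort samples, or `NULL` if the
#'   annotation is unresolvable (caller records it as unmatched).
#' @export
carrier_status <- function(annotation, cohort, diplotypes = NULL) {
  samples <- cohort$samples
  if (annotation$allele_type == "snp") {
    vi <- match(annotation$allele_id, variant_ids(cohort$variants))
    if (is.na(vi)) return(NULL)
    dos <- cohort$dosage[, vi]
    # risk allele may be the alt (dosage counts it) or the ref base
    risk_is_alt <- annotation$risk_allele == cohort$variants$alt[vi]
    risk_is_ref <- annotation$risk_allele == cohort$variants$ref[vi]
    if (!risk_is_alt && !risk_is_ref) return(NULL)
    st <- if (risk_is_alt) dos >= 1L else dos <= 1L
    st[is.na(dos)] <- FALSE
    stats::setNames(st, samples)
  } else {
    if (is.null(diplotypes)) return(NULL)
    sub <- diplotypes[diplotypes$gene == annotation$gene, , drop = FALSE]
    m <- match(samples, sub$sample_id)
    if (all(is.na(m))) return(NULL)
    st <- !is.na(m) & (sub$allele1[m] == annotation$risk_allele |
                         sub$allele2[m] == annotation$risk_allele)
    st[is.na(st)] <- FALSE
    stats::setNames(st, samples)
  }
}

#' Count annotated risk variants carried, per sample
#'
#' @param cohort a [cohort_genotypes].
#' @param annotations `clinical_annotations` rows, all for one drug.
#' @param diplotypes optional `diplotype_calls`.
#' @param dosage_weighted if `TRUE`, a homozygous risk SNP genotype counts
#'   2 instead of 1 (default `FALSE`, carrier-based).
#' @return list: `counts` (named integer vector over samples),
#'   `unmatched` (character vector of annotation ids that could not be
#'   resolved against the cohort/diplotypes, excluded from counting),
#'   `n_missing_genotypes` (missing-GT observations treated as
#'   non-carrier).
#' @export
count_risk_variants <- function(cohort, annotations, diplotypes = NULL,
                                dosage_weighted = FALSE) {
  counts <- stats::setNames(integer(length(cohort$samples)),
                            cohort$samples)
  unmatched <- character(0)
  n_missing <- 0L
  for (i in seq_len(nrow(annotations))) {
    ann <- annotations[i, , drop = FALSE]
    st <- carrier_status(ann, cohort, diplotypes)
    if (is.null(st)) {
      unmatched <- c(unmatched, ann$allele_id)
      next
    }
    if (ann$allele_type == "snp") {
      vi <- match(ann$allele_id, variant_ids(cohort$variants))
      n_missing <- n_missing + sum(is.na(cohort$dosage[, vi]))
      if (dosage_weighted) {
        dos <- cohort$dosage[, vi]
        risk_dos <- if (ann$risk_allele == cohort$variants$alt[vi]) dos
                    else 2L - dos
        risk_dos[is.na(risk_dos)] <- 0L
        counts <- counts + risk_dos
        next
      }
    }
    counts <- counts + as.integer(st)
  }
  if (length(unmatched)) {
    log_warn("count_risk_variants: ", length(unmatched),
             " unresolvable annotation(s) excluded: ",
             paste(utils::head(unique(unmatched), 5), collapse = ", "))
  }
  if (n_missing) {
    log_info("count_risk_variants: ", n_missing,
             " missing genotype observation(s) treated as non-carrier")
  }
  list(counts = counts, unmatched = unmatched,
       n_missing_genotypes = n_missing)
}

## Median with 0.5 resolution (midpoint for even n) and quartiles by the
## midpoint-exclusive (Moore-McCabe) rule: split the sorted data at the
## median, drop the middle observation when n is odd, and take the medians
## of the halves. This yields the half-integer medians typical of count
## data and keeps quartiles at observed values or midpoints.
midpoint_median <- function(x) {
  x <- sort(unname(x))
  n <- length(x)
  if (n %% 2L == 1L) as.numeric(x[(n + 1L) / 2L])
  else (x[n / 2L] + x[n / 2L + 1L]) / 2
}

exclusive_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(c(q1 = as.numeric(x), q3 = as.numeric(x)))
  lower <- x[seq_len(floor(n / 2))]
  upper <- x[seq.int(ceiling(n / 2) + 1L, n)]
  c(q1 = midpoint_median(lower), q3 = midpoint_median(upper))
}

#' Summarise one drug's per-sample risk-variant counts
#'
#' @param drug drug name.
#' @param counts integer vector of per-sample counts (non-empty).
#' @param n_annotations number of annotations behind the counts.
#' @return one-row data frame: `drug`, `n_annotations`, `median`, `min`,
#'   `max`, `q1`, `q3`, `carrier_fraction` (share of samples with count
#'   >= 1).
#' @export
summarize_drug <- function(drug, counts, n_annotations = NA_integer_) {
  if (length(counts) == 0) stop("empty cohort: no counts to summarise",
                                call. = FALSE)
  q <- exclusive_quartiles(counts)
  data.frame(drug = drug, n_annotations = as.integer(n_annotations),
             median = midpoint_median(counts),
             min = as.integer(min(counts)), max = as.integer(max(counts)),
             q1 = q[["q1"]], q3 = q[["q3"]],
             carrier_fraction = mean(counts >= 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pharmacogenomic landscape over a drug list
#'
#' One [summarize_drug()] row per drug with at least one annotation
#' passing the evidence-level filter; drugs with none are returned
#' separately as the no-information list. The level filter is an explicit
#' parameter: `NULL` means all levels.
#'
#' @param cohort a [cohort_genotypes].
#' @param annotations a `clinical_annotations` table (any drugs).
#' @param drugs a `drug_list`.
#' @param diplotypes optional `diplotype_calls`.
#' @param level_filter optional character subset of
#'   `c("1A","1B","2A","2B","3","4")`.
#' @param dosage_weighted see [count_risk_variants()].
#' @return list: `summary` (data frame, one row per drug with
#'   annotations), `no_information` (character vector of drugs without
#'   any passing annotation), `per_sample_counts` (matrix samples x
#'   summarised drugs), `unmatched` (named list per drug).
#' @export
landscape_table <- function(cohort, annotations, drugs, diplotypes = NULL,
                            level_filter = NULL, dosage_weighted = FALSE) {
  if (!is.null(level_filter)) {
    check_vocab(level_filter, annotation_levels(), "evidence level")
    annotations <- annotations[annotations$level %in% level_filter, ,
                               drop = FALSE]
  }
  rows <- list()
  no_info <- character(0)
  unmatched <- list()
  count_mat <- matrix(0L, nrow = length(cohort$samples), ncol = 0,
                      dimnames = list(cohort$samples, NULL))
  for (d in drugs$name) {
    sub <- annotations[annotations$drug == d, , drop = FALSE]
    if (nrow(sub) == 0) {
      no_info <- c(no_info, d)
      next
    }
    cr <- count_risk_variants(cohort, sub, diplotypes, dosage_weighted)
    rows[[d]] <- summarize_drug(d, cr$counts, nrow(sub))
    if (length(cr$unmatched)) unmatched[[d]] <- cr$unmatched
    count_mat <- cbind(count_mat, cr$counts)
    colnames(count_mat)[ncol(count_mat)] <- d
  }
  summary <- if (length(rows)) do.call(rbind, rows) else {
    summarize_drug("x", 0L)[0, ]
  }
  rownames(summary) <- NULL
  list(summary = summary, no_information = no_info,
       per_sample_counts = count_mat, unmatched = unmatched)
}
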