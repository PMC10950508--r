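## Cohort genotypes: a diploid alt-allele dosage matrix (samples x biallelic
## SNVs) with a population label, read from VCF 4.x (GT field), plus allele
## frequency tables for SNPs and for star/HLA alleles from diplotype calls.

#' Construct a cohort genotype container
#'
#' @param population population label.
#' @param samples character vector of sample ids.
#' @param variants data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `rsid` describing biallelic SNVs (1-based coordinates).
#' @param dosage integer matrix (samples x variants) of alt-allele counts in
#'   `{0, 1, 2, NA}`; `NA` is the missing-genotype sentinel.
#' @return object of class `"cohort_genotypes"`.
#' @export
cohort_genotypes <- function(population, samples, variants, dosage) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(is.matrix(dosage),
            nrow(dosage) == length(samples),
            ncol(dosage) == nrow(variants))
  if (nrow(variants) > 0) {
    if (any(variants$ref == variants$alt)) {
      stop("ref and alt alleles must differ", call. = FALSE)
    }
    if (any(variants$pos < 1)) stop("positions are 1-based", call. = FALSE)
  }
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  storage.mode(dosage) <- "integer"
  dimnames(dosage) <- list(samples, variant_ids(variants))
  structure(list(population = population, samples = samples,
                 variants = variants, dosage = dosage),
            class = "cohort_genotypes")
}

variant_ids <- function(variants) {
  ifelse(!is.na(variants$rsid) & nzchar(variants$rsid), variants$rsid,
         paste0(variants$chrom, ":", variants$pos, ":", variants$ref, ">",
                variants$alt))
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat("cohort_genotypes: population '", x$population, "', ",
      length(x$samples), " samples x ", nrow(x$variants), " variants (",
      sum(is.na(x$dosage)), " missing genotypes)\n", sep = "")
  invisible(x)
}

#' Subset a cohort by samples and/or variants
#'
#' @param cohort a `cohort_genotypes`.
#' @param samples sample ids to keep (default all).
#' @param variants variant ids (rsid or `chrom:pos:ref>alt`) to keep.
#' @return the subsetted `cohort_genotypes`.
#' @export
subset_cohort <- function(cohort, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(cohort$samples) else {
    m <- match(samples, cohort$samples)
    if (anyNA(m)) stop("unknown sample id(s): ",
                       paste(samples[is.na(m)], collapse = ", "),
                       call. = FALSE)
    m
  }
  vi <- if (is.null(variants)) seq_len(nrow(cohort$variants)) else {
    m <- match(variants, variant_ids(cohort$variants))
    if (anyNA(m)) stop("unknown variant id(s): ",
                       paste(variants[is.na(m)], collapse = ", "),
                       call. = FALSE)
    m
  }
  cohort_genotypes(cohort$population, cohort$samples[si],
                   cohort$variants[vi, , drop = FALSE],
                   cohort$dosage[si, vi, drop = FALSE])
}

#' Read cohort genotypes from a VCF file
#'
#' Loads biallelic SNVs from a VCF 4.x file into an alt-allele dosage
#' matrix. Multiallelic records, indels and (by default) mitochondrial
#' variants are skipped with a logged count; missing genotypes (`./.`)
#' become the `NA` sentinel and are excluded from downstream allele
#' counts. Phase is ignored: a GT is read as an unordered allele pair.
#'
#' @param path VCF file (plain or bgzipped).
#' @param population population label to attach (default `"cohort"`).
#' @param variant_subset optional character vector of rsIDs or
#'   `chrom:pos:ref>alt` keys to restrict to; requested variants absent
#'   from the file are reported in a log summary, not an error.
#' @param exclude_mt drop chrM/MT records (default `TRUE`), mirroring the
#'   exclusion of mtDNA variants absent from population reference panels.
#' @return a [cohort_genotypes] object.
#' @export
read_vcf <- function(path, population = "cohort", variant_subset = NULL,
                     exclude_mt = TRUE) {
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("malformed VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0) stop("VCF contains no records: ", path, call. = FALSE)
  is_snv <- grepl("^[ACGT]$", fix$REF) & grepl("^[ACGT]$", fix$ALT)
  is_mt <- fix$CHROM %in% c("chrM", "chrMT", "MT", "M")
  keep <- is_snv & (!exclude_mt | !is_mt)
  n_skip <- sum(!is_snv)
  if (n_skip) log_info("read_vcf: skipped ", n_skip,
                       " multiallelic/indel record(s)")
  n_mt <- sum(is_snv & is_mt & exclude_mt)
  if (n_mt) log_info("read_vcf: excluded ", n_mt, " mtDNA record(s)")
  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         rsid = ifelse(is.na(fix$ID[keep]) |
                                         fix$ID[keep] == ".", NA_character_,
                                       fix$ID[keep]),
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  # unordered diploid GT -> dosage; any missing allele -> NA
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- ifelse(a1 %in% c("0", "1") & a2 %in% c("0", "1"),
                (a1 == "1") + (a2 == "1"), NA_integer_)
  dos <- matrix(as.integer(dos), nrow = nrow(gt), ncol = ncol(gt))
  cohort <- cohort_genotypes(population, samples, variants, t(dos))
  if (!is.null(variant_subset)) {
    ids <- variant_ids(cohort$variants)
    found <- intersect(variant_subset, ids)
    absent <- setdiff(variant_subset, ids)
    if (length(absent)) {
      log_info("read_vcf: ", length(absent),
               " requested variant(s) absent from the file: ",
               paste(utils::head(absent, 5), collapse = ", "),
               if (length(absent) > 5) ", ..." else "")
    }
    cohort <- subset_cohort(cohort, variants = found)
  }
  cohort
}

#' Write cohort genotypes as plain-text VCF 4.2
#'
#' Emits a minimal, byte-stable VCF (GT-only FORMAT, unphased genotypes)
#' so that simulated cohorts round-trip through [read_vcf()].
#'
#' @param cohort a `cohort_genotypes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  v <- cohort$variants
  gt_chr <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  d <- t(cohort$dosage)                      # variants x samples
  gt <- matrix(gt_chr[as.character(d)], nrow = nrow(d))
  gt[is.na(gt)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=pgxddi",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$samples), collapse = "\t"))
  id <- ifelse(is.na(v$rsid), ".", v$rsid)
  body <- paste(v$chrom, v$pos, id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (nrow(v) == 0) body <- character(0)
  writeLines(c(header, body), path, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' @param path TSV with columns `sample_id`, `population`.
#' @return data frame.
#' @export
read_population_map <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("sample_id", "population") %in% names(df))) {
    stop("population map must have columns sample_id, population",
         call. = FALSE)
  }
  df[, c("sample_id", "population")]
}

#' Split one cohort into per-population cohorts
#'
#' @param cohort a `cohort_genotypes`.
#' @param pop_map data frame from [read_population_map()].
#' @return named list of `cohort_genotypes`, one per population.
#' @export
split_cohort <- function(cohort, pop_map) {
  m <- match(cohort$samples, pop_map$sample_id)
  if (anyNA(m)) {
    stop("sample(s) missing from population map: ",
         paste(cohort$samples[is.na(m)][1:min(5, sum(is.na(m)))],
               collapse = ", "), call. = FALSE)
  }
  pops <- pop_map$population[m]
  out <- lapply(unique(pops), function(p) {
    sub <- subset_cohort(cohort, samples = cohort$samples[pops == p])
    sub$population <- p
    sub
  })
  names(out) <- unique(pops)
  out
}

#' Allele frequencies of a cohort
#'
#' One row per variant with alt-allele count, total allele count and
#' frequency. Missing genotypes are excluded from both numerator and
#' denominator, so `total_count = 2 x` (non-missing diploid individuals).
#' A variant with all genotypes missing gets `total_count = 0` and `NA`
#' frequency, and is flagged in the log.
#'
#' @param cohort a `cohort_genotypes`.
#' @return data frame with columns `allele_id`, `population`, `alt_count`,
#'   `total_count`, `af`.
#' @export
allele_frequencies <- function(cohort) {
  d <- cohort$dosage
  alt <- colSums(d, na.rm = TRUE)
  tot <- 2L * colSums(!is.na(d))
  if (any(tot == 0)) {
    log_warn("allele_frequencies: ", sum(tot == 0),
             " variant(s) with all genotypes missing (af undefined)")
  }
  data.frame(allele_id = variant_ids(cohort$variants),
             population = cohort$population,
             alt_count = as.integer(alt), total_count = as.integer(tot),
             af = ifelse(tot > 0, alt / tot, NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Allele frequencies from diplotype calls
#'
#' Each individual contributes two allele observations per gene, so the
#' frequency of a named allele is its call count over `2N`. Alleles listed
#' in `allele_universe` but absent from the calls get an explicit zero row.
#'
#' @param calls a `diplotype_calls` table covering every sample exactly
#'   once per gene.
#' @param allele_universe optional character vector of allele names to
#'   report (zero rows emitted for unobserved alleles).
#' @param population population label for the output rows.
#' @return data frame in the same shape as [allele_frequencies()].
#' @export
diplotype_frequencies <- function(calls, allele_universe = NULL,
                                  population = "cohort") {
  out <- lapply(split(calls, calls$gene), function(g) {
    key <- paste(g$sample_id, g$gene)
    if (anyDuplicated(key)) {
      stop("sample '", g$sample_id[which(duplicated(key))[1L]],
           "' has more than one call for gene ", g$gene[1L], call. = FALSE)
    }
    obs <- c(g$allele1, g$allele2)
    # universe entries belong to a gene via their name prefix, e.g.
    # "CYP2C19*2" or "HLA-B*15:02" for genes CYP2C19 / HLA-B
    uni_g <- (allele_universe %||% character(0))
    uni_g <- uni_g[startsWith(toupper(uni_g), paste0(g$gene[1L], "*"))]
    alleles <- sort(unique(c(obs, uni_g)))
    cnt <- vapply(alleles, function(a) sum(obs == a), integer(1))
    data.frame(allele_id = alleles, population = population,
               alt_count = as.integer(cnt),
               total_count = 2L * nrow(g),
               af = cnt / (2L * nrow(g)),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
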