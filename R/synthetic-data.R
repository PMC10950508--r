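## Synthetic inputs with known ground truth. The genotype generator uses
## the Balding-Nichols model: an ancestral allele frequency p per variant,
## population frequencies drawn from a Beta with mean p and variance
## p(1-p)F, genotypes Binomial(2, population frequency). The expected
## Weir-Cockerham Fst between two such populations is approximately F,
## which gives the estimator a closed-form recovery target. CTET catalogs
## are random role-typed bipartite assignments with optional planted
## drug-pair overlaps; the true DDI pair set is recomputed from the
## emitted catalog by brute-force set intersection, never assumed.

#' Simulate multi-population cohort genotypes (Balding-Nichols)
#'
#' @param n_variants number of biallelic SNVs.
#' @param pop_sizes named integer vector of diploid sample counts per
#'   population (names become population labels; unnamed vectors get
#'   `pop1`, `pop2`, ...).
#' @param F divergence parameter in `[0, 1)`; `F = 0` gives identical
#'   population frequencies (no drift). Either a single value shared by
#'   all populations or one value per population, in which case each
#'   population drifts from the common ancestor with its own F and the
#'   expected pairwise Fst is approximately the mean of the two F values.
#' @param ancestral_af_law function `n -> n` ancestral frequencies in
#'   `(0, 1)`; default uniform on `[0.05, 0.95]`, bounded away from the
#'   edges so monomorphic sites do not dominate.
#' @param seed integer seed; all randomness flows from it.
#' @return list with `cohorts` (named list of [cohort_genotypes]) and
#'   `truth` (list: `true_afs` matrix variants x populations,
#'   `ancestral_af`, `divergence_F`, `seed`, `n_resampled` count of
#'   monomorphic redraws).
#' @export
simulate_populations <- function(n_variants, pop_sizes, F = 0,
                                 ancestral_af_law = NULL, seed = 1) {
  if (any(F < 0) || any(F >= 1)) stop("F must be in [0, 1)", call. = FALSE)
  if (any(pop_sizes < 2)) stop("each population needs >= 2 samples",
                               call. = FALSE)
  if (!length(F) %in% c(1L, length(pop_sizes))) {
    stop("F must have length 1 or one value per population",
         call. = FALSE)
  }
  if (is.null(names(pop_sizes))) {
    names(pop_sizes) <- paste0("pop", seq_along(pop_sizes))
  }
  F <- rep_len(F, length(pop_sizes))
  if (is.null(ancestral_af_law)) {
    ancestral_af_law <- function(n) stats::runif(n, 0.05, 0.95)
  }
  with_seed(seed, {
    n_pop <- length(pop_sizes)
    p_anc <- ancestral_af_law(n_variants)
    if (any(p_anc <= 0 | p_anc >= 1)) {
      stop("ancestral_af_law must return frequencies strictly in (0, 1)",
           call. = FALSE)
    }
    draw_pop_afs <- function(p) {
      cols <- lapply(seq_len(n_pop), function(k) {
        if (F[k] == 0) return(p)
        shape_scale <- (1 - F[k]) / F[k]
        stats::rbeta(length(p), p * shape_scale,
                     (1 - p) * shape_scale)
      })
      do.call(cbind, cols)
    }
    pop_afs <- draw_pop_afs(p_anc)
    # a Beta draw can land exactly on 0/1 for skewed shapes; such a site is
    # degenerate in every downstream statistic, so redraw it (logged)
    n_resampled <- 0L
    for (iter in 1:100) {
      bad <- which(apply(pop_afs, 1, function(x) all(x <= 0) || all(x >= 1)))
      if (!length(bad)) break
      n_resampled <- n_resampled + length(bad)
      p_anc[bad] <- ancestral_af_law(length(bad))
      pop_afs[bad, ] <- draw_pop_afs(p_anc[bad])
    }
    if (n_resampled) {
      log_info("simulate_populations: resampled ", n_resampled,
               " monomorphic draw(s)")
    }
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_variants, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                  character(1))
    variants <- data.frame(chrom = "1", pos = seq_len(n_variants) * 100L,
                           ref = ref, alt = alt,
                           rsid = paste0("rs", 1000000L + seq_len(n_variants)),
                           stringsAsFactors = FALSE)
    cohorts <- vector("list", n_pop)
    names(cohorts) <- names(pop_sizes)
    for (k in seq_len(n_pop)) {
      n <- pop_sizes[[k]]
      dos <- matrix(stats::rbinom(n * n_variants, 2L,
                                  rep(pop_afs[, k], each = n)),
                    nrow = n, ncol = n_variants)
      ids <- sprintf("%s_S%04d", names(pop_sizes)[k], seq_len(n))
      cohorts[[k]] <- cohort_genotypes(names(pop_sizes)[k], ids, variants,
                                       dos)
    }
    colnames(pop_afs) <- names(pop_sizes)
    rownames(pop_afs) <- variants$rsid
    list(cohorts = cohorts,
         truth = list(true_afs = pop_afs, ancestral_af = p_anc,
                      divergence_F = F, seed = seed,
                      n_resampled = n_resampled))
  })
}

#' Simulate a CTET catalog with planted drug-pair overlaps
#'
#' Random role-typed drug-gene links: each (drug, role, gene) triple is
#' present independently with probability `role_density[role]`. Each pair
#' in `planted_pairs` is then forced to share at least one named element
#' (a random role and gene planted into both drugs). The returned truth
#' records `true_ddi_pairs`: exactly the unordered pairs whose (role, gene)
#' element sets intersect in the emitted catalog, recomputed by brute
#' force — planted pairs are always among them, random overlaps may add
#' more.
#'
#' @param n_drugs number of drugs (named `drug01`, ... unless `drug_names`
#'   given).
#' @param n_genes size of the gene pool (`G0001`, ...).
#' @param role_density single probability or named vector over the four
#'   CTET roles.
#' @param planted_pairs list of length-2 character vectors of drug names.
#' @param seed integer seed.
#' @param drug_names optional explicit drug names.
#' @return list with `catalog` (a `ctet_catalog`), `drugs` (a `drug_list`
#'   with a neutral group tag) and `truth` (list: `true_ddi_pairs` data
#'   frame `drug_a`/`drug_b`, `planted_pairs`, `seed`).
#' @export
simulate_ctet_catalog <- function(n_drugs, n_genes, role_density = 0.05,
                                  planted_pairs = list(), seed = 1,
                                  drug_names = NULL) {
  if (is.null(drug_names)) {
    drug_names <- sprintf("drug%02d", seq_len(n_drugs))
  }
  stopifnot(length(drug_names) == n_drugs)
  roles <- ctet_roles()
  if (length(role_density) == 1L) {
    role_density <- stats::setNames(rep(role_density, 4), roles)
  }
  stopifnot(all(roles %in% names(role_density)),
            all(role_density >= 0 & role_density <= 1))
  for (p in planted_pairs) {
    if (!all(p %in% drug_names)) {
      stop("planted pair references unknown drug: ",
           paste(setdiff(p, drug_names), collapse = ", "), call. = FALSE)
    }
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    rows <- list()
    for (role in roles) {
      hit <- which(matrix(stats::runif(n_drugs * n_genes) <
                            role_density[[role]],
                          nrow = n_drugs) , arr.ind = TRUE)
      if (nrow(hit)) {
        rows[[role]] <- data.frame(drug = drug_names[hit[, 1]], role = role,
                                   gene = genes[hit[, 2]],
                                   stringsAsFactors = FALSE)
      }
    }
    for (p in planted_pairs) {
      role <- sample(roles, 1)
      gene <- sample(genes, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        drug = c(p[1], p[2]), role = role, gene = gene,
        stringsAsFactors = FALSE)
    }
    cat_df <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(drug = character(0), role = character(0),
                 gene = character(0), stringsAsFactors = FALSE)
    }
    cat_df <- cat_df[order(cat_df$drug, cat_df$role, cat_df$gene), ,
                     drop = FALSE]
    drugs <- as_drug_list(data.frame(name = drug_names,
                                     groups = "cause_treatment",
                                     stringsAsFactors = FALSE))
    catalog <- as_ctet_catalog(cat_df, drugs)
    list(catalog = catalog, drugs = drugs,
         truth = list(true_ddi_pairs = brute_force_ddi_pairs(catalog,
                                                             drug_names),
                      planted_pairs = planted_pairs, seed = seed))
  })
}

#' Brute-force DDI truth: pairs with intersecting element sets
#'
#' Independent of the vector machinery: for every unordered drug pair,
#' intersect their deduplicated (role, gene) element sets directly.
#'
#' @param catalog a `ctet_catalog`.
#' @param drug_names drugs to scan (pairs over this set).
#' @return data frame `drug_a`, `drug_b` (sorted), one row per
#'   intersecting pair.
#' @export
brute_force_ddi_pairs <- function(catalog, drug_names) {
  elems <- lapply(stats::setNames(drug_names, drug_names), function(d) {
    sub <- catalog[catalog$drug == d, , drop = FALSE]
    unique(paste(sub$role, sub$gene, sep = ":"))
  })
  out <- list()
  dn <- sort(drug_names)
  for (i in seq_along(dn)) {
    for (j in seq_len(i - 1L)) {
      if (length(intersect(elems[[dn[i]]], elems[[dn[j]]])) > 0) {
        out[[length(out) + 1L]] <- c(dn[j], dn[i])
      }
    }
  }
  if (!length(out)) {
    return(data.frame(drug_a = character(0), drug_b = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, out)
  df <- data.frame(drug_a = m[, 1], drug_b = m[, 2],
                   stringsAsFactors = FALSE)
  df[order(df$drug_a, df$drug_b), , drop = FALSE]
}

#' Simulate clinical annotations with planted carrier counts
#'
#' Assigns each drug a set of risk SNPs drawn (without replacement, per
#' drug) from the cohort's variants; the risk allele is the variant's alt
#' base. The truth records, per sample and drug, the number of annotated
#' variants at which the sample carries at least one risk allele — counted
#' directly from the genotype matrix, so landscape counting can be checked
#' exactly.
#'
#' @param drugs a `drug_list`.
#' @param cohort a [cohort_genotypes] supplying the variant pool.
#' @param per_drug_counts integer: annotations per drug (recycled, or a
#'   named vector by drug).
#' @param level_mix named probability vector over evidence levels
#'   (default uniform over 1A..4).
#' @param seed integer seed.
#' @return list with `annotations` (a `clinical_annotations` table) and
#'   `truth` (list: `planted_carrier_counts` matrix samples x drugs,
#'   `seed`).
#' @export
simulate_annotations <- function(drugs, cohort, per_drug_counts = 10,
                                 level_mix = NULL, seed = 1) {
  n_drug <- nrow(drugs)
  counts <- if (!is.null(names(per_drug_counts))) {
    stats::setNames(per_drug_counts[drugs$name], drugs$name)
  } else stats::setNames(rep_len(per_drug_counts, n_drug), drugs$name)
  if (anyNA(counts)) stop("per_drug_counts missing for some drugs",
                          call. = FALSE)
  pool_ids <- variant_ids(cohort$variants)
  if (any(counts > length(pool_ids))) {
    stop("requested per-drug annotation count exceeds the variant pool (",
         length(pool_ids), ")", call. = FALSE)
  }
  levels <- annotation_levels()
  if (is.null(level_mix)) {
    level_mix <- stats::setNames(rep(1 / 6, 6), levels)
  }
  with_seed(seed, {
    rows <- list()
    for (d in drugs$name) {
      k <- counts[[d]]
      if (k == 0) next
      idx <- sample.int(length(pool_ids), k)
      rows[[d]] <- data.frame(
        allele_id = pool_ids[idx],
        gene = sprintf("GENE%03d", 1L + (idx %% 50L)),
        drug = d,
        level = sample(levels, k, replace = TRUE, prob = level_mix[levels]),
        risk_allele = cohort$variants$alt[idx],
        phenotype_category = sample(phenotype_categories(), k,
                                    replace = TRUE),
        stringsAsFactors = FALSE)
    }
    ann_df <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(allele_id = character(0), gene = character(0),
                 drug = character(0), level = character(0),
                 risk_allele = character(0),
                 phenotype_category = character(0),
                 stringsAsFactors = FALSE)
    }
    annotations <- as_clinical_annotations(ann_df, drugs)
    # truth: direct recount from the dosage matrix
    truth_counts <- matrix(0L, nrow = length(cohort$samples),
                           ncol = n_drug,
                           dimnames = list(cohort$samples, drugs$name))
    for (d in drugs$name) {
      sub <- annotations[annotations$drug == d, , drop = FALSE]
      if (!nrow(sub)) next
      vi <- match(sub$allele_id, pool_ids)
      carried <- cohort$dosage[, vi, drop = FALSE] >= 1L
      carried[is.na(carried)] <- FALSE
      truth_counts[, d] <- as.integer(rowSums(carried))
    }
    list(annotations = annotations,
         truth = list(planted_carrier_counts = truth_counts, seed = seed))
  })
}

#' Simulate diplotype calls with known allele frequencies
#'
#' Draws two alleles per sample per gene from the given allele-frequency
#' law (independent draws; no haplotype structure).
#'
#' @param sample_ids character vector of samples.
#' @param gene gene symbol (allele names must be prefixed `GENE*`).
#' @param allele_freqs named probability vector over allele names.
#' @param seed integer seed.
#' @return a `diplotype_calls` table.
#' @export
simulate_diplotypes <- function(sample_ids, gene, allele_freqs, seed = 1) {
  stopifnot(abs(sum(allele_freqs) - 1) < 1e-8)
  with_seed(seed, {
    a1 <- sample(names(allele_freqs), length(sample_ids), replace = TRUE,
                 prob = allele_freqs)
    a2 <- sample(names(allele_freqs), length(sample_ids), replace = TRUE,
                 prob = allele_freqs)
    structure(data.frame(sample_id = sample_ids, gene = toupper(gene),
                         allele1 = a1, allele2 = a2,
                         stringsAsFactors = FALSE),
              class = c("diplotype_calls", "data.frame"))
  })
}

#' Simulate a deleteriousness-prediction table
#'
#' Categorical SIFT / PolyPhen-2 / MutationTaster calls per variant with a
#' controllable damaging rate per tool, for exercising the candidate
#' filter.
#'
#' @param variant_ids character vector of variant identifiers.
#' @param genes gene symbol per variant.
#' @param damaging_rate probability each tool calls a variant damaging.
#' @param nonsyn_rate probability a variant is nonsynonymous exonic.
#' @param missing_rate probability a tool abstains.
#' @param seed integer seed.
#' @return a `deleterious_table`.
#' @export
simulate_deleterious <- function(variant_ids, genes, damaging_rate = 0.3,
                                 nonsyn_rate = 0.7, missing_rate = 0.05,
                                 seed = 1) {
  n <- length(variant_ids)
  stopifnot(length(genes) == n)
  draw <- function(damaging, benign) {
    r <- stats::runif(n)
    ifelse(r < missing_rate, "missing",
           ifelse(r < missing_rate + (1 - missing_rate) * damaging_rate,
                  damaging, benign))
  }
  with_seed(seed, {
    sift <- draw("damaging", "tolerated")
    poly_dmg <- ifelse(stats::runif(n) < 0.5, "probably_damaging",
                       "damaging")
    polyphen <- draw("X", "benign")
    polyphen[polyphen == "X"] <- poly_dmg[polyphen == "X"]
    mt <- draw("disease_causing", "polymorphism")
    fc <- ifelse(stats::runif(n) < nonsyn_rate, "nonsynonymous_exonic",
                 "other")
    structure(data.frame(variant_id = variant_ids, gene = toupper(genes),
                         functional_class = fc, sift = sift,
                         polyphen = polyphen, mutation_taster = mt,
                         stringsAsFactors = FALSE),
              class = c("deleterious_table", "data.frame"))
  })
}
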