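# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written against first principles (enumeration,
# direct set scans), not against the package's own code paths.

# -- independent two-sided Fisher oracle: enumerate every 2x2 table with
#    the observed margins and sum the point probabilities that are no
#    larger than the observed one (1e-7 relative tolerance for ties).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  pk <- exp(lchoose(r1, ks) + lchoose(n - r1, c1 - ks) - lchoose(n, c1))
  p_obs <- pk[ks == a]
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# -- independent DDI oracle: per-drug (role, gene) element sets from raw
#    catalog rows, pairwise intersection scan.
ddi_oracle_pairs <- function(catalog_df, drug_names) {
  sets <- lapply(drug_names, function(d) {
    rows <- catalog_df[catalog_df$drug == d, ]
    unique(paste(rows$role, rows$gene))
  })
  names(sets) <- drug_names
  hits <- list()
  dn <- sort(drug_names)
  for (i in seq_along(dn)) for (j in seq_len(i - 1L)) {
    if (any(sets[[dn[i]]] %in% sets[[dn[j]]])) {
      hits[[length(hits) + 1L]] <- paste(dn[j], dn[i])
    }
  }
  sort(unlist(hits) %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- random raw CTET catalog data frame (not via the package simulator)
random_catalog_df <- function(n_drugs, n_genes, density, rng_seed) {
  set.seed(rng_seed)
  drugs <- sprintf("d%02d", seq_len(n_drugs))
  genes <- sprintf("g%03d", seq_len(n_genes))
  roles <- c("carrier", "transporter", "enzyme", "target")
  grid <- expand.grid(drug = drugs, role = roles, gene = genes,
                      stringsAsFactors = FALSE)
  grid[runif(nrow(grid)) < density, , drop = FALSE]
}

# -- tiny cohort built directly from a dosage matrix
make_cohort <- function(dosage, population = "pop",
                        rsid = sprintf("rs%d", seq_len(ncol(dosage)))) {
  n_v <- ncol(dosage)
  cohort_genotypes(
    population,
    samples = sprintf("s%03d", seq_len(nrow(dosage))),
    variants = data.frame(chrom = "1", pos = seq_len(n_v) * 10L,
                          ref = rep("A", n_v), alt = rep("G", n_v),
                          rsid = rsid, stringsAsFactors = FALSE),
    dosage = dosage)
}

write_lines_tsv <- function(lines, path) {
  writeLines(lines, path, useBytes = TRUE)
  path
}

# tiny plain-text VCF on disk
write_test_vcf <- function(path, records, samples = c("s1", "s2", "s3")) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                      "FILTER", "INFO", "FORMAT", samples),
                    collapse = "\t"))
  writeLines(c(header, records), path, useBytes = TRUE)
  path
}
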