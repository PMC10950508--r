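#!/usr/bin/env Rscript
# Cross-population comparison over the annotated variants: pairwise
# weighted Weir-Cockerham Fst between all five populations (the heatmap
# data) and per-variant two-sided Fisher exact tests of allele-frequency
# differences between the focal cohort and each comparison panel,
# restricted to actionable-level SNP annotations.

suppressMessages(library(pgxddi))

inp <- "results/inputs"
out <- "results/popgen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

pops <- c("viet", "eas", "sas", "eur", "afr")
cohorts <- lapply(pops, function(p) {
  read_vcf(file.path(inp, sprintf("genotypes_%s.vcf", p)), population = p)
})
names(cohorts) <- pops

drugs <- read_drug_list(file.path(inp, "drugs.tsv"))
annotations <- read_clinical_annotations(
  file.path(inp, "clinical_annotations.tsv"), drugs)
pgx_snps <- unique(annotations$allele_id[annotations$allele_type == "snp"])
actionable <- annotations[annotations$level %in%
                            c("1A", "1B", "2A", "2B"), ]
act_snps <- unique(actionable$allele_id[actionable$allele_type == "snp"])

## Fst over the full identified pharmacogenomic variant list
m <- fst_matrix(cohorts, variant_subset = pgx_snps)
write.table(m$pairs, file.path(out, "fst_pairs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
fm <- cbind(data.frame(population = rownames(m$matrix)),
            as.data.frame(m$matrix))
write.table(fm, file.path(out, "fst_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
viet_rows <- m$pairs[m$pairs$pop_a == "viet" | m$pairs$pop_b == "viet", ]
other <- ifelse(viet_rows$pop_a == "viet", viet_rows$pop_b,
                viet_rows$pop_a)
ord <- order(viet_rows$weighted_fst)
cat("weighted Fst of the focal cohort against each panel (",
    length(pgx_snps), " pharmacogenomic variants):\n", sep = "")
cat(sprintf("  vs %-4s Fst = %.3f\n", other[ord],
            viet_rows$weighted_fst[ord]), sep = "")
cat("closest panel:", other[ord][1], "| most distinct:",
    other[rev(ord)][1], "\n")

## Fisher exact allele-frequency comparison, focal vs each panel
af_focal <- allele_frequencies(subset_cohort(cohorts$viet,
                                             variants = act_snps))
cmp_all <- do.call(rbind, lapply(pops[-1], function(p) {
  af_p <- allele_frequencies(subset_cohort(cohorts[[p]],
                                           variants = act_snps))
  compare_allele_frequencies(af_focal, af_p, alpha = 0.05)
}))
write.table(cmp_all, file.path(out, "af_comparison.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sig <- tapply(cmp_all$significant, cmp_all$pop_b, mean)
cat(sprintf(
  "actionable variants with significant AF difference vs viet (p < 0.05):\n"))
cat(sprintf("  %-4s %4.1f%% of %d variants\n", names(sig), 100 * sig,
            length(act_snps)), sep = "")
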