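#!/usr/bin/env Rscript
# Candidate-variant discovery beyond the curated annotations: restrict to
# nonsynonymous exonic variants in CTET genes of the drug list, require a
# deleterious call from at least two of SIFT / PolyPhen-2 /
# MutationTaster, and require cohort allele frequency strictly above 1%.

suppressMessages(library(pgxddi))

inp <- "results/inputs"
out <- "results/filter"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

drugs <- read_drug_list(file.path(inp, "drugs.tsv"))
catalog <- read_ctet_catalog(file.path(inp, "ctet_catalog.tsv"), drugs)
delet <- read_deleterious(file.path(inp, "deleterious.tsv"))
focal <- read_vcf(file.path(inp, "genotypes_viet.vcf"),
                  population = "viet")
af <- allele_frequencies(focal)

decisions <- filter_candidates(delet, af, catalog, drugs,
                               af_threshold = 0.01)
write.table(decisions, file.path(out, "filter_decisions.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

n <- nrow(decisions)
cat(sprintf("filter funnel over %d variants:\n", n))
cat(sprintf("  nonsynonymous exonic        %5d\n",
            sum(decisions$passed_class)))
cat(sprintf("  ... and in a CTET gene      %5d\n",
            sum(decisions$passed_class & decisions$passed_gene)))
cat(sprintf("  ... and >=2 damaging votes  %5d\n",
            sum(decisions$passed_class & decisions$passed_gene &
                  decisions$passed_votes)))
cat(sprintf("  ... and AF > 1%% (retained)  %5d\n",
            sum(decisions$retained)))
kept <- decisions[decisions$retained, ]
kept <- kept[order(-kept$af), ]
cat("top retained candidates by cohort AF:\n")
print(head(kept[, c("variant_id", "gene", "damaging_votes", "af")], 5),
      row.names = FALSE)
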