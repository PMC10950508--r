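#!/usr/bin/env Rscript
# Per-drug pharmacogenomic landscape of the focal cohort: for every drug,
# the distribution over individuals of the number of annotated risk
# variants/alleles carried (median, range, quartiles) and the carrier
# fraction — computed once over all evidence levels and once restricted
# to the actionable levels (1A/1B/2A/2B).

suppressMessages(library(pgxddi))

inp <- "results/inputs"
out <- "results/landscape"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

drugs <- read_drug_list(file.path(inp, "drugs.tsv"))
annotations <- read_clinical_annotations(
  file.path(inp, "clinical_annotations.tsv"), drugs)
diplotypes <- read_diplotypes(file.path(inp, "diplotypes.tsv"))
focal <- read_vcf(file.path(inp, "genotypes_viet.vcf"),
                  population = "viet")

for (set in list(list(tag = "all_levels", filter = NULL),
                 list(tag = "actionable",
                      filter = c("1A", "1B", "2A", "2B")))) {
  lt <- landscape_table(focal, annotations, drugs, diplotypes,
                        level_filter = set$filter)
  write.table(lt$summary,
              file.path(out, sprintf("landscape_%s.tsv", set$tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(drug = lt$no_information),
              file.path(out, sprintf("no_information_%s.tsv", set$tag)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf(
    "[%s] %d drugs summarised, %d without pharmacogenomic information\n",
    set$tag, nrow(lt$summary), length(lt$no_information)))
  top <- lt$summary[order(-lt$summary$median), ][1:3, ]
  cat(sprintf("  highest genetic burden: %s\n",
              paste(sprintf("%s median %.1f (range %d-%d)", top$drug,
                            top$median, top$min, top$max),
                    collapse = "; ")))
}

## star/HLA allele frequencies from the diplotype calls, the quantities a
## population report would table alongside the landscape
dip_af <- diplotype_frequencies(diplotypes, population = "viet")
write.table(dip_af, file.path(out, "diplotype_frequencies.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
key <- dip_af[dip_af$allele_id %in% c("CYP2C19*2", "HLA-B*15:02"), ]
cat(sprintf("  %s observed at %.1f%% in the cohort\n", key$allele_id,
            100 * key$af))
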