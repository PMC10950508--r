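#!/usr/bin/env Rscript
# Generate the full synthetic input set for the analysis: a focal cohort
# of 1008 genotyped individuals plus four comparison populations at graded
# divergence, a drug list spanning COVID-19 treatment, post-COVID and
# comorbidity groups, a CTET catalog with planted drug-pair overlaps, a
# clinical-annotation table, deleteriousness predictions and diplotype
# calls for CYP2C19 and HLA-B. Everything is written as plain-text files
# under results/inputs/ so the downstream scripts exercise the same file
# formats a real run would.

suppressMessages(library(pgxddi))

seed <- 20260101L
out <- "results/inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## -- drug list: 18 drugs across the therapeutic groups --------------------
drugs_df <- data.frame(
  name = c("ritonavir", "remdesivir", "tocilizumab", "dexamethasone",
           "methylprednisolone", "warfarin", "apixaban", "rivaroxaban",
           "ceftriaxone", "voriconazole", "cotrimoxazole",
           "duloxetine", "amitriptyline", "salbutamol",
           "metformin", "gliclazide", "atorvastatin", "tamoxifen"),
  groups = c("cause_treatment", "cause_treatment", "cause_treatment",
             "corticoid", "corticoid", "antithrombotic", "antithrombotic",
             "antithrombotic", "superinfection", "superinfection",
             "superinfection", "post_covid_mental", "post_covid_mental",
             "post_covid_respiratory", "comorbidity_t2d",
             "comorbidity_t2d", "comorbidity_cvd", "comorbidity_cancer"),
  stringsAsFactors = FALSE)
drugs <- as_drug_list(drugs_df)
write_drug_list(drugs, file.path(out, "drugs.tsv"))

## -- regimens: COVID-19 treatment set vs comorbidity maintenance sets -----
regimens <- structure(list(
  covid = drugs_df$name[1:11],
  t2d = c("metformin", "gliclazide"),
  cvd = c("atorvastatin", "warfarin"),
  cancer = c("tamoxifen")), class = "regimen_set")
write_regimens(regimens, file.path(out, "regimens.tsv"))

## -- genotypes: focal population plus four comparison panels --------------
## Per-population Balding-Nichols divergence from the shared ancestor;
## pairwise Fst is roughly the mean of the two F values, giving the
## graded near/far structure of continental reference panels.
pop_sizes <- c(viet = 1008, eas = 200, sas = 200, eur = 200, afr = 200)
F_per_pop <- c(viet = 0.01, eas = 0.03, sas = 0.10, eur = 0.14,
               afr = 0.30)
sim_g <- simulate_populations(2000, pop_sizes, F = F_per_pop, seed = seed)
for (p in names(sim_g$cohorts)) {
  write_cohort_vcf(sim_g$cohorts[[p]],
                   file.path(out, sprintf("genotypes_%s.vcf", p)))
}
pop_map <- do.call(rbind, lapply(sim_g$cohorts, function(co) {
  data.frame(sample_id = co$samples, population = co$population,
             stringsAsFactors = FALSE)
}))
write.table(pop_map, file.path(out, "population_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## -- CTET catalog with planted overlaps ----------------------------------
## Planted pairs guarantee known DDIs inside the COVID regimen and across
## regimens (ritonavir/warfarin is the classic CYP-mediated example).
planted <- list(c("ritonavir", "warfarin"), c("ritonavir", "apixaban"),
                c("metformin", "remdesivir"),
                c("atorvastatin", "ritonavir"))
sim_c <- simulate_ctet_catalog(nrow(drugs_df), n_genes = 60,
                               role_density = 0.03,
                               planted_pairs = planted, seed = seed + 1L,
                               drug_names = drugs_df$name)
write_ctet_catalog(sim_c$catalog, file.path(out, "ctet_catalog.tsv"))

## -- clinical annotations: SNPs from the cohort + star/HLA records --------
focal <- sim_g$cohorts$viet
per_drug <- c(ritonavir = 15, remdesivir = 6, tocilizumab = 7,
              dexamethasone = 7, methylprednisolone = 1, warfarin = 34,
              apixaban = 3, rivaroxaban = 2, ceftriaxone = 2,
              voriconazole = 8, cotrimoxazole = 6, duloxetine = 25,
              amitriptyline = 18, salbutamol = 4, metformin = 10,
              gliclazide = 3, atorvastatin = 12, tamoxifen = 0)
sim_a <- simulate_annotations(drugs, focal, per_drug_counts = per_drug,
                              seed = seed + 2L)
ann <- rbind(as.data.frame(sim_a$annotations)[,
               c("allele_id", "gene", "drug", "level", "risk_allele",
                 "phenotype_category")],
             data.frame(
               allele_id = c("CYP2C19*2", "CYP2C19*3", "HLA-B*15:02"),
               gene = c("CYP2C19", "CYP2C19", "HLA-B"),
               drug = c("voriconazole", "voriconazole", "cotrimoxazole"),
               level = c("1A", "1A", "2A"),
               risk_allele = c("CYP2C19*2", "CYP2C19*3", "HLA-B*15:02"),
               phenotype_category = "toxicity"))
write_clinical_annotations(as_clinical_annotations(ann, drugs),
                           file.path(out, "clinical_annotations.tsv"))

## -- diplotypes: CYP2C19 star alleles and HLA-B, known frequency laws -----
## Allele-frequency settings chosen to emulate an East-Asian profile with
## common CYP2C19 no-function alleles and a high-prevalence HLA-B*15:02.
cyp <- simulate_diplotypes(focal$samples, "CYP2C19",
                           c("CYP2C19*1" = 0.643, "CYP2C19*2" = 0.294,
                             "CYP2C19*3" = 0.052, "CYP2C19*17" = 0.011),
                           seed = seed + 3L)
hla <- simulate_diplotypes(focal$samples, "HLA-B",
                           c("HLA-B*15:02" = 0.191,
                             "HLA-B*other" = 0.809), seed = seed + 4L)
write_diplotypes(rbind(cyp, hla), file.path(out, "diplotypes.tsv"))

## -- deleteriousness predictions over the cohort variants -----------------
ids <- focal$variants$rsid
gene_pool <- c(sort(unique(sim_c$catalog$gene)), "OUTSIDE1", "OUTSIDE2")
delet <- simulate_deleterious(
  ids, genes = gene_pool[1L + (seq_along(ids) - 1L) %% length(gene_pool)],
  damaging_rate = 0.3, nonsyn_rate = 0.5, seed = seed + 5L)
write_deleterious(delet, file.path(out, "deleterious.tsv"))

## -- ground truth sidecar --------------------------------------------------
jsonlite::write_json(
  list(seed = seed,
       divergence_F = as.list(F_per_pop),
       true_ddi_pairs = sim_c$truth$true_ddi_pairs,
       planted_pairs = planted,
       planted_carrier_count_totals =
         as.list(colSums(sim_a$truth$planted_carrier_counts))),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
  digits = NA)

cat("simulated inputs written to", out, "\n")
cat(" populations:", paste(sprintf("%s (n=%d)", names(pop_sizes),
                                   pop_sizes), collapse = ", "), "\n")
cat(" drugs:", nrow(drugs_df), "| planted DDI pairs:",
    length(planted), "| true DDI pairs in catalog:",
    nrow(sim_c$truth$true_ddi_pairs), "\n")
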