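test_that("drug lists parse, preserve order and reject bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lines_tsv(c("name\tgroups",
                    "warfarin\tantithrombotic",
                    "ritonavir\tcause_treatment"), f)
  d <- read_drug_list(f)
  expect_s3_class(d, "drug_list")
  expect_identical(d$name, c("warfarin", "ritonavir"))
  expect_identical(d$groups, c("antithrombotic", "cause_treatment"))

  write_lines_tsv("name\tgroups", f)
  expect_identical(nrow(read_drug_list(f)), 0L)

  write_lines_tsv(c("name\tgroups", "a\tcorticoid", "b\tcorticoid",
                    "c\tsteroid"), f)
  expect_error(read_drug_list(f), "steroid.*row 3")

  write_lines_tsv(c("name\tgroups", "a\tcorticoid", "a\tcorticoid"), f)
  expect_error(read_drug_list(f), "duplicate drug name")

  # multiple group tags on one drug
  write_lines_tsv(c("name\tgroups",
                    "aspirin\tpost_covid_cardiovascular;comorbidity_cvd"),
                  f)
  d <- read_drug_list(f)
  expect_identical(drugs_in_group(d, "comorbidity_cvd"), "aspirin")
  expect_identical(drugs_in_group(d, "corticoid"), character(0))
})

test_that("clinical annotations: type inference, dedup and drug filter", {
  drugs <- as_drug_list(data.frame(name = c("voriconazole", "warfarin"),
                                   groups = "superinfection"))
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "allele_id\tgene\tdrug\tlevel\trisk_allele\tphenotype_category"
  write_lines_tsv(c(hdr,
    "CYP2C19*2\tCYP2C19\tvoriconazole\t1A\tCYP2C19*2\ttoxicity",
    "rs9923231\tVKORC1\twarfarin\t1A\tT\tdosage",
    "rs9923231\tVKORC1\twarfarin\t1A\tT\tdosage",
    "HLA-B*15:02\tHLA-B\tnotlisted\t2A\tHLA-B*15:02\ttoxicity"), f)
  expect_message(ann <- read_clinical_annotations(f, drugs),
                 "dropped 1 record")
  expect_identical(nrow(ann), 2L)
  expect_identical(ann$allele_type[ann$allele_id == "CYP2C19*2"], "star")
  expect_identical(ann$allele_type[ann$allele_id == "rs9923231"], "snp")
  expect_false(anyDuplicated(ann[, c("allele_id", "drug")]) > 0)

  # (allele_id, drug) kept once at the strongest level
  write_lines_tsv(c(hdr,
    "rs1\tG1\twarfarin\t3\tA\tefficacy",
    "rs1\tG1\twarfarin\t1B\tA\tefficacy"), f)
  ann <- suppressMessages(read_clinical_annotations(f, drugs))
  expect_identical(ann$level, "1B")

  # explicit allele_type must agree with identifier syntax
  write_lines_tsv(c(paste0(hdr, "\tallele_type"),
    "rs2\tG1\twarfarin\t3\tA\tefficacy\tstar"), f)
  expect_error(read_clinical_annotations(f, drugs), "disagrees")

  # closed level vocabulary, nucleotide risk allele for snps
  write_lines_tsv(c(hdr, "rs2\tG1\twarfarin\t5\tA\tefficacy"), f)
  expect_error(read_clinical_annotations(f, drugs), "evidence level")
  write_lines_tsv(c(hdr, "rs2\tG1\twarfarin\t3\tVKORC1*2\tefficacy"), f)
  expect_error(read_clinical_annotations(f, drugs), "nucleotide")
})

test_that("CTET catalog: dedup, case normalization, drug restriction", {
  drugs <- as_drug_list(data.frame(name = c("drugA", "drugB"),
                                   groups = "cause_treatment"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lines_tsv(c("drug\trole\tgene",
                    "drugA\tenzyme\tCYP3A4",
                    "drugA\tenzyme\tCYP3A4",
                    "drugA\ttarget\tcyp3a4",
                    "drugB\tcarrier\tALB"), f)
  cat_ <- suppressMessages(read_ctet_catalog(f, drugs))
  expect_identical(nrow(cat_), 3L)
  expect_true(all(cat_$gene %in% c("CYP3A4", "ALB")))
  # same gene under two roles stays two entries
  expect_setequal(cat_$role[cat_$gene == "CYP3A4"], c("enzyme", "target"))

  write_lines_tsv(c("drug\trole\tgene", "drugA\tpromoter\tX"), f)
  expect_error(read_ctet_catalog(f, drugs), "CTET role")

  # drug in the list with no catalog rows: legitimate zero-vector case
  write_lines_tsv(c("drug\trole\tgene", "drugA\tenzyme\tCYP3A4"), f)
  cat_ <- read_ctet_catalog(f, drugs)
  expect_false("drugB" %in% cat_$drug)
  expect_true("drugB" %in% drugs$name)
})

test_that("deduplication is idempotent under file self-concatenation", {
  drugs <- as_drug_list(data.frame(name = "d1", groups = "corticoid"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  body <- c("d1\tenzyme\tA", "d1\ttarget\tB", "d1\tenzyme\tC")
  write_lines_tsv(c("drug\trole\tgene", body), f1)
  write_lines_tsv(c("drug\trole\tgene", body, body), f2)
  c1 <- read_ctet_catalog(f1, drugs)
  c2 <- suppressMessages(read_ctet_catalog(f2, drugs))
  expect_identical(as.data.frame(c1), as.data.frame(c2))
})

test_that("regimens resolve against the drug list and keep order", {
  drugs <- as_drug_list(data.frame(name = c("a", "b", "c"),
                                   groups = "cause_treatment"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lines_tsv(c("name\tdrugs", "covid\tc;a", "other\tb"), f)
  regs <- read_regimens(f, drugs)
  expect_identical(regs$covid, c("c", "a"))
  write_lines_tsv(c("name\tdrugs", "covid\ta;zzz"), f)
  expect_error(read_regimens(f, drugs), "zzz")
})

test_that("round-trip identity holds on randomized tables", {
  roles <- c("carrier", "transporter", "enzyme", "target")
  levels <- c("1A", "1B", "2A", "2B", "3", "4")
  set.seed(2024)
  for (i in seq_len(100)) {
    n <- sample(0:12, 1)
    drugs <- as_drug_list(data.frame(
      name = sprintf("drug%02d", seq_len(max(n, 1))),
      groups = sample(c("corticoid", "antithrombotic"), max(n, 1), TRUE),
      stringsAsFactors = FALSE))
    f <- tempfile(fileext = ".tsv")
    kind <- i %% 3
    if (kind == 0) {
      cat_ <- as_ctet_catalog(data.frame(
        drug = sample(drugs$name, n, TRUE),
        role = sample(roles, n, TRUE),
        gene = sample(sprintf("G%02d", 1:8), n, TRUE),
        stringsAsFactors = FALSE)[0:n, , drop = FALSE], drugs)
      write_ctet_catalog(cat_, f)
      expect_identical(as.data.frame(read_ctet_catalog(f, drugs)),
                       as.data.frame(cat_))
    } else if (kind == 1) {
      ann <- as_clinical_annotations(data.frame(
        allele_id = sprintf("rs%d", sample.int(1e6, n)),
        gene = sample(sprintf("G%02d", 1:8), n, TRUE),
        drug = sample(drugs$name, n, TRUE),
        level = sample(levels, n, TRUE),
        risk_allele = sample(c("A", "C", "G", "T"), n, TRUE),
        phenotype_category = sample(c("efficacy", "toxicity"), n, TRUE),
        stringsAsFactors = FALSE)[0:n, , drop = FALSE], drugs)
      write_clinical_annotations(ann, f)
      back <- suppressMessages(read_clinical_annotations(f, drugs))
      expect_identical(as.data.frame(back), as.data.frame(ann))
    } else {
      write_drug_list(drugs, f)
      expect_identical(as.data.frame(read_drug_list(f)),
                       as.data.frame(drugs))
    }
    unlink(f)
  }
})

test_that("regimen round-trip preserves drug order", {
  drugs <- as_drug_list(data.frame(name = letters[1:5],
                                   groups = "cause_treatment"))
  regs <- structure(list(r1 = c("d", "a", "c"), r2 = c("b")),
                    class = "regimen_set")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_regimens(regs, f)
  expect_identical(unclass(read_regimens(f, drugs))[], unclass(regs)[])
})
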