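test_that("predictor votes follow the damaging-category rule", {
  v <- is_deleterious("damaging", "benign", "disease_causing")
  expect_identical(v$votes, 2L); expect_true(v$deleterious)
  v <- is_deleterious("damaging", "benign", "polymorphism")
  expect_identical(v$votes, 1L); expect_false(v$deleterious)
  v <- is_deleterious("missing", "probably_damaging", "disease_causing")
  expect_identical(v$votes, 2L); expect_true(v$deleterious)
  v <- is_deleterious("tolerated", "damaging", "missing")
  expect_identical(v$votes, 1L); expect_false(v$deleterious)
  expect_error(is_deleterious("bad_token", "benign", "missing"),
               "SIFT call")
})

make_filter_inputs <- function(variants) {
  drugs <- as_drug_list(data.frame(name = "d1",
                                   groups = "cause_treatment"))
  catalog <- as_ctet_catalog(data.frame(drug = "d1", role = "enzyme",
                                        gene = "CES1",
                                        stringsAsFactors = FALSE), drugs)
  list(drugs = drugs, catalog = catalog)
}

test_that("the exhaustive truth table reproduces the retention rule", {
  sift_v <- c("damaging", "tolerated", "missing")
  poly_v <- c("probably_damaging", "damaging", "benign", "missing")
  mt_v <- c("disease_causing", "polymorphism", "missing")
  grid <- expand.grid(sift = sift_v, polyphen = poly_v,
                      mutation_taster = mt_v,
                      functional_class = c("nonsynonymous_exonic",
                                           "other"),
                      af = c(0.005, 0.01, 0.032),
                      gene = c("CES1", "NOTINCAT"),
                      stringsAsFactors = FALSE)
  del <- structure(data.frame(
    variant_id = sprintf("v%04d", seq_len(nrow(grid))),
    gene = grid$gene, functional_class = grid$functional_class,
    sift = grid$sift, polyphen = grid$polyphen,
    mutation_taster = grid$mutation_taster, stringsAsFactors = FALSE),
    class = c("deleterious_table", "data.frame"))
  af_tab <- data.frame(allele_id = del$variant_id, population = "viet",
                       alt_count = 0L, total_count = 0L, af = grid$af)
  inp <- make_filter_inputs()
  dec <- filter_candidates(del, af_tab, inp$catalog, inp$drugs,
                           af_threshold = 0.01)
  votes <- (grid$sift == "damaging") +
    (grid$polyphen %in% c("probably_damaging", "damaging")) +
    (grid$mutation_taster == "disease_causing")
  expected <- grid$functional_class == "nonsynonymous_exonic" &
    grid$gene == "CES1" & votes >= 2 & grid$af > 0.01
  expect_identical(dec$retained, expected)
  expect_identical(dec$damaging_votes, as.integer(votes))
  # decision decomposition: retained is exactly the recorded conjunction
  expect_identical(dec$retained,
                   dec$passed_class & dec$passed_gene & dec$passed_votes &
                     !is.na(dec$passed_af) & dec$passed_af)
})

test_that("the AF cutoff is strict and anti-monotone in the threshold", {
  inp <- make_filter_inputs()
  del <- structure(data.frame(
    variant_id = c("v1", "v2", "v3"), gene = "CES1",
    functional_class = "nonsynonymous_exonic",
    sift = "damaging", polyphen = "probably_damaging",
    mutation_taster = "polymorphism", stringsAsFactors = FALSE),
    class = c("deleterious_table", "data.frame"))
  af_tab <- data.frame(allele_id = c("v1", "v2", "v3"),
                       population = "p", alt_count = 0L, total_count = 0L,
                       af = c(0.010, 0.0100001, 0.032))
  dec <- filter_candidates(del, af_tab, inp$catalog, inp$drugs, 0.01)
  expect_identical(dec$retained, c(FALSE, TRUE, TRUE))  # af = 0.01 fails
  for (th in c(0, 0.005, 0.02, 0.05)) {
    lo <- filter_candidates(del, af_tab, inp$catalog, inp$drugs, th)
    hi <- filter_candidates(del, af_tab, inp$catalog, inp$drugs,
                            min(th + 0.03, 0.99))
    expect_true(all(lo$retained | !hi$retained))
  }
})

test_that("variants missing from the AF table are flagged, never retained", {
  inp <- make_filter_inputs()
  del <- structure(data.frame(
    variant_id = c("v1", "vmissing"), gene = "CES1",
    functional_class = "nonsynonymous_exonic", sift = "damaging",
    polyphen = "damaging", mutation_taster = "disease_causing",
    stringsAsFactors = FALSE),
    class = c("deleterious_table", "data.frame"))
  af_tab <- data.frame(allele_id = "v1", population = "p",
                       alt_count = 0L, total_count = 0L, af = 0.2)
  expect_message(
    dec <- filter_candidates(del, af_tab, inp$catalog, inp$drugs),
    "missing from the AF table")
  expect_true(dec$retained[1])
  expect_false(dec$retained[2])
  expect_true(is.na(dec$passed_af[2]))
})

test_that("filter decisions are independent of row order", {
  inp <- make_filter_inputs()
  set.seed(8)
  n <- 40
  del <- structure(data.frame(
    variant_id = sprintf("v%02d", 1:n),
    gene = sample(c("CES1", "OTHER"), n, TRUE),
    functional_class = sample(c("nonsynonymous_exonic", "other"), n, TRUE),
    sift = sample(c("damaging", "tolerated", "missing"), n, TRUE),
    polyphen = sample(c("probably_damaging", "benign"), n, TRUE),
    mutation_taster = sample(c("disease_causing", "polymorphism"), n, TRUE),
    stringsAsFactors = FALSE), class = c("deleterious_table", "data.frame"))
  af_tab <- data.frame(allele_id = del$variant_id, population = "p",
                       alt_count = 0L, total_count = 0L,
                       af = runif(n, 0, 0.05))
  d1 <- filter_candidates(del, af_tab, inp$catalog, inp$drugs)
  perm <- sample(n)
  d2 <- filter_candidates(del[perm, ], af_tab, inp$catalog, inp$drugs)
  expect_identical(d2$retained[order(perm)], d1$retained)
})
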