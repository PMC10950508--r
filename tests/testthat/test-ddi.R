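two_drug_catalog <- function() {
  drugs <- as_drug_list(data.frame(name = c("dA", "dB", "dC"),
                                   groups = "cause_treatment"))
  catalog <- as_ctet_catalog(data.frame(
    drug = c("dA", "dB", "dB", "dC"),
    role = c("enzyme", "enzyme", "enzyme", "target"),
    gene = c("CYP3A4", "CYP3A4", "CYP2C9", "CYP3A4"),
    stringsAsFactors = FALSE), drugs)
  list(drugs = drugs, catalog = catalog)
}

test_that("universes are deduplicated, ordered and keyed per type", {
  x <- two_drug_catalog()
  expect_identical(build_universe(x$catalog, x$drugs$name, "enzyme"),
                   c("CYP2C9", "CYP3A4"))
  # hybrid keying: gene under two roles contributes two elements
  uni_h <- build_universe(x$catalog, x$drugs$name, "hybrid")
  expect_identical(uni_h, c("enzyme:CYP2C9", "enzyme:CYP3A4",
                            "target:CYP3A4"))
  expect_identical(build_universe(x$catalog, x$drugs$name, "hybrid",
                                  hybrid_keying = "gene"),
                   c("CYP2C9", "CYP3A4"))
  # permuting the drug set leaves the universe unchanged
  expect_identical(build_universe(x$catalog, rev(x$drugs$name), "hybrid"),
                   uni_h)
})

test_that("vectors reflect catalog membership with correct popcounts", {
  x <- two_drug_catalog()
  uni <- build_universe(x$catalog, x$drugs$name, "enzyme")
  expect_identical(unname(build_vector("dB", uni, x$catalog, "enzyme")),
                   c(1L, 1L))
  expect_identical(unname(build_vector("dC", uni, x$catalog, "enzyme")),
                   c(0L, 0L))
  uni_h <- build_universe(x$catalog, x$drugs$name, "hybrid")
  v <- build_vector("dB", uni_h, x$catalog, "hybrid")
  expect_identical(sum(v), 2L)  # popcount = deduplicated catalog rows
})

test_that("zero-vector drugs are eliminated with names reported", {
  m <- rbind(dA = c(1L, 0L), dB = c(0L, 0L), dC = c(1L, 1L))
  el <- suppressMessages(eliminate_zero_vectors(m))
  expect_identical(rownames(el$kept), c("dA", "dC"))
  expect_identical(el$dropped, "dB")
  el_all <- suppressMessages(
    eliminate_zero_vectors(rbind(a = 0L, b = 0L)))
  expect_identical(nrow(el_all$kept), 0L)
})

test_that("Russell-Rao similarity is the shared-ones fraction", {
  expect_equal(russell_rao(c(1, 0, 1, 0), c(1, 1, 0, 0)), 0.25)
  expect_equal(russell_rao(rep(1, 6), rep(1, 6)), 1)
  expect_equal(russell_rao(c(1, 1, 0), c(0, 0, 1)), 0)
  expect_equal(russell_rao(c(1, 0, 1), c(1, 1, 0)),
               russell_rao(c(1, 1, 0), c(1, 0, 1)))
  expect_error(russell_rao(c(1, 0), c(1, 0, 1)), "length")
  expect_error(russell_rao(integer(0), integer(0)), "empty universe")
})

test_that("DDI calls equal the brute-force intersection oracle", {
  for (seed in 1:25) {
    raw <- random_catalog_df(n_drugs = 8, n_genes = 15,
                             density = 0.04, rng_seed = seed)
    drugs <- as_drug_list(data.frame(name = sprintf("d%02d", 1:8),
                                     groups = "cause_treatment"))
    catalog <- as_ctet_catalog(raw, drugs)
    res <- suppressMessages(detect_ddis(drugs, catalog))
    got <- sort(paste(res$drug_a[res$is_ddi], res$drug_b[res$is_ddi]))
    expect_identical(got, ddi_oracle_pairs(raw, drugs$name))
  }
})

test_that("hybrid similarity decomposes over roles and respects keying", {
  drugs <- as_drug_list(data.frame(name = c("d1", "d2"),
                                   groups = "cause_treatment"))
  # same gene, different roles: role_gene keying gives no match,
  # gene keying does
  catalog <- as_ctet_catalog(data.frame(
    drug = c("d1", "d2"), role = c("enzyme", "target"), gene = "CYP3A4",
    stringsAsFactors = FALSE), drugs)
  res_rg <- detect_ddis(drugs, catalog, hybrid_keying = "role_gene")
  expect_false(res_rg$is_ddi)
  res_g <- detect_ddis(drugs, catalog, hybrid_keying = "gene")
  expect_true(res_g$is_ddi)

  # positive matches decompose as the sum over roles under role_gene keying
  for (seed in 1:10) {
    raw <- random_catalog_df(6, 10, 0.12, rng_seed = 100 + seed)
    dl <- as_drug_list(data.frame(name = sprintf("d%02d", 1:6),
                                  groups = "corticoid"))
    cat_ <- as_ctet_catalog(raw, dl)
    res <- suppressMessages(detect_ddis(dl, cat_))
    if (nrow(res) == 0) next
    d_by_type <- attr(res, "d")
    role_pm <- mapply(function(a, b) {
      sum(vapply(c("carrier", "transporter", "enzyme", "target"),
                 function(r) {
        ga <- unique(cat_$gene[cat_$drug == a & cat_$role == r])
        gb <- unique(cat_$gene[cat_$drug == b & cat_$role == r])
        length(intersect(ga, gb))
      }, integer(1)))
    }, res$drug_a, res$drug_b)
    expect_identical(res$positive_matches, as.integer(role_pm))
    expect_equal(res$S_hybrid, res$positive_matches / d_by_type[["hybrid"]])
  }
})

test_that("adding unrelated drugs rescales S but never flips a DDI call", {
  base <- two_drug_catalog()
  res1 <- suppressMessages(detect_ddis(base$drugs, base$catalog))
  drugs2 <- as_drug_list(data.frame(name = c(base$drugs$name, "dD"),
                                    groups = "cause_treatment"))
  cat2 <- as_ctet_catalog(rbind(
    as.data.frame(base$catalog),
    data.frame(drug = "dD", role = "carrier", gene = "ALB")), drugs2)
  res2 <- suppressMessages(detect_ddis(drugs2, cat2))
  key1 <- paste(res1$drug_a, res1$drug_b)
  key2 <- paste(res2$drug_a, res2$drug_b)
  shared <- intersect(key1, key2)
  expect_identical(res1$is_ddi[match(shared, key1)],
                   res2$is_ddi[match(shared, key2)])
})

test_that("regimen counting decomposes union = within_a + within_b + cross", {
  x <- two_drug_catalog()
  # DDI pairs in this catalog: (dA,dB) share enzyme CYP3A4; dC only via
  # target so no role_gene match with dA/dB
  rc <- suppressMessages(
    count_regimen_ddis(c("dA", "dB"), c("dC"), x$catalog))
  expect_identical(rc$union, rc$within_a + rc$within_b + rc$cross)
  expect_identical(rc$within_a, 1L)
  expect_identical(rc$cross, 0L)

  # regimen against itself: union = within, cross = 0
  rc_self <- suppressMessages(
    count_regimen_ddis(c("dA", "dB", "dC"), NULL, x$catalog))
  expect_identical(rc_self$cross, 0L)
  expect_identical(rc_self$union, rc_self$within_a)

  # planted example from the contract: regimens {A,B} and {C,D} with
  # DDIs (A,B), (C,D), (A,C)
  dl <- as_drug_list(data.frame(name = c("A", "B", "C", "D"),
                                groups = "cause_treatment"))
  cat_ <- as_ctet_catalog(data.frame(
    drug = c("A", "B", "C", "D", "A", "C"),
    role = "enzyme",
    gene = c("G1", "G1", "G2", "G2", "G3", "G3"),
    stringsAsFactors = FALSE), dl)
  rc2 <- count_regimen_ddis(c("A", "B"), c("C", "D"), cat_)
  expect_identical(c(rc2$within_a, rc2$within_b, rc2$cross, rc2$union),
                   c(1L, 1L, 1L, 3L))
})

test_that("regimen counts equal a brute-force pair scan on planted catalogs", {
  for (seed in 1:20) {
    sim <- simulate_ctet_catalog(9, 18, role_density = 0.05,
                                 planted_pairs = list(c("drug01", "drug07")),
                                 seed = 200 + seed)
    reg_a <- sim$drugs$name[1:5]
    reg_b <- sim$drugs$name[6:9]
    rc <- suppressMessages(
      count_regimen_ddis(reg_a, reg_b, sim$catalog))
    oracle <- ddi_oracle_pairs(as.data.frame(sim$catalog),
                               sim$drugs$name)
    expect_identical(rc$union, length(oracle))
    expect_identical(rc$union, rc$within_a + rc$within_b + rc$cross)
  }
})

test_that("network degrees count distinct partners", {
  drugs <- as_drug_list(data.frame(name = c("d1", "d2", "d3"),
                                   groups = "corticoid"))
  catalog <- as_ctet_catalog(data.frame(
    drug = c("d1", "d2", "d3", "d1", "d1"),
    role = c("enzyme", "enzyme", "enzyme", "target", "enzyme"),
    gene = c("CYP3A4", "CYP3A4", "CYP3A4", "CYP3A4", "ABCB1"),
    stringsAsFactors = FALSE), drugs)
  net <- build_drug_gene_network(catalog, drugs)
  deg <- function(n) net$nodes$degree[net$nodes$name == n]
  expect_identical(deg("CYP3A4"), 3L)  # 3 drugs share it, roles collapsed
  expect_identical(deg("d1"), 2L)      # 2 distinct genes
  expect_identical(nrow(unique(net$edges[, c("drug", "gene")])),
                   sum(net$nodes$degree[net$nodes$kind == "drug"]))
  expect_s3_class(net$graph, "igraph")
})

test_that("network degrees equal independent recounts on random catalogs", {
  for (seed in 1:10) {
    raw <- random_catalog_df(7, 12, 0.1, rng_seed = 300 + seed)
    dl <- as_drug_list(data.frame(name = sprintf("d%02d", 1:7),
                                  groups = "corticoid"))
    cat_ <- as_ctet_catalog(raw, dl)
    net <- build_drug_gene_network(cat_, dl)
    pairs <- unique(data.frame(drug = cat_$drug, gene = cat_$gene))
    for (k in seq_len(nrow(net$nodes))) {
      nd <- net$nodes[k, ]
      expected <- if (nd$kind == "drug") sum(pairs$drug == nd$name)
                  else sum(pairs$gene == nd$name)
      expect_identical(nd$degree, as.integer(expected))
    }
  }
})
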