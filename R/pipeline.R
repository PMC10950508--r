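## End-to-end orchestration: from a single validated config, simulate or
## load all inputs, run the landscape, population-comparison, filter and
## DDI stages, and write a report bundle of plain-text tables plus the
## resolved config and a run log. A bundle is deterministic given the
## config (including its seed): tables are written with fixed formatting
## and the log carries no timestamps.

#' Build and validate a pipeline configuration
#'
#' Scientifically meaningful parameters have no hidden defaults: the
#' evidence-level filter, significance level, AF threshold, DDI vector
#' gating and seed must all be given explicitly. Inputs are either
#' simulated (`simulate` block) or loaded from files (`paths` block) —
#' exactly one of the two.
#'
#' @param simulate `NULL`, or a list with simulation parameters:
#'   `n_variants`, `pop_sizes` (named), `F`, `n_drugs`, `n_genes`,
#'   `role_density`, `n_planted_pairs`, `per_drug_annotations`,
#'   `regimen_sizes` (named integer vector partitioning the drugs into
#'   regimens).
#' @param paths `NULL`, or a list of input files: `vcf`, `population_map`,
#'   `drugs`, `clinical_annotations`, `ctet_catalog`, `deleterious`,
#'   `diplotypes` (optional), `regimens`.
#' @param level_filter evidence levels for the landscape stage (`NULL` =
#'   all levels, stated explicitly by passing `NULL`).
#' @param alpha Fisher-test significance threshold in (0, 1).
#' @param af_threshold strict AF cutoff for the candidate filter, in
#'   `[0, 1)`.
#' @param ddi_vector_type vector type gating the DDI flag (`"hybrid"`
#'   recommended; a single role restricts the analysis to that role).
#' @param hybrid_keying `"role_gene"` or `"gene"`.
#' @param seed integer seed for every stochastic step.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            level_filter, alpha, af_threshold,
                            ddi_vector_type = "hybrid",
                            hybrid_keying = "role_gene", seed) {
  if (is.null(simulate) == is.null(paths)) {
    stop("exactly one of `simulate` or `paths` must be given",
         call. = FALSE)
  }
  if (!is.null(level_filter)) {
    check_vocab(level_filter, annotation_levels(), "evidence level")
  }
  stopifnot(alpha > 0, alpha <= 1, af_threshold >= 0, af_threshold < 1)
  check_vocab(ddi_vector_type, c(ctet_roles(), "hybrid"), "vector type")
  check_vocab(hybrid_keying, c("role_gene", "gene"), "hybrid keying")
  if (!is.null(simulate)) {
    need <- c("n_variants", "pop_sizes", "F", "n_drugs", "n_genes",
              "role_density", "n_planted_pairs", "per_drug_annotations",
              "regimen_sizes")
    miss <- setdiff(need, names(simulate))
    if (length(miss)) stop("simulation block missing: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    if (simulate$n_drugs < 2) stop("need at least 2 drugs", call. = FALSE)
    if (sum(simulate$regimen_sizes) > simulate$n_drugs) {
      stop("regimen sizes exceed the number of drugs", call. = FALSE)
    }
  }
  structure(list(simulate = simulate, paths = paths,
                 level_filter = level_filter, alpha = alpha,
                 af_threshold = af_threshold,
                 ddi_vector_type = ddi_vector_type,
                 hybrid_keying = hybrid_keying,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## Simulate the full input set for a config (internal to run_pipeline,
## exported for the analysis drivers). Seeds for the sub-generators are
## derived deterministically from the config seed.
#' Simulate all pipeline inputs for a configuration
#'
#' @param config a [pipeline_config] with a `simulate` block.
#' @return list of inputs (`cohorts`, `drugs`, `catalog`, `annotations`,
#'   `deleterious`, `regimens`, `truth`).
#' @export
simulate_pipeline_inputs <- function(config) {
  sp <- config$simulate
  seed <- config$seed
  sim_g <- simulate_populations(sp$n_variants, sp$pop_sizes, sp$F,
                                seed = seed)
  planted <- list()
  if (sp$n_planted_pairs > 0) {
    dn <- sprintf("drug%02d", seq_len(sp$n_drugs))
    planted <- with_seed(seed + 1L, {
      lapply(seq_len(sp$n_planted_pairs), function(i) sample(dn, 2))
    })
  }
  sim_c <- simulate_ctet_catalog(sp$n_drugs, sp$n_genes, sp$role_density,
                                 planted, seed = seed + 2L)
  focal <- sim_g$cohorts[[1L]]
  sim_a <- simulate_annotations(sim_c$drugs, focal,
                                sp$per_drug_annotations,
                                seed = seed + 3L)
  # deleterious-table genes cycle through the CTET gene pool plus a few
  # outside genes, so the filter's gene restriction bites both ways
  ids <- variant_ids(focal$variants)
  gene_pool <- c(sort(unique(sim_c$catalog$gene)), "OUT0001", "OUT0002")
  delet <- simulate_deleterious(ids,
                                genes = gene_pool[1L + (seq_along(ids) - 1L)
                                                  %% length(gene_pool)],
                                seed = seed + 4L)
  # regimens partition the drug list front-to-back
  sizes <- sp$regimen_sizes
  stopifnot(!is.null(names(sizes)))
  idx <- cumsum(sizes)
  regimens <- stats::setNames(vector("list", length(sizes)), names(sizes))
  start <- 1L
  for (i in seq_along(sizes)) {
    regimens[[i]] <- sim_c$drugs$name[start:idx[i]]
    start <- idx[i] + 1L
  }
  class(regimens) <- "regimen_set"
  list(cohorts = sim_g$cohorts, drugs = sim_c$drugs,
       catalog = sim_c$catalog, annotations = sim_a$annotations,
       deleterious = delet, regimens = regimens,
       truth = list(genotypes = sim_g$truth, catalog = sim_c$truth,
                    annotations = sim_a$truth))
}

load_pipeline_inputs <- function(config) {
  p <- config$paths
  drugs <- read_drug_list(p$drugs)
  cohort <- read_vcf(p$vcf)
  cohorts <- if (!is.null(p$population_map)) {
    split_cohort(cohort, read_population_map(p$population_map))
  } else stats::setNames(list(cohort), cohort$population)
  list(cohorts = cohorts, drugs = drugs,
       catalog = read_ctet_catalog(p$ctet_catalog, drugs),
       annotations = read_clinical_annotations(p$clinical_annotations,
                                               drugs),
       deleterious = read_deleterious(p$deleterious),
       diplotypes = if (!is.null(p$diplotypes)) read_diplotypes(p$diplotypes),
       regimens = read_regimens(p$regimens, drugs),
       truth = NULL)
}

#' Run the full pipeline and write a report bundle
#'
#' Stages: input acquisition (simulation or loading), per-drug landscape,
#' allele-frequency comparison (first population vs each other), pairwise
#' weighted Fst, candidate-variant filter, DDI detection, regimen-level
#' DDI counting, and drug-gene network export. Any stage error aborts
#' with the stage name. The bundle directory contains every table as TSV,
#' `truth.json` (simulated runs), `config.json` and `run_log.txt`, and is
#' byte-identical across runs with the same config.
#'
#' @param config a [pipeline_config].
#' @param output_dir directory to write the bundle into (created).
#' @return invisibly, a list with the in-memory stage results and
#'   `bundle_dir`.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  collector <- new.env()
  collector$lines <- character(0)
  old_opt <- options(pgxddi.log_collector = collector)
  on.exit(options(old_opt))

  stage <- function(name, expr) {
    log_info("stage ", name, ": start")
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$simulate)) simulate_pipeline_inputs(config)
    else load_pipeline_inputs(config)
  })
  if (nrow(inputs$drugs) == 0) stop("pipeline: empty drug list",
                                    call. = FALSE)
  focal <- inputs$cohorts[[1L]]

  land <- stage("landscape", {
    landscape_table(focal, inputs$annotations, inputs$drugs,
                    inputs$diplotypes, config$level_filter)
  })

  afc <- stage("af_compare", {
    af_focal <- allele_frequencies(focal)
    others <- inputs$cohorts[-1L]
    if (length(others) == 0) NULL else {
      do.call(rbind, lapply(others, function(co) {
        compare_allele_frequencies(af_focal, allele_frequencies(co),
                                   alpha = config$alpha)
      }))
    }
  })

  fst <- stage("fst", {
    if (length(inputs$cohorts) >= 2) fst_matrix(inputs$cohorts) else NULL
  })

  filt <- stage("filter", {
    filter_candidates(inputs$deleterious, allele_frequencies(focal),
                      inputs$catalog, inputs$drugs, config$af_threshold)
  })

  ddi <- stage("ddi", {
    detect_ddis(inputs$drugs, inputs$catalog, config$hybrid_keying)
  })

  reg <- stage("regimen_counts", {
    regs <- inputs$regimens
    rows <- list()
    for (i in seq_along(regs)) {
      for (j in seq_len(i)) {
        rc <- count_regimen_ddis(regs[[j]],
                                 if (i != j) regs[[i]] else NULL,
                                 inputs$catalog, config$hybrid_keying)
        rows[[length(rows) + 1L]] <- data.frame(
          regimen_a = names(regs)[j],
          regimen_b = if (i != j) names(regs)[i] else names(regs)[j],
          within_a = rc$within_a, within_b = rc$within_b,
          cross = rc$cross, union = rc$union,
          n_drugs_after_elimination = rc$n_drugs_after_elimination,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })

  net <- stage("network", {
    build_drug_gene_network(inputs$catalog, inputs$drugs)
  })

  stage("write_bundle", {
    write_tsv_file(land$summary, file.path(output_dir, "landscape.tsv"))
    write_tsv_file(data.frame(drug = land$no_information,
                              stringsAsFactors = FALSE),
                   file.path(output_dir, "no_info_drugs.tsv"))
    cm <- as.data.frame(land$per_sample_counts)
    cm <- cbind(data.frame(sample_id = rownames(land$per_sample_counts),
                           stringsAsFactors = FALSE), cm)
    write_tsv_file(cm, file.path(output_dir, "per_sample_counts.tsv"))
    if (!is.null(afc)) {
      write_tsv_file(afc, file.path(output_dir, "af_comparison.tsv"))
    }
    if (!is.null(fst)) {
      write_tsv_file(fst$pairs, file.path(output_dir, "fst_pairs.tsv"))
      fm <- as.data.frame(fst$matrix)
      fm <- cbind(data.frame(population = rownames(fst$matrix),
                             stringsAsFactors = FALSE), fm)
      write_tsv_file(fm, file.path(output_dir, "fst_matrix.tsv"))
    }
    write_tsv_file(filt, file.path(output_dir, "filter_decisions.tsv"))
    write_tsv_file(ddi, file.path(output_dir, "ddi_pairs.tsv"))
    write_tsv_file(reg, file.path(output_dir, "regimen_counts.tsv"))
    write_tsv_file(net$edges, file.path(output_dir, "network_edges.tsv"))
    write_tsv_file(net$nodes, file.path(output_dir, "network_nodes.tsv"))
    # resolved config: scientific parameters only, so bundles written to
    # different directories stay comparable byte-for-byte
    cfg <- unclass(config)
    cfg$paths <- NULL
    jsonlite::write_json(cfg, file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null")
    if (!is.null(inputs$truth)) {
      tr <- inputs$truth
      jsonlite::write_json(
        list(divergence_F = tr$genotypes$divergence_F,
             seed = config$seed,
             n_true_ddi_pairs = nrow(tr$catalog$true_ddi_pairs),
             true_ddi_pairs = tr$catalog$true_ddi_pairs,
             planted_carrier_count_colsums =
               unname(colSums(tr$annotations$planted_carrier_counts))),
        file.path(output_dir, "truth.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    writeLines(collector$lines, file.path(output_dir, "run_log.txt"),
               useBytes = TRUE)
  })

  invisible(list(bundle_dir = output_dir, inputs = inputs,
                 landscape = land, af_comparison = afc, fst = fst,
                 filter = filt, ddi = ddi, regimen_counts = reg,
                 network = net))
}

#' Summarise a report bundle
#'
#' Re-reads the bundle tables and assembles a plain-text summary in which
#' every number is recomputed from a bundle file (no report-only
#' computation). Regenerating the report is idempotent.
#'
#' @param bundle_dir directory written by [run_pipeline()].
#' @param write if `TRUE`, also write `report.txt` into the bundle.
#' @return character vector of report lines, invisibly when `write`.
#' @export
generate_report <- function(bundle_dir, write = TRUE) {
  need <- c("landscape.tsv", "no_info_drugs.tsv", "filter_decisions.tsv",
            "ddi_pairs.tsv", "regimen_counts.tsv", "network_nodes.tsv")
  for (f in need) {
    if (!file.exists(file.path(bundle_dir, f))) {
      stop("bundle member missing: ", f, call. = FALSE)
    }
  }
  num <- function(df, col) if (nrow(df)) as.numeric(df[[col]]) else numeric(0)
  land <- read_tsv_file(file.path(bundle_dir, "landscape.tsv"))
  noinfo <- read_tsv_file(file.path(bundle_dir, "no_info_drugs.tsv"))
  ddi <- read_tsv_file(file.path(bundle_dir, "ddi_pairs.tsv"))
  reg <- read_tsv_file(file.path(bundle_dir, "regimen_counts.tsv"))
  filt <- read_tsv_file(file.path(bundle_dir, "filter_decisions.tsv"))
  lines <- c(
    "pgxddi pipeline report",
    "======================",
    sprintf("drugs with annotations: %d; without pharmacogenomic information: %d",
            nrow(land), nrow(noinfo)),
    sprintf("candidate variants retained by the filter: %d / %d",
            sum(filt$retained == "TRUE"), nrow(filt)),
    sprintf("potential DDI pairs (similarity > 0): %d / %d scored pairs",
            sum(ddi$is_ddi == "TRUE"), nrow(ddi)))
  if (file.exists(file.path(bundle_dir, "fst_pairs.tsv"))) {
    fst <- read_tsv_file(file.path(bundle_dir, "fst_pairs.tsv"))
    top <- fst[order(-as.numeric(fst$weighted_fst)), , drop = FALSE]
    top <- utils::head(top, 3)
    lines <- c(lines, "top population pairs by weighted Fst:",
               sprintf("  %s vs %s: %s", top$pop_a, top$pop_b,
                       top$weighted_fst))
  }
  lines <- c(lines, "regimen-level DDI counts (union = within_a + within_b + cross):",
             sprintf("  %s + %s: union %s = %s + %s + %s",
                     reg$regimen_a, reg$regimen_b, reg$union,
                     reg$within_a, reg$within_b, reg$cross))
  if (write) {
    writeLines(lines, file.path(bundle_dir, "report.txt"), useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
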