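## Candidate-variant filter: retain nonsynonymous exonic variants located
## in the CTET genes of the active drug list, called deleterious by at
## least two of the three predictors (SIFT "damaging"; PolyPhen-2
## "damaging" or "probably_damaging"; MutationTaster "disease_causing";
## a missing call abstains), with cohort allele frequency strictly above
## the threshold (default 1%).

#' Deleteriousness vote over the three predictors
#'
#' @param sift `damaging` / `tolerated` / `missing`.
#' @param polyphen `probably_damaging` / `damaging` / `benign` /
#'   `missing`.
#' @param mutation_taster `disease_causing` / `polymorphism` / `missing`.
#' @return data frame with `votes` (0-3) and `deleterious`
#'   (`votes >= 2`); vectorised over the inputs.
#' @export
is_deleterious <- function(sift, polyphen, mutation_taster) {
  check_vocab(sift, c("damaging", "tolerated", "missing"), "SIFT call")
  check_vocab(polyphen,
              c("probably_damaging", "damaging", "benign", "missing"),
              "PolyPhen-2 call")
  check_vocab(mutation_taster,
              c("disease_causing", "polymorphism", "missing"),
              "MutationTaster call")
  votes <- (sift == "damaging") +
    (polyphen %in% c("damaging", "probably_damaging")) +
    (mutation_taster == "disease_causing")
  data.frame(votes = as.integer(votes), deleterious = votes >= 2L)
}

#' Filter candidate pharmacogenomic variants
#'
#' Every input variant yields one decision row recording each
#' sub-criterion (functional class, gene in the drug set's CTET catalog,
#' predictor votes, allele frequency) and their conjunction `retained`.
#' Variants absent from the allele-frequency table get `passed_af = NA`
#' and are never retained (logged).
#'
#' @param deleterious_table a `deleterious_table`.
#' @param af_table allele-frequency table of the study cohort
#'   ([allele_frequencies()] output).
#' @param ctet_catalog a `ctet_catalog` restricted to the drug list.
#' @param drugs a `drug_list`; only these drugs' CTET genes count.
#' @param af_threshold retain only `af > af_threshold` (strict; default
#'   0.01).
#' @return data frame, one row per input variant: `variant_id`, `gene`,
#'   `damaging_votes`, `af`, `passed_class`, `passed_gene`,
#'   `passed_votes`, `passed_af`, `retained`.
#' @export
filter_candidates <- function(deleterious_table, af_table, ctet_catalog,
                              drugs, af_threshold = 0.01) {
  stopifnot(af_threshold >= 0, af_threshold < 1)
  cat_genes <- unique(ctet_catalog$gene[ctet_catalog$drug %in% drugs$name])
  votes <- is_deleterious(deleterious_table$sift,
                          deleterious_table$polyphen,
                          deleterious_table$mutation_taster)
  af <- af_table$af[match(deleterious_table$variant_id,
                          af_table$allele_id)]
  n_noaf <- sum(is.na(af))
  if (n_noaf) {
    log_warn("filter_candidates: ", n_noaf,
             " variant(s) missing from the AF table (not retained)")
  }
  passed_class <- deleterious_table$functional_class ==
    "nonsynonymous_exonic"
  passed_gene <- deleterious_table$gene %in% cat_genes
  passed_votes <- votes$deleterious
  passed_af <- af > af_threshold            # NA where af unknown
  retained <- passed_class & passed_gene & passed_votes &
    !is.na(passed_af) & passed_af
  data.frame(variant_id = deleterious_table$variant_id,
             gene = deleterious_table$gene,
             damaging_votes = votes$votes, af = af,
             passed_class = passed_class, passed_gene = passed_gene,
             passed_votes = passed_votes, passed_af = passed_af,
             retained = retained,
             stringsAsFactors = FALSE, row.names = NULL)
}
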