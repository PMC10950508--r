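## The DDI predictive model. Each drug is encoded as binary vectors over
## ordered element universes built from the analyzed drug set: one vector
## per CTET role (carrier, transporter, enzyme, target) plus a hybrid
## vector over all roles. Similarity between two drugs is Russell-Rao:
## S = (positive matches) / d, the number of shared elements over the
## universe size. Drugs whose hybrid vector is all-zero are eliminated
## first; a surviving pair is a potential DDI iff its hybrid S > 0, i.e.
## iff the two drugs share at least one catalogued element. Because d is
## recomputed from the analyzed drug set, S values are universe-relative;
## the S > 0 call is not (adding unrelated drugs rescales S but never
## flips a positive match to zero).

#' Build an ordered element universe
#'
#' For a single role: the union of that role's genes across the drug set,
#' deduplicated and lexicographically ordered. For the hybrid type: the
#' concatenation of the four role universes (carrier, transporter,
#' enzyme, target order), keyed by `(role, gene)` — a gene serving two
#' roles contributes two elements, so hybrid matches decompose over
#' roles. The alternative gene-only keying collapses roles before
#' building the universe (`hybrid_keying = "gene"`).
#'
#' @param catalog a `ctet_catalog`.
#' @param drugs character vector of drug names defining the analysis set.
#' @param vector_type one of `carrier`, `transporter`, `enzyme`,
#'   `target`, `hybrid`.
#' @param hybrid_keying `"role_gene"` (default) or `"gene"`.
#' @return character vector of element keys (`gene` for single roles,
#'   `role:gene` for the hybrid), length `d`; may be empty.
#' @export
build_universe <- function(catalog, drugs, vector_type,
                           hybrid_keying = c("role_gene", "gene")) {
  hybrid_keying <- match.arg(hybrid_keying)
  check_vocab(vector_type, c(ctet_roles(), "hybrid"), "vector type")
  sub <- catalog[catalog$drug %in% drugs, , drop = FALSE]
  if (vector_type != "hybrid") {
    return(sort(unique(sub$gene[sub$role == vector_type])))
  }
  if (hybrid_keying == "gene") return(sort(unique(sub$gene)))
  unlist(lapply(ctet_roles(), function(r) {
    g <- sort(unique(sub$gene[sub$role == r]))
    if (length(g)) paste(r, g, sep = ":") else character(0)
  }), use.names = FALSE)
}

#' Build one drug's binary vector over a universe
#'
#' @param drug drug name.
#' @param universe element universe from [build_universe()].
#' @param catalog a `ctet_catalog`.
#' @param vector_type the type the universe was built for.
#' @param hybrid_keying keying used for a hybrid universe.
#' @return integer 0/1 vector of length `length(universe)`, named by
#'   element.
#' @export
build_vector <- function(drug, universe, catalog, vector_type,
                         hybrid_keying = c("role_gene", "gene")) {
  hybrid_keying <- match.arg(hybrid_keying)
  sub <- catalog[catalog$drug == drug, , drop = FALSE]
  keys <- if (vector_type == "hybrid") {
    if (hybrid_keying == "gene") unique(sub$gene)
    else unique(paste(sub$role, sub$gene, sep = ":"))
  } else unique(sub$gene[sub$role == vector_type])
  stats::setNames(as.integer(universe %in% keys), universe)
}

## All drugs' vectors as a drugs x d binary matrix.
vector_matrix <- function(drugs, universe, catalog, vector_type,
                          hybrid_keying = "role_gene") {
  rows <- lapply(drugs, build_vector, universe = universe,
                 catalog = catalog, vector_type = vector_type,
                 hybrid_keying = hybrid_keying)
  matrix(unlist(rows, use.names = FALSE), nrow = length(drugs),
         ncol = length(universe), byrow = TRUE,
         dimnames = list(drugs, universe))
}

#' Drop drugs with all-zero vectors
#'
#' @param vectors binary matrix (drugs x d).
#' @return list: `kept` (matrix restricted to drugs with at least one
#'   element), `dropped` (character vector of eliminated drug names).
#' @export
eliminate_zero_vectors <- function(vectors) {
  pop <- rowSums(vectors)
  dropped <- rownames(vectors)[pop == 0]
  if (length(dropped)) {
    log_info("eliminate_zero_vectors: dropped ", length(dropped),
             " zero-vector drug(s): ",
             paste(utils::head(dropped, 10), collapse = ", "))
  }
  list(kept = vectors[pop > 0, , drop = FALSE], dropped = dropped)
}

#' Russell-Rao similarity of two binary vectors
#'
#' `S = x^t y / d`: the count of positions where both vectors are 1,
#' divided by the vector length.
#'
#' @param x,y equal-length binary vectors.
#' @return S in `[0, 1]`.
#' @export
russell_rao <- function(x, y) {
  if (length(x) != length(y)) {
    stop("russell_rao: vectors differ in length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) == 0) stop("russell_rao: empty universe (d = 0)",
                           call. = FALSE)
  sum(x == 1L & y == 1L) / length(x)
}

#' Score all drug pairs and call potential DDIs
#'
#' Builds the five vector types over the analyzed drug set, eliminates
#' drugs with all-zero hybrid vectors, computes Russell-Rao similarity
#' for every unordered pair of surviving drugs on every type, and flags a
#' pair as a potential DDI iff its hybrid similarity exceeds 0. Per-type
#' similarities are `NA` where that role's universe is empty (similarity
#' is undefined at d = 0, which is a reporting outcome, not an error).
#'
#' @param drugs character vector of drug names (or a `drug_list`).
#' @param catalog a `ctet_catalog`.
#' @param hybrid_keying `"role_gene"` (default) or `"gene"`; under
#'   gene-only keying a gene shared through different roles still
#'   matches.
#' @return data frame, one row per unordered pair of surviving drugs
#'   (sorted): `drug_a`, `drug_b`, `S_carrier`, `S_transporter`,
#'   `S_enzyme`, `S_target`, `positive_matches` (hybrid), `S_hybrid`,
#'   `is_ddi`. Attributes: `"dropped"` (zero-vector drugs), `"d"` (named
#'   universe sizes).
#' @export
detect_ddis <- function(drugs, catalog,
                        hybrid_keying = c("role_gene", "gene")) {
  hybrid_keying <- match.arg(hybrid_keying)
  if (inherits(drugs, "drug_list")) drugs <- drugs$name
  empty <- data.frame(drug_a = character(0), drug_b = character(0),
                      S_carrier = numeric(0), S_transporter = numeric(0),
                      S_enzyme = numeric(0), S_target = numeric(0),
                      positive_matches = integer(0), S_hybrid = numeric(0),
                      is_ddi = logical(0), stringsAsFactors = FALSE)
  uni_h <- build_universe(catalog, drugs, "hybrid", hybrid_keying)
  vec_h <- vector_matrix(drugs, uni_h, catalog, "hybrid", hybrid_keying)
  elim <- eliminate_zero_vectors(vec_h)
  surv <- sort(rownames(elim$kept))
  if (length(surv) < 2) {
    log_info("detect_ddis: fewer than 2 drugs survive zero-vector ",
             "elimination; no pairs to score")
    attr(empty, "dropped") <- elim$dropped
    return(empty)
  }
  types <- ctet_roles()
  unis <- lapply(stats::setNames(types, types), build_universe,
                 catalog = catalog, drugs = surv)
  unis$hybrid <- build_universe(catalog, surv, "hybrid", hybrid_keying)
  vecs <- lapply(stats::setNames(names(unis), names(unis)), function(tp) {
    vector_matrix(surv, unis[[tp]], catalog, tp, hybrid_keying)
  })
  pairs <- utils::combn(surv, 2)
  score <- function(tp, i, j) {
    if (length(unis[[tp]]) == 0) return(NA_real_)
    russell_rao(vecs[[tp]][i, ], vecs[[tp]][j, ])
  }
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    pm <- sum(vecs$hybrid[a, ] == 1L & vecs$hybrid[b, ] == 1L)
    s_h <- pm / length(unis$hybrid)
    data.frame(drug_a = a, drug_b = b,
               S_carrier = score("carrier", a, b),
               S_transporter = score("transporter", a, b),
               S_enzyme = score("enzyme", a, b),
               S_target = score("target", a, b),
               positive_matches = as.integer(pm), S_hybrid = s_h,
               is_ddi = s_h > 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- elim$dropped
  attr(out, "d") <- vapply(unis, length, integer(1))
  out
}

#' Count potential DDI pairs at regimen level
#'
#' Counts distinct unordered DDI pairs over the union of one or two
#' regimens (drug sets). With two regimens the union count decomposes as
#' `union = within_a + within_b + cross`: a pair is within-A if both
#' drugs are in regimen A, within-B if both are in B and not both in A,
#' and cross otherwise. Drugs present in both regimens are counted once.
#'
#' @param regimen_a character vector of drug names.
#' @param regimen_b optional second regimen.
#' @param catalog a `ctet_catalog`.
#' @param hybrid_keying passed to [detect_ddis()].
#' @return list of class `"regimen_ddi_count"`: `regimen_a`, `regimen_b`
#'   (label or `NA`), `n_drugs_after_elimination`, `within_a`,
#'   `within_b`, `cross`, `union`, `pairs` (the DDI pair data frame with
#'   a `class` column).
#' @export
count_regimen_ddis <- function(regimen_a, regimen_b = NULL, catalog,
                               hybrid_keying = "role_gene") {
  all_drugs <- unique(c(regimen_a, regimen_b))
  res <- detect_ddis(all_drugs, catalog, hybrid_keying)
  ddi <- res[res$is_ddi, , drop = FALSE]
  in_a <- ddi$drug_a %in% regimen_a & ddi$drug_b %in% regimen_a
  in_b <- !is.null(regimen_b) &
    ddi$drug_a %in% regimen_b & ddi$drug_b %in% regimen_b
  cls <- ifelse(in_a, "within_a", ifelse(in_b, "within_b", "cross"))
  ddi$class <- if (nrow(ddi)) cls else character(0)
  structure(list(
    n_drugs_after_elimination = length(all_drugs) -
      length(attr(res, "dropped")),
    within_a = sum(cls == "within_a"),
    within_b = sum(cls == "within_b"),
    cross = sum(cls == "cross"),
    union = nrow(ddi),
    pairs = ddi), class = "regimen_ddi_count")
}

#' @export
print.regimen_ddi_count <- function(x, ...) {
  cat(sprintf(
    "regimen DDI count: union %d = within_a %d + within_b %d + cross %d (%d drugs after elimination)\n",
    x$union, x$within_a, x$within_b, x$cross,
    x$n_drugs_after_elimination))
  invisible(x)
}

#' Drug-gene bipartite network
#'
#' Nodes are drugs and genes (roles collapsed onto edge attributes); the
#' degree of a gene is the number of distinct drugs linked to it, the
#' degree of a drug the number of distinct genes in its pathways — the
#' quantities a network view scales its labels by.
#'
#' @param catalog a `ctet_catalog`.
#' @param drugs character vector of drug names (or `drug_list`).
#' @return list: `edges` (data frame `drug`, `gene`, `role`, one row per
#'   catalog triple), `nodes` (data frame `name`, `kind`
#'   (`drug`/`gene`), `degree`), and `graph` (an [igraph::graph] with a
#'   `type` vertex attribute, for GraphML export or layout).
#' @export
build_drug_gene_network <- function(catalog, drugs) {
  if (inherits(drugs, "drug_list")) drugs <- drugs$name
  sub <- catalog[catalog$drug %in% drugs, , drop = FALSE]
  edges <- sub[order(sub$drug, sub$gene, sub$role),
               c("drug", "role", "gene"), drop = FALSE]
  rownames(edges) <- NULL
  uniq <- unique(edges[, c("drug", "gene")])
  drug_deg <- table(factor(uniq$drug, levels = sort(unique(uniq$drug))))
  gene_deg <- table(factor(uniq$gene, levels = sort(unique(uniq$gene))))
  nodes <- rbind(
    data.frame(name = names(drug_deg), kind = "drug",
               degree = as.integer(drug_deg), stringsAsFactors = FALSE),
    data.frame(name = names(gene_deg), kind = "gene",
               degree = as.integer(gene_deg), stringsAsFactors = FALSE))
  rownames(nodes) <- NULL
  g <- if (nrow(uniq)) {
    gg <- igraph::graph_from_data_frame(
      uniq, directed = FALSE,
      vertices = data.frame(name = nodes$name, kind = nodes$kind))
    igraph::V(gg)$type <- igraph::V(gg)$kind == "gene"
    gg
  } else igraph::make_empty_graph(directed = FALSE)
  list(edges = edges[, c("drug", "gene", "role")], nodes = nodes,
       graph = g)
}
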