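## Readers and writers for the non-genotype inputs: drug lists, clinical
## annotations (PharmGKB-style), CTET catalogs (DrugBank-style role-typed
## drug-gene links), deleteriousness predictions, diplotype calls and
## regimen definitions. All files are tab-delimited UTF-8 with a header;
## within-cell lists are semicolon-separated. Every reader validates its
## closed vocabularies hard (unknown token = error naming the row) and
## logs, never silences, dropped records.

# ---- drug lists -----------------------------------------------------------

#' Read a drug list
#'
#' A drug list is a two-column TSV (`name`, `groups`) where `groups` is a
#' semicolon-separated set of therapeutic group tags drawn from the closed
#' vocabulary (COVID-19 treatment groups, post-COVID condition groups and
#' comorbidity groups; see [vocabularies]). A drug may carry several tags.
#'
#' @param path path to `drugs.tsv`.
#' @return a data frame with columns `name` and `groups` (semicolon-joined),
#'   class `"drug_list"`, input order preserved.
#' @export
read_drug_list <- function(path) {
  raw <- read_tsv_file(path)
  if (!all(c("name", "groups") %in% names(raw))) {
    stop("drug list must have columns 'name' and 'groups'", call. = FALSE)
  }
  as_drug_list(raw[, c("name", "groups")])
}

#' Construct a validated drug list
#'
#' @param df data frame with `name` and `groups` columns.
#' @return the validated `drug_list`.
#' @export
as_drug_list <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    if (any(!nzchar(df$name))) {
      stop("empty drug name (row ", which(!nzchar(df$name))[1L], ")",
           call. = FALSE)
    }
    dup <- duplicated(df$name)
    if (any(dup)) {
      stop("duplicate drug name '", df$name[which(dup)[1L]], "' (row ",
           which(dup)[1L], ")", call. = FALSE)
    }
    toks <- strsplit(df$groups, ";", fixed = TRUE)
    rows <- rep(seq_len(nrow(df)), lengths(toks))
    check_vocab(unlist(toks), drug_group_levels(), "drug group", rows)
  }
  rownames(df) <- NULL
  structure(df, class = c("drug_list", "data.frame"))
}

#' @rdname read_drug_list
#' @param drugs a `drug_list`.
#' @export
write_drug_list <- function(drugs, path) {
  write_tsv_file(as.data.frame(drugs)[, c("name", "groups")], path)
}

#' Drugs carrying a given group tag
#'
#' @param drugs a `drug_list`.
#' @param group one tag from the group vocabulary.
#' @return character vector of drug names, in list order.
#' @export
drugs_in_group <- function(drugs, group) {
  check_vocab(group, drug_group_levels(), "drug group")
  hit <- vapply(strsplit(drugs$groups, ";", fixed = TRUE),
                function(g) group %in% g, logical(1))
  drugs$name[hit]
}

# ---- clinical annotations -------------------------------------------------

infer_allele_type <- function(allele_id) {
  ifelse(grepl("^rs[0-9]+$", allele_id), "snp",
    ifelse(grepl("^HLA-", allele_id), "hla",
      ifelse(grepl("^[A-Za-z0-9]+\\*", allele_id), "star", NA_character_)))
}

#' Read clinical annotations
#'
#' Each record links a variant or named allele (rsID, star allele such as
#' `CYP2C19*2`, or HLA allele such as `HLA-B*15:02`) to a drug with a
#' PharmGKB-style evidence level (1A strongest to 4 weakest), a risk allele
#' and a phenotype category. The allele type is inferred from identifier
#' syntax (`rs` prefix = snp, `HLA-` prefix = hla, gene-prefixed `*` name =
#' star); an explicit `allele_type` column, when present, must agree or
#' loading fails. Records for drugs absent from `drug_list` are dropped
#' with a logged count; duplicates are removed so that each
#' `(allele_id, drug)` pair keeps its single strongest-level record.
#'
#' @param path path to `clinical_annotations.tsv` with columns `allele_id`,
#'   `gene`, `drug`, `level`, `risk_allele`, `phenotype_category` and
#'   optionally `allele_type`.
#' @param drug_list a `drug_list`; annotations are restricted to it.
#' @return data frame of annotations, class `"clinical_annotations"`.
#' @export
read_clinical_annotations <- function(path, drug_list) {
  raw <- read_tsv_file(path)
  need <- c("allele_id", "gene", "drug", "level", "risk_allele",
            "phenotype_category")
  if (!all(need %in% names(raw))) {
    stop("clinical annotation file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if ("allele_type" %in% names(raw)) {
    inferred <- infer_allele_type(raw$allele_id)
    bad <- nzchar(raw$allele_type) & raw$allele_type != inferred
    if (any(bad)) {
      i <- which(bad)[1L]
      stop("allele_type '", raw$allele_type[i], "' disagrees with ",
           "identifier syntax of '", raw$allele_id[i], "' (row ", i, ")",
           call. = FALSE)
    }
  }
  as_clinical_annotations(raw[, need], drug_list)
}

#' @rdname read_clinical_annotations
#' @param df data frame of raw annotation rows.
#' @export
as_clinical_annotations <- function(df, drug_list = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    check_vocab(df$level, annotation_levels(), "evidence level")
    check_vocab(df$phenotype_category, phenotype_categories(),
                "phenotype category")
    df$allele_type <- infer_allele_type(df$allele_id)
    if (anyNA(df$allele_type)) {
      i <- which(is.na(df$allele_type))[1L]
      stop("cannot infer allele type from '", df$allele_id[i], "' (row ",
           i, ")", call. = FALSE)
    }
    bad_snp <- df$allele_type == "snp" &
      !grepl("^[ACGT]$", df$risk_allele)
    if (any(bad_snp)) {
      i <- which(bad_snp)[1L]
      stop("snp record must carry a nucleotide risk allele, got '",
           df$risk_allele[i], "' (row ", i, ")", call. = FALSE)
    }
    df$gene <- toupper(df$gene)
    if (!is.null(drug_list)) {
      keep <- df$drug %in% drug_list$name
      if (any(!keep)) {
        log_info("clinical annotations: dropped ", sum(!keep),
                 " record(s) for drugs outside the active drug list")
        df <- df[keep, , drop = FALSE]
      }
    }
    # exact duplicates first, then one record per (allele_id, drug):
    # keep the strongest evidence level, ties broken by input order
    n0 <- nrow(df)
    df <- df[!duplicated(df), , drop = FALSE]
    lev <- match(df$level, annotation_levels())
    ord <- order(match(paste(df$allele_id, df$drug), # stable
                       unique(paste(df$allele_id, df$drug))), lev)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df[, c("allele_id", "drug")]), , drop = FALSE]
    if (nrow(df) < n0) {
      log_info("clinical annotations: removed ", n0 - nrow(df),
               " duplicate record(s)")
    }
  } else {
    df$allele_type <- character(0)
  }
  rownames(df) <- NULL
  df <- df[, c("allele_id", "allele_type", "gene", "drug", "level",
               "risk_allele", "phenotype_category")]
  structure(df, class = c("clinical_annotations", "data.frame"))
}

#' @rdname read_clinical_annotations
#' @param annotations a `clinical_annotations` table.
#' @export
write_clinical_annotations <- function(annotations, path) {
  write_tsv_file(as.data.frame(annotations), path)
}

# ---- CTET catalog ---------------------------------------------------------

#' Read a CTET catalog
#'
#' The catalog maps each drug to role-typed gene sets: the carrier,
#' transporter, metabolic enzyme and target (CTET) proteins of its
#' pharmacokinetic/pharmacodynamic pathways, one `(drug, role, gene)`
#' triple per row. Duplicated triples are removed, gene symbols are
#' upper-cased and drugs outside `drug_list` are dropped with a logged
#' count. A drug present in the list but absent from the catalog is a
#' legitimate zero-vector candidate downstream.
#'
#' @param path path to `ctet_catalog.tsv` with columns `drug`, `role`,
#'   `gene`.
#' @param drug_list a `drug_list`.
#' @return data frame with class `"ctet_catalog"`.
#' @export
read_ctet_catalog <- function(path, drug_list) {
  raw <- read_tsv_file(path)
  if (!all(c("drug", "role", "gene") %in% names(raw))) {
    stop("CTET catalog must have columns drug, role, gene", call. = FALSE)
  }
  as_ctet_catalog(raw[, c("drug", "role", "gene")], drug_list)
}

#' @rdname read_ctet_catalog
#' @param df data frame of raw catalog rows.
#' @export
as_ctet_catalog <- function(df, drug_list = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    check_vocab(df$role, ctet_roles(), "CTET role")
    df$gene <- toupper(df$gene)
    if (!is.null(drug_list)) {
      keep <- df$drug %in% drug_list$name
      if (any(!keep)) {
        log_info("CTET catalog: dropped ", sum(!keep),
                 " row(s) for drugs outside the active drug list")
        df <- df[keep, , drop = FALSE]
      }
    }
    n0 <- nrow(df)
    df <- df[!duplicated(df), , drop = FALSE]
    if (nrow(df) < n0) {
      log_info("CTET catalog: removed ", n0 - nrow(df),
               " duplicated element(s)")
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("ctet_catalog", "data.frame"))
}

#' @rdname read_ctet_catalog
#' @param catalog a `ctet_catalog`.
#' @export
write_ctet_catalog <- function(catalog, path) {
  write_tsv_file(as.data.frame(catalog), path)
}

# ---- deleteriousness predictions ------------------------------------------

#' Read deleteriousness predictions
#'
#' One row per variant with the categorical calls of three predictors:
#' SIFT (`damaging`/`tolerated`), PolyPhen-2
#' (`probably_damaging`/`damaging`/`benign`) and MutationTaster
#' (`disease_causing`/`polymorphism`). A `missing` value means the tool
#' made no call and abstains from the deleteriousness vote.
#' `functional_class` separates nonsynonymous exonic variants from all
#' others.
#'
#' @param path path to `deleterious.tsv` with columns `variant_id`, `gene`,
#'   `functional_class`, `sift`, `polyphen`, `mutation_taster`.
#' @return data frame with class `"deleterious_table"`.
#' @export
read_deleterious <- function(path) {
  raw <- read_tsv_file(path)
  need <- c("variant_id", "gene", "functional_class", "sift", "polyphen",
            "mutation_taster")
  if (!all(need %in% names(raw))) {
    stop("deleteriousness table must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df <- raw[, need]
  check_vocab(df$functional_class, c("nonsynonymous_exonic", "other"),
              "functional class")
  check_vocab(df$sift, c("damaging", "tolerated", "missing"), "SIFT call")
  check_vocab(df$polyphen,
              c("probably_damaging", "damaging", "benign", "missing"),
              "PolyPhen-2 call")
  check_vocab(df$mutation_taster,
              c("disease_causing", "polymorphism", "missing"),
              "MutationTaster call")
  df$gene <- toupper(df$gene)
  rownames(df) <- NULL
  structure(df, class = c("deleterious_table", "data.frame"))
}

#' @rdname read_deleterious
#' @param x a `deleterious_table`.
#' @export
write_deleterious <- function(x, path) write_tsv_file(as.data.frame(x), path)

# ---- diplotype calls ------------------------------------------------------

#' Read diplotype calls
#'
#' Star-allele and HLA calls: exactly one row per `(sample, gene)` with the
#' two called alleles (e.g. `CYP2C19*1` / `CYP2C19*2`). These are consumed
#' as upstream caller output; no calling happens here.
#'
#' @param path path to `diplotypes.tsv` with columns `sample_id`, `gene`,
#'   `allele1`, `allele2`.
#' @return data frame with class `"diplotype_calls"`.
#' @export
read_diplotypes <- function(path) {
  raw <- read_tsv_file(path)
  need <- c("sample_id", "gene", "allele1", "allele2")
  if (!all(need %in% names(raw))) {
    stop("diplotype table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- raw[, need]
  df$gene <- toupper(df$gene)
  key <- paste(df$sample_id, df$gene)
  if (anyDuplicated(key)) {
    stop("more than one diplotype call for sample/gene '",
         key[which(duplicated(key))[1L]], "'", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("diplotype_calls", "data.frame"))
}

#' @rdname read_diplotypes
#' @param x a `diplotype_calls` table.
#' @export
write_diplotypes <- function(x, path) write_tsv_file(as.data.frame(x), path)

# ---- regimens -------------------------------------------------------------

#' Read regimen definitions
#'
#' A regimen is a named, ordered set of co-administered drugs (e.g. the
#' COVID-19 treatment list, or the maintenance drugs of a comorbidity).
#' Every drug must resolve in the active drug list.
#'
#' @param path path to `regimens.tsv` with columns `name` and `drugs`
#'   (semicolon-separated, order preserved).
#' @param drug_list a `drug_list`.
#' @return named list of character vectors, class `"regimen_set"`.
#' @export
read_regimens <- function(path, drug_list) {
  raw <- read_tsv_file(path)
  if (!all(c("name", "drugs") %in% names(raw))) {
    stop("regimen file must have columns name, drugs", call. = FALSE)
  }
  regs <- lapply(strsplit(raw$drugs, ";", fixed = TRUE), unique)
  names(regs) <- raw$name
  for (i in seq_along(regs)) {
    if (length(regs[[i]]) == 0) {
      stop("regimen '", names(regs)[i], "' is empty", call. = FALSE)
    }
    miss <- setdiff(regs[[i]], drug_list$name)
    if (length(miss)) {
      stop("regimen '", names(regs)[i], "' references unknown drug(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  structure(regs, class = "regimen_set")
}

#' @rdname read_regimens
#' @param regimens a `regimen_set` (named list of drug-name vectors).
#' @export
write_regimens <- function(regimens, path) {
  df <- data.frame(
    name = names(regimens),
    drugs = vapply(regimens, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}
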