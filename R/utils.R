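#' @keywords internal
"_PACKAGE"

## Closed vocabularies shared across readers and simulators.

#' Controlled vocabularies
#'
#' Closed token sets used throughout the pipeline: therapeutic group tags,
#' clinical-annotation evidence levels, CTET roles, phenotype categories and
#' the categorical calls of the three deleteriousness predictors.
#'
#' @name vocabularies
#' @keywords internal
NULL

drug_group_levels <- function() {
  c("cause_treatment", "corticoid", "antithrombotic", "superinfection",
    "post_covid_fatigue", "post_covid_respiratory",
    "post_covid_cardiovascular", "post_covid_mental",
    "comorbidity_t2d", "comorbidity_cvd", "comorbidity_cancer")
}

annotation_levels <- function() c("1A", "1B", "2A", "2B", "3", "4")

ctet_roles <- function() c("carrier", "transporter", "enzyme", "target")

phenotype_categories <- function() {
  c("efficacy", "toxicity", "dosage", "metabolism", "other")
}

allele_types <- function() c("snp", "star", "hla")

#' Evaluate an expression with a local, named random seed
#'
#' All stochastic operations in the package draw their randomness from one
#' explicit integer seed through this helper; the caller's RNG state is
#' saved and restored, so no global state leaks in or out.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

## Leveled logging. Messages go to stderr via message(); run_pipeline()
## additionally collects them into the bundle's run log. No timestamps, so
## logs are byte-stable across runs.
pgx_log <- function(level, ...) {
  line <- paste0("[", level, "] ", paste0(..., collapse = ""))
  collector <- getOption("pgxddi.log_collector", NULL)
  if (!is.null(collector)) collector$lines <- c(collector$lines, line)
  message(line)
  invisible(line)
}

log_info <- function(...) pgx_log("INFO", ...)
log_warn <- function(...) pgx_log("WARN", ...)

#' Read and write tab-separated tables
#'
#' All tabular artifacts are UTF-8, tab-delimited text with a header row;
#' list-valued cells are semicolon-separated. Writing is deterministic
#' (fixed quoting, no row names) so identical inputs give identical bytes.
#'
#' @param path file path.
#' @param x data frame to write.
#' @return `read_tsv_file()` returns a data frame of character columns.
#' @keywords internal
read_tsv_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "", comment.char = "",
                    fileEncoding = "UTF-8")
}

write_tsv_file <- function(x, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "",
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

## Vocabulary check with row context for hard errors on unknown tokens.
check_vocab <- function(values, vocab, what, rows = seq_along(values)) {
  bad <- !(values %in% vocab)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("unknown ", what, " '", values[i], "' (row ", rows[i], "); ",
         "allowed: ", paste(vocab, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

## Canonical unordered drug-pair key, used wherever pairs are compared.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\x1f")
}
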