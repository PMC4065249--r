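#' @importFrom data.table data.table as.data.table setorder setnames := .N .SD
NULL

#' Drug conditions recognized by the pipeline
#'
#' The screen design uses one untreated control (`UNT`) and three
#' DNA-damaging agents: camptothecin (`CPT`), hydroxyurea (`HU`) and methyl
#' methanesulfonate (`MMS`).
#' @export
CEMAP_DRUGS <- c("CPT", "HU", "MMS")

#' @rdname CEMAP_DRUGS
#' @export
CEMAP_CONDITIONS <- c("UNT", CEMAP_DRUGS)

#' Canonicalize gene identifiers
#'
#' Gene symbols and systematic names are compared case-insensitively and
#' stored uppercase. Empty names or names containing whitespace are invalid.
#'
#' @param x character vector of gene names.
#' @return uppercase character vector of the same length.
#' @export
canonical_gene <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(is.na(x) | !nzchar(x))) {
    stop("gene names must be non-empty", call. = FALSE)
  }
  if (any(grepl("\\s", x))) {
    stop("gene names must not contain whitespace: ",
         paste(unique(x[grepl("\\s", x)]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Replicate-level screen container
#'
#' A `screen_tensor` holds S-scores indexed by (query gene, array gene,
#' condition, replicate). Conditions are a drug plus an optional
#' concentration label; the untreated control carries no concentration.
#' Missing measurements are kept as `NA`, never imputed.
#'
#' @param scores data.frame with columns `query`, `array`, `drug`,
#'   `concentration`, `replicate`, `score`. `concentration` is `NA` for
#'   untreated rows; `score` may be `NA` (missing cell) but not infinite.
#' @return an object of class `screen_tensor` with elements `scores`
#'   (a data.table), `queries`, `arrays` and `conditions`.
#' @export
screen_tensor <- function(scores) {
  need <- c("query", "array", "drug", "concentration", "replicate", "score")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    stop("score table lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dt <- as.data.table(scores)[, need, with = FALSE]
  dt[, query := canonical_gene(query)]
  dt[, array := canonical_gene(array)]
  dt[, drug := toupper(trimws(as.character(drug)))]
  bad <- setdiff(unique(dt$drug), CEMAP_CONDITIONS)
  if (length(bad)) {
    stop("unknown drug condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dt[, concentration := as.character(concentration)]
  dt[drug == "UNT", concentration := NA_character_]
  dt[, replicate := as.integer(replicate)]
  dt[, score := as.numeric(score)]
  if (any(is.infinite(dt$score), na.rm = TRUE)) {
    stop("scores must be finite or missing", call. = FALSE)
  }
  if (anyNA(dt$replicate) || any(dt$replicate < 1L)) {
    stop("replicate indices must be positive integers", call. = FALSE)
  }
  key <- dt[, paste(query, array, drug, concentration, replicate, sep = "\r")]
  if (anyDuplicated(key)) {
    d <- dt[duplicated(key)][1L]
    stop(sprintf(
      "duplicate record for (%s, %s, %s%s, replicate %d)",
      d$query, d$array, d$drug,
      ifelse(is.na(d$concentration), "", paste0("@", d$concentration)),
      d$replicate), call. = FALSE)
  }
  if (!any(dt$drug == "UNT")) {
    stop("screen must contain at least one untreated (UNT) condition",
         call. = FALSE)
  }
  setorder(dt, query, array, drug, concentration, replicate, na.last = FALSE)
  conds <- unique(dt[, list(drug, concentration)])
  setorder(conds, drug, concentration, na.last = FALSE)
  structure(
    list(scores = dt,
         queries = unique(dt$query),
         arrays = sort(unique(dt$array)),
         conditions = as.data.frame(conds)),
    class = "screen_tensor")
}

#' @export
print.screen_tensor <- function(x, ...) {
  cat(sprintf(
    "screen_tensor: %d queries x %d array genes, %d conditions, %d rows (%d missing)\n",
    length(x$queries), length(x$arrays), nrow(x$conditions),
    nrow(x$scores), sum(is.na(x$scores$score))))
  invisible(x)
}

condition_label <- function(drug, concentration) {
  ifelse(is.na(concentration), drug, paste0(drug, "@", concentration))
}
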