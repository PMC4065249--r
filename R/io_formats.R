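#' Read a long-format replicate-level score table
#'
#' The canonical exchange format is tab-delimited with one row per measured
#' replicate: query gene, array gene, drug, concentration label, replicate
#' index and S-score. An empty or `NA` score field records a missing cell;
#' any other non-numeric score is a row-level error. Column names in the
#' file may differ from the canonical ones via `dialect`.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect named character vector mapping canonical column names
#'   (`query`, `array`, `drug`, `concentration`, `replicate`, `score`) to
#'   the names used in the file. Unmentioned columns keep their canonical
#'   name.
#' @return a [screen_tensor()].
#' @export
read_scores_long <- function(path, dialect = NULL) {
  cols <- c(query = "query", array = "array", drug = "drug",
            concentration = "concentration", replicate = "replicate",
            score = "score")
  if (!is.null(dialect)) {
    unknown <- setdiff(names(dialect), names(cols))
    if (length(unknown)) {
      stop("dialect maps unknown column(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cols[names(dialect)] <- dialect
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  miss <- setdiff(unname(cols), names(dt))
  if (length(miss)) {
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  dt <- dt[, unname(cols), with = FALSE]
  setnames(dt, unname(cols), names(cols))
  raw <- trimws(dt$score)
  empty <- !nzchar(raw) | toupper(raw) %in% c("NA", "NAN")
  val <- suppressWarnings(as.numeric(raw))
  bad <- which(!empty & is.na(val))
  if (length(bad)) {
    stop(sprintf("non-numeric score '%s' on line %d of %s",
                 raw[bad[1L]], bad[1L] + 1L, path), call. = FALSE)
  }
  val[empty] <- NA_real_
  dt[, score := val]
  dt[!nzchar(trimws(concentration)) | toupper(trimws(concentration)) == "NA",
     concentration := NA_character_]
  screen_tensor(dt)
}

#' Write a screen in the canonical long format
#'
#' Missing scores are written as empty fields; [read_scores_long()] on the
#' result reconstructs the same tensor.
#'
#' @param tensor a [screen_tensor()].
#' @param path output path.
#' @export
write_scores_long <- function(tensor, path) {
  stopifnot(inherits(tensor, "screen_tensor"))
  data.table::fwrite(tensor$scores, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' Construct a set of conditional interaction calls
#'
#' @param query,array gene names.
#' @param drug drug condition; never `UNT` (a call is by definition
#'   conditional on a drug).
#' @param direction `"positive"` or `"negative"`.
#' @param q optional q-value per call (`NA` for calls transcribed from a
#'   printed table).
#' @return data.frame of class `interaction_calls`.
#' @export
interaction_calls <- function(query, array, drug, direction,
                              q = NA_real_) {
  drug <- toupper(trimws(as.character(drug)))
  bad <- setdiff(unique(drug), CEMAP_DRUGS)
  if (length(bad)) {
    stop("interaction calls must name a drug condition, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  direction <- tolower(trimws(as.character(direction)))
  if (!all(direction %in% c("positive", "negative"))) {
    stop("direction must be 'positive' or 'negative'", call. = FALSE)
  }
  out <- data.frame(query = if (length(query)) canonical_gene(query)
                            else character(),
                    array = if (length(array)) canonical_gene(array)
                            else character(),
                    drug = drug, direction = direction,
                    q = rep_len(as.numeric(q), length(query)),
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_calls", "data.frame")
  out
}

#' Read a transcribed significant-interaction table
#'
#' Reads the packaged transcription of the published table of significant
#' conditional interactions (and any file in the same layout): tab-delimited
#' with columns `query`, `drug`, `interaction` (Positive/Negative) and
#' `gene`, one row per called gene. Lines starting with `#` are comments.
#'
#' @param path path to the fixture; defaults to the packaged transcription.
#' @return an [interaction_calls()] object with `q = NA`.
#' @export
read_table1_fixture <- function(path = system.file(
    "extdata", "table1_conditional_interactions.tsv", package = "cemapr")) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  dt <- data.table::fread(text = paste(lines, collapse = "\n"),
                          sep = "\t", header = TRUE, colClasses = "character")
  need <- c("query", "drug", "interaction", "gene")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("fixture lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(dt) == 0L) {
    out <- interaction_calls(character(), character(), character(), character())
    return(out)
  }
  interaction_calls(dt$query, dt$gene, dt$drug, dt$interaction)
}

#' Annotation set for term enrichment
#'
#' @param terms named list mapping term identifiers to character vectors of
#'   gene names.
#' @param background character vector of background genes (the sampling
#'   frame). Annotated genes outside the background are dropped with a
#'   warning.
#' @return object of class `annotation_set` with elements `terms` and
#'   `background`.
#' @export
annotation_set <- function(terms, background) {
  background <- unique(canonical_gene(background))
  if (length(background) < 1L) stop("background is empty", call. = FALSE)
  terms <- lapply(terms, function(g) unique(canonical_gene(g)))
  outside <- unique(unlist(lapply(terms, setdiff, y = background)))
  if (length(outside)) {
    warning(length(outside), " annotated gene(s) absent from background ",
            "dropped: ", paste(utils::head(outside, 5L), collapse = ", "),
            if (length(outside) > 5L) ", ..." else "", call. = FALSE)
    terms <- lapply(terms, intersect, y = background)
  }
  structure(list(terms = terms, background = background),
            class = "annotation_set")
}

#' Read a term-to-gene annotation table
#'
#' @param path two-column tab-delimited file (term, gene), header optional
#'   but recommended (`term`, `gene`).
#' @param background either a character vector of genes or a path to a
#'   one-gene-per-line file; defaults to the union of annotated genes.
#' @return an [annotation_set()].
#' @export
read_annotations <- function(path, background = NULL) {
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          colClasses = "character")
  if (ncol(dt) < 2L) stop("annotation table needs two columns", call. = FALSE)
  term <- dt[[1L]]
  gene <- canonical_gene(dt[[2L]])
  if (is.null(background)) {
    background <- unique(gene)
  } else if (length(background) == 1L && file.exists(background)) {
    background <- readLines(background)
    background <- background[nzchar(trimws(background))]
  }
  annotation_set(split(gene, term), background)
}

#' Export a conditional interaction network
#'
#' `"sif"` writes one line per edge annotation, `query <TAB> DRUG_dir <TAB>
#' array`, readable by common graph viewers; `"edge-table"` writes a
#' tab-delimited table with columns query, array, drug, direction, q, which
#' [read_network_edges()] reads back to the identical edge set.
#'
#' @param network a `gene_network` from [build_network()].
#' @param path output path.
#' @param format `"sif"` or `"edge-table"`.
#' @export
write_network <- function(network, path, format = c("sif", "edge-table")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "gene_network"))
  e <- network$edges
  if (nrow(e) == 0L) {
    stop("refusing to write an empty network", call. = FALSE)
  }
  if (format == "sif") {
    rel <- paste0(e$drug, "_", ifelse(e$direction == "positive", "pos", "neg"))
    writeLines(paste(e$query, rel, e$array, sep = "\t"), path)
  } else {
    data.table::fwrite(e, path, sep = "\t", na = "NA", quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network_edges <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  interaction_calls(dt$query, dt$array, dt$drug, dt$direction,
                    q = if ("q" %in% names(dt)) dt$q else NA_real_)
}
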