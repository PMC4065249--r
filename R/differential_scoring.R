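#' Pool drug concentrations into one condition per drug
#'
#' In the screen design each drug is applied at two concentrations which
#' produce very similar profiles; pooling their replicate lists (3 + 3 -> 6
#' replicates per cell) improves the confidence of the per-cell mean
#' S-score. Replicate indices are re-numbered contiguously per pooled cell;
#' cells missing in one concentration contribute only their present
#' replicates. Untreated rows carrying batch labels are pooled the same way.
#'
#' @param tensor a [screen_tensor()].
#' @return a [screen_tensor()] with one condition per drug
#'   (concentration `NA`).
#' @export
merge_concentrations <- function(tensor) {
  stopifnot(inherits(tensor, "screen_tensor"))
  dt <- data.table::copy(tensor$scores)
  setorder(dt, query, array, drug, concentration, replicate, na.last = FALSE)
  dt[, replicate := seq_len(.N), by = list(query, array, drug)]
  dt[, concentration := NA_character_]
  screen_tensor(dt)
}

#' Per-cell mean S-scores
#'
#' Arithmetic mean over present replicates for every (query, condition,
#' array gene) cell, with the effective replicate count recorded. A cell
#' with no present replicate is missing (`NA`), never zero-filled.
#'
#' @param tensor a [screen_tensor()].
#' @return object of class `mean_score_matrix`: a profiles-by-arrays
#'   `score` matrix (row labels `QUERY|CONDITION`), a matching `n` matrix of
#'   replicate counts, profile metadata `meta`, and `arrays`.
#' @export
mean_scores <- function(tensor) {
  stopifnot(inherits(tensor, "screen_tensor"))
  dt <- tensor$scores
  agg <- dt[, list(mean = if (all(is.na(score))) NA_real_
                   else mean(score, na.rm = TRUE),
                   n = sum(!is.na(score))),
            by = list(query, drug, concentration, array)]
  agg[, label := paste(query, condition_label(drug, concentration), sep = "|")]
  labels <- unique(agg$label)
  arrays <- tensor$arrays
  score <- matrix(NA_real_, length(labels), length(arrays),
                  dimnames = list(labels, arrays))
  n <- matrix(0L, length(labels), length(arrays),
              dimnames = list(labels, arrays))
  score[cbind(agg$label, agg$array)] <- agg$mean
  n[cbind(agg$label, agg$array)] <- agg$n
  meta <- unique(agg[, list(label, query, drug, concentration)])
  structure(list(score = score, n = n, meta = as.data.frame(meta),
                 arrays = arrays),
            class = "mean_score_matrix")
}

profile_row <- function(means, query, drug) {
  hit <- means$meta$query == query & means$meta$drug == drug
  if (!any(hit)) return(NULL)
  if (sum(hit) > 1L) {
    stop("multiple conditions for ", query, "/", drug,
         "; run merge_concentrations() first", call. = FALSE)
  }
  means$score[means$meta$label[hit], ]
}

#' Differential S-scores for one query under one drug
#'
#' `D = S_drug - S_untreated` per array gene; missing wherever either
#' operand is missing.
#'
#' @param means a [mean_scores()] result (post concentration merge).
#' @param query query gene name.
#' @param drug one of `CPT`, `HU`, `MMS`.
#' @return named numeric vector of D over array genes.
#' @export
differential_scores <- function(means, query, drug) {
  stopifnot(inherits(means, "mean_score_matrix"))
  query <- canonical_gene(query)
  drug <- match.arg(toupper(drug), CEMAP_DRUGS)
  s_drug <- profile_row(means, query, drug)
  s_unt <- profile_row(means, query, "UNT")
  if (is.null(s_unt)) {
    stop("no untreated (UNT) profile for query ", query, call. = FALSE)
  }
  if (is.null(s_drug)) {
    stop("no ", drug, " profile for query ", query, call. = FALSE)
  }
  s_drug - s_unt
}

#' Standardize a differential-score vector to Z-scores
#'
#' Each score is centered by the mean and scaled by the sample standard
#' deviation (denominator n - 1) of the non-missing values in its batch.
#' Missing values propagate.
#'
#' @param D numeric vector of differential scores.
#' @return numeric vector of Z-scores, same length and names.
#' @export
standardize <- function(D) {
  ok <- !is.na(D)
  if (sum(ok) < 3L) {
    stop("insufficient data: need at least 3 non-missing differential scores",
         call. = FALSE)
  }
  s <- stats::sd(D[ok])
  if (!is.finite(s) || s == 0) {
    stop("degenerate spread: differential scores are constant", call. = FALSE)
  }
  (D - mean(D[ok])) / s
}

#' Two-sided p-values and tail-area q-values for Z-scores
#'
#' `"theoretical-null"` takes Z as standard normal under the null:
#' `p = 2 * pnorm(-|Z|)`. `"empirical-null"` first fits the null location
#' and scale robustly (median and MAD of the observed Z, which the bulk of
#' true-null scores dominates) and standardizes against that fit, so the
#' q-values are invariant to location-scale changes of the input. q-values
#' are Benjamini-Hochberg step-up on p (see [benjamini_adjust()]).
#'
#' @param Z numeric vector of Z-scores (`NA` propagates).
#' @param method `"empirical-null"` (default; requires >= 50 values) or
#'   `"theoretical-null"`.
#' @return list with numeric vectors `p` and `q`, plus the fitted null
#'   `mu0` and `sigma0`.
#' @export
estimate_fdr <- function(Z, method = c("empirical-null", "theoretical-null")) {
  method <- match.arg(method)
  ok <- !is.na(Z)
  if (method == "empirical-null") {
    if (sum(ok) < 50L) {
      stop("empirical-null fit needs at least 50 Z-scores; use ",
           "theoretical-null for small batches", call. = FALSE)
    }
    mu0 <- stats::median(Z[ok])
    sigma0 <- stats::mad(Z[ok], center = mu0)
    if (sigma0 == 0) {
      stop("degenerate empirical null: MAD of Z is zero", call. = FALSE)
    }
  } else {
    mu0 <- 0
    sigma0 <- 1
  }
  p <- 2 * stats::pnorm(-abs((Z - mu0) / sigma0))
  list(p = p, q = benjamini_adjust(p), mu0 = mu0, sigma0 = sigma0)
}

#' Differential interaction table for a whole screen
#'
#' The core pipeline: pool concentrations, average replicates, subtract the
#' untreated from each drug profile, standardize each (query, drug)
#' differential vector to Z-scores, convert to two-sided p-values against
#' the fitted null and correct for multiple testing across the whole
#' experiment. Pairs missing either operand are reported with `NA`
#' statistics, never as q = 1.
#'
#' @param tensor a [screen_tensor()].
#' @param batch standardization batch: `"per-batch"` (each (query, drug)
#'   vector separately; default) or `"pooled"` (one batch of all
#'   differential scores).
#' @param null FDR null model passed to [estimate_fdr()].
#' @param fdr_batch `"experiment"` corrects across all (query, drug) rows
#'   jointly (default); `"per-batch"` corrects each (query, drug) vector
#'   separately.
#' @param merge pool concentrations first (default `TRUE`).
#' @return data.frame of class `differential_table` with columns query,
#'   array, drug, S_drug, S_unt, D, Z, p, q, direction.
#' @export
differential_table <- function(tensor,
                               batch = c("per-batch", "pooled"),
                               null = c("empirical-null", "theoretical-null"),
                               fdr_batch = c("experiment", "per-batch"),
                               merge = TRUE) {
  batch <- match.arg(batch)
  null <- match.arg(null)
  fdr_batch <- match.arg(fdr_batch)
  if (merge) tensor <- merge_concentrations(tensor)
  means <- mean_scores(tensor)
  drugs <- intersect(CEMAP_DRUGS, means$meta$drug)
  rows <- list()
  for (q in unique(means$meta$query)) {
    s_unt <- profile_row(means, q, "UNT")
    if (is.null(s_unt)) {
      stop("no untreated (UNT) profile for query ", q, call. = FALSE)
    }
    for (d in drugs) {
      s_drug <- profile_row(means, q, d)
      if (is.null(s_drug)) next
      rows[[paste(q, d)]] <- data.table(
        query = q, array = means$arrays, drug = d,
        S_drug = unname(s_drug), S_unt = unname(s_unt),
        D = unname(s_drug - s_unt))
    }
  }
  tab <- data.table::rbindlist(rows)
  if (batch == "per-batch") {
    tab[, Z := standardize(D), by = list(query, drug)]
  } else {
    tab[, Z := standardize(D)]
  }
  if (fdr_batch == "experiment") {
    fit <- estimate_fdr(tab$Z, method = null)
    tab[, c("p", "q") := list(fit$p, fit$q)]
  } else {
    tab[, c("p", "q") := estimate_fdr(Z, method = null)[c("p", "q")],
        by = list(query, drug)]
  }
  tab[, direction := data.table::fifelse(
    is.na(D) | D == 0, NA_character_,
    data.table::fifelse(D > 0, "positive", "negative"))]
  out <- as.data.frame(tab)
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Call significant conditional interactions
#'
#' One call per differential-table row with `q` strictly below `alpha`;
#' direction follows the sign of D, and rows with D = 0 or missing
#' statistics are never called.
#'
#' @param table a [differential_table()].
#' @param alpha calling threshold on q (default 0.05, strict `<`).
#' @return an [interaction_calls()] object.
#' @export
call_significant <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table), "q" %in% names(table))
  hit <- !is.na(table$q) & table$q < alpha &
    !is.na(table$D) & table$D != 0
  interaction_calls(table$query[hit], table$array[hit], table$drug[hit],
                    table$direction[hit], q = table$q[hit])
}

#' Static S-score significance calls
#'
#' Per-condition calls by the conventional fixed thresholds: mean S-score
#' strictly below `lo` is a negative interaction, strictly above `hi` a
#' positive one. Used for distribution summaries (including the untreated
#' condition), not for the conditional network.
#'
#' @param means a [mean_scores()] result.
#' @param lo,hi thresholds (defaults -2.4 and 2.0).
#' @return data.frame with columns query, drug, concentration, array,
#'   S, direction.
#' @export
static_threshold_calls <- function(means, lo = -2.4, hi = 2.0) {
  stopifnot(inherits(means, "mean_score_matrix"))
  if (lo >= hi) stop("lo must be below hi", call. = FALSE)
  hits <- which(!is.na(means$score) & (means$score < lo | means$score > hi),
                arr.ind = TRUE)
  meta <- means$meta[match(rownames(means$score)[hits[, 1L]],
                           means$meta$label), ]
  s <- means$score[hits]
  data.frame(query = meta$query, drug = meta$drug,
             concentration = meta$concentration,
             array = colnames(means$score)[hits[, 2L]],
             S = s,
             direction = ifelse(s > hi, "positive", "negative"),
             row.names = NULL, stringsAsFactors = FALSE)
}
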