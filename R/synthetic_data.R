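#' Configuration for a synthetic conditional screen
#'
#' Defaults mirror the screen design the pipeline targets: 3 query genes
#' crossed to a 1536-mutant array library, three drugs at two concentrations
#' each plus untreated controls, three technical replicates per plate.
#' S-scores are unitless; an |S| around 2-2.5 is the conventional
#' significance scale, so the default planted effect of 6 is a strong,
#' clearly detectable conditional interaction and `noise_sd = 1` a typical
#' replicate-level spread.
#'
#' @param n_queries,n_arrays numbers of query and array genes.
#' @param drugs drug conditions to simulate (subset of `CPT`, `HU`, `MMS`).
#' @param concentrations_per_drug concentrations per drug (labels `c1`,
#'   `c2`, ...). Untreated controls are grown once per concentration batch,
#'   so the untreated cell carries `replicates * concentrations_per_drug`
#'   replicates, matching the two no-drug control plates of the real design.
#' @param replicates technical replicates per plate.
#' @param baseline_sd spread of true condition-independent interactions.
#' @param baseline_interaction_fraction fraction of (query, array) pairs
#'   with a nonzero baseline interaction.
#' @param noise_sd replicate-level measurement noise.
#' @param planted_fraction fraction of (query, array, drug) triples carrying
#'   a planted condition-specific effect.
#' @param effect_size mean |delta| of planted effects (S-score units);
#'   magnitudes are Normal(effect_size, (effect_size/4)^2) truncated
#'   positive, signs random.
#' @param heavy_tail if `TRUE`, 5% of nonzero baselines are drawn from a
#'   3x wider Normal, mimicking the heavy-tailed empirical S-score
#'   distribution.
#' @param shared_baseline_fraction fraction of baseline variance shared
#'   across queries (functionally related queries have correlated untreated
#'   profiles); 0 means independent baselines.
#' @param shared_effects `"none"` plants triples independently;
#'   `"queries"` plants the same (array, drug) effects in every query;
#'   `"queries_and_drugs"` additionally reuses one array-gene set across
#'   drugs (a generic damage-response module).
#' @param seed integer seed driving the single generator instance.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_queries = 3L, n_arrays = 1536L,
                              drugs = CEMAP_DRUGS,
                              concentrations_per_drug = 2L,
                              replicates = 3L,
                              baseline_sd = 2.5,
                              baseline_interaction_fraction = 0.2,
                              noise_sd = 1,
                              planted_fraction = 0.01,
                              effect_size = 6,
                              heavy_tail = FALSE,
                              shared_baseline_fraction = 0,
                              shared_effects = c("none", "queries",
                                                 "queries_and_drugs"),
                              seed = 1L) {
  shared_effects <- match.arg(shared_effects)
  drugs <- match.arg(toupper(drugs), CEMAP_DRUGS, several.ok = TRUE)
  cfg <- list(n_queries = as.integer(n_queries),
              n_arrays = as.integer(n_arrays),
              drugs = drugs,
              concentrations_per_drug = as.integer(concentrations_per_drug),
              replicates = as.integer(replicates),
              baseline_sd = baseline_sd,
              baseline_interaction_fraction = baseline_interaction_fraction,
              noise_sd = noise_sd,
              planted_fraction = planted_fraction,
              effect_size = effect_size,
              heavy_tail = isTRUE(heavy_tail),
              shared_baseline_fraction = shared_baseline_fraction,
              shared_effects = shared_effects,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_queries >= 1L, n_arrays >= 1L, length(drugs) >= 1L,
              concentrations_per_drug >= 1L, replicates >= 1L,
              baseline_sd > 0, noise_sd > 0, effect_size > 0,
              baseline_interaction_fraction >= 0,
              baseline_interaction_fraction <= 1,
              planted_fraction >= 0, planted_fraction <= 1,
              shared_baseline_fraction >= 0, shared_baseline_fraction <= 1)
  })
  structure(cfg, class = "simulation_config")
}

rnorm_trunc_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic conditional screen with known ground truth
#'
#' The generative model matches the structure the differential analysis is
#' built to detect: each (query, array) pair has a condition-independent
#' baseline interaction mu (zero for most pairs), planted triples add a
#' condition-specific effect delta under their drug only, and every
#' replicate adds independent Gaussian noise:
#' `score = mu(q, a) + delta(q, a, drug) + eps`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `tensor` (a [screen_tensor()]) and `truth`
#'   (class `synthetic_truth`: the planted (query, array, drug, delta)
#'   table plus the simulated gene/drug universe).
#' @export
generate_screen <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  queries <- sprintf("QRY%02d", seq_len(config$n_queries))
  arrays <- sprintf("ARR%04d", seq_len(config$n_arrays))
  nq <- config$n_queries; na <- config$n_arrays
  nd <- length(config$drugs)

  # condition-independent baseline mu(q, a)
  mu <- matrix(0, nq, na, dimnames = list(queries, arrays))
  shared <- rep(0, na)
  n_base <- round(config$baseline_interaction_fraction * na)
  if (config$shared_baseline_fraction > 0 && n_base > 0) {
    idx <- sample.int(na, n_base)
    shared[idx] <- stats::rnorm(
      n_base, 0, config$baseline_sd * sqrt(config$shared_baseline_fraction))
  }
  sd_priv <- config$baseline_sd * sqrt(1 - config$shared_baseline_fraction)
  n_pair_base <- round(config$baseline_interaction_fraction * nq * na)
  if (sd_priv > 0 && n_pair_base > 0) {
    idx <- sample.int(nq * na, n_pair_base)
    priv <- stats::rnorm(n_pair_base, 0, sd_priv)
    if (config$heavy_tail) {
      ht <- stats::runif(n_pair_base) < 0.05
      priv[ht] <- stats::rnorm(sum(ht), 0, 3 * sd_priv)
    }
    mu[idx] <- priv
  }
  mu <- sweep(mu, 2L, shared, `+`)

  # planted condition-specific effects delta(q, a, drug)
  n_triples <- nq * na * nd
  planted <- data.table(query = character(), array = character(),
                        drug = character(), delta = numeric())
  if (config$planted_fraction > 0) {
    n_plant <- round(config$planted_fraction * n_triples)
    if (n_plant < 1L) {
      warning("planted_fraction too small for the design; no planted effects",
              call. = FALSE)
    } else if (config$shared_effects == "none") {
      idx <- sample.int(n_triples, n_plant)
      qi <- (idx - 1L) %% nq + 1L
      ai <- ((idx - 1L) %/% nq) %% na + 1L
      di <- (idx - 1L) %/% (nq * na) + 1L
      planted <- data.table(query = queries[qi], array = arrays[ai],
                            drug = config$drugs[di])
    } else {
      n_per_drug <- max(1L, round(n_plant / (nq * nd)))
      if (config$shared_effects == "queries_and_drugs") {
        # one damage-response module: the same arrays react with the same
        # signed effect under every drug
        ai <- sample.int(na, n_per_drug)
        delta <- sample(c(-1, 1), n_per_drug, replace = TRUE) *
          rnorm_trunc_pos(n_per_drug, config$effect_size,
                          config$effect_size / 4)
        grid <- data.frame(
          array = rep(arrays[ai], times = length(config$drugs)),
          drug = rep(config$drugs, each = n_per_drug),
          delta = rep(delta, times = length(config$drugs)),
          stringsAsFactors = FALSE)
      } else {
        grid <- do.call(rbind, lapply(config$drugs, function(d) {
          data.frame(array = arrays[sample.int(na, n_per_drug)], drug = d,
                     stringsAsFactors = FALSE)
        }))
        grid$delta <- sample(c(-1, 1), nrow(grid), replace = TRUE) *
          rnorm_trunc_pos(nrow(grid), config$effect_size,
                          config$effect_size / 4)
      }
      planted <- as.data.table(
        merge(expand.grid(query = queries, stringsAsFactors = FALSE), grid))
    }
    if (nrow(planted) && !"delta" %in% names(planted)) {
      planted[, delta := sample(c(-1, 1), .N, replace = TRUE) *
                rnorm_trunc_pos(.N, config$effect_size, config$effect_size / 4)]
    }
  }

  # assemble replicate-level long table
  conc <- sprintf("c%d", seq_len(config$concentrations_per_drug))
  conds <- rbind(
    data.frame(drug = "UNT", concentration = NA_character_,
               n_rep = config$replicates * config$concentrations_per_drug),
    expand.grid(drug = config$drugs, concentration = conc,
                stringsAsFactors = FALSE) |>
      transform(n_rep = config$replicates))
  cells <- data.table(query = rep(queries, each = na),
                      array = rep(arrays, nq))
  cells[, mu := as.vector(t(mu))]
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    nrep <- conds$n_rep[i]
    d <- cells[rep(seq_len(.N), each = nrep)]
    d[, drug := conds$drug[i]]
    d[, concentration := conds$concentration[i]]
    d[, replicate := rep(seq_len(nrep), times = nrow(cells))]
    rows[[i]] <- d
  }
  dt <- data.table::rbindlist(rows)
  if (nrow(planted)) {
    dt <- merge(dt, planted, by = c("query", "array", "drug"),
                all.x = TRUE, sort = FALSE)
    dt[is.na(delta), delta := 0]
  } else {
    dt[, delta := 0]
  }
  dt[, score := mu + delta + stats::rnorm(.N, 0, config$noise_sd)]
  tensor <- screen_tensor(dt[, list(query, array, drug, concentration,
                                    replicate, score)])
  truth <- structure(
    list(planted = as.data.frame(planted),
         queries = queries, arrays = arrays, drugs = config$drugs,
         config = config),
    class = "synthetic_truth")
  list(tensor = tensor, truth = truth)
}

#' Write planted ground truth as TSV
#' @param truth a `synthetic_truth`.
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  data.table::fwrite(truth$planted, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Confusion counts of calls against planted truth
#'
#' Counts are over (query, array, drug) triples of the simulated universe.
#' A true positive requires the call's direction to match the sign of the
#' planted delta; a call on a planted triple with the opposite direction
#' counts as both a false positive and a false negative.
#'
#' @param calls an [interaction_calls()] object.
#' @param truth a `synthetic_truth` from [generate_screen()].
#' @return list of class `confusion_counts` with `TP`, `FP`, `FN`, `TN`,
#'   plus `sensitivity` and `fdr`.
#' @export
truth_confusion <- function(calls, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  universe <- length(truth$queries) * length(truth$arrays) *
    length(truth$drugs)
  tkey <- with(truth$planted,
               paste(query, array, drug, ifelse(delta > 0, "positive",
                                                "negative"), sep = "\r"))
  ckey <- with(calls, paste(query, array, drug, direction, sep = "\r"))
  if (anyDuplicated(ckey)) ckey <- unique(ckey)
  tp <- sum(ckey %in% tkey)
  fp <- length(ckey) - tp
  fn <- length(tkey) - tp
  structure(list(TP = tp, FP = fp, FN = fn,
                 TN = universe - tp - fp - fn,
                 sensitivity = if (length(tkey)) tp / length(tkey) else NA_real_,
                 fdr = if (length(ckey)) fp / length(ckey) else 0),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d  (sensitivity %.3f, FDR %.3f)\n",
              x$TP, x$FP, x$FN, x$TN, x$sensitivity, x$fdr))
  invisible(x)
}
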