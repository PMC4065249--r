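#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for the number of white balls drawn when `n` balls are drawn
#' without replacement from an urn of `N` balls of which `K` are white.
#' Vectorized over all arguments. This one tail is the p-value of a
#' one-sided (greater) Fisher exact test and of the term-enrichment test.
#'
#' @param k observed overlap (lower bound of the tail).
#' @param K size of the first set.
#' @param n size of the second set (number drawn).
#' @param N universe size.
#' @return numeric vector of tail probabilities.
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(all(k >= 0), all(K <= N), all(n <= N))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build the conditional genetic-interaction network
#'
#' Nodes are query and array genes; an edge joins a (query, array) pair and
#' accumulates one annotation per distinct (drug, direction) under which the
#' pair was called, with the smallest q seen for that annotation. Duplicate
#' calls are idempotent.
#'
#' @param calls an [interaction_calls()] object.
#' @return object of class `gene_network` with `nodes` (gene, role) and
#'   `edges` (query, array, drug, direction, q).
#' @export
build_network <- function(calls) {
  dt <- as.data.table(as.data.frame(calls))
  if (nrow(dt)) {
    dt <- dt[, list(q = suppressWarnings(min(q, na.rm = TRUE))),
             by = list(query, array, drug, direction)]
    dt[is.infinite(q), q := NA_real_]
    setorder(dt, query, array, drug, direction)
  } else {
    dt <- data.table(query = character(), array = character(),
                     drug = character(), direction = character(),
                     q = numeric())
  }
  qn <- unique(dt$query)
  an <- setdiff(unique(dt$array), qn)
  nodes <- data.frame(gene = c(qn, an),
                      role = rep(c("query", "array"),
                                 c(length(qn), length(an))),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = as.data.frame(dt)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d (query, array) pairs, %d annotations\n",
              nrow(x$nodes), nrow(unique(x$edges[c("query", "array")])),
              nrow(x$edges)))
  invisible(x)
}

#' Marginal counts of a conditional interaction network
#'
#' Totals of (edge, annotation) incidences by direction, by drug and by
#' query; the three margins each sum to the total.
#'
#' @param network a [build_network()] result.
#' @return list of class `network_summary` with `total`, `by_direction`,
#'   `by_drug`, `by_query`.
#' @export
count_summary <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  e <- network$edges
  count_by <- function(f) {
    t <- table(factor(e[[f]]))
    stats::setNames(as.integer(t), names(t))
  }
  structure(list(total = nrow(e),
                 by_direction = count_by("direction"),
                 by_drug = count_by("drug"),
                 by_query = count_by("query")),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat("conditional interactions:", x$total, "\n")
  fmt <- function(v) paste(names(v), v, sep = "=", collapse = ", ")
  cat("  by direction:", fmt(x$by_direction), "\n")
  cat("  by drug:     ", fmt(x$by_drug), "\n")
  cat("  by query:    ", fmt(x$by_query), "\n")
  invisible(x)
}

#' Interacting array genes of one query
#'
#' Union of array genes whose (query, array) edge carries an annotation
#' matching the drug and direction filters. This is the compilation rule
#' used for enrichment and overlap testing: all drugs, both directions.
#'
#' @param network a `gene_network`.
#' @param query query gene name.
#' @param drugs subset of drugs to include (default all).
#' @param directions subset of directions (default both).
#' @return character vector of array genes (set semantics).
#' @export
interaction_set <- function(network, query, drugs = CEMAP_DRUGS,
                            directions = c("positive", "negative")) {
  stopifnot(inherits(network, "gene_network"))
  query <- canonical_gene(query)
  e <- network$edges
  if (!query %in% e$query) {
    stop("unknown query gene: ", query, call. = FALSE)
  }
  sort(unique(e$array[e$query == query & e$drug %in% drugs &
                        e$direction %in% directions]))
}

#' Shared/exclusive partition of three gene sets
#'
#' Splits the union of three sets into the seven disjoint regions of their
#' Venn diagram.
#'
#' @param sets named list of exactly three character vectors.
#' @return list with `counts` (named integer vector over the 7 regions) and
#'   `regions` (the gene sets themselves).
#' @export
shared_exclusive_partition <- function(sets) {
  if (!is.list(sets) || length(sets) != 3L || is.null(names(sets))) {
    stop("sets must be a named list of three gene sets", call. = FALSE)
  }
  sets <- lapply(sets, function(g) unique(canonical_gene(g)))
  nm <- names(sets)
  a <- sets[[1L]]; b <- sets[[2L]]; c <- sets[[3L]]
  regions <- list(
    setdiff(a, union(b, c)),
    setdiff(b, union(a, c)),
    setdiff(c, union(a, b)),
    setdiff(intersect(a, b), c),
    setdiff(intersect(a, c), b),
    setdiff(intersect(b, c), a),
    intersect(intersect(a, b), c))
  names(regions) <- c(paste0(nm, "_only"),
                      paste(nm[1L], nm[2L], sep = "&"),
                      paste(nm[1L], nm[3L], sep = "&"),
                      paste(nm[2L], nm[3L], sep = "&"),
                      paste(nm, collapse = "&"))
  list(counts = vapply(regions, length, integer(1L)), regions = regions)
}

#' One-sided (greater) overlap test of two gene sets
#'
#' Tests whether two gene sets drawn from a common screened universe
#' overlap more than expected by chance: the p-value is the hypergeometric
#' upper tail at the observed overlap, which is exactly the one-sided
#' Fisher exact test on the 2x2 membership table. The sample odds ratio is
#' reported alongside (0.5 added to all cells only when a table margin is
#' zero).
#'
#' @param set_a,set_b character vectors of genes.
#' @param universe_n size of the common universe (defaults to the
#'   1536-mutant array library of the screen design).
#' @return list of class `overlap_result`.
#' @export
fisher_overlap <- function(set_a, set_b, universe_n = 1536L) {
  set_a <- unique(canonical_gene(set_a))
  set_b <- unique(canonical_gene(set_b))
  if (length(union(set_a, set_b)) > universe_n) {
    stop("universe smaller than the union of the two sets", call. = FALSE)
  }
  k <- length(intersect(set_a, set_b))
  tab <- c(k, length(set_a) - k, length(set_b) - k,
           universe_n - length(set_a) - length(set_b) + k)
  if (any(c(tab[1L] + tab[2L], tab[1L] + tab[3L],
            tab[2L] + tab[4L], tab[3L] + tab[4L]) == 0)) {
    tab <- tab + 0.5
  }
  structure(list(set_a_size = length(set_a), set_b_size = length(set_b),
                 overlap = k, universe = as.integer(universe_n),
                 odds_ratio = (tab[1L] * tab[4L]) / (tab[2L] * tab[3L]),
                 p = hyper_upper_tail(k, length(set_a), length(set_b),
                                      universe_n)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap %d of %d x %d in universe %d: OR = %.2f, p (greater) = %.3g\n",
    x$overlap, x$set_a_size, x$set_b_size, x$universe, x$odds_ratio, x$p))
  invisible(x)
}
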