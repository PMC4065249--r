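#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped to 1, where p_(1) <= ... <=
#' p_(m) are the sorted p-values. Order-preserving: q is monotone
#' non-decreasing in p. Missing values propagate and do not count toward m.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
benjamini_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0L) return(q)
  pp <- p[idx]
  o <- order(pp)
  adj <- pmin(1, rev(cummin(rev(m * pp[o] / seq_len(m)))))
  q[idx[o]] <- adj
  q
}

#' Term enrichment of a gene list against a screened background
#'
#' For each annotation term with at least one background gene, tests
#' whether the query list contains more of the term's genes than expected
#' under hypergeometric sampling from the background (`p = P(X >= k)`),
#' with Benjamini-Hochberg correction across all tested terms. The
#' background is the screened gene list, not the whole genome, so terms
#' over-represented in the library design do not masquerade as signal.
#' Query genes outside the background are dropped (count reported in the
#' `dropped` attribute).
#'
#' @param genes character vector: the gene list to test.
#' @param annotations an [annotation_set()].
#' @param alpha significance threshold on q (strict `<`, default 0.05).
#' @return data.frame of class `enrichment_table` with columns term, k, n,
#'   K, N, fold, p, q, significant, low_power; sorted by p.
#' @export
enrich <- function(genes, annotations, alpha = 0.05) {
  stopifnot(inherits(annotations, "annotation_set"))
  genes <- unique(canonical_gene(genes))
  bg <- annotations$background
  dropped <- length(setdiff(genes, bg))
  genes <- intersect(genes, bg)
  if (length(genes) == 0L) {
    stop("no query genes in the background", call. = FALSE)
  }
  N <- length(bg)
  n <- length(genes)
  terms <- annotations$terms[vapply(annotations$terms, length,
                                    integer(1L)) >= 1L]
  K <- vapply(terms, length, integer(1L))
  k <- vapply(terms, function(g) length(intersect(g, genes)), integer(1L))
  out <- data.frame(term = names(terms), k = k, n = n, K = K, N = N,
                    fold = (k / n) / (K / N),
                    p = hyper_upper_tail(k, K, n, N),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$q <- benjamini_adjust(out$p)
  out$significant <- out$q < alpha
  out$low_power <- out$K < 2L
  out <- out[order(out$p, out$term), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("enrichment_table", "data.frame")
  out
}
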