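#' Pearson correlation matrix of interaction profiles
#'
#' Correlates every pair of (query, condition) mean-S-score profiles over
#' array genes, using pairwise-complete observations (interaction matrices
#' are sparse and missingness is uneven across pairs). Cells with fewer
#' than `min_pairs` complete pairs, or where a profile has zero variance on
#' the complete pairs, are missing.
#'
#' @param means a [mean_scores()] result.
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return object of class `correlation_matrix`: symmetric `r` with unit
#'   diagonal, matching complete-pair count matrix `n`, and `labels`.
#' @export
correlation_matrix <- function(means, min_pairs = 3L) {
  stopifnot(inherits(means, "mean_score_matrix"))
  m <- means$score
  k <- nrow(m)
  labels <- rownames(m)
  r <- diag(1, k)
  n <- matrix(0L, k, k)
  dimnames(r) <- dimnames(n) <- list(labels, labels)
  diag(n) <- rowSums(!is.na(m))
  degenerate <- character()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < min_pairs) {
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      if (stats::sd(m[i, ok]) == 0 || stats::sd(m[j, ok]) == 0) {
        degenerate <- c(degenerate, paste(labels[i], labels[j], sep = " ~ "))
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      r[i, j] <- r[j, i] <- stats::cor(m[i, ok], m[j, ok])
    }
  }
  if (length(degenerate)) {
    warning("zero-variance profile(s) in: ",
            paste(degenerate, collapse = "; "), call. = FALSE)
  }
  structure(list(r = r, n = n, labels = labels),
            class = "correlation_matrix")
}

#' Hierarchical clustering of interaction profiles
#'
#' Agglomerative clustering on the correlation distance `d = 1 - r`.
#' Profiles enter in label order, which fixes tie-breaking; leaf order is
#' reproducible.
#'
#' @param corr a [correlation_matrix()].
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return an [stats::hclust] object.
#' @export
cluster_profiles <- function(corr, linkage = c("average", "complete",
                                               "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(corr, "correlation_matrix"))
  r <- corr$r
  bad <- which(is.na(r) & upper.tri(r), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("missing correlation for pair(s): ",
         paste(corr$labels[bad[, 1L]], corr$labels[bad[, 2L]],
               sep = " ~ ", collapse = "; "), call. = FALSE)
  }
  stats::hclust(stats::as.dist(1 - r), method = linkage)
}

#' Write a dendrogram as a Newick string
#' @param hc an [stats::hclust] object.
#' @param path output path.
#' @export
write_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' The statistic is the supremum gap between the two empirical CDFs; the
#' p-value uses the exact small-sample distribution when `n_x * n_y <= 1e4`
#' and there are no ties, and the asymptotic two-sided formula otherwise.
#'
#' @param x,y numeric samples (missing values dropped; >= 2 values each).
#' @param label_x,label_y optional profile identifiers carried in the
#'   result.
#' @return list of class `distribution_comparison` with `ks_stat`, `p`,
#'   `n_x`, `n_y` and the labels.
#' @export
ks_two_sided <- function(x, y, label_x = "x", label_y = "y") {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("insufficient data: both samples need at least 2 values",
         call. = FALSE)
  }
  exact <- length(x) * length(y) <= 1e4 && !anyDuplicated(c(x, y))
  kt <- suppressWarnings(
    stats::ks.test(x, y, alternative = "two.sided", exact = exact))
  structure(list(label_x = label_x, label_y = label_y,
                 ks_stat = unname(kt$statistic), p = kt$p.value,
                 n_x = length(x), n_y = length(y)),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("KS %s vs %s: D = %.4f, p = %.3g (n = %d, %d)\n",
              x$label_x, x$label_y, x$ks_stat, x$p, x$n_x, x$n_y))
  invisible(x)
}
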