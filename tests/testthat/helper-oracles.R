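# Independent brute-force oracles and tiny fixture builders.
# These deliberately re-derive results from first principles (enumeration,
# direct formula transcription) and never call the package code they check.

# Benjamini-Hochberg step-up, direct transcription of the definition:
# q_(i) = min_{j >= i} m * p_(j) / j on the sorted p-values.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * sorted[i:m] / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Hypergeometric upper tail P(X >= k) by explicit enumeration of the pmf.
hyper_brute <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Two-sample KS statistic as the supremum gap of empirical CDFs.
ks_stat_brute <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(grid, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# A tiny hand-built screen: 2 queries x 4 arrays, one drug at two
# concentrations plus untreated, 2 replicates, no noise structure.
tiny_screen <- function(scores_fun = function(q, a, d, c, r) 0) {
  grid <- expand.grid(
    query = c("QA", "QB"), array = paste0("G", 1:4),
    cond = c("UNT", "CPT@c1", "CPT@c2"), replicate = 1:2,
    stringsAsFactors = FALSE)
  grid$drug <- sub("@.*", "", grid$cond)
  grid$concentration <- ifelse(grepl("@", grid$cond),
                               sub(".*@", "", grid$cond), NA_character_)
  grid$score <- mapply(scores_fun, grid$query, grid$array, grid$drug,
                       grid$concentration, grid$replicate)
  screen_tensor(grid[, c("query", "array", "drug", "concentration",
                         "replicate", "score")])
}

# Long-format rows as a data.frame, convenience for I/O tests.
score_rows <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query = r[[1]], array = r[[2]], drug = r[[3]],
               concentration = r[[4]], replicate = r[[5]], score = r[[6]],
               stringsAsFactors = FALSE)
  }))
}

fixture_path <- function() {
  system.file("extdata", "table1_conditional_interactions.tsv",
              package = "cemapr")
}
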