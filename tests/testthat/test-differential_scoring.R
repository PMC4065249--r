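test_that("merge_concentrations pools replicate lists per drug", {
  # CPT replicates [1,2,3] at c1 and [3,4,5] at c2 for one cell
  cpt_vals <- list(c1 = c(1, 2, 3), c2 = c(3, 4, 5))
  df <- rbind(
    score_rows(list("Q", "A", "UNT", NA, 1, 0), list("Q", "A", "UNT", NA, 2, 0)),
    do.call(rbind, lapply(names(cpt_vals), function(cc)
      do.call(rbind, lapply(1:3, function(r)
        score_rows(list("Q", "A", "CPT", cc, r, cpt_vals[[cc]][r])))))))
  merged <- merge_concentrations(screen_tensor(df))
  cell <- merged$scores[drug == "CPT"]
  expect_equal(sort(cell$score), c(1, 2, 3, 3, 4, 5))
  expect_equal(cell$replicate, 1:6)
  expect_true(all(is.na(merged$scores$concentration)))

  # single-concentration condition: scores unchanged
  unt <- merged$scores[drug == "UNT"]
  expect_equal(unt$score, c(0, 0))
})

test_that("the paper design pools 3 reps x 2 concentrations into 6", {
  sim <- generate_screen(simulation_config(
    n_queries = 1, n_arrays = 5, replicates = 3,
    concentrations_per_drug = 2, planted_fraction = 0, seed = 4))
  means <- mean_scores(merge_concentrations(sim$tensor))
  expect_true(all(means$n == 6L))
})

test_that("mean_scores averages present replicates and records counts", {
  df <- rbind(
    score_rows(list("Q", "A", "UNT", NA, 1, 2), list("Q", "A", "UNT", NA, 2, NA),
               list("Q", "A", "UNT", NA, 3, 4)),
    score_rows(list("Q", "B", "UNT", NA, 1, NA), list("Q", "B", "UNT", NA, 2, NA)),
    score_rows(list("Q", "A", "CPT", "c1", 1, 1), list("Q", "A", "CPT", "c1", 2, 2),
               list("Q", "A", "CPT", "c1", 3, 3), list("Q", "A", "CPT", "c1", 4, 3),
               list("Q", "A", "CPT", "c1", 5, 4), list("Q", "A", "CPT", "c1", 6, 5)))
  means <- mean_scores(screen_tensor(df))
  expect_equal(means$score["Q|UNT", "A"], 3)   # [2, NA, 4] -> 3, n = 2
  expect_equal(means$n["Q|UNT", "A"], 2L)
  expect_true(is.na(means$score["Q|UNT", "B"]))  # all missing -> missing
  expect_equal(means$n["Q|UNT", "B"], 0L)
  expect_equal(means$score["Q|CPT@c1", "A"], 3)  # [1..3,3..5] -> 3, n = 6
  expect_equal(means$n["Q|CPT@c1", "A"], 6L)
})

test_that("differential_scores is S_drug - S_unt with missing propagation", {
  tensor <- tiny_screen(function(q, a, d, c, r) {
    if (d == "UNT") 0.5 else 2.5
  })
  means <- mean_scores(merge_concentrations(tensor))
  D <- differential_scores(means, "QA", "CPT")
  expect_equal(unname(D), rep(2, 4))

  # missing drug mean -> missing D
  df <- tensor$scores
  df[query == "QA" & array == "G1" & drug == "CPT", score := NA]
  means2 <- mean_scores(merge_concentrations(screen_tensor(df)))
  D2 <- differential_scores(means2, "QA", "CPT")
  expect_true(is.na(D2[["G1"]]))
  expect_false(anyNA(D2[-1]))

  # absent untreated profile is a configuration error
  no_unt <- df[drug != "UNT"]
  expect_error(screen_tensor(no_unt), "untreated")
  expect_error(differential_scores(means, "QX", "CPT"), "QX")
})

test_that("standardize matches the direct arithmetic oracle", {
  expect_equal(standardize(c(-1, 0, 1)), c(-1, 0, 1))
  # mean 5, sample sd sqrt(20/3)
  expect_equal(standardize(c(2, 4, 6, 8)),
               (c(2, 4, 6, 8) - 5) / sqrt(20 / 3), tolerance = 1e-12)
  expect_equal(round(standardize(c(2, 4, 6, 8)), 4),
               c(-1.1619, -0.3873, 0.3873, 1.1619))
  # missing in, missing out; sample moments restored on any valid input
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(3:50, 1), mean = runif(1, -5, 5), sd = runif(1, .1, 9))
    x[sample(length(x), 1)] <- if (i %% 2) NA else x[1]
    z <- standardize(x)
    expect_identical(is.na(z), is.na(x))
    expect_lt(abs(mean(z, na.rm = TRUE)), 1e-10)
    expect_lt(abs(sd(z, na.rm = TRUE) - 1), 1e-10)
  }
  expect_error(standardize(c(3, 3, 3, 3)), "constant")
  expect_error(standardize(c(1, 2, NA, NA)), "at least 3")
})

test_that("estimate_fdr: theoretical null, empirical-null invariance", {
  expect_equal(estimate_fdr(0, method = "theoretical-null")[c("p", "q")],
               list(p = 1, q = 1))

  set.seed(42)
  z <- c(rnorm(400), rnorm(20, 5))
  theo <- estimate_fdr(z, method = "theoretical-null")
  # location-scale change of Z leaves empirical-null q-values invariant
  emp <- estimate_fdr(2 + 3 * z, method = "empirical-null")
  emp0 <- estimate_fdr(z, method = "empirical-null")
  expect_equal(emp$q, emp0$q, tolerance = 1e-9)
  expect_equal(emp$mu0, 2 + 3 * emp0$mu0, tolerance = 1e-9)

  # q is monotone non-decreasing in p within the batch
  o <- order(theo$p)
  expect_true(all(diff(theo$q[o]) >= -1e-15))

  # BH under the pure null controls the q < 0.05 call fraction
  set.seed(7)
  znull <- rnorm(10000)
  fit <- estimate_fdr(znull, method = "theoretical-null")
  frac <- mean(fit$q < 0.05)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 10000))

  expect_error(estimate_fdr(rnorm(10), method = "empirical-null"),
               "at least 50")
  expect_error(estimate_fdr(rep(c(0, 0, 1), 30), method = "empirical-null"),
               "degenerate")
})

test_that("pipeline equivariance under per-row S-score shifts", {
  sim <- generate_screen(simulation_config(
    n_queries = 2, n_arrays = 60, planted_fraction = 0.05, seed = 13))
  base <- differential_table(sim$tensor, null = "theoretical-null")

  shift_rows <- function(tensor, q, d, const) {
    df <- data.table::copy(tensor$scores)
    df[query == q & drug == d, score := score + const]
    screen_tensor(df)
  }

  # shift one (query, drug) row: its D shifts by the constant, Z unchanged
  shifted <- differential_table(shift_rows(sim$tensor, "QRY01", "CPT", 5),
                                null = "theoretical-null")
  moved <- base$query == "QRY01" & base$drug == "CPT"
  expect_equal(shifted$D[moved], base$D[moved] + 5, tolerance = 1e-12)
  expect_equal(shifted$D[!moved], base$D[!moved], tolerance = 1e-12)
  expect_equal(shifted$Z, base$Z, tolerance = 1e-9)
  expect_equal(shifted$q, base$q, tolerance = 1e-9)

  # shift a query's untreated row: all that query's D shift equally, Z fixed
  shifted2 <- differential_table(shift_rows(sim$tensor, "QRY01", "UNT", 5),
                                 null = "theoretical-null")
  q1 <- base$query == "QRY01"
  expect_equal(shifted2$D[q1], base$D[q1] - 5, tolerance = 1e-12)
  expect_equal(shifted2$Z, base$Z, tolerance = 1e-9)
})

test_that("call_significant uses strict thresholds and sign directions", {
  tab <- data.frame(
    query = "Q", array = c("A", "B", "C", "D"), drug = "CPT",
    S_drug = 0, S_unt = 0, D = c(-3, 2, 0, 1),
    Z = c(-4, 3, 0, 2), p = c(1e-5, 1e-4, 1, 0.01),
    q = c(0.049, 0.05, 1, NA),
    direction = c("negative", "positive", NA, "positive"))
  calls <- call_significant(tab, alpha = 0.05)
  # q = 0.049 called with sign(D); q = 0.05 exactly is NOT called; NA never
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$array, "A")
  expect_equal(calls$direction, "negative")
  expect_equal(nrow(call_significant(tab[0, ])), 0L)
})

test_that("static thresholds call S < -2.4 and S > 2.0 strictly", {
  tensor <- tiny_screen(function(q, a, d, c, r) {
    vals <- c(G1 = -2.5, G2 = 2.0, G3 = 0, G4 = 2.01)
    vals[[a]]
  })
  means <- mean_scores(merge_concentrations(tensor))
  calls <- static_threshold_calls(means)
  expect_setequal(unique(calls$array), c("G1", "G4"))
  expect_true(all(calls$direction[calls$array == "G1"] == "negative"))
  expect_true(all(calls$direction[calls$array == "G4"] == "positive"))
  # untreated condition is included in static summaries
  expect_true("UNT" %in% calls$drug)
  expect_error(static_threshold_calls(means, lo = 2, hi = -2), "lo")
})

test_that("null screens produce calls within the nominal FDR budget", {
  sim <- generate_screen(simulation_config(
    n_queries = 3, n_arrays = 200, planted_fraction = 0, seed = 21))
  for (mode in c("empirical-null", "theoretical-null")) {
    calls <- call_significant(differential_table(sim$tensor, null = mode))
    n_tests <- 3 * 200 * 3
    expect_lte(nrow(calls) / n_tests,
               0.05 + 3 * sqrt(0.05 * 0.95 / n_tests))
  }
})
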