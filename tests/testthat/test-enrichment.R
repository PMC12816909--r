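test_that("two-tailed Fisher p matches hand-derived exact values", {
  # two equiprobable tables with these margins
  expect_equal(fisher_two_tailed(c(1, 0, 0, 1)), 1.0)
  # enumeration over a in 0..5 gives 2/252
  expect_equal(fisher_two_tailed(c(5, 0, 0, 5)), 2 / 252, tolerance = 1e-12)
  # zero margin carries no information
  expect_true(is.na(fisher_two_tailed(c(0, 0, 3, 4))))
  expect_true(is.na(fisher_two_tailed(c(0, 3, 0, 4))))
  expect_error(fisher_two_tailed(c(-1, 2, 3, 4)), "non-negative")
})

test_that("Fisher p agrees with stats::fisher.test on random tables", {
  set.seed(51)
  for (i in 1:300) {
    tab <- matrix(rpois(4, sample(1:15, 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_two_tailed(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Fisher p matches the enumeration oracle for all small tables", {
  for (N in c(6, 11, 16)) {
    parts <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    parts <- parts[rowSums(parts) <= N, ]
    parts$d <- N - parts$a - parts$b - parts$c
    for (r in seq_len(nrow(parts))) {
      a <- parts$a[r]; b <- parts$b[r]; c <- parts$c[r]; d <- parts$d[r]
      if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
      expect_equal(fisher_two_tailed(c(a, b, c, d)), oracle_fisher(a, b, c, d),
                   tolerance = 1e-11)
    }
  }
})

test_that("odds ratios use Haldane-Anscombe for zero cells and Woolf intervals", {
  expect_equal(unname(odds_ratio_ci(c(20, 5, 4, 30))["or"]), 30.0)
  bal <- odds_ratio_ci(c(10, 10, 10, 10))
  expect_equal(unname(bal["or"]), 1.0)
  expect_equal(unname(bal["ci_low"]), exp(-qnorm(0.975) * sqrt(0.4)), tolerance = 1e-9)
  expect_equal(unname(bal["ci_high"]), exp(qnorm(0.975) * sqrt(0.4)), tolerance = 1e-9)
  # +0.5 on all four cells when any cell is zero
  expect_equal(unname(odds_ratio_ci(c(5, 0, 5, 5))["or"]), 11.0)
  set.seed(61)
  for (i in 1:100) {
    tab <- rpois(4, 5)
    orci <- odds_ratio_ci(tab)
    expect_lte(orci["ci_low"], orci["or"])
    expect_lte(orci["or"], orci["ci_high"])
  }
})

test_that("Bonferroni q is min(p*m, 1), order-preserving, and validated", {
  expect_equal(adjust_bonferroni(0.01, m = 29), 0.29)
  expect_equal(adjust_bonferroni(0.2, m = 10), 1.0)
  expect_length(adjust_bonferroni(numeric(0)), 0L)
  expect_error(adjust_bonferroni(0.1, m = 0), "positive")
  expect_error(adjust_bonferroni(c(0.1, 0.2), m = 1), "smaller")
  p <- sort(runif(20))
  q <- adjust_bonferroni(p, m = 20)
  expect_true(all(q >= p))
  expect_false(is.unsorted(q))
  # the significant set never grows when m increases
  q2 <- adjust_bonferroni(p, m = 40)
  expect_true(all(which(q2 < 0.05) %in% which(q < 0.05)))
})

test_that("planted cohorts are recovered with the analytic odds ratio", {
  sim <- simulate_cohort(c("F1", "F2", "F3"),
                         prev_pathogenic = c(0.9, 0.5, 0.0005),
                         prev_benign = c(0.5, 0.5, 0.0005),
                         n_path = 1000, n_benign = 1000, seed = 71)
  res <- compare_feature_sets(sim$pathogenic, sim$benign)
  f1 <- res[res$feature == "F1", ]
  expect_equal(f1$call, "pathogenic_associated")
  expect_gt(f1$or, 6.5)   # analytic OR = 9
  expect_lt(f1$or, 12.5)
  expect_equal(res$call[res$feature == "F2"], "not_significant")
  # F3 present in only a handful of variants: insufficient
  expect_equal(res$call[res$feature == "F3"], "insufficient")
  expect_true(is.na(res$p[res$feature == "F3"]))
  # m counts only testable features
  expect_equal(attr(res, "m"), 2L)
  expect_equal(res$q[res$feature == "F1"], min(1, f1$p * 2))
})

test_that("registry mismatches are rejected", {
  a <- make_fm(matrix(1L, 4, 1, dimnames = list(NULL, "F1")))
  b <- make_fm(matrix(1L, 4, 1, dimnames = list(NULL, "F2")))
  expect_error(compare_feature_sets(a, b), "F2")
})

test_that("swapping the matrices inverts log10(OR) exactly and keeps p", {
  set.seed(81)
  sim <- simulate_cohort(paste0("F", 1:6), runif(6, 0.05, 0.95),
                         runif(6, 0.05, 0.95), 300, 200, seed = 82)
  fwd <- compare_feature_sets(sim$pathogenic, sim$benign)
  rev <- compare_feature_sets(sim$benign, sim$pathogenic)
  testable <- fwd$call != "insufficient"
  expect_identical(testable, rev$call != "insufficient")
  expect_identical(rev$log10_or[testable], -fwd$log10_or[testable])
  expect_equal(rev$p[testable], fwd$p[testable], tolerance = 1e-12)
})

test_that("NA cells are excluded from both margins of the contingency table", {
  mat <- matrix(c(1L, 1L, 0L, NA, NA, 1L), ncol = 1,
                dimnames = list(NULL, "F1"))
  ben <- matrix(c(1L, 0L, 0L, 0L, NA, 1L), ncol = 1,
                dimnames = list(NULL, "F1"))
  res <- compare_feature_sets(make_fm(mat), make_fm(ben), min_count = 2)
  expect_equal(unlist(res[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(3L, 1L, 2L, 3L))
})

test_that("stratified comparisons restrict matrices per the stratum design", {
  reg <- c("F1", "F2")
  up <- matrix(c(rep(1L, 45), rep(0L, 5), rep(0L, 45), rep(1L, 5)), ncol = 2,
               dimnames = list(NULL, reg))
  down <- matrix(c(rep(1L, 5), rep(0L, 45), rep(1L, 45), rep(0L, 5)), ncol = 2,
                 dimnames = list(NULL, reg))
  path <- make_fm(rbind(up, down), protein_class = rep(c("kinase", "matrix"), each = 50))
  ben <- make_fm(rbind(down, up), protein_class = rep(c("kinase", "matrix"), each = 50))
  strat <- stratified_compare(path, ben, by = "protein_class")
  f1 <- strat[strat$feature == "F1", ]
  expect_equal(sign(f1$log10_or[f1$stratum == "kinase"]), 1)
  expect_equal(sign(f1$log10_or[f1$stratum == "matrix"]), -1)
  hm <- heatmap_table(strat)
  expect_equal(dim(hm$log10_or), c(2L, 2L))
  expect_equal(hm$call["kinase", "F1"], "pathogenic_associated")

  # stratum absent from the benign matrix in protein-class mode
  ben2 <- make_fm(up, protein_class = "kinase")
  strat2 <- stratified_compare(path, ben2, by = "protein_class")
  expect_true(all(strat2$call[strat2$stratum == "matrix"] == "insufficient"))

  # disease mode compares against the full benign matrix
  path$disease_category <- rep(c("metabolic", "musculoskeletal"), each = 50)
  stratd <- stratified_compare(path, ben, by = "disease_category")
  expect_true(all(stratd$c + stratd$d == 100L, na.rm = TRUE))
})

test_that("z-scored log(OR) standardises per feature across comparisons", {
  df <- data.frame(
    feature = rep(c("F1", "F2", "F3"), each = 3),
    comparison = rep(c("CV_GM", "CV_AMb", "AMp_AMb"), 3),
    log10_or = c(1, 2, 3, 2, 2, 2, -1, 0.5, 2)
  )
  z <- zscore_log_or(df)
  expect_equal(z$z[z$feature == "F1"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_true(all(z$degenerate[z$feature == "F2"]))
  expect_equal(z$z[z$feature == "F2"], c(0, 0, 0))
  expect_true(all(z$inverted[z$feature == "F3"]))
  expect_false(any(z$inverted[z$feature == "F1"]))
  # single comparison gives NA
  single <- zscore_log_or(data.frame(feature = "G", comparison = "only",
                                     log10_or = 0.4))
  expect_true(is.na(single$z))
  # mean 0, population sd 1 whenever sd > 0
  set.seed(91)
  many <- zscore_log_or(data.frame(
    feature = "H", comparison = paste0("c", 1:8), log10_or = rnorm(8)
  ))
  expect_equal(mean(many$z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(many$z^2)), 1, tolerance = 1e-12)
})

test_that("feature proportions carry Wilson intervals", {
  mat <- matrix(c(rep(1L, 30), rep(0L, 70)), ncol = 1, dimnames = list(NULL, "F1"))
  prop <- feature_proportions(make_fm(mat))
  expect_equal(prop$proportion, 0.30)
  expect_equal(prop$ci_low, 0.2189489, tolerance = 1e-4)
  expect_equal(prop$ci_high, 0.3958485, tolerance = 1e-4)
  zero <- feature_proportions(make_fm(matrix(0L, 50, 1, dimnames = list(NULL, "F1"))))
  expect_equal(zero$proportion, 0)
  expect_equal(zero$ci_low, 0)
  allna <- feature_proportions(make_fm(matrix(NA_integer_, 5, 1,
                                              dimnames = list(NULL, "F1"))))
  expect_true(is.na(allna$proportion))
})
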