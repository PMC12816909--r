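#' @title Feature-enrichment statistics
#' @description Two-tailed Fisher exact tests on 2x2 feature-presence
#'   tables, odds ratios with Woolf 95% confidence intervals and
#'   Haldane-Anscombe zero-cell correction, Bonferroni adjustment,
#'   association calls, stratified comparisons, feature proportions with
#'   Wilson intervals, and a z-scored log odds-ratio meta-analysis.
#' @name enrichment
NULL

as_table_counts <- function(table) {
  if (is.matrix(table)) table <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  if (length(table) != 4L || any(is.na(table)) || any(table < 0) ||
      any(table != round(table))) {
    stop("a 2x2 table needs four non-negative integer counts (a, b, c, d)")
  }
  as.numeric(table)
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the probability
#' of the observed table. Floating-point ties are resolved with the
#' conventional relative tolerance of 1e-7 (the rule base R's
#' `fisher.test` uses), so exactly tied tables are always included.
#'
#' @param table Counts `(a, b, c, d)` — feature-present/absent in the
#'   pathogenic group, then in the benign group — as a length-4 vector or a
#'   2x2 matrix.
#' @return The p-value in (0, 1\], or `NA` when a row or column margin is
#'   zero (no information; callers mark such features insufficient).
#' @export
fisher_two_tailed <- function(table) {
  x <- as_table_counts(table)
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(NA_real_)
  support <- max(0, k - m2):min(k, m1)
  dens <- dhyper(support, m1, m2, k)
  obs <- dens[match(a, support)]
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Odds ratio with Woolf confidence interval
#'
#' `OR = (a d) / (b c)`. When any cell is zero, the Haldane-Anscombe
#' correction adds 0.5 to all four cells before computing the OR and its
#' interval, keeping effect sizes finite. The confidence interval is the
#' Woolf log interval `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` on
#' the (corrected) cells.
#'
#' @param table Counts `(a, b, c, d)` as in [fisher_two_tailed()].
#' @param alpha Two-sided error rate (default 0.05 for a 95% interval).
#' @return Named numeric vector `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio_ci <- function(table, alpha = 0.05) {
  x <- as_table_counts(table)
  if (any(x == 0)) x <- x + 0.5
  or <- (x[1] * x[4]) / (x[2] * x[3])
  se <- sqrt(sum(1 / x))
  z <- qnorm(1 - alpha / 2)
  c(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se))
}

#' Bonferroni adjustment
#'
#' `q = min(p * m, 1)` where `m` is the number of tests actually performed
#' (features that were untestable for insufficient counts do not count
#' toward `m`).
#'
#' @param p_values Numeric vector of p-values (`NA` allowed and preserved).
#' @param m Number of tests performed; must be at least the number of
#'   non-`NA` p-values.
#' @return Adjusted q-values, same length and order as `p_values`.
#' @export
adjust_bonferroni <- function(p_values, m = sum(!is.na(p_values))) {
  if (length(p_values) == 0L) return(numeric(0))
  if (is.na(m) || m <= 0) stop("m must be a positive test count")
  if (m < sum(!is.na(p_values))) stop("m is smaller than the number of p-values tested")
  pmin(p_values * m, 1)
}

feature_counts <- function(path_col, benign_col) {
  c(a = sum(path_col == 1L, na.rm = TRUE), b = sum(path_col == 0L, na.rm = TRUE),
    c = sum(benign_col == 1L, na.rm = TRUE), d = sum(benign_col == 0L, na.rm = TRUE))
}

#' Compare two feature matrices feature-by-feature
#'
#' For every feature of the shared registry, builds the 2x2 table of
#' feature presence in the pathogenic versus benign matrix (`NA` cells
#' excluded from both numerator and denominator), flags insufficiency (any
#' zero margin, or fewer than `min_count` feature-present variants across
#' both groups), and for testable features computes the two-tailed Fisher
#' p, the OR with Woolf confidence interval (Haldane-Anscombe corrected for
#' zero cells), and the Bonferroni q over `m` = number of testable
#' features. A feature is `pathogenic_associated` when `OR > 1` and
#' `q < 0.05`, `benign_associated` when `OR < 1` and `q < 0.05`, and
#' `not_significant` otherwise.
#'
#' @param pathogenic,benign `feature_matrix` objects with identical
#'   registries.
#' @param min_count Minimum feature-present total `a + c` for testability
#'   (default 5).
#' @param alpha Significance level for calls and intervals (default 0.05).
#' @return Data frame with one row per feature: counts `a`,`b`,`c`,`d`,
#'   `or`, `ci_low`, `ci_high`, `p`, `q`, `log10_or`, `call`.
#' @export
compare_feature_sets <- function(pathogenic, benign, min_count = 5L, alpha = 0.05) {
  reg_p <- attr(pathogenic, "registry") %||% FEATURE_REGISTRY
  reg_b <- attr(benign, "registry") %||% FEATURE_REGISTRY
  if (!identical(reg_p, reg_b)) {
    stop("feature registries differ: ",
         paste(union(setdiff(reg_p, reg_b), setdiff(reg_b, reg_p)), collapse = ", "))
  }
  res <- data.frame(
    feature = reg_p, a = NA_integer_, b = NA_integer_, c = NA_integer_,
    d = NA_integer_, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
    p = NA_real_, q = NA_real_, log10_or = NA_real_,
    call = "insufficient", stringsAsFactors = FALSE
  )
  for (i in seq_along(reg_p)) {
    f <- reg_p[i]
    cnt <- feature_counts(pathogenic[[f]], benign[[f]])
    res[i, c("a", "b", "c", "d")] <- as.integer(cnt)
    zero_margin <- (cnt["a"] + cnt["b"]) == 0 || (cnt["c"] + cnt["d"]) == 0 ||
      (cnt["a"] + cnt["c"]) == 0 || (cnt["b"] + cnt["d"]) == 0
    if (zero_margin || (cnt["a"] + cnt["c"]) < min_count) next
    orci <- odds_ratio_ci(cnt, alpha = alpha)
    res$or[i] <- orci["or"]
    res$ci_low[i] <- orci["ci_low"]
    res$ci_high[i] <- orci["ci_high"]
    res$p[i] <- fisher_two_tailed(cnt)
    # summed-log form so that swapping the matrices negates log10(OR)
    # exactly, not merely to rounding
    x <- as.numeric(cnt)
    if (any(x == 0)) x <- x + 0.5
    res$log10_or[i] <- (log10(x[1]) + log10(x[4])) - (log10(x[2]) + log10(x[3]))
    res$call[i] <- "testable"
  }
  testable <- res$call == "testable"
  m <- sum(testable)
  if (m > 0) {
    res$q[testable] <- adjust_bonferroni(res$p[testable], m = m)
    res$call[testable] <- ifelse(
      res$q[testable] < alpha & res$or[testable] > 1, "pathogenic_associated",
      ifelse(res$q[testable] < alpha & res$or[testable] < 1, "benign_associated",
             "not_significant")
    )
  }
  attr(res, "m") <- m
  res
}

#' Stratified feature comparison
#'
#' Runs [compare_feature_sets()] once per stratum. In `protein_class` mode
#' both matrices are restricted to the stratum (the comparison is
#' within-class); in `disease_category` mode only the pathogenic matrix is
#' restricted and the full benign matrix is the comparator, matching the
#' design of disease-stratified analyses against a population background.
#' Variants with `NA` stratum labels are excluded. A stratum with no
#' pathogenic variants (or, in protein-class mode, absent from the benign
#' matrix) yields an all-insufficient row block.
#'
#' @param pathogenic,benign `feature_matrix` objects carrying the stratum
#'   column.
#' @param by `"protein_class"` or `"disease_category"`.
#' @param strata Stratum values to analyse; default all values present in
#'   the pathogenic matrix.
#' @param ... Passed to [compare_feature_sets()].
#' @return Long data frame: `stratum` plus the [compare_feature_sets()]
#'   columns; pivot with [heatmap_table()] for plotting.
#' @export
stratified_compare <- function(pathogenic, benign,
                               by = c("protein_class", "disease_category"),
                               strata = NULL, ...) {
  by <- match.arg(by)
  labels_p <- pathogenic[[by]]
  if (is.null(labels_p)) stop("pathogenic matrix lacks stratum column '", by, "'")
  if (is.null(strata)) strata <- sort(unique(labels_p[!is.na(labels_p)]))
  out <- list()
  for (s in strata) {
    sub_p <- pathogenic[!is.na(labels_p) & labels_p == s, , drop = FALSE]
    sub_b <- if (by == "protein_class") {
      labels_b <- benign[[by]]
      benign[!is.na(labels_b) & labels_b == s, , drop = FALSE]
    } else {
      benign
    }
    attr(sub_p, "registry") <- attr(pathogenic, "registry")
    attr(sub_b, "registry") <- attr(benign, "registry")
    res <- compare_feature_sets(sub_p, sub_b, ...)
    res$stratum <- s
    out[[s]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("stratum", setdiff(names(res), "stratum"))]
}

#' Heatmap-ready table from stratified results
#'
#' Pivots [stratified_compare()] output into a strata-by-features matrix of
#' `log10(OR)` plus a parallel matrix of call flags, which distinguish
#' `not_significant` (testable, no association) from `insufficient` (not
#' enough data).
#'
#' @param stratified Output of [stratified_compare()].
#' @return List with matrices `log10_or` and `call` (strata in rows,
#'   features in columns).
#' @export
heatmap_table <- function(stratified) {
  strata <- unique(stratified$stratum)
  features <- unique(stratified$feature)
  shape <- function(col, default) {
    m <- matrix(default, length(strata), length(features),
                dimnames = list(strata, features))
    m[cbind(match(stratified$stratum, strata), match(stratified$feature, features))] <-
      stratified[[col]]
    m
  }
  list(log10_or = shape("log10_or", NA_real_), call = shape("call", NA_character_))
}

#' Z-scored log odds ratios across dataset comparisons
#'
#' Standardises each feature's `log10(OR)` values across two or more
#' dataset comparisons: `z = (x - mean) / sd` with the population standard
#' deviation, computed per feature. Features whose association direction
#' flips between comparisons (a sign change of `log10(OR)`) are flagged
#' `inverted`; features with identical values across comparisons get
#' `z = 0` and a `degenerate` flag; a feature observed in a single
#' comparison gets `NA`.
#'
#' @param results Data frame with columns `feature`, `comparison`,
#'   `log10_or` (e.g. row-bound [compare_feature_sets()] outputs with a
#'   `comparison` label added).
#' @return The input with `z`, `degenerate` and `inverted` columns added.
#' @export
zscore_log_or <- function(results) {
  need <- c("feature", "comparison", "log10_or")
  miss <- setdiff(need, names(results))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  results$z <- NA_real_
  results$degenerate <- FALSE
  results$inverted <- FALSE
  for (f in unique(results$feature)) {
    rows <- which(results$feature == f & !is.na(results$log10_or))
    x <- results$log10_or[rows]
    if (length(x) < 2L) next
    sd_pop <- sqrt(mean((x - mean(x))^2))
    if (sd_pop == 0) {
      results$z[rows] <- 0
      results$degenerate[rows] <- TRUE
    } else {
      results$z[rows] <- (x - mean(x)) / sd_pop
    }
    results$inverted[rows] <- any(x > 0) && any(x < 0)
  }
  results
}

#' Per-feature presence proportions with Wilson intervals
#'
#' The proportion of variants carrying each feature (`NA` cells excluded
#' from numerator and denominator) with a Wilson score interval at
#' `1 - alpha`; the landscape behind per-dataset feature histograms.
#'
#' @param fm A `feature_matrix`.
#' @param alpha Two-sided error rate (default 0.05).
#' @return Data frame: `feature`, `n` (non-`NA` cells), `present`,
#'   `proportion`, `ci_low`, `ci_high`; all-`NA` features yield `NA`.
#' @export
feature_proportions <- function(fm, alpha = 0.05) {
  reg <- attr(fm, "registry") %||% FEATURE_REGISTRY
  z <- qnorm(1 - alpha / 2)
  out <- data.frame(feature = reg, n = NA_integer_, present = NA_integer_,
                    proportion = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(reg)) {
    cells <- fm[[reg[i]]]
    n <- sum(!is.na(cells))
    out$n[i] <- n
    if (n == 0L) next
    x <- sum(cells == 1L, na.rm = TRUE)
    phat <- x / n
    denom <- 1 + z^2 / n
    centre <- (phat + z^2 / (2 * n)) / denom
    half <- (z / denom) * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
    out$present[i] <- x
    out$proportion[i] <- phat
    out$ci_low[i] <- max(0, centre - half)
    out$ci_high[i] <- min(1, centre + half)
  }
  out
}
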