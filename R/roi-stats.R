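# Two-group cohort statistics: normality-gated test selection, Cohen's d
# and r effect sizes with the conventional interpretive cutoffs,
# categorical tests, correlation, and Bonferroni adjustment.

#' Interpret effect sizes by conventional cutoffs
#'
#' Cohen's d: trivial `[0, 0.2)`, small `[0.2, 0.5)`, medium `[0.5, 0.8)`,
#' large `>= 0.8`.  r: trivial `[0, 0.1)`, small `[0.1, 0.3)`, medium
#' `[0.3, 0.5)`, large `>= 0.5`.
#'
#' @param d,r effect-size values (absolute value is taken).
#' @return character vector of interpretations.
#' @export
interpret_d <- function(d) {
  cut(abs(d), breaks = c(0, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("trivial", "small", "medium", "large")) |> as.character()
}

#' @rdname interpret_d
#' @export
interpret_r <- function(r) {
  cut(abs(r), breaks = c(0, 0.1, 0.3, 0.5, Inf), right = FALSE,
      labels = c("trivial", "small", "medium", "large")) |> as.character()
}

#' Pooled-SD Cohen's d from summary statistics
#'
#' `d = |mean_b - mean_a| / s_pooled` with
#' `s_pooled = sqrt(((n_a-1) sd_a^2 + (n_b-1) sd_b^2) / (n_a+n_b-2))`.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summary statistics;
#'   vectorized.
#' @return data.frame with columns `d` and `interpretation`.  Both SDs
#'   zero gives `NA` (flagged undefined).
#' @export
cohens_d_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(all(sd_a >= 0), all(sd_b >= 0), all(n_a >= 2), all(n_b >= 2))
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  d <- abs(mean_b - mean_a) / sp
  d[sp == 0] <- NA_real_
  data.frame(d = d, interpretation = ifelse(is.na(d), NA_character_,
                                            interpret_d(d)))
}

#' Cohen's d from raw samples
#' @param a,b numeric sample vectors.
#' @return scalar pooled-SD d (absolute).
#' @export
cohens_d <- function(a, b) {
  cohens_d_from_summary(mean(a), stats::sd(a), length(a),
                        mean(b), stats::sd(b), length(b))$d
}

#' Normality-gated two-group comparison
#'
#' Runs a one-sample Kolmogorov-Smirnov normality check (against a normal
#' with the sample's own mean and SD, as common statistical packages do)
#' on each group; when both pass at `alpha_normality` an independent
#' two-sample t-test is used, otherwise the Mann-Whitney U test (exact for
#' groups of <= 25 without ties, normal approximation with tie correction
#' otherwise).  Alongside the p-value it reports Cohen's d from the raw
#' samples and the companion correlation-type effect size r
#' (`sqrt(t^2/(t^2+df))` for the t-test, `|Z|/sqrt(N)` for Mann-Whitney).
#'
#' @param a,b numeric samples, each of length >= 3.
#' @param alpha_normality significance level of the normality gate
#'   (default 0.05).
#' @param var_equal use the pooled-variance (Student) t-test (default) or
#'   Welch.
#' @return list of class `comparison_result`: `test` ("student_t",
#'   "welch_t" or "mann_whitney"), `statistic`, `p`, `d`,
#'   `d_interpretation`, `r`, `r_interpretation`, `normality_p` (length
#'   2).  Degenerate input (both groups constant) is flagged with
#'   `test = "degenerate"` and NA results.
#' @export
choose_and_run_test <- function(a, b, alpha_normality = 0.05,
                                var_equal = TRUE) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(structure(list(test = "degenerate", statistic = NA_real_,
                          p = NA_real_, d = NA_real_,
                          d_interpretation = NA_character_,
                          r = NA_real_, r_interpretation = NA_character_,
                          normality_p = c(NA_real_, NA_real_)),
                     class = "comparison_result"))
  }
  ks_p <- function(x) {
    if (stats::sd(x) == 0) return(0)  # constant: certainly not normal
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  np <- c(ks_p(a), ks_p(b))
  n_tot <- length(a) + length(b)
  if (all(np > alpha_normality)) {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    r <- sqrt(tt$statistic^2 / (tt$statistic^2 + tt$parameter))
    res <- list(test = if (var_equal) "student_t" else "welch_t",
                statistic = unname(tt$statistic), p = tt$p.value,
                r = unname(r))
  } else {
    n1 <- length(a); n2 <- length(b)
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- !ties && max(n1, n2) <= 25
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    u <- unname(wt$statistic)
    pooled <- c(a, b)
    rk_ties <- table(rank(pooled))
    tie_term <- sum(rk_ties^3 - rk_ties) / (n_tot * (n_tot - 1))
    sd_u <- sqrt(n1 * n2 / 12 * (n_tot + 1 - tie_term))
    z <- (u - n1 * n2 / 2) / sd_u
    res <- list(test = "mann_whitney", statistic = u, p = wt$p.value,
                r = abs(z) / sqrt(n_tot))
  }
  d <- cohens_d(a, b)
  structure(c(res[c("test", "statistic", "p")],
              list(d = d, d_interpretation = interpret_d(d),
                   r = res$r, r_interpretation = interpret_r(res$r),
                   normality_p = np)),
            class = "comparison_result")
}

#' Categorical two-group comparison
#'
#' Chi-square test of a 2x2 count table, switching to Fisher's exact test
#' when any expected cell count is below 5 or any observed cell is zero
#' (`method = "auto"`).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param method `"auto"` (expected-count rule), `"chisq"` (uncorrected
#'   chi-square) or `"fisher"`.
#' @return list of class `comparison_result` with `test`, `statistic`
#'   (X^2 or odds ratio), `p`.
#' @export
categorical_test <- function(table, method = c("auto", "chisq", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (sum(table) == 0) stop("empty contingency table")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (method == "auto")
    method <- if (any(expected < 5) || any(table == 0)) "fisher" else "chisq"
  if (method == "fisher") {
    ft <- stats::fisher.test(table)
    structure(list(test = "fisher_exact",
                   statistic = unname(ft$estimate), p = ft$p.value),
              class = "comparison_result")
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    structure(list(test = "chi_square",
                   statistic = unname(ct$statistic), p = ct$p.value),
              class = "comparison_result")
  }
}

#' Correlation with two-tailed p-value
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param method `"pearson"` or `"spearman"`.
#' @return list of class `correlation_result`: `r`, `p`, `method`,
#'   `r_interpretation`.  Zero variance in either variable gives NA
#'   (flagged).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(r = NA_real_, p = NA_real_, method = method,
                          r_interpretation = NA_character_,
                          reason = "zero_variance"),
                     class = "correlation_result"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  structure(list(r = unname(ct$estimate), p = ct$p.value, method = method,
                 r_interpretation = interpret_r(unname(ct$estimate)),
                 reason = NA_character_),
            class = "correlation_result")
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)`, order preserved.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param m number of comparisons; defaults to `length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(all(p >= 0), all(p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Group comparison report in summary-table layout
#'
#' Runs the normality-gated comparison per region of a long-format cohort
#' table and assembles a report with group means +/- SD, raw and
#' Bonferroni-adjusted p-values, and both effect sizes.
#'
#' @param cohort data.frame with columns `subject_id`, `group`, `region`,
#'   `value` (as produced by [simulate_cohort()]).
#' @param group_order length-2 character giving which group is reported
#'   first; defaults to the order of appearance.
#' @param alpha_normality normality-gate level.
#' @return data.frame with one row per region: `region`, `mean_a`, `sd_a`,
#'   `n_a`, `mean_b`, `sd_b`, `n_b`, `test`, `p`, `p_bonferroni`, `d`,
#'   `d_interpretation`, `r`, `r_interpretation`.
#' @export
report_table <- function(cohort, group_order = NULL,
                         alpha_normality = 0.05) {
  stopifnot(nrow(cohort) > 0,
            all(c("group", "region", "value") %in% names(cohort)))
  groups <- if (is.null(group_order)) unique(cohort$group) else group_order
  stopifnot(length(groups) == 2L)
  regions <- unique(cohort$region)
  rows <- lapply(regions, function(rg) {
    a <- cohort$value[cohort$region == rg & cohort$group == groups[1L]]
    b <- cohort$value[cohort$region == rg & cohort$group == groups[2L]]
    cmp <- choose_and_run_test(a, b, alpha_normality)
    data.frame(region = rg,
               mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
               test = cmp$test, p = cmp$p, d = cmp$d,
               d_interpretation = cmp$d_interpretation,
               r = cmp$r, r_interpretation = cmp$r_interpretation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p)
  out[, c("region", "mean_a", "sd_a", "n_a", "mean_b", "sd_b", "n_b",
          "test", "p", "p_bonferroni", "d", "d_interpretation",
          "r", "r_interpretation")]
}
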