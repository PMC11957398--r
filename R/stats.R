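#' Assumption-guided two-sample comparison
#'
#' Runs Shapiro-Wilk normality tests on both samples and Levene's test for
#' homogeneity of variance (both at `assumption_alpha`); if every test
#' passes, compares the groups with a pooled-variance two-sample t-test,
#' otherwise with the Mann-Whitney U test. Two-sided throughout. The choice
#' is a pure function of the two samples and the thresholds, and the
#' assumption decisions are recorded on the result.
#'
#' @param sample_a,sample_b numeric vectors, `n >= 3` each.
#' @param metric label carried onto the result.
#' @param alpha significance threshold the comparison is judged against
#'   (typically Bonferroni-corrected).
#' @param assumption_alpha threshold for the normality/homogeneity tests.
#' @return object of class `comparison_result`: `metric`, `test`
#'   (`"t"`/`"mann_whitney"`), `statistic`, `p`, `alpha`, `significant`, and
#'   the assumption p-values.
#' @export
choose_and_run_test <- function(sample_a, sample_b, metric = "",
                                alpha = 0.05, assumption_alpha = 0.05) {
  stopifnot(length(sample_a) >= 3, length(sample_b) >= 3)
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0 &&
      sample_a[1] == sample_b[1]) {
    return(structure(list(metric = metric, test = "none", statistic = NA_real_,
                          p = 1, alpha = alpha, significant = FALSE,
                          normality_p = c(NA, NA), levene_p = NA),
                     class = "comparison_result"))
  }
  norm_p <- c(a = tryCatch(stats::shapiro.test(sample_a)$p.value,
                           error = function(e) 0),
              b = tryCatch(stats::shapiro.test(sample_b)$p.value,
                           error = function(e) 0))
  grp <- factor(rep(c("a", "b"), c(length(sample_a), length(sample_b))))
  lev_p <- tryCatch(
    car::leveneTest(c(sample_a, sample_b) ~ grp)[1, "Pr(>F)"],
    error = function(e) 0)
  parametric <- all(norm_p > assumption_alpha) && lev_p > assumption_alpha
  if (parametric) {
    ht <- stats::t.test(sample_a, sample_b, var.equal = TRUE)
    test <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(sample_a, sample_b,
                                              exact = FALSE))
    test <- "mann_whitney"
  }
  structure(list(metric = metric, test = test,
                 statistic = unname(ht$statistic), p = ht$p.value,
                 alpha = alpha, significant = ht$p.value < alpha,
                 normality_p = norm_p, levene_p = lev_p),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: %s test, stat = %.4g, p = %.4g (alpha = %g)%s\n",
              x$metric, x$test, x$statistic, x$p, x$alpha,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param m number of comparisons in the family (e.g. 4 group-by-condition
#'   cells give 0.05 / 4 = 0.0125).
#' @return corrected per-comparison threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Empirical type-I error of the comparison procedure
#'
#' Repeatedly draws two samples from the same distribution, runs
#' [choose_and_run_test()], and reports the fraction of replicates declared
#' significant at `alpha`.
#'
#' @param n_reps replicates.
#' @param n per-group sample size.
#' @param alpha significance threshold.
#' @param sampler function(n) drawing one sample under the null.
#' @param seed RNG seed.
#' @return empirical false-positive rate.
#' @export
type_i_error_check <- function(n_reps = 2000, n = 15, alpha = 0.05,
                               sampler = stats::rnorm, seed = 1L) {
  if (alpha <= 0) return(0)
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_reps)) {
    res <- choose_and_run_test(sampler(n), sampler(n), alpha = alpha)
    if (isTRUE(res$significant)) hits <- hits + 1L
  }
  hits / n_reps
}
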