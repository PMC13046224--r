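# Normality-gated statistics: each variable (per group) is screened with the
# Shapiro-Wilk test; parametric procedures (t test, Pearson) are used only
# when every group involved passes, otherwise the rank-based analogue
# (Mann-Whitney U, Spearman) is used. All tests are two-sided.

#' Education-adjusted MoCA score
#'
#' One point is added for participants with 12 or fewer years of formal
#' education, and the result is capped at the instrument maximum of 30.
#'
#' @param raw raw MoCA total (0-30), vectorised.
#' @param education_years years of formal education, vectorised.
#' @return adjusted scores.
#' @export
adjust_moca <- function(raw, education_years) {
  if (any(is.na(raw)) || any(raw < 0 | raw > 30))
    stop("data error: raw MoCA scores must lie in [0, 30]")
  pmin(30, raw + as.numeric(education_years <= 12))
}

shapiro_p <- function(x) {
  n <- length(x)
  if (n > 5000) x <- sort(x)[round(seq(1, n, length.out = 5000))]
  shapiro.test(x)$p.value
}

nav_test_result <- function(test_name, statistic, p_value, n, normal_p) {
  structure(list(test_name = test_name,
                 statistic = unname(statistic),
                 p_value = unname(p_value),
                 n = n, normal_p = normal_p),
            class = "nav_test")
}

#' @export
print.nav_test <- function(x, ...) {
  cat(sprintf("<nav_test> %s: statistic=%.4g, p=%.4g (n=%s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk is run on each group at `alpha_normal`; if both groups pass,
#' an independent-samples (Welch) t test is used, otherwise the Mann-Whitney
#' U test. Two-sided either way.
#'
#' @param x,y numeric samples for the two groups (each n >= 3).
#' @param alpha_normal significance level of the normality gate.
#' @return a `nav_test` result: `test_name` (`"t"` or `"mann_whitney"`),
#'   `statistic`, `p_value`, per-group `n`, and the gate's Shapiro p-values.
#' @export
choose_and_run_two_sample <- function(x, y, alpha_normal = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("each group needs at least 3 finite observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: a group is constant")
  px <- shapiro_p(x); py <- shapiro_p(y)
  if (px > alpha_normal && py > alpha_normal) {
    tt <- t.test(x, y, alternative = "two.sided")
    nav_test_result("t", tt$statistic, tt$p.value,
                    c(length(x), length(y)), c(px, py))
  } else {
    wt <- suppressWarnings(
      wilcox.test(x, y, alternative = "two.sided", exact = FALSE, correct = TRUE))
    nav_test_result("mann_whitney", wt$statistic, wt$p.value,
                    c(length(x), length(y)), c(px, py))
  }
}

#' Normality-gated correlation
#'
#' Pearson when both variables pass the Shapiro-Wilk gate, Spearman rank
#' correlation otherwise; two-sided p either way.
#'
#' @param x,y paired numeric vectors (n >= 4 complete pairs).
#' @param alpha_normal significance level of the normality gate.
#' @return a `nav_test` result with `test_name` (`"pearson"`/`"spearman"`)
#'   and `statistic` = the correlation coefficient r.
#' @export
choose_and_run_correlation <- function(x, y, alpha_normal = 0.05) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("correlation needs at least 4 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate input: zero-variance variable")
  px <- shapiro_p(x); py <- shapiro_p(y)
  method <- if (px > alpha_normal && py > alpha_normal) "pearson" else "spearman"
  ct <- suppressWarnings(
    cor.test(x, y, method = method, alternative = "two.sided", exact = FALSE))
  nav_test_result(method, ct$estimate, ct$p.value, length(x), c(px, py))
}
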