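#' Statistical workflow for ossicular-chain measurements
#'
#' Replicates the study's analysis plan: intraclass correlation for
#' replicate consistency and method agreement, normality-gated paired and
#' two-sample comparisons, normality/homogeneity-gated multi-group
#' comparisons, and a chi-square goodness-of-fit for demographics. All
#' results are returned as classed lists with [tidy()] methods so they drop
#' straight into tibble workflows.
#'
#' @name stats_analysis
NULL

comparison_result <- function(test_name, statistic, p_value, n, normality_used,
                              group_labels = NULL, flags = character(), extra = list()) {
  structure(c(list(test_name = test_name, statistic = unname(statistic),
                   p_value = unname(p_value), n = n,
                   normality_used = normality_used,
                   group_labels = group_labels, flags = flags), extra),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$test_name, ": statistic = ",
      format(x$statistic, digits = 4), ", p = ", format(x$p_value, digits = 4),
      " (n = ", paste(x$n, collapse = "/"), ")\n", sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Intraclass correlation for replicate consistency, ICC(3,1)
#'
#' Two-way mixed-effects, consistency, single-measure ICC from the
#' two-way ANOVA decomposition:
#' `ICC = (MS_subjects - MS_error) / (MS_subjects + (k - 1) MS_error)`.
#' Values below 0.4 are labelled poor and above 0.75 high consistency.
#'
#' @param values numeric matrix, subjects in rows, replicates (or methods)
#'   in columns; no missing cells.
#' @return An `icc_result` with `icc`, `model_tag`, `n_subjects`,
#'   `n_raters`, `consistency_band`.
#' @export
icc_consistency <- function(values) {
  m <- as.matrix(values)
  if (anyNA(m)) stop("input error: ICC requires complete subject x replicate cells", call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("input error: need at least 2 subjects and 2 replicates", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- if (msr + (k - 1) * mse == 0) 1 else (msr - mse) / (msr + (k - 1) * mse)
  band <- if (icc < 0.4) "poor" else if (icc > 0.75) "high" else "moderate"
  structure(list(icc = icc, model_tag = "ICC(3,1) two-way mixed, consistency, single measure",
                 n_subjects = n, n_raters = k, consistency_band = band),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc_result> ICC = ", format(x$icc, digits = 4), " [", x$consistency_band,
      "] (", x$model_tag, "; n = ", x$n_subjects, " x ", x$n_raters, ")\n", sep = "")
  invisible(x)
}

shapiro_ok <- function(x, alpha) {
  # Shapiro-Wilk supports 3 <= n <= 5000; constant input counts as non-normal
  if (length(unique(x)) < 3) return(FALSE)
  x <- if (length(x) > 5000) x[seq_len(5000)] else x
  stats::shapiro.test(x)$p.value >= alpha
}

#' Paired comparison with normality gating
#'
#' Shapiro-Wilk on the paired differences decides between the paired t test
#' (normal) and the Wilcoxon signed-rank test (non-normal), two-sided.
#' Identical vectors short-circuit to p = 1 with an exact-equality flag.
#'
#' @param x,y paired numeric vectors of equal length (>= 3).
#' @param alpha gate (and test) significance level.
#' @export
paired_comparison <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("input error: x and y must be paired", call. = FALSE)
  if (length(x) < 3) stop("input error: need at least 3 pairs", call. = FALSE)
  d <- x - y
  if (all(d == 0))
    return(comparison_result("paired t", 0, 1, length(x), NA,
                             flags = "exact-equality: zero-variance differences"))
  normal <- shapiro_ok(d, alpha)
  if (normal) {
    tt <- stats::t.test(x, y, paired = TRUE)
    comparison_result("paired t", tt$statistic, tt$p.value, length(x), TRUE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE))
    comparison_result("Wilcoxon signed-rank", wt$statistic, wt$p.value, length(x), FALSE)
  }
}

#' Independent two-group comparison with normality gating
#'
#' Shapiro-Wilk per group gates between the independent-samples t test
#' (Welch-corrected when Levene's test rejects equal variances) and the
#' Mann-Whitney U test; two-sided.
#'
#' @param x,y numeric vectors (each n >= 3).
#' @param alpha significance level for the gates.
#' @export
group_comparison <- function(x, y, alpha = 0.05) {
  if (length(x) < 3 || length(y) < 3)
    stop("input error: each group needs n >= 3", call. = FALSE)
  if (length(x) == length(y) && all(sort(x) == sort(y)) && stats::var(c(x, y)) == 0)
    return(comparison_result("independent t", 0, 1, c(length(x), length(y)), NA,
                             flags = "exact-tie: identical constant samples"))
  normal <- shapiro_ok(x, alpha) && shapiro_ok(y, alpha)
  if (normal) {
    lev <- levene_p(list(x, y))
    equal_var <- lev >= alpha
    tt <- stats::t.test(x, y, var.equal = equal_var)
    comparison_result(if (equal_var) "independent t" else "Welch t",
                      tt$statistic, tt$p.value, c(length(x), length(y)), TRUE,
                      extra = list(levene_p = lev))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    # normal-approximation Z for reporting alongside U
    z <- stats::qnorm(wt$p.value / 2) * sign(stats::median(x) - stats::median(y))
    comparison_result("Mann-Whitney U", wt$statistic, wt$p.value,
                      c(length(x), length(y)), FALSE,
                      extra = list(z_approx = z))
  }
}

levene_p <- function(groups) {
  v <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(v) == 0) return(1)
  car::leveneTest(v ~ g)[1, "Pr(>F)"]
}

#' Multi-group comparison with normality and homogeneity gating
#'
#' Per-group Shapiro-Wilk plus Levene's homogeneity test gate between
#' one-way ANOVA and the Kruskal-Wallis rank-sum test; gate decisions are
#' recorded on the result.
#'
#' @param groups list of >= 3 numeric vectors (each n >= 2).
#' @param alpha significance level for the gates.
#' @export
multi_group_comparison <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 3)
    stop("input error: need at least 3 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("input error: each group needs n >= 2", call. = FALSE)
  v <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(v) == 0)
    return(comparison_result("one-way ANOVA", 0, 1, lengths(groups), NA,
                             flags = "exact-tie: all values identical"))
  normal <- all(vapply(groups, shapiro_ok, logical(1), alpha = alpha))
  homo <- levene_p(groups) >= alpha
  if (normal && homo) {
    fit <- stats::aov(v ~ g)
    s <- summary(fit)[[1]]
    comparison_result("one-way ANOVA", s[1, "F value"], s[1, "Pr(>F)"],
                      lengths(groups), TRUE,
                      extra = list(gates = c(normal = normal, homogeneous = homo)))
  } else {
    kw <- stats::kruskal.test(v, g)
    comparison_result("Kruskal-Wallis", kw$statistic, kw$p.value, lengths(groups), FALSE,
                      extra = list(gates = c(normal = normal, homogeneous = homo)))
  }
}

#' Chi-square goodness of fit
#'
#' Pearson chi-square of observed counts against expected proportions
#' (uniform by default), df = k - 1.
#'
#' @param observed non-negative count vector with a positive total.
#' @param expected expected proportions (recycled/normalized); default
#'   uniform.
#' @export
chi_square_gof <- function(observed, expected = NULL) {
  if (any(observed < 0) || sum(observed) <= 0)
    stop("input error: counts must be non-negative with a positive total", call. = FALSE)
  p <- if (is.null(expected)) rep(1 / length(observed), length(observed))
       else expected / sum(expected)
  ct <- suppressWarnings(stats::chisq.test(observed, p = p))
  comparison_result("chi-square GOF", ct$statistic, ct$p.value, sum(observed), NA,
                    extra = list(df = unname(ct$parameter)))
}
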