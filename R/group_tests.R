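#' Group-comparison statistics used across the mosaic analyses
#'
#' A thin, tidy wrapper over the standard tests applied to mosaic statistics
#' and arbor measurements: two-tailed Student's t, two-tailed Mann-Whitney
#' (Wilcoxon rank-sum with midranks for ties), one-way ANOVA with Tukey's
#' post-hoc contrasts (multiplicity-corrected), chi-squared on a
#' contingency table, and Levene's variance test (group means as centers).
#' All p-values are two-sided; the conventional alpha is 0.05.
#'
#' @param values Numeric vector of observations (for `"chisq"`, a matrix or
#'   table of counts; `group` is then ignored).
#' @param group Factor (or coercible) of group labels, same length as
#'   `values`.
#' @param test One of `"t"`, `"mann_whitney"`, `"anova_tukey"`, `"chisq"`,
#'   `"levene"`.
#' @param var_equal For `"t"`: pooled-variance (default TRUE, so that with
#'   two groups the one-way ANOVA F equals t^2).
#' @return A data.frame with one row per comparison: `test`, `contrast`,
#'   `statistic`, `p_value`, `degenerate`.
#' @export
run_group_tests <- function(values, group = NULL,
                            test = c("t", "mann_whitney", "anova_tukey",
                                     "chisq", "levene"),
                            var_equal = TRUE) {
  test <- match.arg(test)
  row <- function(contrast, statistic, p, degenerate = FALSE) {
    data.frame(test = test, contrast = contrast, statistic = statistic,
               p_value = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  }
  if (test == "chisq") {
    tab <- as.table(as.matrix(values))
    if (any(dim(tab) < 2)) {
      return(row("table", NA_real_, NA_real_, TRUE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(row("table", unname(ct$statistic), ct$p.value))
  }
  group <- factor(group)
  if (length(group) != length(values)) {
    stop("values and group lengths differ", call. = FALSE)
  }
  n_per <- table(group)
  if (test %in% c("t", "mann_whitney", "levene") && nlevels(group) != 2) {
    stop("two-sample test needs exactly 2 groups", call. = FALSE)
  }
  contrast2 <- paste(levels(group), collapse = " vs ")
  if (test == "t") {
    if (any(n_per < 2) || all(stats::ave(values, group,
                                         FUN = stats::sd) == 0)) {
      return(row(contrast2, NA_real_, NA_real_, TRUE))
    }
    tt <- stats::t.test(values ~ group, var.equal = var_equal)
    return(row(contrast2, unname(tt$statistic), tt$p.value))
  }
  if (test == "mann_whitney") {
    if (any(n_per < 1)) return(row(contrast2, NA_real_, NA_real_, TRUE))
    wt <- suppressWarnings(stats::wilcox.test(values ~ group,
                                              exact = FALSE, correct = TRUE))
    return(row(contrast2, unname(wt$statistic), wt$p.value))
  }
  if (test == "levene") {
    lv <- variance_equality_test(values[group == levels(group)[1]],
                                 values[group == levels(group)[2]])
    return(row(contrast2, lv$f_ratio, lv$p_value, lv$degenerate))
  }
  # anova_tukey
  if (nlevels(group) < 2) {
    stop("ANOVA requires >= 2 groups", call. = FALSE)
  }
  if (any(n_per < 2)) {
    return(row("main effect", NA_real_, NA_real_, TRUE))
  }
  fit <- stats::aov(values ~ group)
  an <- summary(fit)[[1]]
  out <- row("main effect", an[1, "F value"], an[1, "Pr(>F)"])
  tk <- stats::TukeyHSD(fit)$group
  out <- rbind(out, data.frame(
    test = test, contrast = rownames(tk), statistic = tk[, "diff"],
    p_value = tk[, "p adj"], degenerate = FALSE, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
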