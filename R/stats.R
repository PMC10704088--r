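# Descriptive summaries and nonparametric group comparisons for fitted
# cohort parameters.

#' Median and interquartile range summary
#'
#' Exact sample median and 25th/75th percentiles using the
#' linear-interpolation (type 7) quantile definition. Skewed optical
#' parameters are conventionally reported this way rather than as
#' mean +/- SD.
#'
#' @param values Numeric vector, or a data frame / matrix summarized
#'   column-wise.
#' @return Data frame with columns `median`, `p25`, `p75` (one row per
#'   input column).
#' @export
cohort_summary <- function(values) {
  if (is.data.frame(values) || is.matrix(values)) {
    out <- do.call(rbind, lapply(as.data.frame(values), cohort_summary))
    rownames(out) <- colnames(values)
    return(out)
  }
  if (length(values) < 1) stop("at least one observation required")
  qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE,
                 na.rm = TRUE)
  data.frame(median = qs[2], p25 = qs[1], p75 = qs[3])
}

#' Nonparametric group comparison
#'
#' Two groups: Mann-Whitney U test (normal approximation with tie
#' correction). Three or more groups: Kruskal-Wallis test followed by
#' Dunn's pairwise z-tests with Bonferroni-corrected p-values. The
#' significance flag uses p < 0.05.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor), same length.
#' @return List with `method`, `statistic`, `p_value`, `significant`, and
#'   for >= 3 groups a `posthoc` data frame (pairwise z, raw and
#'   Bonferroni-adjusted p, significance).
#' @export
group_tests <- function(values, groups) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  counts <- table(groups)
  if (length(counts) < 2) stop("at least two groups required")
  if (any(counts < 2)) stop("every group needs at least 2 observations")
  if (length(counts) == 2) {
    ht <- wilcox.test(values[groups == levels(groups)[1]],
                      values[groups == levels(groups)[2]],
                      exact = FALSE, correct = FALSE)
    list(method = "mann-whitney", statistic = unname(ht$statistic),
         p_value = ht$p.value, significant = ht$p.value < 0.05)
  } else {
    kw <- kruskal.test(values, groups)
    ph <- dunn_posthoc(values, groups)
    list(method = "kruskal-wallis", statistic = unname(kw$statistic),
         p_value = kw$p.value, significant = kw$p.value < 0.05,
         posthoc = ph)
  }
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise z-tests on mean ranks after a Kruskal-Wallis test, with the
#' standard tie correction; raw two-sided p-values are multiplied by the
#' number of comparisons and capped at 1.
#'
#' @param values Numeric observations.
#' @param groups Group labels (coerced to factor).
#' @return Data frame with one row per group pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  combos <- utils::combn(lev, 2)
  m <- ncol(combos)
  out <- lapply(seq_len(m), function(k) {
    g1 <- combos[1, k]; g2 <- combos[2, k]
    n1 <- sum(groups == g1); n2 <- sum(groups == g2)
    z <- (mean(r[groups == g1]) - mean(r[groups == g2])) /
      sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n1 + 1 / n2))
    p <- 2 * pnorm(-abs(z))
    data.frame(group1 = g1, group2 = g2, z = z, p_raw = p,
               p_adjusted = min(1, p * m))
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_adjusted < 0.05
  out
}

#' Ordinary least-squares trend
#'
#' Linear regression of a parameter on a covariate (e.g. the scattering
#' amplitude on age), returning the slope with its standard error and
#' two-sided p-value.
#'
#' @param x Covariate.
#' @param y Response, same length, n >= 3.
#' @return List with `slope`, `intercept`, `se`, `p_value`, `significant`.
#' @export
trend_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  fit <- lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(slope = cf["x", "Estimate"], intercept = cf["(Intercept)", "Estimate"],
       se = cf["x", "Std. Error"], p_value = cf["x", "Pr(>|t|)"],
       significant = cf["x", "Pr(>|t|)"] < 0.05)
}
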