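# Nonparametric statistical layer ------------------------------------------
#
# Wrappers with fixed conventions: two-sided tests throughout, exact
# small-sample p-values where enumeration is cheap (combined n <= 12 for
# the rank-sum test, n <= 15 for the signed-rank test, no ties), normal /
# chi-square approximations with tie corrections beyond, type-7 quartiles
# for the IQR rule.

test_result <- function(statistic, p_value, n, method, exact) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 method = method, exact = exact),
            class = "trab_test")
}

#' @export
print.trab_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%s; n = %s)\n",
              x$method, x$statistic, x$p_value,
              if (x$exact) "exact" else "approximate",
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Standard normal quantile
#'
#' @param prob probability in (0, 1).
#' @return z value (inverse standard normal CDF).
#' @export
#' @examples
#' round(normal_quantile(0.975), 2)  # 1.96
normal_quantile <- function(prob) {
  if (any(!is.finite(prob)) || any(prob <= 0) || any(prob >= 1))
    stop("prob must lie strictly in (0, 1)", call. = FALSE)
  qnorm(prob)
}

#' Two-group sample size from a power analysis
#'
#' Per-group sample size for a two-sided two-sample comparison of means,
#' \deqn{n = (Z_{\alpha/2} + Z_{1-\beta})^2 \, 2\sigma^2 / (\mu_1-\mu_2)^2}
#' rounded up, and the total sample count inflated for dropout,
#' \eqn{N = \lceil 2n / (1 - \mathrm{dropout}) \rceil}.
#'
#' @param sd pooled standard deviation (> 0).
#' @param mean_diff expected difference of means (non-zero).
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.8).
#' @param dropout anticipated dropout fraction in [0, 1) (default 0.1).
#' @return list with \code{n_per_group} and \code{n_total}.
#' @export
sample_size <- function(sd, mean_diff, alpha = 0.05, power = 0.8,
                        dropout = 0.1) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive", call. = FALSE)
  if (!is.finite(mean_diff) || mean_diff == 0)
    stop("mean difference must be non-zero", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  if (dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  z <- normal_quantile(1 - alpha / 2) + normal_quantile(power)
  n_raw <- z^2 * 2 * sd^2 / mean_diff^2
  n <- ceiling(n_raw)
  list(n_per_group = n, n_total = ceiling(2 * n / (1 - dropout)))
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum comparison. Exact p-value (enumeration) when the
#' combined sample size is at most \code{exact_max} and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param x,y numeric samples (each non-empty).
#' @param alternative "two.sided" (default), "less", or "greater".
#' @param exact_max largest combined n for the exact test (default 12).
#' @return A test result with the U statistic.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided", exact_max = 12L) {
  if (!length(x) || !length(y))
    stop("both groups must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= exact_max && !ties
  w <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = !exact))
  test_result(unname(w$statistic), w$p.value, c(length(x), length(y)),
              "Mann-Whitney U", exact)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of two or more groups; H statistic with tie
#' correction, chi-square p-value on k - 1 degrees of freedom.
#'
#' @param groups list of two or more non-empty numeric vectors.
#' @return A test result with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(!vapply(groups, length, integer(1))))
    stop("need >= 2 non-empty groups", call. = FALSE)
  k <- kruskal.test(groups)
  test_result(unname(k$statistic), k$p.value,
              vapply(groups, length, integer(1)),
              "Kruskal-Wallis", exact = FALSE)
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Zero differences are dropped. Exact p for n <= \code{exact_max} nonzero
#' differences without tied magnitudes, normal approximation beyond.
#'
#' @param differences paired differences with at least one nonzero value.
#' @param exact_max largest n for the exact test (default 15).
#' @return A test result with the signed-rank statistic V.
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 15L) {
  d <- differences[is.finite(differences)]
  d <- d[d != 0]
  if (!length(d))
    stop("all differences are zero; signed-rank test undefined",
         call. = FALSE)
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- length(d) <= exact_max && !ties
  w <- suppressWarnings(wilcox.test(d, mu = 0, exact = exact,
                                    correct = !exact))
  test_result(unname(w$statistic), w$p.value, length(d),
              "Wilcoxon signed-rank", exact)
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks with the t-distribution
#' approximation for the p-value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{r_s}, \code{p_value} and \code{n}.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need n >= 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  rs <- cor(rank(x), rank(y))
  p <- if (abs(rs) >= 1) 0 else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(r_s = rs, p_value = p, n = n)
}

#' Bonferroni multiplicity correction
#'
#' @param p_values p-values in [0, 1].
#' @param m number of tests in the family (default: length of the input).
#' @return Adjusted p-values, \code{pmin(1, p * m)}.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, p_values * m)
}

#' IQR outlier flags
#'
#' Flags values outside the closed fences \eqn{[Q_1 - k\,\mathrm{IQR},
#' Q_3 + k\,\mathrm{IQR}]} with quartiles by linear interpolation
#' (type 7). A constant vector has IQR 0 and flags nothing.
#'
#' @param values >= 4 finite numbers.
#' @param fence_multiplier fence factor k (default 1.5).
#' @return Logical flags, TRUE = outlier.
#' @export
iqr_outliers <- function(values, fence_multiplier = 1.5) {
  if (sum(is.finite(values)) < 4L)
    stop("need >= 4 finite values for the IQR rule", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), na.rm = TRUE, type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - fence_multiplier * iqr
  hi <- q[2] + fence_multiplier * iqr
  out <- values < lo | values > hi
  out[!is.finite(values)] <- NA
  out
}

#' Single-covariate ANCOVA: group effect adjusted for age
#'
#' Least-squares fit of \code{y ~ group + age}; the group effect is tested
#' with the partial F-test against the age-only model, and the age slope
#' reported with its t-test p-value.
#'
#' @param y response values.
#' @param group factor (or coercible) with >= 2 levels.
#' @param age numeric covariate.
#' @return list with \code{group_p}, \code{group_F}, \code{age_coef},
#'   \code{age_p}, and the fitted \code{model}.
#' @export
ancova <- function(y, group, age) {
  group <- factor(group)
  ok <- is.finite(y) & !is.na(group) & is.finite(age)
  y <- y[ok]; group <- droplevels(group[ok]); age <- age[ok]
  if (nlevels(group) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (length(y) <= nlevels(group) + 2L)
    stop("too few observations for the model", call. = FALSE)
  full <- lm(y ~ group + age)
  if (full$rank < nlevels(group) + 1L)
    stop("rank-deficient design (collinear group/age)", call. = FALSE)
  reduced <- lm(y ~ age)
  a <- anova(reduced, full)
  sm <- summary(full)$coefficients
  age_row <- sm[rownames(sm) == "age", , drop = FALSE]
  list(group_p = a[["Pr(>F)"]][2], group_F = a[["F"]][2],
       age_coef = if (nrow(age_row)) age_row[1, 1] else 0,
       age_p = if (nrow(age_row)) age_row[1, 4] else NA_real_,
       model = full)
}

#' Inter- vs intradonor variability comparison
#'
#' Runs both a one-way ANOVA and a Kruskal-Wallis test of the values
#' against the donor grouping (the dual-test regime guards against
#' distributional assumptions). Donors contributing fewer than two values
#' are excluded with a warning.
#'
#' @param values numeric measurements.
#' @param donor donor labels, same length.
#' @return list with \code{anova_F}, \code{anova_p}, \code{kw_H},
#'   \code{kw_p}, \code{ms_between}, \code{ms_within}, \code{n_donors}.
#' @export
variance_partition <- function(values, donor) {
  donor <- factor(donor)
  ok <- is.finite(values) & !is.na(donor)
  values <- values[ok]; donor <- droplevels(donor[ok])
  counts <- table(donor)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding ", length(small), " donor(s) with < 2 values")
    keep <- !(donor %in% small)
    values <- values[keep]; donor <- droplevels(donor[keep])
  }
  if (nlevels(donor) < 2L)
    stop("need >= 2 donors with >= 2 values each", call. = FALSE)

  fit <- lm(values ~ donor)
  a <- anova(fit)
  ms_b <- a$`Mean Sq`[1]; ms_w <- a$`Mean Sq`[2]
  if (!is.finite(ms_w) || ms_w <= 1e-12 * max(ms_b, 1)) {
    f <- Inf; p_f <- 0  # degenerate: zero within-donor variance
  } else {
    f <- a$`F value`[1]; p_f <- a$`Pr(>F)`[1]
  }
  kw <- kruskal.test(values, donor)
  list(anova_F = f, anova_p = p_f,
       kw_H = unname(kw$statistic), kw_p = kw$p.value,
       ms_between = ms_b, ms_within = ms_w,
       n_donors = nlevels(donor))
}

#' Batch group comparisons in long format
#'
#' Runs Mann-Whitney (two groups) or Kruskal-Wallis (more) for each
#' variable against each grouping and returns a long-format table of group
#' means +/- SD and p-values, with an optional Bonferroni family per
#' grouping.
#'
#' @param data data.frame of per-sample values.
#' @param variables character vector of numeric columns to compare.
#' @param groupings character vector of grouping columns.
#' @param bonferroni_family apply Bonferroni across variables within each
#'   grouping (default TRUE).
#' @return data.frame with columns variable, grouping, group summaries,
#'   test, p_value, p_adjusted.
#' @export
compare_groups <- function(data, variables, groupings,
                           bonferroni_family = TRUE) {
  out <- NULL
  for (g in groupings) {
    fac <- factor(data[[g]])
    rows <- lapply(variables, function(v) {
      vals <- split(data[[v]], fac)
      vals <- lapply(vals, function(z) z[is.finite(z)])
      vals <- vals[vapply(vals, length, integer(1)) > 0L]
      if (length(vals) < 2L)
        return(data.frame(variable = v, grouping = g, groups = NA,
                          summary = NA, test = NA, p_value = NA_real_))
      res <- if (length(vals) == 2L)
        mann_whitney(vals[[1]], vals[[2]])
      else
        kruskal_wallis(vals)
      data.frame(variable = v, grouping = g,
                 groups = paste(names(vals), collapse = "|"),
                 summary = paste(sprintf("%.3g +/- %.3g",
                                         vapply(vals, mean, numeric(1)),
                                         vapply(vals, sd, numeric(1))),
                                 collapse = "|"),
                 test = res$method, p_value = res$p_value)
    })
    block <- do.call(rbind, rows)
    block$p_adjusted <- if (bonferroni_family)
      bonferroni(block$p_value, m = sum(is.finite(block$p_value)))
    else block$p_value
    out <- rbind(out, block)
  }
  out
}
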