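#' A labelled sample of one experimental group
#'
#' Records the statistical unit alongside the values, since analyses mix
#' animal-level means with pooled object-level (synapse or cluster) data.
#'
#' @param label group name.
#' @param values numeric measurements.
#' @param unit one of `"animal"`, `"synapse"`, `"cluster"`.
#' @return `group_sample` object.
#' @export
group_sample <- function(label, values, unit = c("animal", "synapse",
                                                 "cluster")) {
  unit <- match.arg(unit)
  values <- as.numeric(values)
  if (length(values) < 1 || any(!is.finite(values)))
    stop("`values` must be non-empty and finite", call. = FALSE)
  structure(list(label = label, values = values, unit = unit),
            class = "group_sample")
}

as_group <- function(x, label = "group", unit = "animal") {
  if (inherits(x, "group_sample")) x else group_sample(label, x, unit)
}

stat_result <- function(test, statistic, df, p, direction = NA_character_,
                        unit = NA_character_, extra = NULL) {
  structure(c(list(test_name = test, statistic = unname(statistic),
                   df = unname(df), p_value = unname(p),
                   effect_direction = direction, unit = unit), extra),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test_name,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Pooled-variance two-sample t test
#'
#' Two-sided t test with pooled variance, df = n_a + n_b - 2 (the reported
#' degrees of freedom of the original analyses imply the pooled form).
#' When both groups have zero variance and equal means the comparison is
#' uninformative and p = 1 is returned by convention.
#'
#' @param a,b `group_sample` objects (or numeric vectors).
#' @return `stat_test_result`.
#' @export
two_sample_t <- function(a, b) {
  a <- as_group(a, "a"); b <- as_group(b, "b")
  x <- a$values; y <- b$values
  if (length(x) < 2 || length(y) < 2)
    stop("need n >= 2 per group", call. = FALSE)
  df <- length(x) + length(y) - 2
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(stat_result("two_sample_t", 0, df, 1, "none", a$unit))
    return(stat_result("two_sample_t", Inf * sign(mean(x) - mean(y)), df, 0,
                       if (mean(x) > mean(y)) "a>b" else "a<b", a$unit))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  stat_result("two_sample_t", tt$statistic, tt$parameter, tt$p.value,
              if (mean(x) > mean(y)) "a>b" else if (mean(x) < mean(y))
                "a<b" else "none", a$unit)
}

#' Mann-Whitney U test
#'
#' U computed from midranks. Without ties and for `n_a * n_b <= 400` the
#' two-sided p comes from the exact null distribution of U; with ties, or
#' for larger samples, a normal approximation with tie correction is used
#' (no continuity correction).
#'
#' @param a,b `group_sample` objects (or numeric vectors).
#' @return `stat_test_result`; the statistic is U for group `a`.
#' @export
mann_whitney_u <- function(a, b) {
  a <- as_group(a, "a"); b <- as_group(b, "b")
  x <- a$values; y <- b$values
  na <- length(x); nb <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && na * nb <= 400) {
    # exact two-sided p by doubling the smaller tail of the U distribution
    lo <- stats::pwilcox(u, na, nb)
    hi <- 1 - stats::pwilcox(u - 1, na, nb)
    p <- min(1, 2 * min(lo, hi))
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    n <- na + nb
    sig2 <- na * nb / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- if (sig2 > 0) (u - mu) / sqrt(sig2) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  stat_result("mann_whitney_u", u, NA_real_, p,
              if (u > na * nb / 2) "a>b" else if (u < na * nb / 2) "a<b"
              else "none", a$unit)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups list of `group_sample` objects (>= 3, each n >= 2).
#' @return `stat_test_result` with elements `tukey` (data.frame of
#'   pairwise comparisons: difference, studentized-range-adjusted p) and
#'   `group_means`.
#' @export
one_way_anova_tukey <- function(groups) {
  if (length(groups) < 3) stop("need >= 3 groups", call. = FALSE)
  groups <- lapply(seq_along(groups), function(i)
    as_group(groups[[i]], paste0("g", i)))
  if (any(vapply(groups, function(g) length(g$values), 0) < 2))
    stop("each group needs n >= 2", call. = FALSE)
  df <- data.frame(
    y = unlist(lapply(groups, `[[`, "values")),
    g = factor(rep(vapply(groups, `[[`, "", "label"),
                   vapply(groups, function(g) length(g$values), 0))))
  msw <- mean(vapply(split(df$y, df$g), function(v) stats::var(v), 0))
  if (msw == 0) {
    means <- vapply(split(df$y, df$g), mean, 0)
    if (max(means) == min(means))
      return(stat_result("one_way_anova", 0,
                         c(nlevels(df$g) - 1, nrow(df) - nlevels(df$g)), 1,
                         unit = groups[[1]]$unit))
    return(stat_result("one_way_anova", Inf,
                       c(nlevels(df$g) - 1, nrow(df) - nlevels(df$g)), 0,
                       unit = groups[[1]]$unit))
  }
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  stat_result("one_way_anova", an["g", "F value"],
              c(an["g", "Df"], an["Residuals", "Df"]), an["g", "Pr(>F)"],
              unit = groups[[1]]$unit,
              extra = list(tukey = tukey,
                           group_means = vapply(split(df$y, df$g), mean, 0)))
}

#' Two-way ANOVA (Type II sums of squares)
#'
#' Main effects and interaction F tests on a possibly unbalanced layout,
#' using Type II sums of squares (appropriate for the main-effects focus
#' of an unbalanced genotype x structure design).
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (e.g. genotype and structure type).
#' @return named list of `stat_test_result` (`factor_a`, `factor_b`,
#'   `interaction`).
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("each factor needs >= 2 levels", call. = FALSE)
  if (any(table(fa, fb) == 0))
    stop("empty cell in the two-way design", call. = FALSE)
  d <- data.frame(y = as.numeric(values), A = fa, B = fb)
  if (stats::var(d$y) == 0) {
    z <- stat_result("two_way_anova", 0, c(NA_real_, NA_real_), 1)
    return(list(factor_a = stat_result("two_way_anova_A", 0,
                                       c(nlevels(fa) - 1, NA), 1),
                factor_b = stat_result("two_way_anova_B", 0,
                                       c(nlevels(fb) - 1, NA), 1),
                interaction = stat_result("two_way_anova_AB", 0,
                                          c(NA_real_, NA), 1)))
  }
  fit <- stats::lm(y ~ A * B, data = d)
  an <- car::Anova(fit, type = 2)
  dfr <- an["Residuals", "Df"]
  get <- function(term, name) {
    stat_result(paste0("two_way_anova_", name), an[term, "F value"],
                c(an[term, "Df"], dfr), an[term, "Pr(>F)"])
  }
  list(factor_a = get("A", "A"), factor_b = get("B", "B"),
       interaction = get("A:B", "AB"))
}

#' Pearson chi-squared test for association
#'
#' `sum((O - E)^2 / E)` without continuity correction,
#' df = (rows - 1)(cols - 1).
#'
#' @param counts matrix (or `ContingencyTable`-like) of non-negative
#'   integer counts.
#' @return `stat_test_result`; `NA` statistic with a warning when any
#'   expected count is zero.
#' @export
chi_squared_association <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected == 0)) {
    warning("zero expected count: chi-squared undefined")
    return(stat_result("chi_squared", NA_real_,
                       (nrow(counts) - 1) * (ncol(counts) - 1), NA_real_))
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  stat_result("chi_squared", ct$statistic, ct$parameter, ct$p.value)
}

#' Normality gate: route to a parametric or non-parametric test
#'
#' Applies the Shapiro-Wilk test (delegated to [stats::shapiro.test()])
#' and routes to the parametric branch when p >= alpha. Samples of n < 3
#' cannot be assessed and are routed non-parametric with a warning.
#'
#' @param sample numeric vector or `group_sample`.
#' @param alpha gate level (0.05).
#' @return list with `route` (`"parametric"`/`"nonparametric"`), `w`, `p`.
#' @export
shapiro_wilk_gate <- function(sample, alpha = 0.05) {
  x <- if (inherits(sample, "group_sample")) sample$values
       else as.numeric(sample)
  if (length(x) < 3) {
    warning("n < 3: normality cannot be assessed, routing non-parametric")
    return(list(route = "nonparametric", w = NA_real_, p = NA_real_))
  }
  if (sd(x) == 0) {
    warning("constant sample: routing non-parametric")
    return(list(route = "nonparametric", w = NA_real_, p = NA_real_))
  }
  sw <- stats::shapiro.test(x)
  list(route = if (sw$p.value >= alpha) "parametric" else "nonparametric",
       w = unname(sw$statistic), p = sw$p.value)
}

#' Normalize condition values to the control mean
#'
#' Expresses each value as a percentage of the control-group mean, so the
#' control maps to 100% on average.
#'
#' @param values_condition,values_control numeric vectors.
#' @return condition values as percentages; `NA` vector (with a warning)
#'   when the control mean is not positive.
#' @export
normalize_to_control <- function(values_condition, values_control) {
  m <- mean(values_control)
  if (!is.finite(m) || m <= 0) {
    warning("control mean is not positive: normalization undefined")
    return(rep(NA_real_, length(values_condition)))
  }
  values_condition * 100 / m
}
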