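test_that("pooled t test matches the hand-computed example", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(r$statistic, 3), -3.674)
  expect_equal(r$df, 4)
  ident <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
})

test_that("t test matches the textbook pooled-variance formula", {
  set.seed(61)
  for (rep in 1:100) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    x <- rnorm(na); y <- rnorm(nb, 0.3)
    r <- two_sample_t(x, y)
    sp2 <- ((na - 1) * var(x) + (nb - 1) * var(y)) / (na + nb - 2)
    t_direct <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / na + 1 / nb))
    p_direct <- 2 * pt(-abs(t_direct), na + nb - 2)
    expect_equal(r$statistic, t_direct, tolerance = 1e-10)
    expect_equal(r$p_value, p_direct, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney U handles separation and symmetry", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  same <- mann_whitney_u(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$statistic, 3 * 3 / 2)
  # symmetry under group exchange: U_a + U_b = n_a n_b, same p
  set.seed(62)
  x <- rnorm(6); y <- rnorm(8)
  ra <- mann_whitney_u(x, y); rb <- mann_whitney_u(y, x)
  expect_equal(ra$statistic + rb$statistic, 48)
  expect_equal(ra$p_value, rb$p_value, tolerance = 1e-12)
})

test_that("exact Mann-Whitney p equals full enumeration for small n", {
  set.seed(63)
  for (rep in 1:12) {
    na <- sample(3:4, 1); nb <- sample(3:5, 1)
    x <- rnorm(na); y <- rnorm(nb, 0.8)
    r <- mann_whitney_u(x, y)
    expect_equal(r$p_value, enumerate_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("one-way ANOVA matches the hand ANOVA table", {
  # groups {1,2,3},{2,3,4},{3,4,5}: SSB 6 (df 2), SSW 6 (df 6) -> F = 3
  r <- one_way_anova_tukey(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$statistic, 3.0, tolerance = 1e-10)
  expect_equal(r$df, c(2, 6))
  ident <- one_way_anova_tukey(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(ident$statistic, 0)
})

test_that("Tukey-adjusted p dominates the unadjusted pairwise t p", {
  set.seed(64)
  for (rep in 1:20) {
    g <- lapply(1:3, function(i) rnorm(6, i * 0.3))
    r <- one_way_anova_tukey(g)
    # compare each Tukey pair with the plain t test on that pair
    combs <- list(c(2, 1), c(3, 1), c(3, 2))
    for (k in seq_along(combs)) {
      i <- combs[[k]][1]; j <- combs[[k]][2]
      p_t <- two_sample_t(g[[i]], g[[j]])$p_value
      expect_gte(r$tukey$p_adj[k] + 1e-12, p_t)
    }
  }
})

test_that("two-way ANOVA recovers a balanced hand decomposition", {
  # balanced 2x2 with 2 replicates; type II equals the classical SS here
  y <- c(10, 12, 20, 22, 30, 32, 44, 46)
  A <- rep(c("a1", "a2"), each = 4)
  B <- rep(c("b1", "b2", "b1", "b2"), each = 2)
  r <- two_way_anova(y, A, B)
  cell <- matrix(c(11, 21, 31, 45), 2, byrow = TRUE)
  ss_a <- 4 * sum((rowMeans(cell) - mean(cell))^2)
  ss_b <- 4 * sum((colMeans(cell) - mean(cell))^2)
  ss_int <- 2 * sum((cell - outer(rowMeans(cell), colMeans(cell), `+`) +
                       mean(cell))^2)
  ss_err <- 8  # each cell pair deviates +/-1
  expect_equal(r$factor_a$statistic, (ss_a / 1) / (ss_err / 4),
               tolerance = 1e-9)
  expect_equal(r$factor_b$statistic, (ss_b / 1) / (ss_err / 4),
               tolerance = 1e-9)
  expect_equal(r$interaction$statistic, (ss_int / 1) / (ss_err / 4),
               tolerance = 1e-9)
  expect_equal(r$factor_a$df, c(1, 4))
})

test_that("constant response gives all-zero F; empty cells error", {
  r <- two_way_anova(rep(5, 8), rep(c("a", "b"), 4), rep(c("x", "y"), each = 4))
  expect_equal(r$factor_a$statistic, 0)
  expect_error(two_way_anova(1:4, c("a", "a", "a", "b"),
                             c("x", "x", "y", "x")), "empty cell")
})

test_that("a simulated genotype effect of one SD is reliably detected", {
  set.seed(65)
  hits <- 0L
  for (rep in 1:200) {
    y <- c(rnorm(24), rnorm(24, 1))          # effect = 1 SD
    A <- rep(c("ctrl", "dis"), each = 24)
    B <- rep(rep(c("s1", "s2"), each = 12), 2)
    r <- two_way_anova(y, A, B)
    if (r$factor_a$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})

test_that("chi-squared matches the direct O/E formula on random tables", {
  set.seed(66)
  for (rep in 1:30) {
    tab <- matrix(rpois(6, 30) + 1, 2, 3)
    r <- chi_squared_association(tab)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(r$statistic, sum((tab - e)^2 / e), tolerance = 1e-10)
    expect_equal(r$df, 2)
  }
  flat <- chi_squared_association(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_warning(z <- chi_squared_association(matrix(c(1, 0, 2, 0), 2)),
                 "expected")
  expect_true(is.na(z$statistic))
})

test_that("normality gate routes by distribution shape", {
  set.seed(67)
  heavy <- rt(50, df = 1)
  expect_identical(shapiro_wilk_gate(heavy)$route, "nonparametric")
  routes <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    shapiro_wilk_gate(rnorm(50))$route
  }, "")
  expect_gte(mean(routes == "parametric"), 0.85)
  expect_warning(g <- shapiro_wilk_gate(c(1, 2)), "n < 3")
  expect_identical(g$route, "nonparametric")
})

test_that("control normalization maps control to 100% and scales linearly", {
  ctrl <- c(0.4, 0.5, 0.6)
  expect_equal(mean(normalize_to_control(ctrl, ctrl)), 100)
  expect_equal(normalize_to_control(0.4, c(0.5, 0.5)), 80)
  expect_warning(z <- normalize_to_control(1, c(0, 0)), "control mean")
  expect_true(all(is.na(z)))
  # ANOVA F for genotype is invariant to the normalization scale
  set.seed(68)
  y <- rnorm(16, 10)
  A <- rep(c("c", "d"), each = 8)
  B <- rep(c("x", "y"), 8)
  raw <- two_way_anova(y, A, B)
  scaled <- two_way_anova(y * 100 / mean(y[A == "c"]), A, B)
  expect_equal(raw$factor_a$statistic, scaled$factor_a$statistic,
               tolerance = 1e-9)
})

test_that("group samples validate and record their unit", {
  g <- group_sample("ctrl", c(1, 2), unit = "synapse")
  expect_identical(g$unit, "synapse")
  expect_error(group_sample("x", numeric(0)), "non-empty")
  expect_error(group_sample("x", c(1, NA)), "finite")
})
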