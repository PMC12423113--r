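test_that("Pillai's trace matches the eigenvalue oracle and stats::manova", {
  set.seed(30)
  n <- 40
  g <- rep(1:2, each = n / 2)
  y <- matrix(rnorm(n * 9), n, 9)
  y[g == 2, 1:3] <- y[g == 2, 1:3] + 0.8
  d <- tibble::as_tibble(as.data.frame(y))
  res <- manova_pillai(d, g)

  # oracle: V = sum(theta / (1 + theta)) over eigenvalues of E^-1 H
  grand <- colMeans(y)
  h <- matrix(0, 9, 9); e <- matrix(0, 9, 9)
  for (lev in 1:2) {
    yi <- y[g == lev, ]
    mi <- colMeans(yi)
    h <- h + nrow(yi) * tcrossprod(mi - grand)
    e <- e + crossprod(sweep(yi, 2, mi))
  }
  theta <- Re(eigen(solve(e) %*% h)$values)
  expect_equal(res$value, sum(theta / (1 + theta)), tolerance = 1e-8)

  sm <- summary(stats::manova(y ~ factor(g)), test = "Pillai")$stats
  expect_equal(res$value, sm[1, "Pillai"], tolerance = 1e-10)
  expect_equal(res$approx_f, sm[1, "approx F"], tolerance = 1e-10)
  expect_equal(res$p_value, sm[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("with one response Pillai's F reduces to the one-way ANOVA F", {
  set.seed(31)
  g <- rep(1:3, each = 10)
  y <- rnorm(30) + 0.5 * g
  d <- tibble::tibble(v = y)
  res <- manova_pillai(d, g, vars = "v")
  a <- anova(lm(y ~ factor(g)))
  expect_equal(res$approx_f, a$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p_value, a$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("Pillai's trace is invariant to per-variable affine rescaling", {
  set.seed(32)
  y <- matrix(rnorm(25 * 4), 25, 4)
  g <- rep(1:2, c(12, 13))
  d1 <- tibble::as_tibble(as.data.frame(y))
  y2 <- sweep(sweep(y, 2, c(2, -3, 0.5, 10), "*"), 2, c(1, -5, 0, 2), "+")
  d2 <- tibble::as_tibble(as.data.frame(y2))
  expect_equal(manova_pillai(d1, g)$value, manova_pillai(d2, g)$value,
               tolerance = 1e-10)
})

test_that("Welch t from raw data matches the direct formula oracle", {
  set.seed(33)
  x1 <- rnorm(14, 1, 2)
  x2 <- rnorm(9, 0, 1)
  d <- tibble::tibble(v = c(x1, x2))
  g <- rep(1:2, c(14, 9))
  res <- posthoc_welch(d, g, vars = "v", m_tests = 1)
  se2 <- var(x1) / 14 + var(x2) / 9
  t_o <- (mean(x1) - mean(x2)) / sqrt(se2)
  df_o <- se2^2 / ((var(x1) / 14)^2 / 13 + (var(x2) / 9)^2 / 8)
  expect_equal(res$t, t_o, tolerance = 1e-12)
  expect_equal(res$df, df_o, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_o), df_o), tolerance = 1e-12)
})

test_that("identical groups give t = 0, p = 1", {
  d <- tibble::tibble(v = rep(c(1, 2, 3), 2))
  g <- rep(1:2, each = 3)
  res <- posthoc_welch(d, g, vars = "v")
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
})

test_that("Bonferroni reporting includes both conventions and is monotone in m", {
  set.seed(34)
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(20 * 9), 20, 9)))
  g <- rep(1:2, each = 10)
  res <- posthoc_welch(d, g)
  expect_equal(unique(res$alpha_adj), 0.05 / 9)
  expect_equal(res$p_adj, pmin(1, 9 * res$p_value))
  res1 <- posthoc_welch(d, g, m_tests = 1)
  expect_true(all(res$p_adj >= res1$p_adj - 1e-12))
})

test_that("summary-statistics Welch t matches the raw-data version", {
  set.seed(35)
  x1 <- rnorm(26, -21, 0.7)
  x2 <- rnorm(19, -20.7, 0.9)
  tt <- t.test(x1, x2)
  res <- welch_t_summary(
    mean(x1), sd(x1) / sqrt(26), 26,
    mean(x2), sd(x2) / sqrt(19), 19
  )
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("assumption checks report diagnostics and degenerate cases", {
  set.seed(36)
  d <- tibble::tibble(
    a = rnorm(40),
    b = rep(1, 40)
  )
  g <- rep(1:2, each = 20)
  res <- assumption_checks(d, g, vars = c("a", "b"))
  a_sw <- res[res$variable == "a" & res$test == "shapiro_wilk", ]
  expect_equal(nrow(a_sw), 2)
  expect_true(all(a_sw$p_value > 0 & a_sw$p_value <= 1))
  a_lev <- res[res$variable == "a" & res$test == "levene", ]
  lt <- car::leveneTest(d$a, factor(g), center = mean)
  expect_equal(a_lev$statistic, lt[1, "F value"], tolerance = 1e-12)
  b_rows <- res[res$variable == "b", ]
  expect_true(all(grepl("not applicable", b_rows$note)))
})

test_that("Shapiro–Wilk and Levene are calibrated under their nulls", {
  set.seed(37)
  sw_reject <- mean(vapply(1:400, function(i) {
    shapiro.test(rnorm(500))$p.value < 0.05
  }, logical(1)))
  expect_lt(abs(sw_reject - 0.05), 0.035)

  lev_reject <- mean(vapply(1:2000, function(i) {
    d <- tibble::tibble(v = rnorm(40))
    g <- rep(1:2, each = 20)
    res <- assumption_checks(d, g, vars = "v")
    res$p_value[res$test == "levene"] < 0.05
  }, logical(1)))
  expect_lt(abs(lev_reject - 0.05), 0.02)
})
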