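#' One-way MANOVA with Pillai's trace
#'
#' Tests whether multivariate group means differ. Pillai's trace
#' `V = trace(H (H + E)^-1)` is computed from the between-group (H) and
#' within-group (E) cross-product matrices, with the standard F
#' approximation: for p responses, g groups, s = min(p, g - 1),
#' m = (|p - g + 1| - 1)/2, n* = (N - g - p - 1)/2,
#' `F = (2n* + s + 1)/(2m + s + 1) * V/(s - V)` on
#' `s(2m + s + 1), s(2n* + s + 1)` df. With a single response this reduces
#' exactly to the one-way ANOVA F.
#'
#' @param data A data frame of response variables (or a tibble containing
#'   them).
#' @param assignments Group labels, one per row.
#' @param vars Response columns; default: all numeric columns.
#' @return A one-row tibble: `statistic` ("Pillai"), `value`, `approx_f`,
#'   `df1`, `df2`, `p_value`, `n`, `groups`.
#' @export
manova_pillai <- function(data, assignments, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, c("fork_length_mm", "year"))
  }
  y <- as.matrix(data[, vars, drop = FALSE])
  g <- factor(assignments)
  if (nlevels(g) < 2) abort("Need at least 2 groups.")
  if (nrow(y) != length(g)) abort("`assignments` length must match rows of `data`.")
  n <- nrow(y)
  p <- ncol(y)
  grand <- colMeans(y)
  h <- matrix(0, p, p)
  e <- matrix(0, p, p)
  for (lev in levels(g)) {
    yi <- y[g == lev, , drop = FALSE]
    ni <- nrow(yi)
    mi <- colMeans(yi)
    h <- h + ni * tcrossprod(mi - grand)
    e <- e + crossprod(sweep(yi, 2, mi))
  }
  he <- h + e
  v <- tryCatch(
    sum(diag(h %*% solve(he))),
    error = function(err) abort("Singular H + E matrix: cannot compute Pillai's trace.")
  )
  df_h <- nlevels(g) - 1
  df_e <- n - nlevels(g)
  s <- min(p, df_h)
  m <- (abs(p - df_h) - 1) / 2
  n_star <- (df_e - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * n_star + s + 1)
  f_stat <- (df2 / df1) * v / (s - v)
  tibble::tibble(
    statistic = "Pillai",
    value = v,
    approx_f = f_stat,
    df1 = df1,
    df2 = df2,
    p_value = pf(f_stat, df1, df2, lower.tail = FALSE),
    n = n,
    groups = nlevels(g)
  )
}

#' Welch's t statistic from summary statistics
#'
#' Two-sample unequal-variance t from group means, standard errors of the
#' means, and sizes — for recomputing published comparisons from printed
#' summary tables: `t = (m1 - m2) / sqrt(se1^2 + se2^2)` with
#' Welch–Satterthwaite df.
#'
#' @param mean1,se1,n1 First group: mean, SE of the mean, size.
#' @param mean2,se2,n2 Second group.
#' @return A one-row tibble: `t`, `df`, `p_value`.
#' @examples
#' welch_t_summary(-21.05, 0.13, 26, -20.7, 0.20, 19)
#' @export
welch_t_summary <- function(mean1, se1, n1, mean2, se2, n2) {
  v1 <- se1^2
  v2 <- se2^2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(
    t = t_stat,
    df = df,
    p_value = 2 * pt(-abs(t_stat), df)
  )
}

#' Post hoc two-group t tests with Bonferroni correction
#'
#' Per measurement, a two-sample t test between the two groups — Welch's
#' unequal-variance t with Welch–Satterthwaite (fractional) df by default, or
#' the classical pooled-variance Student t (`welch = FALSE`). Both Bonferroni
#' conventions are reported: the adjusted significance level
#' `alpha_adj = alpha / m_tests` and adjusted p values
#' `p_adj = min(1, m_tests * p)`.
#'
#' @param data Data frame of measurements.
#' @param assignments Group labels (exactly 2 groups).
#' @param vars Measurement columns; default: all numeric.
#' @param m_tests Number of comparisons for the correction (default:
#'   `length(vars)`).
#' @param welch Use Welch's unequal-variance t? Default `TRUE`.
#' @param alpha Family significance level (default 0.05).
#' @return A tibble with one row per measurement: `measurement`, `mean_1`,
#'   `mean_2`, `t`, `df`, `p_value`, `p_adj`, `alpha_adj`, `significant`.
#' @export
posthoc_welch <- function(data, assignments, vars = NULL, m_tests = NULL,
                          welch = TRUE, alpha = 0.05) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, c("fork_length_mm", "year"))
  }
  g <- factor(assignments)
  if (nlevels(g) != 2) abort("Post hoc t tests require exactly 2 groups.")
  if (any(table(g) < 2)) abort("Each group needs at least 2 observations.")
  if (is.null(m_tests)) m_tests <- length(vars)
  lv <- levels(g)
  rows <- purrr::map_dfr(vars, function(v) {
    x1 <- data[[v]][g == lv[1]]
    x2 <- data[[v]][g == lv[2]]
    if (sd(x1) == 0 && sd(x2) == 0 && mean(x1) == mean(x2)) {
      # identical constant groups: no evidence of difference
      return(tibble::tibble(
        measurement = v, mean_1 = mean(x1), mean_2 = mean(x2),
        t = 0, df = length(x1) + length(x2) - 2, p_value = 1
      ))
    }
    tt <- t.test(x1, x2, var.equal = !welch)
    tibble::tibble(
      measurement = v,
      mean_1 = mean(x1),
      mean_2 = mean(x2),
      t = unname(tt$statistic),
      df = unname(tt$parameter),
      p_value = tt$p.value
    )
  })
  rows$p_adj <- pmin(1, m_tests * rows$p_value)
  rows$alpha_adj <- alpha / m_tests
  rows$significant <- rows$p_value < rows$alpha_adj
  rows
}

#' Normality and equal-variance diagnostics per variable
#'
#' Shapiro–Wilk per group and Levene's test (deviation from the group mean,
#' the original form) across groups, per variable. Diagnostic only — results
#' never gate the pipeline. Constant samples are reported as not applicable
#' rather than erroring.
#'
#' @param data Data frame of measurements.
#' @param assignments Group labels.
#' @param vars Columns to check; default: all numeric.
#' @return A tibble: `variable`, `test`, `group`, `statistic`, `p_value`,
#'   `note`.
#' @export
assumption_checks <- function(data, assignments, vars = NULL) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, c("fork_length_mm", "year"))
  }
  g <- factor(assignments)
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    sw <- purrr::map_dfr(levels(g), function(lev) {
      xi <- x[g == lev]
      if (length(xi) < 3 || sd(xi) == 0) {
        tibble::tibble(
          variable = v, test = "shapiro_wilk", group = lev,
          statistic = NA_real_, p_value = NA_real_,
          note = "not applicable (constant or n < 3)"
        )
      } else {
        s <- shapiro.test(xi)
        tibble::tibble(
          variable = v, test = "shapiro_wilk", group = lev,
          statistic = unname(s$statistic), p_value = s$p.value,
          note = NA_character_
        )
      }
    })
    lev_row <- if (sd(x) == 0 || nlevels(g) < 2) {
      tibble::tibble(
        variable = v, test = "levene", group = "all",
        statistic = NA_real_, p_value = NA_real_,
        note = "not applicable (constant or single group)"
      )
    } else {
      lt <- car::leveneTest(x, g, center = mean)
      tibble::tibble(
        variable = v, test = "levene", group = "all",
        statistic = lt[1, "F value"], p_value = lt[1, "Pr(>F)"],
        note = NA_character_
      )
    }
    dplyr::bind_rows(sw, lev_row)
  })
}
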