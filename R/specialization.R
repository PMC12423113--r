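# Profiled REML criterion for the random-intercept model
#   y = X beta + u_fish + eps,  u ~ N(0, s2B), eps ~ N(0, s2W),
# parameterized by the variance ratio lambda = s2B / s2W. The marginal
# covariance is s2W * H with H = I + lambda Z Z', block diagonal by fish, so
# H^-1 v = v - (lambda / (1 + lambda n_i)) * (fish sum of v) within each
# fish's block, and log|H| = sum_i log(1 + lambda n_i). For fixed lambda the
# GLS fixed effects and the profiled s2W are closed-form; the criterion
# minimized is
#   log|H| + log|X' H^-1 X| + (n - p) log(r' H^-1 r).
reml_profile <- function(lambda, y, x, fish_idx, n_per_fish) {
  n <- length(y)
  p <- ncol(x)
  w <- lambda / (1 + lambda * n_per_fish) # per-fish shrinkage weight

  hinv <- function(v) {
    if (is.matrix(v)) {
      sums <- rowsum(v, fish_idx, reorder = TRUE)
      v - (w[fish_idx] * sums[fish_idx, , drop = FALSE])
    } else {
      sums <- rowsum(v, fish_idx, reorder = TRUE)[, 1]
      v - w[fish_idx] * sums[fish_idx]
    }
  }

  hx <- hinv(x)
  a <- crossprod(x, hx)
  b <- crossprod(x, hinv(y))
  ch <- tryCatch(chol(a), error = function(e) NULL)
  if (is.null(ch)) {
    abort("Singular fixed-effect design in the mixed model.")
  }
  beta <- backsolve(ch, forwardsolve(t(ch), b))
  r <- y - x %*% beta
  q <- sum(r * hinv(r))
  log_det_h <- sum(log1p(lambda * n_per_fish))
  log_det_a <- 2 * sum(log(diag(ch)))
  crit <- log_det_h + log_det_a + (n - p) * log(q)
  list(
    criterion = crit,
    beta = drop(beta),
    sigma2_within = q / (n - p),
    xtx_inv_chol = ch
  )
}

#' Random-intercept REML variance decomposition (WIC / BIC / TNW / IS)
#'
#' Fits the linear mixed model
#' `value ~ fixed effects + (1 | fish)` by restricted maximum likelihood,
#' implemented natively by profiling the REML criterion over the variance
#' ratio `lambda = sigma2_B / sigma2_W` (coarse log-scale multistart grid
#' including the `lambda = 0` boundary, refined by 1-D bounded optimization
#' to tolerance 1e-10), with generalized-least-squares fixed effects at each
#' lambda. The residual variance is the within-individual component (WIC);
#' the fish-level random-intercept variance is the between-individual
#' component (BIC); their sum is the total niche width (TNW); and
#' `IS = WIC / TNW` is the individual specialization index. `lambda` is
#' constrained non-negative, so BIC can sit on the 0 boundary (reported with
#' a flag), in which case IS = 1.
#'
#' @param data A tibble of observations (one row per fish x tissue).
#' @param value Name of the response column (an isotope value, per mil).
#' @param fish Name of the fish-id column (random-intercept grouping).
#' @param fixed Right-hand-side formula of fixed effects
#'   (default `~ fork_length_mm + tissue`, with tissue a two-level contrast,
#'   RBC as reference). Use `~ 1` for intercept only.
#' @return An object of class `niche_decomposition`: `WIC`, `BIC`, `TNW`,
#'   `IS` (all per mil squared except IS), `lambda`, `boundary` flag,
#'   `fixed_effects` tibble (`term`, `estimate`, `std_error`), `n_fish`,
#'   `n_obs`, `criterion`.
#' @examples
#' iso <- simulate_isotopes(synthetic_truth(n_fish = 30, seed = 2))
#' fit_random_intercept_reml(iso, "d13C", "fish_id")
#' @export
fit_random_intercept_reml <- function(data, value, fish,
                                      fixed = ~ fork_length_mm + tissue) {
  y <- data[[value]]
  if (is.null(y)) abort(paste0("No column '", value, "' in `data`."))
  fish_f <- factor(data[[fish]])
  if (nlevels(fish_f) < 2) abort("Need at least 2 fish.")
  if (anyNA(y)) abort("Missing response values.")
  mf <- stats::model.frame(fixed, data = data, na.action = stats::na.fail)
  x <- model.matrix(fixed, mf)
  if (qr(x)$rank < ncol(x)) abort("Singular fixed-effect design matrix.")
  # order rows by fish so block sums are contiguous (estimates are invariant
  # to row order; this is just bookkeeping)
  ord <- order(fish_f)
  y <- y[ord]
  x <- x[ord, , drop = FALSE]
  fish_f <- fish_f[ord]
  fish_idx <- as.integer(fish_f)
  n_per_fish <- as.integer(table(fish_f))

  lambda_cap <- 1e8 # numerical ceiling; at the cap IS is already ~1e-8
  crit_of <- function(lambda) {
    lambda <- min(max(lambda, 0), lambda_cap)
    tryCatch(
      reml_profile(lambda, y, x, fish_idx, n_per_fish)$criterion,
      error = function(e) Inf
    )
  }
  grid <- c(0, 10^seq(-6, 4, by = 0.25))
  vals <- vapply(grid, crit_of, numeric(1))
  best <- which.min(vals)
  if (best == 1) {
    # check the first interior bracket before accepting the boundary
    opt <- optimize(function(t) crit_of(exp(t)),
                    interval = c(log(1e-10), log(grid[3])), tol = 1e-12)
    lambda_hat <- if (opt$objective < vals[1] - 1e-12) exp(opt$minimum) else 0
  } else {
    lo <- grid[max(best - 1, 1)]
    hi <- grid[min(best + 1, length(grid))]
    lo <- max(lo, 1e-12)
    opt <- optimize(function(t) crit_of(exp(t)),
                    interval = log(c(lo, hi)), tol = 1e-12)
    lambda_hat <- exp(opt$minimum)
    if (vals[best] < opt$objective) lambda_hat <- grid[best]
    # Newton polish on t = log(lambda): optimize()'s bracketing accuracy is
    # limited near flat optima; a few second-order steps give ~1e-10 accuracy
    t_hat <- log(lambda_hat)
    h <- 1e-5
    for (i in 1:4) {
      c0 <- crit_of(exp(t_hat))
      cu <- crit_of(exp(t_hat + h))
      cd <- crit_of(exp(t_hat - h))
      g <- (cu - cd) / (2 * h)
      hess <- (cu - 2 * c0 + cd) / h^2
      if (!is.finite(g) || !is.finite(hess) || hess <= 0) break
      t_new <- t_hat - g / hess
      if (!is.finite(t_new)) break
      if (crit_of(exp(t_new)) <= c0) t_hat <- t_new else break
    }
    if (crit_of(exp(t_hat)) <= crit_of(lambda_hat)) {
      lambda_hat <- min(exp(t_hat), lambda_cap)
    }
  }
  sol <- reml_profile(lambda_hat, y, x, fish_idx, n_per_fish)
  wic <- sol$sigma2_within
  bic <- lambda_hat * wic
  ch <- sol$xtx_inv_chol
  xtxinv <- chol2inv(ch)
  se <- sqrt(diag(xtxinv) * wic)

  structure(
    list(
      WIC = wic,
      BIC = bic,
      TNW = wic + bic,
      IS = wic / (wic + bic),
      lambda = lambda_hat,
      boundary = lambda_hat == 0,
      fixed_effects = tibble::tibble(
        term = colnames(x),
        estimate = sol$beta,
        std_error = se
      ),
      n_fish = nlevels(fish_f),
      n_obs = length(y),
      criterion = sol$criterion,
      value = value
    ),
    class = "niche_decomposition"
  )
}

#' @export
print.niche_decomposition <- function(x, ...) {
  cat("<niche_decomposition> ", x$value, ": ", x$n_obs, " obs on ",
      x$n_fish, " fish\n", sep = "")
  cat(sprintf(
    "  WIC = %.4f  BIC = %.4f  TNW = %.4f  IS = %.4f%s\n",
    x$WIC, x$BIC, x$TNW, x$IS,
    if (x$boundary) "  (BIC at 0 boundary)" else ""
  ))
  invisible(x)
}

#' Individual specialization index IS = WIC / TNW
#'
#' The within-individual share of total niche width: near 0 the population is
#' composed of individual specialists, near 1 each individual is as
#' generalist as the whole population.
#'
#' @param wic A `niche_decomposition` object, or the WIC value (per mil^2).
#' @param bic BIC value when `wic` is numeric.
#' @return IS in `[0, 1]`.
#' @examples
#' is_index(0.24, 0.36) # 0.40
#' is_index(0.69, 0.00) # 1.00
#' @export
is_index <- function(wic, bic = NULL) {
  if (inherits(wic, "niche_decomposition")) {
    bic <- wic$BIC
    wic <- wic$WIC
  }
  if (wic < 0 || bic < 0) abort("WIC and BIC must be non-negative.")
  tnw <- wic + bic
  if (tnw <= 0) abort("IS is undefined when TNW = 0.")
  wic / tnw
}

#' Variance decompositions per isotope and morphotype group
#'
#' Runs [fit_random_intercept_reml()] separately for each isotope on each
#' morphotype cluster and on the pooled population, mirroring the reporting
#' unit of the niche-width analysis.
#'
#' @param records Corrected isotope records with `fish_id`, `tissue`,
#'   `fork_length_mm`, a `cluster` column, and corrected value columns.
#' @param value_cols Named character vector: names are isotope labels,
#'   values are the corrected columns (default
#'   `c(d13C = "d13C_corr", d15N = "d15N_corr")`).
#' @param fixed Fixed-effects formula passed through.
#' @return A tibble with one row per isotope x group: `isotope`, `group`,
#'   `WIC`, `BIC`, `TNW`, `IS`, `boundary`, `n_fish`, `n_obs`; class
#'   `niche_decomposition_tbl`.
#' @export
decompose_niche <- function(records,
                            value_cols = c(d13C = "d13C_corr", d15N = "d15N_corr"),
                            fixed = ~ fork_length_mm + tissue) {
  if (!"cluster" %in% names(records)) abort("`records` must have a `cluster` column.")
  groups <- c(
    setNames(
      as.list(sort(unique(records$cluster))),
      paste0("cluster", sort(unique(records$cluster)))
    ),
    list(population = NULL)
  )
  out <- purrr::map_dfr(names(value_cols), function(iso) {
    purrr::map_dfr(names(groups), function(gname) {
      sel <- groups[[gname]]
      sub <- if (is.null(sel)) records else records[records$cluster == sel, ]
      fit <- fit_random_intercept_reml(sub, value_cols[[iso]], "fish_id", fixed)
      tibble::tibble(
        isotope = iso, group = gname,
        WIC = fit$WIC, BIC = fit$BIC, TNW = fit$TNW, IS = fit$IS,
        boundary = fit$boundary, n_fish = fit$n_fish, n_obs = fit$n_obs
      )
    })
  })
  class(out) <- c("niche_decomposition_tbl", class(out))
  out
}

#' Individual WIC values from the tissue-tissue regression
#'
#' Per isotope, an ordinary least-squares line is fit across fish predicting
#' one tissue from the other (default: fast-turnover plasma predicted from
#' slow-turnover RBC); each fish's individual WIC is the absolute residual
#' |observed - predicted|. Only fish with both tissues enter.
#'
#' @param records Corrected isotope records (`fish_id`, `tissue`, corrected
#'   value columns, fish-level metadata).
#' @param value_cols Corrected columns, named by isotope label.
#' @param direction `"plasma_on_rbc"` (default) or `"rbc_on_plasma"`.
#' @return A tibble: `fish_id`, `isotope`, `wic_value` (per mil, >= 0),
#'   `predicted`, `observed`, plus carried metadata (`cluster`,
#'   `fork_length_mm`, `year` when present).
#' @export
individual_wic <- function(records,
                           value_cols = c(d13C = "d13C_corr", d15N = "d15N_corr"),
                           direction = c("plasma_on_rbc", "rbc_on_plasma")) {
  direction <- match.arg(direction)
  meta_cols <- intersect(c("cluster", "fork_length_mm", "year", "morphotype"),
                         names(records))
  purrr::map_dfr(names(value_cols), function(iso) {
    col <- value_cols[[iso]]
    wide <- tidyr::pivot_wider(
      dplyr::select(records, "fish_id", "tissue",
                    dplyr::all_of(c(col, meta_cols))),
      names_from = "tissue", values_from = dplyr::all_of(col)
    )
    wide <- wide[complete.cases(wide[, c("RBC", "plasma")]), ]
    if (nrow(wide) < 3) abort("Need at least 3 paired fish per isotope.")
    if (direction == "plasma_on_rbc") {
      pred_var <- wide$RBC
      resp <- wide$plasma
    } else {
      pred_var <- wide$plasma
      resp <- wide$RBC
    }
    if (sd(pred_var) == 0) abort("Zero variance in the predictor tissue.")
    fit <- lm(resp ~ pred_var)
    out <- tibble::tibble(
      fish_id = wide$fish_id,
      isotope = iso,
      observed = resp,
      predicted = unname(predict(fit)),
      wic_value = abs(resp - unname(predict(fit)))
    )
    for (mc in meta_cols) out[[mc]] <- wide[[mc]]
    out
  })
}

#' GLM of log10 individual WIC on cluster, fork length and year
#'
#' Gaussian identity-link linear model on `log10(wic_value)`. WIC values of
#' exactly 0 are floored at half the smallest positive observed WIC before
#' the transform (with a logged count). Year is treated as categorical.
#' Estimates and standard errors are reported both on the log10 scale and
#' back-transformed as `10^value`.
#'
#' @param iwic An [individual_wic()] table for a single isotope (or filtered
#'   to one).
#' @param formula Model formula on the log10 scale; default
#'   `log10_wic ~ cluster + fork_length_mm + year`. Interaction terms may be
#'   added and later pruned with [simplify_by_aic()].
#' @return An object of class `wic_glm`: `model` (an `lm`), `coefficients`
#'   tibble (`term`, `estimate`, `std_error`, `t`, `p_value`,
#'   `estimate_back`, `std_error_back`), `aic`, `n`, `floored`.
#' @export
wic_glm <- function(iwic,
                    formula = log10_wic ~ cluster + fork_length_mm + year) {
  if (length(unique(iwic$isotope)) > 1) {
    abort("`iwic` mixes isotopes; filter to one before modelling.")
  }
  if (nrow(iwic) < 10) abort("Need at least 10 observations for the WIC GLM.")
  w <- iwic$wic_value
  floored <- sum(w == 0)
  if (floored > 0) {
    floor_val <- min(w[w > 0]) / 2
    w[w == 0] <- floor_val
    inform(paste0(floored, " zero WIC value(s) floored at ", signif(floor_val, 3),
                  " before log10 transform."))
  }
  d <- iwic
  d$log10_wic <- log10(w)
  if ("cluster" %in% all.vars(formula)) d$cluster <- factor(d$cluster)
  if ("year" %in% all.vars(formula)) d$year <- factor(d$year)
  fit <- lm(formula, data = d)
  if (anyNA(coef(fit))) {
    abort(paste0(
      "Rank-deficient design; aliased term(s): ",
      paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")
    ))
  }
  cs <- summary(fit)$coefficients
  structure(
    list(
      model = fit,
      coefficients = tibble::tibble(
        term = rownames(cs),
        estimate = unname(cs[, 1]),
        std_error = unname(cs[, 2]),
        t = unname(cs[, 3]),
        p_value = unname(cs[, 4]),
        estimate_back = unname(10^cs[, 1]),
        std_error_back = unname(10^cs[, 2])
      ),
      aic = AIC(fit),
      n = nrow(d),
      floored = floored,
      data = d
    ),
    class = "wic_glm"
  )
}

#' @export
print.wic_glm <- function(x, ...) {
  cat("<wic_glm> n =", x$n, " AIC =", round(x$aic, 2), "\n")
  print(x$coefficients)
  invisible(x)
}

#' Sequential AIC-guarded pruning of interaction terms
#'
#' Iteratively considers the non-significant (term-level p >= `alpha`)
#' interaction terms of a fitted linear model, starting with the weakest — the
#' term with the smallest |t| (for multi-df factor interactions, the
#' equivalent F-scale ordering). A term is dropped unless its removal raises
#' AIC by more than `delta_aic` (default 2), in which case it is restored and
#' locked. Main effects are never dropped. Gaussian AIC follows the
#' `stats::AIC()` convention (`-2 logLik + 2k`, normal likelihood with the ML
#' variance); term-level tests and per-deletion AICs come from
#' `drop1(..., test = "F")`, converted to that convention.
#'
#' @param model An `lm`/`glm`, or a [wic_glm()] object.
#' @param alpha Significance threshold for considering a term (default 0.05).
#' @param delta_aic AIC increase above which a term is retained (default 2).
#' @return A list: `model` (final fit), `log` — a tibble recording each step
#'   (`term`, `t_equiv`, `p_value`, `aic_full`, `aic_reduced`, `action`).
#' @export
simplify_by_aic <- function(model, alpha = 0.05, delta_aic = 2) {
  if (inherits(model, "wic_glm")) model <- model$model
  locked <- character()
  log_rows <- list()
  repeat {
    labels <- attr(stats::terms(model), "term.labels")
    inter <- setdiff(labels[grepl(":", labels)], locked)
    if (length(inter) == 0) break
    d1 <- stats::drop1(model, scope = as.formula(
      paste("~", paste(inter, collapse = " + "))
    ), test = "F")
    cand_tbl <- tibble::tibble(
      term = rownames(d1)[-1],
      f = d1$`F value`[-1],
      p_value = d1$`Pr(>F)`[-1]
    )
    nonsig <- cand_tbl[cand_tbl$p_value >= alpha, ]
    if (nrow(nonsig) == 0) break
    # smallest |t| first; on the F scale that is the smallest F
    cand <- nonsig$term[which.min(nonsig$f)]
    # refit against the stored model frame so the original data object need
    # not be visible in the calling environment
    new_f <- update(stats::formula(model), paste(". ~ . -", cand))
    reduced <- if (inherits(model, "glm")) {
      stats::glm(new_f, data = stats::model.frame(model), family = model$family)
    } else {
      lm(new_f, data = stats::model.frame(model))
    }
    aic_full <- AIC(model)
    aic_reduced <- AIC(reduced)
    if (aic_reduced - aic_full > delta_aic) {
      locked <- c(locked, cand)
      action <- "retained (AIC penalty)"
    } else {
      model <- reduced
      action <- "dropped"
    }
    row <- nonsig[nonsig$term == cand, ]
    log_rows[[length(log_rows) + 1]] <- tibble::tibble(
      term = cand,
      t_equiv = sqrt(row$f),
      p_value = row$p_value,
      aic_full = aic_full,
      aic_reduced = aic_reduced,
      action = action
    )
  }
  list(
    model = model,
    log = if (length(log_rows)) dplyr::bind_rows(log_rows) else
      tibble::tibble(
        term = character(), t_equiv = numeric(), p_value = numeric(),
        aic_full = numeric(), aic_reduced = numeric(), action = character()
      )
  )
}
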