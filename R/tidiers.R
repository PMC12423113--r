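#' Tidy a morphometric PCA
#'
#' @param x A `morpho_pca` (including `shape_pca`).
#' @param matrix Which component to return: `"scores"` (default),
#'   `"loadings"`, or `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.morpho_pca <- function(x, matrix = c("scores", "loadings", "eigenvalues"),
                            ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    return(tidyr::pivot_longer(x$scores, -"specimen_id",
                               names_to = "component", values_to = "score"))
  }
  if (matrix == "loadings") {
    l <- tibble::as_tibble(x$loadings, rownames = "variable")
    return(tidyr::pivot_longer(l, -"variable",
                               names_to = "component", values_to = "loading"))
  }
  tibble::tibble(
    component = paste0("PC", seq_along(x$eigenvalues)),
    eigenvalue = x$eigenvalues,
    percent_variance = x$percent_variance,
    cumulative_percent = cumsum(x$percent_variance)
  )
}

#' @rdname tidy.morpho_pca
#' @export
glance.morpho_pca <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$scores),
    n_components = length(x$eigenvalues),
    pc1_percent = x$percent_variance[1],
    pc2_percent = if (length(x$percent_variance) > 1) x$percent_variance[2] else NA_real_
  )
}

#' Tidy a GPA alignment into long coordinate form
#'
#' @param x A `gpa_alignment`.
#' @param ... Unused.
#' @return A tibble: `specimen_id`, `landmark`, `x`, `y` (aligned, unit
#'   centroid-size coordinates).
#' @export
tidy.gpa_alignment <- function(x, ...) {
  purrr::map2_dfr(x$aligned$specimen_id, x$aligned$coords, function(id, m) {
    tibble::tibble(
      specimen_id = id, landmark = seq_len(nrow(m)),
      x = m[, 1], y = m[, 2]
    )
  })
}

#' @rdname tidy.gpa_alignment
#' @export
glance.gpa_alignment <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$aligned),
    iterations = x$iterations,
    converged = x$converged,
    n_excluded = length(x$excluded)
  )
}

#' Tidy a niche variance decomposition
#'
#' @param x A `niche_decomposition`.
#' @param ... Unused.
#' @return Fixed-effect estimates as a tibble.
#' @export
tidy.niche_decomposition <- function(x, ...) {
  x$fixed_effects
}

#' @rdname tidy.niche_decomposition
#' @export
glance.niche_decomposition <- function(x, ...) {
  tibble::tibble(
    WIC = x$WIC, BIC = x$BIC, TNW = x$TNW, IS = x$IS,
    boundary = x$boundary, n_fish = x$n_fish, n_obs = x$n_obs
  )
}

#' Tidy a WIC GLM
#'
#' @param x A `wic_glm`.
#' @param ... Unused.
#' @return Coefficient tibble with back-transformed (`10^`) estimates.
#' @export
tidy.wic_glm <- function(x, ...) {
  x$coefficients
}

#' @rdname tidy.wic_glm
#' @export
glance.wic_glm <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    n = x$n,
    aic = x$aic,
    r_squared = s$r.squared,
    sigma = s$sigma,
    floored = x$floored
  )
}
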