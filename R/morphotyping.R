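#' PCA of size-adjusted linear measurements
#'
#' Eigen-decomposition of the correlation matrix (variables standardized to
#' unit variance), the common choice for measurements of mixed magnitude;
#' set `scale = FALSE` for the covariance matrix. Loadings follow a
#' deterministic sign convention: within each component the largest-magnitude
#' loading is positive.
#'
#' @param adjusted A tibble of size-adjusted measurements (e.g. from
#'   [reist_adjust()]).
#' @param vars Measurement columns; defaults to the nine standard names
#'   present in the table.
#' @param scale Standardize variables? Default `TRUE`.
#' @return An object of class `morpho_pca`: `scores` tibble,
#'   `percent_variance`, `eigenvalues`, `loadings` matrix.
#' @export
measurement_pca <- function(adjusted, vars = NULL, scale = TRUE) {
  if (is.null(vars)) {
    vars <- intersect(measurement_names(), names(adjusted))
    if (length(vars) == 0) {
      vars <- setdiff(
        names(adjusted)[vapply(adjusted, is.numeric, logical(1))],
        c("fork_length_mm", "year")
      )
    }
  }
  x <- as.matrix(adjusted[, vars, drop = FALSE])
  if (anyNA(x)) abort("Missing values in measurement columns.")
  if (nrow(x) < 3) abort("PCA needs at least 3 specimens.")
  sds <- apply(x, 2, sd)
  if (scale && any(sds == 0)) {
    # standardization divides by the sd, so constant variables are fatal here;
    # covariance-matrix PCA carries them as zero-variance directions
    abort(paste0(
      "Constant variable(s): ", paste(vars[sds == 0], collapse = ", ")
    ))
  }
  pca <- prcomp(x, center = TRUE, scale. = scale)
  # sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(pca$rotation))) {
    i_max <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[i_max, j] < 0) {
      pca$rotation[, j] <- -pca$rotation[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  ev <- pca$sdev^2
  scores <- dplyr::bind_cols(
    tibble::tibble(specimen_id = adjusted$specimen_id %||%
                     sprintf("S%03d", seq_len(nrow(x)))),
    tibble::as_tibble(pca$x)
  )
  structure(
    list(
      scores = scores,
      percent_variance = 100 * ev / sum(ev),
      eigenvalues = ev,
      loadings = pca$rotation,
      center = pca$center,
      scale = if (scale) pca$scale else NULL
    ),
    class = "morpho_pca"
  )
}

#' @export
print.morpho_pca <- function(x, ...) {
  cat("<morpho_pca> ", nrow(x$scores), " specimens, ",
      length(x$eigenvalues), " components\n", sep = "")
  cat("  percent variance:",
      paste(sprintf("%.1f", head(x$percent_variance, 5)), collapse = ", "),
      if (length(x$percent_variance) > 5) "..." else "", "\n")
  invisible(x)
}

# Extract a numeric score matrix from a morpho_pca, tibble or matrix.
score_matrix <- function(scores, pcs = NULL) {
  if (inherits(scores, "morpho_pca")) scores <- scores$scores
  if (is.data.frame(scores)) {
    num <- scores[vapply(scores, is.numeric, logical(1))]
    scores <- as.matrix(num)
  }
  if (!is.null(pcs)) scores <- scores[, seq_len(min(pcs, ncol(scores))), drop = FALSE]
  scores
}

#' K-means clustering of PC scores
#'
#' Lloyd's algorithm with seeded random restarts; the solution with the
#' smallest total within-cluster sum of squares is kept (stats::kmeans
#' re-seeds empty clusters internally). The seed only scopes this call — the
#' caller's RNG state is untouched.
#'
#' @param scores A `morpho_pca`, tibble or numeric matrix of coordinates.
#' @param k Number of clusters.
#' @param restarts Random restarts (default 50).
#' @param seed RNG seed for the restarts.
#' @param pcs Use only the first `pcs` columns (default: all supplied).
#' @return A list: `assignments` (integer vector), `centers`,
#'   `tot_withinss`, `size`.
#' @export
kmeans_cluster <- function(scores, k, restarts = 50, seed = 1, pcs = NULL) {
  x <- score_matrix(scores, pcs)
  if (k < 1) abort("`k` must be at least 1.")
  if (k > nrow(x)) abort("`k` cannot exceed the number of observations.")
  fit <- with_subseed(seed, k, {
    for (attempt in 1:5) {
      res <- tryCatch(
        suppressWarnings(
          kmeans(x, centers = k, nstart = restarts,
                 algorithm = "Lloyd", iter.max = 200)
        ),
        error = function(e) e
      )
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error")) abort(paste0("k-means failed: ", conditionMessage(res)))
    res
  })
  list(
    assignments = as.integer(fit$cluster),
    centers = fit$centers,
    tot_withinss = fit$tot.withinss,
    size = fit$size
  )
}

# Mean silhouette width for a labelled clustering (Euclidean distances).
mean_silhouette <- function(x, assignments) {
  sil <- cluster::silhouette(assignments, dist(x))
  mean(sil[, "sil_width"])
}

#' Choose the number of morphotype clusters by the silhouette method
#'
#' For each candidate k, runs [kmeans_cluster()] and computes the mean
#' silhouette width (Euclidean); the chosen k maximizes it, with ties broken
#' toward the smaller k.
#'
#' @inheritParams kmeans_cluster
#' @param k_range Candidate cluster counts (subset of `2:(n-1)`).
#' @return An object of class `kselect`: `chosen_k`, `silhouette_by_k`
#'   tibble (`k`, `mean_silhouette`, `tot_withinss`), and `clustering` — the
#'   [kmeans_cluster()] result at the chosen k.
#' @export
select_k_silhouette <- function(scores, k_range = 2:8, restarts = 50,
                                seed = 1, pcs = NULL) {
  x <- score_matrix(scores, pcs)
  n <- nrow(x)
  if (n < 3) abort("Silhouette k-selection needs at least 3 observations.")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) abort("No admissible k in `k_range`.")
  fits <- lapply(k_range, function(k) kmeans_cluster(x, k, restarts, seed))
  widths <- vapply(seq_along(k_range), function(i) {
    mean_silhouette(x, fits[[i]]$assignments)
  }, numeric(1))
  best <- which.max(widths) # which.max returns the first (smallest k) on ties
  structure(
    list(
      chosen_k = k_range[best],
      silhouette_by_k = tibble::tibble(
        k = k_range,
        mean_silhouette = widths,
        tot_withinss = vapply(fits, `[[`, numeric(1), "tot_withinss")
      ),
      clustering = fits[[best]]
    ),
    class = "kselect"
  )
}

#' @export
print.kselect <- function(x, ...) {
  cat("<kselect> chosen k =", x$chosen_k, "\n")
  print(x$silhouette_by_k)
  invisible(x)
}
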