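#' Centroid size of a landmark configuration
#'
#' The standard size measure in geometric morphometrics: the square root of
#' the summed squared distances of the landmarks from their centroid.
#'
#' @param coords An n x 2 coordinate matrix.
#' @return A positive scalar in the units of `coords`.
#' @examples
#' centroid_size(matrix(c(-0.5, -0.5, 0.5, 0.5, -0.5, 0.5, -0.5, 0.5), 4, 2))
#' @export
centroid_size <- function(coords) {
  if (!is.matrix(coords) || ncol(coords) != 2 || nrow(coords) < 2) {
    abort("`coords` must be an n x 2 matrix with n >= 2.")
  }
  centered <- sweep(coords, 2, colMeans(coords))
  cs <- sqrt(sum(centered^2))
  if (cs <= .Machine$double.eps) {
    abort("Degenerate shape: all landmarks coincide (centroid size 0).")
  }
  cs
}

# Optimal rotation (no reflection: det = +1) aligning `x` onto `target`,
# both centered. Returns the rotated configuration.
rotate_onto <- function(x, target) {
  sv <- svd(crossprod(x, target))
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  r <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  x %*% r
}

#' Generalized Procrustes alignment of landmark configurations
#'
#' Iteratively removes position, size and orientation: each configuration is
#' centered, scaled to unit centroid size, and rotated (rotation only,
#' determinant +1, via SVD of the cross-covariance with the running mean)
#' onto the current mean shape; the mean is then recomputed and
#' re-standardized, until the change in summed squared Procrustes distance
#' falls below `tol`. Reflections are never used: all photographs are
#' same-side lateral views. Optionally the aligned shapes are orthogonally
#' projected onto the tangent plane at the mean (on by default; turn off to
#' keep exact unit centroid size).
#'
#' Degenerate configurations (all landmarks coincident) are excluded with a
#' message rather than aborting the alignment.
#'
#' @param landmarks A landmark tibble (`specimen_id`, `coords` in mm) or a
#'   list of coordinate matrices.
#' @param tol Convergence tolerance on the summed squared Procrustes
#'   distance (default 1e-8).
#' @param max_iter Iteration cap (default 100); hitting it flags
#'   `converged = FALSE` rather than failing.
#' @param tangent Project onto the tangent plane at the mean shape?
#' @return An object of class `gpa_alignment`: a list with `aligned` (tibble:
#'   `specimen_id`, `coords` list of aligned 21 x 2 matrices,
#'   `centroid_size` in mm), `mean_shape`, `iterations`, `converged`,
#'   `excluded` (character vector of degenerate specimen ids).
#' @export
gpa <- function(landmarks, tol = 1e-8, max_iter = 100, tangent = TRUE) {
  if (is.data.frame(landmarks)) {
    ids <- landmarks$specimen_id
    coords <- landmarks$coords
  } else {
    coords <- landmarks
    ids <- names(coords) %||% sprintf("S%03d", seq_along(coords))
  }
  if (length(coords) < 1) abort("Need at least one configuration.")
  n_lm <- nrow(coords[[1]])
  ok <- vapply(coords, function(m) nrow(m) == n_lm, logical(1))
  if (!all(ok)) abort("All configurations must share the same landmark count.")

  degenerate <- vapply(coords, function(m) {
    centered <- sweep(m, 2, colMeans(m))
    sum(centered^2) <= .Machine$double.eps
  }, logical(1))
  if (any(degenerate)) {
    inform(paste0(
      "Excluding ", sum(degenerate), " degenerate configuration(s): ",
      paste(ids[degenerate], collapse = ", ")
    ))
  }
  keep_ids <- ids[!degenerate]
  coords <- coords[!degenerate]
  if (length(coords) < 1) abort("No non-degenerate configurations remain.")

  sizes <- vapply(coords, centroid_size, numeric(1))
  unitized <- purrr::map2(coords, sizes, function(m, s) {
    sweep(m, 2, colMeans(m)) / s
  })

  if (length(unitized) == 1) {
    aligned <- unitized
    mean_shape <- unitized[[1]]
    iters <- 0L
    converged <- TRUE
  } else {
    mean_shape <- unitized[[1]]
    last_ss <- Inf
    converged <- FALSE
    iters <- 0L
    aligned <- unitized
    for (it in seq_len(max_iter)) {
      aligned <- lapply(aligned, rotate_onto, target = mean_shape)
      mean_shape <- Reduce(`+`, aligned) / length(aligned)
      mean_shape <- sweep(mean_shape, 2, colMeans(mean_shape))
      mean_shape <- mean_shape / sqrt(sum(mean_shape^2))
      ss <- sum(vapply(aligned, function(m) sum((m - mean_shape)^2), numeric(1)))
      iters <- it
      if (abs(last_ss - ss) < tol) {
        converged <- TRUE
        break
      }
      last_ss <- ss
    }
    if (!converged) {
      warn(paste0("GPA did not converge in ", max_iter, " iterations."))
    }
  }

  if (tangent && length(aligned) > 1) {
    m_vec <- as.vector(mean_shape)
    aligned <- lapply(aligned, function(x) {
      xv <- as.vector(x)
      matrix(xv + (1 - sum(xv * m_vec)) * m_vec, ncol = 2,
             dimnames = dimnames(x))
    })
  }

  structure(
    list(
      aligned = tibble::tibble(
        specimen_id = keep_ids,
        coords = aligned,
        centroid_size = sizes
      ),
      mean_shape = mean_shape,
      iterations = iters,
      converged = converged,
      excluded = ids[degenerate]
    ),
    class = "gpa_alignment"
  )
}

#' @export
print.gpa_alignment <- function(x, ...) {
  cat("<gpa_alignment> ", nrow(x$aligned), " configuration(s), ",
      x$iterations, " iteration(s), converged: ", x$converged, "\n", sep = "")
  invisible(x)
}

#' Procrustes distance between two aligned configurations
#'
#' Root summed squared coordinate difference after centering, unit scaling
#' and optimal rotation of `b` onto `a`.
#'
#' @param a,b n x 2 coordinate matrices.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  ua <- sweep(a, 2, colMeans(a))
  ua <- ua / sqrt(sum(ua^2))
  ub <- sweep(b, 2, colMeans(b))
  ub <- ub / sqrt(sum(ub^2))
  ub <- rotate_onto(ub, ua)
  sqrt(sum((ua - ub)^2))
}

#' PCA of Procrustes shape coordinates
#'
#' Centered (unstandardized) principal component analysis of the flattened
#' aligned coordinates. Percent variance sums to 100. For each component the
#' extreme shapes mean +/- max|score| x eigenvector are reported as
#' per-landmark displacement vectors, standing in for deformation-grid
#' visualization.
#'
#' @param alignment A `gpa_alignment` from [gpa()].
#' @param n_pcs Number of components to keep (default: all with positive
#'   variance).
#' @return An object of class `shape_pca`: `scores` tibble (`specimen_id`,
#'   `PC1`, ...), `percent_variance`, `eigenvalues`, `rotation`,
#'   `mean_shape`, and `extremes` — a tibble of per-landmark displacements
#'   (`pc`, `direction`, `landmark`, `dx`, `dy`).
#' @export
shape_pca <- function(alignment, n_pcs = NULL) {
  stopifnot(inherits(alignment, "gpa_alignment"))
  n <- nrow(alignment$aligned)
  if (n < 3) abort("Shape PCA needs at least 3 specimens.")
  flat <- t(vapply(alignment$aligned$coords, as.vector,
                   numeric(length(alignment$mean_shape))))
  pca <- prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- pca$sdev^2
  keep <- if (is.null(n_pcs)) which(ev > 1e-12 * max(ev, 1e-300)) else seq_len(n_pcs)
  if (length(keep) == 0) keep <- 1L
  pct <- 100 * ev / sum(ev)

  scores <- tibble::as_tibble(pca$x[, keep, drop = FALSE])
  scores <- dplyr::bind_cols(
    tibble::tibble(specimen_id = alignment$aligned$specimen_id), scores
  )

  n_lm <- nrow(alignment$mean_shape)
  extremes <- purrr::map_dfr(keep, function(j) {
    rng <- max(abs(pca$x[, j]))
    purrr::map_dfr(c(1, -1), function(s) {
      disp <- matrix(s * rng * pca$rotation[, j], ncol = 2)
      tibble::tibble(
        pc = paste0("PC", j),
        direction = if (s > 0) "max" else "min",
        landmark = seq_len(n_lm),
        dx = disp[, 1],
        dy = disp[, 2]
      )
    })
  })

  structure(
    list(
      scores = scores,
      percent_variance = pct,
      eigenvalues = ev,
      rotation = pca$rotation[, keep, drop = FALSE],
      center = pca$center,
      mean_shape = alignment$mean_shape,
      extremes = extremes
    ),
    class = c("shape_pca", "morpho_pca")
  )
}
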