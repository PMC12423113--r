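# Shared fixtures and independent oracles used across test files.

# Wrap a list of coordinate matrices as a minimal landmark tibble.
landmark_tbl <- function(coord_list, ids = NULL, scale = NA_real_,
                         scale_applied = TRUE) {
  n <- length(coord_list)
  tibble::tibble(
    specimen_id = ids %||% sprintf("S%03d", seq_len(n)),
    coords = coord_list,
    scale = scale,
    scale_applied = scale_applied,
    n_landmarks = vapply(coord_list, nrow, integer(1)),
    valid = vapply(coord_list, nrow, integer(1)) == 21L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply a similarity transform (rotation angle, translation, scale factor).
transform_config <- function(xy, angle = 0, tx = 0, ty = 0, s = 1) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(s * (xy %*% r), 2, c(tx, ty), "+")
}

# Independent mean-silhouette oracle: direct formula on a distance matrix.
silhouette_oracle <- function(x, cl) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    a <- if (length(own) > 1) mean(d[i, setdiff(own, i)]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g) {
      mean(d[i, cl == g])
    }, numeric(1)))
    s[i] <- if (length(own) > 1) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Best assignment accuracy over label permutations (2 clusters).
label_accuracy <- function(truth, assigned) {
  max(mean(truth == assigned), mean(truth == (3 - assigned)))
}

# Dense-matrix REML criterion oracle: builds the full marginal covariance
# H = I + lambda Z Z' and evaluates the profiled criterion with generic
# linear algebra (no block shortcuts) — independent of the package's solver.
reml_criterion_dense <- function(lambda, y, x, fish) {
  z <- model.matrix(~ 0 + factor(fish))
  h <- diag(length(y)) + lambda * tcrossprod(z)
  hi <- solve(h)
  a <- t(x) %*% hi %*% x
  beta <- solve(a, t(x) %*% hi %*% y)
  r <- y - x %*% beta
  q <- drop(t(r) %*% hi %*% r)
  determinant(h)$modulus + determinant(a)$modulus +
    (length(y) - ncol(x)) * log(q)
}

# Grid-based REML oracle over lambda, returning WIC/BIC. Two-stage: a coarse
# log-scale sweep, then a dense linear grid across the best coarse bracket.
reml_oracle_grid <- function(y, x, fish, grid = c(0, 10^seq(-4, 2, by = 0.05))) {
  crit <- vapply(grid, reml_criterion_dense, numeric(1), y = y, x = x, fish = fish)
  i <- which.min(crit)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  fine <- seq(lo, hi, length.out = 4001)
  crit_f <- vapply(fine, reml_criterion_dense, numeric(1), y = y, x = x, fish = fish)
  lam <- fine[which.min(crit_f)]
  z <- model.matrix(~ 0 + factor(fish))
  h <- diag(length(y)) + lam * tcrossprod(z)
  hi <- solve(h)
  a <- t(x) %*% hi %*% x
  beta <- solve(a, t(x) %*% hi %*% y)
  r <- y - x %*% beta
  q <- drop(t(r) %*% hi %*% r)
  s2w <- q / (length(y) - ncol(x))
  list(WIC = s2w, BIC = lam * s2w, lambda = lam)
}
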