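test_that("centroid size matches closed forms and is homogeneous", {
  sq <- matrix(c(-0.5, -0.5, 0.5, 0.5, -0.5, 0.5, -0.5, 0.5), 4, 2)
  expect_equal(centroid_size(sq), sqrt(2))
  expect_equal(centroid_size(3.7 * sq), 3.7 * sqrt(2))

  set.seed(1)
  xy <- matrix(rnorm(42), 21, 2)
  oracle <- sqrt(sum(sweep(xy, 2, colMeans(xy))^2))
  expect_equal(centroid_size(xy), oracle, tolerance = 1e-12)

  expect_error(centroid_size(matrix(1, 5, 2)), "Degenerate")
})

test_that("a single configuration aligns to its centered unit-size version", {
  set.seed(2)
  xy <- matrix(rnorm(42), 21, 2)
  g <- gpa(landmark_tbl(list(xy)))
  centered <- sweep(xy, 2, colMeans(xy))
  expect_equal(g$aligned$coords[[1]], centered / sqrt(sum(centered^2)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(g$mean_shape, g$aligned$coords[[1]], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("similarity-transformed copies align to Procrustes distance ~ 0", {
  tri <- rbind(reference_template()) # any 21-point shape
  copies <- list(
    tri,
    transform_config(tri, angle = 37 * pi / 180, tx = 5, ty = -3, s = 3),
    transform_config(tri, angle = -1.2, tx = -8, ty = 2, s = 0.5)
  )
  g <- gpa(landmark_tbl(copies))
  cc <- g$aligned$coords
  for (i in 2:3) {
    expect_lt(sqrt(sum((cc[[1]] - cc[[i]])^2)), 1e-10)
  }
})

test_that("GPA output is invariant to arbitrary pre-transforms of the inputs", {
  set.seed(3)
  base <- lapply(1:6, function(i) reference_template() + matrix(rnorm(42, 0, 0.01), 21, 2))
  g1 <- gpa(landmark_tbl(base), tangent = FALSE)
  moved <- lapply(base, function(xy) {
    transform_config(xy, angle = runif(1, 0, 2 * pi),
                     tx = runif(1, -10, 10), ty = runif(1, -10, 10),
                     s = runif(1, 0.2, 5))
  })
  g2 <- gpa(landmark_tbl(moved), tangent = FALSE)
  # shapes agree up to a global rotation
  expect_lt(procrustes_distance(g1$mean_shape, g2$mean_shape), 1e-9)
  d1 <- vapply(g1$aligned$coords, function(m) sum((m - g1$mean_shape)^2), numeric(1))
  d2 <- vapply(g2$aligned$coords, function(m) sum((m - g2$mean_shape)^2), numeric(1))
  expect_equal(d1, d2, tolerance = 1e-9)
})

test_that("aligned configurations are centered with unit centroid size", {
  lms <- simulate_landmarks(synthetic_truth(n_fish = 15, seed = 6))
  g <- gpa(lms, tangent = FALSE)
  for (m in g$aligned$coords) {
    expect_lt(max(abs(colMeans(m))), 1e-9)
    expect_equal(sqrt(sum(m^2)), 1, tolerance = 1e-9)
  }
  # mean shape is the re-standardized coordinate-wise mean
  avg <- Reduce(`+`, g$aligned$coords) / length(g$aligned$coords)
  avg <- sweep(avg, 2, colMeans(avg))
  expect_equal(g$mean_shape, avg / sqrt(sum(avg^2)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("GPA mean shape matches a rotation-grid brute-force oracle", {
  set.seed(4)
  tri <- matrix(c(0, 0, 1, 0, 0.4, 0.9), 3, 2, byrow = TRUE)
  noisy <- lapply(1:5, function(i) {
    transform_config(tri + matrix(rnorm(6, 0, 0.03), 3, 2),
                     angle = runif(1, 0, 2 * pi), tx = runif(1, -2, 2),
                     ty = runif(1, -2, 2), s = runif(1, 0.5, 2))
  })
  g <- gpa(landmark_tbl(noisy), tangent = FALSE)

  # oracle: same centering/unit scaling, rotations by exhaustive grid search
  unitize <- function(m) {
    m <- sweep(m, 2, colMeans(m))
    m / sqrt(sum(m^2))
  }
  rot <- function(m, a) m %*% matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  angles <- seq(0, 2 * pi, by = 1e-3)
  configs <- lapply(noisy, unitize)
  mean_o <- configs[[1]]
  for (it in 1:30) {
    configs <- lapply(configs, function(m) {
      ss <- vapply(angles, function(a) sum((rot(m, a) - mean_o)^2), numeric(1))
      rot(m, angles[which.min(ss)])
    })
    mean_o <- unitize(Reduce(`+`, configs) / length(configs))
  }
  # compare shapes after grid-aligning the oracle mean onto the GPA mean
  ss <- vapply(angles, function(a) sum((rot(mean_o, a) - g$mean_shape)^2),
               numeric(1))
  aligned_o <- rot(mean_o, angles[which.min(ss)])
  expect_lt(max(abs(aligned_o - g$mean_shape)), 1e-3)
})

test_that("degenerate configurations are excluded with a log entry", {
  good <- lapply(1:3, function(i) reference_template() + 0.01 * i)
  bad <- matrix(1, 21, 2)
  expect_message(
    g <- gpa(landmark_tbl(c(good, list(bad)))),
    "degenerate"
  )
  expect_equal(nrow(g$aligned), 3)
  expect_equal(g$excluded, "S004")
})

test_that("shape PCA percent variance sums to 100 and degenerate cases behave", {
  lms <- simulate_landmarks(synthetic_truth(n_fish = 12, seed = 9))
  g <- gpa(lms)
  sp <- shape_pca(g)
  expect_true(all(sp$percent_variance >= 0))
  expect_equal(sum(sp$percent_variance), 100, tolerance = 1e-9)
  expect_equal(nrow(sp$scores), 12)

  # identical shapes: all eigenvalues (numerically) zero
  same <- landmark_tbl(lapply(1:4, function(i) reference_template()))
  g0 <- gpa(same)
  sp0 <- shape_pca(g0)
  expect_lt(max(sp0$eigenvalues), 1e-20)
})

test_that("shape PCA scores match a direct eigendecomposition oracle", {
  set.seed(10)
  lms <- landmark_tbl(lapply(1:4, function(i) {
    reference_template() + matrix(rnorm(42, 0, 0.02), 21, 2)
  }))
  g <- gpa(lms)
  sp <- shape_pca(g)
  flat <- t(vapply(g$aligned$coords, as.vector, numeric(42)))
  cen <- scale(flat, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(cen) / (nrow(cen) - 1), symmetric = TRUE)
  scores_o <- cen %*% eig$vectors[, 1:3]
  scores <- as.matrix(sp$scores[, -1])
  for (j in 1:3) {
    expect_equal(abs(scores[, j]), abs(scores_o[, j]), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("single-axis variation loads 100% on PC1", {
  base <- reference_template()
  lms <- landmark_tbl(lapply(seq(-0.02, 0.02, length.out = 5), function(d) {
    m <- base
    m[1, 1] <- m[1, 1] + d
    m
  }))
  sp <- shape_pca(gpa(lms, tangent = FALSE))
  expect_gt(sp$percent_variance[1], 99.9)
})
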