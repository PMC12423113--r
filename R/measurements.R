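#' Inter-landmark linear measurements
#'
#' Computes the nine named Euclidean distances (mm) plus fork length from a
#' landmark table whose coordinates are in mm (scale applied). Distances are
#' invariant to the rotation/translation of each configuration.
#'
#' @param landmarks A landmark tibble with `specimen_id` and `coords` in mm.
#' @param pair_map Named list of landmark index pairs, one per measurement,
#'   plus a `fork_length` pair; see [default_pair_map()].
#' @return A tibble: `specimen_id`, one mm column per measurement,
#'   `fork_length_mm`.
#' @export
interlandmark_distances <- function(landmarks, pair_map = default_pair_map()) {
  if ("scale_applied" %in% names(landmarks) && !all(landmarks$scale_applied)) {
    abort("Coordinates must be in mm: run apply_scale() first.")
  }
  if (!"fork_length" %in% names(pair_map)) {
    abort("`pair_map` must include a `fork_length` pair.")
  }
  n_lm <- nrow(landmarks$coords[[1]])
  for (nm in names(pair_map)) {
    pr <- pair_map[[nm]]
    if (length(pr) != 2 || any(pr < 1) || any(pr > n_lm)) {
      abort(paste0("pair_map entry '", nm, "' has indices outside 1..", n_lm, "."))
    }
  }
  dist_of <- function(xy, pr) sqrt(sum((xy[pr[1], ] - xy[pr[2], ])^2))
  meas <- setdiff(names(pair_map), "fork_length")
  out <- tibble::tibble(specimen_id = landmarks$specimen_id)
  for (nm in meas) {
    out[[nm]] <- vapply(landmarks$coords, dist_of, numeric(1), pr = pair_map[[nm]])
  }
  out$fork_length_mm <- vapply(
    landmarks$coords, dist_of, numeric(1), pr = pair_map$fork_length
  )
  out
}

#' Reist allometric size adjustment of linear measurements
#'
#' Standardizes each measurement to a common body length:
#' `Y_i = log10(M_i) + b * (log10(L_m) - log10(L_i))`, where `b` is the
#' ordinary least-squares slope of `log10(M)` on `log10(L)` pooled across all
#' retained fish, `L_i` the fish's fork length and `L_m` the alignment
#' length — by default the mean fork length of the retained fish, overridable
#' (e.g. 368.1 mm). Adjusted values are in log10(mm) units; by construction
#' the OLS slope of `Y` on `log10(L)` is zero.
#'
#' @param measurements A tibble from [interlandmark_distances()] (columns:
#'   `specimen_id`, measurement mm columns, `fork_length_mm`).
#' @param l_m Alignment fork length in mm; `NULL` (default) uses the mean of
#'   `fork_length_mm`.
#' @param vars Measurement columns to adjust; defaults to every numeric
#'   column except `fork_length_mm`.
#' @return A tibble `specimen_id`, `fork_length_mm`, and one adjusted
#'   (log10 mm) column per measurement, with attributes `slopes` (named
#'   vector of pooled allometric slopes) and `l_m`.
#' @export
reist_adjust <- function(measurements, l_m = NULL, vars = NULL) {
  if (is.null(vars)) {
    vars <- setdiff(
      names(measurements)[vapply(measurements, is.numeric, logical(1))],
      c("fork_length_mm", "year")
    )
  }
  li <- measurements$fork_length_mm
  if (any(li <= 0)) abort("Fork lengths must be positive.")
  if (nrow(measurements) < 3) abort("Need at least 3 specimens to estimate slopes.")
  log_l <- log10(li)
  if (var(log_l) <= 0) abort("Zero variance in log10 fork length: slope undefined.")
  if (is.null(l_m)) l_m <- mean(li)

  out <- tibble::tibble(
    specimen_id = measurements$specimen_id,
    fork_length_mm = li
  )
  slopes <- setNames(numeric(length(vars)), vars)
  for (v in vars) {
    m <- measurements[[v]]
    if (any(m <= 0)) abort(paste0("Measurement '", v, "' has non-positive values."))
    log_m <- log10(m)
    b <- coef(lm(log_m ~ log_l))[2]
    slopes[v] <- b
    out[[v]] <- log_m + b * (log10(l_m) - log_l)
  }
  attr(out, "slopes") <- slopes
  attr(out, "l_m") <- l_m
  out
}

#' Pooled allometric slopes from a Reist-adjusted table
#' @param adjusted Output of [reist_adjust()].
#' @return Named numeric vector of per-measurement log-log slopes.
#' @export
reist_slopes <- function(adjusted) {
  s <- attr(adjusted, "slopes")
  if (is.null(s)) abort("No slopes attribute: not a reist_adjust() result?")
  s
}
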