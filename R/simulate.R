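# Stage indices for sub-seed derivation; fixed so each stage has its own
# reproducible stream regardless of which generator is called first.
.stages <- c(
  fork_length = 1L, morphotype = 2L, year = 3L, pose = 4L,
  digitization = 5L, latent = 6L, within = 7L, dropout = 8L
)

# Shared specimen-level draws (fork length, morphotype, year). Both the
# landmark and the isotope generator call this, so the two datasets describe
# the same fish whenever they are built from the same truth object.
simulate_specimens <- function(truth) {
  n <- truth$n_fish
  fl <- with_subseed(truth$seed, .stages[["fork_length"]], {
    abs(rnorm(n, truth$fork_length_mean, truth$fork_length_sd))
  })
  morph <- with_subseed(truth$seed, .stages[["morphotype"]], {
    sample(seq_along(truth$morphotype_fractions), n,
           replace = TRUE, prob = truth$morphotype_fractions)
  })
  year <- with_subseed(truth$seed, .stages[["year"]], {
    sample(truth$year_labels, n, replace = TRUE, prob = truth$year_fractions)
  })
  tibble::tibble(
    specimen_id = sprintf("FISH%04d", seq_len(n)),
    fork_length_mm = fl,
    morphotype = morph,
    year = as.integer(year)
  )
}

#' Simulate landmark configurations with known morphotype labels
#'
#' Each specimen is its morphotype's shape template, scaled so that linear
#' body measurements vary with fork length as FL^`allometric_exponent`
#' (exponent 1 gives isometry and a digitized fork length equal to the
#' specimen's fork length), randomly rotated and translated, with Gaussian
#' digitization noise of sd `digitization_sd` mm added to every coordinate.
#'
#' @param truth A [synthetic_truth()] object.
#' @return A tibble with one row per specimen: `specimen_id`, `coords`
#'   (list of 21 x 2 matrices, mm, y up), `scale` (mm per stored unit),
#'   `scale_applied`, `photo_quality`, `landmark_quality` (list of 21 ranks),
#'   `n_landmarks`, `valid`, `fork_length_mm`, `year`, and the true
#'   `morphotype` label for recovery tests.
#' @examples
#' lm_tbl <- simulate_landmarks(synthetic_truth(n_fish = 10, seed = 3))
#' @export
simulate_landmarks <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- simulate_specimens(truth)
  n <- nrow(spec)

  # template fork length (units) so that exponent-1 scaling reproduces the
  # specimen's fork length exactly in the digitized configuration
  fl_ref <- truth$fork_length_mean
  pose <- with_subseed(truth$seed, .stages[["pose"]], {
    tibble::tibble(
      angle = runif(n, 0, 2 * pi),
      tx = runif(n, -50, 50),
      ty = runif(n, -50, 50)
    )
  })
  noise <- with_subseed(truth$seed, .stages[["digitization"]], {
    array(rnorm(n * 21 * 2, 0, truth$digitization_sd), dim = c(21, 2, n))
  })

  coords <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- truth$shape_templates[[spec$morphotype[i]]]
    d0 <- sqrt(sum((tmpl[13, ] - tmpl[1, ])^2))
    size <- (fl_ref / d0) * (spec$fork_length_mm[i] / fl_ref)^truth$allometric_exponent
    xy <- tmpl * size
    a <- pose$angle[i]
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    xy <- xy %*% rot
    xy <- sweep(xy, 2, c(pose$tx[i], pose$ty[i]), "+")
    xy <- xy + noise[, , i]
    # store in image units when an image scale is simulated, so apply_scale()
    # has work to do downstream
    xy <- xy / truth$image_scale
    colnames(xy) <- c("x", "y")
    coords[[i]] <- xy
  }

  tibble::tibble(
    specimen_id = spec$specimen_id,
    coords = coords,
    scale = truth$image_scale,
    scale_applied = FALSE,
    photo_quality = 3L,
    landmark_quality = replicate(n, rep(3L, 21), simplify = FALSE),
    n_landmarks = 21L,
    valid = TRUE,
    fork_length_mm = spec$fork_length_mm,
    year = spec$year,
    morphotype = spec$morphotype
  )
}

#' Simulate two-tissue stable-isotope records with known variance structure
#'
#' Per fish i and isotope, a latent mean is drawn as
#' `Normal(group mean + slope * (FL_i - mean FL), sigma2_between)`; the
#' observation for tissue t is the latent mean plus the tissue's diet-tissue
#' offset plus `Normal(0, sigma2_within)` noise. Values are emitted raw
#' (before discrimination correction) so the pipeline's correction step is
#' exercised. A deterministic count `round(n_fish * missing_tissue_fraction)`
#' of fish lose one randomly chosen tissue.
#'
#' @param truth A [synthetic_truth()] object.
#' @return A tibble of records: `fish_id`, `tissue` ("RBC"/"plasma"),
#'   `d13C`, `d15N` (raw, per mil), `year`, `fork_length_mm`, and the true
#'   `morphotype`.
#' @examples
#' iso <- simulate_isotopes(synthetic_truth(n_fish = 10, seed = 3))
#' @export
simulate_isotopes <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  spec <- simulate_specimens(truth)
  n <- nrow(spec)
  isotopes <- unique(truth$isotope_group_means$isotope)
  fl_centered <- spec$fork_length_mm - mean(spec$fork_length_mm)

  latent <- with_subseed(truth$seed, .stages[["latent"]], {
    out <- list()
    for (iso in isotopes) {
      gm <- truth$isotope_group_means
      mu0 <- gm$mean[match(
        paste(iso, spec$morphotype),
        paste(gm$isotope, gm$morphotype)
      )]
      out[[iso]] <- rnorm(
        n,
        mu0 + truth$fork_length_slope * fl_centered,
        sqrt(truth$sigma2_between)
      )
    }
    out
  })

  tissues <- c("RBC", "plasma")
  eps <- with_subseed(truth$seed, .stages[["within"]], {
    lapply(setNames(isotopes, isotopes), function(iso) {
      matrix(rnorm(n * 2, 0, sqrt(truth$sigma2_within)), n, 2,
             dimnames = list(NULL, tissues))
    })
  })

  offsets <- truth$tissue_offsets
  rows <- tidyr::expand_grid(i = seq_len(n), tissue = tissues)
  value_of <- function(iso) {
    off <- offsets$delta[match(paste(rows$tissue, iso),
                               paste(offsets$tissue, offsets$isotope))]
    off[is.na(off)] <- 0
    latent[[iso]][rows$i] + off +
      eps[[iso]][cbind(rows$i, match(rows$tissue, tissues))]
  }

  records <- tibble::tibble(
    fish_id = spec$specimen_id[rows$i],
    tissue = rows$tissue,
    year = spec$year[rows$i],
    fork_length_mm = spec$fork_length_mm[rows$i],
    morphotype = spec$morphotype[rows$i]
  )
  for (iso in isotopes) records[[iso]] <- value_of(iso)

  n_drop <- round(truth$n_fish * truth$missing_tissue_fraction)
  if (n_drop > 0) {
    drops <- with_subseed(truth$seed, .stages[["dropout"]], {
      tibble::tibble(
        fish = sample(spec$specimen_id, n_drop),
        tissue = sample(tissues, n_drop, replace = TRUE)
      )
    })
    keep <- !(paste(records$fish_id, records$tissue) %in%
                paste(drops$fish, drops$tissue))
    records <- records[keep, ]
  }
  dplyr::select(
    records,
    "fish_id", "tissue", dplyr::all_of(isotopes),
    "year", "fork_length_mm", "morphotype"
  )
}

#' Write the specimen table CSV used by the pipeline
#'
#' Schema: `specimen_id`, `fork_length_mm`, `year`.
#'
#' @param landmarks A tibble from [simulate_landmarks()] (or any table with
#'   the three schema columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimen_csv <- function(landmarks, path) {
  utils::write.csv(
    dplyr::select(landmarks, "specimen_id", "fork_length_mm", "year"),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Write the isotope table CSV used by the pipeline
#'
#' Schema: `fish_id`, `tissue`, `d13C`, `d15N`, `year` (raw per-mil values).
#'
#' @param records A tibble from [simulate_isotopes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_isotope_csv <- function(records, path) {
  utils::write.csv(
    dplyr::select(records, "fish_id", "tissue", "d13C", "d15N", "year"),
    path, row.names = FALSE
  )
  invisible(path)
}
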