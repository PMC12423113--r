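default_config <- function() {
  list(
    input = NULL,      # list(tps=, specimen_csv=, isotope_csv=)
    synthetic = NULL,  # named args for synthetic_truth()
    quality = list(min_photo_rank = 2, min_landmark_rank = 2),
    pair_map = default_pair_map(),
    l_m = NULL,
    clustering = list(pcs = 2, k_range = c(2, 8), restarts = 50),
    discrimination = NULL, # named list overriding discrimination_factors()
    specialization = list(direction = "plasma_on_rbc"),
    seed = 1L,
    out_dir = NULL
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path or a list. Unknown keys are rejected; exactly one
#' of `input` (real data paths) or `synthetic` (generator parameters) must be
#' present; all defaults are filled in. Errors are aggregated and reported
#' together, not first-fail.
#'
#' @param config A list or a path to a YAML config file.
#' @return A normalized config list (class `morphospec_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  defaults <- default_config()
  errors <- character()

  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  if (has_input && has_synth) {
    errors <- c(errors, "keys `input` and `synthetic` are mutually exclusive")
  }
  if (!has_input && !has_synth) {
    errors <- c(errors, "one of `input` or `synthetic` is required")
  }
  if (has_input) {
    need <- c("tps", "specimen_csv", "isotope_csv")
    missing_keys <- setdiff(need, names(config$input))
    if (length(missing_keys) > 0) {
      errors <- c(errors, paste0(
        "input: missing key(s): ", paste(missing_keys, collapse = ", ")
      ))
    }
  }
  if (has_synth && !is.list(config$synthetic)) {
    errors <- c(errors, "`synthetic` must be a list of synthetic_truth() arguments")
  }
  if (has_synth && is.list(config$synthetic)) {
    bad <- setdiff(names(config$synthetic), names(formals(synthetic_truth)))
    if (length(bad) > 0) {
      errors <- c(errors, paste0(
        "synthetic: unknown parameter(s): ", paste(bad, collapse = ", ")
      ))
    }
  }
  for (k in c("quality", "clustering", "specialization")) {
    if (!is.null(config[[k]])) {
      bad <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(bad) > 0) {
        errors <- c(errors, paste0(k, ": unknown key(s): ", paste(bad, collapse = ", ")))
      }
    }
  }
  if (!is.null(config$seed) &&
      (!is.numeric(config$seed) || length(config$seed) != 1)) {
    errors <- c(errors, "`seed` must be a single integer")
  }
  if (length(errors) > 0) {
    abort(paste0(
      "Invalid configuration:\n",
      paste0("  - ", errors, collapse = "\n")
    ))
  }

  out <- defaults
  for (k in names(config)) {
    if (is.null(config[[k]])) next # keep the default (possibly NULL) entry
    if (is.list(defaults[[k]]) && is.list(config[[k]]) && k != "pair_map" &&
        k != "synthetic" && k != "input") {
      out[[k]] <- modifyList(defaults[[k]], config[[k]])
    } else {
      out[[k]] <- config[[k]]
    }
  }
  out$seed <- as.integer(out$seed)
  class(out) <- c("morphospec_config", "list")
  out
}

# Build the tissue offsets / discrimination tibble from a config override
# like list(d13C_plasma = 1.2, d15N_RBC = 1.1, ...).
config_discrimination <- function(override) {
  fac <- discrimination_factors()
  if (is.null(override)) return(fac)
  for (nm in names(override)) {
    parts <- strsplit(nm, "_")[[1]]
    idx <- which(fac$isotope == parts[1] & fac$tissue == parts[2])
    if (length(idx) != 1) abort(paste0("Unrecognized discrimination key: ", nm))
    fac$delta[idx] <- override[[nm]]
  }
  fac
}

#' Run the full morphotype and specialization pipeline
#'
#' Executes, in order: quality filter, scale application, generalized
#' Procrustes alignment and shape PCA, inter-landmark measurements and Reist
#' size adjustment, measurement PCA with silhouette k-selection and k-means
#' morphotyping, MANOVA and Bonferroni-corrected post hoc tests with
#' assumption diagnostics, diet-tissue discrimination correction,
#' tissue-switch metrics, per-group WIC/BIC/TNW/IS variance decompositions,
#' and the individual-WIC GLM with AIC-guarded simplification. All stochastic
#' stages draw sub-seeds derived from `config$seed`, so reruns of the same
#' config are identical.
#'
#' @param config A config list or YAML path; see [validate_config()].
#' @return A `morphospec_report`: a named list of stage results (`landmarks`,
#'   `quality`, `alignment`, `shape_pca`, `measurements`, `adjusted`,
#'   `measurement_pca`, `kselect`, `assignments`, `manova`, `posthoc`,
#'   `assumptions`, `isotopes`, `switch`, `switch_tests`, `decomposition`,
#'   `individual_wic`, `wic_models`, `log`, `config`). When
#'   `config$out_dir` is set, stage artifacts are also written as CSV plus a
#'   YAML summary.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines[[length(log_lines) + 1]] <<- line
    inform(line)
  }

  # ---- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    truth <- do.call(synthetic_truth, config$synthetic)
    landmarks <- simulate_landmarks(truth)
    isotopes_raw <- simulate_isotopes(truth)
    note("Synthetic inputs: ", nrow(landmarks), " specimens (seed ",
         truth$seed, ").")
  } else {
    landmarks <- read_tps(config$input$tps)
    spec_tbl <- tibble::as_tibble(
      utils::read.csv(config$input$specimen_csv, stringsAsFactors = FALSE)
    )
    landmarks <- dplyr::left_join(landmarks, spec_tbl, by = "specimen_id")
    isotopes_raw <- tibble::as_tibble(
      utils::read.csv(config$input$isotope_csv, stringsAsFactors = FALSE)
    )
    isotopes_raw <- dplyr::left_join(
      isotopes_raw,
      dplyr::select(spec_tbl, "specimen_id", "fork_length_mm"),
      by = c(fish_id = "specimen_id")
    )
    note("Read ", nrow(landmarks), " landmark records and ",
         nrow(isotopes_raw), " isotope records.")
  }

  # ---- quality filter and scaling ----------------------------------------
  n_invalid <- sum(!landmarks$valid)
  if (n_invalid > 0) {
    note("Dropping ", n_invalid, " record(s) without 21 landmarks.")
    landmarks <- landmarks[landmarks$valid, ]
  }
  qf <- quality_filter(
    landmarks,
    min_photo_rank = config$quality$min_photo_rank,
    min_landmark_rank = config$quality$min_landmark_rank
  )
  note("Quality filter retained ", nrow(qf$retained), " of ",
       nrow(landmarks), " specimens.")
  retained <- qf$retained
  if (!all(retained$scale_applied)) retained <- apply_scale(retained)

  # ---- morphometry --------------------------------------------------------
  alignment <- gpa(retained)
  spca <- shape_pca(alignment)
  note("GPA converged in ", alignment$iterations, " iteration(s); shape PC1 ",
       sprintf("%.1f%%", spca$percent_variance[1]), ".")
  measurements <- interlandmark_distances(retained, config$pair_map)
  adjusted <- reist_adjust(measurements, l_m = config$l_m)
  note("Reist adjustment to L_m = ",
       sprintf("%.1f", attr(adjusted, "l_m")), " mm.")

  # ---- morphotyping -------------------------------------------------------
  mpca <- measurement_pca(adjusted)
  kr <- config$clustering$k_range
  ks <- select_k_silhouette(
    mpca,
    k_range = seq(kr[1], kr[length(kr)]),
    restarts = config$clustering$restarts,
    seed = config$seed,
    pcs = config$clustering$pcs
  )
  assignments <- tibble::tibble(
    specimen_id = mpca$scores$specimen_id,
    cluster = ks$clustering$assignments
  )
  note("Silhouette chose k = ", ks$chosen_k, " (clustered on first ",
       config$clustering$pcs, " PCs; PC1 ",
       sprintf("%.1f%%", mpca$percent_variance[1]), ", PC2 ",
       sprintf("%.1f%%", mpca$percent_variance[2]), ").")

  vars <- intersect(measurement_names(), names(adjusted))
  manova_res <- manova_pillai(adjusted, assignments$cluster, vars)
  assumptions <- assumption_checks(adjusted, assignments$cluster, vars)
  posthoc <- if (ks$chosen_k == 2) {
    posthoc_welch(adjusted, assignments$cluster, vars)
  } else {
    note("Post hoc two-group tests skipped: chosen k != 2.")
    NULL
  }

  # ---- isotopes -----------------------------------------------------------
  fac <- config_discrimination(config$discrimination)
  iso <- apply_discrimination(isotopes_raw, fac)
  iso <- dplyr::left_join(
    iso, assignments, by = c(fish_id = "specimen_id")
  )
  n_unassigned <- sum(is.na(iso$cluster))
  if (n_unassigned > 0) {
    note(n_unassigned,
         " isotope record(s) lack a morphotype (specimen filtered out); ",
         "excluded from group-level niche metrics.")
  }
  iso_clustered <- iso[!is.na(iso$cluster), ]
  switch_tbl <- tissue_switch(iso_clustered)
  switch_tests <- if (length(unique(iso_clustered$cluster)) == 2) {
    dplyr::bind_rows(
      d13C = compare_groups(switch_tbl, switch_tbl$cluster, "d13C_switch"),
      d15N = compare_groups(switch_tbl, switch_tbl$cluster, "d15N_switch"),
      .id = "isotope"
    )
  } else {
    NULL
  }

  # ---- specialization -----------------------------------------------------
  decomposition <- decompose_niche(iso_clustered)
  iwic <- individual_wic(
    iso_clustered,
    direction = config$specialization$direction
  )
  wic_models <- list()
  for (iso_name in unique(iwic$isotope)) {
    d <- iwic[iwic$isotope == iso_name, ]
    terms <- c(
      if (length(unique(d$cluster)) > 1) "cluster",
      if ("fork_length_mm" %in% names(d)) "fork_length_mm",
      if ("year" %in% names(d) && length(unique(d$year)) > 1) "year"
    )
    if (nrow(d) >= 10 && length(terms) > 0) {
      f <- as.formula(paste("log10_wic ~", paste(terms, collapse = " + ")))
      m <- wic_glm(d, f)
      wic_models[[iso_name]] <- list(
        glm = m,
        simplified = simplify_by_aic(m)
      )
    } else {
      note("WIC GLM skipped for ", iso_name, ": too few paired fish.")
    }
  }

  report <- structure(
    list(
      landmarks = landmarks,
      quality = qf,
      alignment = alignment,
      shape_pca = spca,
      measurements = measurements,
      adjusted = adjusted,
      measurement_pca = mpca,
      kselect = ks,
      assignments = assignments,
      manova = manova_res,
      posthoc = posthoc,
      assumptions = assumptions,
      isotopes = iso,
      switch = switch_tbl,
      switch_tests = switch_tests,
      decomposition = decomposition,
      individual_wic = iwic,
      wic_models = wic_models,
      log = log_lines,
      config = config
    ),
    class = "morphospec_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.morphospec_report <- function(x, ...) {
  cat("<morphospec_report>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  cat("  decomposition:\n")
  print(tibble::as_tibble(x$decomposition))
  invisible(x)
}

# Write stage artifacts as CSV plus a YAML machine summary. Column units:
# raw measurements are mm, adjusted measurements log10(mm), isotope values
# per mil, variances per mil squared.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")), row.names = FALSE)
  }
  wr(report$assignments, "assignments")
  wr(report$kselect$silhouette_by_k, "silhouette_by_k")
  wr(report$manova, "manova")
  if (!is.null(report$posthoc)) wr(report$posthoc, "posthoc")
  wr(report$assumptions, "assumption_checks")
  adj <- report$adjusted
  names(adj) <- ifelse(
    names(adj) %in% measurement_names(),
    paste0(names(adj), "_log10mm"), names(adj)
  )
  wr(adj, "measurements_adjusted")
  wr(report$measurements, "measurements_raw_mm")
  wr(tibble::tibble(
    measurement = names(reist_slopes(report$adjusted)),
    slope = reist_slopes(report$adjusted)
  ), "reist_slopes")
  wr(report$isotopes, "isotopes_corrected")
  wr(report$switch, "tissue_switch")
  if (!is.null(report$switch_tests)) wr(report$switch_tests, "switch_tests")
  wr(report$decomposition, "variance_decomposition")
  wr(report$individual_wic, "individual_wic")
  for (iso in names(report$wic_models)) {
    wr(report$wic_models[[iso]]$glm$coefficients, paste0("wic_glm_", iso))
  }
  summary <- list(
    seed = report$config$seed,
    n_landmark_records = nrow(report$landmarks),
    n_retained = nrow(report$quality$retained),
    n_excluded = nrow(report$quality$excluded),
    gpa_iterations = report$alignment$iterations,
    chosen_k = report$kselect$chosen_k,
    manova_pillai = report$manova$value,
    manova_f = report$manova$approx_f,
    decomposition = lapply(
      split(report$decomposition, seq_len(nrow(report$decomposition))),
      function(r) as.list(r[c("isotope", "group", "WIC", "BIC", "TNW", "IS")])
    ),
    log = report$log
  )
  yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}
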