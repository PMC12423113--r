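#' Delta notation from isotope ratios
#'
#' `delta = (R_sample / R_standard - 1) * 1000` per mil, the standard
#' expression of an isotope ratio relative to an international reference
#' (V-PDB for carbon, atmospheric N2 for nitrogen).
#'
#' @param r_sample,r_standard Positive isotope ratios (e.g. 13C/12C);
#'   vectorized.
#' @return Delta value(s), per mil.
#' @examples
#' delta_from_ratio(1.001, 1) # 1 per mil
#' @export
delta_from_ratio <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    abort("Isotope ratios must be positive.")
  }
  (r_sample / r_standard - 1) * 1000
}

#' Inverse of [delta_from_ratio()]
#' @param delta Delta value(s), per mil.
#' @param r_standard Reference ratio.
#' @return Sample ratio(s).
#' @export
ratio_from_delta <- function(delta, r_standard) {
  (delta / 1000 + 1) * r_standard
}

#' Apply diet-tissue discrimination correction
#'
#' Subtracts the tissue- and isotope-specific discrimination factor from each
#' raw value (consumer-minus-diet convention: since
#' `Delta = delta_consumer - delta_food`, subtraction places both tissues on
#' a common, diet-referenced scale). The correction is a rigid shift within
#' tissue, so all variance-based niche metrics are invariant to the sign
#' convention; it is isolated here so the convention is swappable.
#'
#' @param records A tibble with `tissue` and raw isotope columns `d13C`,
#'   `d15N` (any subset).
#' @param factors A discrimination-factor tibble (`tissue`, `isotope`,
#'   `delta`); default [discrimination_factors()].
#' @return `records` with `<isotope>_corr` columns appended.
#' @export
apply_discrimination <- function(records, factors = discrimination_factors()) {
  if (!"tissue" %in% names(records)) abort("`records` must have a `tissue` column.")
  unknown <- setdiff(unique(records$tissue), unique(factors$tissue))
  if (length(unknown) > 0) {
    abort(paste0("Unknown tissue(s): ", paste(unknown, collapse = ", ")))
  }
  isotopes <- intersect(unique(factors$isotope), names(records))
  if (length(isotopes) == 0) abort("No isotope columns found to correct.")
  for (iso in isotopes) {
    d <- factors$delta[match(
      paste(records$tissue, iso),
      paste(factors$tissue, factors$isotope)
    )]
    d[is.na(d)] <- 0
    records[[paste0(iso, "_corr")]] <- records[[iso]] - d
  }
  records
}

#' Per-fish tissue-switch metrics (RBC minus plasma)
#'
#' The contrast between slow-turnover (RBC, weeks–months) and fast-turnover
#' (plasma, days–weeks) tissues indexes recent habitat (delta13C) and trophic
#' (delta15N) switches. Fish missing either tissue are excluded with a logged
#' count; sign convention is RBC minus plasma.
#'
#' @param records Discrimination-corrected records (columns `fish_id`,
#'   `tissue` and one or more `*_corr` columns).
#' @param value_cols Corrected-value columns to contrast; default: all
#'   `*_corr` columns.
#' @return A tibble with one row per paired fish: `fish_id`,
#'   `<col>_switch` columns, plus any fish-level metadata (`year`,
#'   `fork_length_mm`, `morphotype`, `cluster`) carried through.
#' @export
tissue_switch <- function(records, value_cols = NULL) {
  if (is.null(value_cols)) {
    value_cols <- grep("_corr$", names(records), value = TRUE)
  }
  if (length(value_cols) == 0) {
    abort("No corrected value columns: run apply_discrimination() first.")
  }
  meta_cols <- intersect(
    c("year", "fork_length_mm", "morphotype", "cluster"), names(records)
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(records, "fish_id", "tissue",
                  dplyr::all_of(c(value_cols, meta_cols))),
    names_from = "tissue",
    values_from = dplyr::all_of(value_cols),
    values_fn = mean # fish-level metadata is constant within fish
  )
  rbc_cols <- paste0(value_cols, "_RBC")
  pl_cols <- paste0(value_cols, "_plasma")
  if (length(value_cols) == 1) {
    # pivot_wider drops the value prefix for a single value column
    rbc_cols <- "RBC"
    pl_cols <- "plasma"
  }
  paired <- complete.cases(wide[, c(rbc_cols, pl_cols)])
  n_dropped <- sum(!paired)
  if (n_dropped > 0) {
    inform(paste0(
      n_dropped, " fish missing one tissue excluded from switch metrics (",
      sum(paired), " paired fish retained)."
    ))
  }
  wide <- wide[paired, , drop = FALSE]
  out <- tibble::tibble(fish_id = wide$fish_id)
  for (i in seq_along(value_cols)) {
    nm <- sub("_corr$", "", value_cols[i])
    out[[paste0(nm, "_switch")]] <- wide[[rbc_cols[i]]] - wide[[pl_cols[i]]]
  }
  for (mc in meta_cols) out[[mc]] <- wide[[mc]]
  out
}

#' Compare an isotope metric between two morphotype groups
#'
#' A single two-group Welch t test (no multiplicity correction, `m_tests =
#' 1`); thin wrapper over [posthoc_welch()].
#'
#' @param data Data frame containing the value column.
#' @param assignments Two-level group labels.
#' @param var Name of the value column.
#' @param welch Use Welch's unequal-variance t? Default `TRUE`.
#' @return A one-row tibble as in [posthoc_welch()].
#' @export
compare_groups <- function(data, assignments, var, welch = TRUE) {
  posthoc_welch(data, assignments, vars = var, m_tests = 1, welch = welch)
}
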