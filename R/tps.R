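#' Read a tpsDig-style landmark file
#'
#' Parses the classic TPS dialect: each record starts with `LM=<n>`, followed
#' by n whitespace-separated `x y` coordinate rows, then optional `IMAGE=`,
#' `ID=` and `SCALE=` lines (keys case-insensitive; blank lines ignored). An
#' optional `COMMENT=photo_quality:<r>;landmark_quality:<r1,...,r21>` line
#' carries the quality ranks this package's filter uses — a documented
#' extension of the dialect. Coordinates are stored on file in image
#' convention (y increases downward) and converted to mathematical convention
#' (y up) on load; [write_tps()] reverses the conversion, so round trips are
#' lossless.
#'
#' Records whose landmark count differs from 21 are loaded but flagged
#' `valid = FALSE`; validation never drops data silently.
#'
#' @param path Path to a TPS file.
#' @return A tibble with one row per record: `specimen_id`, `image`, `coords`
#'   (list of n x 2 matrices), `scale` (mm per unit, `NA` if absent),
#'   `scale_applied` (`FALSE` on load), `photo_quality`, `landmark_quality`,
#'   `n_landmarks`, `valid`.
#' @seealso [write_tps()], [apply_scale()], [quality_filter()]
#' @export
read_tps <- function(path) {
  if (!file.exists(path)) abort(paste0("TPS file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    line <- trimws(lines[i])
    if (line == "") {
      i <- i + 1L
      next
    }
    if (!grepl("^lm\\s*=", line, ignore.case = TRUE)) {
      abort(paste0("Line ", i, ": expected an LM= record header, got '", line, "'"))
    }
    n_lm <- suppressWarnings(as.integer(sub("^lm\\s*=\\s*", "", line, ignore.case = TRUE)))
    if (is.na(n_lm) || n_lm < 0) {
      abort(paste0("Line ", i, ": unparseable landmark count in '", line, "'"))
    }
    i <- i + 1L
    xy <- matrix(NA_real_, n_lm, 2, dimnames = list(NULL, c("x", "y")))
    for (k in seq_len(n_lm)) {
      while (i <= n_lines && trimws(lines[i]) == "") i <- i + 1L
      if (i > n_lines || grepl("^[a-zA-Z]", trimws(lines[i]))) {
        abort(paste0(
          "Line ", i, ": record declares LM=", n_lm,
          " but only ", k - 1L, " coordinate rows found."
        ))
      }
      parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2 || anyNA(vals)) {
        abort(paste0("Line ", i, ": malformed coordinate row '", trimws(lines[i]), "'"))
      }
      xy[k, ] <- vals
      i <- i + 1L
    }
    rec <- list(
      specimen_id = NA_character_, image = NA_character_,
      scale = NA_real_, photo_quality = NA_integer_,
      landmark_quality = rep(NA_integer_, n_lm)
    )
    while (i <= n_lines) {
      meta <- trimws(lines[i])
      if (meta == "") {
        i <- i + 1L
        next
      }
      if (grepl("^lm\\s*=", meta, ignore.case = TRUE)) break
      key <- toupper(sub("\\s*=.*$", "", meta))
      val <- sub("^[^=]*=\\s*", "", meta)
      if (key == "IMAGE") {
        rec$image <- val
      } else if (key == "ID") {
        rec$specimen_id <- val
      } else if (key == "SCALE") {
        sc <- suppressWarnings(as.numeric(val))
        if (is.na(sc) || sc <= 0) {
          abort(paste0("Line ", i, ": SCALE must be a positive number, got '", val, "'"))
        }
        rec$scale <- sc
      } else if (key == "COMMENT") {
        pq <- regmatches(val, regexec("photo_quality:([0-9]+)", val))[[1]]
        if (length(pq) == 2) rec$photo_quality <- as.integer(pq[2])
        lq <- regmatches(val, regexec("landmark_quality:([0-9,]+)", val))[[1]]
        if (length(lq) == 2) {
          ranks <- as.integer(strsplit(lq[2], ",")[[1]])
          if (length(ranks) == n_lm) rec$landmark_quality <- ranks
        }
      }
      # unknown keys are ignored (forward compatibility)
      i <- i + 1L
    }
    xy[, 2] <- -xy[, 2] # image convention (y down) -> math convention (y up)
    recs[[length(recs) + 1L]] <- tibble::tibble(
      specimen_id = rec$specimen_id,
      image = rec$image,
      coords = list(xy),
      scale = rec$scale,
      scale_applied = FALSE,
      photo_quality = rec$photo_quality,
      landmark_quality = list(rec$landmark_quality),
      n_landmarks = n_lm,
      valid = n_lm == 21L
    )
  }
  out <- dplyr::bind_rows(recs)
  inform(paste0(
    "Read ", nrow(out), " landmark record(s) from ", basename(path),
    " (", sum(out$valid), " with the expected 21 landmarks)."
  ))
  out
}

#' Write landmark configurations to a TPS file
#'
#' Inverse of [read_tps()]: coordinates are written in image convention
#' (y down), with `IMAGE=`, `ID=`, `SCALE=` and the quality-rank `COMMENT=`
#' extension when present.
#'
#' @param landmarks A tibble with at least `specimen_id` and `coords`
#'   columns (as returned by [read_tps()] or [simulate_landmarks()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(landmarks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(landmarks))) {
    xy <- landmarks$coords[[i]]
    writeLines(paste0("LM=", nrow(xy)), con)
    writeLines(sprintf("%.12g %.12g", xy[, 1], -xy[, 2]), con)
    img <- landmarks$image[i] %||% NA_character_
    if (!is.null(landmarks$image) && !is.na(landmarks$image[i])) {
      writeLines(paste0("IMAGE=", landmarks$image[i]), con)
    }
    writeLines(paste0("ID=", landmarks$specimen_id[i]), con)
    if (!is.null(landmarks$scale) && !is.na(landmarks$scale[i])) {
      writeLines(sprintf("SCALE=%.12g", landmarks$scale[i]), con)
    }
    pq <- if (!is.null(landmarks$photo_quality)) landmarks$photo_quality[i] else NA
    lq <- if (!is.null(landmarks$landmark_quality)) landmarks$landmark_quality[[i]] else NULL
    if (!is.na(pq) || (!is.null(lq) && !anyNA(lq))) {
      parts <- character()
      if (!is.na(pq)) parts <- c(parts, paste0("photo_quality:", pq))
      if (!is.null(lq) && !anyNA(lq)) {
        parts <- c(parts, paste0("landmark_quality:", paste(lq, collapse = ",")))
      }
      writeLines(paste0("COMMENT=", paste(parts, collapse = ";")), con)
    }
  }
  invisible(path)
}

#' Convert landmark coordinates from image units to mm
#'
#' Multiplies every coordinate by the record's `scale` (mm per image unit)
#' and marks the scale as consumed. Applying the scale twice is an error, as
#' is a missing scale — there is no silent pass-through.
#'
#' @param landmarks A landmark tibble with `coords`, `scale` and
#'   `scale_applied` columns.
#' @return The tibble with `coords` in mm, `scale` set to 1 and
#'   `scale_applied = TRUE`.
#' @export
apply_scale <- function(landmarks) {
  if (!all(c("coords", "scale", "scale_applied") %in% names(landmarks))) {
    abort("`landmarks` must have `coords`, `scale` and `scale_applied` columns.")
  }
  if (any(landmarks$scale_applied)) {
    abort("Scale has already been applied to one or more records; refusing to apply twice.")
  }
  if (anyNA(landmarks$scale)) {
    abort(paste0(
      "Missing SCALE for record(s): ",
      paste(landmarks$specimen_id[is.na(landmarks$scale)], collapse = ", ")
    ))
  }
  if (any(landmarks$scale <= 0)) abort("All scales must be positive.")
  landmarks$coords <- purrr::map2(
    landmarks$coords, landmarks$scale,
    function(xy, s) xy * s
  )
  landmarks$scale <- 1
  landmarks$scale_applied <- TRUE
  landmarks
}

#' Filter specimens by photo and landmark quality ranks
#'
#' Ranks run 1 (poor) to 3 (excellent). A specimen is retained when its photo
#' rank and all 21 landmark ranks meet the thresholds. Specimens without
#' ranks pass with a warning (deposited datasets may omit them). The result
#' partitions the input: `retained` plus `excluded` reproduce it exactly.
#'
#' @param landmarks A landmark tibble with optional `photo_quality` and
#'   `landmark_quality` columns.
#' @param min_photo_rank,min_landmark_rank Minimum acceptable ranks
#'   (defaults 2 = average or better).
#' @return A list with `retained` (tibble) and `excluded` (tibble with a
#'   `reason` column naming the failing criterion).
#' @export
quality_filter <- function(landmarks, min_photo_rank = 2, min_landmark_rank = 2) {
  n <- nrow(landmarks)
  pq <- if ("photo_quality" %in% names(landmarks)) landmarks$photo_quality else rep(NA_integer_, n)
  lq <- if ("landmark_quality" %in% names(landmarks)) landmarks$landmark_quality else rep(list(NULL), n)

  reason <- rep(NA_character_, n)
  unranked <- 0L
  for (i in seq_len(n)) {
    has_pq <- !is.na(pq[i])
    ranks <- lq[[i]]
    has_lq <- !is.null(ranks) && !anyNA(ranks)
    if (!has_pq && !has_lq) {
      unranked <- unranked + 1L
      next
    }
    if (has_pq && pq[i] < min_photo_rank) {
      reason[i] <- paste0("photo rank ", pq[i], " < ", min_photo_rank)
      next
    }
    if (has_lq && any(ranks < min_landmark_rank)) {
      bad <- which(ranks < min_landmark_rank)
      reason[i] <- paste0(
        "landmark ", paste(bad, collapse = ","),
        " rank below ", min_landmark_rank
      )
    }
  }
  if (unranked > 0) {
    warn(paste0(unranked, " specimen(s) lack quality ranks and pass unfiltered."))
  }
  keep <- is.na(reason)
  excluded <- landmarks[!keep, , drop = FALSE]
  excluded$reason <- reason[!keep]
  inform(paste0(
    "Quality filter: retained ", sum(keep), " of ", n, " specimen(s)."
  ))
  list(retained = landmarks[keep, , drop = FALSE], excluded = excluded)
}
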