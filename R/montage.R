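#' Load and validate a probe montage and channel atlas
#'
#' A montage file is a TSV with a `record` column separating two blocks:
#' `optode` rows (id, type = source/detector/reference, x/y/z in mm) and
#' `channel` rows (channel index, source id, detector id). The atlas is a TSV
#' with columns `channel`, `hemisphere` (`left`/`right`/`midline`) and `roi`
#' (one of `PreM_SMA`, `FEF`, `BROCA`, `FPA`, `DLPFC`).
#'
#' Validation enforces the acquisition design: exactly 16 sources and 16
#' detectors, 53 channels with unique contiguous indices 1..53, every
#' source-detector separation within `tolerance_mm` of
#' `expected_distance_mm`; the atlas must cover all 53 channels, label
#' exactly channels 25, 28 and 29 as midline, and partition the remaining 50
#' channels into ten non-empty hemisphere-by-region groups.
#'
#' @param montage_file Path to the montage TSV.
#' @param atlas_file Path to the atlas TSV.
#' @param expected_distance_mm Nominal source-detector separation (mm).
#' @param tolerance_mm Allowed deviation from the nominal separation (mm).
#' @return A list with components `montage` (class `fc_montage`: tibbles
#'   `optodes` and `channels`, plus the nominal separation) and `atlas`
#'   (class `fc_atlas`, a tibble).
#' @examples
#' m <- load_montage(
#'   nirsnet_example("synthetic_montage_53ch.tsv"),
#'   nirsnet_example("synthetic_atlas_53ch.tsv")
#' )
#' m$montage
#' table(m$atlas$hemisphere)
#' @export
load_montage <- function(montage_file, atlas_file,
                         expected_distance_mm = 30, tolerance_mm = 1) {
  montage <- read_montage(montage_file, expected_distance_mm, tolerance_mm)
  atlas <- read_atlas(atlas_file)
  list(montage = montage, atlas = atlas)
}

#' @rdname load_montage
#' @export
read_montage <- function(montage_file, expected_distance_mm = 30,
                         tolerance_mm = 1) {
  if (!file.exists(montage_file)) {
    abort(sprintf("montage file not found: %s", montage_file))
  }
  raw <- readr::read_tsv(montage_file, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("record", "id", "type", "x", "y", "z", "source", "detector",
            "channel")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    abort(sprintf("montage file lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  optodes <- raw %>%
    filter(.data$record == "optode") %>%
    select("id", "type", "x", "y", "z")
  channels <- raw %>%
    filter(.data$record == "channel") %>%
    select("channel", "source", "detector") %>%
    mutate(channel = as.integer(.data$channel)) %>%
    arrange(.data$channel)

  n_src <- sum(optodes$type == "source")
  n_det <- sum(optodes$type == "detector")
  if (n_src != 16L) abort(sprintf("montage must have 16 sources, found %d", n_src))
  if (n_det != 16L) abort(sprintf("montage must have 16 detectors, found %d", n_det))
  if (nrow(channels) != 53L) {
    abort(sprintf("montage must define 53 channels, found %d", nrow(channels)))
  }
  if (anyDuplicated(channels$channel)) {
    dup <- channels$channel[duplicated(channels$channel)][1]
    abort(sprintf("duplicate channel index %d in montage", dup))
  }
  if (!identical(sort(channels$channel), 1:53)) {
    abort("channel indices must be contiguous 1..53")
  }
  bad_ref <- setdiff(channels$source, optodes$id[optodes$type == "source"])
  if (length(bad_ref)) {
    abort(sprintf("channel references unknown source '%s'", bad_ref[1]))
  }
  bad_ref <- setdiff(channels$detector, optodes$id[optodes$type == "detector"])
  if (length(bad_ref)) {
    abort(sprintf("channel references unknown detector '%s'", bad_ref[1]))
  }

  xyz <- as.matrix(optodes[, c("x", "y", "z")])
  rownames(xyz) <- optodes$id
  sdd <- sqrt(rowSums((xyz[channels$source, , drop = FALSE] -
                         xyz[channels$detector, , drop = FALSE])^2))
  off <- which(abs(sdd - expected_distance_mm) > tolerance_mm)
  if (length(off)) {
    abort(sprintf(
      "channel %d source-detector distance %.2f mm outside %g +/- %g mm",
      channels$channel[off[1]], sdd[off[1]], expected_distance_mm,
      tolerance_mm))
  }
  channels$distance_mm <- sdd

  structure(
    list(optodes = optodes, channels = channels,
         source_detector_distance = expected_distance_mm),
    class = "fc_montage")
}

#' @rdname load_montage
#' @export
read_atlas <- function(atlas_file) {
  if (!file.exists(atlas_file)) {
    abort(sprintf("atlas file not found: %s", atlas_file))
  }
  atlas <- readr::read_tsv(atlas_file, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("channel", "hemisphere", "roi")
  missing_cols <- setdiff(need, names(atlas))
  if (length(missing_cols)) {
    abort(sprintf("atlas lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  atlas <- atlas %>%
    mutate(channel = as.integer(.data$channel)) %>%
    arrange(.data$channel)
  validate_atlas(atlas)
  structure(as_tibble(atlas), class = c("fc_atlas", class(as_tibble(atlas))))
}

validate_atlas <- function(atlas) {
  if (!identical(sort(atlas$channel), 1:53)) {
    abort("atlas must cover channels 1..53 exactly once")
  }
  bad_h <- setdiff(unique(atlas$hemisphere), c("left", "right", "midline"))
  if (length(bad_h)) {
    abort(sprintf("unknown hemisphere label '%s'", bad_h[1]))
  }
  rois <- c("PreM_SMA", "FEF", "BROCA", "FPA", "DLPFC")
  bad_r <- setdiff(unique(atlas$roi), rois)
  if (length(bad_r)) abort(sprintf("unknown roi label '%s'", bad_r[1]))
  mid <- sort(atlas$channel[atlas$hemisphere == "midline"])
  if (!identical(mid, c(25L, 28L, 29L))) {
    abort(sprintf(
      "midline channels must be exactly 25, 28, 29; found: %s",
      paste(mid, collapse = ", ")))
  }
  groups <- atlas %>%
    filter(.data$hemisphere != "midline") %>%
    dplyr::count(.data$hemisphere, .data$roi)
  if (nrow(groups) != 10L || any(groups$n < 1L)) {
    abort(sprintf(
      "non-midline channels must form 10 non-empty hemisphere x roi groups, found %d",
      nrow(groups)))
  }
  invisible(atlas)
}

#' @export
print.fc_montage <- function(x, ...) {
  cat(sprintf(
    "<fc_montage> %d sources, %d detectors, %d channels (nominal %g mm)\n",
    sum(x$optodes$type == "source"), sum(x$optodes$type == "detector"),
    nrow(x$channels), x$source_detector_distance))
  invisible(x)
}

#' Region labels for the ten hemisphere-by-region groups
#'
#' Returns the atlas rows of the 50 lateral channels together with a compact
#' `region` label (`L_FPA`, `R_DLPFC`, ...) used throughout result tables.
#'
#' @param atlas An `fc_atlas` table.
#' @return A tibble with columns `channel`, `hemisphere`, `roi`, `region`.
#' @export
atlas_regions <- function(atlas) {
  atlas %>%
    filter(.data$hemisphere != "midline") %>%
    mutate(region = paste0(ifelse(.data$hemisphere == "left", "L_", "R_"),
                           .data$roi)) %>%
    as_tibble()
}
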