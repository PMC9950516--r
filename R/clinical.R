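crsr_subscales <- c("auditory", "visual", "motor", "oromotor",
                    "communication", "arousal")
# CRS-R item ceilings per subscale
crsr_max <- c(auditory = 4, visual = 5, motor = 6, oromotor = 3,
              communication = 2, arousal = 3)

#' Parse a clinical table of subject records with CRS-R scores
#'
#' Reads a TSV with columns `id`, `group` (`MCS`/`HC`), `mcs_subtype`,
#' `gender` (`M`/`F`), `age`, `etiology`, `duration_months`, the six Coma
#' Recovery Scale-Revised subscales (`auditory`, `visual`, `motor`,
#' `oromotor`, `communication`, `arousal`) and `crsr_total`.
#'
#' The total is always recomputed as the sum of the six subscales; a stored
#' total that disagrees with the subscale sum is flagged
#' (`total_mismatch = TRUE`, with the stored value kept in
#' `crsr_total_stored`) and the recomputed sum takes precedence. Subscale
#' values outside their defined ranges are an error.
#'
#' @param file Path to the clinical TSV.
#' @return A tibble of subject records (class `fc_clinical`) with the
#'   recomputed `crsr_total`, the stored total, and a `total_mismatch` flag.
#' @examples
#' rec <- parse_crsr_table(nirsnet_example("clinical_mcs.tsv"))
#' rec[rec$total_mismatch, c("id", "crsr_total_stored", "crsr_total")]
#' @export
parse_crsr_table <- function(file) {
  if (!file.exists(file)) abort(sprintf("clinical table not found: %s", file))
  hdr <- strsplit(readLines(file, n = 1L), "\t")[[1]]
  char_cols <- intersect(c("id", "group", "mcs_subtype", "gender",
                           "etiology"), hdr)
  spec <- stats::setNames(
    as.list(rep("c", length(char_cols))), char_cols)
  tab <- readr::read_tsv(file, show_col_types = FALSE, progress = FALSE,
                         col_types = do.call(readr::cols,
                                             c(spec, .default = "d")))
  need <- c("id", "group", "gender", "age", "duration_months",
            crsr_subscales, "crsr_total")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("clinical table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  validate_clinical(tab)

  sums <- rowSums(tab[, crsr_subscales])
  tab <- tab %>%
    mutate(crsr_total_stored = as.integer(.data$crsr_total),
           crsr_total = as.integer(sums),
           total_mismatch = !is.na(sums) &
             !is.na(.data$crsr_total_stored) &
             .data$crsr_total_stored != .data$crsr_total)
  mism <- which(tab$total_mismatch)
  if (length(mism)) {
    inform(sprintf(
      "CRS-R total mismatch for %s: stored %s, subscale sum %s (sum kept)",
      paste(tab$id[mism], collapse = ", "),
      paste(tab$crsr_total_stored[mism], collapse = ", "),
      paste(tab$crsr_total[mism], collapse = ", ")))
  }
  structure(tab, class = c("fc_clinical", class(tab)))
}

validate_clinical <- function(tab) {
  bad_g <- setdiff(unique(tab$group), c("MCS", "HC"))
  if (length(bad_g)) abort(sprintf("unknown group label '%s'", bad_g[1]))
  bad_sex <- setdiff(unique(tab$gender), c("M", "F"))
  if (length(bad_sex)) abort(sprintf("unknown gender label '%s'", bad_sex[1]))
  for (s in crsr_subscales) {
    v <- tab[[s]]
    miss <- which(is.na(v) & tab$group == "MCS")
    if (length(miss)) {
      abort(sprintf("missing value in subscale '%s' for patient row %d",
                    s, miss[1]))
    }
    bad <- which(!is.na(v) & (v < 0 | v > crsr_max[[s]] | v != round(v)))
    if (length(bad)) {
      abort(sprintf(
        "row %d ('%s'): subscale '%s' value %s outside 0..%d",
        bad[1], tab$id[bad[1]], s, v[bad[1]], crsr_max[[s]]))
    }
  }
  invisible(tab)
}

#' Serialize subject records back to the clinical TSV schema
#'
#' Writes the records field-for-field in the schema read by
#' [parse_crsr_table()]; the stored total column is restored so a parse /
#' serialize round trip reproduces the source file (flags aside).
#'
#' @param records An `fc_clinical` tibble.
#' @param file Output path.
#' @export
write_crsr_table <- function(records, file) {
  out <- as_tibble(records)
  if ("crsr_total_stored" %in% names(out)) {
    out$crsr_total <- out$crsr_total_stored
    out$crsr_total_stored <- NULL
    out$total_mismatch <- NULL
  }
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Per-group demographic and clinical summary
#'
#' Group-wise counts, gender split, and mean/SD (sample SD, n - 1
#' denominator) of age, illness duration and recomputed CRS-R total.
#'
#' @param records A tibble of subject records (see [parse_crsr_table()]).
#' @return A tibble with one row per group: `n`, `n_male`, `n_female`, and
#'   mean/SD columns for age, duration and CRS-R total.
#' @examples
#' rec <- parse_crsr_table(nirsnet_example("clinical_mcs.tsv"))
#' demographics_summary(rec)
#' @export
demographics_summary <- function(records) {
  if (nrow(records) == 0) abort("no records")
  counts <- records %>% dplyr::count(.data$group)
  if (any(counts$n < 2)) {
    abort(sprintf("group '%s' has fewer than 2 records",
                  counts$group[counts$n < 2][1]))
  }
  records %>%
    group_by(.data$group) %>%
    summarise(
      n = dplyr::n(),
      n_male = sum(.data$gender == "M"),
      n_female = sum(.data$gender == "F"),
      age_mean = mean(.data$age),
      age_sd = sd(.data$age),
      duration_mean = mean(.data$duration_months),
      duration_sd = sd(.data$duration_months),
      crsr_mean = mean(.data$crsr_total),
      crsr_sd = sd(.data$crsr_total),
      .groups = "drop")
}
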