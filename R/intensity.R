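#' Construct a raw dual-wavelength intensity recording
#'
#' Container for one subject's continuous-wave recording: a
#' `channels x wavelengths x samples` array of strictly positive light
#' intensities at 690 and 830 nm.
#'
#' @param data Numeric array, `n_channels x 2 x n_samples`.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject Subject identifier.
#' @param wavelengths Wavelengths in nm (default `c(690, 830)`).
#' @return An object of class `fc_raw`.
#' @export
raw_intensity <- function(data, sampling_rate = 20, subject = "subject",
                          wavelengths = c(690, 830)) {
  if (length(dim(data)) != 3L || dim(data)[2] != length(wavelengths)) {
    abort("data must be a channels x wavelengths x samples array")
  }
  if (anyNA(data)) abort("intensity data contains NA")
  if (any(data <= 0)) abort("intensities must be strictly positive")
  if (sampling_rate <= 0) abort("sampling_rate must be positive")
  structure(
    list(subject = subject, data = data, wavelengths = wavelengths,
         sampling_rate = sampling_rate,
         duration = dim(data)[3] / sampling_rate),
    class = "fc_raw")
}

#' @export
print.fc_raw <- function(x, ...) {
  cat(sprintf(
    "<fc_raw> subject '%s': %d channels x %d wavelengths x %d samples (%g Hz, %.1f s)\n",
    x$subject, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
    x$sampling_rate, x$duration))
  invisible(x)
}

#' Read or write a raw recording in the columnar CSV dialect
#'
#' The CSV dialect stores one row per sample and one column per
#' (channel, wavelength) pair, named `ch<index>_<wavelength>` (e.g.
#' `ch01_690`); the header is mandatory, and a leading comment line
#' `# nirsnet-intensity subject=<id> sampling_rate=<Hz>` carries the
#' metadata. `load_intensity()` is the dialect-dispatching entry point;
#' SNIRF containers are recognized but not supported in this build (no HDF5
#' reader among the package's dependencies), and requesting them raises an
#' error.
#'
#' @param file Path to the recording.
#' @param dialect Input dialect, `"csv"` (the columnar dialect above).
#' @param sampling_rate Fallback sampling rate used if the file carries no
#'   metadata line.
#' @return An `fc_raw` object.
#' @examples
#' raw <- raw_intensity(array(1 + runif(53 * 2 * 40), c(53, 2, 40)))
#' f <- tempfile(fileext = ".csv")
#' write_intensity(raw, f)
#' identical(dim(load_intensity(f)$data), dim(raw$data))
#' @export
load_intensity <- function(file, dialect = c("csv", "snirf"),
                           sampling_rate = 20) {
  dialect <- match.arg(dialect)
  if (dialect == "snirf") {
    abort(paste0(
      "SNIRF input is not supported by this build (no HDF5 reader ",
      "available); export the recording to the columnar CSV dialect"))
  }
  read_intensity_csv(file, sampling_rate = sampling_rate)
}

#' @rdname load_intensity
#' @export
read_intensity_csv <- function(file, sampling_rate = 20) {
  if (!file.exists(file)) abort(sprintf("recording not found: %s", file))
  first <- readLines(file, n = 1L)
  subject <- "subject"
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("subject=([^ ]+)", first))[[1]]
    if (length(m) == 2) subject <- m[2]
    m <- regmatches(first, regexec("sampling_rate=([0-9.]+)", first))[[1]]
    if (length(m) == 2) sampling_rate <- as.numeric(m[2])
  }
  tab <- readr::read_csv(file, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  cn <- names(tab)
  parsed <- regmatches(cn, regexec("^ch([0-9]+)_([0-9]+)$", cn))
  ok <- lengths(parsed) == 3
  if (!all(ok)) {
    abort(sprintf("unrecognized column name '%s' (expect ch<idx>_<nm>)",
                  cn[!ok][1]))
  }
  ch <- as.integer(vapply(parsed, `[`, "", 2))
  wl <- as.integer(vapply(parsed, `[`, "", 3))
  channels <- sort(unique(ch))
  wavelengths <- sort(unique(wl))
  if (!identical(channels, seq_along(channels))) {
    abort("channel indices in header must be contiguous from 1")
  }
  n <- nrow(tab)
  data <- array(NA_real_, c(length(channels), length(wavelengths), n))
  for (j in seq_along(cn)) {
    data[ch[j], match(wl[j], wavelengths), ] <- tab[[j]]
  }
  if (anyNA(data)) abort("recording has missing (channel, wavelength) traces or NA samples")
  if (any(data <= 0)) abort("recording contains non-positive intensities")
  raw_intensity(data, sampling_rate = sampling_rate, subject = subject,
                wavelengths = wavelengths)
}

#' @rdname load_intensity
#' @param raw An `fc_raw` object to write.
#' @export
write_intensity <- function(raw, file) {
  stopifnot(inherits(raw, "fc_raw"))
  nch <- dim(raw$data)[1]
  cols <- list()
  for (i in seq_len(nch)) {
    for (w in seq_along(raw$wavelengths)) {
      cols[[sprintf("ch%02d_%d", i, raw$wavelengths[w])]] <- raw$data[i, w, ]
    }
  }
  tab <- as_tibble(cols)
  writeLines(sprintf("# nirsnet-intensity subject=%s sampling_rate=%g",
                     raw$subject, raw$sampling_rate), file)
  readr::write_csv(tab, file, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(file)
}
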