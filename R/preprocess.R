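#' Convert raw intensities to optical density changes
#'
#' Per channel and wavelength, `OD(t) = -ln(I(t) / mean(I))`, i.e. optical
#' density change relative to the trace's own temporal mean. A constant
#' trace maps to identically zero OD.
#'
#' @param raw An `fc_raw` recording.
#' @return An object of class `fc_od` with the same array shape.
#' @export
intensity_to_od <- function(raw) {
  stopifnot(inherits(raw, "fc_raw"))
  if (any(raw$data <= 0)) abort("intensities must be strictly positive")
  od <- raw$data
  d <- dim(od)
  for (i in seq_len(d[1])) {
    for (w in seq_len(d[2])) {
      tr <- od[i, w, ]
      od[i, w, ] <- -log(tr / mean(tr))
    }
  }
  structure(
    list(subject = raw$subject, data = od, wavelengths = raw$wavelengths,
         sampling_rate = raw$sampling_rate),
    class = "fc_od")
}

#' @export
print.fc_od <- function(x, ...) {
  cat(sprintf("<fc_od> subject '%s': %d x %d x %d at %g Hz\n", x$subject,
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate))
  invisible(x)
}

#' Trim the first and last seconds of a recording
#'
#' Removes `seconds` from each end of the record (default 60 s), discarding
#' settling and removal transients. `seconds = 0` is the identity.
#'
#' @param series An `fc_raw`, `fc_od` or `fc_hemo` object.
#' @param seconds Seconds to drop from each end.
#' @return The same class of object with the reduced duration.
#' @export
trim_edges <- function(series, seconds = 60) {
  n <- dim(series$data)[3]
  fs <- series$sampling_rate
  k <- round(seconds * fs)
  if (n <= 2 * k) {
    abort(sprintf("record too short to trim: %d samples, need > %d",
                  n, 2 * k))
  }
  if (k > 0) {
    series$data <- series$data[, , (k + 1):(n - k), drop = FALSE]
  }
  if (!is.null(series$duration)) series$duration <- dim(series$data)[3] / fs
  series
}

#' Detect motion artifacts by moving-window statistics
#'
#' Flags, per channel, every sample interval where the moving-window
#' standard deviation exceeds `sd_mult` times the channel's median
#' moving-window SD, or where the window's peak-to-peak amplitude exceeds
#' `amp_thresh` (optical density units). Flagged windows are merged and
#' extended by `margin_s` on each side. Detection runs on the wavelength
#' with the larger overall variance per channel and the mask is shared by
#' both wavelengths (head movement affects both).
#'
#' @param od An `fc_od` series.
#' @param window_s Moving window length in seconds.
#' @param sd_mult Multiplier on the channel's median moving-window SD.
#' @param amp_thresh Peak-to-peak threshold in OD units.
#' @param margin_s Margin added to each flagged interval, in seconds.
#' @return An `fc_mask`: a list with per-channel interval matrices
#'   (`start`, `end` sample indices, non-overlapping) plus the mask
#'   parameters.
#' @export
detect_motion <- function(od, window_s = 1, sd_mult = 13.5,
                          amp_thresh = 0.4, margin_s = 0.5) {
  stopifnot(inherits(od, "fc_od"))
  if (window_s <= 0 || sd_mult <= 0 || amp_thresh <= 0) {
    abort("thresholds must be positive")
  }
  fs <- od$sampling_rate
  n <- dim(od$data)[3]
  w <- max(2L, round(window_s * fs))
  if (w > n) abort("window longer than record")
  margin <- round(margin_s * fs)
  nch <- dim(od$data)[1]

  intervals <- vector("list", nch)
  for (i in seq_len(nch)) {
    v1 <- var(od$data[i, 1, ]); v2 <- var(od$data[i, 2, ])
    x <- od$data[i, if (v2 > v1) 2 else 1, ]
    st <- roll_stats(x, w)
    med_sd <- median(st$sd)
    bad <- (med_sd > 0 & st$sd > sd_mult * med_sd) | (st$p2p > amp_thresh)
    if (!any(bad)) { intervals[[i]] <- matrix(integer(), 0, 2); next }
    # a bad window starting at t covers samples t..t+w-1
    flag <- logical(n)
    idx <- which(bad)
    for (t in idx) flag[t:min(n, t + w - 1L)] <- TRUE
    if (margin > 0) {
      runs <- rle_runs(flag)
      for (r in seq_len(nrow(runs))) {
        flag[max(1L, runs[r, 1] - margin):min(n, runs[r, 2] + margin)] <- TRUE
      }
    }
    intervals[[i]] <- rle_runs(flag)
  }
  structure(
    list(intervals = intervals, n_samples = n, sampling_rate = fs,
         window_s = window_s, sd_mult = sd_mult, amp_thresh = amp_thresh,
         margin_s = margin_s),
    class = "fc_mask")
}

# moving-window SD and peak-to-peak over windows of length w
# (returns one value per window start 1..n-w+1)
roll_stats <- function(x, w) {
  n <- length(x)
  cs <- cumsum(c(0, x)); cs2 <- cumsum(c(0, x^2))
  k <- n - w + 1L
  s <- cs[(w + 1):(n + 1)] - cs[1:k]
  s2 <- cs2[(w + 1):(n + 1)] - cs2[1:k]
  v <- pmax(0, (s2 - s^2 / w) / (w - 1))
  emb <- matrix(NA_real_, k, w)
  for (j in seq_len(w)) emb[, j] <- x[(j):(j + k - 1L)]
  list(sd = sqrt(v),
       p2p = apply(emb, 1, max) - apply(emb, 1, min))
}

rle_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Fraction of samples flagged, per channel
#'
#' @param mask An `fc_mask` from [detect_motion()].
#' @return Numeric vector, one fraction per channel.
#' @export
mask_fraction <- function(mask) {
  vapply(mask$intervals, function(iv) {
    if (nrow(iv) == 0) 0 else sum(iv[, 2] - iv[, 1] + 1L) / mask$n_samples
  }, numeric(1))
}

#' Correct flagged motion intervals with a smoothing spline
#'
#' Within each flagged interval, a smoothing spline fitted to the segment is
#' subtracted and the segment is re-levelled to the mean of the preceding
#' second of clean (already corrected) signal, so step discontinuities are
#' removed while unflagged samples are left untouched. Intervals too short
#' for a spline fall back to a linear fit; when there is no preceding clean
#' signal the following clean second is used as the level reference.
#'
#' @param od An `fc_od` series.
#' @param mask An `fc_mask` from [detect_motion()].
#' @param spar Smoothing parameter passed to [stats::smooth.spline()];
#'   the default (0, with knots at every sample) is near-interpolating, so
#'   the fit tracks the artifact closely and subtracting it removes nearly
#'   all within-interval excursion before re-levelling.
#' @return The corrected `fc_od` series.
#' @export
spline_correct <- function(od, mask, spar = 0) {
  stopifnot(inherits(od, "fc_od"), inherits(mask, "fc_mask"))
  if (mask$n_samples != dim(od$data)[3]) {
    abort("mask does not match the series length")
  }
  fs <- od$sampling_rate
  ref <- max(1L, round(fs))  # 1 s of level reference
  for (i in seq_along(mask$intervals)) {
    iv <- mask$intervals[[i]]
    if (nrow(iv) == 0) next
    for (w in seq_len(dim(od$data)[2])) {
      x <- od$data[i, w, ]
      for (r in seq_len(nrow(iv))) {
        a <- iv[r, 1]; b <- iv[r, 2]
        seg <- x[a:b]
        m <- length(seg)
        fit <- if (m >= 8) {
          tryCatch(predict(smooth.spline(seq_len(m), seg, spar = spar,
                                         all.knots = TRUE),
                           seq_len(m))$y,
                   error = function(e) fit_linear(seg))
        } else {
          fit_linear(seg)
        }
        resid <- seg - fit
        level <- if (a > 1) {
          mean(x[max(1L, a - ref):(a - 1L)])
        } else if (b < length(x)) {
          mean(x[(b + 1L):min(length(x), b + ref)])
        } else 0
        x[a:b] <- resid + level
      }
      od$data[i, w, ] <- x
    }
  }
  od
}

fit_linear <- function(seg) {
  t <- seq_along(seg)
  unname(cbind(1, t) %*% coef(lm.fit(cbind(1, t), seg)))[, 1]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 3rd-order Butterworth band-pass (default 0.01-0.1 Hz, the
#' low-frequency hemodynamic band) with zero phase. The filter is realized
#' as a symmetrized forward-backward pass on an odd-reflection-padded
#' signal: the average of the forward-backward output and the time-reversed
#' forward-backward output of the time-reversed signal. This keeps the
#' squared Butterworth magnitude response and is exactly time-reversal
#' symmetric, so filtering a reversed trace and reversing the result equals
#' filtering the trace directly.
#'
#' @param od An `fc_od` or `fc_hemo` series, or a numeric vector.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order of the band-pass prototype.
#' @param sampling_rate Required when `od` is a bare numeric vector.
#' @return The filtered object (same class as the input).
#' @export
bandpass <- function(od, low = 0.01, high = 0.1, order = 3,
                     sampling_rate = NULL) {
  if (is.numeric(od) && is.null(dim(od))) {
    if (is.null(sampling_rate)) abort("sampling_rate required for vectors")
    return(bandpass_vec(od, low, high, order, sampling_rate))
  }
  fs <- od$sampling_rate
  if (high >= fs / 2) abort("high edge must be below the Nyquist frequency")
  if (low <= 0 || low >= high) abort("invalid band edges")
  d <- dim(od$data)
  for (i in seq_len(d[1])) {
    for (w in seq_len(d[2])) {
      od$data[i, w, ] <- bandpass_vec(od$data[i, w, ], low, high, order, fs)
    }
  }
  od
}

bandpass_vec <- function(x, low, high, order, fs) {
  if (high >= fs / 2) abort("high edge must be below the Nyquist frequency")
  if (low <= 0 || low >= high) abort("invalid band edges")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- length(x)
  np <- min(n - 1L, as.integer(ceiling(3 * fs / low)))
  fb <- function(v) {
    vp <- pad_reflect(v, np)
    y <- signal::filtfilt(bf, vp)
    y[(np + 1):(np + length(v))]
  }
  (fb(x) + rev(fb(rev(x)))) / 2
}

# odd (point-symmetric) reflection padding at both ends
pad_reflect <- function(x, np) {
  n <- length(x)
  if (np == 0) return(x)
  left <- 2 * x[1] - x[(np + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - np)]
  c(left, x, right)
}

#' Coefficients of the modified Beer-Lambert law
#'
#' Bundles the extinction coefficients, differential pathlength factors and
#' source-detector separation used to convert optical density changes to
#' chromophore concentration changes. Defaults use a standard published
#' compilation of hemoglobin extinction spectra at 690/830 nm (in
#' 1/(mM cm)), DPF 6.0 at both wavelengths and a 3 cm separation; all are
#' overridable.
#'
#' @param extinction 2 x 2 matrix, rows = wavelengths (690, 830 nm),
#'   columns = chromophores (HbO, HbR), units 1/(mM cm).
#' @param dpf Differential pathlength factor per wavelength.
#' @param distance_cm Source-detector separation in cm.
#' @return An object of class `fc_mbll`.
#' @export
mbll_coefficients <- function(
    extinction = matrix(c(0.2764, 2.0520, 0.9740, 0.6930), 2, 2,
                        byrow = TRUE,
                        dimnames = list(c("690", "830"), c("HbO", "HbR"))),
    dpf = c(6, 6), distance_cm = 3) {
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2))) {
    abort("extinction must be a 2 x 2 matrix (wavelength x chromophore)")
  }
  if (abs(det(extinction)) < 1e-10) {
    abort("extinction matrix is singular; chromophores are not separable")
  }
  if (any(dpf <= 0) || distance_cm <= 0) {
    abort("dpf and distance must be positive")
  }
  structure(list(extinction = extinction, dpf = dpf,
                 distance_cm = distance_cm),
            class = "fc_mbll")
}

mbll_system_matrix <- function(coeffs) {
  # OD(lambda) = sum_c extinction[lambda, c] * conc_mM[c] * d * dpf(lambda)
  coeffs$extinction * (coeffs$distance_cm * coeffs$dpf)
}

#' Convert optical density to hemoglobin concentration changes
#'
#' Solves, per channel and sample, the 2 x 2 modified Beer-Lambert system
#' `OD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) d DPF(lambda)`
#' for the oxy- and deoxyhemoglobin concentration changes (returned in
#' micromolar).
#'
#' @param od An `fc_od` series (wavelengths 690, 830 nm).
#' @param coeffs An `fc_mbll` coefficient set.
#' @return An `fc_hemo` object: `channels x {HbO, HbR} x samples` in uM.
#' @export
od_to_hemoglobin <- function(od, coeffs = mbll_coefficients()) {
  stopifnot(inherits(od, "fc_od"), inherits(coeffs, "fc_mbll"))
  A <- mbll_system_matrix(coeffs)
  Ainv <- solve(A)
  d <- dim(od$data)
  hemo <- array(NA_real_, c(d[1], 2, d[3]),
                dimnames = list(NULL, c("HbO", "HbR"), NULL))
  for (i in seq_len(d[1])) {
    conc <- Ainv %*% od$data[i, , ]  # mM
    hemo[i, , ] <- conc * 1000       # uM
  }
  structure(
    list(subject = od$subject, data = hemo, chromophores = c("HbO", "HbR"),
         sampling_rate = od$sampling_rate),
    class = "fc_hemo")
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes (uM) to optical density changes at
#' the two wavelengths; the exact inverse of [od_to_hemoglobin()].
#'
#' @param hemo An `fc_hemo` object.
#' @param coeffs An `fc_mbll` coefficient set.
#' @return An `fc_od` object.
#' @export
hemoglobin_to_od <- function(hemo, coeffs = mbll_coefficients()) {
  stopifnot(inherits(hemo, "fc_hemo"), inherits(coeffs, "fc_mbll"))
  A <- mbll_system_matrix(coeffs)
  d <- dim(hemo$data)
  od <- array(NA_real_, c(d[1], 2, d[3]))
  for (i in seq_len(d[1])) {
    od[i, , ] <- A %*% (hemo$data[i, , ] / 1000)
  }
  structure(
    list(subject = hemo$subject, data = od, wavelengths = c(690, 830),
         sampling_rate = hemo$sampling_rate),
    class = "fc_od")
}

#' @export
print.fc_hemo <- function(x, ...) {
  cat(sprintf("<fc_hemo> subject '%s': %d channels x {HbO, HbR} x %d at %g Hz\n",
              x$subject, dim(x$data)[1], dim(x$data)[3], x$sampling_rate))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Collects every tunable preprocessing parameter: trim length, motion
#' detection thresholds, spline smoothing, band edges and filter order,
#' modified Beer-Lambert constants, and the subject-level exclusion rule
#' (exclude when more than `exclude_sample_frac` of samples are flagged on
#' more than `exclude_channel_frac` of channels).
#'
#' @param trim_s Seconds trimmed from each end.
#' @param window_s,sd_mult,amp_thresh,margin_s Motion detection parameters
#'   (see [detect_motion()]).
#' @param spar Spline smoothing parameter (see [spline_correct()]).
#' @param low,high,order Band-pass parameters (see [bandpass()]).
#' @param mbll An `fc_mbll` coefficient set.
#' @param exclude_sample_frac,exclude_channel_frac Exclusion rule fractions.
#' @return A list of class `fc_preproc_config`.
#' @export
preprocess_config <- function(trim_s = 60, window_s = 1, sd_mult = 13.5,
                              amp_thresh = 0.4, margin_s = 0.5, spar = 0,
                              low = 0.01, high = 0.1, order = 3,
                              mbll = mbll_coefficients(),
                              exclude_sample_frac = 0.2,
                              exclude_channel_frac = 0.3) {
  structure(as.list(environment()), class = "fc_preproc_config")
}

#' Run the full preprocessing chain on one subject
#'
#' Composition, in order: intensity to optical density, edge trimming,
#' motion detection and spline correction, zero-phase band-pass, modified
#' Beer-Lambert conversion. Only the HbO traces are carried into the
#' downstream network analysis (better signal-to-noise than HbR); both
#' chromophores are returned. Subjects whose motion mask exceeds the
#' configured exclusion rule are marked excluded with reason
#' `"head movement"`.
#'
#' @param raw An `fc_raw` recording.
#' @param config An `fc_preproc_config`.
#' @return A list of class `fc_preproc`: `hemo` (an `fc_hemo`, or `NULL` if
#'   excluded), `mask`, `excluded`, `exclusion_reason`, and a per-stage
#'   `log` (character).
#' @examples
#' cfg <- synth_config(n_hc = 2, n_mcs = 2, duration_s = 150, seed = 1)
#' cohort <- generate_cohort(cfg)
#' pp <- run_preprocess(cohort$raw[[1]], preprocess_config())
#' pp$hemo
#' @export
run_preprocess <- function(raw, config = preprocess_config()) {
  stopifnot(inherits(raw, "fc_raw"), inherits(config, "fc_preproc_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  od <- intensity_to_od(raw)
  note("od: converted %d x %d x %d", dim(od$data)[1], dim(od$data)[2],
       dim(od$data)[3])
  od <- trim_edges(od, config$trim_s)
  note("trim: %g s each end -> %d samples", config$trim_s, dim(od$data)[3])
  mask <- detect_motion(od, config$window_s, config$sd_mult,
                        config$amp_thresh, config$margin_s)
  frac <- mask_fraction(mask)
  note("motion: %d channel(s) flagged, max masked fraction %.3f",
       sum(frac > 0), max(frac))

  if (mean(frac > config$exclude_sample_frac) > config$exclude_channel_frac) {
    note("exclude: >%d%% of samples masked on >%d%% of channels",
         round(100 * config$exclude_sample_frac),
         round(100 * config$exclude_channel_frac))
    return(structure(
      list(subject = raw$subject, hemo = NULL, mask = mask, excluded = TRUE,
           exclusion_reason = "head movement", log = log),
      class = "fc_preproc"))
  }

  od <- spline_correct(od, mask, config$spar)
  note("spline: corrected %d interval(s)",
       sum(vapply(mask$intervals, nrow, integer(1))))
  od <- bandpass(od, config$low, config$high, config$order)
  note("bandpass: %g-%g Hz order %d", config$low, config$high, config$order)
  hemo <- od_to_hemoglobin(od, config$mbll)
  note("mbll: converted to HbO/HbR (uM); HbO used downstream")

  structure(
    list(subject = raw$subject, hemo = hemo, mask = mask, excluded = FALSE,
         exclusion_reason = NA_character_, log = log),
    class = "fc_preproc")
}

#' Extract the HbO channel-by-time matrix
#'
#' @param hemo An `fc_hemo` object.
#' @return A numeric matrix, channels x samples.
#' @export
hbo_matrix <- function(hemo) {
  stopifnot(inherits(hemo, "fc_hemo"))
  hemo$data[, "HbO", ]
}
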