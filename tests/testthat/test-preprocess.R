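make_od <- function(mat, fs = 20) {
  # channels x samples -> fc_od with both wavelengths carrying `mat`
  arr <- array(NA_real_, c(nrow(mat), 2, ncol(mat)))
  arr[, 1, ] <- mat
  arr[, 2, ] <- mat
  structure(list(subject = "t", data = arr, wavelengths = c(690, 830),
                 sampling_rate = fs), class = "fc_od")
}

test_that("optical density conversion follows -ln(I/mean)", {
  # constant trace -> identically zero
  arr <- array(2.5, c(2, 2, 100))
  od <- intensity_to_od(raw_intensity(arr))
  expect_equal(max(abs(od$data)), 0)

  # one sample at twice the trace mean -> OD = -ln 2 there
  n <- 100
  b <- 2 * (n - 1) / (n - 2)
  x <- c(rep(1, n - 1), b)
  arr <- array(rep(x, each = 4), c(2, 2, n))
  arr[1, 1, ] <- x
  od <- intensity_to_od(raw_intensity(arr))
  expect_equal(od$data[1, 1, n], -log(2), tolerance = 1e-12)

  # Jensen: the OD trace mean is a small non-negative residual
  raw <- toy_raw(nch = 3, n = 2000)
  od <- intensity_to_od(raw)
  m <- apply(od$data, c(1, 2), mean)
  expect_true(all(m >= 0))
  expect_true(all(m < 1e-3))
})

test_that("edge trimming arithmetic and guards", {
  raw <- toy_raw(nch = 2, n = 6000, fs = 20)
  expect_equal(dim(trim_edges(raw, 60)$data)[3], 3600)  # (300-120)*20
  expect_error(trim_edges(toy_raw(n = 2000), 60), "too short")  # 100 s record
  expect_equal(trim_edges(raw, 0)$data, raw$data)
})

test_that("motion detection flags injected steps and nothing else", {
  fs <- 20
  tt <- (0:3999) / fs
  clean <- sin(2 * pi * 0.05 * tt) * 0.05
  od <- make_od(rbind(clean, clean), fs)
  expect_equal(sum(vapply(detect_motion(od)$intervals, nrow, integer(1))), 0)

  spiky <- clean
  spiky[2000:4000] <- spiky[2000:4000] + 10 * sd(clean)
  od2 <- make_od(rbind(spiky, clean), fs)
  mask <- detect_motion(od2)
  expect_equal(nrow(mask$intervals[[1]]), 1)
  iv <- mask$intervals[[1]]
  expect_true(iv[1, 1] <= 2000 && iv[1, 2] >= 2000)  # covers the step onset
  expect_equal(nrow(mask$intervals[[2]]), 0)

  # unreachable thresholds -> empty mask
  mask3 <- detect_motion(od2, sd_mult = Inf, amp_thresh = Inf)
  expect_equal(sum(vapply(mask3$intervals, nrow, integer(1))), 0)
  expect_error(detect_motion(od, window_s = 500), "window")
})

manual_mask <- function(intervals_by_channel, n, fs = 20) {
  structure(list(
    intervals = intervals_by_channel, n_samples = as.integer(n),
    sampling_rate = fs, window_s = 1, sd_mult = 13.5, amp_thresh = 0.4,
    margin_s = 0.5), class = "fc_mask")
}

test_that("spline correction removes step artifacts and keeps clean samples", {
  fs <- 20
  tt <- (0:3999) / fs
  clean <- sin(2 * pi * 0.05 * tt) * 0.05
  spiky <- clean
  spiky[2000:4000] <- spiky[2000:4000] + 0.8  # step artifact at t = 100 s
  od <- make_od(rbind(spiky, clean), fs)

  mask0 <- detect_motion(od, sd_mult = Inf, amp_thresh = Inf)
  expect_equal(spline_correct(od, mask0)$data, od$data)  # empty mask: identity

  iv <- cbind(start = 1980L, end = 2060L)
  mask <- manual_mask(list(iv, matrix(integer(), 0, 2)), 4000, fs)
  fixed <- spline_correct(od, mask)
  seg_before <- od$data[1, 1, 1980:2060]
  seg_after <- fixed$data[1, 1, 1980:2060]
  # peak-to-peak of the flagged interval drops by >= 80%
  expect_lt(diff(range(seg_after)), 0.2 * diff(range(seg_before)))
  # the interval is re-levelled to the preceding clean mean
  expect_lt(abs(mean(seg_after) - mean(od$data[1, 1, 1960:1979])), 0.1)
  outside <- setdiff(seq_along(spiky), 1980:2060)
  expect_equal(fixed$data[1, 1, outside], od$data[1, 1, outside])
  expect_equal(fixed$data[2, 1, ], od$data[2, 1, ])  # untouched channel

  # full-record masks: adjacent segments stay mean-level continuous
  x <- clean
  x[1300:2600] <- x[1300:2600] + 1
  odx <- make_od(matrix(x, 1), fs)
  allmask <- manual_mask(list(cbind(start = c(1L, 1501L, 3001L),
                                    end = c(1500L, 3000L, 4000L))),
                         4000, fs)
  fx <- spline_correct(odx, allmask)
  y <- fx$data[1, 1, ]
  for (a in c(1501L, 3001L)) {
    expect_lt(abs(y[a] - y[a - 1L]), 0.4)  # no jump above amp_thresh
  }
})

test_that("band-pass passes the hemodynamic band and rejects physiology", {
  fs <- 20
  tt <- (0:5999) / fs
  gain_at <- function(f) {
    y <- bandpass(sin(2 * pi * f * tt), sampling_rate = fs)
    mid <- y[1500:4500]
    max(abs(mid))
  }
  expect_gt(gain_at(0.05), 10^(-3 / 20))   # within 3 dB
  expect_lt(gain_at(0.40), 10^(-20 / 20))  # respiration: >= 20 dB down
  expect_lt(gain_at(1.20), 10^(-20 / 20))  # cardiac: >= 20 dB down
  expect_error(bandpass(tt, low = 0.01, high = 11, sampling_rate = fs),
               "Nyquist")
})

test_that("the filter is exactly zero-phase (time-reversal symmetric)", {
  withr::with_seed(3, x <- cumsum(rnorm(4000)))
  a <- bandpass(x, sampling_rate = 20)
  b <- rev(bandpass(rev(x), sampling_rate = 20))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("modified Beer-Lambert inversion is exact", {
  coeffs <- mbll_coefficients()
  # zero OD -> zero concentrations
  od0 <- make_od(matrix(0, 2, 50))
  h0 <- od_to_hemoglobin(od0, coeffs)
  expect_equal(max(abs(h0$data)), 0)

  # forward-synthesized OD recovers the known concentrations to 1e-9
  withr::with_seed(4, {
    hemo <- array(rnorm(3 * 2 * 200, sd = 0.5), c(3, 2, 200),
                  dimnames = list(NULL, c("HbO", "HbR"), NULL))
  })
  hob <- structure(list(subject = "t", data = hemo,
                        chromophores = c("HbO", "HbR"), sampling_rate = 20),
                   class = "fc_hemo")
  back <- od_to_hemoglobin(hemoglobin_to_od(hob, coeffs), coeffs)
  expect_equal(back$data, hemo, tolerance = 1e-9)

  # proportional extinction rows are rejected
  expect_error(mbll_coefficients(extinction = matrix(c(1, 2, 2, 4), 2, 2)),
               "singular")
})

test_that("the preprocessing chain yields the documented shape and is deterministic", {
  cfg <- synth_config(n_hc = 2, n_mcs = 2, duration_s = 300, seed = 21,
                      spike_rate_per_min = 0)
  truth <- build_truth(cfg)
  raw <- simulate_subject(attr(truth$hc, "full"), cfg, seed = 9)
  pp1 <- run_preprocess(raw)
  expect_false(pp1$excluded)
  expect_equal(dim(pp1$hemo$data), c(53, 2, 3600))
  expect_equal(dimnames(pp1$hemo$data)[[2]], c("HbO", "HbR"))
  pp2 <- run_preprocess(raw)
  expect_identical(pp1$hemo$data, pp2$hemo$data)
  expect_true(any(grepl("bandpass", pp1$log)))
})

test_that("pervasive motion triggers subject exclusion for head movement", {
  raw <- toy_raw(nch = 53, n = 6000, fs = 20)
  # square-wave intensity drops on 40% of channels over ~30% of samples
  blocks <- seq(500, 5500, by = 400)
  for (ch in 1:21) {
    for (b in blocks) {
      raw$data[ch, , b:(b + 120)] <- raw$data[ch, , b:(b + 120)] * exp(-0.8)
    }
  }
  pp <- run_preprocess(raw)
  expect_true(pp$excluded)
  expect_equal(pp$exclusion_reason, "head movement")
  expect_null(pp$hemo)
})
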