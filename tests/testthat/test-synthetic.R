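test_that("ground-truth matrices encode blocks, attenuation and PSD-ness", {
  atlas <- packaged_atlas()
  # no attenuation: both groups identical
  cfg1 <- synth_config(attenuation = 1, seed = 1)
  tr1 <- build_truth(cfg1, atlas)
  expect_equal(tr1$hc, tr1$mcs)

  cfg <- synth_config(r_within = 0.6, r_between = 0.2, attenuation = 0.5,
                      seed = 1)
  tr <- build_truth(cfg, atlas)
  expect_equal(dim(tr$mcs), c(50, 50))
  expect_equal(diag(tr$mcs), rep(1, 50))
  expect_true(isSymmetric(tr$mcs))

  # attenuated blocks sit near 0.3 (within) / 0.1 (cross), modulo the
  # PSD projection; untouched blocks keep the base levels
  reg <- atlas_regions(atlas)
  nodes <- attr(tr$mcs, "nodes")
  fpa <- match(reg$channel[reg$region == "L_FPA"], nodes)
  prem_r <- match(reg$channel[reg$region == "R_PreM_SMA"], nodes)
  within_fpa <- tr$mcs[fpa, fpa][upper.tri(diag(5))]
  cross <- tr$mcs[fpa, prem_r]
  expect_equal(mean(within_fpa), 0.3, tolerance = 0.02)
  expect_equal(mean(cross), 0.1, tolerance = 0.02)
  within_prem <- tr$mcs[prem_r, prem_r][upper.tri(diag(5))]
  expect_equal(mean(within_prem), 0.6, tolerance = 0.02)

  # eigenvalues non-negative after projection
  ev <- eigen(tr$mcs, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
})

test_that("subject simulation is deterministic and spike-free when told so", {
  cfg <- synth_config(duration_s = 120, spike_rate_per_min = 0, seed = 2)
  truth <- build_truth(cfg)
  r1 <- simulate_subject(attr(truth$hc, "full"), cfg, seed = 77)
  r2 <- simulate_subject(attr(truth$hc, "full"), cfg, seed = 77)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_subject(attr(truth$hc, "full"), cfg, seed = 78)
  expect_false(identical(r1$data, r3$data))

  # no spikes: motion detection stays silent after trimming
  od <- trim_edges(intensity_to_od(r1), 20)
  mask <- detect_motion(od)
  expect_equal(sum(vapply(mask$intervals, nrow, integer(1))), 0)
})

test_that("full-length recordings reproduce the target correlations", {
  cfg <- synth_config(seed = 3, spike_rate_per_min = 0)
  truth <- build_truth(cfg)
  raw <- simulate_subject(truth$hc, cfg, seed = 5)
  # untrimmed preprocessing isolates generator fidelity from windowing noise
  pp <- run_preprocess(raw, preprocess_config(trim_s = 0))
  r <- correlation_matrix(pp$hemo)
  lat <- attr(truth$hc, "nodes")
  ut <- upper.tri(truth$hc)
  mad <- mean(abs(r[lat, lat][ut] - truth$hc[ut]))
  expect_lte(mad, 0.1)
})

test_that("preprocessing recovers the band-limited neural signal on clean channels", {
  cfg <- synth_config(seed = 4)
  truth <- build_truth(cfg)
  raw <- simulate_subject(truth$hc, cfg, seed = 6, keep_truth = TRUE)
  pp <- run_preprocess(raw)
  ht <- attr(raw, "hbo_truth")
  fs <- cfg$sampling_rate
  idx <- (60 * fs + 1):(240 * fs)
  rec <- hbo_matrix(pp$hemo)
  cors <- vapply(seq_len(nrow(rec)), function(i) {
    cor(rec[i, ], bandpass(ht[i, idx], sampling_rate = fs))
  }, numeric(1))
  clean <- mask_fraction(pp$mask) == 0
  expect_gte(median(cors[clean]), 0.95)
  expect_gte(min(cors[clean]), 0.80)
})

test_that("cohort generation: counts, determinism, coupling and file output", {
  cfg <- synth_config(n_hc = 3, n_mcs = 3, duration_s = 120, seed = 9)
  cohort <- generate_cohort(cfg)
  expect_equal(length(cohort$raw), 6)
  expect_equal(nrow(cohort$manifest), 6)
  expect_equal(sum(cohort$manifest$group == "MCS"), 3)
  expect_true(all(cohort$manifest$attenuation[cohort$manifest$group == "HC"] == 1))

  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort$raw[[1]]$data, cohort2$raw[[1]]$data)
  expect_identical(cohort$clinical, cohort2$clinical)

  # clinical table round-trips through the parser
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(cohort$clinical, f)
  rec <- parse_crsr_table(f)
  expect_equal(nrow(rec), 6)
  expect_false(any(rec$total_mismatch))

  d <- withr::local_tempdir()
  cohort3 <- generate_cohort(cfg, dir = d)
  expect_true(all(file.exists(cohort3$manifest$file)))
  back <- load_intensity(cohort3$manifest$file[1])
  expect_equal(back$data, cohort3$raw[[1]]$data, tolerance = 1e-9)
})

test_that("the auditory subscale tracks the true attenuation at high coupling", {
  cfg <- synth_config(n_hc = 2, n_mcs = 40, duration_s = 60,
                      coupling = 0.9, seed = 10)
  # clinical scores only; recordings are irrelevant here but cheap at 60 s
  cohort <- generate_cohort(cfg)
  mcs <- cohort$manifest$group == "MCS"
  r_high <- cor(cohort$manifest$attenuation[mcs],
                cohort$clinical$auditory[mcs])
  expect_gt(r_high, 0.5)

  cfg0 <- synth_config(n_hc = 2, n_mcs = 40, duration_s = 60,
                       coupling = 0, seed = 10)
  cohort0 <- generate_cohort(cfg0)
  r_zero <- cor(cohort0$manifest$attenuation[mcs],
                cohort0$clinical$auditory[mcs])
  expect_lt(abs(r_zero), 0.4)
})
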