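#' Configuration of the synthetic two-group cohort generator
#'
#' Defines the ground truth and nuisance structure of a simulated
#' resting-state cohort: block-structured inter-channel correlations by
#' hemisphere-by-region group, group-dependent attenuation of designated
#' regions in the patient group, physiological oscillations (Mayer waves,
#' respiration, cardiac pulsation), slow drift, sparse motion spikes, and a
#' configurable coupling between each patient's connectivity attenuation
#' and the auditory CRS-R subscale.
#'
#' Defaults emulate the acquisition design: 53 channels, two wavelengths,
#' 20 Hz, 300 s per subject, 16 healthy controls versus 15 patients,
#' attenuation 0.6 centred on the left frontopolar and right dorsolateral
#' prefrontal blocks.
#'
#' @param n_hc,n_mcs Group sizes.
#' @param duration_s,sampling_rate Recording length (s) and rate (Hz).
#' @param r_within,r_between Target correlation within / between
#'   hemisphere-by-region blocks (healthy level).
#' @param attenuation Mean multiplicative attenuation of connections
#'   touching the designated regions in the patient group.
#' @param attenuation_sd Between-patient SD of the attenuation factor
#'   (truncated to `[0.05, 1]`).
#' @param attenuated_regions Region labels (e.g. `"L_FPA"`) whose
#'   connections are attenuated.
#' @param neural_sd SD of the band-limited neural HbO signal (uM).
#' @param mayer_amp,resp_amp,cardiac_amp Amplitudes (uM) of the ~0.1 Hz
#'   Mayer, ~0.4 Hz respiratory and ~1.1 Hz cardiac oscillations
#'   (per-channel random phase).
#' @param mayer_freq,resp_freq,cardiac_freq Component frequencies (Hz).
#' @param drift_amp,drift_freq Slow drift amplitude (uM) and frequency (Hz).
#' @param spike_rate_per_min Expected motion-spike events per minute.
#' @param spike_amp Spike step amplitude in OD units.
#' @param spike_tau_s Spike decay time constant (s).
#' @param hbr_scale,hbr_noise_sd HbR is `hbr_scale * HbO` plus white noise.
#' @param coupling Correlation between the patients' true attenuation level
#'   and the latent auditory subscale score.
#' @param mbll Forward modified Beer-Lambert coefficients.
#' @param seed Master seed; everything downstream derives from it.
#' @return A list of class `fc_synth_config`.
#' @export
synth_config <- function(n_hc = 16, n_mcs = 15, duration_s = 300,
                         sampling_rate = 20,
                         r_within = 0.65, r_between = 0.35,
                         attenuation = 0.6, attenuation_sd = 0.12,
                         attenuated_regions = c("L_FPA", "R_DLPFC"),
                         neural_sd = 0.06,
                         mayer_amp = 0.015, mayer_freq = 0.1,
                         resp_amp = 0.04, resp_freq = 0.4,
                         cardiac_amp = 0.06, cardiac_freq = 1.1,
                         drift_amp = 0.15, drift_freq = 0.002,
                         spike_rate_per_min = 0.5, spike_amp = 0.5,
                         spike_tau_s = 2,
                         hbr_scale = -0.3, hbr_noise_sd = 0.02,
                         coupling = 0.8,
                         mbll = mbll_coefficients(), seed = 1) {
  cfg <- as.list(environment())
  if (n_hc < 2 || n_mcs < 2) abort("group sizes must be >= 2")
  if (r_within < 0 || r_within >= 1 || r_between < 0 ||
      r_between > r_within) {
    abort("need 0 <= r_between <= r_within < 1")
  }
  if (attenuation <= 0 || attenuation > 1) {
    abort("attenuation must be in (0, 1]")
  }
  if (abs(coupling) > 1) abort("coupling must be in [-1, 1]")
  structure(cfg, class = "fc_synth_config")
}

default_atlas <- function() {
  read_atlas(nirsnet_example("synthetic_atlas_53ch.tsv"))
}

#' Ground-truth correlation matrices per group
#'
#' Block matrix over the atlas's hemisphere-by-region groups (`r_within` on
#' the block diagonal, `r_between` off it, unit diagonal); in the patient
#' matrix every entry touching a designated region is multiplied by the
#' attenuation factor, and the result is projected to the nearest
#' positive-semidefinite correlation matrix by eigenvalue clipping.
#'
#' @param config An `fc_synth_config`.
#' @param atlas An `fc_atlas` (defaults to the packaged one).
#' @param attenuation Attenuation factor to apply (defaults to the
#'   configured mean; the cohort generator passes each patient's own draw).
#' @return A list `hc`/`mcs` of 50 x 50 matrices over the lateral channels
#'   (node indices in attribute `nodes`), each with the 53-channel matrix
#'   used by the forward simulator in attribute `full`.
#' @export
build_truth <- function(config, atlas = default_atlas(),
                        attenuation = config$attenuation) {
  regions <- atlas_regions(atlas)
  block <- character(nrow(atlas))
  block[atlas$hemisphere == "midline"] <- "midline"
  block[match(regions$channel, atlas$channel)] <- regions$region

  n <- nrow(atlas)
  same <- outer(block, block, `==`)
  C <- ifelse(same, config$r_within, config$r_between)
  diag(C) <- 1

  hc_full <- nearest_psd_corr(C)
  touched <- block %in% config$attenuated_regions
  S <- C
  hit <- outer(touched, touched, `|`)
  S[hit] <- S[hit] * attenuation
  diag(S) <- 1
  mcs_full <- nearest_psd_corr(S)

  lat <- atlas$channel[atlas$hemisphere != "midline"]
  out <- lapply(list(hc = hc_full, mcs = mcs_full), function(M) {
    m <- M[lat, lat]
    attr(m, "nodes") <- lat
    attr(m, "full") <- M
    m
  })
  ev <- eigen(out$mcs, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) abort("patient truth matrix not PSD after projection")
  out
}

# eigenvalue clipping + unit-diagonal rescale
nearest_psd_corr <- function(C, tol = 1e-10) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, tol)
  M <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(M))
  M <- M / outer(d, d)
  (M + t(M)) / 2
}

#' Simulate one subject's raw dual-wavelength recording
#'
#' Forward model, the exact inverse of the preprocessing chain:
#' band-limited (0.01-0.1 Hz) Gaussian HbO signals with the target
#' correlation structure; HbR as negatively scaled HbO plus noise;
#' additive sinusoidal Mayer/respiratory/cardiac components with random
#' per-channel phases plus slow drift; hemoglobin mapped to optical density
#' through the forward modified Beer-Lambert model; Poisson-placed
#' step-and-decay motion spikes added in OD; intensities
#' `I = I0 exp(-OD)`, strictly positive.
#'
#' @param truth A 53-channel target correlation matrix (the `full`
#'   attribute of [build_truth()] output, or any PSD correlation matrix
#'   matching the channel count).
#' @param config An `fc_synth_config`.
#' @param seed Integer seed for this subject.
#' @param subject Subject identifier.
#' @param keep_truth Attach the clean neural HbO matrix (uM, channels x
#'   samples, before physiology/drift/spikes) as attribute `hbo_truth`,
#'   for validation studies.
#' @return An `fc_raw` recording.
#' @export
simulate_subject <- function(truth, config, seed, subject = "sim",
                             keep_truth = FALSE) {
  full <- attr(truth, "full") %||% truth
  nch <- nrow(full)
  fs <- config$sampling_rate
  n <- round(config$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs

  withr::with_seed(seed, {
    # band-limited noise on an extended record (the central n samples are
    # free of filter edge transients), then empirical whitening: with ~50
    # effective samples in a 0.01-0.1 Hz band over 5 min, raw mixing would
    # add O(0.15) correlation noise; whitening makes the record's sample
    # covariance equal the target exactly.
    nb <- round(120 * fs)
    G <- matrix(rnorm(nch * (n + 2 * nb)), nch, n + 2 * nb)
    for (i in seq_len(nch)) {
      G[i, ] <- bandpass_vec(G[i, ], 0.01, 0.1, 3, fs)
    }
    G <- G[, (nb + 1):(nb + n), drop = FALSE]
    G <- G - rowMeans(G)
    Rg <- chol(tcrossprod(G) / n)
    G <- solve(t(Rg), G)
    U <- chol(full + diag(1e-8, nch))
    hbo <- config$neural_sd * (t(U) %*% G)
    hbr <- config$hbr_scale * hbo +
      matrix(rnorm(nch * n, sd = config$hbr_noise_sd), nch, n)

    physio <- function(amp, freq) {
      ph <- runif(nch, 0, 2 * pi)
      amp * sin(outer(ph, 2 * pi * freq * tt, `+`))
    }
    osc <- physio(config$mayer_amp, config$mayer_freq) +
      physio(config$resp_amp, config$resp_freq) +
      physio(config$cardiac_amp, config$cardiac_freq)
    drift <- physio(config$drift_amp, config$drift_freq) +
      outer(runif(nch, -config$drift_amp, config$drift_amp), tt / max(tt))
    hbo <- hbo + osc + drift
    hbr <- hbr + config$hbr_scale * (osc + drift)

    hemo <- array(NA_real_, c(nch, 2, n),
                  dimnames = list(NULL, c("HbO", "HbR"), NULL))
    hemo[, 1, ] <- hbo
    hemo[, 2, ] <- hbr
    hemo_obj <- structure(
      list(subject = subject, data = hemo,
           chromophores = c("HbO", "HbR"), sampling_rate = fs),
      class = "fc_hemo")
    od <- hemoglobin_to_od(hemo_obj, config$mbll)

    n_spikes <- rpois(1, config$spike_rate_per_min * config$duration_s / 60)
    if (n_spikes > 0) {
      for (k in seq_len(n_spikes)) {
        ch <- sample.int(nch, 1)
        t0 <- sample.int(n - 1, 1)
        sgn <- sample(c(-1, 1), 1)
        idx <- t0:n
        shape <- sgn * config$spike_amp *
          exp(-(tt[idx] - tt[t0]) / config$spike_tau_s)
        od$data[ch, 1, idx] <- od$data[ch, 1, idx] + shape
        od$data[ch, 2, idx] <- od$data[ch, 2, idx] + 0.8 * shape
      }
    }

    I0 <- matrix(runif(nch * 2, 0.5, 2), nch, 2)
    intens <- array(NA_real_, c(nch, 2, n))
    for (w in 1:2) intens[, w, ] <- I0[, w] * exp(-od$data[, w, ])
    out <- raw_intensity(intens, sampling_rate = fs, subject = subject)
    if (keep_truth) attr(out, "hbo_truth") <- config$neural_sd * (t(U) %*% G)
    out
  })
}

#' Generate a full synthetic two-group cohort
#'
#' Draws each patient's attenuation level around the configured mean,
#' simulates every subject's raw recording, and builds a clinical table in
#' the patient-table schema whose auditory subscale is coupled to the true
#' attenuation level with the configured correlation (higher attenuation
#' factor, i.e. better-preserved connectivity, maps to higher auditory
#' scores). All randomness derives from the master seed, so identical
#' configurations yield identical cohorts.
#'
#' @param config An `fc_synth_config`.
#' @param atlas An `fc_atlas`.
#' @param dir Optional output directory; when given, recordings are written
#'   as CSV, the clinical table as TSV, and the manifest as JSON (requires
#'   the jsonlite package).
#' @return A list of class `fc_cohort`: `raw` (named list of `fc_raw`),
#'   `manifest` (tibble: id, group, seed, file, attenuation, true auditory
#'   latent), `clinical` (tibble in the clinical-table schema), `truth`
#'   (group-level matrices from [build_truth()]), `config`.
#' @examples
#' cfg <- synth_config(n_hc = 2, n_mcs = 2, duration_s = 150, seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort$manifest[, c("id", "group", "attenuation")]
#' @export
generate_cohort <- function(config, atlas = default_atlas(), dir = NULL) {
  stopifnot(inherits(config, "fc_synth_config"))
  n_all <- config$n_hc + config$n_mcs
  ids <- c(sprintf("HC%02d", seq_len(config$n_hc)),
           sprintf("MCS%02d", seq_len(config$n_mcs)))
  groups <- rep(c("HC", "MCS"), c(config$n_hc, config$n_mcs))
  seeds <- config$seed + 1000L * seq_len(n_all)

  truth <- build_truth(config, atlas)

  draws <- withr::with_seed(config$seed, {
    att <- pmin(1, pmax(0.05, rnorm(config$n_mcs, config$attenuation,
                                    config$attenuation_sd)))
    eps <- rnorm(config$n_mcs)
    list(att = att, eps = eps,
         hc_age = round(rnorm(config$n_hc, 58.6, 14.5)),
         mcs_age = round(rnorm(config$n_mcs, 67.5, 16.5)),
         hc_male = sample(rep(c("M", "F"), length.out = config$n_hc)),
         mcs_male = sample(rep(c("M", "F"), length.out = config$n_mcs)),
         duration = round(pmax(1, rexp(config$n_mcs, 1 / 3)), 1),
         visual = sample(0:3, config$n_mcs, replace = TRUE),
         motor = sample(2:5, config$n_mcs, replace = TRUE),
         oromotor = sample(0:2, config$n_mcs, replace = TRUE),
         communication = sample(0:1, config$n_mcs, replace = TRUE,
                                prob = c(0.8, 0.2)),
         arousal = sample(1:2, config$n_mcs, replace = TRUE))
  })

  # auditory subscale: latent = coupling * z(attenuation) + noise
  za <- if (sd(draws$att) > 0) {
    (draws$att - mean(draws$att)) / sd(draws$att)
  } else {
    rep(0, config$n_mcs)
  }
  latent <- config$coupling * za +
    sqrt(max(0, 1 - config$coupling^2)) * draws$eps
  auditory <- as.integer(cut(latent,
                             breaks = c(-Inf, qnorm(c(0.2, 0.4, 0.6, 0.8)),
                                        Inf),
                             labels = FALSE)) - 1L

  attenuations <- c(rep(1, config$n_hc), draws$att)
  raw <- vector("list", n_all)
  names(raw) <- ids
  for (s in seq_len(n_all)) {
    tr <- if (groups[s] == "HC") {
      truth$hc
    } else {
      build_truth(config, atlas, attenuation = attenuations[s])$mcs
    }
    raw[[s]] <- simulate_subject(tr, config, seed = seeds[s],
                                 subject = ids[s])
  }

  mcs_idx <- which(groups == "MCS")
  clinical <- tibble(
    id = ids,
    group = groups,
    mcs_subtype = ifelse(groups == "MCS", "MCS-", "none"),
    gender = c(draws$hc_male, draws$mcs_male),
    age = c(draws$hc_age, draws$mcs_age),
    etiology = ifelse(groups == "MCS", "simulated injury", "none"),
    duration_months = c(rep(NA_real_, config$n_hc), draws$duration),
    auditory = NA_integer_, visual = NA_integer_, motor = NA_integer_,
    oromotor = NA_integer_, communication = NA_integer_,
    arousal = NA_integer_)
  clinical$auditory[mcs_idx] <- auditory
  clinical$visual[mcs_idx] <- draws$visual
  clinical$motor[mcs_idx] <- draws$motor
  clinical$oromotor[mcs_idx] <- draws$oromotor
  clinical$communication[mcs_idx] <- draws$communication
  clinical$arousal[mcs_idx] <- draws$arousal
  clinical$crsr_total <- rowSums(clinical[, crsr_subscales])

  files <- rep(NA_character_, n_all)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (s in seq_len(n_all)) {
      files[s] <- file.path(dir, paste0(ids[s], ".csv"))
      write_intensity(raw[[s]], files[s])
    }
    readr::write_tsv(clinical, file.path(dir, "clinical.tsv"),
                     progress = FALSE)
  }

  manifest <- tibble(id = ids, group = groups, seed = seeds, file = files,
                     attenuation = attenuations)
  if (!is.null(dir) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(config = config[setdiff(names(config), "mbll")],
           manifest = manifest),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }

  structure(
    list(raw = raw, manifest = manifest, clinical = clinical, truth = truth,
         config = config),
    class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("<fc_cohort> %d HC + %d MCS subjects, %g s at %g Hz (seed %d)\n",
              x$config$n_hc, x$config$n_mcs, x$config$duration_s,
              x$config$sampling_rate, x$config$seed))
  invisible(x)
}
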