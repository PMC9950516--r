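packaged_atlas <- function() {
  read_atlas(nirsnet_example("synthetic_atlas_53ch.tsv"))
}

packaged_montage <- function() {
  read_montage(nirsnet_example("synthetic_montage_53ch.tsv"))
}

packaged_clinical <- function() {
  suppressMessages(parse_crsr_table(nirsnet_example("clinical_mcs.tsv")))
}

# a small raw recording with smooth positive traces
toy_raw <- function(nch = 4, n = 400, fs = 20, seed = 1) {
  withr::with_seed(seed, {
    tt <- (seq_len(n) - 1) / fs
    data <- array(NA_real_, c(nch, 2, n))
    for (i in seq_len(nch)) {
      for (w in 1:2) {
        data[i, w, ] <- 1 + 0.05 * sin(2 * pi * 0.05 * tt + i + w) +
          0.01 * rnorm(n)
      }
    }
    raw_intensity(data, sampling_rate = fs,
                  subject = sprintf("toy%d", seed))
  })
}

# rewrite the packaged atlas with a modification, returning a temp path
mutated_atlas_file <- function(mutate) {
  at <- readr::read_tsv(nirsnet_example("synthetic_atlas_53ch.tsv"),
                        show_col_types = FALSE)
  at <- mutate(at)
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  readr::write_tsv(at, f)
  f
}

# small cohort settings used across pipeline tests
small_cohort <- function(seed = 5, n_hc = 3, n_mcs = 3, duration_s = 150) {
  generate_cohort(synth_config(n_hc = n_hc, n_mcs = n_mcs,
                               duration_s = duration_s, seed = seed))
}
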