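# Shared fixtures, generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# a small annotated synthetic corpus (6 classes, 1 recording each)
fixture_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    dir <- file.path(tempdir(), "fixture-corpus")
    unlink(dir, recursive = TRUE)
    cfg <- synth_corpus_config(n_patients_per_class = 1L,
                               recordings_per_patient = 1L,
                               recording_duration_s = c(12, 16),
                               seed = 421L)
    idx <- synth_corpus(cfg, default_archetypes(), dir)
    .fixture_env$corpus <- list(dir = dir, index = idx, cfg = cfg)
  }
  .fixture_env$corpus
}

# one standardized 6-s segment holding a pure tone
tone_segment <- function(freq_hz, amp = 0.5, rate = 22050L, dur_s = 6) {
  amp * sin(2 * pi * freq_hz * seq_len(rate * dur_s) / rate)
}

# seeded white-noise segment
noise_segment <- function(seed = 1L, rate = 22050L, dur_s = 6) {
  withr::with_seed(seed, stats::rnorm(rate * dur_s, sd = 0.1))
}

random_cycles <- function(n, seed = 1L) {
  withr::with_seed(seed, {
    start <- round(cumsum(runif(n, 0.2, 3)), 3)
    end <- round(start + runif(n, 0.5, 4), 3)
    tibble::tibble(start_s = start, end_s = end,
                   crackle = runif(n) < 0.4, wheeze = runif(n) < 0.3)
  })
}

# small random feature triples for model-level tests
random_triples <- function(n, seed = 1L, n_frames = 259L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      structure(list(mfcc = matrix(rnorm(20 * n_frames), 20),
                     chroma = matrix(rnorm(12 * n_frames), 12),
                     mspec = matrix(rnorm(128 * n_frames), 128),
                     n_frames = as.integer(n_frames),
                     label = (i - 1L) %% 6L),
                class = "feature_triple")
    })
  })
}
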