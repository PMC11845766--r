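# Seeded generator of annotated synthetic lung-sound corpora in the ICBHI
# on-disk layout. Breath cycles are band-limited noise under an
# inhale/exhale envelope; adventitious sounds are inserted as damped
# sinusoid transients (crackles) and sustained tones with one harmonic
# (wheezes), and the written annotations reflect exactly what was
# inserted. The archetypes are test fixtures with class-distinct
# parameters, not clinical models.

#' Class archetype for synthetic lung sounds
#'
#' @param label Diagnosis label (one of the six classes).
#' @param cycle_duration_s Mean and sd of cycle duration, seconds.
#' @param crackle_rate Expected crackles per cycle (Poisson rate).
#' @param wheeze_prob Per-cycle probability of a wheeze.
#' @param wheeze_f0_hz Two-element frequency range of the wheeze
#'   fundamental, Hz.
#' @param noise_tilt_db_per_oct Spectral slope of the breath noise,
#'   dB/octave relative to 100 Hz (negative = low-frequency weighted).
#' @param amplitude Target RMS of the cycle.
#' @return A list of class `class_archetype`.
#' @export
class_archetype <- function(label, cycle_duration_s = c(3.5, 0.5),
                            crackle_rate = 0, wheeze_prob = 0,
                            wheeze_f0_hz = c(300, 600),
                            noise_tilt_db_per_oct = -6, amplitude = 0.15) {
  stopifnot(label %in% DIAGNOSIS_LEVELS, crackle_rate >= 0,
            wheeze_prob >= 0, wheeze_prob <= 1,
            all(wheeze_f0_hz > 0), length(cycle_duration_s) == 2L)
  structure(list(label = label, cycle_duration_s = cycle_duration_s,
                 crackle_rate = crackle_rate, wheeze_prob = wheeze_prob,
                 wheeze_f0_hz = wheeze_f0_hz,
                 noise_tilt_db_per_oct = noise_tilt_db_per_oct,
                 amplitude = amplitude),
            class = "class_archetype")
}

#' Default archetypes for the six classes
#'
#' Distinct crackle rates, wheeze bands, spectral tilts and cycle
#' durations per class: COPD wheeze-dominated with prolonged expiration,
#' Pneumonia and Bronchiectasis crackle-dominated, Healthy a clean
#' envelope, Bronchiolitis and URTI intermediate mixtures.
#'
#' @return Named list of six [class_archetype()]s, in class-code order.
#' @export
default_archetypes <- function() {
  a <- list(
    class_archetype("Bronchiectasis", c(3.0, 0.4), crackle_rate = 3,
                    wheeze_prob = 0.10, wheeze_f0_hz = c(200, 300),
                    noise_tilt_db_per_oct = -6, amplitude = 0.16),
    class_archetype("Bronchiolitis", c(2.4, 0.3), crackle_rate = 1.2,
                    wheeze_prob = 0.45, wheeze_f0_hz = c(550, 750),
                    noise_tilt_db_per_oct = -4, amplitude = 0.12),
    class_archetype("COPD", c(4.6, 0.6), crackle_rate = 0.3,
                    wheeze_prob = 0.9, wheeze_f0_hz = c(280, 430),
                    noise_tilt_db_per_oct = -7, amplitude = 0.18),
    class_archetype("Healthy", c(3.4, 0.4), crackle_rate = 0,
                    wheeze_prob = 0, noise_tilt_db_per_oct = -9,
                    amplitude = 0.10),
    class_archetype("Pneumonia", c(3.0, 0.5), crackle_rate = 4.5,
                    wheeze_prob = 0.2, wheeze_f0_hz = c(330, 420),
                    noise_tilt_db_per_oct = -3, amplitude = 0.20),
    class_archetype("URTI", c(2.0, 0.3), crackle_rate = 0.8,
                    wheeze_prob = 0.6, wheeze_f0_hz = c(800, 1100),
                    noise_tilt_db_per_oct = -5, amplitude = 0.14))
  names(a) <- vapply(a, `[[`, "", "label")
  a
}

#' Synthetic corpus configuration
#'
#' @param n_patients_per_class Patients per diagnosis class.
#' @param recordings_per_patient Recordings per patient.
#' @param recording_duration_s Two-element duration range, seconds.
#' @param sample_rate Native sampling rate in Hz (default 4,000, the
#'   digital-stethoscope rate; the pipeline upsamples to 22,050 Hz).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A list of class `synth_corpus_config`.
#' @export
synth_corpus_config <- function(n_patients_per_class = 2L,
                                recordings_per_patient = 2L,
                                recording_duration_s = c(30, 38),
                                sample_rate = 4000L, seed = 0L) {
  stopifnot(n_patients_per_class >= 1L, recordings_per_patient >= 1L,
            length(recording_duration_s) == 2L,
            recording_duration_s[1] > 0, sample_rate > 0)
  structure(list(n_patients_per_class = as.integer(n_patients_per_class),
                 recordings_per_patient = as.integer(recordings_per_patient),
                 recording_duration_s = as.numeric(recording_duration_s),
                 sample_rate = as.integer(sample_rate),
                 seed = as.integer(seed)),
            class = "synth_corpus_config")
}

# spectrally tilted band-limited (100-1800 Hz) noise via FFT shaping
shaped_noise <- function(n, rate, tilt_db_per_oct) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, rate - f)                      # two-sided frequency axis
  gain <- numeric(n)
  band <- f >= 100 & f <= 1800
  gain[band] <- 10^((tilt_db_per_oct * log2(f[band] / 100)) / 20)
  Re(stats::fft(X * gain, inverse = TRUE)) / n
}

# raised-cosine inhale/exhale amplitude envelope
breath_envelope <- function(n) {
  t <- seq(0, 1, length.out = n)
  attack <- 0.35; decay <- 0.45
  env <- rep(1, n)
  a <- t < attack
  env[a] <- 0.5 * (1 - cos(pi * t[a] / attack))
  d <- t > 1 - decay
  env[d] <- 0.5 * (1 - cos(pi * (1 - t[d]) / decay))
  env
}

# <= 15 ms damped-sinusoid transient
crackle_burst <- function(rate) {
  n <- round(0.015 * rate)
  t <- seq_len(n) / rate
  f <- stats::runif(1, 400, 900)
  exp(-t / 0.003) * sin(2 * pi * f * t)
}

#' Generate one synthetic breath cycle
#'
#' Band-limited shaped noise under an inhale/exhale envelope, with
#' Poisson-count crackle transients and (with probability `wheeze_prob`) a
#' sustained wheeze tone plus one harmonic. Consumes the current RNG
#' state; seed it for reproducibility.
#'
#' @param archetype A [class_archetype()].
#' @param rate Sampling rate in Hz.
#' @return List with `samples` and a one-row annotation tibble (`start_s`
#'   0, `end_s` the cycle duration, and flags reflecting what was actually
#'   inserted).
#' @export
gen_breath_cycle <- function(archetype, rate) {
  dur <- max(1.2, stats::rnorm(1, archetype$cycle_duration_s[1],
                               archetype$cycle_duration_s[2]))
  n <- round(dur * rate)
  x <- shaped_noise(n, rate, archetype$noise_tilt_db_per_oct)
  x <- x / max(stats::sd(x), 1e-12)
  env <- breath_envelope(n)
  x <- x * env

  n_crackles <- stats::rpois(1, archetype$crackle_rate)
  if (n_crackles > 0) {
    burst_len <- round(0.015 * rate)
    for (i in seq_len(n_crackles)) {
      pos <- sample.int(max(1L, n - burst_len), 1L)
      b <- crackle_burst(rate) * 6
      ix <- pos:min(n, pos + length(b) - 1L)
      x[ix] <- x[ix] + b[seq_along(ix)]
    }
  }

  has_wheeze <- stats::runif(1) < archetype$wheeze_prob
  if (has_wheeze) {
    f0 <- stats::runif(1, archetype$wheeze_f0_hz[1],
                       archetype$wheeze_f0_hz[2])
    t <- seq_len(n) / rate
    tone <- sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi)) +
      0.3 * sin(2 * pi * 2 * f0 * t)
    x <- x + 1.5 * tone * env
  }

  x <- x * archetype$amplitude / max(sqrt(mean(x^2)), 1e-12)
  list(samples = x,
       annotation = tibble(start_s = 0, end_s = dur,
                           crackle = n_crackles > 0,
                           wheeze = has_wheeze))
}

#' Generate one synthetic recording
#'
#' Tiles breath cycles separated by short pauses until the requested
#' duration is filled; annotations are non-overlapping, strictly
#' increasing and lie inside the recording. Output is clipped to
#' \[-1, 1\].
#'
#' @param archetype A [class_archetype()].
#' @param duration_s Recording duration in seconds.
#' @param rate Sampling rate in Hz.
#' @return List with `samples` (length `duration_s * rate`) and a
#'   cycle-annotation tibble.
#' @export
synth_recording <- function(archetype, duration_s, rate) {
  n_total <- round(duration_s * rate)
  min_cycle <- 1.2
  if (duration_s < min_cycle) {
    abort("recording duration too short for one cycle")
  }
  samples <- numeric(n_total)
  anns <- list()
  t0 <- stats::runif(1, 0, 0.3)
  while (TRUE) {
    cyc <- gen_breath_cycle(archetype, rate)
    end <- t0 + cyc$annotation$end_s
    if (end > duration_s) break
    i0 <- round(t0 * rate)
    ix <- (i0 + 1L):(i0 + length(cyc$samples))
    samples[ix] <- samples[ix] + cyc$samples
    anns[[length(anns) + 1L]] <- tibble(
      start_s = t0, end_s = end,
      crackle = cyc$annotation$crackle, wheeze = cyc$annotation$wheeze)
    t0 <- end + stats::runif(1, 0.2, 0.6)
    if (t0 >= duration_s - min_cycle) break
  }
  if (!length(anns)) abort("recording duration too short for one cycle")
  list(samples = pmax(-1, pmin(1, samples)),
       annotations = dplyr::bind_rows(anns))
}

#' Write a synthetic corpus in the ICBHI layout
#'
#' One wav + annotation txt per recording (ICBHI naming
#' `patientId_token_location_mode_equipment.wav`) plus a diagnosis table;
#' byte-identical across runs with the same config. Per-recording RNG
#' substreams are derived from the master seed by counter, so the corpus
#' is reproducible regardless of generation order.
#'
#' @param cfg A [synth_corpus_config()].
#' @param archetypes Named list of six archetypes
#'   ([default_archetypes()]).
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress the index summary message.
#' @return The `dataset_index` of the written corpus (round-tripped
#'   through [index_dataset()]).
#' @export
synth_corpus <- function(cfg = synth_corpus_config(),
                         archetypes = default_archetypes(),
                         outdir, quiet = TRUE) {
  stopifnot(length(archetypes) == 6L)
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory ", outdir))
  }
  labels <- vapply(archetypes, `[[`, "", "label")
  stopifnot(setequal(labels, DIAGNOSIS_LEVELS))
  diag_rows <- character(0)
  counter <- 0L
  for (ci in seq_along(DIAGNOSIS_LEVELS)) {
    arch <- archetypes[[which(labels == DIAGNOSIS_LEVELS[ci])]]
    for (p in seq_len(cfg$n_patients_per_class)) {
      pid <- 100L + (ci - 1L) * cfg$n_patients_per_class + p
      diag_rows <- c(diag_rows, paste0(pid, ",", DIAGNOSIS_LEVELS[ci]))
      for (r in seq_len(cfg$recordings_per_patient)) {
        counter <- counter + 1L
        rec <- with_seed(derive_seed(cfg$seed, counter), {
          dur <- stats::runif(1, cfg$recording_duration_s[1],
                              cfg$recording_duration_s[2])
          synth_recording(arch, dur, cfg$sample_rate)
        })
        stem <- sprintf("%d_%db%d_Al_sc_Synth", pid, r, ci)
        write_wav(rec$samples, cfg$sample_rate,
                  file.path(outdir, paste0(stem, ".wav")))
        writeLines(sub("\n$", "", write_annotation_file(rec$annotations)),
                   file.path(outdir, paste0(stem, ".txt")))
      }
    }
  }
  writeLines(diag_rows, file.path(outdir, "diagnosis.csv"))
  index_dataset(outdir, quiet = quiet)
}
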