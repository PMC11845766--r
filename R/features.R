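# The three spectral representations computed per standardized segment:
# 20-coefficient MFCCs, 12-bin chromagram and 128-band mel spectrogram.
# STFT settings (n_fft 2048, hop 512, Hann, centered with reflect padding)
# are the unique common convention that yields 259 frames from a 6-s
# segment at 22,050 Hz: 1 + floor(132300 / 512) = 259.

#' Default STFT settings
#'
#' @param n_fft Window length in samples.
#' @param hop Hop length in samples.
#' @param centered Center frames on the signal with reflect padding.
#' @param window Taper name (only `"hann"` implemented).
#' @return A list of class `stft_spec`.
#' @export
stft_spec <- function(n_fft = 2048L, hop = 512L, centered = TRUE,
                      window = "hann") {
  stopifnot(hop >= 1L, n_fft >= hop, window == "hann")
  structure(list(n_fft = as.integer(n_fft), hop = as.integer(hop),
                 centered = isTRUE(centered), window = window),
            class = "stft_spec")
}

#' Number of STFT frames for a signal
#'
#' Centered framing yields `1 + floor(n_samples / hop)` frames; uncentered
#' framing yields `1 + floor((n_samples - n_fft) / hop)`.
#'
#' @param n_samples Signal length in samples.
#' @param hop Hop length in samples.
#' @param centered Logical; centered framing.
#' @param n_fft Window length (needed for uncentered framing).
#' @return Integer frame count.
#' @export
stft_frame_count <- function(n_samples, hop, centered = TRUE,
                             n_fft = 2048L) {
  if (n_samples < 1L || hop < 1L) abort("n_samples and hop must be >= 1")
  if (centered) return(1L + n_samples %/% as.integer(hop))
  if (n_samples < n_fft) abort("uncentered framing needs n_samples >= n_fft")
  1L + (n_samples - as.integer(n_fft)) %/% as.integer(hop)
}

# magnitude-squared STFT: (1 + n_fft/2) x T power matrix
stft_power <- function(x, spec = stft_spec()) {
  if (!length(x)) abort("empty segment")
  n_fft <- spec$n_fft
  hop <- spec$hop
  if (spec$centered) {
    pad <- n_fft %/% 2L
    n <- length(x)
    # reflect padding without repeating the edge sample; index pattern
    # 2..n-1 folds back and forth for signals shorter than the pad
    fold <- function(i, n) {
      if (n == 1L) return(rep(1L, length(i)))
      p <- (i - 1L) %% (2L * (n - 1L))
      1L + ifelse(p < n, p, 2L * (n - 1L) - p)
    }
    left <- x[fold(1L + rev(seq_len(pad)), n)]
    right <- x[fold(n + seq_len(pad), n)]
    x <- c(left, x, right)
    n_frames <- 1L + n %/% hop
  } else {
    n_frames <- stft_frame_count(length(x), hop, FALSE, n_fft)
  }
  w <- hann_window(n_fft)
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(n_fft), starts, `+`)
  frames <- matrix(x[idx], nrow = n_fft) * w
  spect <- stats::mvfft(frames)[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  Re(spect)^2 + Im(spect)^2
}

# periodic Hann, the analysis convention
hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / n))

fft_bin_freqs <- function(rate, n_fft) {
  seq(0, rate / 2, length.out = n_fft %/% 2L + 1L)
}

# Mel scale, Slaney flavour: linear below 1 kHz, logarithmic above.
hz_to_mel <- function(f) {
  m <- f / (200 / 3)
  hi <- f >= 1000
  m[hi] <- 15 + log(f[hi] / 1000) / (log(6.4) / 27)
  m
}

mel_to_hz <- function(m) {
  f <- m * (200 / 3)
  hi <- m >= 15
  f[hi] <- 1000 * exp((m[hi] - 15) * log(6.4) / 27)
  f
}

#' Mel filterbank matrix
#'
#' Triangular filters on the Slaney mel scale, area-normalized so each
#' filter integrates to the same energy.
#'
#' @param n_mels Number of bands.
#' @param rate Sampling rate in Hz.
#' @param n_fft FFT length.
#' @param fmin,fmax Frequency range in Hz.
#' @return `n_mels` x `(1 + n_fft/2)` matrix.
#' @export
mel_filterbank <- function(n_mels = 128L, rate = TARGET_RATE_HZ,
                           n_fft = 2048L, fmin = 0, fmax = rate / 2) {
  freqs <- fft_bin_freqs(rate, n_fft)
  mpts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2L)
  fpts <- mel_to_hz(mpts)
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- fpts[m]; mid <- fpts[m + 1L]; hi <- fpts[m + 2L]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down)) * 2 / (hi - lo)
  }
  fb
}

# power -> decibels relative to the matrix maximum, floored at -top_db;
# an all-silent matrix sits uniformly at the floor
power_to_db <- function(S, top_db = 80, amin = 1e-10) {
  ref <- max(S, amin)
  if (max(S) <= amin) return(S * 0 - top_db)
  db <- 10 * log10(pmax(S, amin)) - 10 * log10(ref)
  pmax(db, -top_db)
}

# orthonormal DCT-II matrix (n_out x n_in)
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1L
  n <- seq_len(n_in) - 1L
  M <- cos(pi / n_in * outer(k, n + 0.5))
  M <- M * sqrt(2 / n_in)
  M[1L, ] <- M[1L, ] / sqrt(2)
  M
}

segment_samples <- function(segment) {
  if (inherits(segment, "audio_segment")) {
    if (segment$rate != TARGET_RATE_HZ) {
      abort("segment must be standardized to 22,050 Hz")
    }
    segment$samples
  } else {
    as.numeric(segment)
  }
}

#' Mel spectrogram of a standardized segment
#'
#' 128-band mel power spectrogram in decibels, floored 80 dB below the
#' segment maximum.
#'
#' @param segment `audio_segment` or numeric vector at 22,050 Hz.
#' @param spec STFT settings ([stft_spec()]).
#' @param n_mels Number of mel bands.
#' @return `n_mels` x T matrix (T = 259 for a 6-s segment).
#' @export
compute_melspec <- function(segment, spec = stft_spec(), n_mels = 128L) {
  x <- segment_samples(segment)
  P <- stft_power(x, spec)
  fb <- mel_filterbank(n_mels, TARGET_RATE_HZ, spec$n_fft)
  power_to_db(fb %*% P)
}

#' MFCCs of a standardized segment
#'
#' Orthonormal DCT-II of the log-mel spectrogram, keeping the first
#' `n_mfcc` coefficients.
#'
#' @inheritParams compute_melspec
#' @param n_mfcc Number of cepstral coefficients.
#' @return `n_mfcc` x T matrix.
#' @export
compute_mfcc <- function(segment, spec = stft_spec(), n_mfcc = 20L) {
  M <- compute_melspec(segment, spec, n_mels = 128L)
  dct_matrix(n_mfcc, nrow(M)) %*% M
}

#' Chromagram of a standardized segment
#'
#' Folds STFT power onto the 12 pitch classes (C = bin 1, A4 = 440 Hz) and
#' max-normalizes each frame to \[0, 1\]; all-zero frames stay zero.
#'
#' @inheritParams compute_melspec
#' @return 12 x T matrix with values in \[0, 1\].
#' @export
compute_chroma <- function(segment, spec = stft_spec()) {
  x <- segment_samples(segment)
  P <- stft_power(x, spec)
  freqs <- fft_bin_freqs(TARGET_RATE_HZ, spec$n_fft)
  pc <- rep(NA_integer_, length(freqs))
  nz <- freqs > 0
  midi <- 69 + 12 * log2(freqs[nz] / 440)
  pc[nz] <- (as.integer(round(midi)) %% 12L) + 1L
  C <- matrix(0, 12L, ncol(P))
  for (b in which(nz)) C[pc[b], ] <- C[pc[b], ] + P[b, ]
  mx <- apply(C, 2L, max)
  pos <- mx > 0
  C[, pos] <- sweep(C[, pos, drop = FALSE], 2L, mx[pos], `/`)
  C
}

znorm <- function(M) {
  s <- stats::sd(M)
  if (!is.finite(s) || s == 0) return(M * 0)
  (M - mean(M)) / s
}

#' Extract the three spectral features of a segment
#'
#' Computes the MFCC (20 x T), chroma (12 x T) and mel-spectrogram
#' (128 x T) matrices of one standardized 6-s segment, optionally
#' z-scoring each matrix (the form consumed by the model).
#'
#' @param segment `audio_segment` or numeric vector at 22,050 Hz.
#' @param spec STFT settings.
#' @param normalize Z-score each matrix to mean 0, sd 1.
#' @return A list of class `feature_triple` with elements `mfcc`, `chroma`,
#'   `mspec`, `n_frames` and `label`.
#' @export
extract_feature_triple <- function(segment, spec = stft_spec(),
                                   normalize = TRUE) {
  mspec <- compute_melspec(segment, spec)
  mfcc <- compute_mfcc(segment, spec)
  chroma <- compute_chroma(segment, spec)
  stopifnot(ncol(mfcc) == ncol(chroma), ncol(chroma) == ncol(mspec))
  if (normalize) {
    mfcc <- znorm(mfcc); chroma <- znorm(chroma); mspec <- znorm(mspec)
  }
  if (anyNA(mfcc) || anyNA(chroma) || anyNA(mspec)) {
    abort("non-finite values in extracted features")
  }
  structure(list(mfcc = mfcc, chroma = chroma, mspec = mspec,
                 n_frames = ncol(mfcc),
                 label = if (inherits(segment, "audio_segment"))
                   segment$label else NA_integer_),
            class = "feature_triple")
}

#' Extract features for a list of segments
#'
#' @param segments List of `audio_segment` objects.
#' @param spec STFT settings.
#' @param normalize Z-score each matrix.
#' @return List of `feature_triple` objects.
#' @export
extract_features <- function(segments, spec = stft_spec(),
                             normalize = TRUE) {
  lapply(segments, extract_feature_triple, spec = spec,
         normalize = normalize)
}

#' Plot a feature triple
#'
#' Draws the three time-frequency matrices of one segment as tiled heat
#' maps on a shared time axis.
#'
#' @param object A `feature_triple`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.feature_triple <- function(object, ...) {
  melt <- function(M, name) {
    tibble(feature = name,
           row = rep(seq_len(nrow(M)), times = ncol(M)),
           frame = rep(seq_len(ncol(M)), each = nrow(M)),
           value = as.vector(M))
  }
  df <- dplyr::bind_rows(melt(object$mfcc, "mfcc"),
                         melt(object$chroma, "chroma"),
                         melt(object$mspec, "mel spectrogram"))
  ggplot2::ggplot(df, ggplot2::aes(.data$frame, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~feature, ncol = 1, scales = "free_y") +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = "frame", y = NULL)
}
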