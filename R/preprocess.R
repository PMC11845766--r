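# Standardization of raw recordings into fixed-length mono segments:
# resample to 22,050 Hz, slice out each annotated respiratory cycle, then
# zero-pad or trim to exactly 6 s (132,300 samples).

#' Band-limited resampling
#'
#' Polyphase FIR resampling between arbitrary integer rates, with
#' anti-aliasing when downsampling. When the rates match the input is
#' returned unchanged.
#'
#' @param samples Numeric vector.
#' @param src_rate,target_rate Source and target sampling rates in Hz.
#' @return Resampled numeric vector of length
#'   `round(length(samples) * target_rate / src_rate)` (+/- 1).
#' @export
resample_audio <- function(samples, src_rate, target_rate) {
  if (!length(samples)) abort("empty input signal")
  if (src_rate <= 0 || target_rate <= 0) abort("rates must be positive")
  src_rate <- as.integer(round(src_rate))
  target_rate <- as.integer(round(target_rate))
  if (src_rate == target_rate) return(as.numeric(samples))
  g <- gcd_int(target_rate, src_rate)
  as.numeric(signal::resample(as.numeric(samples),
                              p = target_rate %/% g, q = src_rate %/% g))
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Slice one annotated respiratory cycle out of a recording
#'
#' Sample indexing is 0-based and half-open: the returned window is
#' `samples[floor(start_s * rate) : floor(end_s * rate))`, clamped to the
#' signal end (with a warning) when the annotation overruns the recording.
#'
#' @param samples Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param ann One-row cycle annotation (fields `start_s`, `end_s`).
#' @return Numeric vector holding the cycle.
#' @export
slice_cycle <- function(samples, rate, ann) {
  start_s <- ann$start_s[[1]]
  end_s <- ann$end_s[[1]]
  stopifnot(is.finite(start_s), is.finite(end_s))
  if (start_s < 0 || end_s <= start_s) abort("need 0 <= start < end")
  i0 <- floor(start_s * rate)            # 0-based inclusive
  i1 <- floor(end_s * rate)              # 0-based exclusive
  n <- length(samples)
  if (i0 >= n) abort("cycle start beyond signal end")
  if (i1 > n) {
    warn(sprintf("cycle end %.3f s beyond signal end; clamped", end_s))
    i1 <- n
  }
  samples[(i0 + 1L):i1]
}

#' Pad or trim a segment to a fixed duration
#'
#' Segments shorter than the target are right-padded with zeros (silence
#' appended after the cycle); longer segments keep their first
#' `rate * target_s` samples.
#'
#' @param segment Numeric vector.
#' @param rate Sampling rate in Hz.
#' @param target_s Target duration in seconds (default 6).
#' @return Numeric vector of exactly `rate * target_s` samples.
#' @export
fix_length <- function(segment, rate, target_s = SEGMENT_SECONDS) {
  if (!length(segment)) abort("empty segment")
  n_target <- as.integer(round(rate * target_s))
  n <- length(segment)
  if (n == n_target) return(as.numeric(segment))
  if (n > n_target) return(as.numeric(segment[seq_len(n_target)]))
  c(as.numeric(segment), numeric(n_target - n))
}

#' Preprocess one recording into standardized segments
#'
#' Applies the full standardization chain: resample to 22,050 Hz, slice
#' each annotated cycle, pad/trim to 6 s. Cycle order is preserved and
#' every segment inherits the recording's diagnosis label.
#'
#' @param samples Numeric vector (raw recording).
#' @param src_rate Recording sample rate in Hz.
#' @param annotations Cycle-annotation tibble
#'   (see [parse_cycle_annotations()]).
#' @param meta One-row recording metadata (needs `diagnosis` or
#'   `class_code`); may be `NULL` for unlabeled use.
#' @return A list of `audio_segment` objects: lists with `samples`
#'   (132,300 values), `rate` (22,050), `label` (class code or `NA`),
#'   `cycle_index` and `source` metadata.
#' @export
preprocess_recording <- function(samples, src_rate, annotations,
                                 meta = NULL) {
  if (!nrow(annotations)) {
    warn("recording has no annotated cycles; returning no segments")
    return(list())
  }
  label <- NA_integer_
  if (!is.null(meta)) {
    if ("class_code" %in% names(meta)) {
      label <- as.integer(meta$class_code[[1]])
    } else if ("diagnosis" %in% names(meta)) {
      label <- diagnosis_code(meta$diagnosis[[1]])
    }
  }
  x <- resample_audio(samples, src_rate, TARGET_RATE_HZ)
  out <- vector("list", nrow(annotations))
  for (i in seq_len(nrow(annotations))) {
    seg <- slice_cycle(x, TARGET_RATE_HZ, annotations[i, ])
    seg <- fix_length(seg, TARGET_RATE_HZ, SEGMENT_SECONDS)
    out[[i]] <- structure(
      list(samples = seg, rate = TARGET_RATE_HZ, label = label,
           cycle_index = i, source = meta),
      class = "audio_segment")
  }
  out
}

#' Preprocess an indexed corpus
#'
#' Runs [preprocess_recording()] over every row of a dataset index and
#' returns all segments plus a manifest tibble (segment id, source
#' recording, cycle index, label).
#'
#' @param index A `dataset_index` from [index_dataset()].
#' @return List with `segments` (list of `audio_segment`) and `manifest`
#'   (tibble).
#' @export
preprocess_dataset <- function(index) {
  segments <- list()
  man <- list()
  for (i in seq_len(nrow(index))) {
    wav <- read_wav(index$audio_path[[i]])
    segs <- preprocess_recording(wav$samples, wav$rate,
                                 index$cycles[[i]], index[i, ])
    for (s in segs) {
      segments[[length(segments) + 1L]] <- s
      man[[length(man) + 1L]] <- tibble(
        segment_id = sprintf("%s_c%02d",
                             sub("\\.wav$", "",
                                 basename(index$audio_path[[i]])),
                             s$cycle_index),
        audio_path = index$audio_path[[i]],
        cycle_index = s$cycle_index,
        diagnosis = index$diagnosis[[i]],
        label = s$label)
    }
  }
  list(segments = segments, manifest = dplyr::bind_rows(man))
}
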