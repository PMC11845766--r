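# Reading and writing lung-sound corpora in the ICBHI-2017 on-disk layout:
# one .wav per recording, a tab-separated annotation .txt with one line per
# respiratory cycle (start s, end s, crackle flag, wheeze flag), filenames
# encoding patient/location/mode/equipment, and one patient-diagnosis table.

#' Parse respiratory-cycle annotations
#'
#' Each non-empty line of an ICBHI annotation file holds four
#' whitespace-separated fields: cycle start (s), cycle end (s), a 0/1
#' crackle flag and a 0/1 wheeze flag.
#'
#' @param text Annotation-file contents as a single string, or a character
#'   vector of lines.
#' @return A tibble with columns `start_s`, `end_s`, `crackle`, `wheeze`,
#'   one row per annotated cycle, in file order.
#' @export
parse_cycle_annotations <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  keep <- which(nzchar(trimws(lines)))
  out <- tibble(start_s = numeric(0), end_s = numeric(0),
                crackle = logical(0), wheeze = logical(0))
  if (!length(keep)) return(out)
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    ln <- keep[j]
    fields <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
    if (length(fields) != 4L) {
      abort(paste0("expected 4 fields, got ", length(fields),
                   " at line ", ln))
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals) || !all(is.finite(vals))) {
      abort(paste0("non-numeric field at line ", ln))
    }
    if (!vals[3] %in% c(0, 1) || !vals[4] %in% c(0, 1)) {
      abort(paste0("crackle/wheeze flag not 0/1 at line ", ln))
    }
    if (vals[1] < 0) abort(paste0("negative start time at line ", ln))
    if (vals[2] <= vals[1]) abort(paste0("end before start at line ", ln))
    rows[[j]] <- vals
  }
  m <- do.call(rbind, rows)
  tibble(start_s = m[, 1], end_s = m[, 2],
         crackle = m[, 3] == 1, wheeze = m[, 4] == 1)
}

#' Write respiratory-cycle annotations
#'
#' Inverse of [parse_cycle_annotations()]: formats cycles as tab-separated
#' lines with times printed to millisecond precision.
#'
#' @param cycles Tibble/data frame with `start_s`, `end_s`, `crackle`,
#'   `wheeze`.
#' @return File contents as a single string (possibly empty).
#' @export
write_annotation_file <- function(cycles) {
  if (!nrow(cycles)) return("")
  stopifnot(all(c("start_s", "end_s", "crackle", "wheeze") %in%
                  names(cycles)))
  if (any(!is.finite(cycles$start_s)) || any(!is.finite(cycles$end_s)) ||
      any(cycles$end_s <= cycles$start_s) || any(cycles$start_s < 0)) {
    abort("invalid cycle annotation (need finite 0 <= start < end)")
  }
  paste0(paste(sprintf("%.3f", cycles$start_s),
               sprintf("%.3f", cycles$end_s),
               as.integer(cycles$crackle),
               as.integer(cycles$wheeze), sep = "\t"),
         collapse = "\n") |> paste0("\n")
}

#' Parse an ICBHI recording filename
#'
#' ICBHI names encode five fields:
#' `patientId_token_chestLocation_mode_equipment.wav`.
#'
#' @param name Filename or path.
#' @return One-row tibble with `patient_id`, `recording_token`,
#'   `chest_location`, `acquisition_mode`, `equipment` (diagnosis unset).
#' @export
parse_recording_filename <- function(name) {
  base <- sub("\\.wav$", "", basename(name), ignore.case = TRUE)
  tok <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(tok) != 5L) {
    abort(paste0("recording name '", basename(name),
                 "' does not have 5 underscore-separated fields"))
  }
  pid <- suppressWarnings(as.integer(tok[1]))
  if (is.na(pid) || pid < 0) {
    abort(paste0("non-integer patient id in '", basename(name), "'"))
  }
  tibble(patient_id = pid, recording_token = tok[2], chest_location = tok[3],
         acquisition_mode = tok[4], equipment = tok[5])
}

#' Load a patient-diagnosis table
#'
#' Two-column delimited text mapping patient id to one of the six diagnosis
#' labels; the separator (tab or comma) is auto-detected and labels are
#' matched case-insensitively, then canonicalized.
#'
#' @param text Table contents as a single string or character vector of
#'   lines, or a path to an existing file.
#' @return Named character vector: diagnosis label keyed by patient id.
#' @export
load_diagnosis_table <- function(text) {
  if (length(text) == 1L && !grepl("[\n,\t]", text) && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  lines <- if (length(text) == 1L) strsplit(text, "\r?\n")[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  out <- character(0)
  for (i in seq_along(lines)) {
    sep <- if (grepl(",", lines[i], fixed = TRUE)) "," else "[ \t]+"
    fields <- trimws(strsplit(trimws(lines[i]), sep)[[1]])
    if (length(fields) != 2L) {
      abort(paste0("expected 'patient_id<sep>label' at line ", i))
    }
    pid <- suppressWarnings(as.integer(fields[1]))
    if (is.na(pid)) abort(paste0("non-integer patient id at line ", i))
    hit <- match(tolower(fields[2]), tolower(DIAGNOSIS_LEVELS))
    if (is.na(hit)) abort(paste0("unknown label ", fields[2]))
    label <- DIAGNOSIS_LEVELS[hit]
    key <- as.character(pid)
    if (key %in% names(out) && out[[key]] != label) {
      abort(paste0("conflicting labels for patient ", pid, ": ",
                   out[[key]], " vs ", label))
    }
    out[[key]] <- label
  }
  out
}

#' Index a lung-sound corpus directory
#'
#' Scans `root` for paired `.wav`/`.txt` files and a diagnosis table
#' (any `*.csv`/`*diagnosis*.txt` two-column file), parses filenames and
#' annotations, and assembles a dataset index. Recordings with a missing
#' annotation file, unreadable audio, an unparsable name, or an unknown
#' patient are skipped with a warning; the index is sorted by filename so
#' repeated runs are identical.
#'
#' @param root Corpus directory.
#' @param diagnosis_file Optional explicit path to the diagnosis table.
#' @param quiet Suppress the summary message.
#' @return A tibble of class `dataset_index`, one row per recording, with
#'   columns `audio_path`, `annotation_path`, the filename metadata,
#'   `diagnosis`, `class_code` and a list-column `cycles` of per-cycle
#'   annotation tibbles.
#' @export
index_dataset <- function(root, diagnosis_file = NULL, quiet = FALSE) {
  if (!dir.exists(root)) abort(paste0("no such directory: ", root))
  wavs <- sort(list.files(root, pattern = "\\.wav$", ignore.case = TRUE,
                          full.names = TRUE))
  if (is.null(diagnosis_file)) {
    cand <- sort(c(
      list.files(root, pattern = "\\.csv$", full.names = TRUE),
      list.files(root, pattern = "diagnosis.*\\.txt$", ignore.case = TRUE,
                 full.names = TRUE)))
    if (!length(cand)) abort("no diagnosis table found under root")
    diagnosis_file <- cand[[1]]
  }
  diagnosis <- load_diagnosis_table(diagnosis_file)

  rows <- list()
  for (w in wavs) {
    ann <- sub("\\.wav$", ".txt", w, ignore.case = TRUE)
    meta <- tryCatch(parse_recording_filename(w), error = function(e) {
      warn(paste0("skipping ", basename(w), ": ", conditionMessage(e)))
      NULL
    })
    if (is.null(meta)) next
    if (!file.exists(ann)) {
      warn(paste0("skipping ", basename(w), ": no annotation file"))
      next
    }
    label <- diagnosis[[as.character(meta$patient_id)]]
    if (is.null(label)) {
      warn(paste0("skipping ", basename(w), ": patient ", meta$patient_id,
                  " not in diagnosis table"))
      next
    }
    cycles <- tryCatch(
      parse_cycle_annotations(readLines(ann, warn = FALSE)),
      error = function(e) {
        warn(paste0("skipping ", basename(w), ": ", conditionMessage(e)))
        NULL
      })
    if (is.null(cycles)) next
    hdr <- tryCatch(read_wav(w), error = function(e) {
      warn(paste0("skipping ", basename(w), ": unreadable audio (",
                  conditionMessage(e), ")"))
      NULL
    })
    if (is.null(hdr)) next
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      meta,
      audio_path = w, annotation_path = ann,
      diagnosis = label, class_code = diagnosis_code(label),
      rate = hdr$rate, n_samples = length(hdr$samples),
      cycles = list(cycles))
  }
  if (!length(rows)) abort("no records under root")
  idx <- dplyr::bind_rows(rows)
  idx <- idx[, c("audio_path", "annotation_path", "patient_id",
                 "recording_token", "chest_location", "acquisition_mode",
                 "equipment", "diagnosis", "class_code", "rate",
                 "n_samples", "cycles")]
  class(idx) <- c("dataset_index", class(idx))
  if (!quiet) inform(format_index_summary(idx))
  idx
}

#' Summarize a dataset index
#'
#' @param index A `dataset_index` tibble.
#' @return A list with `n_recordings`, `n_cycles`, `n_crackle`, `n_wheeze`,
#'   `n_both` and a per-class count tibble.
#' @export
index_summary <- function(index) {
  all_cycles <- dplyr::bind_rows(index$cycles)
  per_class <- dplyr::count(as_tibble(index), .data$diagnosis,
                            name = "n_recordings")
  list(
    n_recordings = nrow(index),
    n_cycles = nrow(all_cycles),
    n_crackle = sum(all_cycles$crackle),
    n_wheeze = sum(all_cycles$wheeze),
    n_both = sum(all_cycles$crackle & all_cycles$wheeze),
    per_class = per_class
  )
}

format_index_summary <- function(index) {
  s <- index_summary(index)
  paste0("indexed ", s$n_recordings, " recordings, ", s$n_cycles,
         " cycles (", s$n_crackle, " crackle, ", s$n_wheeze, " wheeze, ",
         s$n_both, " both); classes: ",
         paste0(s$per_class$diagnosis, "=", s$per_class$n_recordings,
                collapse = ", "))
}

#' Export a dataset index as JSON lines
#'
#' One JSON object per recording, cycles inlined.
#'
#' @param index A `dataset_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index_jsonl <- function(index, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(index))) {
    rec <- as.list(as_tibble(index)[i, ])
    rec$cycles <- rec$cycles[[1]]
    writeLines(jsonlite::toJSON(rec, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(path)
}
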