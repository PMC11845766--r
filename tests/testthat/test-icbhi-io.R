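# Corpus reader/writer: annotation parsing, filename metadata, diagnosis
# table, directory indexing, and the wav round trip.

test_that("cycle annotations parse field-by-field and preserve order", {
  cyc <- parse_cycle_annotations("0.036\t0.579\t0\t0")
  expect_equal(nrow(cyc), 1L)
  expect_equal(cyc$start_s, 0.036)
  expect_equal(cyc$end_s, 0.579)
  expect_false(cyc$crackle)
  expect_false(cyc$wheeze)

  multi <- parse_cycle_annotations("0.0\t1.5\t1\t0\n1.5\t3.2\t0\t1\n")
  expect_equal(multi$start_s, c(0, 1.5))
  expect_equal(multi$crackle, c(TRUE, FALSE))
  expect_equal(multi$wheeze, c(FALSE, TRUE))

  expect_equal(nrow(parse_cycle_annotations("")), 0L)
})

test_that("malformed annotation lines are rejected with the line number", {
  expect_error(parse_cycle_annotations("1.0\t0.5\t0\t1"),
               "end before start at line 1")
  expect_error(parse_cycle_annotations("0.0\t1.0\t0\t1\n2.0\t1.0\t0\t0"),
               "line 2")
  expect_error(parse_cycle_annotations("0.0\t1.0\t0"), "4 fields")
  expect_error(parse_cycle_annotations("a\tb\t0\t0"), "non-numeric")
  expect_error(parse_cycle_annotations("0.0\t1.0\t2\t0"), "flag")
})

test_that("annotation writing inverts parsing (round trip at 1 ms)", {
  one <- tibble::tibble(start_s = 0, end_s = 2.5, crackle = TRUE,
                        wheeze = FALSE)
  expect_equal(write_annotation_file(one), "0.000\t2.500\t1\t0\n")
  expect_equal(write_annotation_file(one[0, ]), "")

  cyc <- random_cycles(100, seed = 7)
  back <- parse_cycle_annotations(write_annotation_file(cyc))
  expect_equal(back$start_s, cyc$start_s, tolerance = 1e-3)
  expect_equal(back$end_s, cyc$end_s, tolerance = 1e-3)
  expect_equal(back$crackle, cyc$crackle)
  expect_equal(back$wheeze, cyc$wheeze)

  expect_error(write_annotation_file(
    tibble::tibble(start_s = 2, end_s = 1, crackle = FALSE,
                   wheeze = FALSE)), "invalid")
})

test_that("recording filenames decompose into the five metadata fields", {
  meta <- parse_recording_filename("101_1b1_Al_sc_Meditron.wav")
  expect_equal(meta$patient_id, 101L)
  expect_equal(meta$recording_token, "1b1")
  expect_equal(meta$chest_location, "Al")
  expect_equal(meta$acquisition_mode, "sc")
  expect_equal(meta$equipment, "Meditron")

  expect_equal(parse_recording_filename("7_2a_Pl_mc_AKGC417L.wav")$patient_id,
               7L)
  expect_error(parse_recording_filename("badname.wav"), "5 underscore")
})

test_that("diagnosis tables accept tab or comma and reject bad labels", {
  expect_equal(load_diagnosis_table("101\tCOPD"), c("101" = "COPD"))
  two <- load_diagnosis_table("101,COPD\n102,Healthy")
  expect_equal(length(two), 2L)
  expect_equal(two[["102"]], "Healthy")
  # case-insensitive match, canonical spelling out
  expect_equal(load_diagnosis_table("5,copd")[["5"]], "COPD")
  expect_error(load_diagnosis_table("101\tFlu"), "unknown label Flu")
  expect_error(load_diagnosis_table("101,COPD\n101,Healthy"), "conflicting")
})

test_that("wav files round-trip through the PCM writer and reader", {
  x <- tone_segment(200, amp = 0.8, rate = 4000L, dur_s = 2)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 4000L, path)
  back <- read_wav(path)
  expect_equal(back$rate, 4000L)
  expect_equal(length(back$samples), length(x))
  expect_lt(max(abs(back$samples - x)), 1 / 32767 + 1e-9)
})

test_that("indexing a generated corpus finds every recording", {
  fx <- fixture_corpus()
  idx <- index_dataset(fx$dir, quiet = TRUE)
  expect_s3_class(idx, "dataset_index")
  expect_equal(nrow(idx), 6L)
  expect_setequal(idx$diagnosis, diagnosis_labels())
  # order-stable: sorted by filename, identical across calls
  idx2 <- index_dataset(fx$dir, quiet = TRUE)
  expect_identical(idx$audio_path, sort(idx$audio_path))
  expect_identical(idx$audio_path, idx2$audio_path)
  # summary counts agree with the parsed annotations
  s <- index_summary(idx)
  all_cycles <- dplyr::bind_rows(idx$cycles)
  expect_equal(s$n_cycles, nrow(all_cycles))
  expect_equal(s$n_crackle, sum(all_cycles$crackle))
})

test_that("orphan wavs are skipped with a warning, empty roots error", {
  dir <- withr::local_tempdir()
  expect_error(index_dataset(dir), "no diagnosis table")
  writeLines("1,COPD", file.path(dir, "diagnosis.csv"))
  expect_error(index_dataset(dir, quiet = TRUE), "no records")
  # orphan wav: no annotation file
  write_wav(tone_segment(100, rate = 4000L, dur_s = 1), 4000L,
            file.path(dir, "1_1a_Al_sc_X.wav"))
  expect_error(expect_warning(index_dataset(dir, quiet = TRUE),
                              "no annotation"), "no records")
  # add the annotation: one usable record
  writeLines("0.0\t0.8\t0\t0", file.path(dir, "1_1a_Al_sc_X.txt"))
  idx <- index_dataset(dir, quiet = TRUE)
  expect_equal(nrow(idx), 1L)
})

test_that("index export writes one JSON line per recording", {
  fx <- fixture_corpus()
  idx <- index_dataset(fx$dir, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_index_jsonl(idx, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(idx))
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("audio_path", "diagnosis", "cycles") %in% names(rec)))
})
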