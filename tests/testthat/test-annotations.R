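tsv_lines <- function(df) {
  c(paste(names(df), collapse = "\t"),
    apply(df, 1, paste, collapse = "\t"))
}

seven_syllables <- function() {
  onsets <- seq(100, 1900, by = 300)
  data.frame(label = sprintf("syl%d", 1:7),
             syllable_onset_ms = onsets - 30,
             nucleus_onset_ms = onsets,
             nucleus_end_ms = onsets + 90,
             weight = rep(c("strong", "weak"), length.out = 7),
             nucleus_type = c(rep("vowel", 6), "sonorant"),
             stringsAsFactors = FALSE)
}

test_that("TSV annotations load into a validated stimulus", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tsv_lines(seven_syllables()), path)
  stim <- read_annotation(path, format = "tsv", stimulus_id = "s01",
                          duration_ms = 2100)
  expect_s3_class(stim, "sentence_stimulus")
  expect_equal(nrow(stim$syllables), 7L)
  expect_equal(stim$duration_ms, 2100)
  expect_equal(stim$n_repetitions, 10L)
  expect_equal(stim$pause_ms, 400)
  expect_equal(stim$first_analyzed_repetition, 3L)
})

test_that("annotation invariants reject malformed syllable tiers", {
  syl <- seven_syllables()
  bad <- syl
  bad$nucleus_end_ms[3] <- bad$nucleus_onset_ms[3] - 10
  expect_error(syllable_annotations(bad),
               class = "speechsync_validation_error")
  bad <- syl
  bad$weight[1] <- "medium"
  expect_error(syllable_annotations(bad),
               class = "speechsync_validation_error")
  bad <- syl
  bad$nucleus_end_ms[2] <- bad$nucleus_onset_ms[3] + 50  # overlap
  expect_error(syllable_annotations(bad),
               class = "speechsync_validation_error")
  expect_error(sentence_stimulus("x", 500, syl),  # onsets beyond duration
               class = "speechsync_validation_error")
})

write_demo_textgrid <- function(path) {
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "xmin = 0", "xmax = 1.2",
    "tiers? <exists>", "size = 2", "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    '        name = "syllable"',
    "        xmin = 0", "        xmax = 1.2",
    "        intervals: size = 4",
    "        intervals [1]:",
    "            xmin = 0", "            xmax = 0.32",
    '            text = "the"',
    "        intervals [2]:",
    "            xmin = 0.32", "            xmax = 0.70",
    '            text = "stars"',
    "        intervals [3]:",
    "            xmin = 0.70", "            xmax = 1.05",
    '            text = "twin"',
    "        intervals [4]:",
    "            xmin = 1.05", "            xmax = 1.2",
    '            text = ""',
    "    item [2]:",
    '        class = "IntervalTier"',
    '        name = "nucleus"',
    "        xmin = 0", "        xmax = 1.2",
    "        intervals: size = 6",
    "        intervals [1]:",
    "            xmin = 0", "            xmax = 0.05",
    '            text = ""',
    "        intervals [2]:",
    "            xmin = 0.05", "            xmax = 0.13",
    '            text = "weak-vowel"',
    "        intervals [3]:",
    "            xmin = 0.13", "            xmax = 0.35",
    '            text = ""',
    "        intervals [4]:",
    "            xmin = 0.35", "            xmax = 0.47",
    '            text = "strong-vowel"',
    "        intervals [5]:",
    "            xmin = 0.47", "            xmax = 0.80",
    '            text = ""',
    "        intervals [6]:",
    "            xmin = 0.80", "            xmax = 0.92",
    '            text = "weak-sonorant"')
  writeLines(lines, path)
}

test_that("TextGrid annotations convert seconds to ms and pair tiers", {
  path <- withr::local_tempfile(fileext = ".TextGrid")
  write_demo_textgrid(path)
  stim <- read_annotation(path, format = "textgrid", stimulus_id = "tg1")
  expect_equal(stim$duration_ms, 1200)
  expect_equal(stim$syllables$nucleus_onset_ms, c(50, 350, 800))
  expect_equal(stim$syllables$nucleus_end_ms, c(130, 470, 920))
  expect_equal(stim$syllables$label, c("the", "stars", "twin"))
  expect_equal(stim$syllables$weight, c("weak", "strong", "weak"))
  expect_equal(stim$syllables$nucleus_type, c("vowel", "vowel", "sonorant"))
})

test_that("TextGrid read then TSV write yields ms = 1000 x seconds", {
  tg_path <- withr::local_tempfile(fileext = ".TextGrid")
  write_demo_textgrid(tg_path)
  stim <- read_annotation(tg_path, format = "textgrid")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tsv(stim, tsv_path)
  back <- read_annotation(tsv_path, format = "tsv", duration_ms = 1200)
  expect_equal(back$syllables$nucleus_onset_ms,
               1000 * c(0.05, 0.35, 0.80))
  expect_equal(back$syllables, stim$syllables)
})
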