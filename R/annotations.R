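#' Validate a syllable-annotation table
#'
#' Each row is one syllable of a sentence: its label, syllable onset, the
#' onset and end of its nucleus (the sonority peak a tap is expected to
#' align with), the metrical weight of the syllable (strong = stressed,
#' weak = unstressed) and the nucleus type (vowel, or a syllabic sonorant
#' in some weak syllables). All times in milliseconds from sentence onset.
#'
#' @param syllables `data.frame` with columns `label`, `syllable_onset_ms`,
#'   `nucleus_onset_ms`, `nucleus_end_ms`, `weight`, `nucleus_type`.
#' @return The validated table, ordered by nucleus onset.
#' @export
syllable_annotations <- function(syllables) {
  req <- c("label", "syllable_onset_ms", "nucleus_onset_ms",
           "nucleus_end_ms", "weight", "nucleus_type")
  missing_cols <- setdiff(req, names(syllables))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf("annotation lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  s <- syllables[order(syllables$nucleus_onset_ms), req, drop = FALSE]
  rownames(s) <- NULL
  if (any(!s$weight %in% c("strong", "weak"))) {
    stop_validation("metrical weight must be 'strong' or 'weak'")
  }
  if (any(!s$nucleus_type %in% c("vowel", "sonorant"))) {
    stop_validation("nucleus type must be 'vowel' or 'sonorant'")
  }
  if (any(s$nucleus_end_ms <= s$nucleus_onset_ms)) {
    stop_validation("each nucleus must have positive duration (end > onset)")
  }
  if (any(s$syllable_onset_ms > s$nucleus_onset_ms)) {
    stop_validation("syllable onset must not follow its nucleus onset")
  }
  if (nrow(s) > 1L) {
    overlap <- s$nucleus_onset_ms[-1L] < s$nucleus_end_ms[-nrow(s)]
    if (any(overlap)) stop_validation("syllable nuclei overlap in time")
  }
  s
}

#' Construct a sentence stimulus
#'
#' Bundles the syllable tier of one recorded sentence with the loop
#' parameters of the synchronization task: the sentence is played
#' `n_repetitions` times separated by `pause_ms` of silence, and taps are
#' analysed from `first_analyzed_repetition` onwards.
#'
#' @param stimulus_id Identifier.
#' @param duration_ms Sentence duration in ms.
#' @param syllables Syllable table accepted by [syllable_annotations()].
#' @param n_repetitions Loop length (default 10).
#' @param pause_ms Inter-repetition silence (default 400).
#' @param first_analyzed_repetition First repetition entering analysis
#'   (default 3; participants start tapping at the third repetition).
#' @return Object of class `sentence_stimulus`.
#' @export
sentence_stimulus <- function(stimulus_id, duration_ms, syllables,
                              n_repetitions = 10, pause_ms = 400,
                              first_analyzed_repetition = 3) {
  assert_number(duration_ms, "duration_ms", lower = 0)
  assert_number(pause_ms, "pause_ms", lower = 0)
  assert_number(n_repetitions, "n_repetitions", lower = 1)
  assert_number(first_analyzed_repetition, "first_analyzed_repetition",
                lower = 1, upper = n_repetitions)
  syl <- syllable_annotations(syllables)
  if (any(syl$nucleus_onset_ms < 0 | syl$nucleus_onset_ms > duration_ms)) {
    stop_validation("all nucleus onsets must lie within [0, duration_ms]")
  }
  structure(list(stimulus_id = as.character(stimulus_id),
                 duration_ms = as.numeric(duration_ms),
                 syllables = syl,
                 n_repetitions = as.integer(n_repetitions),
                 pause_ms = as.numeric(pause_ms),
                 first_analyzed_repetition = as.integer(first_analyzed_repetition)),
            class = "sentence_stimulus")
}

#' @export
print.sentence_stimulus <- function(x, ...) {
  cat(sprintf("<sentence_stimulus '%s'>: %.0f ms, %d syllables, %dx loop (%g ms pause), analysed from repetition %d\n",
              x$stimulus_id, x$duration_ms, nrow(x$syllables),
              x$n_repetitions, x$pause_ms, x$first_analyzed_repetition))
  invisible(x)
}

#' Read a sentence annotation
#'
#' Two formats are supported. TSV: tab-separated with columns `label`,
#' `syllable_onset_ms`, `nucleus_onset_ms`, `nucleus_end_ms`, `weight`,
#' `nucleus_type`, times in ms. TextGrid (Praat long text format, times in
#' seconds, converted to ms): an interval tier named `syllable` whose
#' non-empty intervals carry the syllable labels, and an interval tier named
#' `nucleus` whose non-empty intervals delimit each nucleus and are labelled
#' `weight-type` (e.g. `strong-vowel`, `weak-sonorant`). Each nucleus is
#' assigned to the syllable interval containing its onset.
#'
#' @param path Annotation file.
#' @param format `"tsv"` or `"textgrid"`.
#' @param stimulus_id Identifier for the resulting stimulus; defaults to the
#'   file name without extension.
#' @param duration_ms Sentence duration; defaults to the TextGrid's `xmax`
#'   (converted to ms) or, for TSV, the last nucleus end.
#' @param ... Passed to [sentence_stimulus()] (loop parameters).
#' @return A [sentence_stimulus()].
#' @export
read_annotation <- function(path, format = c("tsv", "textgrid"),
                            stimulus_id = NULL, duration_ms = NULL, ...) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("annotation not found: %s", path))
  stimulus_id <- stimulus_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "tsv") {
    syl <- utils::read.delim(path, stringsAsFactors = FALSE)
    dur <- duration_ms %||% max(syl$nucleus_end_ms)
  } else {
    tg <- read_textgrid(path)
    tiers <- vapply(tg$tiers, `[[`, "", "name")
    for (nm in c("syllable", "nucleus")) {
      if (!nm %in% tiers) {
        stop_format(sprintf("TextGrid %s lacks interval tier '%s'", path, nm))
      }
    }
    syl_tier <- tg$tiers[[match("syllable", tiers)]]$intervals
    nuc_tier <- tg$tiers[[match("nucleus", tiers)]]$intervals
    syl_tier <- syl_tier[nzchar(trimws(syl_tier$label)), , drop = FALSE]
    nuc_tier <- nuc_tier[nzchar(trimws(nuc_tier$label)), , drop = FALSE]
    parts <- strsplit(trimws(nuc_tier$label), "-", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) {
      stop_validation(sprintf("nucleus label '%s' is not of the form weight-type",
                              nuc_tier$label[which(bad)[1L]]))
    }
    # attach each nucleus to the syllable interval containing its onset
    syl_onset <- vapply(nuc_tier$xmin, function(t) {
      i <- which(syl_tier$xmin <= t & t < syl_tier$xmax)
      if (length(i) != 1L) {
        stop_validation(sprintf(
          "nucleus at %.3f s is not inside exactly one syllable interval", t))
      }
      syl_tier$xmin[i]
    }, numeric(1))
    labels <- vapply(nuc_tier$xmin, function(t) {
      i <- which(syl_tier$xmin <= t & t < syl_tier$xmax)
      trimws(syl_tier$label[i])
    }, character(1))
    syl <- data.frame(label = labels,
                      syllable_onset_ms = 1000 * syl_onset,
                      nucleus_onset_ms = 1000 * nuc_tier$xmin,
                      nucleus_end_ms = 1000 * nuc_tier$xmax,
                      weight = vapply(parts, `[[`, "", 1L),
                      nucleus_type = vapply(parts, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
    dur <- duration_ms %||% (1000 * tg$xmax)
  }
  sentence_stimulus(stimulus_id, dur, syl, ...)
}

#' Write a stimulus annotation as TSV
#'
#' Inverse of `read_annotation(format = "tsv")` for the syllable tier.
#'
#' @param stimulus A [sentence_stimulus()].
#' @param path Output path.
#' @export
write_annotation_tsv <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "sentence_stimulus"))
  utils::write.table(stimulus$syllables, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Minimal reader for Praat's long ("text") TextGrid format, interval tiers
# only. Returns list(xmin, xmax, tiers = list(list(name, intervals))).
read_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  num_after <- function(pattern, from = 1L, to = length(lines)) {
    i <- grep(pattern, lines[from:to])
    if (length(i) == 0L) return(numeric(0))
    as.numeric(sub(".*=\\s*", "", lines[from:to][i]))
  }
  get_field <- function(line) sub(".*=\\s*", "", line)
  if (!any(grepl("ooTextFile", lines))) {
    stop_format(sprintf("%s does not look like a Praat TextGrid", path))
  }
  tier_starts <- grep("^\\s*item\\s*\\[\\d+\\]", lines)
  if (length(tier_starts) == 0L) stop_format("TextGrid contains no tiers")
  xmax_global <- num_after("^\\s*xmax", to = tier_starts[1L])[1L]
  xmin_global <- num_after("^\\s*xmin", to = tier_starts[1L])[1L]
  bounds <- c(tier_starts, length(lines) + 1L)
  tiers <- vector("list", length(tier_starts))
  for (k in seq_along(tier_starts)) {
    block <- lines[tier_starts[k]:(bounds[k + 1L] - 1L)]
    cls <- grep("^\\s*class\\s*=", block, value = TRUE)
    name_line <- grep("^\\s*name\\s*=", block, value = TRUE)
    name <- gsub('"', "", trimws(get_field(name_line[1L])))
    if (length(cls) > 0L && !grepl("IntervalTier", cls[1L])) {
      tiers[[k]] <- list(name = name,
                         intervals = data.frame(xmin = numeric(0),
                                                xmax = numeric(0),
                                                label = character(0)))
      next
    }
    int_starts <- grep("^\\s*intervals\\s*\\[\\d+\\]", block)
    xmin <- xmax <- numeric(length(int_starts))
    label <- character(length(int_starts))
    int_bounds <- c(int_starts, length(block) + 1L)
    for (j in seq_along(int_starts)) {
      piece <- block[int_starts[j]:(int_bounds[j + 1L] - 1L)]
      xmin[j] <- as.numeric(get_field(grep("^\\s*xmin", piece, value = TRUE)[1L]))
      xmax[j] <- as.numeric(get_field(grep("^\\s*xmax", piece, value = TRUE)[1L]))
      lab <- get_field(grep("^\\s*text\\s*=", piece, value = TRUE)[1L])
      label[j] <- gsub('"', "", trimws(lab))
    }
    tiers[[k]] <- list(name = name,
                       intervals = data.frame(xmin = xmin, xmax = xmax,
                                              label = label,
                                              stringsAsFactors = FALSE))
  }
  list(xmin = xmin_global, xmax = xmax_global, tiers = tiers)
}
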