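#' Column mapping for tabular tap logs
#'
#' Tap logs are long-format delimited tables with one row per detected tap.
#' The dialect maps the package's canonical column names onto whatever the
#' acquisition software wrote, and fixes the field separator and the
#' duplicate-collapse window (piezo sensors double-trigger within ~1 ms).
#'
#' @param participant,task,stimulus,time Column names in the file.
#' @param sep Field separator (`","` or `"\t"`).
#' @param dedup_ms Taps closer than this (per participant x task x stimulus)
#'   are collapsed to the earliest one. Default 1 ms.
#' @return A named list used by [read_tap_log()].
#' @export
tap_log_dialect <- function(participant = "participant_id", task = "task",
                            stimulus = "stimulus_id", time = "time_ms",
                            sep = ",", dedup_ms = 1) {
  assert_number(dedup_ms, "dedup_ms", lower = 0)
  list(participant = participant, task = task, stimulus = stimulus,
       time = time, sep = sep, dedup_ms = dedup_ms)
}

#' Read and validate a tap log
#'
#' Reads a delimited tap log, checks the schema declared in `dialect`,
#' coerces times to numeric milliseconds, sorts within each
#' (participant, task, stimulus) series and collapses duplicate timestamps
#' closer than `dialect$dedup_ms`.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param dialect A [tap_log_dialect()].
#' @return A `data.frame` with columns `participant_id`, `task`,
#'   `stimulus_id`, `time_ms`, sorted and deduplicated.
#' @export
read_tap_log <- function(path, dialect = tap_log_dialect()) {
  if (!file.exists(path)) stop_format(sprintf("tap log not found: %s", path))
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE)
  needed <- c(participant = dialect$participant, task = dialect$task,
              stimulus = dialect$stimulus, time = dialect$time)
  missing_cols <- setdiff(unname(needed), names(raw))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf("tap log %s lacks required column(s): %s",
                        path, paste(missing_cols, collapse = ", ")))
  }
  time_chr <- raw[[dialect$time]]
  time_num <- suppressWarnings(as.numeric(time_chr))
  bad <- which(is.na(time_num) & !is.na(time_chr))
  if (length(bad) > 0L) {
    # +1 for the header line
    stop_format(sprintf("non-numeric time value '%s' in %s at line %d",
                        time_chr[bad[1L]], path, bad[1L] + 1L))
  }
  taps <- data.frame(participant_id = raw[[dialect$participant]],
                     task = raw[[dialect$task]],
                     stimulus_id = raw[[dialect$stimulus]],
                     time_ms = time_num,
                     stringsAsFactors = FALSE)
  validate_tap_events(taps, dedup_ms = dialect$dedup_ms)
}

#' Validate a tap-event table
#'
#' Enforces the tap-event contract: known task labels, non-negative times,
#' strictly increasing times per series after collapsing near-duplicates.
#'
#' @param taps `data.frame` with `participant_id`, `task`, `stimulus_id`,
#'   `time_ms`.
#' @param dedup_ms Collapse window in ms; successive taps in a series closer
#'   than this are merged into the earliest.
#' @return The validated, sorted, deduplicated `data.frame`.
#' @export
validate_tap_events <- function(taps, dedup_ms = 1) {
  req <- c("participant_id", "task", "stimulus_id", "time_ms")
  missing_cols <- setdiff(req, names(taps))
  if (length(missing_cols) > 0L) {
    stop_format(sprintf("tap table lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(taps$time_ms))) stop_validation("tap times contain NA")
  if (any(taps$time_ms < 0)) stop_validation("tap times must be >= 0")
  unknown <- setdiff(unique(taps$task), sms_tasks())
  if (length(unknown) > 0L) {
    stop_validation(sprintf("unknown task label(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  taps <- taps[order(taps$participant_id, taps$task, taps$stimulus_id,
                     taps$time_ms), , drop = FALSE]
  key <- interaction(taps$participant_id, taps$task, taps$stimulus_id,
                     drop = TRUE)
  keep <- unlist(lapply(split(taps$time_ms, key), function(t) {
    if (length(t) <= 1L) return(rep(TRUE, length(t)))
    k <- logical(length(t))
    last <- -Inf
    for (i in seq_along(t)) {
      if (t[i] - last >= dedup_ms) {
        k[i] <- TRUE
        last <- t[i]
      }
    }
    k
  }), use.names = FALSE)
  # split() regroups rows; rebuild the keep mask in original row order
  ord <- order(key)
  mask <- logical(nrow(taps))
  mask[ord] <- keep
  out <- taps[mask, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a results table to CSV
#'
#' Round-trip safe with [read_results()] to 1e-9 relative tolerance:
#' numeric columns are written at full precision.
#'
#' @param table Non-empty `data.frame`.
#' @param path Output path.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop_validation("results table must be a non-empty data.frame")
  }
  out <- table
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      v <- formatC(out[[j]], digits = 17, format = "g")
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return `data.frame` with numeric columns restored.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("results file not found: %s", path))
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_along(out)) {
    if (is.character(out[[j]])) {
      nonmissing <- !is.na(out[[j]])
      num <- suppressWarnings(as.numeric(out[[j]]))
      if (any(nonmissing) && !anyNA(num[nonmissing])) out[[j]] <- num
    }
  }
  out
}
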