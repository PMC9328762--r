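# Trial-level records for urgent pro-/antisaccade tasks.
#
# A trial table is a plain data.frame with one row per trial and (at least)
# the columns documented in `trial_table()`. Derived columns (target side,
# raw processing time, correctness) are always recomputed from the design
# columns so they can never drift out of sync.

.SIDES <- c("L", "R")
.TASKS <- c("pro", "anti")

#' Raw processing time
#'
#' Computes the raw processing time (rPT), the time the cue was visible
#' before the saccade was committed: `rPT = RT - gap`. Negative values are
#' legitimate and indicate a saccade initiated before (or too soon after)
#' cue onset to be informed by it.
#'
#' @param rt_ms Reaction time in ms (go signal to saccade onset). May be
#'   `NA` for aborted trials; `NA` propagates.
#' @param gap_ms Gap in ms between the go signal and cue onset (negative
#'   values = cue before go, i.e. non-urgent trials).
#' @return Numeric vector of rPT values in ms.
#' @export
compute_rpt <- function(rt_ms, gap_ms) {
  stopifnot(is.numeric(rt_ms) || all(is.na(rt_ms)),
            is.numeric(gap_ms))
  if (any(!is.na(rt_ms) & rt_ms < 0)) {
    stop("rt_ms must be nonnegative where defined")
  }
  as.numeric(rt_ms) - as.numeric(gap_ms)
}

#' Target side implied by the task rule
#'
#' For a prosaccade the target is the cue location; for an antisaccade it is
#' the diametrically opposite location.
#'
#' @param task "pro" or "anti" (vectorised).
#' @param cue_side "L" or "R" (vectorised).
#' @return Character vector of target sides ("L"/"R").
#' @export
target_side <- function(task, cue_side) {
  n <- max(length(task), length(cue_side))
  task <- match_task(rep_len(task, n))
  cue_side <- match_side(rep_len(cue_side, n))
  ifelse(task == "pro", cue_side, flip_side(cue_side))
}

flip_side <- function(side) ifelse(side == "L", "R", "L")

match_task <- function(task) {
  task <- as.character(task)
  bad <- !is.na(task) & !(task %in% .TASKS)
  if (any(bad)) stop("task must be 'pro' or 'anti' (got: ",
                     paste(unique(task[bad]), collapse = ", "), ")")
  task
}

match_side <- function(side, allow_na = FALSE) {
  side <- as.character(side)
  bad <- !is.na(side) & !(side %in% .SIDES)
  if (any(bad)) stop("side must be 'L' or 'R' (got: ",
                     paste(unique(side[bad]), collapse = ", "), ")")
  if (!allow_na && anyNA(side)) stop("side must not be NA")
  side
}

#' Score a trial by the direction of the first saccade
#'
#' A trial is correct when the chosen side equals the target side implied by
#' the task rule (toward the cue for pro, away from it for anti). A missing
#' choice (aborted trial) scores `NA`.
#'
#' @param task "pro" or "anti".
#' @param cue_side Cue location, "L" or "R".
#' @param choice_side Side of the first saccade, "L", "R" or `NA`.
#' @return Logical vector: `TRUE` correct, `FALSE` error, `NA` aborted.
#' @export
score_trial <- function(task, cue_side, choice_side) {
  n <- max(length(task), length(cue_side), length(choice_side))
  choice_side <- match_side(rep_len(choice_side, n), allow_na = TRUE)
  choice_side == target_side(rep_len(task, n), rep_len(cue_side, n))
}

#' Assemble and validate a trial table
#'
#' Builds the canonical trial table from design and response variables and
#' recomputes all derived columns. Completed trials are scored and retained
#' even when the reaction time exceeds the task's 425 ms deadline; trials
#' with a missing choice are flagged aborted rather than dropped, so abort
#' rates remain computable.
#'
#' @param participant_id Character labels.
#' @param task "pro"/"anti" per trial.
#' @param block "single_task" or "interleaved".
#' @param luminance "high" or "low".
#' @param gap_ms Integer gap in ms (negative = non-urgent).
#' @param cue_side,choice_side "L"/"R"; `choice_side` may be `NA` (abort).
#' @param rt_ms Reaction time in ms; `NA` for aborts.
#' @param trial_index Optional integer giving presentation order within a
#'   participant/block (required for history conditioning).
#' @return A `data.frame` with the input columns plus derived `target_side`,
#'   `rpt_ms`, `correct` and `aborted`.
#' @export
trial_table <- function(participant_id, task, gap_ms, cue_side, rt_ms,
                        choice_side,
                        block = "single_task", luminance = "high",
                        trial_index = NULL) {
  n <- max(length(task), length(gap_ms), length(cue_side),
           length(rt_ms), length(choice_side))
  task <- match_task(rep_len(task, n))
  cue_side <- match_side(rep_len(cue_side, n))
  choice_side <- match_side(rep_len(choice_side, n), allow_na = TRUE)
  gap_ms <- rep_len(gap_ms, n)
  rt_ms <- rep_len(rt_ms, n)
  if (!all(block %in% c("single_task", "interleaved")))
    stop("block must be 'single_task' or 'interleaved'")
  if (!all(luminance %in% c("high", "low")))
    stop("luminance must be 'high' or 'low'")
  aborted <- is.na(choice_side)
  if (any(!aborted & is.na(rt_ms)))
    stop("rt_ms missing on a non-aborted trial")
  df <- data.frame(
    participant_id = as.character(rep_len(participant_id, n)),
    task = task,
    block = rep_len(as.character(block), n),
    luminance = rep_len(as.character(luminance), n),
    gap_ms = as.numeric(gap_ms),
    cue_side = cue_side,
    target_side = target_side(task, cue_side),
    choice_side = choice_side,
    rt_ms = as.numeric(rt_ms),
    rpt_ms = compute_rpt(rt_ms, gap_ms),
    correct = score_trial(task, cue_side, choice_side),
    aborted = aborted,
    stringsAsFactors = FALSE
  )
  if (!is.null(trial_index)) {
    stopifnot(length(trial_index) == n)
    df$trial_index <- as.integer(trial_index)
  }
  df
}

#' Keep urgent, completed trials
#'
#' Urgent trials are those with `gap_ms >= 0` (cue at or after the go
#' signal). Aborted trials are removed as well. The operation is idempotent.
#'
#' @param trials A trial table.
#' @return The filtered trial table.
#' @export
filter_urgent <- function(trials) {
  stopifnot(is.data.frame(trials), all(c("gap_ms", "aborted") %in% names(trials)))
  trials[!is.na(trials$gap_ms) & trials$gap_ms >= 0 & !trials$aborted, ,
         drop = FALSE]
}

.FILE_COLS <- c("participant_id", "task", "block", "luminance", "gap_ms",
                "cue_side", "target_side", "choice_side", "rt_ms", "rpt_ms",
                "correct", "aborted")

#' Read a trial table from CSV
#'
#' Expects a comma-separated UTF-8 file with one header row; sides coded
#' "L"/"R" and booleans 0/1 (the dialect written by [write_trials()]).
#' Derived columns present in the file are checked for consistency with the
#' design columns; inconsistencies are reported with their row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated trial table.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("participant_id", "task", "gap_ms", "cue_side",
                "choice_side", "rt_ms")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("trial file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  unknown <- setdiff(names(raw), c(.FILE_COLS, "trial_index"))
  if (length(unknown) > 0)
    stop("trial file ", path, " has unknown column(s): ",
         paste(unknown, collapse = ", "))
  num <- function(col) {
    x <- raw[[col]]
    x[x == ""] <- NA
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0)
      stop("unparseable value in column '", col, "' at row ", bad[1])
    out
  }
  chr <- function(col, default = NULL) {
    if (!col %in% names(raw)) return(rep_len(default, nrow(raw)))
    x <- raw[[col]]
    x[x == ""] <- NA
    x
  }
  trials <- trial_table(
    participant_id = chr("participant_id"),
    task = chr("task"),
    block = chr("block", "single_task"),
    luminance = chr("luminance", "high"),
    gap_ms = num("gap_ms"),
    cue_side = chr("cue_side"),
    rt_ms = num("rt_ms"),
    choice_side = chr("choice_side"),
    trial_index = if ("trial_index" %in% names(raw)) num("trial_index")
  )
  # cross-check any derived columns stored in the file
  if ("target_side" %in% names(raw)) {
    stored <- chr("target_side")
    bad <- which(!is.na(stored) & stored != trials$target_side)
    if (length(bad) > 0)
      stop("target_side inconsistent with task/cue_side at row ", bad[1])
  }
  if ("rpt_ms" %in% names(raw)) {
    stored <- num("rpt_ms")
    bad <- which(!is.na(stored) & abs(stored - trials$rpt_ms) > 1e-9)
    if (length(bad) > 0)
      stop("rpt_ms inconsistent with rt_ms - gap_ms at row ", bad[1])
  }
  trials
}

#' Write a trial table to CSV
#'
#' Writes the canonical comma-separated dialect read back by
#' [read_trials()]: sides "L"/"R", booleans 0/1, empty string for `NA`.
#'
#' @param trials A trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  out <- trials[, intersect(c(.FILE_COLS, "trial_index"), names(trials)),
                drop = FALSE]
  out$correct <- ifelse(is.na(out$correct), "", as.integer(out$correct))
  out$aborted <- as.integer(out$aborted)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Per-condition trial counts
#'
#' Summary used for sanity-checking a loaded table: counts per task, gap and
#' participant, plus abort and urgent counts.
#'
#' @param trials A trial table.
#' @return A list of count tables.
#' @export
summarize_trials <- function(trials) {
  list(
    n_trials = nrow(trials),
    n_aborted = sum(trials$aborted),
    n_urgent = nrow(filter_urgent(trials)),
    by_task = table(trials$task),
    by_gap = table(trials$gap_ms),
    by_participant = table(trials$participant_id)
  )
}
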