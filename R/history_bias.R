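# Conditioning performance on the history of prior target locations, and
# quantifying how the guessing-regime chance level relates to the rise
# point of the tachometric curve.
#
# History is defined on TARGET locations (where the response should have
# gone), not on cue locations or on the participant's actual choices. A
# trial preceded (within the conditioning depth) by an aborted trial, or
# lacking enough predecessors in its participant/block run, is left
# unlabeled.

#' Label trials by target-location history
#'
#' For depth `d`, a trial is labeled `"repeat"` when the targets of the `d`
#' preceding trials all equal its own target (patterns AA, AAA, AAAA) and
#' `"switch"` when the `d` preceding targets agree with each other but
#' differ from its own (patterns AB, AAB, AAAB). Any other history, a
#' missing predecessor, or an aborted trial in the lookback window leaves
#' the trial unlabeled (`NA`).
#'
#' @param trials A trial table carrying `trial_index` (presentation order
#'   within each `participant_id` x `block` run; aborted trials included so
#'   the sequence is contiguous).
#' @param depth Trials back to condition on (1, 2 or 3).
#' @return `trials` with an added `history` column
#'   (`"repeat"`/`"switch"`/`NA`) and a `history_pattern` attribute-free
#'   label column `history_depth`.
#' @export
label_history <- function(trials, depth = 1) {
  stopifnot(depth >= 1, depth <= 3)
  if (!"trial_index" %in% names(trials))
    stop("label_history needs a 'trial_index' column giving session order")
  grp <- paste(trials$participant_id, trials$block, sep = "\r")
  ord <- order(grp, trials$trial_index)
  tr <- trials[ord, , drop = FALSE]
  n <- nrow(tr)
  lab <- rep(NA_character_, n)
  tgt <- tr$target_side
  idx <- tr$trial_index
  g <- grp[ord]
  prev_ok <- function(k) {
    # rows whose k-th predecessor exists, is contiguous, same run, not abort
    i <- seq_len(n)
    j <- i - k
    ok <- j >= 1
    ok[ok] <- g[j[ok]] == g[i[ok]] & idx[j[ok]] == idx[i[ok]] - k &
              !tr$aborted[j[ok]]
    ok
  }
  eligible <- !tr$aborted
  same <- matrix(FALSE, n, depth)   # k-th predecessor target == own target
  agree <- rep(TRUE, n)             # predecessors agree among themselves
  for (k in seq_len(depth)) {
    okk <- prev_ok(k)
    eligible <- eligible & okk
    j <- seq_len(n) - k
    same[okk, k] <- tgt[j[okk]] == tgt[okk]
    if (k >= 2) {
      jk <- seq_len(n) - k
      j1 <- seq_len(n) - 1
      agree[okk] <- agree[okk] & (tgt[jk[okk]] == tgt[j1[okk]])
    }
  }
  all_same <- rowSums(same) == depth
  all_diff <- rowSums(same) == 0 & agree
  lab[eligible & all_same] <- "repeat"
  lab[eligible & all_diff] <- "switch"
  # map labels back to the original row order
  out <- trials
  out$history <- NA_character_
  out$history[ord] <- lab
  out$history_depth <- depth
  rownames(out) <- NULL
  out
}

history_pattern <- function(depth, kind) {
  if (kind == "repeat") strrep("A", depth + 1)
  else paste0(strrep("A", depth), "B")
}

#' History-conditioned tachometric analysis
#'
#' Splits one task's urgent trials into repeat and switch history
#' conditions at the given depth, builds the tachometric curve for each,
#' and fits it with the chance parameter FREE (anti: `AL`; pro: `B`), so
#' that the guessing-regime offset induced by the motor bias is measured
#' rather than assumed away. Returns the fitted chance level and rise point
#' per condition.
#'
#' @param trials A trial table (aborts still included; they gate the
#'   labeling, then are excluded from the curves).
#' @param task `"pro"` or `"anti"`.
#' @param depth Trials back (1-3).
#' @param min_bin_n Binning threshold passed to [tachometric()].
#' @param n_restarts Fit restarts.
#' @return List with elements `repeat` and `switch`, each of class
#'   `history_condition`: list with `pattern`, `depth`, `n_trials`,
#'   `curve`, `fit`, `chance_level`, `rise_point_ms`, `low_n` (fewer than
#'   500 trials).
#' @export
conditioned_analysis <- function(trials, task, depth = 1, min_bin_n = 10,
                                 n_restarts = 10) {
  stopifnot(task %in% c("pro", "anti"))
  labeled <- label_history(trials, depth)
  one <- function(kind) {
    sub <- labeled[!is.na(labeled$history) & labeled$history == kind &
                   labeled$task == task, , drop = FALSE]
    sub <- filter_urgent(sub)
    if (nrow(sub) == 0) stop("no ", kind, " trials at depth ", depth)
    curve <- tachometric(sub, min_bin_n = min_bin_n, task = task)
    fit <- if (task == "anti")
      fit_anti(curve, fix_chance = FALSE, n_restarts = n_restarts)
    else
      fit_pro(curve, fix_chance = FALSE, n_restarts = n_restarts)
    structure(list(pattern = history_pattern(depth, kind), depth = depth,
                   n_trials = nrow(sub), curve = curve, fit = fit,
                   chance_level = chance_level(fit),
                   rise_point_ms = rise_point(fit),
                   low_n = nrow(sub) < 500),
              class = "history_condition")
  }
  out <- list(one("repeat"), one("switch"))
  names(out) <- c("repeat", "switch")
  if (out[["repeat"]]$low_n || out[["switch"]]$low_n)
    warning("a history condition has fewer than 500 trials; ",
            "estimates may be unstable")
  out
}

#' @export
print.history_condition <- function(x, ...) {
  cat(sprintf(
    "History condition %s (depth %d): %d trials, chance %.3f, rise %.1f ms%s\n",
    x$pattern, x$depth, x$n_trials, x$chance_level, x$rise_point_ms,
    if (x$low_n) " [low n]" else ""))
  invisible(x)
}

#' Rise-point change per unit of chance level
#'
#' Expresses how much earlier the rise point of the tachometric curve
#' occurs as the guessing-regime chance level increases, as a positive
#' "drop in rise point per full 0-to-1 chance increase" (ms). With two
#' conditions it is the exact ratio of differences,
#' `(rise_a - rise_b) / (chance_b - chance_a)`; with more points it is the
#' slope of a least-absolute-deviations line (negated).
#'
#' @param chance_levels Numeric vector of fitted chance levels.
#' @param rise_points_ms Numeric vector of fitted rise points (ms).
#' @return Drop in rise point (ms) per unit chance.
#' @export
rise_vs_chance_slope <- function(chance_levels, rise_points_ms) {
  stopifnot(length(chance_levels) == length(rise_points_ms),
            length(chance_levels) >= 2)
  if (length(unique(chance_levels)) < 2)
    stop("slope undefined: chance levels are all equal")
  if (length(chance_levels) == 2) {
    return((rise_points_ms[1] - rise_points_ms[2]) /
           (chance_levels[2] - chance_levels[1]))
  }
  # least-absolute-deviations line, initialized at the LS solution
  ls <- stats::coef(stats::lm(rise_points_ms ~ chance_levels))
  lad <- stats::optim(ls, function(ab) {
    sum(abs(rise_points_ms - ab[1] - ab[2] * chance_levels))
  }, method = "Nelder-Mead", control = list(maxit = 2000, reltol = 1e-10))
  unname(-lad$par[2])
}

#' Model bias sweep: chance level versus rise point
#'
#' Simulates sessions of the race model at several lateral-bias values,
#' fits each tachometric curve with the chance parameter free, and relates
#' the fitted chance levels to the fitted rise points via
#' [rise_vs_chance_slope()]. For the antisaccade model the rise point falls
#' as the chance level rises (a bias toward the target location helps the
#' endogenous rescue); for the prosaccade model the rise point is nearly
#' bias-independent.
#'
#' @param params A `race_params` object (its `bias` field is overridden).
#' @param biases Bias values spanning both signs.
#' @param task `"pro"` or `"anti"`.
#' @param n_trials Trials per bias value.
#' @param seed Integer seed; per-bias runs use `seed + index`.
#' @param min_bin_n Binning threshold (default 300; these are large
#'   simulated sessions).
#' @param n_restarts Fit restarts per bias.
#' @return List with `table` (data.frame: bias, chance_level,
#'   rise_point_ms, fit_failed), `slope_ms_per_chance` and `fits`.
#' @export
model_bias_sweep <- function(params, biases, task, n_trials = 50000,
                             seed = NULL, min_bin_n = 300, n_restarts = 6) {
  stopifnot(length(biases) >= 2)
  if (min(biases) > 0 || max(biases) < 0)
    stop("biases must span both signs (or include zero)")
  rows <- list()
  fits <- list()
  for (i in seq_along(biases)) {
    b <- biases[i]
    p <- do.call(race_params,
                 c(list(bias = b, luminance = params$luminance),
                   unclass(params)[setdiff(names(unclass(params)),
                                           c("bias", "luminance"))]))
    tr <- filter_urgent(simulate_session(p, task, n_trials,
                                         seed = if (!is.null(seed)) seed + i))
    curve <- tachometric(tr, min_bin_n = min_bin_n, task = task)
    fit <- tryCatch(
      suppressWarnings(
        if (task == "anti") fit_anti(curve, fix_chance = FALSE,
                                     n_restarts = n_restarts)
        else fit_pro(curve, fix_chance = FALSE, n_restarts = n_restarts)),
      error = function(e) NULL)
    failed <- is.null(fit) || isTRUE(fit$degenerate)
    rows[[i]] <- data.frame(
      bias = b,
      chance_level = if (failed) NA_real_ else chance_level(fit),
      rise_point_ms = if (failed) NA_real_ else rise_point(fit),
      fit_failed = failed)
    fits[[i]] <- fit
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$fit_failed
  slope <- if (sum(ok) >= 2)
    rise_vs_chance_slope(tab$chance_level[ok], tab$rise_point_ms[ok])
  else NA_real_
  list(table = tab, slope_ms_per_chance = slope, fits = fits)
}

#' Per-participant timing landmarks
#'
#' Collects, for each participant, the antisaccade drop point and rise
#' point and the prosaccade rise point into one table ready for
#' [permutation_correlation()] (e.g. pro rise vs anti drop). Participants
#' with a missing or degenerate fit are excluded.
#'
#' @param fits Named list (one element per participant), each a list with
#'   components `anti` (an `anti_fit`) and `pro` (a `pro_fit`).
#' @return data.frame with columns `participant`, `anti_drop_ms`,
#'   `anti_rise_ms`, `pro_rise_ms`.
#' @export
participant_timing_table <- function(fits) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    if (is.null(f$anti) || is.null(f$pro)) return(NULL)
    row <- data.frame(participant = id,
                      anti_drop_ms = drop_point(f$anti),
                      anti_rise_ms = rise_point(f$anti),
                      pro_rise_ms = rise_point(f$pro))
    if (anyNA(row[-1])) return(NULL)
    row
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) out <- data.frame(participant = character(),
                                      anti_drop_ms = numeric(),
                                      anti_rise_ms = numeric(),
                                      pro_rise_ms = numeric())
  rownames(out) <- NULL
  out
}
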