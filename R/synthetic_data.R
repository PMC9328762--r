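# Synthetic trial generator with known ground truth.
#
# Generates trial tables directly from a stated accuracy-vs-rPT function,
# an RT distribution and a guessing-bias specification -- independently of
# the race model -- so that binning, fitting, shift and history analyses
# can be validated against a known truth.

#' Parametric truth curves for the generator
#'
#' Convenience constructors returning an accuracy function of rPT:
#' `true_curve_pro()` a rising sigmoid, `true_curve_anti()` a drop-recover
#' curve, `true_curve_flat()` a constant.
#'
#' @param A,B,C,D,AL,AR,BLR,CL,CR,DL,DR Curve parameters (see
#'   [sigmoid_pro()] and [sigmoid_anti()]).
#' @param p Constant accuracy for the flat curve.
#' @return A function mapping rPT (ms) to probability correct.
#' @export
true_curve_pro <- function(A = 1, B = 0.5, C = 100, D = 10) {
  force(A); force(B); force(C); force(D)
  function(rpt) sigmoid_pro(rpt, A, B, C, D)
}

#' @rdname true_curve_pro
#' @export
true_curve_anti <- function(AL = 0.5, AR = 1, BLR = 0.05, CL = 95,
                            CR = 150, DL = 5, DR = 10) {
  force(AL); force(AR); force(BLR); force(CL); force(CR); force(DL); force(DR)
  function(rpt) sigmoid_anti(rpt, AL, AR, BLR, CL, CR, DL, DR)
}

#' @rdname true_curve_pro
#' @export
true_curve_flat <- function(p = 0.5) {
  force(p)
  function(rpt) rep_len(p, length(rpt))
}

#' Generator specification
#'
#' Bundles everything the synthetic generator needs. Defaults emulate the
#' urgent-task design: the design gap set (-200 to 350 ms, sampled
#' uniformly), cue at one of two locations with equal probability, and an
#' RT distribution (truncated normal, mean 230 ms, sd 60, support
#' [80, 600] ms) whose induced rPT mass spans the guessing-through-
#' asymptotic range.
#'
#' In the guessing regime (rPT below `guess_below_ms`, where the truth
#' curve sits at its baseline) choices are drawn with a lateral/history
#' bias: the probability of guessing toward the previous trial's target is
#' `0.5 + b`, with `b = base + increment * (run_length - 1)` capped at
#' `cap` (the bias grows with consecutive target repeats). Outside the
#' guessing regime correctness is Bernoulli with `p = true_curve(rPT)`.
#'
#' @param true_curve Function rPT -> probability correct (values must lie
#'   in `[0, 1]`).
#' @param n_trials Number of trials.
#' @param task `"pro"` or `"anti"`.
#' @param gap_set_ms,gap_probs Gap values (ms) and sampling probabilities
#'   (default uniform over the design set).
#' @param rt_mean_ms,rt_sd_ms,rt_range_ms Truncated-normal RT model.
#' @param bias_spec List with `guess_below_ms`, `base`, `increment`,
#'   `cap`, `lateral` (fixed rightward guessing offset).
#' @param abort_rate Fraction of trials aborted at random (choice and RT
#'   missing).
#' @param participant_id,block Labels.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(true_curve, n_trials = 10000,
                           task = c("anti", "pro"),
                           gap_set_ms = c(-200, -100, 0, 75, 100, 125, 150,
                                          175, 200, 250, 350),
                           gap_probs = NULL,
                           rt_mean_ms = 230, rt_sd_ms = 60,
                           rt_range_ms = c(80, 600),
                           bias_spec = list(),
                           abort_rate = 0,
                           participant_id = "synth", block = "single_task") {
  task <- match.arg(task)
  stopifnot(is.function(true_curve), n_trials > 0,
            length(gap_set_ms) >= 1, abort_rate >= 0, abort_rate < 1)
  if (is.null(gap_probs))
    gap_probs <- rep(1 / length(gap_set_ms), length(gap_set_ms))
  stopifnot(length(gap_probs) == length(gap_set_ms))
  if (abs(sum(gap_probs) - 1) > 1e-8)
    stop("gap_probs must sum to 1")
  probe <- true_curve(seq(-400, 600, by = 5))
  if (any(!is.finite(probe)) || any(probe < 0) || any(probe > 1))
    stop("true_curve must return probabilities in [0, 1]")
  bs <- utils::modifyList(
    list(guess_below_ms = 80, base = 0, increment = 0, cap = 0.3,
         lateral = 0), bias_spec)
  structure(list(true_curve = true_curve, n_trials = n_trials, task = task,
                 gap_set_ms = gap_set_ms, gap_probs = gap_probs,
                 rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
                 rt_range_ms = rt_range_ms, bias_spec = bs,
                 abort_rate = abort_rate, participant_id = participant_id,
                 block = block),
            class = "generator_spec")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Generate a synthetic trial table
#'
#' Samples each trial's gap, cue side and RT, computes rPT, and draws the
#' choice: informed trials (rPT at or above the guessing cutoff) are
#' correct with probability `true_curve(rPT)`; guessing trials are drawn
#' toward the previous target location with the specified (possibly
#' cumulative) bias. Trials are produced in presentation order with a
#' `trial_index` column, so history conditioning applies directly.
#'
#' @param spec A [generator_spec()].
#' @param seed Integer seed.
#' @return A trial table.
#' @export
generate_trials <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_trials
  gaps <- sample(spec$gap_set_ms, n, replace = TRUE, prob = spec$gap_probs)
  cue <- sample(c("L", "R"), n, replace = TRUE)
  tgt <- target_side(spec$task, cue)
  rt <- rtruncnorm(n, spec$rt_mean_ms, spec$rt_sd_ms,
                   spec$rt_range_ms[1], spec$rt_range_ms[2])
  rpt <- rt - gaps
  p_true <- spec$true_curve(rpt)
  aborted <- stats::runif(n) < spec$abort_rate

  bs <- spec$bias_spec
  guess <- rpt < bs$guess_below_ms

  # run length of the target sequence ending at the previous trial
  run_before <- c(0, sequence_runs(tgt)[-n])
  prev_tgt <- c(NA, tgt[-n])
  prev_ab <- c(TRUE, aborted[-n])   # treat trial 1 as having no usable history
  b_hist <- ifelse(run_before >= 1 & !prev_ab,
                   pmin(bs$base + bs$increment * (run_before - 1), bs$cap),
                   0)
  # guessing: P(choice = R)
  dir_prev <- ifelse(is.na(prev_tgt), 0, ifelse(prev_tgt == "R", 1, -1))
  p_right <- pmin(pmax(0.5 + bs$lateral + dir_prev * b_hist, 0.02), 0.98)
  u <- stats::runif(n)
  choice_guess <- ifelse(u < p_right, "R", "L")
  correct_informed <- stats::runif(n) < p_true
  choice <- ifelse(guess, choice_guess,
                   ifelse(correct_informed, tgt, flip_side(tgt)))
  choice[aborted] <- NA_character_
  rt[aborted] <- NA_real_

  trial_table(participant_id = spec$participant_id, task = spec$task,
              gap_ms = gaps, cue_side = cue, rt_ms = rt,
              choice_side = choice, block = spec$block,
              trial_index = seq_len(n))
}

# for each position, the length of the run of equal values ending there
sequence_runs <- function(x) {
  r <- rle(x)
  unlist(lapply(r$lengths, seq_len), use.names = FALSE)
}
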