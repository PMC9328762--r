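# Accelerated race-to-threshold model of urgent saccadic choice.
#
# Two motor plans (toward the cue and toward the opposite, "anti" location)
# ramp toward a fixed threshold with randomly drawn buildup rates. Cue
# onset triggers, after an afferent delay, the exogenous response interval
# (ERI): the cue-directed plan is briefly halted and then accelerated,
# while the anti plan is halted throughout. After the ERI, the endogenous
# (goal-driven) signal accelerates the plan toward the task-defined target
# and decelerates the other. The antisaccade (CAS) and prosaccade (CPS)
# variants differ ONLY in which plan the endogenous signal favors; all
# exogenous dynamics are identical. The first plan to reach threshold
# triggers a saccade after a fixed efferent delay.
#
# Integration is explicit 1 ms Euler: accelerations add to a plan's rate on
# every active step, rates are piecewise constant between events, and a
# decelerated rate may go negative (the plan shrinks) but activity is
# floored at zero.

#' Race-model parameter set
#'
#' Returns the model's full parameter list. Defaults are read from the
#' versioned configuration shipped with the package
#' (`extdata/race_params_default.json`), calibrated once so that the
#' simulated antisaccade curve shows oculomotor capture (accuracy dropping
#' toward zero) at rPTs of roughly 90-140 ms and recovers toward 100%
#' correct by about 200 ms. The `"low"` luminance preset delays the
#' exogenous response and weakens it, emulating a less salient cue.
#'
#' @param ... Named overrides of any default field (see Details).
#' @param luminance `"high"` (default) or `"low"` preset.
#' @details Fields: `build_mean`, `build_sd` (activity units/ms) and
#'   `build_corr` for the bivariate buildup-rate draw; `threshold`
#'   (activity units); `efferent_delay_ms`; `go_latency_mean_ms` and
#'   `go_latency_sd_ms` (ramp onset after the go signal); `exo_latency_ms`
#'   (cue onset to ERI start); `eri_duration_ms`; `halt_ms` (initial halt of
#'   the cue-directed plan inside the ERI); `exo_accel` (units/ms^2 added to
#'   the cue plan's rate after the halt, during the ERI); `endo_accel`,
#'   `endo_decel` (units/ms^2 applied to the correct/incorrect plan after
#'   the ERI); `bias` (lateral guessing bias in [-0.5, 0.5]: the larger
#'   buildup rate goes to the cue-directed plan with probability
#'   `0.5 + bias`); `timeout_ms` (hard cap on the integration).
#' @return A list of class `race_params`.
#' @export
race_params <- function(..., luminance = c("high", "low")) {
  luminance <- match.arg(luminance)
  cfg <- default_race_config()
  p <- cfg$high
  if (luminance == "low") p[names(cfg$low)] <- cfg$low
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0)
    stop("unknown race parameter(s): ", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  p$luminance <- luminance
  validate_race_params(p)
  structure(p, class = "race_params")
}

.race_config_cache <- new.env(parent = emptyenv())

default_race_config <- function() {
  if (!is.null(.race_config_cache$cfg)) return(.race_config_cache$cfg)
  path <- system.file("extdata", "race_params_default.json",
                      package = "tachorace")
  if (path == "") path <- file.path("inst", "extdata",
                                    "race_params_default.json")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  .race_config_cache$cfg <- cfg
  cfg
}

validate_race_params <- function(p) {
  num1 <- function(f) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("race parameter '", f, "' must be a single finite number")
  }
  for (f in c("build_mean", "build_sd", "build_corr", "threshold",
              "efferent_delay_ms", "go_latency_mean_ms", "go_latency_sd_ms",
              "exo_latency_ms", "eri_duration_ms", "halt_ms", "exo_accel",
              "endo_accel", "endo_decel", "bias", "timeout_ms")) num1(f)
  if (p$threshold <= 0) stop("threshold must be positive")
  if (abs(p$build_corr) > 1) stop("|build_corr| must be <= 1")
  if (abs(p$bias) > 0.5) stop("|bias| must be <= 0.5")
  for (f in c("build_sd", "efferent_delay_ms", "go_latency_mean_ms",
              "go_latency_sd_ms", "exo_latency_ms", "eri_duration_ms",
              "halt_ms", "timeout_ms"))
    if (p[[f]] < 0) stop("race parameter '", f, "' must be nonnegative")
  if (p$halt_ms > p$eri_duration_ms)
    stop("halt_ms cannot exceed eri_duration_ms")
  invisible(p)
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race-model parameters (", x$luminance, "-luminance preset):\n",
      sep = "")
  for (f in setdiff(names(x), "luminance"))
    cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

#' Draw buildup rates for the two competing plans
#'
#' Samples rate pairs from a bivariate normal distribution (mean
#' `build_mean`, sd `build_sd`, correlation `build_corr`; negative draws
#' floored at 0) and assigns them to the cue-directed and anti plans. With
#' lateral bias `b`, the larger rate of the pair goes to the cue-directed
#' plan with probability `0.5 + b` (e.g. bias 0.1 gives a 60% assignment
#' probability), producing a tendency to guess toward (`b > 0`) or away
#' from (`b < 0`) the cue.
#'
#' Uses the current RNG stream; seed upstream for reproducibility.
#'
#' @param params A `race_params` object.
#' @param n Number of trials.
#' @return List with numeric vectors `rate_cue` and `rate_anti`.
#' @export
draw_buildup_rates <- function(params, n) {
  stopifnot(inherits(params, "race_params"), n >= 1)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  rho <- params$build_corr
  u <- params$build_mean + params$build_sd * z1
  v <- params$build_mean + params$build_sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  u <- pmax(u, 0)
  v <- pmax(v, 0)
  hi <- pmax(u, v)
  lo <- pmin(u, v)
  to_cue <- stats::runif(n) < 0.5 + params$bias
  list(rate_cue = ifelse(to_cue, hi, lo),
       rate_anti = ifelse(to_cue, lo, hi))
}

# Vectorized 1 ms Euler integration of the two-plan race for n trials.
# Inputs are per-trial vectors; returns crossing time, winning plan and
# timeout flag. With record_trace = TRUE (n == 1) also returns the full
# activity traces.
race_engine <- function(params, task, gap_ms, rate_cue, rate_anti,
                        go_latency, record_trace = FALSE) {
  n <- length(gap_ms)
  stopifnot(task %in% c("pro", "anti"), length(rate_cue) == n,
            length(rate_anti) == n, length(go_latency) == n)
  thr <- params$threshold
  eri_start <- gap_ms + params$exo_latency_ms
  halt_end <- eri_start + params$halt_ms
  eri_end <- eri_start + params$eri_duration_ms
  # endogenous signs: anti task steers away from the cue
  endo_cue <- if (task == "pro") params$endo_accel else -params$endo_decel
  endo_anti <- if (task == "pro") -params$endo_decel else params$endo_accel

  a_cue <- numeric(n); a_anti <- numeric(n)
  r_cue <- rate_cue; r_anti <- rate_anti
  cross_t <- rep(NA_real_, n)
  winner <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  cap <- params$timeout_ms
  trace <- if (record_trace) matrix(NA_real_, nrow = cap, ncol = 2)

  t <- 0
  while (t < cap && any(alive)) {
    t <- t + 1
    i <- which(alive)
    # rate modulation during this step
    in_accel <- t > halt_end[i] & t <= eri_end[i]
    if (any(in_accel))
      r_cue[i[in_accel]] <- r_cue[i[in_accel]] + params$exo_accel
    post <- t > eri_end[i]
    if (any(post)) {
      j <- i[post]
      r_cue[j] <- r_cue[j] + endo_cue
      r_anti[j] <- r_anti[j] + endo_anti
    }
    # advance activities; halted plans do not move
    started <- t > go_latency[i]
    cue_halted <- t > eri_start[i] & t <= halt_end[i]
    anti_halted <- t > eri_start[i] & t <= eri_end[i]
    adv_cue <- i[started & !cue_halted]
    adv_anti <- i[started & !anti_halted]
    a_cue[adv_cue] <- pmax(a_cue[adv_cue] + r_cue[adv_cue], 0)
    a_anti[adv_anti] <- pmax(a_anti[adv_anti] + r_anti[adv_anti], 0)
    if (record_trace) trace[t, ] <- c(a_cue[1], a_anti[1])
    # threshold crossing; simultaneous crossings resolved by overshoot
    crossed <- a_cue[i] >= thr | a_anti[i] >= thr
    if (any(crossed)) {
      j <- i[crossed]
      over_cue <- a_cue[j] - thr
      over_anti <- a_anti[j] - thr
      w <- ifelse(over_cue > over_anti, "cue",
                  ifelse(over_anti > over_cue, "anti", NA))
      ties <- is.na(w)
      if (any(ties))
        w[ties] <- ifelse(stats::runif(sum(ties)) < 0.5, "cue", "anti")
      cross_t[j] <- t
      winner[j] <- w
      alive[j] <- FALSE
    }
  }
  out <- list(crossing_ms = cross_t, winner = winner,
              timeout = is.na(cross_t))
  if (record_trace) {
    tt <- if (is.na(cross_t[1])) cap else cross_t[1]
    out$trace <- list(
      t = seq_len(tt),
      a_cue = trace[seq_len(tt), 1],
      a_anti = trace[seq_len(tt), 2],
      eri_window = c(eri_start[1], eri_end[1])
    )
  }
  out
}

#' Simulate one trial with full motor-plan traces
#'
#' Runs the race for a single trial and returns both the scored trial record
#' and the activity traces of the two plans (mapped to left/right by the cue
#' location). Intended for inspecting single-trial dynamics; use
#' [simulate_session()] for batches.
#'
#' @param params A `race_params` object.
#' @param task `"pro"` (CPS) or `"anti"` (CAS).
#' @param cue_side `"L"` or `"R"`.
#' @param gap_ms Urgent gap in ms (must be `>= 0`).
#' @param seed Optional integer seed.
#' @return List with elements `trial` (one-row trial table) and `trace`
#'   (list with `t`, `r_left`, `r_right`, `eri_window`, `crossing_ms`,
#'   `winner`).
#' @export
simulate_trial <- function(params, task, cue_side, gap_ms, seed = NULL) {
  stopifnot(gap_ms >= 0)
  if (!is.null(seed)) set.seed(seed)
  cue_side <- match_side(cue_side)
  rates <- draw_buildup_rates(params, 1)
  go_lat <- pmax(stats::rnorm(1, params$go_latency_mean_ms,
                              params$go_latency_sd_ms), 0)
  res <- race_engine(params, task, gap_ms, rates$rate_cue, rates$rate_anti,
                     go_lat, record_trace = TRUE)
  choice <- if (res$timeout) NA_character_
            else if (res$winner == "cue") cue_side else flip_side(cue_side)
  rt <- if (res$timeout) NA_real_
        else res$crossing_ms + params$efferent_delay_ms
  trial <- trial_table(participant_id = "sim", task = task, gap_ms = gap_ms,
                       cue_side = cue_side, rt_ms = rt, choice_side = choice)
  trial$timeout <- res$timeout
  tr <- res$trace
  left_is_cue <- cue_side == "L"
  trace <- list(
    t = tr$t,
    r_left = if (left_is_cue) tr$a_cue else tr$a_anti,
    r_right = if (left_is_cue) tr$a_anti else tr$a_cue,
    eri_window = tr$eri_window,
    crossing_ms = res$crossing_ms,
    winner = if (res$timeout) NA_character_
             else if (res$winner == "cue") cue_side else flip_side(cue_side)
  )
  list(trial = trial, trace = trace)
}

#' Simulate a session of urgent race-model trials
#'
#' Samples the gap and cue side uniformly at random per trial (as in the
#' task design), draws buildup rates and go-signal latencies, integrates
#' the race and scores each trial. Timeout trials (no threshold crossing
#' within `timeout_ms`) are returned flagged with a missing choice so that
#' [filter_urgent()] excludes them.
#'
#' @param params A `race_params` object.
#' @param task `"pro"` (CPS) or `"anti"` (CAS).
#' @param n_trials Number of trials.
#' @param gap_set_ms Urgent gap values sampled uniformly (default the task's
#'   design set `0, 75, 100, 125, 150, 175, 200, 250, 350` ms).
#' @param seed Optional integer seed.
#' @param participant_id Label stored per trial.
#' @return A trial table with an additional `timeout` column.
#' @export
simulate_session <- function(params, task, n_trials,
                             gap_set_ms = c(0, 75, 100, 125, 150, 175,
                                            200, 250, 350),
                             seed = NULL, participant_id = "sim") {
  stopifnot(inherits(params, "race_params"), n_trials > 0)
  if (length(gap_set_ms) == 0) stop("gap_set_ms must be non-empty")
  if (any(gap_set_ms < 0)) stop("simulation covers urgent gaps only (>= 0)")
  if (!is.null(seed)) set.seed(seed)
  gaps <- sample(gap_set_ms, n_trials, replace = TRUE)
  cue <- sample(c("L", "R"), n_trials, replace = TRUE)
  rates <- draw_buildup_rates(params, n_trials)
  go_lat <- pmax(stats::rnorm(n_trials, params$go_latency_mean_ms,
                              params$go_latency_sd_ms), 0)
  res <- race_engine(params, task, gaps, rates$rate_cue, rates$rate_anti,
                     go_lat)
  choice <- ifelse(res$timeout, NA_character_,
                   ifelse(res$winner == "cue", cue, flip_side(cue)))
  rt <- ifelse(res$timeout, NA_real_,
               res$crossing_ms + params$efferent_delay_ms)
  trials <- trial_table(participant_id = participant_id, task = task,
                        gap_ms = gaps, cue_side = cue, rt_ms = rt,
                        choice_side = choice,
                        luminance = params$luminance,
                        trial_index = seq_len(n_trials))
  trials$timeout <- res$timeout
  trials
}

#' Model-predicted tachometric curve
#'
#' Simulates a session and bins it into a tachometric curve. Because the
#' curve is a model expectation rather than an empirical estimate, only
#' well-populated bins are reported (`min_bin_n = 1000` by default at the
#' default 50,000 trials).
#'
#' @inheritParams simulate_session
#' @param bin_width_ms,min_bin_n Binning controls, see [tachometric()].
#' @return A `tachometric_curve`.
#' @export
predicted_tachometric <- function(params, task, n_trials = 50000,
                                  seed = NULL, bin_width_ms = 21,
                                  min_bin_n = 1000, ...) {
  trials <- simulate_session(params, task, n_trials, seed = seed, ...)
  tachometric(filter_urgent(trials), bin_width_ms = bin_width_ms,
              min_bin_n = min_bin_n, task = task)
}
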