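# Shared fixtures: small trial tables and analytic curves built in code.

# A scored trial table with rPTs and correctness drawn at given values.
# The gap defaults to 300 ms so that negative rPTs still imply valid
# (nonnegative) reaction times.
make_trials <- function(rpt, correct, task = "anti", gap = 300) {
  n <- length(rpt)
  cue <- rep(c("L", "R"), length.out = n)
  tgt <- target_side(rep(task, n), cue)
  choice <- ifelse(correct, tgt, ifelse(tgt == "L", "R", "L"))
  trial_table(participant_id = "t", task = task, gap_ms = rep(gap, n),
              cue_side = cue, rt_ms = rpt + gap, choice_side = choice,
              trial_index = seq_len(n))
}

# Random scored table with known flat accuracy p0.
random_trials <- function(n, p0 = 0.7, rpt_lo = -50, rpt_hi = 250) {
  rpt <- runif(n, rpt_lo, rpt_hi)
  make_trials(rpt, runif(n) < p0)
}

# Naive O(n * grid) double-loop tachometric oracle with half-open bins
# [c - w/2, c + w/2), matching the production convention by definition.
brute_force_tacho <- function(trials, bin_width = 21, step = 1,
                              min_bin_n = 10) {
  rpt <- trials$rpt_ms
  correct <- trials$correct
  grid <- seq(floor(min(rpt)), ceiling(max(rpt)), by = step)
  half <- bin_width / 2
  frac <- rep(NA_real_, length(grid))
  n <- integer(length(grid))
  for (i in seq_along(grid)) {
    inside <- rpt >= grid[i] - half & rpt < grid[i] + half
    n[i] <- sum(inside)
    if (n[i] >= min_bin_n) frac[i] <- mean(correct[inside])
  }
  list(rpt = grid, frac = frac, n = n)
}

# Analytic pro-style curve object on a 1 ms grid.
analytic_pro_curve <- function(A = 1, B = 0.5, C = 100, D = 10,
                               lo = 0, hi = 250) {
  x <- seq(lo, hi, by = 1)
  as_tachometric_curve(x, sigmoid_pro(x, A, B, C, D))
}
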