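test_that("parameter construction validates fields and presets", {
  p <- race_params()
  expect_s3_class(p, "race_params")
  expect_equal(p$luminance, "high")
  lo <- race_params(luminance = "low")
  expect_gt(lo$exo_latency_ms, p$exo_latency_ms)
  expect_lt(lo$exo_accel, p$exo_accel)
  # the presets differ only in the exogenous-response fields
  same <- setdiff(names(unclass(p)),
                  c("exo_latency_ms", "exo_accel", "luminance"))
  expect_identical(unclass(p)[same], unclass(lo)[same])
  expect_error(race_params(not_a_field = 1), "unknown race parameter")
  expect_error(race_params(bias = 0.7), "bias")
  expect_error(race_params(build_corr = 1.5), "build_corr")
  expect_error(race_params(threshold = -1), "threshold")
  expect_error(race_params(halt_ms = 30, eri_duration_ms = 25), "halt_ms")
})

test_that("bias controls the probability that the faster plan is cue-directed", {
  set.seed(401)
  n <- 10000
  frac_cue_faster <- function(bias) {
    r <- draw_buildup_rates(race_params(bias = bias), n)
    mean(r$rate_cue >= r$rate_anti)
  }
  # 4-sigma binomial bands around the expected assignment probabilities
  tol <- 4 * sqrt(0.25 / n)
  expect_lt(abs(frac_cue_faster(0) - 0.5), tol)
  expect_lt(abs(frac_cue_faster(0.1) - 0.6), tol)
  expect_lt(abs(frac_cue_faster(-0.1) - 0.4), tol)
  r <- draw_buildup_rates(race_params(bias = 0.5), n)
  expect_true(all(r$rate_cue >= r$rate_anti))
  expect_true(all(r$rate_cue >= 0) && all(r$rate_anti >= 0))
})

test_that("pro and anti traces are identical through the ERI, then diverge", {
  # the two task variants share all exogenous dynamics; the endogenous
  # signal only acts after the ERI ends
  p <- race_params()
  found_divergence <- FALSE
  for (s in 1:12) {
    a <- simulate_trial(p, "anti", "L", gap_ms = 150, seed = s)
    b <- simulate_trial(p, "pro", "L", gap_ms = 150, seed = s)
    eri_end <- a$trace$eri_window[2]
    shared <- seq_len(min(floor(eri_end), length(a$trace$t),
                          length(b$trace$t)))
    expect_equal(a$trace$r_left[shared], b$trace$r_left[shared])
    expect_equal(a$trace$r_right[shared], b$trace$r_right[shared])
    if (!isTRUE(all.equal(a$trial$rt_ms, b$trial$rt_ms)))
      found_divergence <- TRUE
  }
  expect_true(found_divergence)
})

test_that("crossings before the exogenous response are gain-independent", {
  p1 <- race_params()
  p2 <- race_params(exo_accel = 5, endo_accel = 1, endo_decel = 5)
  t1 <- simulate_session(p1, "anti", 4000, gap_set_ms = 350, seed = 77)
  t2 <- simulate_session(p2, "anti", 4000, gap_set_ms = 350, seed = 77)
  pre <- !t1$aborted & !is.na(t1$rpt_ms) &
         t1$rpt_ms < p1$exo_latency_ms + p1$efferent_delay_ms
  expect_gt(sum(pre), 100)
  expect_equal(t1$rt_ms[pre], t2$rt_ms[pre])
  expect_equal(t1$choice_side[pre], t2$choice_side[pre])
})

test_that("an unbiased race guesses at chance with balanced choices", {
  set.seed(402)
  tt <- filter_urgent(simulate_session(race_params(), "anti", 10000,
                                       gap_set_ms = 350, seed = 402))
  guesses <- tt[tt$rpt_ms < 60, , drop = FALSE]
  expect_gt(nrow(guesses), 2000)
  tol <- 4 * sqrt(0.25 / nrow(guesses))
  expect_lt(abs(mean(guesses$correct) - 0.5), tol)
  expect_lt(abs(mean(guesses$choice_side == "R") - 0.5), tol)
})

test_that("simulation is deterministic under a seed and balanced over cues", {
  p <- race_params()
  a <- simulate_session(p, "anti", 2000, seed = 9)
  b <- simulate_session(p, "anti", 2000, seed = 9)
  expect_identical(a, b)
  c <- simulate_session(p, "anti", 2000, seed = 10)
  expect_false(identical(a$rt_ms, c$rt_ms))
  tol <- 4 * sqrt(0.25 / 2000)
  expect_lt(abs(mean(a$cue_side == "L") - 0.5), tol)
  expect_error(simulate_session(p, "anti", 100, gap_set_ms = numeric(0)),
               "non-empty")
  expect_error(simulate_session(p, "anti", 100, gap_set_ms = -50), "urgent")
})

test_that("opposite biases give complementary guessing accuracies", {
  # uninformed antisaccade guesses succeed when the anti plan got the
  # faster rate: bias +b gives early accuracy near 0.5 - b and bias -b
  # near 0.5 + b, so the two accuracies are complementary
  early_acc <- function(bias, seed) {
    tt <- filter_urgent(simulate_session(race_params(bias = bias), "anti",
                                         10000, gap_set_ms = 350,
                                         seed = seed))
    g <- tt$correct[tt$rpt_ms < 60]
    c(mean(g), length(g))
  }
  a <- early_acc(0.15, 31)
  b <- early_acc(-0.15, 32)
  tol <- 4 * sqrt(0.25 / min(a[2], b[2])) + 0.02
  expect_lt(abs(a[1] + b[1] - 1), tol)
  expect_lt(a[1], 0.45)
  expect_gt(b[1], 0.55)
  # informed (late-rPT) accuracy stays high regardless of bias sign
  late <- function(bias, seed) {
    tt <- filter_urgent(simulate_session(race_params(bias = bias), "anti",
                                         6000, seed = seed))
    mean(tt$correct[tt$rpt_ms > 220])
  }
  expect_gt(late(0.15, 33), 0.85)
  expect_gt(late(-0.15, 34), 0.85)
})

test_that("gap_set {0} makes rPT equal RT", {
  tt <- simulate_session(race_params(), "pro", 200, gap_set_ms = 0,
                         seed = 12)
  expect_equal(tt$rpt_ms, tt$rt_ms)
})

test_that("stronger exogenous gain deepens CAS capture and lifts CPS", {
  band <- function(curve, lo, hi) {
    sel <- curve$rpt >= lo & curve$rpt <= hi & !is.na(curve$frac)
    curve$frac[sel]
  }
  cas_mean <- numeric(0); cps_mean <- numeric(0)
  for (g in c(0.6, 1.2, 2.4)) {
    p <- race_params(exo_accel = g)
    cas <- predicted_tachometric(p, "anti", n_trials = 15000, seed = 55,
                                 min_bin_n = 300)
    cps <- predicted_tachometric(p, "pro", n_trials = 15000, seed = 56,
                                 min_bin_n = 300)
    cas_mean <- c(cas_mean, mean(band(cas, 90, 140)))
    cps_mean <- c(cps_mean, mean(band(cps, 90, 140)))
  }
  expect_true(all(diff(cas_mean) <= 0.02))
  expect_true(all(diff(cps_mean) >= -0.02))
  expect_lt(cas_mean[3], cas_mean[1])
  expect_gt(cps_mean[3], cps_mean[1])
})

test_that("single-trial traces respect threshold and efferent delay", {
  p <- race_params()
  out <- simulate_trial(p, "anti", "R", gap_ms = 100, seed = 21)
  tr <- out$trace
  expect_false(out$trial$aborted)
  expect_equal(out$trial$rt_ms, tr$crossing_ms + p$efferent_delay_ms)
  peak <- max(c(tr$r_left, tr$r_right), na.rm = TRUE)
  expect_gte(peak, p$threshold)
  # activity before the crossing stays below threshold
  before <- seq_len(tr$crossing_ms - 1)
  expect_true(all(tr$r_left[before] < p$threshold))
  expect_true(all(tr$r_right[before] < p$threshold))
  expect_true(all(tr$r_left >= 0 & tr$r_right >= 0))
})
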