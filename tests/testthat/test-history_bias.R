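# Hand-built session for label checks: one participant, one block, target
# sides fully controlled via an antisaccade task (target = opposite of cue).
session_with_targets <- function(targets, aborted = rep(FALSE, length(targets))) {
  cue <- ifelse(targets == "L", "R", "L")
  choice <- ifelse(aborted, NA, targets)
  trial_table(participant_id = "p", task = "anti", gap_ms = 100,
              cue_side = cue,
              rt_ms = ifelse(aborted, NA, 250), choice_side = choice,
              trial_index = seq_along(targets))
}

test_that("depth-1 labels follow the AA/AB pattern definitions", {
  tt <- session_with_targets(c("L", "L", "R", "R", "L"))
  lab <- label_history(tt, depth = 1)$history
  expect_equal(lab, c(NA, "repeat", "switch", "repeat", "switch"))
})

test_that("aborted predecessors and gaps leave trials unlabeled", {
  tt <- session_with_targets(c("L", "L", "L", "L"),
                             aborted = c(FALSE, TRUE, FALSE, FALSE))
  lab <- label_history(tt, depth = 1)$history
  expect_equal(lab, c(NA, NA, NA, "repeat"))
  # non-contiguous trial_index breaks the lookback
  tt2 <- session_with_targets(c("L", "L"))
  tt2$trial_index <- c(1L, 3L)
  expect_equal(label_history(tt2, depth = 1)$history,
               c(NA_character_, NA_character_))
  expect_error(label_history(tt2[, setdiff(names(tt2), "trial_index")]),
               "trial_index")
})

test_that("deeper labels require agreement among predecessors", {
  tt <- session_with_targets(c("L", "L", "L", "R", "L", "R", "R"))
  lab2 <- label_history(tt, depth = 2)$history
  # trial 3: L,L before L -> AAA; trial 4: L,L before R -> AAB
  expect_equal(lab2[3], "repeat")
  expect_equal(lab2[4], "switch")
  # trial 6: R,L predecessors disagree -> unlabeled
  expect_true(is.na(lab2[6]))
  expect_true(all(is.na(lab2[1:2])))
  expect_equal(history_pattern(2, "repeat"), "AAA")
  expect_equal(history_pattern(3, "switch"), "AAAB")
})

test_that("labels partition trials: repeat + switch + unlabeled = all", {
  set.seed(501)
  spec <- generator_spec(true_curve_flat(0.5), n_trials = 2000)
  tt <- generate_trials(spec, seed = 501)
  lab <- label_history(tt, depth = 1)$history
  expect_equal(sum(lab == "repeat", na.rm = TRUE) +
               sum(lab == "switch", na.rm = TRUE) + sum(is.na(lab)),
               nrow(tt))
  # with two equiprobable targets, roughly half the labeled trials repeat
  expect_lt(abs(mean(lab == "repeat", na.rm = TRUE) - 0.5),
            4 * sqrt(0.25 / sum(!is.na(lab))))
})

test_that("labels are invariant to row shuffling", {
  set.seed(502)
  tt <- session_with_targets(sample(c("L", "R"), 50, replace = TRUE))
  base <- label_history(tt, depth = 1)$history
  shuf <- sample(nrow(tt))
  got <- label_history(tt[shuf, ], depth = 1)$history
  expect_equal(got, base[shuf])
})

test_that("two-point slope matches the exact ratio of differences", {
  expect_equal(rise_vs_chance_slope(c(0.36, 0.64), c(154, 143)), 275 / 7)
  expect_equal(275 / 7, 39.2857, tolerance = 1e-4)
  expect_equal(rise_vs_chance_slope(c(0.4, 0.6), c(150, 150)), 0)
  expect_error(rise_vs_chance_slope(c(0.5, 0.5), c(150, 140)), "equal")
})

test_that("multi-point slope recovers a collinear relation exactly", {
  ch <- c(0.3, 0.4, 0.5, 0.6, 0.7)
  rise <- 175 - 50 * ch
  expect_equal(rise_vs_chance_slope(ch, rise), 50, tolerance = 1e-4)
  # least-absolute-deviations is robust to a single outlier
  rise_out <- rise; rise_out[3] <- rise_out[3] + 40
  expect_equal(rise_vs_chance_slope(ch, rise_out), 50, tolerance = 0.5)
})

test_that("conditioned analysis recovers injected guessing bias", {
  # constant repeat-bias b = 0.14: repeat-condition guesses favor the
  # target at 0.64, switch-condition guesses at 0.36
  spec <- generator_spec(true_curve_anti(), n_trials = 50000,
                         bias_spec = list(base = 0.14))
  tt <- generate_trials(spec, seed = 503)
  conds <- conditioned_analysis(tt, "anti", depth = 1)
  expect_equal(conds[["repeat"]]$pattern, "AA")
  expect_equal(conds[["switch"]]$pattern, "AB")
  expect_lt(abs(conds[["repeat"]]$chance_level - 0.64), 0.03)
  expect_lt(abs(conds[["switch"]]$chance_level - 0.36), 0.03)
  # the two chance levels are complementary offsets about 0.5
  expect_lt(abs(conds[["repeat"]]$chance_level +
                conds[["switch"]]$chance_level - 1), 0.04)
  expect_gt(conds[["repeat"]]$n_trials, 5000)
  expect_false(conds[["repeat"]]$low_n)
})

test_that("cumulative bias grows with history depth", {
  # increment > 0: longer repeat runs push guesses harder toward the
  # previous target, so the repeat-condition chance level grows with depth
  spec <- generator_spec(true_curve_anti(), n_trials = 80000,
                         bias_spec = list(base = 0.08, increment = 0.08))
  tt <- generate_trials(spec, seed = 504)
  ch <- vapply(1:3, function(d) {
    suppressWarnings(conditioned_analysis(tt, "anti", depth = d))[[
      "repeat"]]$chance_level
  }, numeric(1))
  expect_true(all(diff(ch) > 0))
  expect_gt(ch[3], ch[1] + 0.05)
})

test_that("sparse conditions warn about instability", {
  spec <- generator_spec(true_curve_anti(), n_trials = 900)
  tt <- generate_trials(spec, seed = 505)
  expect_warning(conditioned_analysis(tt, "anti", depth = 1, min_bin_n = 5),
                 "fewer than 500")
})

test_that("participant timing table drops incomplete fits", {
  x <- seq(0, 300, by = 1)
  anti <- fit_anti(as_tachometric_curve(
    x, sigmoid_anti(x, 0.5, 1, 0.03, 95, 150, 5, 10)))
  pro <- fit_pro(as_tachometric_curve(x, sigmoid_pro(x, 1, 0.5, 110, 10)))
  degen <- suppressWarnings(
    fit_anti(as_tachometric_curve(x, rep(0.5, length(x)))))
  fits <- list(p1 = list(anti = anti, pro = pro),
               p2 = list(anti = degen, pro = pro),
               p3 = list(anti = anti, pro = NULL))
  tab <- participant_timing_table(fits)
  expect_equal(tab$participant, "p1")
  expect_equal(tab$anti_drop_ms, drop_point(anti))
  expect_equal(tab$pro_rise_ms, rise_point(pro))
  expect_equal(nrow(participant_timing_table(list())), 0)
})

test_that("model_bias_sweep validates its bias grid", {
  p <- race_params()
  expect_error(model_bias_sweep(p, c(0.1, 0.2), "anti"), "span both signs")
  expect_error(model_bias_sweep(p, 0.1, "anti"), "length")
})
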