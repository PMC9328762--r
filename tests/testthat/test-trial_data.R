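test_that("compute_rpt matches rt - gap and propagates NA", {
  expect_equal(compute_rpt(300, 150), 150)
  expect_equal(compute_rpt(250, 0), 250)
  expect_equal(compute_rpt(100, 350), -250)
  expect_true(is.na(compute_rpt(NA, 100)))
  expect_error(compute_rpt(-5, 0), "nonnegative")
  rt <- runif(200, 0, 600); gap <- sample(-200:350, 200, replace = TRUE)
  expect_equal(compute_rpt(rt, gap), rt - gap)
})

test_that("target side follows the task rule and recycles", {
  expect_equal(target_side("pro", "L"), "L")
  expect_equal(target_side("pro", "R"), "R")
  expect_equal(target_side("anti", "L"), "R")
  expect_equal(target_side("anti", "R"), "L")
  expect_equal(target_side("anti", c("L", "R", "L")), c("R", "L", "R"))
  expect_equal(target_side(c("pro", "anti"), "L"), c("L", "R"))
  expect_error(target_side("both", "L"), "task")
  expect_error(target_side("pro", "up"), "side")
})

test_that("scoring covers all task/cue/choice combinations", {
  grid <- expand.grid(task = c("pro", "anti"), cue = c("L", "R"),
                      choice = c("L", "R"), stringsAsFactors = FALSE)
  got <- score_trial(grid$task, grid$cue, grid$choice)
  want <- ifelse(grid$task == "pro", grid$choice == grid$cue,
                 grid$choice != grid$cue)
  expect_equal(got, want)
  expect_true(is.na(score_trial("anti", "L", NA)))
})

test_that("scoring is mirror-symmetric under L/R exchange", {
  grid <- expand.grid(task = c("pro", "anti"), cue = c("L", "R"),
                      choice = c("L", "R"), stringsAsFactors = FALSE)
  flip <- function(s) ifelse(s == "L", "R", "L")
  expect_equal(score_trial(grid$task, grid$cue, grid$choice),
               score_trial(grid$task, flip(grid$cue), flip(grid$choice)))
})

test_that("trial_table recomputes derived columns consistently", {
  tt <- trial_table(participant_id = "p1", task = c("pro", "anti"),
                    gap_ms = c(100, 200), cue_side = c("L", "L"),
                    rt_ms = c(250, 320), choice_side = c("L", "R"))
  expect_equal(tt$target_side, c("L", "R"))
  expect_equal(tt$rpt_ms, c(150, 120))
  expect_equal(tt$correct, c(TRUE, TRUE))
  expect_equal(tt$aborted, c(FALSE, FALSE))
  # anti target is never the cue side
  expect_true(all(tt$target_side[tt$task == "anti"] !=
                  tt$cue_side[tt$task == "anti"]))
})

test_that("aborted trials are flagged, not dropped, and rt is required otherwise", {
  tt <- trial_table(participant_id = "p1", task = "anti", gap_ms = 100,
                    cue_side = "L", rt_ms = NA, choice_side = NA)
  expect_true(tt$aborted)
  expect_true(is.na(tt$correct))
  expect_error(
    trial_table(participant_id = "p1", task = "anti", gap_ms = 100,
                cue_side = "L", rt_ms = NA, choice_side = "L"),
    "rt_ms missing")
})

test_that("filter_urgent keeps completed gap >= 0 trials and is idempotent", {
  tt <- trial_table(participant_id = "p", task = "anti",
                    gap_ms = c(-100, 0, 150, 200),
                    cue_side = "L", rt_ms = c(250, 250, 250, NA),
                    choice_side = c("R", "R", "R", NA))
  u <- filter_urgent(tt)
  expect_equal(u$gap_ms, c(0, 150))
  expect_identical(filter_urgent(u), u)
})

test_that("trial CSV round-trips exactly", {
  set.seed(11)
  tt <- random_trials(80)
  tt$choice_side[3] <- NA; tt$rt_ms[3] <- NA
  tt$correct[3] <- NA; tt$rpt_ms[3] <- NA; tt$aborted[3] <- TRUE
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_trials(tt, path)
  back <- read_trials(path)
  for (col in c("participant_id", "task", "gap_ms", "cue_side",
                "target_side", "choice_side", "correct", "aborted",
                "trial_index"))
    expect_equal(back[[col]], tt[[col]], info = col)
  expect_equal(back$rt_ms, tt$rt_ms, tolerance = 1e-9)
  expect_equal(back$rpt_ms, tt$rpt_ms, tolerance = 1e-9)
})

test_that("reader rejects malformed files with row-level messages", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c("participant_id,task,gap_ms,cue_side,choice_side",
               "p,anti,100,L,R"), path)
  expect_error(read_trials(path), "missing required column")
  writeLines(c("participant_id,task,gap_ms,cue_side,choice_side,rt_ms,extra",
               "p,anti,100,L,R,250,1"), path)
  expect_error(read_trials(path), "unknown column")
  writeLines(c("participant_id,task,gap_ms,cue_side,choice_side,rt_ms",
               "p,anti,abc,L,R,250"), path)
  expect_error(read_trials(path), "unparseable.*gap_ms")
  writeLines(c(paste0("participant_id,task,gap_ms,cue_side,choice_side,",
                      "rt_ms,target_side"),
               "p,anti,100,L,R,250,L"), path)
  expect_error(read_trials(path), "target_side inconsistent.*row 1")
  writeLines(c(paste0("participant_id,task,gap_ms,cue_side,choice_side,",
                      "rt_ms,rpt_ms"),
               "p,anti,100,L,R,250,999"), path)
  expect_error(read_trials(path), "rpt_ms inconsistent.*row 1")
})

test_that("summarize_trials counts add up", {
  set.seed(5)
  tt <- random_trials(120)
  s <- summarize_trials(tt)
  expect_equal(s$n_trials, 120)
  expect_equal(sum(s$by_task), 120)
  expect_equal(s$n_urgent, nrow(filter_urgent(tt)))
})
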