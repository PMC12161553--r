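test_that("quota-based rules award 10/5/0 by conditions met", {
  # strength: both quotas -> 10, one -> 5, none -> 0; quotas are minimums
  expect_equal(score_indicator(session_log(moderate_strength_bouts = 6,
                                           high_strength_bouts = 3), "STT"), 10)
  expect_equal(score_indicator(session_log(moderate_strength_bouts = 9,
                                           high_strength_bouts = 4), "STT"), 10)
  expect_equal(score_indicator(session_log(moderate_strength_bouts = 6,
                                           high_strength_bouts = 0), "STT"), 5)
  expect_equal(score_indicator(session_log(moderate_strength_bouts = 0,
                                           high_strength_bouts = 3), "STT"), 5)
  expect_equal(score_indicator(session_log(moderate_strength_bouts = 5,
                                           high_strength_bouts = 2), "STT"), 0)

  # endurance: all three types -> 10, exactly two -> 5, else 0
  expect_equal(score_indicator(session_log(
    endurance_types_completed = c("aerobic", "anaerobic", "hybrid")), "ENT"), 10)
  expect_equal(score_indicator(session_log(
    endurance_types_completed = c("aerobic", "anaerobic")), "ENT"), 5)
  expect_equal(score_indicator(session_log(
    endurance_types_completed = "hybrid"), "ENT"), 0)

  # regional: both conditions -> 10, one -> 5, none -> 0
  expect_equal(score_indicator(session_log(
    regional_completed = c("barrier_free", "obstacle")), "RET"), 10)
  expect_equal(score_indicator(session_log(
    regional_completed = "obstacle"), "RET"), 5)
  expect_equal(score_indicator(session_log(), "RET"), 0)
})

test_that("binary rules award 10/0 and recovery has a 5-point floor", {
  expect_equal(score_indicator(session_log(sprint_within_time = TRUE), "SPT"), 10)
  expect_equal(score_indicator(session_log(sprint_within_time = FALSE), "SPT"), 0)
  expect_equal(score_indicator(session_log(stress_test_passed = TRUE), "RST"), 10)
  expect_equal(score_indicator(session_log(basic_skills_standard = TRUE), "BST"), 10)
  expect_equal(score_indicator(session_log(basic_skills_standard = FALSE), "BST"), 0)

  # recovery: strictly slower than the group mean -> 5, else 10;
  # equality is not "higher than", so it scores 10
  expect_equal(score_indicator(session_log(recovery_time = 40,
                                           group_mean_recovery_time = 30), "RCT"), 5)
  expect_equal(score_indicator(session_log(recovery_time = 30,
                                           group_mean_recovery_time = 30), "RCT"), 10)
  expect_equal(score_indicator(session_log(recovery_time = 20,
                                           group_mean_recovery_time = 30), "RCT"), 10)
})

test_that("score_session applies all seven rules in canonical order", {
  expect_equal(unname(score_session(all_max_log())), rep(10, 7))
  # nothing achieved and slower-than-average recovery: RCT floor is 5
  nothing <- session_log(recovery_time = 40, group_mean_recovery_time = 30)
  expect_equal(unname(score_session(nothing)), c(0, 0, 0, 0, 0, 5, 0))
  expect_equal(names(score_session(nothing)), indicator_codes())
  # mixed case, derived by hand from the rules
  mixed <- session_log(moderate_strength_bouts = 6, high_strength_bouts = 0,
                       sprint_within_time = TRUE,
                       recovery_time = 40, group_mean_recovery_time = 30)
  expect_equal(unname(score_session(mixed)), c(5, 10, 0, 0, 0, 5, 0))
})

test_that("the mapping is total and lands in each level set (exhaustive)", {
  levels <- indicator_levels()
  for (m in c(0, 5, 6, 9)) for (h in c(0, 2, 3, 5)) {
    s <- score_indicator(session_log(moderate_strength_bouts = m,
                                     high_strength_bouts = h), "STT")
    expect_true(s %in% levels$STT)
  }
  types <- c("aerobic", "anaerobic", "hybrid")
  for (i in 0:3) for (combo in utils::combn(types, i, simplify = FALSE)) {
    s <- score_indicator(session_log(endurance_types_completed = combo), "ENT")
    expect_true(s %in% levels$ENT)
  }
  conds <- c("barrier_free", "obstacle")
  for (i in 0:2) for (combo in utils::combn(conds, i, simplify = FALSE)) {
    s <- score_indicator(session_log(regional_completed = combo), "RET")
    expect_true(s %in% levels$RET)
  }
  for (flag in c(TRUE, FALSE)) {
    expect_true(score_indicator(session_log(sprint_within_time = flag), "SPT")
                %in% levels$SPT)
    expect_true(score_indicator(session_log(stress_test_passed = flag), "RST")
                %in% levels$RST)
    expect_true(score_indicator(session_log(basic_skills_standard = flag), "BST")
                %in% levels$BST)
  }
  for (rt in c(10, 30, 50)) {
    expect_true(score_indicator(session_log(recovery_time = rt,
                                            group_mean_recovery_time = 30), "RCT")
                %in% levels$RCT)
  }
})

test_that("completing more never lowers any score (monotonicity)", {
  base_logs <- list(
    session_log(),
    session_log(moderate_strength_bouts = 6,
                endurance_types_completed = "aerobic",
                regional_completed = "obstacle"),
    session_log(moderate_strength_bouts = 5, high_strength_bouts = 2,
                endurance_types_completed = c("aerobic", "anaerobic"))
  )
  augmentations <- list(
    function(l) { l$moderate_strength_bouts <- l$moderate_strength_bouts + 1L; l },
    function(l) { l$high_strength_bouts <- l$high_strength_bouts + 1L; l },
    function(l) { l$sprint_within_time <- TRUE; l },
    function(l) { l$endurance_types_completed <-
      unique(c(l$endurance_types_completed, "hybrid")); l },
    function(l) { l$regional_completed <-
      unique(c(l$regional_completed, "barrier_free")); l },
    function(l) { l$stress_test_passed <- TRUE; l },
    function(l) { l$basic_skills_standard <- TRUE; l }
  )
  for (log in base_logs) for (aug in augmentations) {
    more <- aug(log)
    class(more) <- "session_log"
    expect_true(all(score_session(more) >= score_session(log)))
  }
})

test_that("invalid logs and unknown indicators are rejected", {
  expect_error(session_log(moderate_strength_bouts = -1), "non-negative")
  expect_error(session_log(recovery_time = 0), "positive")
  expect_error(session_log(endurance_types_completed = "swimming"), "subset")
  expect_error(score_indicator(session_log(), "XYZ"))
  expect_error(score_indicator(list(), "STT"), "session_log")
})
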