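#' Record the raw activity of one training session
#'
#' Collects the raw facts the seven scoring rules need: bout counts for
#' moderate- and high-intensity strength work, whether the 100 m sprint
#' was run within the required time, which endurance training types were
#' completed (of aerobic, anaerobic, hybrid), which regional conditions
#' were completed (of barrier_free, obstacle), whether the
#' post-high-intensity stress test was passed, the measured physiological
#' recovery time against the group mean, and whether the basic football
#' skill movements were executed to standard.
#'
#' What counts as "high intensity", the sprint time cut-off and the
#' physiological recovery standard are the caller's concern; the log
#' records outcomes, not definitions.
#'
#' @param moderate_strength_bouts,high_strength_bouts completed bout
#'   counts (non-negative integers).
#' @param sprint_within_time logical; 100 m sprint within the required time.
#' @param endurance_types_completed character subset of
#'   `c("aerobic", "anaerobic", "hybrid")`.
#' @param regional_completed character subset of
#'   `c("barrier_free", "obstacle")`.
#' @param stress_test_passed logical.
#' @param recovery_time,group_mean_recovery_time positive times (minutes).
#' @param basic_skills_standard logical.
#' @return An object of class `session_log`.
#' @seealso [score_indicator()], [score_session()]
#' @export
session_log <- function(moderate_strength_bouts = 0, high_strength_bouts = 0,
                        sprint_within_time = FALSE,
                        endurance_types_completed = character(),
                        regional_completed = character(),
                        stress_test_passed = FALSE,
                        recovery_time = 30, group_mean_recovery_time = 30,
                        basic_skills_standard = FALSE) {
  check_count <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
      stop("`", name, "` must be a single non-negative integer", call. = FALSE)
    }
  }
  check_flag <- function(x, name) {
    if (!is.logical(x) || length(x) != 1 || is.na(x)) {
      stop("`", name, "` must be TRUE or FALSE", call. = FALSE)
    }
  }
  check_count(moderate_strength_bouts, "moderate_strength_bouts")
  check_count(high_strength_bouts, "high_strength_bouts")
  check_flag(sprint_within_time, "sprint_within_time")
  check_flag(stress_test_passed, "stress_test_passed")
  check_flag(basic_skills_standard, "basic_skills_standard")
  endurance_types_completed <- unique(as.character(endurance_types_completed))
  if (!all(endurance_types_completed %in% c("aerobic", "anaerobic", "hybrid"))) {
    stop("`endurance_types_completed` must be a subset of ",
         '{"aerobic", "anaerobic", "hybrid"}', call. = FALSE)
  }
  regional_completed <- unique(as.character(regional_completed))
  if (!all(regional_completed %in% c("barrier_free", "obstacle"))) {
    stop('`regional_completed` must be a subset of {"barrier_free", "obstacle"}',
         call. = FALSE)
  }
  for (nm in c("recovery_time", "group_mean_recovery_time")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val <= 0) {
      stop("`", nm, "` must be a single positive time", call. = FALSE)
    }
  }
  structure(
    list(
      moderate_strength_bouts = as.integer(moderate_strength_bouts),
      high_strength_bouts = as.integer(high_strength_bouts),
      sprint_within_time = sprint_within_time,
      endurance_types_completed = endurance_types_completed,
      regional_completed = regional_completed,
      stress_test_passed = stress_test_passed,
      recovery_time = recovery_time,
      group_mean_recovery_time = group_mean_recovery_time,
      basic_skills_standard = basic_skills_standard
    ),
    class = "session_log"
  )
}

#' Score one indicator from a session log
#'
#' Applies the rule for a single indicator:
#' \describe{
#'   \item{STT (strength)}{10 points for completing both the 6 moderate-
#'     intensity and the 3 high-intensity bout quotas; 5 for exactly one
#'     quota; 0 otherwise. Quotas are minimums — exceeding them still scores.}
#'   \item{SPT (speed)}{10 if the 100 m sprint was within time, else 0.}
#'   \item{ENT (endurance)}{10 for completing all three of aerobic,
#'     anaerobic and hybrid training; 5 for exactly two; 0 otherwise.}
#'   \item{RET (regional)}{10 for completing both barrier-free and
#'     obstacle conditions; 5 for one; 0 otherwise.}
#'   \item{RST (resisted stress)}{10 if the stress test was passed, else 0.}
#'   \item{RCT (recovery)}{5 if recovery time is strictly higher than the
#'     group mean, else 10. Equal-to-mean recovery scores 10; there is no
#'     0 level.}
#'   \item{BST (basic skill)}{10 if the basic movements met the standard,
#'     else 0.}
#' }
#'
#' @param log a [session_log()].
#' @param indicator one of `indicator_codes()`.
#' @return The awarded points (a single number from the indicator's
#'   admissible levels).
#' @examples
#' score_indicator(session_log(moderate_strength_bouts = 6,
#'                             high_strength_bouts = 3), "STT")  # 10
#' @export
score_indicator <- function(log, indicator) {
  if (!inherits(log, "session_log")) {
    stop("`log` must be created with session_log()", call. = FALSE)
  }
  indicator <- match.arg(indicator, indicator_codes())
  switch(indicator,
    STT = {
      done <- (log$moderate_strength_bouts >= 6) + (log$high_strength_bouts >= 3)
      c(0, 5, 10)[done + 1]
    },
    SPT = if (log$sprint_within_time) 10 else 0,
    ENT = {
      done <- length(log$endurance_types_completed)
      if (done == 3) 10 else if (done == 2) 5 else 0
    },
    RET = {
      done <- length(log$regional_completed)
      c(0, 5, 10)[done + 1]
    },
    RST = if (log$stress_test_passed) 10 else 0,
    RCT = if (log$recovery_time > log$group_mean_recovery_time) 5 else 10,
    BST = if (log$basic_skills_standard) 10 else 0
  )
}

#' Score all seven indicators of a session
#'
#' @param log a [session_log()].
#' @return A named numeric vector of seven scores in the canonical order
#'   STT, SPT, ENT, RET, RST, RCT, BST.
#' @examples
#' score_session(session_log())  # no conditions met: 0,0,0,0,0,10,0
#' @export
score_session <- function(log) {
  vapply(indicator_codes(), function(k) score_indicator(log, k), numeric(1))
}
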