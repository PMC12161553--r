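#' Configuration for the synthetic session-table generator
#'
#' Describes a training study of `n_athletes` athletes observed for
#' `n_days` days with `sessions_per_day` scored sessions per day (the
#' default 20 x 30 x 4 design yields 2400 athlete-sessions). Scores arise
#' from a latent-trait model: each athlete has a stable ability, each
#' session adds a shared daily-form fluctuation, and each indicator adds
#' its own execution noise; the latent sum is cut into the indicator's
#' ordinal levels. A continuous performance outcome is the
#' `indicator_weights`-weighted sum of the seven scores plus Gaussian
#' noise, and the binary label splits the outcome at its within-dataset
#' median.
#'
#' @param n_athletes,n_days,sessions_per_day positive counts defining the
#'   study design (defaults 20, 30, 4).
#' @param seed optional integer seed; a fixed seed makes the generated
#'   table bit-reproducible.
#' @param indicator_weights seven non-negative weights giving each
#'   indicator's influence on the performance outcome, in the order
#'   `indicator_codes()`. The default concentrates the signal on STT, SPT
#'   and BST, the trio the indicator-importance analysis singles out.
#' @param ability_sd spread (standard deviation) of the stable per-athlete
#'   ability trait; must be > 0. Default 1.
#' @param form_sd spread of the per-session daily-form fluctuation shared
#'   by all indicators within a session; >= 0. Default 2.
#' @param indicator_sd spread of the indicator-specific execution noise
#'   within a session; >= 0. Default 0.5.
#' @param noise_sd spread of the Gaussian noise added to the continuous
#'   performance outcome (points scale); >= 0. Default 1.
#' @param mid_level_prob marginal probability of the 5-point
#'   partial-completion level on the three-level indicators (STT, ENT,
#'   RET); must lie in \[0.05, 0.9\] so every admissible level keeps
#'   probability at least 0.05. Default 0.10.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_dataset()]
#' @export
generator_config <- function(n_athletes = 20, n_days = 30, sessions_per_day = 4,
                             seed = NULL,
                             indicator_weights = c(1, 1, 0.3, 0.15, 0.3, 0.15, 1),
                             ability_sd = 1, form_sd = 2, indicator_sd = 0.5,
                             noise_sd = 1, mid_level_prob = 0.10) {
  check_count <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x)) {
      stop("invalid configuration: `", name, "` must be a single integer >= 1",
           call. = FALSE)
    }
  }
  check_count(n_athletes, "n_athletes")
  check_count(n_days, "n_days")
  check_count(sessions_per_day, "sessions_per_day")
  if (!is.numeric(indicator_weights) || length(indicator_weights) != 7 ||
      anyNA(indicator_weights) || any(indicator_weights < 0)) {
    stop("invalid configuration: `indicator_weights` must be 7 non-negative numbers",
         call. = FALSE)
  }
  if (all(indicator_weights == 0)) {
    stop("invalid configuration: `indicator_weights` must not be all zero",
         call. = FALSE)
  }
  if (!is.numeric(ability_sd) || length(ability_sd) != 1 || is.na(ability_sd) ||
      ability_sd <= 0) {
    stop("invalid configuration: `ability_sd` must be a single number > 0",
         call. = FALSE)
  }
  for (nm in c("form_sd", "indicator_sd", "noise_sd")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || is.na(val) || val < 0) {
      stop("invalid configuration: `", nm, "` must be a single number >= 0",
           call. = FALSE)
    }
  }
  if (!is.numeric(mid_level_prob) || length(mid_level_prob) != 1 ||
      is.na(mid_level_prob) || mid_level_prob < 0.05 || mid_level_prob > 0.9) {
    stop("invalid configuration: `mid_level_prob` must lie in [0.05, 0.9]",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
      stop("invalid configuration: `seed` must be a single integer or NULL",
           call. = FALSE)
    }
    seed <- as.integer(seed)
  }
  structure(
    list(
      n_athletes = as.integer(n_athletes),
      n_days = as.integer(n_days),
      sessions_per_day = as.integer(sessions_per_day),
      seed = seed,
      indicator_weights = as.numeric(indicator_weights),
      ability_sd = ability_sd,
      form_sd = form_sd,
      indicator_sd = indicator_sd,
      noise_sd = noise_sd,
      mid_level_prob = mid_level_prob
    ),
    class = "generator_config"
  )
}

#' Generate a synthetic athlete training session table
#'
#' Draws a full session table under the latent-trait model described in
#' [generator_config()]. Rows are athlete-sessions (athletes x days x
#' sessions per day); the seven indicator columns carry ordinal scores
#' respecting each indicator's admissible levels. The returned table also
#' carries the continuous `latent_outcome` and the binary `label`
#' (1 = outcome at or above the dataset median).
#'
#' Level cutpoints are placed on the latent scale so that each completion
#' bit (score >= 5) is balanced at 50% marginally and the 5-point partial
#' level of three-level indicators keeps probability `mid_level_prob`.
#'
#' @param config a [generator_config()].
#' @return A `data.frame` of class `session_table` with columns
#'   `athlete_id`, `session` (within-day ordinal label, "1st".."4th"),
#'   the seven indicator columns `STT`..`BST`, `latent_outcome`, `label`.
#' @examples
#' tab <- generate_dataset(generator_config(seed = 1))
#' dim(tab)        # 2400 rows
#' table(tab$STT)  # ordinal levels 0/5/10
#' @export
generate_dataset <- function(config = generator_config()) {
  if (!inherits(config, "generator_config")) {
    stop("`config` must be created with generator_config()", call. = FALSE)
  }
  codes <- indicator_codes()
  n <- config$n_athletes * config$n_days * config$sessions_per_day
  with_rng(config$seed, {
    ability <- rep(stats::rnorm(config$n_athletes, 0, config$ability_sd),
                   each = config$n_days * config$sessions_per_day)
    form <- stats::rnorm(n, 0, config$form_sd)
    z <- matrix(ability + form, n, 7) +
      matrix(stats::rnorm(n * 7, 0, config$indicator_sd), n, 7)
    total_sd <- sqrt(config$ability_sd^2 + config$form_sd^2 + config$indicator_sd^2)
    # three-level marginals: P(0) = 0.5, P(5) = mid_level_prob, P(10) = rest
    cut_mid <- stats::qnorm(0.5 + config$mid_level_prob, 0, total_sd)
    scores <- matrix(0, n, 7, dimnames = list(NULL, codes))
    for (k in c(1L, 3L, 4L)) {             # STT, ENT, RET in {0,5,10}
      scores[, k] <- ifelse(z[, k] < 0, 0, ifelse(z[, k] < cut_mid, 5, 10))
    }
    for (k in c(2L, 5L, 7L)) {             # SPT, RST, BST in {0,10}
      scores[, k] <- ifelse(z[, k] < 0, 0, 10)
    }
    scores[, 6L] <- ifelse(z[, 6L] < 0, 5, 10)  # RCT in {5,10}
    outcome <- as.vector(scores %*% config$indicator_weights) +
      stats::rnorm(n, 0, config$noise_sd)
    label <- as.integer(outcome >= stats::median(outcome))
    tab <- data.frame(
      athlete_id = rep(paste0("A", seq_len(config$n_athletes)),
                       each = config$n_days * config$sessions_per_day),
      session = rep(ordinal_label(seq_len(config$sessions_per_day)),
                    times = config$n_athletes * config$n_days),
      scores,
      latent_outcome = outcome,
      label = label,
      stringsAsFactors = FALSE
    )
    class(tab) <- c("session_table", "data.frame")
    tab
  })
}

#' Write a session table to CSV
#'
#' Serialises a session table as comma-separated text with the header
#' `ID,session,ind1,...,ind7[,label]` (indicator columns in canonical
#' order STT..BST). The continuous `latent_outcome`, when present, is not
#' serialised; [read_dataset()] restores everything else losslessly.
#'
#' @param table a session table (`data.frame` with `athlete_id`,
#'   `session` and the seven indicator columns; `label` optional).
#' @param destination path of the file to write.
#' @return The destination path, invisibly.
#' @export
write_dataset <- function(table, destination) {
  codes <- indicator_codes()
  if (!is.data.frame(table) ||
      !all(c("athlete_id", "session", codes) %in% names(table))) {
    stop("`table` must contain athlete_id, session and the seven indicator columns",
         call. = FALSE)
  }
  out <- data.frame(
    ID = table$athlete_id,
    session = table$session,
    stringsAsFactors = FALSE
  )
  for (k in seq_along(codes)) out[[paste0("ind", k)]] <- table[[codes[k]]]
  if ("label" %in% names(table)) out$label <- table$label
  ok <- tryCatch({
    utils::write.table(out, destination, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    stop("cannot write dataset to '", destination, "': ",
         conditionMessage(ok), call. = FALSE)
  }
  invisible(destination)
}

#' Read a session table from CSV
#'
#' Parses a file written by [write_dataset()] (or an external file using
#' the same layout: header `ID,session,ind1..ind7` with an optional
#' trailing `label`). Scores are validated against each indicator's
#' admissible levels; the session column is accepted as free text.
#'
#' @param source path of the CSV file.
#' @return A `session_table` data.frame (without `latent_outcome`; the
#'   `label` column only if present in the file).
#' @export
read_dataset <- function(source) {
  if (!file.exists(source)) {
    stop("file not found: '", source, "'", call. = FALSE)
  }
  raw <- utils::read.csv(source, stringsAsFactors = FALSE)
  expected <- c("ID", "session", paste0("ind", 1:7))
  if (ncol(raw) < length(expected) ||
      !identical(names(raw)[seq_along(expected)], expected) ||
      !(ncol(raw) == length(expected) ||
        (ncol(raw) == length(expected) + 1 && names(raw)[ncol(raw)] == "label"))) {
    stop("unrecognised dataset header: expected ID,session,ind1..ind7[,label], got ",
         paste(names(raw), collapse = ","), call. = FALSE)
  }
  codes <- indicator_codes()
  tab <- data.frame(
    athlete_id = as.character(raw$ID),
    session = as.character(raw$session),
    stringsAsFactors = FALSE
  )
  for (k in seq_along(codes)) {
    v <- raw[[paste0("ind", k)]]
    if (!is.numeric(v) && nrow(raw) > 0) {
      stop("non-numeric scores in indicator column ind", k, call. = FALSE)
    }
    tab[[codes[k]]] <- as.numeric(v)
  }
  if (nrow(tab) > 0) check_score_levels(as.matrix(tab[, codes]))
  if ("label" %in% names(raw)) tab$label <- as.integer(raw$label)
  class(tab) <- c("session_table", "data.frame")
  tab
}
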