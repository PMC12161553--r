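#' Bipolar encoding of indicator scores
#'
#' Maps each ordinal score to a neuron state: +1 for at least partial
#' completion (score >= 5), -1 for failure. One neuron per indicator
#' gives the 7-neuron network of the standard design. Note that RCT,
#' whose levels are \{5, 10\}, always encodes +1.
#'
#' @param scores a 7-entry score vector, a score matrix (rows = sessions)
#'   or a session table; levels are validated per indicator.
#' @return A bipolar matrix with one row per session and columns named by
#'   `indicator_codes()`.
#' @examples
#' encode_scores(c(10, 0, 5, 10, 0, 10, 10))
#' @export
encode_scores <- function(scores) {
  m <- as_score_matrix(scores)
  check_score_levels(m)
  out <- ifelse(m >= 5, 1L, -1L)
  dimnames(out) <- list(NULL, indicator_codes())
  out
}

#' Binary performance label from total score
#'
#' Labels a session positive when its total indicator score reaches the
#' cutoff. With all seven indicators the total ranges 0-70; the default
#' cutoff 40 asks for clearly more than half the attainable points.
#'
#' @param scores scores as in [encode_scores()].
#' @param cutoff total-points cutoff in \[0, 70\] (default 40; a total
#'   exactly at the cutoff is positive).
#' @return An integer vector of labels (1 = positive, 0 = negative).
#' @export
label_scores <- function(scores, cutoff = 40) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
      cutoff < 0 || cutoff > 70) {
    stop("`cutoff` must be a single number in [0, 70]", call. = FALSE)
  }
  m <- as_score_matrix(scores)
  check_score_levels(m)
  as.integer(rowSums(m) >= cutoff)
}

#' Shuffle-and-partition train/test/validation split
#'
#' Shuffles the row indices with the seeded RNG and partitions them into
#' train, test and validation sets whose sizes are the fractions of the
#' total under largest-remainder rounding (so 2400 rows at 0.6/0.2/0.2
#' give exactly 1440/480/480).
#'
#' @param table a session table, or a single row count.
#' @param fractions three non-negative fractions summing to 1.
#' @param seed optional RNG seed; the split is deterministic per seed.
#' @return An object of class `split_dataset`: a list with integer index
#'   vectors `train`, `test`, `validation`.
#' @export
split_dataset <- function(table, fractions = c(0.6, 0.2, 0.2), seed = NULL) {
  n <- if (is.data.frame(table)) nrow(table) else {
    if (!is.numeric(table) || length(table) != 1 || table < 0 ||
        table != floor(table)) {
      stop("`table` must be a data.frame or a single row count", call. = FALSE)
    }
    as.integer(table)
  }
  if (!is.numeric(fractions) || length(fractions) != 3 || anyNA(fractions) ||
      any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be 3 non-negative numbers summing to 1", call. = FALSE)
  }
  base <- floor(n * fractions)
  remainder <- n * fractions - base
  short <- n - sum(base)
  if (short > 0) {
    top_up <- order(remainder, decreasing = TRUE)[seq_len(short)]
    base[top_up] <- base[top_up] + 1
  }
  idx <- with_rng(seed, sample.int(n))
  ends <- cumsum(base)
  structure(
    list(
      train = sort(idx[seq_len(base[1])]),
      test = sort(idx[seq_len(base[2]) + ends[1]]),
      validation = sort(idx[seq_len(base[3]) + ends[2]])
    ),
    class = "split_dataset", sizes = as.integer(base)
  )
}

#' Fit the Markov-threshold Hopfield forecaster
#'
#' Implements the training stage: per-neuron activation thresholds are
#' extracted from the m-step Markov transition matrix of the raw training
#' score matrix ([first_step_matrix()] then [step_matrix()] with m equal
#' to the neuron count, then [markov_thresholds()]); one bipolar class
#' prototype per label is formed as the elementwise sign of the class
#' mean encoded pattern (ties resolved to +1); the prototypes are stored
#' by [hebbian_weights()]; and every distinct training pattern is run to
#' convergence to report the attractor dynamics.
#'
#' @param table a session table (or score matrix) of training rows.
#' @param labels binary labels for the rows; taken from `table$label`
#'   when omitted. Both classes must be present.
#' @param config a [fit_config()] controlling the dynamics.
#' @param markov_mode passed to [first_step_matrix()]. With the `"shape_adaptive"`
#'   mode and more rows than indicators the transition matrix lives in
#'   observation space and its threshold vector cannot drive the 7-neuron
#'   network; this raises an error suggesting `"indicator_space"`.
#' @return An object of class `dhnn_model`.
#' @seealso [predict.dhnn_model()], [run_pipeline()]
#' @export
fit_dhnn <- function(table, labels = NULL, config = fit_config(),
                     markov_mode = c("indicator_space", "shape_adaptive")) {
  markov_mode <- match.arg(markov_mode)
  S <- as_score_matrix(table)
  check_score_levels(S)
  if (is.null(labels)) {
    if (is.data.frame(table) && "label" %in% names(table)) {
      labels <- table$label
    } else {
      stop("`labels` must be supplied (or present as a `label` column)",
           call. = FALSE)
    }
  }
  if (length(labels) != nrow(S)) {
    stop("`labels` length does not match the number of rows", call. = FALSE)
  }
  if (nrow(S) < 1) stop("training slice is empty", call. = FALSE)
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2) {
    universe <- if (all(labels %in% c(0, 1))) c("0", "1") else NULL
    missing <- if (!is.null(universe)) setdiff(universe, classes) else NULL
    stop("training slice must contain both classes",
         if (length(missing)) paste0(" (missing class ", missing, ")") else
           paste0(" (found only: ", paste(classes, collapse = ", "), ")"),
         call. = FALSE)
  }

  P1 <- first_step_matrix(S, mode = markov_mode)
  m <- nrow(P1)
  Pm <- step_matrix(P1, m)
  thresholds <- markov_thresholds(Pm)
  X <- encode_scores(S)
  n_neurons <- ncol(X)
  if (length(thresholds) != n_neurons) {
    stop("the '", markov_mode, "' Markov mode produced ", length(thresholds),
         " thresholds for a ", n_neurons, "-neuron network; use markov_mode = ",
         '"indicator_space" so thresholds live in indicator space', call. = FALSE)
  }

  prototypes <- t(vapply(classes, function(cl) {
    p <- sgn(colMeans(X[as.character(labels) == cl, , drop = FALSE]))
    as.integer(p)
  }, integer(n_neurons)))
  rownames(prototypes) <- classes
  colnames(prototypes) <- colnames(X)

  W <- hebbian_weights(prototypes)

  # attractor report over the distinct training patterns
  uniq <- unique(X)
  runs <- apply(uniq, 1, function(x0)
    run_to_convergence(W, x0, thresholds, config))
  pattern_sweeps <- vapply(runs, `[[`, integer(1), "sweeps")
  pattern_conv <- vapply(runs, `[[`, logical(1), "converged")

  structure(
    list(
      weights = W,
      thresholds = thresholds,
      prototypes = prototypes,
      classes = classes,
      config = config,
      markov = list(mode = markov_mode, branch = attr(P1, "branch"),
                    P1 = P1, Pm = Pm, m = m),
      convergence = list(
        n_patterns = nrow(uniq),
        all_converged = all(pattern_conv),
        max_sweeps = max(pattern_sweeps),
        mean_sweeps = mean(pattern_sweeps)
      ),
      n_train = nrow(S)
    ),
    class = "dhnn_model"
  )
}

#' @export
print.dhnn_model <- function(x, ...) {
  cat("Markov-threshold discrete Hopfield forecaster\n")
  cat("  neurons:     ", ncol(x$prototypes), " (", paste(colnames(x$prototypes),
      collapse = ", "), ")\n", sep = "")
  cat("  classes:     ", paste(x$classes, collapse = " / "), "\n", sep = "")
  cat("  trained on:  ", x$n_train, " sessions\n", sep = "")
  cat("  thresholds:  ", paste(sprintf("%.3f", x$thresholds), collapse = " "),
      "\n", sep = "")
  cat("  markov mode: ", x$markov$mode, " (m = ", x$markov$m, ")\n", sep = "")
  cat("  attractors:  ", x$convergence$n_patterns, " distinct patterns, ",
      if (x$convergence$all_converged) "all converged" else "NOT all converged",
      ", max ", x$convergence$max_sweeps, " sweeps\n", sep = "")
  invisible(x)
}

# internal: relax each encoded row to its attractor and measure Hamming
# distances to the prototypes; deduplicates identical patterns.
relax_and_distances <- function(model, X) {
  key <- apply(X, 1, paste, collapse = ",")
  uniq_keys <- unique(key)
  uniq <- X[match(uniq_keys, key), , drop = FALSE]
  D <- matrix(0, nrow(uniq), nrow(model$prototypes),
              dimnames = list(NULL, model$classes))
  for (r in seq_len(nrow(uniq))) {
    final <- run_to_convergence(model$weights, uniq[r, ], model$thresholds,
                                model$config)$state
    D[r, ] <- colSums(t(model$prototypes) != final)
  }
  D[match(key, uniq_keys), , drop = FALSE]
}

#' Predict classes with a fitted forecaster
#'
#' Encodes each row, lets the network relax from the encoded state to an
#' attractor, and assigns the class whose prototype is nearest to the
#' final state in Hamming distance; ties go to the first (sorted) class
#' label.
#'
#' @param object a fitted `dhnn_model`.
#' @param newdata scores as in [encode_scores()].
#' @param ... unused.
#' @return A character vector of class labels.
#' @export
predict.dhnn_model <- function(object, newdata, ...) {
  X <- encode_scores(newdata)
  D <- relax_and_distances(object, X)
  object$classes[apply(D, 1, which.min)]   # which.min takes the first on ties
}

#' Continuous forecast confidence
#'
#' The signed Hamming margin of the relaxed state: distance to the first
#' (negative) prototype minus distance to the second (positive)
#' prototype. Positive margins favour the positive class; magnitude
#' grows with the separation between the attractor and the rival
#' prototype.
#'
#' @inheritParams predict.dhnn_model
#' @param model a fitted `dhnn_model`.
#' @return A numeric vector of margins.
#' @export
forecast_margin <- function(model, newdata) {
  X <- encode_scores(newdata)
  D <- relax_and_distances(model, X)
  D[, 1] - D[, 2]
}

#' Confusion-matrix metrics of a forecast
#'
#' Computes accuracy, precision, recall, F1 (harmonic mean of precision
#' and recall) and G-score (geometric mean of precision and recall) from
#' predicted and true binary labels. A degenerate denominator (no
#' predicted positives, or no true positives) yields 0 for the affected
#' metric and sets the `degenerate` flag.
#'
#' @param predictions,truths equal-length binary label vectors.
#' @param positive the label counted as positive; defaults to the
#'   largest (last sorted) label of `truths`.
#' @return An object of class `forecast_metrics`: a list with `accuracy`,
#'   `precision`, `recall`, `f1`, `g_score`, the confusion `counts`
#'   (tp, fp, fn, tn) and the `degenerate` flag.
#' @examples
#' evaluate_forecast(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
evaluate_forecast <- function(predictions, truths, positive = NULL) {
  if (length(predictions) != length(truths) || length(truths) == 0) {
    stop("`predictions` and `truths` must be non-empty and of equal length",
         call. = FALSE)
  }
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (is.null(positive)) positive <- max(sort(unique(truths)))
  positive <- as.character(positive)
  tp <- sum(predictions == positive & truths == positive)
  fp <- sum(predictions == positive & truths != positive)
  fn <- sum(predictions != positive & truths == positive)
  tn <- sum(predictions != positive & truths != positive)
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- ratio(2 * precision * recall, precision + recall)
  structure(
    list(
      accuracy = (tp + tn) / length(truths),
      precision = precision,
      recall = recall,
      f1 = f1,
      g_score = sqrt(precision * recall),
      counts = c(tp = tp, fp = fp, fn = fn, tn = tn),
      positive = positive,
      degenerate = degenerate
    ),
    class = "forecast_metrics"
  )
}

#' @export
print.forecast_metrics <- function(x, ...) {
  cat(sprintf(
    "accuracy %.3f | precision %.3f | recall %.3f | F1 %.3f | G-score %.3f\n",
    x$accuracy, x$precision, x$recall, x$f1, x$g_score))
  cat(sprintf("counts: TP %d FP %d FN %d TN %d (positive = %s)%s\n",
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"],
              x$positive,
              if (x$degenerate) " [degenerate denominator]" else ""))
  invisible(x)
}

#' Run the full forecasting pipeline
#'
#' Splits the session table 60/20/20 into train/test/validation, fits the
#' Markov-threshold Hopfield forecaster on the training slice, and
#' evaluates it on all three slices: the training accuracy, the testing
#' accuracy and the predicted (validation) accuracy, each with the full
#' metric set.
#'
#' @param table a session table with a `label` column (e.g. from
#'   [generate_dataset()]); if `label` is absent it is derived with
#'   [label_scores()] at `label_cutoff`.
#' @param fractions train/test/validation fractions (default 0.6/0.2/0.2).
#' @param config a [fit_config()].
#' @param markov_mode passed to [fit_dhnn()].
#' @param seed RNG seed for the split.
#' @param label_cutoff cutoff for [label_scores()] when the table has no
#'   `label` column (default 40).
#' @return An object of class `dhnn_report`: a list with `metrics`
#'   (train/test/validation [evaluate_forecast()] objects), the fitted
#'   `model`, the `split` sizes and the seed.
#' @examples
#' tab <- generate_dataset(generator_config(n_athletes = 4, n_days = 5, seed = 1))
#' run_pipeline(tab, seed = 1)
#' @export
run_pipeline <- function(table, fractions = c(0.6, 0.2, 0.2),
                         config = fit_config(),
                         markov_mode = c("indicator_space", "shape_adaptive"),
                         seed = NULL, label_cutoff = 40) {
  markov_mode <- match.arg(markov_mode)
  if (!is.data.frame(table)) {
    stop("`table` must be a session table (data.frame)", call. = FALSE)
  }
  if (!"label" %in% names(table)) {
    table$label <- label_scores(table, cutoff = label_cutoff)
  }
  parts <- split_dataset(table, fractions, seed = seed)
  train <- table[parts$train, , drop = FALSE]
  model <- fit_dhnn(train, config = config, markov_mode = markov_mode)
  eval_slice <- function(rows) {
    slice <- table[rows, , drop = FALSE]
    evaluate_forecast(predict(model, slice), slice$label)
  }
  structure(
    list(
      metrics = list(
        train = eval_slice(parts$train),
        test = eval_slice(parts$test),
        validation = eval_slice(parts$validation)
      ),
      model = model,
      split = attr(parts, "sizes"),
      indices = parts,
      seed = seed
    ),
    class = "dhnn_report"
  )
}

#' @export
print.dhnn_report <- function(x, ...) {
  cat("DHNN forecast report (split ",
      paste(x$split, collapse = "/"), ")\n", sep = "")
  for (nm in names(x$metrics)) {
    m <- x$metrics[[nm]]
    cat(sprintf("  %-10s acc %.3f  prec %.3f  rec %.3f  F1 %.3f  G %.3f\n",
                nm, m$accuracy, m$precision, m$recall, m$f1, m$g_score))
  }
  cat("  thresholds: ", paste(sprintf("%.3f", x$model$thresholds), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
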