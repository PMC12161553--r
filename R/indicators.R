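#' The seven training indicators
#'
#' The indicator battery covers the physical-fitness factors (strength,
#' speed, endurance) and the skill/condition factors (regional,
#' resisted-stress, recovery, basic-skill) of event-group training theory.
#' Each session is scored per indicator on an ordinal point scale; the
#' admissible point levels differ by indicator: `STT`, `ENT` and `RET`
#' use \{0, 5, 10\}, `SPT`, `RST` and `BST` use \{0, 10\}, and `RCT` uses
#' \{5, 10\} (recovery is never scored 0 — slower-than-average recovery
#' still earns 5 points).
#'
#' @return `indicator_codes()` returns the seven indicator codes in
#'   canonical column order; `indicator_levels()` returns a named list of
#'   admissible score levels per indicator.
#' @examples
#' indicator_codes()
#' indicator_levels()$RCT
#' @export
indicator_codes <- function() {
  c("STT", "SPT", "ENT", "RET", "RST", "RCT", "BST")
}

#' @rdname indicator_codes
#' @export
indicator_levels <- function() {
  list(
    STT = c(0, 5, 10),
    SPT = c(0, 10),
    ENT = c(0, 5, 10),
    RET = c(0, 5, 10),
    RST = c(0, 10),
    RCT = c(5, 10),
    BST = c(0, 10)
  )
}

# internal: assert a score matrix/data.frame obeys the per-indicator level
# sets; reports the first offending row/column on failure.
check_score_levels <- function(scores, where = "scores") {
  codes <- indicator_codes()
  levels <- indicator_levels()
  for (k in seq_along(codes)) {
    bad <- which(!(scores[, k] %in% levels[[codes[k]]]))
    if (length(bad) > 0) {
      stop(sprintf(
        "invalid score %s for indicator %s (column %d) at row %d: allowed levels are {%s}",
        format(scores[bad[1], k]), codes[k], k, bad[1],
        paste(levels[[codes[k]]], collapse = ", ")
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# internal: pull the 7-column score matrix out of whatever the user handed us
as_score_matrix <- function(x) {
  codes <- indicator_codes()
  if (is.data.frame(x)) {
    if (!all(codes %in% names(x))) {
      stop("expected a session table with the seven indicator columns ",
           paste(codes, collapse = ", "), call. = FALSE)
    }
    x <- as.matrix(x[, codes])
  } else if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != 7L) {
      stop("a score vector must have exactly 7 entries (one per indicator), got ",
           length(x), call. = FALSE)
    }
    x <- matrix(x, nrow = 1, dimnames = list(NULL, codes))
  } else if (is.matrix(x)) {
    if (ncol(x) != 7L) {
      stop("a score matrix must have exactly 7 columns, got ", ncol(x), call. = FALSE)
    }
    colnames(x) <- codes
  } else {
    stop("cannot interpret object of class ", class(x)[1], " as indicator scores",
         call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

# internal: run expr with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards; NULL seed means "use the current RNG stream".
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# internal: English ordinal labels 1 -> "1st", 2 -> "2nd", 11 -> "11th", ...
ordinal_label <- function(i) {
  suffix <- rep("th", length(i))
  last2 <- i %% 100
  last1 <- i %% 10
  suffix[last1 == 1 & last2 != 11] <- "st"
  suffix[last1 == 2 & last2 != 12] <- "nd"
  suffix[last1 == 3 & last2 != 13] <- "rd"
  paste0(i, suffix)
}
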