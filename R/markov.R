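#' Row-normalise a non-negative matrix into a one-step transition matrix
#'
#' Divides every row by its sum so the result is row-stochastic. A row
#' that sums to zero carries no probabilistic information and is replaced
#' by the uniform distribution over the columns.
#'
#' @param m a non-negative numeric matrix.
#' @return A row-stochastic matrix of the same shape with attribute
#'   `step = 1`.
#' @examples
#' normalize_rows(rbind(c(10, 5, 5), c(0, 10, 10)))
#' @export
normalize_rows <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || anyNA(m)) {
    stop("`m` must be a numeric matrix without missing values", call. = FALSE)
  }
  if (any(m < 0)) {
    stop("`m` must be non-negative to define transition probabilities",
         call. = FALSE)
  }
  rs <- rowSums(m)
  zero <- rs == 0
  out <- m / ifelse(rs == 0, 1, rs)
  if (any(zero)) out[zero, ] <- 1 / ncol(m)
  structure(out, step = 1L)
}

#' First-step Markov probability transition matrix of a score matrix
#'
#' Builds the one-step transition matrix P(1) from a V x K training score
#' matrix S (rows = observations, columns = indicators). Two modes are
#' offered:
#' \describe{
#'   \item{`"indicator_space"` (default)}{always row-normalises the Gram
#'     matrix \eqn{S^T S}, giving a K x K matrix over the indicator
#'     neurons regardless of the V:K ratio. This matches a network with
#'     one neuron per indicator (m = K = 7 in the standard design) and
#'     keeps the construction linear in V.}
#'   \item{`"shape_adaptive"`}{branches on the shape: if K = V, row-normalise S
#'     itself (m = K); if K > V, row-normalise \eqn{S^T S} (m = K); if
#'     K < V, row-normalise \eqn{S S^T} (m = V). Note the K < V branch
#'     ties the neuron count to the observation count, which conflicts
#'     with a fixed-size indicator network; it is provided for fidelity.}
#' }
#'
#' @param S a non-negative numeric matrix (or session table) of scores.
#' @param mode `"indicator_space"` or `"shape_adaptive"`.
#' @return A row-stochastic m x m matrix with attributes `step = 1` and
#'   `branch` (one of `"direct"`, `"gram_indicator"`, `"gram_observation"`).
#' @export
first_step_matrix <- function(S, mode = c("indicator_space", "shape_adaptive")) {
  mode <- match.arg(mode)
  if (is.data.frame(S)) S <- as_score_matrix(S)
  S <- as.matrix(S)
  if (!is.numeric(S) || anyNA(S)) {
    stop("`S` must be a numeric matrix without missing values", call. = FALSE)
  }
  if (any(S < 0)) stop("`S` must be non-negative", call. = FALSE)
  V <- nrow(S); K <- ncol(S)
  if (mode == "indicator_space") {
    P <- normalize_rows(crossprod(S))          # t(S) %*% S, K x K
    branch <- "gram_indicator"
  } else if (K == V) {
    P <- normalize_rows(S)
    branch <- "direct"
  } else if (K > V) {
    P <- normalize_rows(crossprod(S))
    branch <- "gram_indicator"
  } else {
    P <- normalize_rows(tcrossprod(S))         # S %*% t(S), V x V
    branch <- "gram_observation"
  }
  attr(P, "branch") <- branch
  P
}

#' m-step transition matrix
#'
#' Raises a one-step transition matrix to the m-th power
#' (Chapman-Kolmogorov), so entry (i, j) is the probability of moving
#' from state i to state j in m steps. Uses exponentiation by squaring.
#'
#' @param P1 a row-stochastic square matrix.
#' @param m number of steps (integer >= 1).
#' @return The m-step matrix with attribute `step = m`.
#' @examples
#' P1 <- rbind(c(0.5, 0.5), c(0.25, 0.75))
#' step_matrix(P1, 2)
#' @export
step_matrix <- function(P1, m) {
  P1 <- as.matrix(P1)
  if (nrow(P1) != ncol(P1)) stop("`P1` must be square", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1 || is.na(m) || m < 1 || m != floor(m)) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  check_stochastic(P1)
  m <- as.integer(m)
  result <- diag(nrow(P1))
  base <- unclass(P1)
  e <- m
  while (e > 0) {
    if (e %% 2L == 1L) result <- result %*% base
    base <- base %*% base
    e <- e %/% 2L
  }
  dimnames(result) <- dimnames(P1)
  structure(result, step = m)
}

#' Per-neuron activation thresholds from an m-step transition matrix
#'
#' The threshold of neuron i is the maximum entry of row i of P(m): the
#' largest m-step probability reachable from state i, read as the
#' probability with which the i-th neuron is activated. Row maxima of a
#' row-stochastic matrix lie in (0, 1] and are at least 1/m.
#'
#' @param Pm a row-stochastic square matrix (e.g. from [step_matrix()]).
#' @return A numeric vector of per-row maxima.
#' @export
markov_thresholds <- function(Pm) {
  Pm <- as.matrix(Pm)
  check_stochastic(Pm)
  apply(Pm, 1, max)
}

# internal: row-stochasticity check, 1e-9 absolute per row
check_stochastic <- function(P, tol = 1e-9) {
  if (!is.numeric(P) || anyNA(P)) {
    stop("transition matrix must be numeric without missing values", call. = FALSE)
  }
  if (any(P < -tol) || any(P > 1 + tol)) {
    stop("transition matrix entries must lie in [0, 1]", call. = FALSE)
  }
  dev <- abs(rowSums(P) - 1)
  if (any(dev > tol)) {
    stop(sprintf("transition matrix row %d sums to %.12f, not 1",
                 which.max(dev), rowSums(P)[which.max(dev)]), call. = FALSE)
  }
  invisible(TRUE)
}
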