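#' Sign activation
#'
#' The bipolar threshold activation of the discrete Hopfield network:
#' +1 for a non-negative net input, -1 otherwise (zero maps to +1).
#'
#' @param x numeric vector of finite values.
#' @return An integer vector of +1/-1.
#' @examples
#' sgn(c(-0.1, 0, 2.5))
#' @export
sgn <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be finite numeric", call. = FALSE)
  }
  ifelse(x >= 0, 1L, -1L)
}

#' Hebbian outer-product weights
#'
#' Stores bipolar patterns in a symmetric zero-diagonal weight matrix by
#' the classic Hebbian rule \eqn{w_{ij} = (1/n) \sum_p \xi_{p,i} \xi_{p,j}}
#' for \eqn{i \ne j}, so each stored pattern becomes an attractor of the
#' dynamics (within capacity).
#'
#' @param patterns a matrix with one bipolar (+1/-1) pattern per row, or
#'   a list of equal-length bipolar vectors.
#' @return An n x n symmetric numeric matrix with zero diagonal.
#' @examples
#' hebbian_weights(rbind(c(1, -1, 1)))
#' @export
hebbian_weights <- function(patterns) {
  if (is.list(patterns)) {
    if (length(patterns) == 0) stop("need at least one pattern", call. = FALSE)
    lens <- lengths(patterns)
    if (length(unique(lens)) != 1) {
      stop("all patterns must have the same length", call. = FALSE)
    }
    patterns <- do.call(rbind, patterns)
  }
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 1) stop("need at least one pattern", call. = FALSE)
  if (!all(patterns %in% c(-1, 1))) {
    stop("patterns must be bipolar (+1/-1)", call. = FALSE)
  }
  n <- ncol(patterns)
  W <- crossprod(patterns) / n
  diag(W) <- 0
  W
}

#' Hopfield energy
#'
#' The Lyapunov function of the thresholded network,
#' \eqn{E = -\frac{1}{2} \sum_{i,j} w_{ij} x_i x_j + \lambda \sum_j T_j x_j}.
#' Asynchronous sign-threshold updates on a symmetric zero-diagonal
#' weight matrix never increase this quantity, which is what guarantees
#' convergence to a fixed point.
#'
#' @param W symmetric zero-diagonal weight matrix.
#' @param x bipolar state vector.
#' @param thresholds per-neuron thresholds (default 0).
#' @param lambda threshold scale \eqn{\lambda \ge 0} (default 1).
#' @return The scalar energy.
#' @export
hopfield_energy <- function(W, x, thresholds = 0, lambda = 1) {
  W <- as.matrix(W)
  n <- length(x)
  if (nrow(W) != n || ncol(W) != n) {
    stop("dimensions of `W` and `x` disagree", call. = FALSE)
  }
  thresholds <- rep_len(thresholds, n)
  -0.5 * sum(x * (W %*% x)) + lambda * sum(thresholds * x)
}

#' Configuration of the network dynamics
#'
#' @param j_max maximum number of full asynchronous sweeps (default 1000).
#' @param update_mode `"deterministic"` applies every computed update;
#'   `"stochastic"` applies the computed update of neuron j with
#'   probability equal to its threshold \eqn{T_j} per visit (the
#'   "activated with probability T" reading), otherwise keeping the old
#'   value.
#' @param threshold_scale \eqn{\lambda \ge 0}, multiplies the thresholds
#'   in the net input (default 1; 0 recovers the classic zero-threshold
#'   network).
#' @param seed optional RNG seed governing stochastic acceptance and
#'   shuffled update order.
#' @param neuron_order `"fixed"` sweeps neurons in ascending index;
#'   `"shuffled"` redraws a random order each sweep.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(j_max = 1000, update_mode = c("deterministic", "stochastic"),
                       threshold_scale = 1, seed = NULL,
                       neuron_order = c("fixed", "shuffled")) {
  if (!is.numeric(j_max) || length(j_max) != 1 || is.na(j_max) || j_max < 1) {
    stop("`j_max` must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(threshold_scale) || length(threshold_scale) != 1 ||
      is.na(threshold_scale) || threshold_scale < 0) {
    stop("`threshold_scale` must be a single number >= 0", call. = FALSE)
  }
  structure(
    list(
      j_max = as.integer(j_max),
      update_mode = match.arg(update_mode),
      threshold_scale = threshold_scale,
      seed = if (is.null(seed)) NULL else as.integer(seed),
      neuron_order = match.arg(neuron_order)
    ),
    class = "fit_config"
  )
}

# internal single sweep; assumes the RNG is already positioned.
# Returns list(state, flips, trace-record vectors).
sweep_once <- function(W, x, thresholds, lambda, update_mode, neuron_order) {
  n <- length(x)
  order <- if (neuron_order == "shuffled") sample.int(n) else seq_len(n)
  neuron <- integer(n); net <- numeric(n)
  old <- integer(n); new <- integer(n); energy <- numeric(n)
  flips <- 0L
  for (idx in seq_len(n)) {
    j <- order[idx]
    net_j <- sum(W[, j] * x) - lambda * thresholds[j]
    candidate <- if (net_j >= 0) 1L else -1L
    accept <- if (update_mode == "stochastic") {
      stats::runif(1) < thresholds[j]
    } else TRUE
    neuron[idx] <- j
    net[idx] <- net_j
    old[idx] <- x[j]
    if (accept && candidate != x[j]) {
      x[j] <- candidate
      flips <- flips + 1L
    } else if (accept) {
      x[j] <- candidate
    }
    new[idx] <- x[j]
    energy[idx] <- hopfield_energy(W, x, thresholds, lambda)
  }
  list(state = x, flips = flips,
       trace = data.frame(neuron = neuron, net = net, old = old,
                          new = new, energy = energy))
}

# internal lightweight sweep: no trace, no energies (used in hot loops)
sweep_fast <- function(W, x, thresholds, lambda, update_mode, neuron_order) {
  n <- length(x)
  order <- if (neuron_order == "shuffled") sample.int(n) else seq_len(n)
  flips <- 0L
  for (j in order) {
    net_j <- sum(W[, j] * x) - lambda * thresholds[j]
    candidate <- if (net_j >= 0) 1L else -1L
    accept <- update_mode != "stochastic" || stats::runif(1) < thresholds[j]
    if (accept && candidate != x[j]) {
      x[j] <- candidate
      flips <- flips + 1L
    }
  }
  list(state = x, flips = flips)
}

#' One asynchronous update sweep
#'
#' Visits every neuron once (in fixed or shuffled order). For neuron j
#' the net input is \eqn{net_j = \sum_i w_{ij} x_i - \lambda T_j} and the
#' candidate state is `sgn(net_j)`; in deterministic mode the candidate
#' is always applied, in stochastic mode it is applied with probability
#' \eqn{T_j}.
#'
#' @param W symmetric zero-diagonal weight matrix.
#' @param x bipolar state vector.
#' @param thresholds per-neuron thresholds (recycled; default 0).
#' @param config a [fit_config()].
#' @return A list with `state` (the updated bipolar vector), `flips`
#'   (number of sign changes), and `trace` (a data.frame with one row per
#'   visit: neuron, net, old, new, energy after the visit).
#' @export
update_sweep <- function(W, x, thresholds = 0, config = fit_config()) {
  check_net_args(W, x)
  thresholds <- rep_len(thresholds, length(x))
  with_rng(config$seed,
    sweep_once(W, as.integer(x), thresholds, config$threshold_scale,
               config$update_mode, config$neuron_order))
}

#' Run the network dynamics to convergence
#'
#' Repeats asynchronous sweeps until a full sweep changes no neuron
#' (a fixed point) or `j_max` sweeps elapse. For deterministic updates on
#' a symmetric zero-diagonal weight matrix the energy function descends,
#' so a fixed point is always reached in finitely many sweeps.
#'
#' @inheritParams update_sweep
#' @param x0 the initial bipolar state.
#' @return A list with `state` (final bipolar vector), `sweeps` (number
#'   of sweeps executed, counting the final zero-flip sweep), `converged`
#'   (logical), and `energies` (energy after each sweep).
#' @examples
#' W <- hebbian_weights(rbind(c(1, -1, 1)))
#' run_to_convergence(W, c(-1, -1, 1), config = fit_config(threshold_scale = 0))
#' @export
run_to_convergence <- function(W, x0, thresholds = 0, config = fit_config()) {
  check_net_args(W, x0)
  thresholds <- rep_len(thresholds, length(x0))
  with_rng(config$seed, {
    x <- as.integer(x0)
    energies <- numeric(0)
    converged <- FALSE
    sweeps <- 0L
    for (j in seq_len(config$j_max)) {
      res <- sweep_fast(W, x, thresholds, config$threshold_scale,
                        config$update_mode, config$neuron_order)
      x <- res$state
      sweeps <- j
      energies[j] <- hopfield_energy(W, x, thresholds, config$threshold_scale)
      if (res$flips == 0L) {
        converged <- TRUE
        break
      }
    }
    list(state = x, sweeps = sweeps, converged = converged, energies = energies)
  })
}

# internal: shared argument checks for the dynamics
check_net_args <- function(W, x) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("`W` must be square", call. = FALSE)
  if (length(x) != nrow(W)) {
    stop("state length (", length(x), ") does not match weight matrix size (",
         nrow(W), ")", call. = FALSE)
  }
  if (!all(x %in% c(-1, 1))) stop("state must be bipolar (+1/-1)", call. = FALSE)
  invisible(TRUE)
}
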