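# independent oracles and small fixture builders shared across tests

# naive repeated multiplication (oracle for the squaring-based step_matrix)
naive_matrix_power <- function(P, m) {
  out <- diag(nrow(P))
  for (i in seq_len(m)) out <- out %*% P
  out
}

# random row-stochastic matrix built from uniforms
random_stochastic <- function(n) {
  M <- matrix(stats::runif(n * n), n, n)
  M / rowSums(M)
}

# brute-force stable states of the deterministic dynamics: a state is
# stable iff no single flip is "improving" under the energy, i.e. every
# flip raises the energy, or leaves it unchanged while the rule's
# zero-field tie (net = 0 -> +1) already holds.
stable_states_bruteforce <- function(W, thresholds, lambda) {
  n <- nrow(W)
  states <- as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
  stable <- apply(states, 1, function(x) {
    h <- as.vector(W %*% x) - lambda * thresholds
    delta_e <- 2 * x * h          # energy change of flipping each neuron
    all(delta_e > 0 | (delta_e == 0 & x == 1L))
  })
  states[stable, , drop = FALSE]
}

# all bipolar states of length n, one per row
all_states <- function(n) {
  as.matrix(expand.grid(rep(list(c(-1L, 1L)), n)))
}

# a session log meeting every maximum-score condition
all_max_log <- function() {
  session_log(
    moderate_strength_bouts = 6, high_strength_bouts = 3,
    sprint_within_time = TRUE,
    endurance_types_completed = c("aerobic", "anaerobic", "hybrid"),
    regional_completed = c("barrier_free", "obstacle"),
    stress_test_passed = TRUE,
    recovery_time = 20, group_mean_recovery_time = 30,
    basic_skills_standard = TRUE
  )
}

# a small perfectly separated labelled table: class 1 = all-max scores,
# class 0 = all-min scores (RCT floor 5), n rows per class
separated_table <- function(n_per_class = 8) {
  hi <- c(10, 10, 10, 10, 10, 10, 10)
  lo <- c(0, 0, 0, 0, 0, 5, 0)
  scores <- rbind(
    matrix(hi, n_per_class, 7, byrow = TRUE),
    matrix(lo, n_per_class, 7, byrow = TRUE)
  )
  colnames(scores) <- indicator_codes()
  tab <- data.frame(athlete_id = paste0("A", seq_len(2 * n_per_class)),
                    session = "1st", scores,
                    label = rep(c(1L, 0L), each = n_per_class))
  tab
}
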