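# Shared fixture builders. Everything is generated in code under fixed seeds.

# Tie-free random rank matrix: each row an independent permutation of 1..n.
random_rank_matrix <- function(m, n, seed = 1) {
  set.seed(seed)
  r <- t(vapply(seq_len(m), function(i) sample(n), integer(n)))
  rownames(r) <- paste0("clf", seq_len(m))
  colnames(r) <- paste0("s", seq_len(n))
  r + 0.0
}

# Exact population moments of a two-class mixture with independent
# conditionals: ranks_i | y has mean mu_{i|y}, variance s2[y], zero skew.
# Returns the quantities the unsupervised pipeline consumes.
population_moments <- function(rho, delta, s0, s1) {
  m <- length(delta)
  p <- rho * (1 - rho)
  Q <- p * outer(delta, delta)
  diag(Q) <- rho * s1 + (1 - rho) * s0 + p * delta^2
  m2 <- diag(Q)
  m3 <- 3 * p * delta * (s0 - s1) + p * (2 * rho - 1) * delta^3
  Toff <- array(p * (2 * rho - 1) * outer(outer(delta, delta), delta), c(m, m, m))
  list(Q = Q, T = Toff, m2 = m2, m3 = m3)
}

# Standard simulated ensemble used across tests: M=10 conditionally
# independent classifiers, AUCs spread over [0.55, 0.9], prevalence 0.4.
sim_ensemble <- function(seed, n = 1000, m = 10, rho = 0.4,
                         aucs = seq(0.55, 0.9, length.out = m),
                         corr = diag(m)) {
  simulate_predictions(aucs, rho, n, conditional_corr = corr, seed = seed)
}

# Label-computed independence-form weights: w_i = beta * Delta_i / diag(C)_i.
reference_independent_weights <- function(ranks, labels) {
  mom <- conditioned_moments(ranks, labels)
  w <- mom$delta / diag(mom$C)
  w / sqrt(sum(w^2))
}
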