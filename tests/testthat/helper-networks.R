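# shared test fixtures and independent oracles

# random signed regulatory matrix with at least one nonzero per row
rand_regmat <- function(n, max_pred = n, bias = 0.5) {
  M <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    k <- sample.int(max_pred, 1L)
    cols <- sample.int(n, k)
    M[i, cols] <- ifelse(runif(k) < bias, 1L, -1L)
  }
  regulatory_matrix(M)
}

# brute-force TPM: enumerate every perturbation pattern; the no-flip
# pattern follows the majority-vote map, any other pattern is applied
# to the current state.  Independent of build_tpm's closed form.
brute_tpm <- function(R, p) {
  n <- nrow(R)
  N <- 2^n
  P <- matrix(0, N, N)
  for (x in 0:(N - 1)) {
    v <- state_to_gap(x, n)
    fx <- gap_to_state(majority_vote_update(R, v))
    for (w in 0:(N - 1)) {
      d <- sum(state_to_gap(w, n))
      prob <- p^d * (1 - p)^(n - d)
      y <- if (w == 0L) fx else bitwXor(x, w)
      P[x + 1, y + 1] <- P[x + 1, y + 1] + prob
    }
  }
  P
}

# power-iteration steady state, independent of the linear-solve path
power_ssd <- function(P, tol = 1e-13, max_iter = 100000L) {
  pi <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(max_iter)) {
    nxt <- as.numeric(pi %*% P)
    if (max(abs(nxt - pi)) < tol) return(nxt)
    pi <- nxt
  }
  stop("power iteration did not converge")
}

# hand-constructable controlled class for partition/OBC unit tests
fake_controlled_class <- function(mass, mass_controlled, lambda, Pi) {
  structure(list(mass = mass, mass_controlled = mass_controlled,
                 shift = mass - mass_controlled, lambda = lambda,
                 Pi = Pi),
            class = c("controlled_class", "uncertainty_class"))
}
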