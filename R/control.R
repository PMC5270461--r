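#' Controlled transition matrix under a single-gene action
#'
#' External control flips the expression of one control gene before the
#' transition: under action `a = 1` the transition probabilities at state
#' `x` are those of the original chain at the state `x~` obtained from `x`
#' by flipping bit `cgene`.  Action `a = 0` leaves the chain untouched.
#'
#' @param tm a [build_tpm()] model.
#' @param cgene control gene index in `1:n` (gene 1 is the most
#'   significant bit) or a gene name.
#' @param action 0 (no intervention) or 1 (flip the control gene).
#' @return A `bnp_tpm` with the action applied to every row.
#' @export
controlled_tpm <- function(tm, cgene, action) {
  stopifnot(inherits(tm, "bnp_tpm"))
  if (!action %in% 0:1) stop("action must be 0 or 1")
  if (action == 0) return(tm)
  xt <- flipped_rows(tm, cgene)
  out <- tm
  out$P <- tm$P[xt, , drop = FALSE]
  out$f <- tm$f[xt]
  out
}

# row indices (1-based) of the flip-partner states x~ for each x
flipped_rows <- function(tm, cgene) {
  cgene <- resolve_gene(tm, cgene)
  bitwXor(0:(2^tm$n - 1), bitwShiftL(1L, tm$n - cgene)) + 1L
}

resolve_gene <- function(tm, cgene) {
  if (is.character(cgene)) {
    i <- match(cgene, tm$genes)
    if (is.na(i)) stop("unknown control gene: ", cgene)
    return(i)
  }
  cgene <- as.integer(cgene)
  if (cgene < 1L || cgene > tm$n)
    stop("control gene index out of range 1..", tm$n)
  cgene
}

# policy -> N x 2 matrix of mu(a | x); accepts a 0/1 action vector or a
# matrix of per-state action probabilities
as_policy_matrix <- function(policy, N) {
  if (is.matrix(policy)) {
    stopifnot(nrow(policy) == N, ncol(policy) == 2)
    if (any(policy < 0) || max(abs(rowSums(policy) - 1)) > 1e-8)
      stop("policy rows must be probability distributions over {0, 1}")
    return(policy)
  }
  stopifnot(length(policy) == N, all(policy %in% 0:1))
  cbind(1 - policy, policy)
}

# controlled chain Q(mu) = sum_a P(a) mu(a | x) row-wise
policy_chain <- function(tm, cgene, mu) {
  xt <- flipped_rows(tm, cgene)
  tm$P * mu[, 1] + tm$P[xt, , drop = FALSE] * mu[, 2]
}

#' Long-run undesirable occupancy of a control policy
#'
#' Builds the controlled chain `Q(mu)` (mixing the two action TPMs row by
#' row with the policy's action probabilities), computes its stationary
#' distribution, and returns the long-run fraction of time spent in the
#' undesirable states.  Equivalently, the occupation-measure cost
#' `sum_{x in U, a} nu_xa(mu)` with `nu_xa = mu(a|x) pi_x(mu)`.
#'
#' @inheritParams controlled_tpm
#' @param U undesirable states (0-based integers).
#' @param policy length-`2^n` 0/1 action vector, or a `2^n` by 2 matrix of
#'   action probabilities (stationary randomized policy).
#' @return The cost `J(mu)`, a probability.
#' @export
policy_cost <- function(tm, U, policy, cgene) {
  stopifnot(inherits(tm, "bnp_tpm"))
  mu <- as_policy_matrix(policy, 2^tm$n)
  Q <- policy_chain(tm, cgene, mu)
  undesirable_mass(steady_state(Q), U)
}

#' Optimal external control of a BNp
#'
#' Finds a stationary deterministic policy minimizing the long-run
#' expected occupation of the undesirable states, i.e. the
#' occupation-measure program
#' \deqn{\min \sum_{x \in U} \sum_a \nu_{xa} \quad \mathrm{s.t.} \quad
#'   \sum_a \nu_{xa} = \sum_{y,a} \nu_{ya} P_{yx}(a),\;
#'   \sum_{x,a} \nu_{xa} = 1,\; \nu \ge 0.}
#' The program is solved by Howard policy iteration on the equivalent
#' average-cost Markov decision process, which performs block-pivoting
#' simplex steps on the same linear program and terminates at an optimal
#' basic solution, i.e. a stationary deterministic policy.  The optimal
#' occupation measure is recovered as `nu_xa = mu*(a|x) pi_x(mu*)`.
#'
#' Ties between the two actions (within `tie_tol` in the optimality
#' condition) are resolved to no intervention, the less invasive action.
#' The reported cost `J*` is recomputed from the stationary distribution
#' of the controlled chain; it must agree with the policy-iteration gain
#' within `1e-7` or an error is raised.
#'
#' @inheritParams policy_cost
#' @param tie_tol tie tolerance on the action comparison (default `1e-9`).
#' @param max_iter safeguard on policy-iteration sweeps.
#' @return An object of class `control_result`: list with `J` (optimal
#'   cost), `policy` (0/1 action per state), `pi_star` (controlled SSD),
#'   `nu` (`2^n` by 2 occupation measure), `mass_uncontrolled`, `shift`
#'   (`mass_uncontrolled - J`), `gain` (policy-iteration gain), `cgene`
#'   and `iterations`.
#' @examples
#' R <- regulatory_matrix(rbind(c(0, -1), c(-1, 0)), c("a", "b"))
#' tm <- build_tpm(R, 0.05)
#' res <- optimal_control(tm, U = c(0, 1), cgene = 2)
#' res$J <= undesirable_mass(steady_state(tm), c(0, 1))
#' @export
optimal_control <- function(tm, U, cgene, tie_tol = 1e-9,
                            max_iter = 100L) {
  stopifnot(inherits(tm, "bnp_tpm"))
  N <- 2^tm$n
  P0 <- tm$P
  xt <- flipped_rows(tm, cgene)
  P1 <- P0[xt, , drop = FALSE]
  cost <- numeric(N)
  if (length(U)) cost[U + 1L] <- 1
  a <- integer(N)                       # start from no intervention
  s0 <- s1 <- numeric(N)
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    ev <- pi_evaluate(P0, P1, a, cost)
    s0 <- as.numeric(P0 %*% ev$h)
    s1 <- as.numeric(P1 %*% ev$h)
    # switch only on strict improvement (anti-cycling)
    a_new <- a
    a_new[a == 0L & s1 < s0 - tie_tol] <- 1L
    a_new[a == 1L & s0 < s1 - tie_tol] <- 0L
    if (identical(a_new, a)) break
    a <- a_new
    if (it == max_iter) stop("policy iteration did not converge in ",
                             max_iter, " sweeps")
  }
  # greedy policy at the optimal bias, ties -> no intervention
  a <- as.integer(s1 < s0 - tie_tol)
  sel <- a == 1L
  Q <- P0
  Q[sel, ] <- P1[sel, , drop = FALSE]
  pi_star <- steady_state(Q)
  J <- undesirable_mass(pi_star, U)
  if (abs(J - ev$g) > 1e-7)
    stop("controlled-SSD cost ", format(J),
         " disagrees with policy-iteration gain ", format(ev$g))
  pi0 <- steady_state(tm)
  m0 <- undesirable_mass(pi0, U)
  nu <- cbind(pi_star * (1 - a), pi_star * a)
  structure(list(J = J, policy = a, pi_star = pi_star, nu = nu,
                 mass_uncontrolled = m0, shift = m0 - J, gain = ev$g,
                 cgene = resolve_gene(tm, cgene), iterations = iters),
            class = "control_result")
}

# average-cost policy evaluation: gain g and bias h (h[1] = 0) of the
# chain following action vector a, from g + h = cost + Q h
pi_evaluate <- function(P0, P1, a, cost) {
  N <- length(a)
  sel <- a == 1L
  Q <- P0
  Q[sel, ] <- P1[sel, , drop = FALSE]
  M <- diag(N) - Q
  M[, 1] <- 1                            # column of the gain unknown
  z <- solve(M, cost)
  h <- z
  h[1] <- 0
  list(g = z[1], h = h)
}

#' @export
print.control_result <- function(x, ...) {
  cat(sprintf(
    "Optimal control (gene %d): J* = %.6f, uncontrolled = %.6f, shift = %.6f\n",
    x$cgene, x$J, x$mass_uncontrolled, x$shift))
  cat("  intervention in", sum(x$policy), "of", length(x$policy),
      "states\n")
  invisible(x)
}

#' Exhaustive search over stationary deterministic policies
#'
#' Evaluates [policy_cost()] for every one of the `2^(2^n)` deterministic
#' policies and returns the minimizer.  Only feasible for very small
#' networks (`n <= 4`); serves as an independent optimality oracle for
#' [optimal_control()].
#'
#' @inheritParams policy_cost
#' @return A list with `J`, `policy` and `n_policies`.
#' @export
exhaustive_policy_search <- function(tm, U, cgene) {
  stopifnot(inherits(tm, "bnp_tpm"))
  N <- 2^tm$n
  if (tm$n > 4L)
    stop("exhaustive policy search enumerates 2^(2^n) policies; ",
         "refusing n > 4")
  best <- Inf
  best_policy <- integer(N)
  for (code in 0:(2^N - 1)) {
    pol <- bitwAnd(bitwShiftR(code, (N - 1):0), 1L)
    J <- policy_cost(tm, U, pol, cgene)
    if (J < best - 1e-15) {
      best <- J
      best_policy <- pol
    }
  }
  list(J = best, policy = best_policy, n_policies = 2^N)
}
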