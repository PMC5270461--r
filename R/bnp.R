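#' Majority-vote update of a gene activity profile
#'
#' Synchronous majority-vote dynamics: gene `i` switches on when its
#' active activators outnumber its active suppressors
#' (`sum_j R_ij v_j > 0`), off when suppressors dominate, and keeps its
#' current value on a tie.  Genes with no predictors always hit the tie
#' branch and hold their value.
#'
#' @param R a [regulatory_matrix].
#' @param v binary GAP vector of length `n`.
#' @return The successor GAP vector.
#' @export
majority_vote_update <- function(R, v) {
  n <- n_genes(R)
  if (length(v) != n)
    stop("GAP length ", length(v), " does not match network size ", n)
  if (!all(v %in% 0:1)) stop("GAP entries must be 0 or 1")
  s <- as.numeric(unclass(R) %*% v)
  ifelse(s > 0, 1L, ifelse(s < 0, 0L, as.integer(v)))
}

# deterministic successor state f(x) for every x in S, as a 0-based
# integer vector of length 2^n (vectorized majority vote)
transition_map <- function(R, V = NULL) {
  n <- n_genes(R)
  if (is.null(V)) V <- state_table(n)
  s <- V %*% t(unclass(R))
  Vn <- (s > 0) + (s == 0) * V
  as.integer(Vn %*% 2^((n - 1):0))
}

#' Perturbation kernel of a Boolean network with perturbation
#'
#' Matrix `K` with `K[x, y] = p^d (1-p)^(n-d)` where `d` is the Hamming
#' distance between the GAPs of `x` and `y`: the probability that the
#' random per-gene perturbation maps `x` to `y`.  The kernel depends only
#' on `n` and `p`, so it can be computed once and shared across all
#' networks of the same size (see [build_tpm()]).
#'
#' @param n number of genes.
#' @param p per-gene perturbation probability, `0 < p < 1`.
#' @return A `2^n` by `2^n` matrix.
#' @export
perturbation_kernel <- function(n, p) {
  check_p(p)
  N <- 2^n
  pc <- rowSums(state_table(n))                # popcount of 0..N-1
  D <- matrix(pc[outer(0:(N - 1), 0:(N - 1), bitwXor) + 1L], N, N)
  geom <- p^(0:n) * (1 - p)^(n - (0:n))
  matrix(geom[D + 1L], N, N)
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("perturbation probability p must satisfy 0 < p < 1")
  invisible(p)
}

#' Transition probability matrix of a Boolean network with perturbation
#'
#' Builds the `2^n` by `2^n` TPM of the synchronous majority-vote Boolean
#' network with random gene perturbation.  Each gene independently flips
#' with probability `p`; when no gene flips (probability `(1-p)^n`) the
#' state follows the deterministic update `f`, otherwise the realized flip
#' pattern is applied:
#' `P[x, y] = 1(f(x) = y) (1-p)^n + 1(d(x,y) >= 1) p^d (1-p)^(n-d)`
#' with `d` the Hamming distance between the GAPs of `x` and `y`.  Every
#' entry is at least `p^n > 0`, so the chain is ergodic.
#'
#' @inheritParams majority_vote_update
#' @inheritParams perturbation_kernel
#' @param kernel optional precomputed [perturbation_kernel()] for this
#'   `(n, p)`, shared across networks for speed.
#' @return An object of class `bnp_tpm`: list with elements `n`, `p`,
#'   `P` (row-stochastic matrix) and `f` (deterministic successor map,
#'   0-based).
#' @examples
#' R <- regulatory_matrix(rbind(c(0, 1), c(-1, 0)), c("a", "b"))
#' tm <- build_tpm(R, p = 0.05)
#' rowSums(tm$P)
#' @export
build_tpm <- function(R, p, kernel = NULL) {
  check_p(p)
  n <- n_genes(R)
  N <- 2^n
  if (is.null(kernel)) kernel <- perturbation_kernel(n, p)
  stopifnot(nrow(kernel) == N)
  f <- transition_map(R)
  P <- kernel
  noflip <- (1 - p)^n
  diag_idx <- cbind(seq_len(N), seq_len(N))
  P[diag_idx] <- P[diag_idx] - noflip
  f_idx <- cbind(seq_len(N), f + 1L)
  P[f_idx] <- P[f_idx] + noflip
  structure(list(n = n, p = p, P = P, f = f,
                 genes = genes_of(R)),
            class = "bnp_tpm")
}

#' @export
print.bnp_tpm <- function(x, ...) {
  cat("BNp transition model:", x$n, "genes,", 2^x$n, "states, p =",
      x$p, "\n")
  invisible(x)
}

as_tpm_matrix <- function(tm) {
  if (inherits(tm, "bnp_tpm")) tm$P
  else if (is.matrix(tm)) tm
  else stop("expected a 'bnp_tpm' or a row-stochastic matrix")
}

#' Steady-state distribution of an ergodic chain
#'
#' Solves `pi P = pi`, `sum(pi) = 1` for the unique stationary
#' distribution by replacing one stationarity equation with the
#' normalization row and solving the resulting linear system directly.
#' Falls back to the principal left eigenvector if the solve fails or its
#' residual exceeds `tol`.
#'
#' @param tm a [build_tpm()] model or a row-stochastic matrix.
#' @param tol residual tolerance for `pi P = pi` (default `1e-10`).
#' @return Numeric vector `pi` over states `0:(2^n - 1)`.
#' @export
steady_state <- function(tm, tol = 1e-10) {
  P <- as_tpm_matrix(tm)
  N <- nrow(P)
  pi <- tryCatch({
    A <- t(P) - diag(N)
    A[N, ] <- 1
    solve(A, c(rep(0, N - 1), 1))
  }, error = function(e) NULL)
  bad <- is.null(pi) || any(pi < -tol) ||
    max(abs(as.numeric(pi %*% P) - pi)) > tol
  if (bad) {
    e <- eigen(t(P))
    k <- which.min(abs(e$values - 1))
    pi <- Re(e$vectors[, k])
    pi <- pi / sum(pi)
    if (max(abs(as.numeric(pi %*% P) - pi)) > tol)
      stop("steady-state solve failed: stationarity residual ",
           format(max(abs(as.numeric(pi %*% P) - pi))), " exceeds ",
           format(tol))
  }
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Steady-state mass of the undesirable states
#'
#' @param pi steady-state distribution over `0:(2^n - 1)`.
#' @param U undesirable states (0-based integers).
#' @return `sum(pi[U])`, a probability in `[0, 1]`.
#' @export
undesirable_mass <- function(pi, U) {
  if (length(U) == 0L) return(0)
  stopifnot(all(U >= 0), all(U < length(pi)))
  sum(pi[U + 1L])
}

#' Simulate a BNp trajectory
#'
#' Direct simulation of the chain: each step flips every gene
#' independently with probability `p`; if no gene flips the majority-vote
#' successor is taken.  Used to check TPMs and SSDs against empirical
#' occupation frequencies.
#'
#' @inheritParams steady_state
#' @param n_steps number of transitions.
#' @param init initial state (0-based), default 0.
#' @return Integer vector of visited states of length `n_steps + 1`.
#' @export
simulate_bnp <- function(tm, n_steps, init = 0L) {
  stopifnot(inherits(tm, "bnp_tpm"))
  n <- tm$n
  x <- integer(n_steps + 1)
  x[1] <- as.integer(init)
  masks <- 2^((n - 1):0)
  for (k in seq_len(n_steps)) {
    flips <- stats::runif(n) < tm$p
    if (any(flips)) {
      x[k + 1] <- bitwXor(x[k], as.integer(sum(masks[flips])))
    } else {
      x[k + 1] <- tm$f[x[k] + 1L]
    }
  }
  x
}
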