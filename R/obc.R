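#' Effective class-conditional densities over the state space
#'
#' For each prognosis class `i`, the effective density at state `x` is
#' the conditional-prior mixture of member steady-state distributions,
#' `f_i(x) = sum_{R in class i} pi_R(x) Lambda_i(R)`.  Together with the
#' class probabilities `c_i` these are the class-conditional sampling
#' distributions of a single observed GAP.  Empty classes yield zero
#' densities and `c_i = 0`.
#'
#' @param part a [partition_prognosis()] result.
#' @return List with `f` (4 by `2^n` matrix of densities, one row per
#'   class) and `c` (class probabilities).
#' @export
effective_densities <- function(part) {
  stopifnot(inherits(part, "prognosis_partition"))
  N <- ncol(part$Pi)
  f <- matrix(0, 4, N)
  for (i in 1:4) {
    sel <- part$labels == i
    if (any(sel))
      f[i, ] <- colSums(part$Pi[sel, , drop = FALSE] *
                          part$lambda_cond[sel])
  }
  list(f = f, c = part$class_prob)
}

# prior-weighted class scores w_i(x) = c_i f_i(x) =
# sum_{R in class i} pi_R(x) Lambda(R); the argmax rule and all error
# quantities derive from this 4 x N matrix
class_scores <- function(part) {
  N <- ncol(part$Pi)
  w <- matrix(0, 4, N)
  for (i in 1:4) {
    sel <- part$labels == i
    if (any(sel))
      w[i, ] <- colSums(part$Pi[sel, , drop = FALSE] * part$lambda[sel])
  }
  w
}

#' Optimal Bayesian classification of an observed network state
#'
#' Builds the exact optimal Bayesian classifier for the four prognosis
#' classes: an observed state `x` is assigned to the class maximizing the
#' prior-weighted effective density `c_i f_i(x)`; ties go to the smallest
#' class index.  Because the class-conditional distributions and class
#' probabilities are known exactly, the expected misclassification rate,
#' the per-state class posteriors and each member network's probability
#' of correct classification are all exact sums, with no sampling.
#'
#' @param part a [partition_prognosis()] result.
#' @return An object of class `obc_result`: list with `psi` (decision per
#'   state, length `2^n`), `expected_error`, `posteriors` (`2^n` by 4
#'   matrix, rows summing to 1), `correct_prob` (per member network, the
#'   mass of states mapped to its label), `class_error` (per-class
#'   contributions `c_i E[error | class i]`), and the `densities`.
#' @examples
#' # see vignette("prognosis-under-network-uncertainty", "prognet")
#' @export
obc_classifier <- function(part) {
  stopifnot(inherits(part, "prognosis_partition"))
  w <- class_scores(part)
  psi <- apply(w, 2, which.max)           # smallest index wins ties
  total <- colSums(w)
  if (any(total <= 0))
    stop("zero total density at some state; is p > 0?")
  posteriors <- t(w) / total
  correct <- network_correct_prob(part, psi)
  err <- expected_error_scores(w, psi)
  class_error <- vapply(1:4, function(i) {
    sel <- part$labels == i
    if (!any(sel)) return(0)
    sum(w[i, psi != i])
  }, numeric(1))
  structure(list(psi = as.integer(psi), expected_error = err,
                 posteriors = posteriors, correct_prob = correct,
                 class_error = class_error,
                 densities = effective_densities(part)),
            class = "obc_result")
}

#' @export
print.obc_result <- function(x, ...) {
  cat(sprintf("Optimal Bayesian classifier: expected error %.6f\n",
              x$expected_error))
  cat("  decisions:", paste(table(factor(x$psi, 1:4)), collapse = "/"),
      "states per class\n")
  invisible(x)
}

#' Classify observed states with a fitted OBC
#'
#' @param object an [obc_classifier()] result.
#' @param x integer state(s) in `0:(2^n - 1)`.
#' @param ... unused.
#' @return Integer class label(s) in 1-4.
#' @export
predict.obc_result <- function(object, x, ...) {
  object$psi[as.integer(x) + 1L]
}

expected_error_scores <- function(w, psi) {
  1 - sum(w[cbind(psi, seq_len(ncol(w)))])
}

#' Expected misclassification rate of an arbitrary classifier
#'
#' Exact prior-expected error of any decision map over the state space:
#' the prior-weighted steady-state mass each network places on states
#' mapped to a different label than its own.
#'
#' @inheritParams obc_classifier
#' @param psi integer vector of decisions (labels 1-4), one per state.
#' @return A probability.
#' @export
expected_error <- function(part, psi) {
  stopifnot(inherits(part, "prognosis_partition"),
            length(psi) == ncol(part$Pi), all(psi %in% 1:4))
  expected_error_scores(class_scores(part), as.integer(psi))
}

#' Per-state posterior probabilities of the prognosis classes
#'
#' Row `x` is the probability of each class label conditioned on
#' observing state `x`:
#' `P(i | x) = c_i f_i(x) / sum_j c_j f_j(x)`.
#'
#' @inheritParams obc_classifier
#' @return `2^n` by 4 matrix with rows summing to 1.
#' @export
state_posteriors <- function(part) {
  w <- class_scores(part)
  total <- colSums(w)
  if (any(total <= 0))
    stop("zero total density at some state; is p > 0?")
  t(w) / total
}

#' Per-network probability of correct classification
#'
#' For each member network with label `i`, the steady-state mass of the
#' states that the classifier maps to `i`: the chance that a single GAP
#' drawn from that patient's network is classified correctly.
#'
#' @inheritParams expected_error
#' @return Numeric vector, one probability per class member.
#' @export
network_correct_prob <- function(part, psi) {
  stopifnot(inherits(part, "prognosis_partition"),
            length(psi) == ncol(part$Pi))
  vapply(seq_along(part$labels), function(k) {
    sum(part$Pi[k, psi == part$labels[k]])
  }, numeric(1))
}
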