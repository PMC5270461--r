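#' Enumerate mutated regulatory matrices
#'
#' Generates every matrix obtained from `R` by removing up to `rem`
#' existing edges (an entry in `{-1, 1}` set to 0) and, independently,
#' adding up to `add` new signed edges (a 0 entry set to `+1` or `-1`;
#' each sign is a distinct mutation).  The unmutated matrix is excluded.
#' A combined removal-plus-addition counts as two mutations; direct sign
#' flips (`+1` to `-1`) are not in the mutation alphabet.  Diagonal
#' entries (self-loops) are mutable like any other entry.
#'
#' @param R healthy [regulatory_matrix].
#' @param rem maximum number of edges removed (non-negative integer).
#' @param add maximum number of signed edges added.
#' @return List of candidates; each element has `entries` (the mutated
#'   [regulatory_matrix]), `l` (mutation count = entries changed) and
#'   `edits` (data frame of `i`, `j`, `from`, `to`).
#' @examples
#' R <- regulatory_matrix(rbind(c(1, -1), c(0, 1)), c("a", "b"))
#' length(enumerate_mutations(R, rem = 1, add = 0))  # one per edge
#' @export
enumerate_mutations <- function(R, rem = 1L, add = 1L) {
  stopifnot(inherits(R, "regulatory_matrix"), rem >= 0, add >= 0)
  nz <- which(unclass(R) != 0)               # column-major cell indices
  z <- which(unclass(R) == 0)
  rem_sets <- subsets_up_to(nz, rem)
  add_sets <- signed_subsets_up_to(z, add)
  out <- vector("list", 0L)
  for (rs in rem_sets) {
    for (as_ in add_sets) {
      l <- length(rs) + nrow(as_)
      if (l == 0L) next
      M <- unclass(R)
      M[rs] <- 0L
      if (nrow(as_)) M[as_$cell] <- as_$sign
      out[[length(out) + 1L]] <- list(
        entries = regulatory_matrix(M, genes = genes_of(R)),
        l = as.integer(l),
        edits = edit_table(R, rs, as_))
    }
  }
  out
}

# combn() treats a scalar first argument as 1:x; force set semantics
combs <- function(cells, size) {
  if (length(cells) == 1L && size == 1L) return(list(cells))
  utils::combn(cells, size, simplify = FALSE)
}

# all subsets of `cells` of size 0..k, smallest first
subsets_up_to <- function(cells, k) {
  out <- list(integer(0))
  k <- min(k, length(cells))
  for (size in seq_len(k)) {
    out <- c(out, combs(cells, size))
  }
  out
}

# all sign-assigned subsets of zero cells of size 0..k, as data frames
signed_subsets_up_to <- function(cells, k) {
  out <- list(data.frame(cell = integer(0), sign = integer(0)))
  k <- min(k, length(cells))
  for (size in seq_len(k)) {
    for (cmb in combs(cells, size)) {
      signs <- expand.grid(rep(list(c(1L, -1L)), size))
      for (r in seq_len(nrow(signs))) {
        out[[length(out) + 1L]] <- data.frame(
          cell = cmb, sign = as.integer(signs[r, ]))
      }
    }
  }
  out
}

edit_table <- function(R, removed, added) {
  n <- n_genes(R)
  ij <- function(cell) cbind((cell - 1L) %% n + 1L, (cell - 1L) %/% n + 1L)
  rows <- list()
  if (length(removed)) {
    idx <- ij(removed)
    rows[[1]] <- data.frame(i = idx[, 1], j = idx[, 2],
                            from = unclass(R)[removed], to = 0L)
  }
  if (nrow(added)) {
    idx <- ij(added$cell)
    rows[[length(rows) + 1L]] <- data.frame(
      i = idx[, 1], j = idx[, 2], from = 0L, to = added$sign)
  }
  if (!length(rows))
    return(data.frame(i = integer(0), j = integer(0),
                      from = integer(0), to = integer(0)))
  do.call(rbind, rows)
}

#' Geometric mutation prior over an uncertainty class
#'
#' Networks with `l` mutations receive unnormalized weight
#' `gamma^l / N_l`, where `N_l` is the number of class members carrying
#' exactly `l` mutations: mutation counts follow a truncated geometric
#' law and all networks with the same count are equally likely.  Weights
#' are normalized to sum to one.
#'
#' @param l integer vector of mutation counts, one per member.
#' @param gamma decay of the mutation-count distribution, `0 < gamma <= 1`.
#' @return Numeric vector of prior probabilities summing to 1.
#' @export
mutation_prior <- function(l, gamma = 0.5) {
  if (!length(l)) stop("empty uncertainty class has no prior")
  stopifnot(gamma > 0, gamma <= 1, all(l >= 1))
  Nl <- table(l)
  w <- gamma^l / as.numeric(Nl[as.character(l)])
  w / sum(w)
}

#' Build the uncertainty class of mutated networks
#'
#' Enumerates all mutants of the healthy network within the mutation
#' limits, computes every candidate's steady-state distribution, and
#' retains those whose undesirable mass is (i) at least the healthy
#' network's and (ii) at least the mean undesirable mass of all
#' single-mutation candidates (both computed before filtering; ties are
#' kept).  Surviving members receive the geometric prior of
#' [mutation_prior()].
#'
#' @inheritParams enumerate_mutations
#' @param p perturbation probability of the BNp.
#' @param U undesirable states (0-based integers).
#' @param gamma prior decay; `gamma = 1` with a single mutation level
#'   gives a uniform prior.
#' @return An object of class `uncertainty_class`: list with `members`
#'   (as in [enumerate_mutations()]), `l`, `mass` (undesirable SSD mass
#'   per member), `Pi` (members-by-states matrix of SSDs), `lambda`
#'   (prior), `healthy_mass`, `single_mean` (the two inclusion
#'   thresholds), `n_candidates`, plus the study parameters.
#' @export
uncertainty_class <- function(R, p, U, rem = 1L, add = 1L, gamma = 0.5) {
  stopifnot(inherits(R, "regulatory_matrix"))
  check_p(p)
  n <- n_genes(R)
  kernel <- perturbation_kernel(n, p)
  healthy_mass <- undesirable_mass(
    steady_state(build_tpm(R, p, kernel)), U)
  cand <- enumerate_mutations(R, rem, add)
  if (!length(cand))
    return(empty_class(R, p, U, rem, add, gamma, healthy_mass))
  Pi_all <- t(vapply(cand, function(m)
    steady_state(build_tpm(m$entries, p, kernel)), numeric(2^n)))
  mass_all <- if (length(U)) rowSums(Pi_all[, U + 1L, drop = FALSE])
              else numeric(nrow(Pi_all))
  l_all <- vapply(cand, `[[`, integer(1), "l")
  single_mean <- mean(mass_all[l_all == 1L])
  keep <- mass_all >= healthy_mass & mass_all >= single_mean
  if (!any(keep)) {
    warning("no candidate network passes the undesirable-mass filter")
    return(empty_class(R, p, U, rem, add, gamma, healthy_mass,
                       single_mean, length(cand)))
  }
  structure(list(
    members = cand[keep],
    l = l_all[keep],
    mass = mass_all[keep],
    Pi = Pi_all[keep, , drop = FALSE],
    lambda = mutation_prior(l_all[keep], gamma),
    healthy = R, healthy_mass = healthy_mass,
    single_mean = single_mean,
    n_candidates = length(cand),
    p = p, U = U, rem = rem, add = add, gamma = gamma),
    class = "uncertainty_class")
}

empty_class <- function(R, p, U, rem, add, gamma, healthy_mass,
                        single_mean = NA_real_, n_candidates = 0L) {
  structure(list(members = list(), l = integer(0), mass = numeric(0),
                 Pi = matrix(numeric(0), 0, 2^n_genes(R)),
                 lambda = numeric(0), healthy = R,
                 healthy_mass = healthy_mass, single_mean = single_mean,
                 n_candidates = n_candidates,
                 p = p, U = U, rem = rem, add = add, gamma = gamma),
            class = "uncertainty_class")
}

#' @export
print.uncertainty_class <- function(x, ...) {
  cat("Uncertainty class:", length(x$members), "of", x$n_candidates,
      "candidate networks (rem <=", x$rem, ", add <=", x$add, ")\n")
  cat(sprintf(
    "  healthy undesirable mass %.6f; single-mutation mean %.6f\n",
    x$healthy_mass, x$single_mean))
  if (length(x$mass))
    cat(sprintf("  member mass range [%.6f, %.6f]; gamma = %g\n",
                min(x$mass), max(x$mass), x$gamma))
  invisible(x)
}

#' Optimally control every member of an uncertainty class
#'
#' Runs [optimal_control()] for the given control gene on each member
#' network and records the controlled undesirable mass and the
#' steady-state shift.
#'
#' @param uc an [uncertainty_class()].
#' @param cgene control gene index or name.
#' @param keep_policies keep each member's optimal policy vector
#'   (default `FALSE` to save memory).
#' @return A `controlled_class`: the input augmented with
#'   `mass_controlled`, `shift`, `cgene` and optionally `policies`.
#' @export
control_class <- function(uc, cgene, keep_policies = FALSE) {
  stopifnot(inherits(uc, "uncertainty_class"))
  n <- n_genes(uc$healthy)
  kernel <- perturbation_kernel(n, uc$p)
  policies <- if (keep_policies) vector("list", length(uc$members))
  mass_c <- numeric(length(uc$members))
  for (k in seq_along(uc$members)) {
    tm <- build_tpm(uc$members[[k]]$entries, uc$p, kernel)
    res <- optimal_control(tm, uc$U, cgene)
    mass_c[k] <- res$J
    if (keep_policies) policies[[k]] <- res$policy
  }
  uc$mass_controlled <- mass_c
  uc$shift <- uc$mass - mass_c
  uc$cgene <- cgene
  if (keep_policies) uc$policies <- policies
  class(uc) <- c("controlled_class", "uncertainty_class")
  uc
}

#' Prognosis thresholds giving (almost) equal class sizes
#'
#' Picks the partition thresholds so the four prognosis classes have
#' nearly equal member counts: `alpha` is the median controlled
#' undesirable mass, `beta1` the median shift among members controlled
#' below `alpha`, and `beta2` the median shift among the rest.  Medians
#' use the usual midpoint interpolation for even counts
#' ([stats::median()]).
#'
#' @param cls a [control_class()] result, or a list with numeric fields
#'   `mass_controlled` and `shift`.
#' @return List with `alpha`, `beta1`, `beta2`.
#' @export
auto_thresholds <- function(cls) {
  mc <- cls$mass_controlled
  shift <- cls$shift
  stopifnot(length(mc) == length(shift))
  if (length(mc) < 4L)
    stop("need at least 4 members to pick four-class thresholds")
  if (max(mc) - min(mc) < 1e-12 && max(shift) - min(shift) < 1e-12)
    stop("members are indistinguishable; thresholds cannot separate them")
  alpha <- stats::median(mc)
  lo <- mc < alpha
  if (!any(lo) || all(lo))
    stop("controlled masses do not straddle their median; ",
         "cannot split on alpha")
  list(alpha = alpha,
       beta1 = stats::median(shift[lo]),
       beta2 = stats::median(shift[!lo]))
}

#' Partition an uncertainty class into four prognosis classes
#'
#' Labels every member by controlled undesirable mass and steady-state
#' shift:
#' class 1 (`mass* < alpha`, `shift < beta1`) -- not critical;
#' class 2 (`mass* < alpha`, `shift >= beta1`) -- responds well to
#' treatment; class 3 (`mass* >= alpha`, `shift >= beta2`) -- improvable
#' to some extent; class 4 (`mass* >= alpha`, `shift < beta2`) -- poor
#' and untreatable.  Also computes the class prior probabilities
#' `c_i = sum_{R in class i} Lambda(R)` and the conditional priors
#' `Lambda(R) / c_i`.
#'
#' @param cls a [control_class()] result.
#' @param thresholds `"auto"` for [auto_thresholds()], or a list with
#'   `alpha`, `beta1`, `beta2` in `(0, 1]`.
#' @return A `prognosis_partition`: the input augmented with `labels`
#'   (1-4 per member), `thresholds`, `class_prob` (`c_i`) and
#'   `lambda_cond` (conditional prior per member).
#' @export
partition_prognosis <- function(cls, thresholds = "auto") {
  stopifnot(inherits(cls, "controlled_class"))
  auto <- identical(thresholds, "auto")
  if (auto) thresholds <- auto_thresholds(cls)
  for (nm in c("alpha", "beta1", "beta2")) {
    v <- thresholds[[nm]]
    if (is.null(v)) stop("threshold '", nm, "' is missing")
    # user thresholds must lie in (0, 1]; data-derived shift medians may
    # legitimately sit at 0 when control brings no benefit
    if (!auto && (v <= 0 || v > 1))
      stop("threshold '", nm, "' must lie in (0, 1]")
  }
  mc <- cls$mass_controlled
  shift <- cls$shift
  lo <- mc < thresholds$alpha
  labels <- ifelse(lo,
                   ifelse(shift < thresholds$beta1, 1L, 2L),
                   ifelse(shift >= thresholds$beta2, 3L, 4L))
  class_prob <- vapply(1:4, function(i) sum(cls$lambda[labels == i]),
                       numeric(1))
  lambda_cond <- cls$lambda / class_prob[labels]
  cls$labels <- as.integer(labels)
  cls$thresholds <- thresholds
  cls$class_prob <- class_prob
  cls$lambda_cond <- lambda_cond
  class(cls) <- c("prognosis_partition", class(cls))
  cls
}

#' @export
print.prognosis_partition <- function(x, ...) {
  cat("Prognosis partition of", length(x$labels), "networks",
      "(control gene", x$cgene, ")\n")
  cat(sprintf("  alpha = %.4g, beta1 = %.4g, beta2 = %.4g\n",
              x$thresholds$alpha, x$thresholds$beta1, x$thresholds$beta2))
  tab <- table(factor(x$labels, 1:4))
  cat("  sizes:", paste(tab, collapse = "/"),
      " class probs:", paste(sprintf("%.3f", x$class_prob),
                             collapse = "/"), "\n")
  invisible(x)
}

#' Prior expectation of a member statistic
#'
#' Averages a per-member quantity (`"mass"`, `"mass_controlled"` or
#' `"shift"`) over the uncertainty class, either weighted by the
#' mutation prior or unweighted.  The published summary tables for the
#' real-network studies report unweighted means over the class (see the
#' methods vignette), so both estimators are exposed.
#'
#' @param uc an [uncertainty_class()] (controlled, for controlled
#'   statistics).
#' @param what one of `"mass"`, `"mass_controlled"`, `"shift"`.
#' @param weights `"prior"` (expectation under the mutation prior) or
#'   `"uniform"` (plain mean over members).
#' @return A scalar.
#' @export
class_expectation <- function(uc, what = c("mass", "mass_controlled",
                                           "shift"),
                              weights = c("prior", "uniform")) {
  what <- match.arg(what)
  weights <- match.arg(weights)
  v <- uc[[what]]
  if (is.null(v)) stop("field '", what, "' not present; ",
                       "run control_class() first?")
  if (weights == "prior") sum(uc$lambda * v) else mean(v)
}
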