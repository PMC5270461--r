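#' Configuration for the synthetic-network study
#'
#' Bundles the study parameters with their defaults: 7-gene networks
#' with at most 3 predictors per gene, activation and suppression equally
#' likely, perturbation probability 0.01, at most one edge removed and
#' one added per mutant, prior decay 0.5, and 250 random seed networks.
#' The undesirable states are those where gene 1 (the most significant
#' bit, the "target" gene) is downregulated -- exactly half of the state
#' space -- and every other gene is an allowed control gene.
#'
#' @param n number of genes.
#' @param r_max maximum predictors per gene.
#' @param bias probability that a generated edge is activating.
#' @param p perturbation probability.
#' @param rem,add mutation limits for the uncertainty class.
#' @param gamma prior decay.
#' @param n_seeds number of random seed networks.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 7L, r_max = 3L, bias = 0.5, p = 0.01,
                             rem = 1L, add = 1L, gamma = 0.5,
                             n_seeds = 250L) {
  stopifnot(r_max >= 1, r_max <= n, bias >= 0, bias <= 1)
  check_p(p)
  structure(list(n = as.integer(n), r_max = as.integer(r_max),
                 bias = bias, p = p, rem = as.integer(rem),
                 add = as.integer(add), gamma = gamma,
                 n_seeds = as.integer(n_seeds)),
            class = "synthetic_config")
}

#' Generate a random seed regulatory matrix
#'
#' Per gene, the number of predictors `r(i)` is uniform on
#' `{1, ..., r_max}`, the predictor set is uniform over subsets of that
#' size, and each chosen edge is activating with probability `bias`,
#' suppressing otherwise.  Randomness comes from R's RNG; seed it for
#' reproducibility.
#'
#' @inheritParams synthetic_config
#' @return A [regulatory_matrix].
#' @export
generate_seed_network <- function(n = 7L, r_max = 3L, bias = 0.5) {
  stopifnot(r_max >= 1, r_max <= n)
  M <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    r_i <- sample.int(r_max, 1L)
    pred <- sample.int(n, r_i)
    M[i, pred] <- ifelse(stats::runif(r_i) < bias, 1L, -1L)
  }
  regulatory_matrix(M)
}

#' Select the healthy network around a seed matrix
#'
#' Enumerates every single-mutation variant of the seed matrix (each
#' edge removed, and each sign of each absent edge added) and returns
#' the variant with minimum undesirable steady-state mass.  Ties are
#' broken by enumeration order: removals before additions, cells in
#' column-major order, `+1` before `-1`.
#'
#' @param R_seed seed [regulatory_matrix].
#' @param p perturbation probability.
#' @param U undesirable states (0-based).
#' @return List with `R` (the healthy [regulatory_matrix]) and `mass`
#'   (its undesirable steady-state mass).
#' @export
select_healthy_network <- function(R_seed, p, U) {
  cand <- enumerate_mutations(R_seed, rem = 1L, add = 0L)
  cand <- c(cand, enumerate_mutations(R_seed, rem = 0L, add = 1L))
  kernel <- perturbation_kernel(n_genes(R_seed), p)
  mass <- vapply(cand, function(m)
    undesirable_mass(steady_state(build_tpm(m$entries, p, kernel)), U),
    numeric(1))
  best <- which.min(mass)               # first minimum = enumeration order
  list(R = cand[[best]]$entries, mass = mass[best])
}

#' Run the synthetic prognosis study
#'
#' End-to-end study over random seed networks: for each seed, pick the
#' healthy network ([select_healthy_network()]), build and prioritize
#' its uncertainty class, optimally control every member under each
#' allowed control gene (genes `2:n`; gene 1 defines the undesirable
#' states), auto-partition into the four prognosis classes, fit the
#' optimal Bayesian classifier, and record its exact expected error.
#' Seeds whose class is too small to partition (< 4 members) are
#' recorded with `NA` results; other per-seed failures propagate as
#' warnings and `NA`.
#'
#' @param config a [synthetic_config()].
#' @param n_seeds optional override of `config$n_seeds` (smaller runs
#'   for testing).
#' @param seed RNG seed for reproducibility.
#' @param verbose print per-seed progress.
#' @return A list with `summary` (data frame: one row per seed and
#'   control gene, with healthy mass, class size, expected uncontrolled
#'   and controlled masses under the prior, and OBC expected error) and
#'   `posterior_mean` (state-by-class matrix: per-state class posteriors
#'   averaged over all runs under the last control gene).
#' @export
run_synthetic_study <- function(config = synthetic_config(),
                                n_seeds = config$n_seeds, seed = NULL,
                                verbose = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  U <- 0:(2^(n - 1) - 1)                # gene 1 (MSB) downregulated
  control_genes <- seq_len(n)[-1]
  rows <- list()
  post_sum <- matrix(0, 2^n, 4)
  post_n <- 0L
  for (s in seq_len(n_seeds)) {
    R_seed <- generate_seed_network(n, config$r_max, config$bias)
    res <- tryCatch({
      healthy <- select_healthy_network(R_seed, config$p, U)
      uc <- uncertainty_class(healthy$R, config$p, U,
                              rem = config$rem, add = config$add,
                              gamma = config$gamma)
      per_gene <- lapply(control_genes, function(cg) {
        if (length(uc$members) < 4L)
          return(list(mass_c = NA_real_, err = NA_real_, post = NULL))
        cc <- control_class(uc, cg)
        part <- partition_prognosis(cc, "auto")
        fit <- obc_classifier(part)
        list(mass_c = class_expectation(cc, "mass_controlled"),
             err = fit$expected_error, post = fit$posteriors)
      })
      list(healthy = healthy, uc = uc, per_gene = per_gene)
    }, error = function(e) {
      warning("seed ", s, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) {
      rows[[length(rows) + 1L]] <- data.frame(
        seed_index = s, control_gene = NA_integer_,
        healthy_mass = NA_real_, class_size = NA_integer_,
        mass_uncontrolled = NA_real_, mass_controlled = NA_real_,
        obc_error = NA_real_)
      next
    }
    EmU <- if (length(res$uc$members))
      class_expectation(res$uc, "mass") else NA_real_
    for (k in seq_along(control_genes)) {
      pg <- res$per_gene[[k]]
      rows[[length(rows) + 1L]] <- data.frame(
        seed_index = s, control_gene = control_genes[k],
        healthy_mass = res$healthy$mass,
        class_size = length(res$uc$members),
        mass_uncontrolled = EmU,
        mass_controlled = pg$mass_c,
        obc_error = pg$err)
      if (k == length(control_genes) && !is.null(pg$post)) {
        post_sum <- post_sum + pg$post
        post_n <- post_n + 1L
      }
    }
    if (verbose)
      message(sprintf("seed %d/%d: |Theta| = %d", s, n_seeds,
                      length(res$uc$members)))
  }
  list(summary = do.call(rbind, rows),
       posterior_mean = if (post_n) post_sum / post_n else NULL,
       config = config, n_seeds = n_seeds)
}
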