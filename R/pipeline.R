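#' Full prognosis-prediction study for one network
#'
#' Drives the whole pipeline for a healthy network: build its BNp,
#' enumerate and filter the uncertainty class of mutants, assign the
#' mutation prior, optimally control every member with the chosen
#' control gene, partition into the four prognosis classes, and fit the
#' optimal Bayesian classifier.
#'
#' @param R healthy [regulatory_matrix], or a fixture name
#'   (`"cellcycle"`, `"p53"`).
#' @param cgene control gene (index or name).
#' @param p perturbation probability.
#' @param U undesirable states (0-based); defaults to the fixture's set
#'   when `R` names a fixture.
#' @param rem,add mutation limits.
#' @param gamma prior decay.
#' @param thresholds `"auto"` or a list with `alpha`, `beta1`, `beta2`.
#' @return List of class `prognosis_study` with components `fixture`
#'   (name or `NULL`), `class` (the [partition_prognosis()] object,
#'   which embeds the controlled uncertainty class) and `obc` (the
#'   [obc_classifier()] fit).
#' @examples
#' \donttest{
#' st <- prognosis_study("cellcycle", cgene = "E2F", rem = 1, add = 0,
#'                       gamma = 1)
#' st$obc$expected_error
#' }
#' @export
prognosis_study <- function(R, cgene, p = 0.01, U = NULL, rem = 1L,
                            add = 1L, gamma = 0.5,
                            thresholds = "auto") {
  fixture <- NULL
  if (is.character(R) && length(R) == 1L && !inherits(R, "regulatory_matrix")) {
    fx <- load_fixture(R)
    fixture <- fx$name
    if (is.null(U)) U <- fx$U
    R <- fx$R
  }
  if (is.null(U)) stop("undesirable states U must be given")
  uc <- uncertainty_class(R, p, U, rem = rem, add = add, gamma = gamma)
  cc <- control_class(uc, cgene)
  part <- partition_prognosis(cc, thresholds)
  fit <- obc_classifier(part)
  structure(list(fixture = fixture, class = part, obc = fit),
            class = "prognosis_study")
}

#' @export
print.prognosis_study <- function(x, ...) {
  if (!is.null(x$fixture)) cat("Study:", x$fixture, "\n")
  print(x$class)
  print(x$obc)
  invisible(x)
}

#' Reproduce the per-control-gene summary table for a fixture study
#'
#' Runs the full pipeline for every allowed control gene of a packaged
#' network and tabulates the class-average controlled undesirable mass
#' and the OBC expected error, alongside the class size and the healthy
#' and expected uncontrolled masses.  The mass columns are unweighted
#' means over the class members -- the estimator used by the published
#' summary tables this mirrors -- while the classifier and its error use
#' the mutation prior.
#'
#' @param fixture `"cellcycle"` or `"p53"`.  The cell-cycle study uses
#'   single edge removals and a uniform prior; the p53 study allows one
#'   removal plus one addition with `gamma = 0.5`.
#' @param control_genes subset of the fixture's allowed control genes
#'   (default: all).
#' @param p perturbation probability.
#' @return A data frame with one row per control gene and columns
#'   `control_gene`, `mass_controlled` (mean over members),
#'   `obc_error`, plus attributes `healthy_mass`, `mass_uncontrolled`
#'   and `class_size`.
#' @export
study_table <- function(fixture = c("cellcycle", "p53"),
                        control_genes = NULL, p = 0.01) {
  fixture <- match.arg(fixture)
  fx <- load_fixture(fixture)
  if (is.null(control_genes)) control_genes <- fx$control_genes
  stopifnot(all(control_genes %in% fx$control_genes))
  rem <- 1L
  add <- if (fixture == "p53") 1L else 0L
  gamma <- if (fixture == "p53") 0.5 else 1
  uc <- uncertainty_class(fx$R, p, fx$U, rem = rem, add = add,
                          gamma = gamma)
  rows <- lapply(control_genes, function(cg) {
    cc <- control_class(uc, cg)
    part <- partition_prognosis(cc, "auto")
    fit <- obc_classifier(part)
    data.frame(control_gene = cg,
               mass_controlled = class_expectation(cc, "mass_controlled",
                                                   weights = "uniform"),
               obc_error = fit$expected_error)
  })
  out <- do.call(rbind, rows)
  attr(out, "healthy_mass") <- uc$healthy_mass
  attr(out, "mass_uncontrolled") <- class_expectation(uc, "mass",
                                                      weights = "uniform")
  attr(out, "class_size") <- length(uc$members)
  out
}
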