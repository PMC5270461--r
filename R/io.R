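#' Serialize an uncertainty class to a directory
#'
#' Writes `members.tsv` (edit set, mutation count, undesirable mass and,
#' if present, controlled mass, shift and prognosis label per member),
#' `prior.tsv` (the mutation prior) and, for partitioned classes,
#' `thresholds.json`.  A `config.json` records the study parameters for
#' provenance.
#'
#' @param uc an [uncertainty_class()] (possibly controlled/partitioned).
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_uncertainty_class <- function(uc, dir) {
  stopifnot(inherits(uc, "uncertainty_class"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edits <- vapply(uc$members, function(m) {
    paste(sprintf("%d,%d:%+d>%+d", m$edits$i, m$edits$j,
                  m$edits$from, m$edits$to), collapse = ";")
  }, character(1))
  df <- data.frame(member = seq_along(uc$members), edits = edits,
                   l = uc$l, mass = uc$mass)
  if (!is.null(uc$mass_controlled)) {
    df$mass_controlled <- uc$mass_controlled
    df$shift <- uc$shift
  }
  if (!is.null(uc$labels)) df$label <- uc$labels
  utils::write.table(df, file.path(dir, "members.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(member = seq_along(uc$lambda), lambda = uc$lambda),
    file.path(dir, "prior.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(uc$thresholds))
    jsonlite::write_json(uc$thresholds,
                         file.path(dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA)
  cfg <- list(p = uc$p, rem = uc$rem, add = uc$add, gamma = uc$gamma,
              undesirable_states = uc$U,
              healthy_mass = uc$healthy_mass,
              single_mutation_mean = uc$single_mean,
              n_candidates = uc$n_candidates,
              n_members = length(uc$members))
  if (!is.null(uc$cgene)) cfg$control_gene <- uc$cgene
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read or write a control policy as JSON
#'
#' The file maps each state (as a character key of its integer value) to
#' the action taken there.
#'
#' @param policy 0/1 action vector over states `0:(2^n - 1)`.
#' @param path JSON file path.
#' @return `read_policy()` returns the integer action vector.
#' @export
write_policy <- function(policy, path) {
  stopifnot(all(policy %in% 0:1))
  obj <- as.list(as.integer(policy))
  names(obj) <- as.character(seq_along(policy) - 1L)
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pol <- as.integer(obj[order(as.integer(names(obj)))])
  if (!all(pol %in% 0:1)) stop("policy actions must be 0 or 1")
  pol
}

#' Export a fitted classifier
#'
#' Writes `decisions.tsv` with one row per state (decision and the four
#' class posteriors) and `summary.json` with the expected error and the
#' per-class error contributions.
#'
#' @param fit an [obc_classifier()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_classifier <- function(fit, dir) {
  stopifnot(inherits(fit, "obc_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(state = seq_along(fit$psi) - 1L, label = fit$psi)
  for (i in 1:4) df[[paste0("posterior_", i)]] <- fit$posteriors[, i]
  utils::write.table(df, file.path(dir, "decisions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(expected_error = fit$expected_error,
         class_error = fit$class_error),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
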