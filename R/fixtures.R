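#' Packaged regulatory-network fixtures
#'
#' Two literature-derived signed regulatory networks ship with the
#' package:
#'
#' * `"cellcycle"` -- the 10-gene mammalian cell-cycle network (CycD, Rb,
#'   p27, E2F, CycE, CycA, Cdc20, Cdh1, UbcH10, CycB) under
#'   majority-vote dynamics.  Undesirable states are those in which CycD,
#'   Rb and p27 are all simultaneously downregulated (uncontrolled
#'   proliferation in the absence of growth factors); every gene except
#'   these three is an allowed control gene.
#' * `"p53"` -- a 9-node p53 stress-response network (DNAdamage, p53,
#'   p14ARF, ATR, ATM, CHEK1, CHEK2, MDM2, MDMX) covering the signaling
#'   upstream of p53.  Undesirable states have DNA damage present but
#'   p53 inactive; every node except DNAdamage and p53 may be
#'   controlled.
#'
#' @param name `"cellcycle"` or `"p53"`.
#' @return A list with `name`, `R` (the [regulatory_matrix]),
#'   `undesirable_spec` (named gene/value vector), `U` (0-based
#'   undesirable states) and `control_genes` (character vector).
#' @examples
#' fx <- load_fixture("cellcycle")
#' length(fx$U)   # 128 of the 1024 states
#' @export
load_fixture <- function(name = c("cellcycle", "p53")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "prognet", mustWork = TRUE)
  R <- read_regulatory_matrix(path)
  spec <- switch(name,
    cellcycle = c(CycD = 0L, Rb = 0L, p27 = 0L),
    p53 = c(DNAdamage = 1L, p53 = 0L))
  excluded <- switch(name,
    cellcycle = c("CycD", "Rb", "p27"),
    p53 = c("DNAdamage", "p53"))
  list(name = name,
       R = R,
       undesirable_spec = spec,
       U = undesirable_states(R, spec),
       control_genes = setdiff(genes_of(R), excluded))
}
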