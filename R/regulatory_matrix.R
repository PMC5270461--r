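#' Signed regulatory matrix of a Boolean network
#'
#' Constructs the n-by-n signed regulatory matrix of a Boolean gene
#' regulatory network.  Entry `(i, j)` is `+1` if gene `j` activates gene
#' `i`, `-1` if it suppresses it, and `0` if gene `j` is not a predictor
#' of gene `i`.  Row `i` therefore lists the predictors of gene `i`; a row
#' may be all zero (a gene with no predictors holds its value except under
#' random perturbation).
#'
#' @param entries integer matrix with values in `{-1, 0, 1}`; square.
#' @param genes character vector of gene names, one per row/column.
#'   Defaults to the rownames of `entries`, or `g1..gn`.
#' @return An object of class `regulatory_matrix`: the integer matrix with
#'   gene names as dimnames.
#' @examples
#' R <- regulatory_matrix(rbind(c(1, -1), c(1, 0)), genes = c("a", "b"))
#' majority_vote_update(R, c(1, 1))
#' @export
regulatory_matrix <- function(entries, genes = NULL) {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries))
    stop("regulatory matrix must be square, got ",
         nrow(entries), "x", ncol(entries))
  if (!all(entries %in% c(-1L, 0L, 1L)))
    stop("regulatory matrix entries must be in {-1, 0, 1}")
  if (is.null(genes)) genes <- rownames(entries)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(entries)))
  if (length(genes) != nrow(entries))
    stop("length(genes) must equal the matrix dimension")
  storage.mode(entries) <- "integer"
  dimnames(entries) <- list(genes, genes)
  structure(entries, class = c("regulatory_matrix", "matrix", "array"))
}

#' @export
print.regulatory_matrix <- function(x, ...) {
  cat("Regulatory matrix:", nrow(x), "genes,", sum(x != 0), "edges\n")
  print(unclass(x), ...)
  invisible(x)
}

genes_of <- function(R) rownames(R)

n_genes <- function(R) nrow(R)

#' Read or write a regulatory matrix
#'
#' TSV files carry a header row and a leading column of gene names with
#' integer entries in `{-1, 0, 1}`.  Files ending in `.json` use the layout
#' `{"genes": [...], "entries": [[...], ...]}` instead.
#'
#' @param path file path; format chosen by extension (`.json` vs TSV).
#' @return `read_regulatory_matrix()` returns a [regulatory_matrix].
#' @export
read_regulatory_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$genes) || is.null(obj$entries))
      stop("JSON regulatory matrix needs fields 'genes' and 'entries'")
    return(regulatory_matrix(obj$entries, genes = obj$genes))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  regulatory_matrix(as.matrix(df), genes = rownames(df))
}

#' @param R a [regulatory_matrix].
#' @rdname read_regulatory_matrix
#' @export
write_regulatory_matrix <- function(R, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(genes = genes_of(R), entries = unclass(R)),
      path, auto_unbox = TRUE)
  } else {
    df <- as.data.frame(unclass(R))
    utils::write.table(cbind(gene = genes_of(R), df), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Convert between integer states and gene activity profiles
#'
#' A network on `n` genes has state space `S = {0, ..., 2^n - 1}`.  State
#' `x` corresponds to the binary gene activity profile (GAP)
#' `v = (v_1, ..., v_n)` with gene 1 as the most significant bit:
#' `x = sum_i 2^(n-i) v_i`.
#'
#' @param x integer state(s) in `0:(2^n - 1)`.
#' @param n number of genes.
#' @return `state_to_gap()`: a binary vector (or matrix, one row per
#'   state); `gap_to_state()`: integer state(s).
#' @export
state_to_gap <- function(x, n) {
  stopifnot(all(x >= 0), all(x < 2^n))
  V <- vapply(seq_len(n),
              function(i) bitwAnd(bitwShiftR(as.integer(x), n - i), 1L),
              integer(length(x)))
  if (length(x) == 1L) as.integer(V) else matrix(V, nrow = length(x))
}

#' @param v binary GAP vector, or a matrix with one GAP per row.
#' @rdname state_to_gap
#' @export
gap_to_state <- function(v) {
  if (is.matrix(v)) {
    stopifnot(all(v %in% 0:1))
    return(as.integer(v %*% 2^((ncol(v) - 1):0)))
  }
  stopifnot(all(v %in% 0:1))
  as.integer(sum(v * 2^((length(v) - 1):0)))
}

# all 2^n GAPs as a (2^n x n) 0/1 matrix, row x+1 = GAP of state x
state_table <- function(n) {
  x <- 0:(2^n - 1)
  vapply(seq_len(n),
         function(i) bitwAnd(bitwShiftR(x, n - i), 1L),
         integer(2^n))
}

#' Undesirable state sets
#'
#' Materializes the set `U` of undesirable states from a predicate on gene
#' values, given either as a named vector/list of required values (e.g.
#' `c(CycD = 0, Rb = 0, p27 = 0)`) or as a function mapping a GAP vector
#' to `TRUE`/`FALSE`.
#'
#' @param genes character vector of gene names defining bit order, or a
#'   [regulatory_matrix].
#' @param spec named vector/list of `gene = value` requirements, or a
#'   predicate function on GAP vectors.
#' @return Sorted integer vector of undesirable states (0-based).
#' @examples
#' undesirable_states(c("a", "b"), c(a = 0))   # states 0 and 1
#' @export
undesirable_states <- function(genes, spec) {
  if (inherits(genes, "regulatory_matrix")) genes <- genes_of(genes)
  n <- length(genes)
  V <- state_table(n)
  if (is.function(spec)) {
    keep <- apply(V, 1, function(v) isTRUE(spec(v)))
  } else {
    spec <- unlist(spec)
    bad <- setdiff(names(spec), genes)
    if (length(bad)) stop("unknown gene(s) in undesirable spec: ",
                          paste(bad, collapse = ", "))
    keep <- rep(TRUE, nrow(V))
    for (g in names(spec)) keep <- keep & V[, match(g, genes)] == spec[[g]]
  }
  sort(which(keep) - 1L)
}

#' @param path JSON file holding `{"gene": value, ...}` requirement pairs.
#' @rdname undesirable_states
#' @export
read_undesirable_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  unlist(obj)
}
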