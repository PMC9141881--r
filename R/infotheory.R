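## Shannon entropy, joint entropy, mutual information and co-information on
## maximum-likelihood (plug-in) probability estimates over discrete joint
## states.  All quantities are in bits (log base 2).  No bias correction is
## applied: estimates are intended for complete phenotypic recordings, not
## subsampled data.

.TOL <- 1e-9

## Intern an arbitrary discrete column as integer codes 0..k-1.
.col_codes <- function(x) {
  u <- sort(unique(x))
  list(code = match(x, u) - 1L, k = length(u))
}

## Mixed-radix joint code over a set of columns of a data frame.
## Returns a numeric vector of codes (doubles; exact while the joint state
## space stays below 2^53, far beyond any enumerable table here).
.joint_codes <- function(states, cols) {
  code <- numeric(nrow(states))
  for (cl in cols) {
    cc <- .col_codes(states[[cl]])
    code <- code * cc$k + cc$code
  }
  code
}

.entropy_of_codes <- function(code) {
  if (length(code) == 0L) return(0)
  counts <- tabulate(match(code, unique(code)))
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

.resolve_cols <- function(table, ids, arg = "subset") {
  stopifnot(inherits(table, "paired_table"))
  if (length(ids) == 0L) stop("'", arg, "' must name at least one node")
  bad <- setdiff(ids, names(table$states))
  if (length(bad) > 0L)
    stop("unknown node id(s) in '", arg, "': ", paste(bad, collapse = ", "))
  ids
}

#' Shannon entropy in bits
#'
#' `entropy()` is generic: it accepts a bare vector of probabilities, a
#' [prob_table] produced by [estimate_probabilities()], or a [paired_table]
#' together with a `subset` of node ids (in which case the maximum-likelihood
#' joint distribution over the subset is used).
#'
#' @param x probabilities, a `prob_table`, or a `paired_table`.
#' @param ... further arguments passed to methods.
#' @return Entropy in bits (non-negative; 0 for a single-state distribution).
#' @examples
#' entropy(c(0.5, 0.5))        # a fair coin: 1 bit
#' entropy(c(1/6, 5/6))        # a rarely-on sensor: ~0.65 bits
#' @export
entropy <- function(x, ...) UseMethod("entropy")

#' @rdname entropy
#' @export
entropy.default <- function(x, ...) {
  p <- as.numeric(x)
  if (any(p < 0)) stop("probabilities must be non-negative")
  s <- sum(p)
  if (abs(s - 1) > 1e-6) stop("probabilities must sum to 1")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @rdname entropy
#' @export
entropy.prob_table <- function(x, ...) entropy.default(unclass(x))

#' @rdname entropy
#' @param subset node ids selecting the joint variable (paired_table method).
#' @export
entropy.paired_table <- function(x, subset, ...) joint_entropy(x, subset)

#' Joint entropy of a set of nodes
#'
#' Entropy, in bits, of the joint state of `subset`, estimated by counting
#' unique joint states in the table (maximum-likelihood plug-in estimate).
#'
#' @param table a [paired_table].
#' @param subset character vector of node ids (columns of the table).
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(table, subset) {
  subset <- .resolve_cols(table, subset)
  .entropy_of_codes(.joint_codes(table$states, unique(subset)))
}

#' Mutual information (shared entropy) between two sets of nodes
#'
#' Computed as `H(A) + H(B) - H(AB)`.  The sets may overlap; the joint
#' variable deduplicates columns, so `mutual_information(t, "x", "x")`
#' equals `H(x)`.  Plug-in mutual information is mathematically
#' non-negative; tiny negative floating-point residue is clipped to zero.
#'
#' @param table a [paired_table].
#' @param setA,setB character vectors of node ids.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(table, setA, setB) {
  setA <- .resolve_cols(table, setA, "setA")
  setB <- .resolve_cols(table, setB, "setB")
  v <- joint_entropy(table, setA) + joint_entropy(table, setB) -
    joint_entropy(table, unique(c(setA, setB)))
  max(v, 0)
}

#' Three-way co-information
#'
#' `I(A;C) + I(B;C) - I(AB;C)`: the triple-overlap region of the
#' three-variable entropy Venn diagram.  Unlike pairwise mutual
#' information, co-information may be negative; a negative value signals
#' synergy, the hallmark of one-time-pad (XOR) encryption, where each
#' variable is the key unlocking the information shared by the other two.
#'
#' @param table a [paired_table].
#' @param A,B,C character vectors of node ids.
#' @return Co-information in bits (may be negative).
#' @export
co_information <- function(table, A, B, C) {
  A <- .resolve_cols(table, A, "A")
  B <- .resolve_cols(table, B, "B")
  C <- .resolve_cols(table, C, "C")
  mutual_information(table, A, C) + mutual_information(table, B, C) -
    mutual_information(table, unique(c(A, B)), C)
}

#' Three-variable entropy Venn decomposition
#'
#' All seven regions of the entropy Venn diagram for variables (A, B, C),
#' derived from joint and marginal entropies only: the three conditional
#' entropies (unique regions), the three pairwise conditional informations,
#' and the triple co-information.  The regions of each circle sum to that
#' variable's entropy.
#'
#' @param table a [paired_table].
#' @param A,B,C character vectors of node ids.
#' @return An object of class `venn3`: a list with the seven regions
#'   (`a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`) and marginal
#'   entropies `h` (named numeric of length 3).
#' @export
venn3 <- function(table, A, B, C) {
  A <- .resolve_cols(table, A, "A")
  B <- .resolve_cols(table, B, "B")
  C <- .resolve_cols(table, C, "C")
  hA <- joint_entropy(table, A)
  hB <- joint_entropy(table, B)
  hC <- joint_entropy(table, C)
  hAB <- joint_entropy(table, unique(c(A, B)))
  hAC <- joint_entropy(table, unique(c(A, C)))
  hBC <- joint_entropy(table, unique(c(B, C)))
  hABC <- joint_entropy(table, unique(c(A, B, C)))
  out <- list(
    a_only = hABC - hBC,                  # H(A|BC)
    b_only = hABC - hAC,                  # H(B|AC)
    c_only = hABC - hAB,                  # H(C|AB)
    ab = hAC + hBC - hC - hABC,           # I(A;B|C)
    ac = hAB + hBC - hB - hABC,           # I(A;C|B)
    bc = hAB + hAC - hA - hABC,           # I(B;C|A)
    abc = hA + hB + hC - hAB - hAC - hBC + hABC,  # I(A;B;C)
    h = c(A = hA, B = hB, C = hC)
  )
  class(out) <- "venn3"
  out
}

#' @export
print.venn3 <- function(x, ...) {
  cat("Three-variable entropy Venn decomposition (bits)\n")
  cat(sprintf("  H(A)=%.4g  H(B)=%.4g  H(C)=%.4g\n",
              x$h[["A"]], x$h[["B"]], x$h[["C"]]))
  cat(sprintf("  unique: A=%.4g B=%.4g C=%.4g\n", x$a_only, x$b_only, x$c_only))
  cat(sprintf("  pairwise|third: AB=%.4g AC=%.4g BC=%.4g\n", x$ab, x$ac, x$bc))
  cat(sprintf("  triple co-information: %.4g\n", x$abc))
  invisible(x)
}

#' Regions of one circle of a `venn3` decomposition
#'
#' Convenience accessor: the four regions making up the circle of one
#' variable, in the order (unique, overlap with first other, overlap with
#' second other, triple).  They sum to the variable's entropy.
#'
#' @param v a [venn3] object.
#' @param which one of "A", "B", "C".
#' @return Numeric vector of length 4.
#' @export
venn3_circle <- function(v, which = c("C", "A", "B")) {
  which <- match.arg(which)
  switch(which,
    A = c(v$a_only, v$ab, v$ac, v$abc),
    B = c(v$b_only, v$ab, v$bc, v$abc),
    C = c(v$c_only, v$ac, v$bc, v$abc)
  )
}
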