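## Hand-built brains and synthetic paired tables with known information
## structure.  These are first-class regression anchors: every analysis
## stage can be tested against expectations derivable by hand or brute
## force, without running evolution.

## A 2-input copy gate: writes its first input to `dst`, padded to the
## minimum gate arity with a constant-0 second output (OR with 0 is the
## identity, so the pad is inert wherever it lands).
.copy_gate <- function(src, dst, pad_out) {
  list(ins = c(src, src), outs = c(dst, pad_out),
       table = cbind(c(0L, 1L, 0L, 1L), 0L))
}

.xor_gate <- function(srcs, dst, pad_out) {
  list(ins = srcs, outs = c(dst, pad_out),
       table = cbind(c(0L, 1L, 1L, 0L), 0L))
}

#' Shift-register brain solving n-Back perfectly
#'
#' A chain of copy gates `i1 -> m1 -> m2 -> ... -> m8` so that
#' memory-before node `mk` always holds the input from `k` updates ago;
#' each output taps the memory node matching its delay.  Information is
#' simply passed from node to node: every feature has fragmentation 1 and
#' the flow graph is a set of linear chains.
#'
#' @param delays echo delays; each needs a memory tap, so
#'   `max(delays) <= 8`.
#' @return A [markov_brain] with the n-Back layout.
#' @export
make_copy_chain <- function(delays = c(1L, 3L, 5L, 7L, 8L)) {
  layout <- nback_layout()
  stopifnot(max(delays) <= layout$n_memory)
  n_out <- layout$n_output
  t0_mem <- function(k) 1L + k            # T0: i1, m1..m8
  t1_mem <- function(k) n_out + k         # T1: o1..o5, m1..m8
  pad <- t1_mem(layout$n_memory)          # writes 0 into m8's OR: inert
  gates <- list(.copy_gate(1L, t1_mem(1L), pad))
  for (k in 2:layout$n_memory)
    gates <- c(gates, list(.copy_gate(t0_mem(k - 1L), t1_mem(k), pad)))
  for (j in seq_along(delays))
    gates <- c(gates, list(.copy_gate(t0_mem(delays[j]), j, pad)))
  markov_brain(gates, layout)
}

#' XOR time-delay (one-time-pad) circuit
#'
#' Implements the encryption/decryption cycle observed in evolved brains:
#' `m6` stores the current input bit, `m2` copies `m6`, `m7` stores
#' `m2 XOR m6`, and `o5` is decoded as `m2 XOR m7`, so that
#' `o5(t+3) = x_t`: a three-step time delay achieved by consecutive
#' encryption with a one-time pad.  The pair `{m2, m7}` is the only DIS for
#' `o5` (fragmentation 2): each node alone carries zero information about
#' `o5`, and the entropy Venn diagram of `(m2, m7, o5)` has regions
#' `(0, 1, 1, -1)`.
#'
#' @return A [markov_brain] with the n-Back layout.
#' @export
make_xor_delay <- function() {
  layout <- nback_layout()
  n_out <- layout$n_output
  t0_mem <- function(k) 1L + k
  t1_mem <- function(k) n_out + k
  pad <- t1_mem(8L)
  gates <- list(
    .copy_gate(1L, t1_mem(6L), pad),                       # m6 <- i1
    .copy_gate(t0_mem(6L), t1_mem(2L), pad),               # m2 <- m6
    .xor_gate(c(t0_mem(2L), t0_mem(6L)), t1_mem(7L), pad), # m7 <- m2 ^ m6
    .xor_gate(c(t0_mem(2L), t0_mem(7L)), 5L, pad))         # o5 <- m2 ^ m7
  markov_brain(gates, layout)
}

#' Synthetic paired table with planted structure
#'
#' Generates observations of `n_nodes` fair predictor bits `p1..pn` plus
#' one feature column `y` with planted structure:
#'
#' * `"independent"`: `n_rows` i.i.d. rows; `y` is a fair bit independent
#'   of all predictors (fragmentation -1 at theta = 1);
#' * `"copy"`: `n_rows` i.i.d. rows; `y` duplicates `p1` (fragmentation 1);
#' * `"parity"`: `y` is the XOR of the first `k` predictors — a `k`-node
#'   one-time pad.  The predictor rows are a complete factorial design
#'   (every joint state equally often, `n_rows` rounded up to a multiple of
#'   `2^n_nodes`), so that, exactly as in the generating distribution, any
#'   strict subset of the parity set carries zero bits about `y`: the
#'   parity set is irreducible and fragmentation is `k`.
#'
#' @param n_nodes number of predictor bits.
#' @param n_rows number of rows (lower bound for `"parity"`, see above).
#' @param structure planted structure (see above).
#' @param k parity order (only for `structure = "parity"`).
#' @return A [paired_table] with predictors `p1..pn` and feature `y`.
#' @export
make_random_table <- function(n_nodes, n_rows,
                              structure = c("independent", "copy", "parity"),
                              k = NULL) {
  structure <- match.arg(structure)
  if (structure == "parity") {
    if (is.null(k)) k <- n_nodes
    stopifnot(k >= 1, k <= n_nodes)
    P <- as.matrix(expand.grid(rep(list(0:1), n_nodes)))
    P <- P[rep(seq_len(nrow(P)), ceiling(n_rows / nrow(P))), , drop = FALSE]
    P <- P[sample.int(nrow(P)), , drop = FALSE]
    colnames(P) <- paste0("p", seq_len(n_nodes))
    y <- as.integer(rowSums(P[, seq_len(k), drop = FALSE]) %% 2L)
  } else {
    P <- matrix(sample(0:1, n_nodes * n_rows, replace = TRUE), nrow = n_rows)
    colnames(P) <- paste0("p", seq_len(n_nodes))
    y <- switch(structure,
      independent = sample(0:1, n_rows, replace = TRUE),
      copy = P[, 1])
  }
  d <- as.data.frame(P)
  rownames(d) <- NULL
  d$y <- y
  paired_table(d, predictors = colnames(P), features = "y")
}

#' The canonical XOR-triple table
#'
#' The four equiprobable joint states of two independent fair bits `A`,
#' `B` and `C = A XOR B`: joint entropy 2 bits (not 3), every pairwise
#' mutual information 0, co-information -1.
#'
#' @return A [paired_table] with predictors `A`, `B` and feature `C`.
#' @export
xor_triple_table <- function() {
  d <- data.frame(A = c(0L, 0L, 1L, 1L), B = c(0L, 1L, 0L, 1L))
  d$C <- bitwXor(d$A, d$B)
  paired_table(d, predictors = c("A", "B"), features = "C")
}
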