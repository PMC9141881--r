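## Genome-decoded network substrates.  Both substrates map a T0 state
## (inputs then memory-before) to a T1 state (outputs then memory-after):
##
##   * Markov Brains: sparse networks of 2-4-input / 2-4-output logic
##     gates decoded from a byte genome by scanning for start codons;
##     colliding writes to one T1 node combine by OR.
##   * RNNs: fully connected single-layer recurrent networks
##     y = tanh(W x + c), with outputs and memory discretized to {0,1}
##     (<= 0 -> 0, > 0 -> 1) before recording and recurrence, so that on
##     binary inputs the network induces a finite-state deterministic map.

START_CODON <- c(42L, 213L)

#' Node layout of a brain
#'
#' T0 node order is inputs then memory-before; T1 order is outputs then
#' memory-after.  Node ids are `i1..`, `o1..`, `m1..`.
#'
#' @param n_input,n_output,n_memory node counts (memory defaults to 8).
#' @return An object of class `brain_layout`.
#' @export
brain_layout <- function(n_input, n_output, n_memory = 8L) {
  structure(list(
    n_input = as.integer(n_input), n_output = as.integer(n_output),
    n_memory = as.integer(n_memory),
    t0_ids = c(if (n_input > 0) paste0("i", seq_len(n_input)),
               if (n_memory > 0) paste0("m", seq_len(n_memory))),
    t1_ids = c(if (n_output > 0) paste0("o", seq_len(n_output)),
               if (n_memory > 0) paste0("m", seq_len(n_memory)))),
    class = "brain_layout")
}

#' Random byte genome
#'
#' @param length genome length in sites (bytes); runs start from 5000.
#' @return Integer vector of values 0-255.
#' @export
random_genome <- function(length = 5000L) {
  sample.int(256L, length, replace = TRUE) - 1L
}

#' Seed a genome with start codons
#'
#' Overwrites byte pairs at `n` evenly spaced positions with the start
#' codon so that freshly initialized Markov genomes decode to a non-empty
#' gate set.
#'
#' @param g genome (integer vector 0-255).
#' @param n number of codons to place.
#' @param codon the start codon byte pair.
#' @return The modified genome.
#' @export
seed_start_codons <- function(g, n = 6L, codon = START_CODON) {
  pos <- floor(seq(1, length(g) - 60, length.out = n))
  for (p in pos) g[p:(p + 1L)] <- codon
  g
}

#' Construct a Markov Brain from explicit gates
#'
#' @param gates list of gates; each gate is a list with integer vectors
#'   `ins` (T0 node indices, 2-4 of them), `outs` (T1 node indices, 2-4),
#'   and `table`, a `2^length(ins) x length(outs)` 0/1 matrix.  The row
#'   looked up for an input pattern treats the first listed input as the
#'   least significant bit: row `1 + sum(t0[ins] * 2^(0:(k-1)))`.
#' @param layout a [brain_layout].
#' @return Object of class `markov_brain`.
#' @export
markov_brain <- function(gates, layout) {
  n_t0 <- layout$n_input + layout$n_memory
  n_t1 <- layout$n_output + layout$n_memory
  for (g in gates) {
    stopifnot(length(g$ins) >= 2L, length(g$ins) <= 4L,
              length(g$outs) >= 2L, length(g$outs) <= 4L,
              all(g$ins >= 1L), all(g$ins <= n_t0),
              all(g$outs >= 1L), all(g$outs <= n_t1),
              nrow(g$table) == 2^length(g$ins),
              ncol(g$table) == length(g$outs),
              all(g$table %in% c(0L, 1L)))
  }
  structure(list(gates = gates, layout = layout), class = "markov_brain")
}

#' @export
print.markov_brain <- function(x, ...) {
  l <- x$layout
  cat(sprintf("Markov Brain: %d gate(s); %d inputs, %d outputs, %d memory nodes\n",
              length(x$gates), l$n_input, l$n_output, l$n_memory))
  invisible(x)
}

#' Decode a Markov Brain from a byte genome
#'
#' Scans the genome for start codons; each occurrence opens a gene that is
#' decoded to one logic gate.  The gene layout after the codon is: one byte
#' for the number of inputs (`byte %% 3 + 2`), one for the number of
#' outputs, four input-address bytes (`%% n_T0`), four output-address bytes
#' (`%% n_T1`), then `2^n_in * n_out` lookup-table bytes (`%% 2`).  Only
#' the first `n_in`/`n_out` addresses are used.  A gene truncated by the
#' genome end is skipped; decoding is a total function of the byte string,
#' and a genome with no codons yields a legal zero-gate (inert) brain.
#' The codon byte pair is a configurable convention, not derived from the
#' task.
#'
#' @param g genome (integer vector 0-255).
#' @param layout a [brain_layout].
#' @param codon start codon byte pair.
#' @return A [markov_brain].
#' @export
decode_markov_brain <- function(g, layout, codon = START_CODON) {
  n_t0 <- layout$n_input + layout$n_memory
  n_t1 <- layout$n_output + layout$n_memory
  g <- as.integer(g)
  starts <- which(g[-length(g)] == codon[1] & g[-1] == codon[2])
  gates <- list()
  for (p in starts) {
    if (p + 11L > length(g)) next                  # truncated header
    n_in <- g[p + 2L] %% 3L + 2L
    n_out <- g[p + 3L] %% 3L + 2L
    ins <- g[p + 4L:7L][seq_len(n_in)] %% n_t0 + 1L
    outs <- g[p + 8L:11L][seq_len(n_out)] %% n_t1 + 1L
    tab_len <- 2L^n_in * n_out
    if (p + 11L + tab_len > length(g)) next        # truncated table
    tab <- matrix(g[(p + 12L):(p + 11L + tab_len)] %% 2L,
                  nrow = 2L^n_in, ncol = n_out, byrow = TRUE)
    gates[[length(gates) + 1L]] <- list(ins = ins, outs = outs, table = tab)
  }
  markov_brain(gates, layout)
}

#' One Markov Brain update
#'
#' All T1 nodes default to 0; every gate reads its T0 inputs, looks up its
#' output pattern, and writes it; colliding writes to the same T1 node are
#' combined by OR.  The update is a pure function of (brain, t0).
#'
#' @param b a [markov_brain].
#' @param t0 integer 0/1 vector of length inputs + memory.
#' @return Integer 0/1 vector of length outputs + memory.
#' @export
markov_update <- function(b, t0) {
  l <- b$layout
  stopifnot(length(t0) == l$n_input + l$n_memory, all(t0 %in% c(0L, 1L)))
  t1 <- integer(l$n_output + l$n_memory)
  for (g in b$gates) {
    r <- 1L + sum(t0[g$ins] * 2L^(seq_along(g$ins) - 1L))
    for (j in seq_along(g$outs)) {    # sequential OR: a gate may list one
      o <- g$outs[j]                  # node twice among its outputs
      t1[o] <- bitwOr(t1[o], g$table[r, j])
    }
  }
  t1
}

#' Construct an RNN brain from explicit parameters
#'
#' @param W weight matrix (`n_T1 x n_T0`), entries in `[-1, 1]`.
#' @param b bias vector (length `n_T1`), entries in `[-3, 3]`.
#' @param layout a [brain_layout].
#' @return Object of class `rnn_brain`.
#' @export
rnn_brain <- function(W, b, layout) {
  n_t0 <- layout$n_input + layout$n_memory
  n_t1 <- layout$n_output + layout$n_memory
  stopifnot(nrow(W) == n_t1, ncol(W) == n_t0, length(b) == n_t1,
            all(W >= -1), all(W <= 1), all(b >= -3), all(b <= 3))
  structure(list(W = W, b = b, layout = layout), class = "rnn_brain")
}

#' @export
print.rnn_brain <- function(x, ...) {
  l <- x$layout
  cat(sprintf("RNN brain: %d x %d weights; %d inputs, %d outputs, %d memory nodes\n",
              nrow(x$W), ncol(x$W), l$n_input, l$n_output, l$n_memory))
  invisible(x)
}

#' Decode an RNN from a byte genome
#'
#' The first `(n_T0 + 1) * n_T1` genome sites are mapped linearly onto the
#' parameters, one T1 node at a time (its `n_T0` weights, then its bias):
#' weights `byte/255 * 2 - 1` in `[-1, 1]`, biases `byte/255 * 6 - 3` in
#' `[-3, 3]`.  Surplus genome is ignored; the site count is fixed by the
#' layout.
#'
#' @param g genome (integer vector 0-255), at least
#'   `(n_T0 + 1) * n_T1` sites long.
#' @param layout a [brain_layout].
#' @return An [rnn_brain].
#' @export
decode_rnn <- function(g, layout) {
  n_t0 <- layout$n_input + layout$n_memory
  n_t1 <- layout$n_output + layout$n_memory
  need <- (n_t0 + 1L) * n_t1
  if (length(g) < need)
    stop("genome too short: ", length(g), " sites < ", need, " required")
  W <- matrix(0, n_t1, n_t0)
  b <- numeric(n_t1)
  pos <- 1L
  for (i in seq_len(n_t1)) {
    W[i, ] <- g[pos:(pos + n_t0 - 1L)] / 255 * 2 - 1
    b[i] <- g[pos + n_t0] / 255 * 6 - 3
    pos <- pos + n_t0 + 1L
  }
  rnn_brain(W, b, layout)
}

#' One RNN update with discretization
#'
#' `y = tanh(W x + c)`, then every T1 value is discretized (`<= 0 -> 0`,
#' `> 0 -> 1`) before it is recorded or fed back as memory.
#'
#' @param b an [rnn_brain].
#' @param t0 integer 0/1 vector of length inputs + memory.
#' @return Integer 0/1 vector of length outputs + memory.
#' @export
rnn_update <- function(b, t0) {
  stopifnot(length(t0) == ncol(b$W))
  y <- tanh(as.numeric(b$W %*% t0) + b$b)
  as.integer(y > 0)
}

#' A scripted stub brain
#'
#' Wraps an arbitrary update function as a brain, for null models and
#' scripted behaviors in tests (e.g. an agent emitting i.i.d. random output
#' bits).  The function may close over state or draw from the session RNG.
#'
#' @param update_fn function taking the T0 state vector and returning the
#'   T1 state vector (outputs then memory).
#' @param layout a [brain_layout].
#' @return Object of class `stub_brain`.
#' @export
stub_brain <- function(update_fn, layout) {
  structure(list(update_fn = update_fn, layout = layout),
            class = "stub_brain")
}

#' A stub agent emitting independent uniform random output bits
#'
#' Null model for task baselines: memory stays 0, each output is a fair
#' coin drawn from the session RNG.
#'
#' @param layout a [brain_layout].
#' @return A [stub_brain].
#' @export
random_output_brain <- function(layout) {
  n_out <- layout$n_output
  n_mem <- layout$n_memory
  stub_brain(function(t0) c(sample(0:1, n_out, replace = TRUE),
                            integer(n_mem)),
             layout)
}

#' One brain update (generic)
#'
#' Dispatches to [markov_update()], [rnn_update()] or a stub's scripted
#' update function.
#'
#' @param b a brain object.
#' @param t0 T0 state vector.
#' @return T1 state vector.
#' @export
brain_update <- function(b, t0) UseMethod("brain_update")

#' @export
brain_update.markov_brain <- function(b, t0) markov_update(b, t0)

#' @export
brain_update.rnn_brain <- function(b, t0) rnn_update(b, t0)

#' @export
brain_update.stub_brain <- function(b, t0) as.integer(b$update_fn(t0))

#' Physical connectome of a substrate
#'
#' Directed links from T0 node ids to T1 node ids: a link `s -> n` exists
#' iff some gate reads `s` and writes `n` (Markov Brain), or the weight
#' `w[n, s]` is nonzero (RNN; all weights count as links unless exactly
#' zero).  Used by [disambiguate()] to prune coincidental predictive sets.
#'
#' @param b a [markov_brain] or [rnn_brain].
#' @return A data.frame of class `connectome` with columns `from`, `to`.
#' @export
connectome_of <- function(b) UseMethod("connectome_of")

#' @export
connectome_of.markov_brain <- function(b) {
  l <- b$layout
  links <- unique(do.call(rbind, lapply(b$gates, function(g)
    expand.grid(from = l$t0_ids[g$ins], to = l$t1_ids[g$outs],
                stringsAsFactors = FALSE))))
  if (is.null(links))
    links <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  rownames(links) <- NULL
  class(links) <- c("connectome", "data.frame")
  links
}

#' @export
connectome_of.rnn_brain <- function(b) {
  l <- b$layout
  idx <- which(b$W != 0, arr.ind = TRUE)
  links <- data.frame(from = l$t0_ids[idx[, "col"]],
                      to = l$t1_ids[idx[, "row"]],
                      stringsAsFactors = FALSE)
  links <- unique(links)
  rownames(links) <- NULL
  class(links) <- c("connectome", "data.frame")
  links
}

#' Write a brain description as JSON
#'
#' Gates (Markov) or weights/biases (RNN) plus the layout, for inspection
#' and fixture authoring.
#'
#' @param b a brain.
#' @param path output path.
#' @export
write_brain_json <- function(b, path) {
  l <- b$layout
  base <- list(n_input = l$n_input, n_output = l$n_output,
               n_memory = l$n_memory)
  obj <- if (inherits(b, "markov_brain")) {
    c(base, list(type = "markov",
                 gates = lapply(b$gates, function(g)
                   list(ins = g$ins, outs = g$outs,
                        table = apply(g$table, 1, identity,
                                      simplify = FALSE)))))
  } else if (inherits(b, "rnn_brain")) {
    c(base, list(type = "rnn",
                 weights = apply(b$W, 1, identity, simplify = FALSE),
                 biases = b$b))
  } else stop("unsupported brain type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## Flatten a brain into the list the compiled task loops consume.
compile_brain <- function(b) {
  l <- b$layout
  if (inherits(b, "markov_brain")) {
    list(type = "markov",
         n_input = l$n_input, n_output = l$n_output, n_memory = l$n_memory,
         gate_nin = vapply(b$gates, function(g) length(g$ins), integer(1)),
         gate_nout = vapply(b$gates, function(g) length(g$outs), integer(1)),
         gate_ins = as.integer(unlist(lapply(b$gates, `[[`, "ins"),
                                      use.names = FALSE)) - 1L,
         gate_outs = as.integer(unlist(lapply(b$gates, `[[`, "outs"),
                                       use.names = FALSE)) - 1L,
         gate_tab = as.integer(unlist(lapply(b$gates, function(g)
           as.vector(t(g$table))), use.names = FALSE)))
  } else if (inherits(b, "rnn_brain")) {
    list(type = "rnn",
         n_input = l$n_input, n_output = l$n_output, n_memory = l$n_memory,
         W = b$W, b = b$b)
  } else NULL  # stub brains take the interpreted path
}
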