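## Task environments: the n-Back memory task and the Block Catch active
## categorical perception task.  Each evaluation returns a fitness in
## [0, 1] and (optionally) a full state recording of inputs, outputs,
## memory before/after, and (for Block Catch) world features per update.
##
## Markov and RNN brains run through the compiled loops; stub/scripted
## brains take an interpreted path with identical semantics (the two paths
## are cross-checked in the test suite).

#' n-Back task configuration
#'
#' The agent reads one bit per update and must echo, on each scored update,
#' the bits seen `delays` updates earlier.  The first `warmup` updates of a
#' lifetime are neither scored nor recorded, giving the network time to
#' load its memory; `max(delays)` may not exceed the warm-up.
#'
#' @param delays integer echo delays.
#' @param n_lifetimes number of test strings per evaluation.
#' @param string_length bits per lifetime.
#' @param warmup unscored updates at the start of each lifetime.
#' @return Object of class `nback_config`.
#' @export
nback_config <- function(delays = c(1L, 3L, 5L, 7L, 8L), n_lifetimes = 25L,
                         string_length = 33L, warmup = 8L) {
  stopifnot(max(delays) <= warmup, warmup < string_length)
  structure(list(delays = as.integer(delays),
                 n_lifetimes = as.integer(n_lifetimes),
                 string_length = as.integer(string_length),
                 warmup = as.integer(warmup)),
            class = "nback_config")
}

#' Block Catch task configuration
#'
#' Blocks of sizes 2, 3 and 4 fall through a world `height` units high and
#' `width` units wide (lateral wraparound), drifting one unit left or right
#' per update.  Every (size, direction, start column) combination is one
#' lifetime: `3 * 2 * width = 120` lifetimes by default.  The agent is a
#' paddle whose body spans its four upward sensors and the two-unit blind
#' spot between them (mask `S S _ _ S S`).  Size-2 blocks and right-moving
#' size-3 blocks must be caught (any overlap of block and paddle at
#' landing); size-4 blocks and left-moving size-3 blocks must be avoided.
#'
#' @param width,height world dimensions.
#' @param updates updates per lifetime (the block descends from the top and
#'   lands after `updates` steps).
#' @return Object of class `blockcatch_config`.
#' @export
blockcatch_config <- function(width = 20L, height = 32L, updates = 31L) {
  structure(list(width = as.integer(width), height = as.integer(height),
                 updates = as.integer(updates),
                 n_lifetimes = 3L * 2L * as.integer(width)),
            class = "blockcatch_config")
}

#' Names of the Block Catch world-feature columns
#'
#' Ten binary features per update: to-be-caught, moving-left, four block
#' size indicators (size 1 is a never-used control and stays constant 0),
#' and the four direction-by-decision conjunctions.
#'
#' @return Character vector of length 10.
#' @export
world_feature_names <- function() {
  c("catch", "left", "size1", "size2", "size3", "size4",
    "left_catch", "left_avoid", "right_catch", "right_avoid")
}

#' n-Back layout helper
#' @param n_memory memory nodes (default 8).
#' @return A [brain_layout] with 1 input and 5 outputs.
#' @export
nback_layout <- function(n_memory = 8L) brain_layout(1L, 5L, n_memory)

#' Block Catch layout helper
#' @param n_memory memory nodes (default 8).
#' @return A [brain_layout] with 4 inputs and 2 outputs.
#' @export
blockcatch_layout <- function(n_memory = 8L) brain_layout(4L, 2L, n_memory)

.mem_ids <- function(n) paste0("m", seq_len(n))

.assemble_recording <- function(res, layout, world = FALSE) {
  n_mem <- layout$n_memory
  inputs <- paste0("i", seq_len(layout$n_input))
  outputs <- paste0("o", seq_len(layout$n_output))
  mem <- .mem_ids(n_mem)
  d <- data.frame(lifetime = res$lifetime, update = res$update)
  d[inputs] <- as.data.frame(res$input)
  d[outputs] <- as.data.frame(res$output)
  d[mem] <- as.data.frame(res$mem_before)
  d[paste0(mem, "_next")] <- as.data.frame(res$mem_after)
  wnames <- character(0)
  if (world) {
    wnames <- world_feature_names()
    d[wnames] <- as.data.frame(res$world)
  }
  state_recording(d, inputs = inputs, outputs = outputs, memory = mem,
                  world = wnames)
}

#' Evaluate a brain on the n-Back task
#'
#' Input bits are drawn i.i.d. uniform per lifetime from the session RNG
#' (seed it, or pass `seed`, for reproducible evaluations).  Fitness is the
#' number of correct answers divided by the total number of answers; random
#' guessing scores 0.5 in expectation.
#'
#' @param brain a [markov_brain], [rnn_brain] or [stub_brain] with an
#'   n-Back layout (1 input, one output per delay).
#' @param cfg an [nback_config].
#' @param seed optional integer seed for the input strings (and any
#'   stochastic stub brain).
#' @param record collect a [state_recording] of the scored updates?
#' @return Object of class `evaluation_result`: list with `fitness`,
#'   `recording` (or `NULL`), and `task`.
#' @export
run_nback <- function(brain, cfg = nback_config(), seed = NULL,
                      record = TRUE) {
  l <- brain$layout
  if (l$n_input != 1L || l$n_output != length(cfg$delays))
    stop("brain layout does not match the n-Back configuration")
  if (!is.null(seed)) set.seed(seed)
  bits <- matrix(sample(0:1, cfg$n_lifetimes * cfg$string_length,
                        replace = TRUE),
                 nrow = cfg$n_lifetimes, ncol = cfg$string_length)
  cb <- compile_brain(brain)
  res <- if (!is.null(cb)) {
    .cpp_run_nback(cb, bits, cfg$delays, cfg$warmup, record)
  } else {
    .r_run_nback(brain, bits, cfg$delays, cfg$warmup, record)
  }
  structure(list(fitness = res$fitness,
                 recording = if (record) .assemble_recording(res, l)
                             else NULL,
                 task = "nback"),
            class = "evaluation_result")
}

## Interpreted reference path; semantics identical to the compiled loop.
.r_run_nback <- function(brain, bits, delays, warmup, record) {
  l <- brain$layout
  n_mem <- l$n_memory
  n_out <- length(delays)
  n_life <- nrow(bits); L <- ncol(bits)
  scored <- L - warmup
  rows <- vector("list", n_life * scored)
  correct <- 0L; total <- 0L; row <- 0L
  for (lt in seq_len(n_life)) {
    mem <- integer(n_mem)
    for (u in seq_len(L)) {
      t0 <- c(bits[lt, u], mem)
      t1 <- brain_update(brain, t0)
      if (u > warmup) {
        expected <- bits[lt, u - delays]
        correct <- correct + sum(t1[seq_len(n_out)] == expected)
        total <- total + n_out
        if (record) {
          row <- row + 1L
          rows[[row]] <- c(lt, u, bits[lt, u], t1[seq_len(n_out)], mem,
                           t1[n_out + seq_len(n_mem)])
        }
      }
      mem <- t1[n_out + seq_len(n_mem)]
    }
  }
  out <- list(fitness = correct / total)
  if (record) {
    m <- do.call(rbind, rows)
    out$lifetime <- m[, 1]; out$update <- m[, 2]
    out$input <- m[, 3, drop = FALSE]
    out$output <- m[, 3 + seq_len(n_out), drop = FALSE]
    out$mem_before <- m[, 3 + n_out + seq_len(n_mem), drop = FALSE]
    out$mem_after <- m[, 3 + n_out + n_mem + seq_len(n_mem), drop = FALSE]
  }
  out
}

#' Evaluate a brain on the Block Catch task
#'
#' Deterministic: every (size, direction, start) combination is replayed
#' once.  Within an update the agent senses and moves first, then the block
#' descends one unit and drifts one unit laterally.  Fitness is the number
#' of correct catch-or-avoid decisions divided by the number of lifetimes.
#'
#' @param brain a brain with a Block Catch layout (4 inputs, 2 outputs).
#'   Motor semantics: output pattern `(1,0)` moves one unit left, `(0,1)`
#'   one unit right, `(0,0)`/`(1,1)` stays.
#' @param cfg a [blockcatch_config].
#' @param record collect a [state_recording] (including the ten
#'   world-feature columns)?
#' @return An `evaluation_result` with additional element `life_correct`.
#' @export
run_blockcatch <- function(brain, cfg = blockcatch_config(), record = TRUE) {
  l <- brain$layout
  if (l$n_input != 4L || l$n_output != 2L)
    stop("brain layout does not match the Block Catch configuration")
  cb <- compile_brain(brain)
  res <- if (!is.null(cb)) {
    .cpp_run_blockcatch(cb, cfg$width, cfg$updates, record)
  } else {
    .r_run_blockcatch(brain, cfg, record)
  }
  structure(list(fitness = res$fitness,
                 life_correct = res$life_correct,
                 recording = if (record)
                   .assemble_recording(res, l, world = TRUE) else NULL,
                 task = "blockcatch"),
            class = "evaluation_result")
}

.blockcatch_world <- function(size, dir) {
  should_catch <- (size == 2L) || (size == 3L && dir == 1L)
  as.integer(c(should_catch, dir == -1L,
               size == 1L, size == 2L, size == 3L, size == 4L,
               dir == -1L && should_catch, dir == -1L && !should_catch,
               dir == 1L && should_catch, dir == 1L && !should_catch))
}

.r_run_blockcatch <- function(brain, cfg, record) {
  l <- brain$layout
  width <- cfg$width; updates <- cfg$updates
  n_mem <- l$n_memory
  sensor_off <- c(0L, 1L, 4L, 5L)
  body <- 6L
  rows <- list(); life_correct <- integer(0)
  correct <- 0L; lt <- 0L
  for (size in c(2L, 3L, 4L)) for (dir in c(-1L, 1L)) {
    should_catch <- (size == 2L) || (size == 3L && dir == 1L)
    world <- .blockcatch_world(size, dir)
    for (start in 0:(width - 1L)) {
      lt <- lt + 1L
      block <- start; pad <- 0L
      mem <- integer(n_mem)
      for (u in seq_len(updates)) {
        block_cols <- (block + 0:(size - 1L)) %% width
        sensors <- as.integer((pad + sensor_off) %% width %in% block_cols)
        t1 <- brain_update(brain, c(sensors, mem))
        if (t1[1] == 1L && t1[2] == 0L) pad <- (pad - 1L) %% width
        else if (t1[1] == 0L && t1[2] == 1L) pad <- (pad + 1L) %% width
        if (record)
          rows[[length(rows) + 1L]] <-
            c(lt, u, sensors, t1[1:2], mem, t1[2L + seq_len(n_mem)], world)
        mem <- t1[2L + seq_len(n_mem)]
        block <- (block + dir) %% width
      }
      block_cols <- (block + 0:(size - 1L)) %% width
      caught <- any((pad + 0:(body - 1L)) %% width %in% block_cols)
      ok <- caught == should_catch
      life_correct[lt] <- as.integer(ok)
      if (ok) correct <- correct + 1L
    }
  }
  out <- list(fitness = correct / lt, life_correct = life_correct)
  if (record) {
    m <- do.call(rbind, rows)
    out$lifetime <- m[, 1]; out$update <- m[, 2]
    out$input <- m[, 2L + 1:4, drop = FALSE]
    out$output <- m[, 6L + 1:2, drop = FALSE]
    out$mem_before <- m[, 8L + seq_len(n_mem), drop = FALSE]
    out$mem_after <- m[, 8L + n_mem + seq_len(n_mem), drop = FALSE]
    out$world <- m[, 8L + 2L * n_mem + 1:10, drop = FALSE]
  }
  out
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("%s evaluation: fitness %.4f%s\n",
              switch(x$task, nback = "n-Back", blockcatch = "Block Catch",
                     x$task),
              x$fitness,
              if (is.null(x$recording)) "" else
                sprintf(" (%d recorded state rows)", nrow(x$recording$data))))
  invisible(x)
}

#' Extract the world-feature columns of a Block Catch trace
#'
#' @param x an `evaluation_result` from [run_blockcatch()] (with
#'   `record = TRUE`) or a [state_recording] carrying world columns.
#' @return data.frame of the ten binary world-feature columns.
#' @export
world_features <- function(x) {
  rec <- if (inherits(x, "evaluation_result")) x$recording else x
  if (is.null(rec) || length(rec$groups$world) == 0L)
    stop("no world features recorded; run the task with record = TRUE")
  rec$data[rec$groups$world]
}
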