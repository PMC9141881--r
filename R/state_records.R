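## Discrete multivariate state recordings collected over agent lifetimes,
## and their projection into paired (t-1 predictor, t feature) tables.
##
## A recording holds, per lifetime and per scored update, the input, output
## and world-feature states at that update together with the memory state
## before ("m1", ...) and after ("m1_next", ...) the update.  The
## consistency invariant m_next(u) == m(u+1) within each lifetime encodes
## the fact that the memory recording has one more element than the other
## recordings: L scored updates carry L+1 memory states.

#' Construct a state recording
#'
#' @param data a data.frame with columns `lifetime`, `update`, one column
#'   per input/output/world node, and for every memory node `m` the two
#'   columns `m` (state before the update) and `m_next` (state after).
#' @param inputs,outputs,memory,world character vectors of node ids per
#'   group (any may be empty except that at least one column group must be
#'   present).
#' @return An object of class `state_recording`.
#' @export
state_recording <- function(data, inputs = character(), outputs = character(),
                            memory = character(), world = character()) {
  stopifnot(is.data.frame(data))
  need <- c("lifetime", "update", inputs, outputs, world,
            memory, paste0(memory, "_next"))
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L)
    stop("recording is missing column(s): ", paste(miss, collapse = ", "))
  data <- data[order(data$lifetime, data$update), need, drop = FALSE]
  rownames(data) <- NULL
  rec <- structure(
    list(data = data,
         groups = list(input = inputs, output = outputs,
                       memory = memory, world = world)),
    class = "state_recording")
  validate_recording(rec)
  rec
}

#' @export
print.state_recording <- function(x, ...) {
  g <- x$groups
  cat(sprintf("State recording: %d lifetimes, %d scored updates total\n",
              n_lifetimes(x), nrow(x$data)))
  cat(sprintf("  inputs: %s\n  outputs: %s\n  memory: %s\n  world: %s\n",
              paste(g$input, collapse = " "), paste(g$output, collapse = " "),
              paste(g$memory, collapse = " "),
              if (length(g$world)) paste(g$world, collapse = " ") else "(none)"))
  invisible(x)
}

#' Number of lifetimes in a recording
#' @param rec a [state_recording].
#' @export
n_lifetimes <- function(rec) length(unique(rec$data$lifetime))

## Internal: check memory before/after chaining and update ordering.
validate_recording <- function(rec) {
  d <- rec$data
  mem <- rec$groups$memory
  for (lt in unique(d$lifetime)) {
    rows <- d[d$lifetime == lt, , drop = FALSE]
    if (nrow(rows) == 0L) next
    if (any(diff(rows$update) <= 0))
      stop("lifetime ", lt, ": update indices must be strictly increasing")
    for (m in mem) {
      before <- rows[[m]]
      after <- rows[[paste0(m, "_next")]]
      if (nrow(rows) > 1L &&
          any(after[-nrow(rows)] != before[-1L]))
        stop("lifetime ", lt, ", node ", m,
             ": memory state after update ", rows$update[which(
               after[-nrow(rows)] != before[-1L])[1]],
             " does not match the state before the next update")
    }
  }
  invisible(rec)
}

#' Read a state recording from a delimited file
#'
#' The file must be comma- or tab-separated with a header
#' `lifetime,update,<node ids...>`; memory-after columns carry the `_next`
#' suffix.  Symbols may be any discrete tokens; if `alphabets` is supplied,
#' every symbol is checked against the declared alphabet of its node.
#'
#' @param path file path.
#' @param inputs,outputs,memory,world node-group declaration (memory ids
#'   without the `_next` suffix).
#' @param alphabets optional named list of allowed symbols per node id.
#' @return A [state_recording].
#' @export
load_recording <- function(path, inputs = character(), outputs = character(),
                           memory = character(), world = character(),
                           alphabets = NULL) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) sep <- "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("lifetime", "update") %in% names(d)))
    stop("recording file must have 'lifetime' and 'update' columns: ", path)
  if (!is.null(alphabets)) {
    for (id in names(alphabets)) {
      if (!id %in% names(d)) next
      bad <- which(!d[[id]] %in% alphabets[[id]])
      if (length(bad) > 0L)
        stop("undeclared symbol '", d[[id]][bad[1]], "' for node ", id,
             " (lifetime ", d$lifetime[bad[1]], ", update ",
             d$update[bad[1]], ")")
    }
  }
  state_recording(d, inputs = inputs, outputs = outputs,
                  memory = memory, world = world)
}

#' Write a state recording to a delimited file
#'
#' @param rec a [state_recording].
#' @param path output path; a `.tsv` extension selects tab separation,
#'   anything else comma separation.
#' @export
write_recording <- function(rec, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(rec$data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Keep only the last fraction of every lifetime
#'
#' Each lifetime keeps its last `max(1, round(fraction * L))` scored updates
#' (rounding half-up), emulating analysis windows restricted to late-life
#' behavior, after an agent has "made up its mind".  Memory chaining is
#' preserved because each kept row carries its own before/after pair.
#'
#' @param rec a [state_recording].
#' @param fraction proportion in (0, 1]; `1` is the identity.
#' @return A trimmed [state_recording].
#' @export
trim_late_lifetime <- function(rec, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("'fraction' must be a single number in (0, 1]")
  d <- rec$data
  keep <- unlist(lapply(split(seq_len(nrow(d)), d$lifetime), function(idx) {
    L <- length(idx)
    k <- max(1L, as.integer(floor(fraction * L + 0.5)))  # round half-up
    idx[(L - k + 1L):L]
  }), use.names = FALSE)
  out <- rec
  out$data <- d[sort(keep), , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Construct a paired predictor/feature table directly
#'
#' Low-level constructor, used by the fixture generators and tests; most
#' analyses build paired tables from recordings with [pair_states()].
#'
#' @param states data.frame of joint states, one row per observation.
#' @param predictors,features character vectors naming columns of `states`.
#' @return An object of class `paired_table`.
#' @export
paired_table <- function(states, predictors, features) {
  stopifnot(is.data.frame(states))
  bad <- setdiff(c(predictors, features), names(states))
  if (length(bad) > 0L)
    stop("unknown column(s): ", paste(bad, collapse = ", "))
  structure(list(states = states[, c(predictors, features), drop = FALSE],
                 predictors = predictors, features = features),
            class = "paired_table")
}

#' @export
print.paired_table <- function(x, ...) {
  cat(sprintf("Paired table: %d rows\n  predictors (t-1): %s\n  features (t): %s\n",
              nrow(x$states), paste(x$predictors, collapse = " "),
              paste(x$features, collapse = " ")))
  invisible(x)
}

#' Pair t-1 predictor states with t feature states
#'
#' Builds one row per scored update per lifetime, joining the requested
#' predictor nodes (inputs and memory-before at t-1) with the requested
#' feature nodes (outputs, memory-after, world features at t).  Pairing
#' never crosses lifetime boundaries.  Memory ids given as features are
#' resolved to the after-update view and appear in the result under the
#' `_next`-suffixed column name.
#'
#' @param rec a [state_recording].
#' @param predictors node ids among inputs and memory.
#' @param features node ids among outputs, world features and memory
#'   (resolved to memory-after).
#' @return A [paired_table].
#' @export
pair_states <- function(rec, predictors, features) {
  if (nrow(rec$data) == 0L) stop("empty recording")
  g <- rec$groups
  pred_ok <- c(g$input, g$memory)
  bad <- setdiff(predictors, pred_ok)
  if (length(bad) > 0L)
    stop("predictor id(s) not among inputs/memory: ",
         paste(bad, collapse = ", "))
  feat_cols <- vapply(features, function(f) {
    if (f %in% c(g$output, g$world)) f
    else if (f %in% g$memory) paste0(f, "_next")
    else if (f %in% paste0(g$memory, "_next")) f
    else stop("feature id not among outputs/world/memory: ", f)
  }, character(1))
  if (length(predictors) == 0L || length(features) == 0L)
    stop("predictors and features must be non-empty")
  cols <- c(predictors, unname(feat_cols))
  if (anyDuplicated(cols)) stop("duplicated column selection")
  paired_table(rec$data, predictors, unname(feat_cols))
}

#' Maximum-likelihood probabilities of joint states
#'
#' Projects the table onto `subset` and counts unique joint states; the
#' returned probabilities are the maximum-likelihood estimators of the true
#' joint distribution (counts divided by the number of rows).
#'
#' @param table a [paired_table].
#' @param subset non-empty character vector of node ids.
#' @return An object of class `prob_table`: a named numeric vector of
#'   probabilities (names are comma-joined joint states, ordered by
#'   decreasing probability, ties by name), with attributes `counts` and
#'   `n` (support size).
#' @export
estimate_probabilities <- function(table, subset) {
  subset <- .resolve_cols(table, subset)
  if (nrow(table$states) == 0L) stop("empty table")
  key <- do.call(paste, c(table$states[unique(subset)], sep = ","))
  counts <- table(key)
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  p <- as.numeric(counts) / sum(counts)
  names(p) <- names(counts)
  structure(p, counts = as.integer(counts), n = length(p),
            class = "prob_table")
}

#' @export
print.prob_table <- function(x, ...) {
  cat(sprintf("Probability table over %d observed joint state(s):\n",
              attr(x, "n")))
  print(round(unclass(x), 6))
  invisible(x)
}
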