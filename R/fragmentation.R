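## Power-set search for distinct informative sets (DISs), fragmentation
## values and fragmentation matrices.
##
## A DIS for a feature Y, at threshold theta, is an irreducible subset S of
## the predictor pool with I(S;Y) >= theta * H(Y): irreducible means S is
## not a proper superset of another qualifying set.  The fragmentation
## F_theta(X;Y) is the size of the smallest DIS, or -1 when even the full
## pool fails the threshold.  Subsets are enumerated smallest-first, so the
## search can prune supersets as soon as a qualifying set is found.
##
## Subsets are represented internally as bitmasks over pool indices, which
## keeps superset pruning to a single bitwAnd.

.DEFAULT_POOL_CAP <- 16L

## All non-empty subset bitmasks of m elements, size-ascending and
## lexicographic (by index tuple) within size.  combn() enumerates index
## tuples in exactly that order.
.subset_masks <- function(m) {
  masks <- integer(0)
  for (s in seq_len(m)) {
    idx <- utils::combn(m, s)
    masks <- c(masks, as.integer(colSums(matrix(2^(idx - 1L), nrow = s))))
  }
  masks
}

.mask_ids <- function(mask, pool) pool[bitwAnd(mask, 2^(seq_along(pool) - 1L)) != 0L]

.mask_size <- function(mask) {
  s <- 0L
  while (mask > 0L) {
    s <- s + bitwAnd(mask, 1L)
    mask <- bitwShiftR(mask, 1L)
  }
  s
}

.check_pool <- function(pool, cap) {
  if (length(pool) == 0L) stop("predictor pool must be non-empty")
  if (anyDuplicated(pool)) stop("predictor pool contains duplicates")
  if (length(pool) > cap)
    stop("pool has ", length(pool), " nodes (> cap ", cap, "): exhaustive ",
         "power-set search is exponential; raise 'cap' explicitly to force it")
}

#' Enumerate all non-empty subsets of a predictor pool
#'
#' Yields all `2^m - 1` non-empty subsets ordered by size, then
#' lexicographically within size (in the order the pool is given).  This is
#' the canonical column order of fragmentation matrices, which makes
#' "the first qualifying column" a deterministic lookup.
#'
#' @param pool character vector of node ids.
#' @param cap refuse pools larger than this (default 16, i.e. 65535
#'   subsets); the power set grows as `2^m`.
#' @return A list of character vectors.
#' @export
iter_subsets <- function(pool, cap = .DEFAULT_POOL_CAP) {
  .check_pool(pool, cap)
  lapply(.subset_masks(length(pool)), .mask_ids, pool = pool)
}

#' Canonical label of a node set
#' @param ids character vector of node ids.
#' @return Single string, ids joined by `+` (e.g. `"m1+m7"`).
#' @export
subset_label <- function(ids) paste(ids, collapse = "+")

## Precompute per-column integer codes for the pool and a feature, so the
## subset scan can build joint codes by mixed radix without re-interning.
.pool_codes <- function(table, pool) {
  lapply(table$states[pool], .col_codes)
}

.mask_joint_code <- function(codes, mask) {
  code <- 0
  for (i in seq_along(codes)) {
    if (bitwAnd(mask, bitwShiftL(1L, i - 1L)) != 0L)
      code <- code * codes[[i]]$k + codes[[i]]$code
  }
  code
}

#' Find all distinct informative sets for a feature
#'
#' Enumerates subsets of the pool smallest-first, keeping every subset `S`
#' with `I(S;Y) >= theta * H(Y) - 1e-9` that is not a proper superset of a
#' previously accepted set.  Features with zero entropy are trivially
#' predicted and return an empty collection flagged as such.
#'
#' @param table a [paired_table].
#' @param pool character vector of predictor node ids.
#' @param feature single feature node id.
#' @param theta proportion of the feature entropy to explain, in `[0, 1]`;
#'   `theta = 1` demands perfect prediction.
#' @param cap pool-size cap (see [iter_subsets()]).
#' @return An object of class `dis_collection`: list with `feature`,
#'   `theta`, `sets` (list of character vectors), `minimal_size` (or -1
#'   when no set qualifies), `h_feature`, and `trivially_predicted`.
#' @export
find_dis <- function(table, pool, feature, theta = 1, cap = .DEFAULT_POOL_CAP) {
  .check_pool(pool, cap)
  stopifnot(length(feature) == 1L)
  .resolve_cols(table, feature, "feature")
  if (is.numeric(theta) && length(theta) == 1L && theta >= 0 && theta <= 1) {
  } else stop("'theta' must be a single number in [0, 1]")

  hy <- joint_entropy(table, feature)
  res <- structure(list(feature = feature, theta = theta, sets = list(),
                        minimal_size = -1L, h_feature = hy,
                        trivially_predicted = FALSE),
                   class = "dis_collection")
  if (hy <= .TOL) {
    res$trivially_predicted <- TRUE
    return(res)
  }
  codes <- .pool_codes(table, pool)
  ycode <- .col_codes(table$states[[feature]])
  need <- theta * hy - .TOL
  found <- integer(0)
  for (mask in .subset_masks(length(pool))) {
    if (length(found) > 0L && any(bitwAnd(mask, found) == found)) next
    scode <- .mask_joint_code(codes, mask)
    hs <- .entropy_of_codes(scode)
    hsy <- .entropy_of_codes(scode * ycode$k + ycode$code)
    if (hs + hy - hsy >= need) {
      found <- c(found, mask)
      res$sets <- c(res$sets, list(.mask_ids(mask, pool)))
    }
  }
  if (length(found) > 0L)
    res$minimal_size <- min(vapply(res$sets, length, integer(1)))
  res
}

#' @export
print.dis_collection <- function(x, ...) {
  cat(sprintf("Distinct informative sets for '%s' (theta = %g, H = %.4g bits)\n",
              x$feature, x$theta, x$h_feature))
  if (x$trivially_predicted) {
    cat("  feature has zero entropy: trivially predicted, no DIS\n")
  } else if (length(x$sets) == 0L) {
    cat("  no qualifying set (fragmentation sentinel -1)\n")
  } else {
    for (s in x$sets) cat("  {", subset_label(s), "}\n", sep = "")
    cat(sprintf("  minimal size: %d\n", x$minimal_size))
  }
  invisible(x)
}

#' Fragmentation of a feature
#'
#' The size of the smallest subset of the pool whose mutual information
#' with the feature reaches `theta * H(Y)`; `-1` when no subset (including
#' the full pool) qualifies, and `0` for a zero-entropy (trivially
#' predicted) feature.  The search stops at the first qualifying size.
#'
#' @inheritParams find_dis
#' @return Integer fragmentation value.
#' @export
fragmentation_value <- function(table, pool, feature, theta = 1,
                                cap = .DEFAULT_POOL_CAP) {
  .check_pool(pool, cap)
  .resolve_cols(table, feature, "feature")
  hy <- joint_entropy(table, feature)
  if (hy <= .TOL) return(0L)
  codes <- .pool_codes(table, pool)
  ycode <- .col_codes(table$states[[feature]])
  need <- theta * hy - .TOL
  m <- length(pool)
  for (s in seq_len(m)) {
    for (idx in as.data.frame(utils::combn(m, s))) {
      mask <- sum(bitwShiftL(1L, idx - 1L))
      scode <- .mask_joint_code(codes, mask)
      hs <- .entropy_of_codes(scode)
      hsy <- .entropy_of_codes(scode * ycode$k + ycode$code)
      if (hs + hy - hsy >= need) return(s)
    }
  }
  -1L
}

#' Information fragmentation matrix
#'
#' Shared entropy between every non-empty subset of the predictor pool
#' (columns, ordered size-then-lexicographic) and every feature (rows),
#' both as raw bits and normalized by the feature entropy.  Zero-entropy
#' features are flagged trivially predicted and their normalized row is
#' defined as 1.
#'
#' @param table a [paired_table].
#' @param pool character vector of predictor node ids.
#' @param features feature node ids (default: all features of the table).
#' @param cap pool-size cap (see [iter_subsets()]).
#' @return An object of class `fragmentation_matrix`: list with `bits` and
#'   `norm` (features x subsets matrices), `h_features`, `labels`, `masks`,
#'   `pool`, `features`, `n_obs` and `trivially_predicted`.
#' @export
fragmentation_matrix <- function(table, pool, features = NULL,
                                 cap = .DEFAULT_POOL_CAP) {
  .check_pool(pool, cap)
  if (is.null(features)) features <- table$features
  for (f in features) .resolve_cols(table, f, "features")
  masks <- .subset_masks(length(pool))
  labels <- vapply(masks, function(m) subset_label(.mask_ids(m, pool)),
                   character(1))
  codes <- .pool_codes(table, pool)
  ycodes <- lapply(table$states[features], .col_codes)
  hy <- vapply(features, function(f) joint_entropy(table, f), numeric(1))
  hy_feat <- vapply(ycodes, function(yc) .entropy_of_codes(yc$code), numeric(1))

  bits <- matrix(0, nrow = length(features), ncol = length(masks),
                 dimnames = list(features, labels))
  for (j in seq_along(masks)) {
    scode <- .mask_joint_code(codes, masks[j])
    hs <- .entropy_of_codes(scode)
    for (i in seq_along(features)) {
      yc <- ycodes[[i]]
      hsy <- .entropy_of_codes(scode * yc$k + yc$code)
      bits[i, j] <- max(hs + hy_feat[i] - hsy, 0)
    }
  }
  trivial <- hy <= .TOL
  norm <- bits
  for (i in seq_along(features))
    norm[i, ] <- if (trivial[i]) 1 else pmin(bits[i, ] / hy[i], 1)
  structure(list(bits = bits, norm = norm, h_features = hy, labels = labels,
                 masks = masks, pool = pool, features = features,
                 n_obs = nrow(table$states),
                 trivially_predicted = trivial),
            class = "fragmentation_matrix")
}

#' @export
print.fragmentation_matrix <- function(x, ...) {
  cat(sprintf("Fragmentation matrix: %d feature(s) x %d predictor subsets (pool: %s)\n",
              length(x$features), length(x$labels),
              paste(x$pool, collapse = " ")))
  cat(sprintf("  estimated from %d pooled state observations\n", x$n_obs))
  full <- x$norm[, ncol(x$norm)]
  for (i in seq_along(x$features))
    cat(sprintf("  %s: H = %.4g bits, full-pool prediction = %.3f%s\n",
                x$features[i], x$h_features[i], full[i],
                if (x$trivially_predicted[i]) " (trivially predicted)" else ""))
  invisible(x)
}

#' @export
summary.fragmentation_matrix <- function(object, theta = 1, ...) {
  frag <- vapply(object$features, function(f)
    fragmentation_from_matrix(object, f, theta), integer(1))
  data.frame(feature = object$features,
             entropy = unname(object$h_features),
             fragmentation = unname(frag),
             full_pool = unname(object$norm[, ncol(object$norm)]),
             row.names = NULL)
}

#' @export
as.matrix.fragmentation_matrix <- function(x, normalized = TRUE, ...) {
  if (normalized) x$norm else x$bits
}

#' Grayscale image of a fragmentation matrix
#'
#' Features on the y axis, predictor subsets (size-ascending) on the x
#' axis; white cells indicate perfect prediction.
#'
#' @param x a [fragmentation_matrix].
#' @param ... passed on to [graphics::image()].
#' @export
plot.fragmentation_matrix <- function(x, ...) {
  z <- t(x$norm[rev(seq_len(nrow(x$norm))), , drop = FALSE])
  graphics::image(z = z, x = seq_len(ncol(x$norm)), y = seq_len(nrow(x$norm)),
                  col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = "predictor subsets (size-ascending)", ylab = "",
                  yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(x$norm)), labels = rev(x$features),
                 las = 1)
  invisible(x)
}

#' Fragmentation looked up from a matrix
#'
#' Scans the feature's row for the first column (in the canonical
#' size-then-lexicographic order) whose shared entropy reaches
#' `theta * H(Y)` and returns that column's subset size; `-1` when no
#' column qualifies, `0` for trivially predicted features.  Consistent with
#' [fragmentation_value()] on the same inputs.
#'
#' @param fm a [fragmentation_matrix].
#' @param feature feature id present in the matrix.
#' @param theta proportion in `[0, 1]`.
#' @return Integer fragmentation value.
#' @export
fragmentation_from_matrix <- function(fm, feature, theta = 1) {
  i <- match(feature, fm$features)
  if (is.na(i)) stop("feature not in matrix: ", feature)
  if (fm$trivially_predicted[i]) return(0L)
  need <- theta * fm$h_features[i] - .TOL
  j <- which(fm$bits[i, ] >= need)
  if (length(j) == 0L) return(-1L)
  .mask_size(fm$masks[j[1]])
}

#' Export a fragmentation matrix
#'
#' Writes the normalized matrix as TSV (rows = features, columns = canonical
#' subset labels such as `m1+m7`) and/or a JSON dump carrying raw bits,
#' normalized values, feature entropies and, optionally, DIS annotations.
#'
#' @param fm a [fragmentation_matrix].
#' @param tsv,json output paths (either may be `NULL`).
#' @param dis optional named list of [find_dis()] results to embed in the
#'   JSON export.
#' @export
write_fragmentation_matrix <- function(fm, tsv = NULL, json = NULL,
                                       dis = NULL) {
  if (!is.null(tsv)) {
    d <- data.frame(feature = fm$features, fm$norm, check.names = FALSE)
    utils::write.table(d, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json)) {
    obj <- list(pool = fm$pool, features = fm$features, labels = fm$labels,
                entropies = as.list(fm$h_features),
                bits = apply(fm$bits, 1, identity, simplify = FALSE),
                normalized = apply(fm$norm, 1, identity, simplify = FALSE),
                trivially_predicted = as.list(
                  stats::setNames(fm$trivially_predicted, fm$features)))
    if (!is.null(dis))
      obj$dis <- lapply(dis, function(d)
        list(feature = d$feature, theta = d$theta, sets = d$sets,
             minimal_size = d$minimal_size))
    jsonlite::write_json(obj, json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(fm)
}
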