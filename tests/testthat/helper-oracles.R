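# Independent brute-force oracles: literal inclusion-exclusion over
# enumerated joint states via paste()/table(), and an exhaustive
# filter-by-definition DIS search.  Deliberately a different code path from
# the package's mixed-radix/bitmask implementation.

oracle_entropy <- function(df, cols) {
  key <- do.call(paste, c(df[cols], sep = "\r"))
  p <- as.numeric(table(key))
  p <- p / sum(p)
  -sum(p * log2(p))
}

oracle_mi <- function(df, A, B) {
  oracle_entropy(df, A) + oracle_entropy(df, B) -
    oracle_entropy(df, unique(c(A, B)))
}

oracle_coinfo <- function(df, A, B, C) {
  oracle_mi(df, A, C) + oracle_mi(df, B, C) -
    oracle_mi(df, unique(c(A, B)), C)
}

# All qualifying subsets, then drop every proper superset of another
# qualifying set.
oracle_dis <- function(df, pool, feature, theta) {
  hy <- oracle_entropy(df, feature)
  subsets <- unlist(lapply(seq_along(pool), function(s)
    utils::combn(pool, s, simplify = FALSE)), recursive = FALSE)
  qual <- Filter(function(s)
    oracle_mi(df, s, feature) >= theta * hy - 1e-9, subsets)
  Filter(function(s) !any(vapply(qual, function(q)
    length(q) < length(s) && all(q %in% s), logical(1))), qual)
}

oracle_fragmentation <- function(df, pool, feature, theta) {
  hy <- oracle_entropy(df, feature)
  if (hy <= 1e-9) return(0L)
  d <- oracle_dis(df, pool, feature, theta)
  if (length(d) == 0L) -1L else min(vapply(d, length, integer(1)))
}

# Random binary paired table (sampled rows; arbitrary dependence structure
# induced by mixing copies, noise and XORs of earlier columns).
random_paired_table <- function(n_nodes, n_rows) {
  P <- matrix(sample(0:1, n_nodes * n_rows, replace = TRUE), nrow = n_rows)
  for (j in seq_len(n_nodes)[-1]) {
    mode <- sample(3, 1)
    if (mode == 1L) P[, j] <- P[, j - 1L]                       # copy
    if (mode == 2L) P[, j] <- bitwXor(P[, j], P[, sample(j - 1L, 1L)])
  }
  colnames(P) <- paste0("p", seq_len(n_nodes))
  d <- as.data.frame(P)
  d$y <- bitwXor(P[, sample(n_nodes, 1)], sample(0:1, n_rows, TRUE,
                                                 prob = c(0.8, 0.2)))
  paired_table(d, predictors = colnames(P), features = "y")
}

# Canonical sorted representation of a DIS collection for exact comparison.
canon_sets <- function(sets) {
  s <- lapply(sets, sort)
  s[order(vapply(s, length, integer(1)),
          vapply(s, paste, character(1), collapse = "+"))]
}
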