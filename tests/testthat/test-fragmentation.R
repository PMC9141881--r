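test_that("subset enumeration is size-ascending, lexicographic and complete", {
  s3 <- iter_subsets(c("a", "b", "c"))
  expect_equal(s3, list("a", "b", "c", c("a", "b"), c("a", "c"),
                        c("b", "c"), c("a", "b", "c")))
  expect_length(iter_subsets(paste0("m", 1:8)), 255)
  # a 13-node pool: 2^13 subsets counting the empty set
  expect_length(iter_subsets(paste0("n", 1:13)), 2^13 - 1)
  expect_error(iter_subsets(paste0("x", 1:17)), "cap")
  expect_length(iter_subsets(paste0("x", 1:17), cap = 17), 2^17 - 1)
})

test_that("DIS search finds copies, pairs, and prunes supersets", {
  set.seed(5)
  # copy: a single-node DIS
  cp <- make_random_table(4, 60, "copy")
  d <- find_dis(cp, cp$predictors, "y", theta = 1)
  expect_equal(d$sets, list("p1"))
  expect_equal(d$minimal_size, 1)
  expect_equal(fragmentation_value(cp, cp$predictors, "y", 1), 1L)

  # XOR pair: neither singleton qualifies
  par2 <- make_random_table(4, 64, "parity", k = 2)
  d2 <- find_dis(par2, par2$predictors, "y", theta = 1)
  expect_equal(d2$sets, list(c("p1", "p2")))
  expect_equal(mutual_information(par2, "p1", "y"), 0)
  expect_equal(mutual_information(par2, "p2", "y"), 0)
  expect_equal(fragmentation_value(par2, par2$predictors, "y", 1), 2L)

  # {A,B} and {A,C} both qualify; {A,B,C} is pruned as a superset
  d3 <- data.frame(A = c(0, 0, 1, 1), B = c(0, 1, 0, 1))
  d3$C <- d3$B
  d3$y <- bitwXor(d3$A, d3$B)
  t3 <- paired_table(d3, c("A", "B", "C"), "y")
  dd <- find_dis(t3, c("A", "B", "C"), "y", theta = 1)
  expect_equal(canon_sets(dd$sets),
               canon_sets(list(c("A", "B"), c("A", "C"))))
})

test_that("fragmentation sentinel and boundary thetas behave as defined", {
  set.seed(6)
  ind <- make_random_table(3, 40, "independent")
  expect_equal(fragmentation_value(ind, ind$predictors, "y", 1), -1L)
  d <- find_dis(ind, ind$predictors, "y", theta = 1)
  expect_length(d$sets, 0)
  expect_equal(d$minimal_size, -1L)
  # theta = 0: any singleton satisfies I >= 0
  expect_equal(fragmentation_value(ind, ind$predictors, "y", 0), 1L)
  # zero-entropy feature: trivially predicted
  z <- paired_table(data.frame(p1 = c(0, 1, 0, 1), y = 0),
                    "p1", "y")
  expect_equal(fragmentation_value(z, "p1", "y", 1), 0L)
  expect_true(find_dis(z, "p1", "y", 1)$trivially_predicted)
})

test_that("fragmentation matrices have canonical shape and full-pool column", {
  set.seed(8)
  b <- make_copy_chain()
  rec <- run_nback(b, seed = 21)$recording
  tab <- pair_states(rec, paste0("m", 1:8), paste0("o", 1:5))
  fm <- fragmentation_matrix(tab, paste0("m", 1:8))
  expect_equal(dim(fm$bits), c(5, 255))
  expect_equal(colnames(fm$bits)[1], "m1")
  expect_equal(colnames(fm$bits)[255], subset_label(paste0("m", 1:8)))
  # a perfect brain: the full-pool column predicts every output perfectly
  expect_equal(unname(fm$norm[, 255]), rep(1, 5), tolerance = 1e-9)
  # all features of the copy chain have fragmentation 1
  for (o in paste0("o", 1:5))
    expect_equal(fragmentation_from_matrix(fm, o, 1), 1L)
  expect_error(fragmentation_from_matrix(fm, "o9", 1), "not in matrix")
})

test_that("matrix cells are monotone along nested subset chains", {
  set.seed(9)
  tab <- random_paired_table(4, 50)
  fm <- fragmentation_matrix(tab, tab$predictors)
  masks <- fm$masks
  for (j in seq_along(masks)) for (l in seq_along(masks)) {
    if (j != l && bitwAnd(masks[j], masks[l]) == masks[j]) {
      expect_gte(fm$bits["y", l], fm$bits["y", j] - 1e-9)
    }
  }
})

test_that("matrix lookup agrees with direct search for all thetas", {
  set.seed(10)
  for (i in 1:5) {
    tab <- random_paired_table(sample(3:5, 1), 40)
    fm <- fragmentation_matrix(tab, tab$predictors)
    for (theta in c(0, 0.25, 0.5, 0.8, 1)) {
      expect_equal(fragmentation_from_matrix(fm, "y", theta),
                   fragmentation_value(tab, tab$predictors, "y", theta))
    }
  }
})

test_that("DIS collections match the exhaustive brute-force filter", {
  set.seed(12)
  for (i in 1:20) {
    tab <- random_paired_table(sample(3:6, 1), sample(c(16, 32, 64), 1))
    theta <- sample(c(0.5, 0.9, 1), 1)
    d <- find_dis(tab, tab$predictors, "y", theta = theta)
    expect_equal(canon_sets(d$sets),
                 canon_sets(oracle_dis(tab$states, tab$predictors, "y",
                                       theta)))
    expect_equal(fragmentation_value(tab, tab$predictors, "y", theta),
                 oracle_fragmentation(tab$states, tab$predictors, "y",
                                      theta))
  }
})

test_that("planted k-parity is recovered with strict subsets at zero bits", {
  set.seed(14)
  for (k in 2:4) {
    tab <- make_random_table(5, 64, "parity", k = k)
    expect_equal(fragmentation_value(tab, tab$predictors, "y", 1), k)
    d <- find_dis(tab, tab$predictors, "y", theta = 1)
    expect_true(any(vapply(canon_sets(d$sets), identical, logical(1),
                           paste0("p", seq_len(k)))))
    for (drop in seq_len(k)) {
      strict <- paste0("p", setdiff(seq_len(k), drop))
      expect_equal(mutual_information(tab, strict, "y"), 0)
    }
  }
})

test_that("matrix export writes TSV and JSON faithfully", {
  set.seed(15)
  tab <- make_random_table(3, 32, "parity", k = 2)
  fm <- fragmentation_matrix(tab, tab$predictors)
  tsv <- tempfile(fileext = ".tsv"); json <- tempfile(fileext = ".json")
  write_fragmentation_matrix(fm, tsv = tsv, json = json,
                             dis = list(y = find_dis(tab, tab$predictors,
                                                     "y", 1)))
  back <- utils::read.table(tsv, header = TRUE, sep = "\t",
                            check.names = FALSE)
  expect_equal(back$feature, "y")
  expect_equal(as.numeric(back[1, -1]), unname(fm$norm[1, ]),
               tolerance = 1e-12)
  j <- jsonlite::read_json(json)
  expect_equal(unlist(j$dis$y$sets[[1]]), c("p1", "p2"))
  expect_equal(j$entropies$y, unname(fm$h_features["y"]))
  unlink(c(tsv, json))
})
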