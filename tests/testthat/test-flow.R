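test_that("copy-chain flow is a set of linear chains with unit labels", {
  b <- make_copy_chain()
  rec <- run_nback(b, seed = 17)$recording
  fg <- build_flow_graph(rec, theta = 1)
  # every target has exactly one single-node DIS: in-degree 1, label 1
  indeg <- table(fg$edges$to)
  expect_true(all(indeg == 1))
  expect_true(all(fg$edges$necessity == "necessary"))
  expect_equal(fg$edges$label, rep(1, nrow(fg$edges)), tolerance = 1e-9)
  # 8 memory writes (i1->m1->...->m8) + 5 output taps
  expect_equal(flow_complexity(fg), 13)
  expect_length(fg$unexplained, 0)
  # in-degree equals the fragmentation value for single-DIS targets
  for (target in names(fg$dis))
    expect_equal(sum(fg$edges$to == target),
                 fg$dis[[target]]$minimal_size)
})

test_that("the XOR-delay circuit yields encrypted zero-label edges", {
  b <- make_xor_delay()
  res <- run_nback(b, seed = 19)
  fg <- build_flow_graph(res$recording, theta = 1)
  e_o5 <- fg$edges[fg$edges$to == "o5", ]
  expect_setequal(e_o5$from, c("m2", "m7"))
  expect_true(all(e_o5$necessity == "necessary"))
  # each arrow alone conveys (essentially) no information: labels ~ 0
  expect_true(all(e_o5$label < 0.01))
  # m7 is predicted by {m2, m6}; m2 by m6 alone
  expect_setequal(fg$edges$from[fg$edges$to == "m7"], c("m2", "m6"))
  expect_equal(fg$edges$from[fg$edges$to == "m2"], "m6")
  # zero-entropy memory nodes are not shown
  expect_false(any(c("m1", "m3", "m4", "m5", "m8") %in% fg$nodes$id))
  # replay: o5(t) = x(t-3) on every scored update of every lifetime
  d <- res$recording$data
  for (lt in unique(d$lifetime)) {
    rows <- d[d$lifetime == lt, ]
    u <- rows$update
    for (i in seq_along(u)) {
      j <- match(u[i] - 3L, u)
      if (!is.na(j)) expect_equal(rows$o5[i], rows$i1[j])
    }
  }
})

test_that("redundant predictive sets are split into necessary and possible edges", {
  # feature y = A XOR B with C mirroring B: two DISs {A,B} and {A,C};
  # A is in both (necessary), B and C in one each (possible)
  d <- expand.grid(A = 0:1, B = 0:1)
  d <- d[rep(seq_len(4), 4), ]
  d$C <- d$B
  d$y <- bitwXor(d$A, d$B)
  # wrap as a recording so build_flow_graph accepts it
  rec <- state_recording(
    data.frame(lifetime = 1, update = seq_len(nrow(d)),
               i1 = d$A, i2 = d$B, i3 = d$C, o1 = d$y,
               m1 = 0L, m1_next = 0L),
    inputs = c("i1", "i2", "i3"), outputs = "o1", memory = "m1")
  fg <- build_flow_graph(rec, theta = 1)
  e <- fg$edges[fg$edges$to == "o1", ]
  expect_equal(e$necessity[e$from == "i1"], "necessary")
  expect_setequal(e$from[e$necessity == "possible"], c("i2", "i3"))

  # a connectome that only wires {i1, i2} -> o1 resolves the redundancy
  conn <- data.frame(from = c("i1", "i2"), to = "o1")
  fg2 <- disambiguate(fg, conn)
  e2 <- fg2$edges[fg2$edges$to == "o1", ]
  expect_setequal(e2$from, c("i1", "i2"))
  expect_true(all(e2$necessity == "necessary"))
  expect_equal(length(fg2$dis$o1$sets), 1L)

  # a connectome wiring both candidate sets cannot resolve it
  conn_both <- data.frame(from = c("i1", "i2", "i1", "i3"), to = "o1")
  fg3 <- disambiguate(fg, conn_both)
  expect_setequal(fg3$edges$from[fg3$edges$necessity == "possible"],
                  c("i2", "i3"))
})

test_that("disambiguation leaves single-DIS targets untouched", {
  b <- make_xor_delay()
  rec <- run_nback(b, seed = 23)$recording
  fg <- build_flow_graph(rec)
  fg2 <- disambiguate(fg, connectome_of(b))
  expect_equal(fg2$edges[order(fg2$edges$to, fg2$edges$from), ],
               fg$edges[order(fg$edges$to, fg$edges$from), ],
               ignore_attr = TRUE)
  expect_equal(flow_complexity(fg2), flow_complexity(fg))
})

test_that("flow graphs export to DOT and round-trip through GraphML", {
  b <- make_copy_chain()
  rec <- run_nback(b, seed = 29)$recording
  fg <- build_flow_graph(rec)
  dot <- tempfile(fileext = ".dot")
  export_graph(fg, dot, "dot")
  lines <- readLines(dot)
  expect_length(grep(" -> ", lines), flow_complexity(fg))
  expect_length(grep("color=red", lines), 0)

  gml <- tempfile(fileext = ".graphml")
  export_graph(fg, gml, "graphml")
  back <- read_flow_graphml(gml)
  expect_setequal(back$nodes$id, unique(fg$nodes$id))
  key <- function(e) paste(e$from, e$to, e$necessity,
                           round(e$label, 9))
  expect_setequal(key(back$edges), key(fg$edges))
  expect_equal(flow_complexity(back), flow_complexity(fg))

  json <- tempfile(fileext = ".json")
  write_dis_json(fg, json)
  j <- jsonlite::read_json(json)
  expect_equal(unlist(j$o1$sets[[1]]), "m1")
  expect_error(export_graph(fg, tempfile(), "svg"))
  unlink(c(dot, gml, json))
})

test_that("an empty flow graph has zero complexity", {
  fg <- structure(list(nodes = data.frame(), edges = data.frame(),
                       dis = list(), unexplained = character(0), theta = 1),
                  class = "flow_graph")
  expect_equal(flow_complexity(fg), 0)
})
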