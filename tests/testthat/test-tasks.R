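test_that("the shift-register brain solves n-Back perfectly on every seed", {
  b <- make_copy_chain()
  for (seed in c(1, 99, 2024)) {
    res <- run_nback(b, seed = seed, record = FALSE)
    expect_equal(res$fitness, 1.0)
  }
  res <- run_nback(b, seed = 5)
  # 25 lifetimes x 25 scored updates pooled
  expect_equal(nrow(res$recording$data), 625)
  expect_equal(min(res$recording$data$update), 9)   # warm-up excluded
  expect_equal(max(res$recording$data$update), 33)
})

test_that("n-Back evaluation is deterministic and layout-checked", {
  set.seed(41)
  b <- decode_markov_brain(seed_start_codons(random_genome(5000)),
                           nback_layout())
  r1 <- run_nback(b, seed = 7)
  r2 <- run_nback(b, seed = 7)
  expect_identical(r1$fitness, r2$fitness)
  expect_identical(r1$recording$data, r2$recording$data)
  wrong <- markov_brain(list(), brain_layout(2, 2, 8))
  expect_error(run_nback(wrong), "layout")
  expect_error(run_blockcatch(wrong), "layout")
})

test_that("compiled and interpreted task loops agree bit-exactly", {
  set.seed(43)
  for (i in 1:3) {
    g <- seed_start_codons(random_genome(4000))
    bn <- decode_markov_brain(g, nback_layout())
    # wrap the same brain as a stub to force the interpreted path
    stub_n <- stub_brain(function(t0) markov_update(bn, t0), bn$layout)
    rc <- run_nback(bn, seed = 100 + i)
    rs <- run_nback(stub_n, seed = 100 + i)
    expect_equal(rc$fitness, rs$fitness)
    expect_identical(rc$recording$data, rs$recording$data)

    bb <- decode_markov_brain(g, blockcatch_layout())
    stub_b <- stub_brain(function(t0) markov_update(bb, t0), bb$layout)
    rc2 <- run_blockcatch(bb)
    rs2 <- run_blockcatch(stub_b)
    expect_equal(rc2$fitness, rs2$fitness)
    expect_equal(as.integer(rc2$life_correct), as.integer(rs2$life_correct))
    expect_identical(rc2$recording$data, rs2$recording$data)
  }
  # the RNN substrate too
  set.seed(47)
  g <- random_genome(500)
  rn <- decode_rnn(g, blockcatch_layout())
  stub_r <- stub_brain(function(t0) rnn_update(rn, t0), rn$layout)
  expect_identical(run_blockcatch(rn)$recording$data,
                   run_blockcatch(stub_r)$recording$data)
})

test_that("Block Catch runs all 120 conditions for 31 updates", {
  b <- markov_brain(list(), blockcatch_layout())   # motionless agent
  res <- run_blockcatch(b)
  expect_equal(n_lifetimes(res$recording), 120)
  expect_equal(nrow(res$recording$data), 120 * 31)
  expect_length(res$life_correct, 120)
  expect_gte(res$fitness, 0); expect_lte(res$fitness, 1)
})

test_that("a motionless agent's catches follow hand-simulated geometry", {
  b <- markov_brain(list(), blockcatch_layout())   # outputs stay (0,0)
  res <- run_blockcatch(b)
  # hand geometry: paddle fixed at columns 0..5; a block of size s starting
  # at column c moving right lands at (c + 31) mod 20 and is caught iff its
  # span intersects 0..5
  lt <- 0
  for (size in c(2, 3, 4)) for (dir in c(-1, 1)) for (start in 0:19) {
    lt <- lt + 1
    land <- (start + dir * 31) %% 20
    caught <- any(((land + seq_len(size) - 1) %% 20) %in% 0:5)
    should <- (size == 2) || (size == 3 && dir == 1)
    expect_equal(as.integer(res$life_correct[lt]),
                 as.integer(caught == should))
  }
})

test_that("world features encode the catch rule and block identity", {
  b <- markov_brain(list(), blockcatch_layout())
  res <- run_blockcatch(b)
  w <- world_features(res)
  expect_equal(names(w), world_feature_names())
  # size 1 is a never-used control: constant zero, zero entropy
  expect_true(all(w$size1 == 0))
  d <- res$recording$data
  # lifetime order: (size 2, 3, 4) x (left, right) x 20 starts
  # size-3 right-moving blocks (lifetimes 61..80) are to be caught
  expect_true(all(w$catch[d$lifetime %in% 61:80] == 1))
  expect_true(all(w$size3[d$lifetime %in% 41:80] == 1))
  expect_true(all(w$left[d$lifetime %in% 41:60] == 1))
  # size-4 blocks (81..120) are to be avoided in either direction
  expect_true(all(w$catch[d$lifetime %in% 81:120] == 0))
  # each lifetime appears 31 times with constant world state
  expect_true(all(table(d$lifetime) == 31))
  # pooled feature entropies: catch is 1 for 3 of 6 block types
  tab <- pair_states(res$recording, paste0("m", 1:8), "catch")
  expect_equal(joint_entropy(tab, "catch"), 1.0)
})

test_that("a late-life sensor active in 1 of 6 block types has 0.65 bits", {
  # scripted-behavior stub recording: sensor i3 on for exactly one of the
  # six equally frequent block types during late life, other sensors off
  types <- rep(1:6, each = 20)
  d <- data.frame(lifetime = seq_along(types), update = 1,
                  i1 = 0L, i2 = 0L, i3 = as.integer(types == 4), i4 = 0L,
                  o1 = 0L, o2 = 0L, m1 = 0L, m1_next = 0L)
  rec <- state_recording(d, inputs = paste0("i", 1:4),
                         outputs = c("o1", "o2"), memory = "m1")
  tab <- pair_states(rec, paste0("i", 1:4), "o1")
  expect_equal(round(joint_entropy(tab, "i3"), 2), 0.65)
  for (s in c("i1", "i2", "i4"))
    expect_equal(joint_entropy(tab, s), 0)
})
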