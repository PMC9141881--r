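test_that("point mutation hits the expected number of sites", {
  cfg <- evolution_config(point_rate = 5e-3, indel_rate = 0)
  g <- rep(100L, 5000)
  set.seed(51)
  n_rep <- 2000
  changed <- vapply(seq_len(n_rep), function(i)
    sum(mutate_genome(g, cfg) != g), numeric(1))
  # expected hits 25/offspring; observed changes 25 * 255/256 (a
  # randomized site may redraw its own value)
  expected <- 5000 * 5e-3 * 255 / 256
  se <- sqrt(5000 * 5e-3 * (1 - 5e-3)) / sqrt(n_rep)
  expect_lt(abs(mean(changed) - expected), 4 * se)
  # zero rates: identity
  expect_identical(mutate_genome(g, evolution_config(point_rate = 0,
                                                     indel_rate = 0)), g)
})

test_that("segmental mutations respect genome length bounds", {
  set.seed(53)
  cfg <- evolution_config(point_rate = 0, indel_rate = 5e-4)
  g <- rep(1L, 2000)
  for (i in 1:50) {
    n <- length(mutate_genome(g, cfg))
    expect_gte(n, 2000)                      # deletions skipped at the floor
    expect_lte(n, 20000)
  }
  g_top <- rep(1L, 19900)
  for (i in 1:20) {
    n <- length(mutate_genome(g_top, cfg))
    expect_lte(n, 20000)                     # inserts skipped at the ceiling
  }
  # inserts copy existing content: only bytes already present appear
  g2 <- sample(0:9, 3000, replace = TRUE)
  m <- mutate_genome(g2, evolution_config(point_rate = 0, indel_rate = 1e-3))
  expect_true(all(m %in% 0:9))
})

test_that("tournament selection prefers the fittest with the closed-form rate", {
  set.seed(55)
  N <- 10; k <- 5
  fit <- c(rep(0.2, N - 1), 0.9)             # index N strictly best
  picks <- vapply(1:4000, function(i) tournament_select(fit, k), integer(1))
  p_best <- 1 - (1 - 1 / N)^k
  expect_lt(abs(mean(picks == N) - p_best), 3 * sqrt(p_best * (1 - p_best) / 4000))
  # uniform fitness: selection is uniform (chi-square)
  picks_u <- vapply(1:5000, function(i) tournament_select(rep(1, N), k),
                    integer(1))
  expect_gt(stats::chisq.test(tabulate(picks_u, N))$p.value, 1e-4)
  # k = 1: a uniform random parent
  picks_1 <- vapply(1:5000, function(i) tournament_select(fit, 1), integer(1))
  expect_gt(stats::chisq.test(tabulate(picks_1, N))$p.value, 1e-4)
})

test_that("evolution runs are seed-reproducible and lineage-consistent", {
  cfg <- evolution_config(population = 20, generations = 5,
                          genome_length = 2000, store_genomes = TRUE)
  r1 <- evolve("nback", "markov", cfg, seed = 57)
  r2 <- evolve("nback", "markov", cfg, seed = 57)
  expect_identical(r1$fitness, r2$fitness)
  expect_identical(r1$parents, r2$parents)
  expect_identical(r1$population, r2$population)

  lod <- line_of_descent(r1)
  expect_equal(nrow(lod), 6)                 # generations 0..5
  expect_equal(lod$generation, 0:5)
  # the stored genome path is internally consistent with parent pointers
  for (g in 2:6)
    expect_identical(lod$genome[[g - 1]],
                     r1$genomes[[g - 1]][[r1$parents[g - 1, lod$index[g]]]])
  # 0 generations: the initial population is returned
  r0 <- evolve("nback", "markov",
               evolution_config(population = 5, generations = 0,
                                genome_length = 2000), seed = 59)
  expect_length(r0$population, 5)
  expect_equal(nrow(r0$fitness), 1)
})

test_that("selection lifts n-Back fitness above the random-guess baseline", {
  cfg <- evolution_config(population = 50, generations = 40,
                          genome_length = 3000)
  for (seed in c(61, 62, 63)) {
    run <- evolve("nback", "markov", cfg, seed = seed)
    expect_gt(run$best$fitness, 0.5)
  }
})

test_that("mutational robustness follows its defining ratio", {
  # neutral mutations: R = 1 exactly
  g <- rep(1L, 2000)
  rob <- mutational_robustness(g, function(g) 1.0,
                               evolution_config(point_rate = 0,
                                                indel_rate = 0),
                               n_mutants = 10)
  expect_equal(rob$R, 1.0)
  # arithmetic: B0 = 0.5, <B> = 0.4 -> R = 0.8
  fits <- c(0.5, rep(0.4, 10))
  i <- 0
  rob2 <- mutational_robustness(g, function(g) {
    i <<- i + 1; fits[i]
  }, n_mutants = 10)
  expect_equal(rob2$B0, 0.5)
  expect_equal(rob2$R, 0.8)
  # perfect-scoring agents: R is simply the average mutant score
  fits3 <- c(1.0, stats::runif(10))
  i <- 0
  rob3 <- mutational_robustness(g, function(g) {
    i <<- i + 1; fits3[i]
  }, n_mutants = 10)
  expect_equal(rob3$R, mean(fits3[-1]))
  expect_error(mutational_robustness(g, function(g) 0, n_mutants = 2),
               "undefined")
})

test_that("run manifests capture the fitness trajectory", {
  cfg <- evolution_config(population = 10, generations = 3,
                          genome_length = 2000)
  run <- evolve("nback", "markov", cfg, seed = 67)
  path <- tempfile(fileext = ".json")
  write_run_manifest(run, path)
  j <- jsonlite::read_json(path)
  expect_length(j$max_fitness, 4)
  expect_equal(j$best$fitness, run$best$fitness)
  expect_equal(j$config$population, 10)
  unlink(path)
})
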