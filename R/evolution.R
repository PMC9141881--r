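## Genetic algorithm over byte genomes: tournament selection, point and
## segmental (copy-insert / delete) mutation, line-of-descent
## reconstruction, and mutational robustness scoring.

#' Evolution configuration
#'
#' Defaults follow the study conditions: population 100, tournament size 5,
#' per-site point mutation rate 5e-3 (randomize to a uniform byte), insert
#' mutations that copy a segment of 128-512 sites to a new location at a
#' per-site rate of 2e-5, deletions with the same parameters, and genome
#' length clamped to 2000-20000 sites by skipping violating operations.
#' `generations` is deliberately left to the caller: full-scale runs used
#' tens of thousands of generations, desk-scale replications hundreds.
#'
#' @param population population size.
#' @param tournament tournament size for selection.
#' @param generations number of generations.
#' @param point_rate per-site point mutation probability.
#' @param indel_rate per-site probability of triggering a segmental copy or
#'   deletion event.
#' @param segment_range inclusive bounds on segment length.
#' @param genome_bounds inclusive bounds on genome length after mutation.
#' @param genome_length initial genome length.
#' @param store_genomes keep every generation's genomes in the lineage
#'   (memory-heavy; the default keeps parent pointers, fitnesses and the
#'   final generation, which [line_of_descent()] and the analyses need).
#' @return Object of class `evolution_config`.
#' @export
evolution_config <- function(population = 100L, tournament = 5L,
                             generations = 100L, point_rate = 5e-3,
                             indel_rate = 2e-5,
                             segment_range = c(128L, 512L),
                             genome_bounds = c(2000L, 20000L),
                             genome_length = 5000L,
                             store_genomes = FALSE) {
  stopifnot(point_rate >= 0, point_rate <= 1, indel_rate >= 0,
            indel_rate <= 1, population >= 1, tournament >= 1)
  structure(list(population = as.integer(population),
                 tournament = as.integer(tournament),
                 generations = as.integer(generations),
                 point_rate = point_rate, indel_rate = indel_rate,
                 segment_range = as.integer(segment_range),
                 genome_bounds = as.integer(genome_bounds),
                 genome_length = as.integer(genome_length),
                 store_genomes = isTRUE(store_genomes)),
            class = "evolution_config")
}

#' Mutate a byte genome
#'
#' Applies, in order: point mutations (each site randomized to a uniform
#' byte, possibly resampling its current value, with probability
#' `point_rate`), then copy-insert events, then deletion events.  The
#' per-offspring count of segmental events is Poisson with mean
#' `length * indel_rate` (the aggregate of independent per-site triggers);
#' each event copies (or deletes) one uniformly chosen segment of uniform
#' length within `segment_range`.  Any event that would push the genome
#' outside `genome_bounds` is skipped.
#'
#' @param g genome (integer vector 0-255).
#' @param cfg an [evolution_config].
#' @return The mutated genome.
#' @export
mutate_genome <- function(g, cfg = evolution_config()) {
  n <- length(g)
  if (cfg$point_rate > 0) {
    hits <- which(stats::runif(n) < cfg$point_rate)
    if (length(hits) > 0L)
      g[hits] <- sample.int(256L, length(hits), replace = TRUE) - 1L
  }
  if (cfg$indel_rate > 0) {
    lo <- cfg$segment_range[1]; hi <- cfg$segment_range[2]
    n_ins <- stats::rpois(1L, length(g) * cfg$indel_rate)
    for (i in seq_len(n_ins)) {
      len <- sample(lo:hi, 1L)
      if (length(g) + len > cfg$genome_bounds[2] || len > length(g)) next
      src <- sample.int(length(g) - len + 1L, 1L)
      seg <- g[src:(src + len - 1L)]
      at <- sample.int(length(g) + 1L, 1L)       # insert before position
      g <- append(g, seg, after = at - 1L)
    }
    n_del <- stats::rpois(1L, length(g) * cfg$indel_rate)
    for (i in seq_len(n_del)) {
      len <- sample(lo:hi, 1L)
      if (length(g) - len < cfg$genome_bounds[1] || len >= length(g)) next
      src <- sample.int(length(g) - len + 1L, 1L)
      g <- g[-(src:(src + len - 1L))]
    }
  }
  g
}

#' Tournament selection
#'
#' Samples `k` indices uniformly with replacement and returns the index of
#' the fittest; ties are broken uniformly at random.
#'
#' @param fitnesses numeric vector of population fitnesses.
#' @param k tournament size.
#' @return Selected parent index.
#' @export
tournament_select <- function(fitnesses, k = 5L) {
  cand <- sample.int(length(fitnesses), k, replace = TRUE)
  best <- cand[fitnesses[cand] == max(fitnesses[cand])]
  if (length(best) == 1L) best else sample(best, 1L)
}

#' Evolve brains on a task
#'
#' Generational loop: evaluate, then fill the next generation with
#' `population` independent tournaments, mutating every offspring (no
#' elitism).  Markov genomes are seeded with six start codons at
#' initialization.  For the n-Back task a fresh set of input strings is
#' drawn each generation and shared by all individuals of that generation.
#' The run is fully reproducible from its seed.
#'
#' @param task `"nback"` or `"blockcatch"`.
#' @param substrate `"markov"` or `"rnn"`.
#' @param cfg an [evolution_config].
#' @param task_cfg task configuration (defaults to the task's standard
#'   configuration).
#' @param seed integer seed for the whole run.
#' @return Object of class `evolution_run`: list with `population` (final
#'   genomes), `fitness` (generations x population matrix, row g holding
#'   the fitness of the individuals *entering* generation g), `parents`
#'   (generations x population parent indices), `best` (list: genome,
#'   fitness, generation, index), `layout`, `config`, `task`, `substrate`,
#'   `seed`, and `genomes` when `store_genomes = TRUE`.
#' @export
evolve <- function(task = c("nback", "blockcatch"),
                   substrate = c("markov", "rnn"),
                   cfg = evolution_config(), task_cfg = NULL, seed = NULL) {
  task <- match.arg(task)
  substrate <- match.arg(substrate)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(task_cfg))
    task_cfg <- switch(task, nback = nback_config(),
                       blockcatch = blockcatch_config())
  layout <- switch(task, nback = nback_layout(),
                   blockcatch = blockcatch_layout())

  make_genome <- function() {
    g <- random_genome(cfg$genome_length)
    if (substrate == "markov") g <- seed_start_codons(g)
    g
  }
  decode <- function(g) switch(substrate,
    markov = decode_markov_brain(g, layout),
    rnn = decode_rnn(g, layout))
  evaluate <- switch(task,
    nback = function(brain, bits) {
      cb <- compile_brain(brain)
      .cpp_run_nback(cb, bits, task_cfg$delays, task_cfg$warmup,
                     FALSE)$fitness
    },
    blockcatch = function(brain, bits) {
      cb <- compile_brain(brain)
      .cpp_run_blockcatch(cb, task_cfg$width, task_cfg$updates,
                          FALSE)$fitness
    })

  pop <- replicate(cfg$population, make_genome(), simplify = FALSE)
  fitness <- matrix(NA_real_, cfg$generations + 1L, cfg$population)
  parents <- matrix(NA_integer_, cfg$generations, cfg$population)
  genomes <- if (cfg$store_genomes) vector("list", cfg$generations + 1L)
  best <- list(fitness = -Inf)
  for (gen in seq_len(cfg$generations + 1L)) {
    bits <- if (task == "nback")
      matrix(sample(0:1, task_cfg$n_lifetimes * task_cfg$string_length,
                    replace = TRUE),
             nrow = task_cfg$n_lifetimes)
    fitness[gen, ] <- vapply(pop, function(g) evaluate(decode(g), bits),
                             numeric(1))
    if (cfg$store_genomes) genomes[[gen]] <- pop
    gb <- which.max(fitness[gen, ])
    if (fitness[gen, gb] > best$fitness)
      best <- list(genome = pop[[gb]], fitness = fitness[gen, gb],
                   generation = gen - 1L, index = gb)
    if (gen > cfg$generations) break
    parents[gen, ] <- vapply(seq_len(cfg$population), function(i)
      tournament_select(fitness[gen, ], cfg$tournament), integer(1))
    pop <- lapply(parents[gen, ], function(p) mutate_genome(pop[[p]], cfg))
  }
  structure(list(population = pop, fitness = fitness, parents = parents,
                 best = best, layout = layout, config = cfg, task = task,
                 substrate = substrate, seed = seed,
                 genomes = genomes),
            class = "evolution_run")
}

#' @export
print.evolution_run <- function(x, ...) {
  cat(sprintf("Evolution run: %s on %s, %d generations, population %d\n",
              x$substrate, x$task, x$config$generations, x$config$population))
  cat(sprintf("  best fitness %.4f (generation %d)\n",
              x$best$fitness, x$best$generation))
  invisible(x)
}

#' Line of descent of an individual
#'
#' Walks parent pointers from an individual of the final generation back to
#' generation 0.  The ancestry path is the backbone along which all fixed
#' mutations of the run accumulated.
#'
#' @param run an [evolve()] result.
#' @param index individual in the final generation (default: the fittest).
#' @return data.frame with columns `generation`, `index`, `fitness`, one
#'   row per generation from 0 to the final generation; when the run stored
#'   genomes, a list-column `genome`.
#' @export
line_of_descent <- function(run, index = NULL) {
  G <- run$config$generations
  if (is.null(index)) index <- which.max(run$fitness[G + 1L, ])
  idx <- integer(G + 1L)
  idx[G + 1L] <- index
  for (gen in rev(seq_len(G)))
    idx[gen] <- run$parents[gen, idx[gen + 1L]]
  out <- data.frame(generation = 0:G, index = idx,
                    fitness = run$fitness[cbind(seq_len(G + 1L), idx)])
  if (!is.null(run$genomes) && length(run$genomes) == G + 1L)
    out$genome <- lapply(seq_len(G + 1L),
                         function(g) run$genomes[[g]][[idx[g]]])
  out
}

#' Mutational robustness of a genome
#'
#' Evaluates the genome for a baseline fitness `B0`, generates `n_mutants`
#' independent mutants with the standard per-offspring mutation rates,
#' and reports `R = <B> / B0`, the mean mutant fitness relative to
#' baseline.  For a perfect-scoring agent, `R` is simply the average
#' mutant score.
#'
#' @param g genome.
#' @param evaluate function mapping a genome to a fitness in `[0, 1]`.
#' @param cfg an [evolution_config] supplying the mutation rates.
#' @param n_mutants number of mutants.
#' @return Object of class `robustness_result`: list with `B0`, `mean_B`,
#'   `R` and the vector `mutant_fitness`.
#' @export
mutational_robustness <- function(g, evaluate, cfg = evolution_config(),
                                  n_mutants = 100L) {
  B0 <- evaluate(g)
  if (B0 == 0) stop("baseline fitness is 0: robustness R is undefined")
  mut <- vapply(seq_len(n_mutants),
                function(i) evaluate(mutate_genome(g, cfg)), numeric(1))
  structure(list(B0 = B0, mean_B = mean(mut), R = mean(mut) / B0,
                 mutant_fitness = mut),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("Mutational robustness: B0 = %.4f, <B> = %.4f over %d mutants, R = %.4f\n",
              x$B0, x$mean_B, length(x$mutant_fitness), x$R))
  invisible(x)
}

#' Write a run manifest as JSON
#'
#' Configuration, seed and per-generation max/mean fitness, sufficient to
#' reproduce the run.
#'
#' @param run an [evolution_run].
#' @param path output path.
#' @export
write_run_manifest <- function(run, path) {
  obj <- list(task = run$task, substrate = run$substrate, seed = run$seed,
              config = unclass(run$config),
              max_fitness = apply(run$fitness, 1, max),
              mean_fitness = apply(run$fitness, 1, mean),
              best = list(fitness = run$best$fitness,
                          generation = run$best$generation))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
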