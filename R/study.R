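## Desk-scale replication of the complexity-versus-robustness experiment:
## evolve replicate Block Catch populations, take the fittest end-of-run
## agent from each replicate's line of descent, and relate its information
## flow complexity to its mutational robustness.

#' Complexity-versus-robustness study on Block Catch
#'
#' Runs `n_runs` independent Block Catch evolution replicates, and for the
#' best end-of-run agent of each replicate computes full-lifetime flow
#' complexity (edge count of the information flow graph at theta = 1) and
#' mutational robustness R over `n_mutants` mutants.  The expectation,
#' which holds as a trend rather than at any fixed magnitude, is a
#' *negative* association: brains with more complex information flow lose
#' more fitness per mutation.
#'
#' Defaults are a deliberately reduced problem size (hundreds rather than
#' tens of thousands of generations, tens rather than hundreds of
#' replicates); they keep the full study in the minutes range on one core
#' while preserving the structure of the experiment.
#'
#' @param n_runs number of evolution replicates.
#' @param generations generations per replicate.
#' @param substrate `"markov"` or `"rnn"`.
#' @param n_mutants mutants per robustness estimate.
#' @param seed master seed; replicate r uses `seed + r`.
#' @param verbose print one line per replicate.
#' @return data.frame with one row per replicate: `run`, `seed`,
#'   `fitness`, `complexity`, `R`, plus attribute `spearman` (the Spearman
#'   rank correlation between complexity and R).
#' @export
complexity_robustness_study <- function(n_runs = 20L, generations = 250L,
                                        substrate = c("markov", "rnn"),
                                        n_mutants = 100L, seed = 1L,
                                        verbose = FALSE) {
  substrate <- match.arg(substrate)
  layout <- blockcatch_layout()
  decode <- function(g) switch(substrate,
    markov = decode_markov_brain(g, layout),
    rnn = decode_rnn(g, layout))
  eval_genome <- function(g)
    run_blockcatch(decode(g), record = FALSE)$fitness
  cfg <- evolution_config(generations = generations)
  rows <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    run_seed <- seed + r
    run <- evolve("blockcatch", substrate, cfg, seed = run_seed)
    lod <- line_of_descent(run)
    final <- run$population[[lod$index[nrow(lod)]]]
    res <- run_blockcatch(decode(final))
    fg <- build_flow_graph(res$recording)
    rob <- mutational_robustness(final, eval_genome, cfg,
                                 n_mutants = n_mutants)
    rows[[r]] <- data.frame(run = r, seed = run_seed,
                            fitness = res$fitness,
                            complexity = flow_complexity(fg),
                            R = rob$R)
    if (verbose)
      message(sprintf("run %d/%d: fitness %.3f, complexity %d, R %.3f",
                      r, n_runs, res$fitness, flow_complexity(fg), rob$R))
  }
  out <- do.call(rbind, rows)
  attr(out, "spearman") <- stats::cor(out$complexity, out$R,
                                      method = "spearman")
  out
}
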