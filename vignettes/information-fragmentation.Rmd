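---
title: "Locating, quantifying and tracing information in discrete networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating, quantifying and tracing information in discrete networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infofrag)
```

## The problem

A network of discrete nodes — neurons firing or silent, genes on or off,
logic gates in an evolved circuit — performs a function, but the mapping
from node states to that function is rarely one node per concept.
Information about a feature of interest can be *localized* in a single
node, *fragmented* across several, or *encrypted* so that no strict subset
of its carriers reveals anything at all.  Structural tools (wiring
diagrams, connectivity statistics) cannot see this; the analysis here is
purely functional: it needs only the recorded joint states of all nodes
over time, and optionally uses the wiring to disambiguate causation
afterwards.

All estimates are plug-in (maximum-likelihood) frequencies over observed
joint states, in bits.  No bias correction (Miller–Madow or similar) is
applied: the intended regime is *complete* phenotypic data — every node
observed on every update of every lifetime — not subsampled recordings.
Continuous-valued estimators (binning or nearest-neighbor) are
deliberately out of scope; continuous substrates are discretized at the
substrate level before recording.

## Distinct informative sets and fragmentation

For a feature $Y$ and a predictor system $X = X_1 \dots X_m$, a *distinct
informative set* (DIS) at threshold $\theta \in [0,1]$ is an irreducible
subset $S \subseteq X$ with

$$I(S;Y) \ge \theta\, H(Y),$$

where irreducible means $S$ is not a proper superset of another qualifying
set.  *Fragmentation* $F_\theta(X;Y)$ is the size of the smallest DIS, or
$-1$ when even the full pool fails the threshold.  Subsets are enumerated
smallest-first (size, then lexicographic within size, in pool order),
which has three consequences:

* the search can stop at the first qualifying size when only $F$ is
  needed;
* supersets of accepted sets are pruned with a single bitmask test when
  the full DIS collection is needed;
* "the first matrix column reaching $\theta$" is a deterministic lookup
  equal to the direct search (a tested consistency property).

A feature may have *several* DISs ("redundant predictive sets").  All
irreducible sets are kept, not only the minimal-size ones: two sets of
different sizes that each lack a member of the other are both retained,
which is what downstream necessity classification needs.

### Numerical choices

* **Threshold tolerance.** The DIS test is $I \ge \theta H(Y) -
  10^{-9}$: plug-in entropies of identical partitions can differ by a few
  ulps depending on summation order, and $10^{-9}$ bits is far below any
  meaningful signal at the sample sizes involved (hundreds to thousands of
  rows).
* **Zero-entropy features** are *trivially predicted*: no DIS is emitted,
  fragmentation is defined as 0, and normalized matrix cells are set to 1.
  This matches hiding zero-entropy nodes in flow graphs and keeps the
  never-used control feature dark in world-feature matrices.
* **Pool cap.** Exhaustive power-set search is $2^m$; pools above 16 nodes
  (65 535 subsets) are refused unless the cap is raised explicitly.
  Greedy or heuristic search for large pools is a non-goal.
* **Mutual information clipping.** Plug-in MI is mathematically
  non-negative; tiny negative floating-point residue is clipped to zero.
  Co-information is *not* clipped — its negativity is the point.

## Flow graphs

When predictors are the $t-1$ state (inputs + memory-before) and features
the $t$ state (outputs + memory-after), DIS membership induces a directed
information-flow graph.  Per target: members present in every DIS give
*necessary* (black) edges; members in some but not all DISs give
*possible* (red) edges.  Every edge is labeled
$I(\text{source};\text{target})/H(\text{target})$ — deliberately the
*single-source* proportion even for necessary edges, so a perfectly
encrypted pair shows two black arrows each labeled 0.  *Flow complexity*
is the total edge count; when a target has exactly one DIS its in-degree
equals its fragmentation.

Zero-entropy nodes are omitted on both sides (a constant node can neither
carry nor receive information; excluding constant predictors from the pool
is exactly equivalent to including them, since they change no joint
entropy).  A positive-entropy target with *no* DIS at $\theta = 1$ is kept
in the graph, flagged "unexplained", and warned about rather than silently
dropped — this occurs for non-deterministic or truncated recordings, never
for a complete recording of a deterministic substrate (the full $T_0$ pool
always qualifies there, a tested invariant).

Connectome disambiguation removes any DIS containing a member with no
physical link to the target, then recomputes necessity; redundancies the
wiring cannot resolve stay red.  A connectome link exists iff some gate
reads the source and writes the target (Markov Brains) or the
corresponding weight is nonzero (RNNs — *exactly* zero, since any nonzero
weight can carry signal through the threshold nonlinearity).

## The testbed

The analysis layer is substrate-agnostic; the testbed exists so that every
stage can be validated on networks whose information structure is known by
construction, and so that the evolutionary study below can be run
end-to-end.

**Tasks.** *n-Back*: one input bit per update, five outputs echoing delays
{1, 3, 5, 7, 8}; 25 lifetimes of 33 bits; the first 8 updates are neither
scored nor recorded (the longest delay must fit in the warm-up); fitness
is the fraction of correct answers, 0.5 for random guessing.  *Block
Catch*: a 32-high, 20-wide laterally wrapping world; blocks of sizes
{2, 3, 4} drift left or right one unit per update while falling one unit
per update for 31 updates; every (size, direction, start column)
combination is one lifetime, 120 in all; size-2 and right-moving size-3
blocks must be caught (any overlap at landing), the rest avoided.  Ten
binary world features (catch/avoid, direction, four size indicators with
size 1 as a never-used control, four direction-by-decision conjunctions)
are recorded per update for world-knowledge matrices.

Three task details are underdetermined by the task description and frozen
here as explicit conventions: the paddle body equals its 6-unit sensor
span `S S _ _ S S` (the sensor geometry is given; a body width is not);
motor semantics are (1,0) = left, (0,1) = right, (0,0)/(1,1) = stay; and
within an update the agent senses and moves *before* the block advances.
These choices affect individual trajectories, not the analysis method, and
the fixture tests are written to be insensitive to them where possible
(the motionless-agent test re-derives landing geometry from the same
convention it checks against, by hand).

**Substrates.** Markov Brains decode a byte genome by scanning for a
two-byte start codon; each occurrence opens a gene: one byte each for the
number of inputs and outputs (`%% 3 + 2`, so 2–4), four input and four
output address bytes (modulo the node-layer size; surplus addresses
unused), then `2^n_in * n_out` lookup-table bytes modulo 2.  Colliding
writes OR.  The codon value (42, 213) and this byte layout are
*conventions of this package*: the encoding is stated here only as "a
start codon opens a gate gene", so a concrete layout was frozen,
documented, and unit-tested against hand-decoded genes to keep every
decode example reproducible.  Truncated genes are skipped; decoding is a
total function of any byte string.  RNNs map the first $(n+1)m$ genome
sites linearly onto weights in $[-1,1]$ and biases in $[-3,3]$, update by
$y = \tanh(Wx + c)$, and discretize every $T_1$ value ($\le 0 \to 0$,
$> 0 \to 1$; exactly zero maps to zero, a boundary the update rule leaves
open) before recording and recurrence — so on binary inputs an RNN induces
a finite-state deterministic map and is analyzable at $\theta = 1$ exactly
like a gate network.

**Evolution.** Population 100, tournament size 5, generational
replacement with as many tournaments as population slots, every offspring
mutated, no elitism (the simplest reading of plain tournament selection;
selection details beyond the tournament are not otherwise constrained).
Point mutations randomize sites at $5 \times 10^{-3}$ per site (a
randomized site may redraw its own value); copy-insert and deletion events
occur at a per-offspring Poisson rate of $2 \times 10^{-5}$ per site with
segment lengths uniform in 128–512, skipping any event that would leave
the genome outside 2000–20 000 sites; genomes start at 5000 random bytes,
Markov genomes seeded with six start codons.  The line of descent is the
parent-pointer walk from a final individual to generation 0.  Storing
every genome of every generation costs hundreds of megabytes at study
scale, so by default runs keep parent pointers, all fitnesses and the
final generation (sufficient for all analyses here); `store_genomes =
TRUE` keeps everything.

**Robustness.** $R = \langle B \rangle / B_0$: the mean fitness of 100
independently mutated offspring over the baseline fitness of the
unmutated agent; for a perfect scorer $R$ is simply the mean mutant score.

## What the generators emulate — and what they do not

The synthetic fixtures plant known structure: a copied feature
(fragmentation 1), an independent feature (fragmentation $-1$ at $\theta =
1$), and $k$-node parity — a $k$-wise one-time pad generalizing the XOR
pair, generated as a balanced complete factorial so that every strict
subset of the parity set carries *exactly* zero empirical bits, stressing
the irreducibility pruning without sampling noise.  The hand-built brains
(an 8-stage shift register solving the memory task perfectly with
fragmentation 1 everywhere, and an XOR delay circuit whose output is
predicted only by a node pair with triple co-information $-1$) anchor the
full pipeline: substrate, task, recording, matrix, DIS, flow graph.

Passing on these generators shows the estimators and the search are
*exact* on clean discrete data.  It does not show robustness to
undersampling, missing nodes, observation noise, or continuous dynamics —
real neural or genetic recordings have all four, and plug-in estimates on
undersampled joint states are biased upward.  Conclusions about real data
need the complete-data regime this package assumes.

## The reduced-scale evolutionary study

`complexity_robustness_study()` evolves replicate Block Catch populations,
takes each replicate's best end-of-lineage agent, and relates
full-lifetime flow complexity to mutational robustness.  The desk-scale
configuration — 20 replicates, 250 generations, population 100 — was
chosen once as this package's study condition: hundreds of generations
produce well-above-baseline but heterogeneous fitness and heterogeneous
architectures on one core in minutes.  At full scale
(hundreds of replicates, tens of thousands of generations, analysis
restricted to perfect scorers) the association has been reported as a
clear negative trend; at desk scale the package asserts only the *sign* of
the Spearman rank correlation between complexity and $R$, not a
magnitude, and the specific evolved champion networks of the full-scale
campaigns are not reproduced.  Relatedly, late-lifetime recordings
(`trim_late_lifetime`, keeping the last `max(1, round(f * L))` updates per
lifetime, rounding half-up) typically yield simpler flow graphs than full
lifetimes for evolved agents that have "made up their mind" — a trend we
observe on evolved examples but do not assert as an invariant, since
nothing forces it for an arbitrary agent.

One bookkeeping asymmetry deserves note: for flow matrices the natural
feature set (outputs + memory-after) has more members than the predictor
pool (inputs + memory-before) whenever outputs outnumber inputs, and
published descriptions of the matrix shape are not always consistent about
orientation or about counting the empty set.  This package follows the
definitions: rows are features, columns are the $2^m - 1$ non-empty
predictor subsets.

## Known limitations

* Exhaustive search is exponential in the pool size; the cap is a guard,
  not a solution.  Large systems need heuristics that are out of scope.
* Plug-in estimates require sample sizes well above the joint state space
  of the sets being tested; $\theta = 1$ analyses of stochastic systems
  will generically return "unexplained" targets.
* Venn decompositions stop at three variables; partial information
  decomposition beyond co-information is deliberately excluded.
* The GA is a minimal generational implementation; it is a data generator
  for the analysis layer, not a general-purpose evolutionary framework.
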