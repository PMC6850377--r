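---
title: "Maximizing NODF: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximizing NODF: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestmax)
```

## The problem

Binary bipartite interaction matrices (plants × pollinators, hosts ×
parasites, ...) are called *nested* when the partners of specialists are
subsets of the partners of generalists. NODF quantifies this on a 0–100
scale. Because raw NODF depends strongly on matrix shape and fill, a
network's observed NODF is normalized by the *maximum* NODF any matrix of
the same shape could reach, over the set of **feasible** matrices: same
numbers of rows, columns and links, every row and column keeping at least
one link. `nestmax` computes NODF, searches for that maximum, and derives
the normalized statistics

$$\mathrm{NODF}_n = \frac{\mathrm{NODF}}{\max(\mathrm{NODF})},\qquad
  \mathrm{NODF}_c = \frac{\mathrm{NODF}_n}{C\,\log S},$$

with connectance $C = L/(mn)$ and size $S = \sqrt{mn}$ for an $m\times n$
matrix with $L$ links.

## The NODF form used

We use the pairwise, order-invariant formulation: an unordered pair of
rows (or columns) with degrees $d_i \ne d_j$ and $o$ shared links
contributes $100\,o/\min(d_i, d_j)$; equal degrees contribute 0
("decreasing fill"); NODF is the sum over all $\binom{m}{2}+\binom{n}{2}$
pairs divided by the number of pairs. This is algebraically identical to
the classical presentation on a matrix pre-sorted by decreasing marginal
totals, but needs no tie-breaking convention for equal-degree orderings
and is manifestly invariant under row/column permutation and
transposition (the test suite asserts both, and cross-checks random
matrices against `vegan::nestednodf`). Pairs involving an empty line are
defined to contribute 0 (their overlap is 0 anyway); a $1\times 1$ matrix
has no pairs and raises an undefined-metric error.

NODF is reported on the conventional 0–100 scale; the optimizers
internally minimize the cost $1 - \mathrm{NODF}/100 \in [0, 1]$.

## Incremental evaluation

Moving one link changes the degrees of at most two rows and two columns
and the overlaps of pairs involving them, so the NODF delta of a move can
be computed from cached degrees and pairwise overlap counts in
$O(m + n)$ rather than $O(m^2 + n^2)$ work. `nodf_state()` /
`apply_move()` expose this machinery in R; the annealer uses the same
scheme in compiled code. Two hygiene rules: the compiled path recomputes
the cached pair sum from the (integer, hence exact) overlap tables every
4096 moves to cancel floating-point drift, and all incremental-vs-full
comparisons in the tests use a 1e-9 relative tolerance — a delta update
followed by its reverse restores the cached total only to within rounding,
not bit-exactly.

## Maximization

**Exhaustive enumeration** (`brute_force_max()`) scores every feasible
placement of $L$ links in $mn$ cells and is the exact oracle for the
other two methods. It refuses shapes with more than `cap` (default
$5\times 10^6$) candidate placements outright — never a silent
approximation.

**Greedy placement** (`greedy_maximize()`) adds links one at a time at
the empty position with the largest NODF gain, breaking ties toward the
first position in row-major order (deterministic and testable). A pure
greedy build can strand feasibility when few links remain, so placement
is restricted to positions that keep full coverage achievable: when the
remaining budget equals the number of uncovered rows (or columns), the
next link must cover a new row (or column). This single rule produces a
feasible matrix for every feasible shape, including sparse shapes with
$L < m + n - 1$ where no matrix containing a full first row *and* full
first column exists; we chose it over a fixed seeded backbone for exactly
that reason. Greedy has no backtracking and regularly terminates in local
optima — which is the point of comparing it with annealing.

**Simulated annealing** (`simulated_annealing()`) is the classical
algorithm: start from a random feasible matrix, propose a random
neighbour (a single link moved to an empty cell, never emptying a row or
column on removal), accept downhill or equal-cost moves always and uphill
moves with probability $\exp((\mathrm{cost} - \mathrm{cost}')/T)$, run
$N$ proposals per temperature level, cool geometrically $T \leftarrow
\alpha T$, stop below $T_{\min}$, and return the best matrix observed
anywhere along the run. The proposal draws a uniformly random removable
link (rejection sampling) and a uniformly random empty target, so every
legal move has positive probability.

### Schedule defaults

The tunables, all overridable through `annealing_schedule()`:

| parameter | default | rationale |
|---|---|---|
| `t0` | calibrated | chosen so ~80% of uphill moves from the start would be accepted, using the mean uphill cost change of 100 sampled moves; temperatures are in cost units (dimensionless, cost ∈ [0,1]) |
| `alpha` | 0.95 | a conventional slow geometric cooling; with the default `t_min` it gives ≈180 temperature levels |
| `n_per_temp` | `10 * n_links` | moves per level proportional to the number of links, so effort scales with the size of the move space |
| `t_min` | `t0 * 1e-4` | uphill acceptance is negligible four decades below `t0` |
| `seed` | 1 | one seeded RNG stream drives the start matrix, calibration and every proposal, so a fixed seed gives a bit-identical result |

### Neighbourhood structure

A move may not empty a row or column, so matrices in which every link
sits in a degree-1 row or degree-1 column have no legal moves (e.g.
permutation matrices). Two facts keep this benign. First, any matrix
*reached by* a move contains a movable link: the link just added lands on
a matrix that was feasible before the addition, so its row and column
both end with degree ≥ 2. Second, the random starting matrices only lack
moves when $L = \max(m, n)$, where the longer side's lines all have
degree 1, every pair term vanishes, and *every* feasible matrix —
including the optimum — scores 0. So the annealer never freezes below an
attainable optimum; `propose_move()` still signals an
exhausted-neighbourhood error for callers who hit such a state directly.

### Comparing with greedy

`compare_to_greedy()` reports $100\,(\mathrm{SA} -
\mathrm{greedy})/\mathrm{greedy}$. By default the annealer is seeded with
the greedy matrix; since best-so-far tracking starts at the seed, the
comparison is non-negative by construction, and any positive value is a
certificate that greedy missed the maximum. With a random start the
guarantee disappears but the comparison is unbiased. When greedy scores
0, every feasible matrix of that shape scores 0 (greedy's 0 only occurs
on degenerate shapes where the pair terms vanish identically), and the
percentage change is reported as 0, or flagged undefined if annealing
somehow exceeded it.

## Normalization choices

`NODF_n` uses observed and maximum on the same 0–100 scale, so the ratio
is scale-free. The logarithm in `NODF_c` is natural by default
(`log_base` is an argument): the defining formula does not fix a base,
and any fixed base only rescales `NODF_c` by a constant, which cancels in
cross-network comparisons. `NODF_c` requires $S > 1$; a maximum of 0
makes the normalization undefined and raises an error rather than
returning infinity. Because an under-estimated maximum inflates
`NODF_n`, the test suite asserts the ordering: normalizing by a
heuristic maximum never yields a smaller `NODF_n` than normalizing by
the exact enumerated maximum.

## Synthetic data

The generators exist so every claim is testable offline:

* `random_feasible_matrix()` draws a random covering (each line of the
  longer side gets one link through a permutation that also covers the
  shorter side) and sprinkles the remaining links uniformly over empty
  cells. It emulates the *feasibility structure* of empirical webs, not
  their ecology: it is not uniform over all feasible matrices and has no
  degree-sequence realism, no modularity, no sampling effort artefacts.
  Tests passing on these matrices validate the algebra and the
  optimizers' contracts; they do not certify behaviour on any particular
  empirical network.
* `perfect_staircase()` builds the NODF = 100 reference. Full marks
  require strictly distinct degrees on *both* sides of a fully nested
  matrix; since a nested matrix's column degrees are determined by its
  row degrees, that forces $k\times k$ shapes with $k(k+1)/2$ links —
  the constructor enforces this and errors otherwise.
* `enumerate_feasible()` streams every feasible matrix of a small shape;
  its counts are tested against an independent inclusion–exclusion
  calculation.

## Problem sizes in the test suite

The suite enumerates every feasible shape with at most 12 cells (plus
the 3×4 family) against the brute-force oracle with 20 annealing seeds
per shape; tracks ~10^4 incremental moves on matrices up to 20×20; and
runs the greedy-vs-annealing battery on 20 random shapes with 5–15 rows
and columns at connectance 0.15–0.4. These sizes make the whole suite a
matter of a minute or two on one core while still covering every code
path; the algorithms themselves run comfortably on empirical
plant–pollinator networks (hundreds of species), where the incremental
evaluator is what keeps annealing cheap.

## Known limitations

* Annealing offers no optimality certificate: a positive gain over
  greedy proves greedy suboptimal, while agreement proves nothing about
  the global maximum.
* The default schedule is a robust general-purpose choice, not tuned per
  network; very large or very sparse networks may warrant a larger
  `n_per_temp` or slower `alpha`.
* Only binary NODF is implemented — no weighted NODF, no other
  nestedness indices, and no null-model z-scores (the normalization by
  the maximum exists precisely to avoid them).
* Maximization assumes the feasibility constraint (no empty rows or
  columns); observed matrices violating it are read with a warning, and
  their shape is not a valid maximization target.
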