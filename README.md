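# nestmax

Nestedness — the tendency for specialists in a bipartite mutualistic
network to interact with subsets of the partners of generalists — is
usually measured with NODF (nestedness based on overlap and decreasing
fill, 0–100). Raw NODF is not comparable across networks of different
size and fill, so it is normalized by the *maximum* NODF attainable by
any binary matrix with the same numbers of plants (rows), pollinators
(columns) and links, under the feasibility constraint that every plant
and pollinator keeps at least one link:

    NODF_n = NODF / max(NODF)
    NODF_c = NODF_n / (C · log S)

where `C = links / (rows · cols)` is connectance and `S = sqrt(rows · cols)`
the geometric mean of the guild sizes. The quality of `max(NODF)`
matters: a greedy link-placement heuristic gets stuck in local optima
and under-estimates the maximum, silently inflating `NODF_n`. `nestmax`
is for network ecologists who need defensible normalized nestedness
values: it computes NODF, and estimates `max(NODF)` three ways —

* **exhaustive enumeration** (`brute_force_max()`) — exact, tiny shapes only;
* **greedy link placement** (`greedy_maximize()`) — fast, deterministic,
  prone to local optima;
* **simulated annealing** (`simulated_annealing()`) — single-link moves,
  Metropolis/Kirkpatrick acceptance `min(1, exp((cost − cost′)/T))` on the
  cost `1 − NODF/100`, geometric cooling `T ← αT` with `N` moves per
  temperature level, best-anywhere tracking, and an incremental NODF
  evaluator that re-scores a move in O(rows + cols).

NODF here is the order-invariant pairwise form: an unordered pair of rows
(or columns) with degrees `d_i ≠ d_j` and `o` shared links contributes
`100 · o / min(d_i, d_j)`; equal-degree pairs contribute 0; NODF is the
mean over all row and column pairs.

## Worked example

```r
library(nestmax)

web <- read_matrix(system.file("extdata", "synthetic_web.csv", package = "nestmax"))
#> read 8 x 10 matrix with 24 links from .../synthetic_web.csv
nodf(web)
#> NODF: 21.23 (row pair sum 600, column pair sum 950 over 73 pairs)

mx <- simulated_annealing(shape_of(web), annealing_schedule(seed = 1),
                          init = "greedy")
mx
#> anneal: best NODF 77.168950 (8 x 10, 24 links; 43,301 NODF evaluations)

combined_statistic(web, nodf_max = mx$best_nodf)
#> network 8 x 10, 24 links (C = 0.3000, S = 8.944)
#>   NODF = 21.233  max(NODF) = 77.169
#>   NODF_n = 0.27515  NODF_c = 0.4186
```

The observed network realizes about 28% of the nestedness its shape
allows (`NODF_n`); `NODF_c` additionally corrects that ratio for
connectance and size so it can be compared across networks. On shapes
where greedy placement traps itself, annealing finds strictly more
nestedness:

```r
compare_to_greedy(network_shape(14, 9, 25), annealing_schedule(seed = 13))
#> greedy 46.194226 vs annealing 54.986877: +19.034% change (14 x 9, 25 links)
```

Because `compare_to_greedy()` seeds the annealer with the greedy matrix
and annealing keeps the best solution it ever visits, the change is never
negative.

A command-line interface wraps the same functions
(`inst/cli/nestmax.R`): `compute`, `maximize`, `normalize` and
`benchmark` subcommands emit JSON (logs on stderr), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "nestmax.R", package = "nestmax"))')" \
    maximize --rows 14 --cols 9 --links 25 --algorithm anneal --seed 13
```

The `benchmark` subcommand runs the greedy-vs-annealing comparison over a
directory of matrix files (e.g. Web of Life `M_PL_*` downloads) and
prints a per-network table of both maxima and the percentage change.

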