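# grcs — minimum local parsimonious DCJ scenarios

`grcs` computes rearrangement scenarios between two genomes with equal
syntenic-block content under the double cut and join (DCJ) model, for
comparative genomicists who want scenarios that respect *positional
constraints* rather than an arbitrary member of the (exponentially large)
set of parsimonious scenarios.  Every adjacency of the source genome
carries a color — for example a spatial locality derived from chromatin
conformation (Hi-C) data — and a DCJ cutting two adjacencies of different
colors is *rare* (weight 1) while all other moves are *likely* (weight 0):

    w(ρ) = 0  if i_ρ = j_ρ or col(i_ρ) = col(j_ρ),   1 otherwise

where `i_ρ, j_ρ` are the adjacencies cut by `ρ`.  Among all scenarios of
minimum length `d_DCJ(A,B) = N − (C + I/2)` (blocks `N`, cycles `C`,
odd paths `I` of the adjacency graph `G(A,B)`), the package finds one
minimizing `Σ w(ρ_i)` in polynomial time, via:

* **MNCP** — the Minimum Noncrossing Colored Partition of each component's
  A-side edge colors (an `O(n³)` interval dynamic program generalizing
  Maximum Independent Set on circle graphs); a component with partition
  cardinality `k` needs exactly `k − 1` rare moves;
* **even-path mixing** — the two cycles obtained by joining an AA-path and
  a BB-path at their telomeres bound every way of mixing the pair, and an
  exact maximum-weight bipartite matching decides which pairs to mix;
* a **solver** that emits the full scenario (mixing moves, partition
  splits, likely completions), replays it, and asserts that its weight
  equals the matching optimum.

Exhaustive brute-force oracles (BFS distance, Catalan-pruned partition
enumeration, exhaustive mixing, memoized DFS over all parsimonious
scenarios) and a seeded random-instance generator back every algorithm in
the test suite.

## Worked example

The bundled fixture is the two-linear-chromosome pair
`A = {(∘,5,−1,−2,6,−4,−8,∘), (∘,−3,7,∘)}`,
`B = {(∘,1,2,3,4,5,6,∘), (∘,7,8,∘)}` with a synthetic 4-color map over
A's ten adjacencies (file `worked_A_colors_synthetic.tsv`; telomeric
adjacencies are colored too).

```r
library(grcs)
a   <- parse_genomes(readLines(system.file("extdata", "worked_A.txt", package = "grcs")))[[1]]
b   <- parse_genomes(readLines(system.file("extdata", "worked_B.txt", package = "grcs")))[[1]]
col <- parse_color_map(readLines(system.file("extdata",
         "worked_A_colors_synthetic.tsv", package = "grcs")), a)

dcj_distance(a, b)
#> [1] 6

res <- sort_genomes(a, b, col)
res
#> DCJ scenario: 6 move(s), total weight 5
#> minimum rare moves: 5; mixed pairs: 0

scenario_table(res$scenario)
#>   step  cut1  cut2  new1  new2 weight color1 color2
#> 1    1  3h-$ 4t-8h 3h-4t  8h-$      1      d      c
#> 2    2  5t-$ 4h-6h 4h-5t  6h-$      1      a      c
#> 3    3  7h-$  8t-$ 7h-8t     -      1      b      -
#> 4    4 1t-2h 3t-7t 2h-3t 1t-7t      1      b      a
#> 5    5 1h-5h 2t-6t 1h-2t 5h-6t      1      a      b
#> 6    6 1t-7t     -  1t-$  7t-$      0      a      a
```

The adjacency graph of this pair has one cycle, two even-length paths and
two odd-length paths, giving distance `8 − (1 + 2/2) = 6`; under this
coloring five of the six moves must be rare (the brute-force oracle
`brute_force_min_rare(a, b, col)` confirms 5), and the final fission is
likely.  Each row is one DCJ: the cut adjacencies, the reglued products
(`-` when a telomere pair is absorbed), the move's weight and the colors
routed onto the products.

The MNCP on the eight-element color sequence `b,a,b,c,a,d,a,c`:

```r
mncp(c("b","a","b","c","a","d","a","c"))$classes
#> [[1]] 1 3   [[2]] 2   [[3]] 4 8   [[4]] 5 7   [[5]] 6     (k = 5)
```

A command-line wrapper is installed at `inst/cli/grcs`:

```sh
Rscript inst/cli/grcs distance A.txt B.txt
Rscript inst/cli/grcs sort A.txt B.txt --colors colors.tsv --out scenario.tsv
Rscript inst/cli/grcs mncp --colors b,a,b,c,a,d,a,c
Rscript inst/cli/grcs random --blocks 6 --linear 2 --colors 3 --seed 7 --out-prefix inst1
```

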