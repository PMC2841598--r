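# grangernet

Temporal-precedence clustering of time-course gene expression data.

Static similarity measures (Pearson correlation, Euclidean distance)
ignore the sequential nature of a time course: reorder the time points
and the score does not change. `grangernet` clusters genes by *temporal
precedence* instead — gene *Y* is associated with gene *X* when the past
of *Y* improves the forecast of *X* beyond *X*'s own past (Granger
causality). It is aimed at analysts of time-course microarray / RNA-seq
experiments who want candidate functional modules, not a reconstructed
causal circuit.

## The method

For every ordered gene pair (*X*, *Y*) and lag order *p*, two nested
autoregressions are fitted by OLS:

> unrestricted: x_t = c + Σ α_i x_{t−i} + Σ β_i y_{t−i} + u_t (RSS₁)
> restricted: the same without the y lags (RSS₀)

and the exclusion hypothesis H₀: β₁ = … = β_p = 0 is tested with

> S = ((RSS₀ − RSS₁)/p) / (RSS₁/(n − 2p − 1)) ~ F(p, n − 2p − 1),

α = 0.05 by default; *p* is chosen per pair by minimising the AIC of the
bivariate VAR, AIC(p) = ln det σ̂ + 2·m²·p/n with m = 2. The pair's
association weight is the larger of its two directional F statistics
(zero when neither rejects); a quantile threshold (0.975 small sets,
0.99 large sets) keeps the dominant edges; and dense regions are
extracted by a molecular-complex algorithm: vertices weighted by
k_max × density of the highest k-core of their closed neighbourhood,
greedy seeded expansion (neighbour joins when its weight exceeds
(1 − vwp) × seed weight), 2-core filtering, haircut, and ranking by
score D_c × |V_c|. A seeded VAR simulator provides benchmark systems
with known causal structure, and a network-statistics suite (degree
distribution, shared neighbours, closeness, topological coefficient)
characterises the result. See the vignette
`vignettes/temporal-precedence-clustering.Rmd` for the full account.

## Worked example

Three independent benchmark systems (5 + 4 + 6 processes, known lag
structure) are embedded in one 15-process system; the pipeline should
rediscover the three "islands" without cross-talk and pull out dense
modules:

```r
library(grangernet)

sim <- combined_system(T = 1000, seed = 42)    # 15 x 1000 matrix
d   <- pairwise_causality(sim$data, alpha = 0.05, p = "auto")
#> Directed causality strengths: 15 genes, 210 tests, 52 rejected directions (alpha = 0.05)

net <- threshold_quantile(symmetrize_max(d), q = 0.8)
#> Association network: 15 genes, 9 edges (thresholded at q = 0.8, cutoff = 256.4)
head(network_edges(net), 5)
#>   geneA geneB    weight
#> 2    x7    x8 1323.1311
#> 5   x12   x13  805.2683
#> 9   x14   x15  643.9823
#> 3   x10   x11  603.6948
#> 4   x11   x12  578.2544

find_complexes(net)
#> 1 complex(es) detected
#>   #1 score 3.333 (4 vertices, density 0.833, seed x12): x12, x13, x14, x15

network_summary(as_igraph(net, drop_isolated = TRUE))
#> Network statistics
#>   nodes: 10, edges: 9, sparsity: 0.2
#>   components: 3
#>   mean shortest path: 1.76, diameter: 4
```

Reading the output: 52 of the 210 directed tests reject, every retained
edge stays inside its generating subsystem (components {x1, x4},
{x7, x8}, {x10…x15} — no cross-island edge survives the threshold), and
the one detected complex is a dense 4-gene region of the third system
(density 5/6, score 10/3). The F statistics in `weight` are the edge
strengths: x7→x8 is the strongest link because x7 drives x8 directly at
lag 3 with nothing else feeding x8.

The same flow for a file-based run:

```r
cfg <- pipeline_config("expression.tsv", "out_dir",
                       diff = TRUE, flat_filter_k = 2, q = 0.975)
res <- run_pipeline(cfg)   # writes network.tsv/.graphml, complexes.tsv,
                           # stats.json, manifest.json
```

or from the shell (subcommands: simulate, preprocess, test-pairs,
network, find-complexes, stats, pipeline):

```sh
Rscript inst/cli/grangernet.R simulate --dataset combined --T 1000 \
    --seed 42 --out matrix.tsv
Rscript inst/cli/grangernet.R pipeline --in matrix.tsv --no-diff \
    --q 0.8 --out-dir out
```

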