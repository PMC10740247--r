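# pwsc — polynomial weight-adjusted sparse clustering

`pwsc` clusters samples (patients) described by extremely sparse
non-negative feature-by-sample matrices — somatic mutation tables where 1-2%
of entries are non-zero, microbial abundance profiles at ~4% — where raw
Euclidean distances between samples are dominated by zeros and conventional
hierarchical clustering degenerates.  It is aimed at cancer-subtyping and
microbiome stratification workflows, as a library plus a small command-line
driver.

## The method

Given `D ∈ R^{m×n}` (features × samples), let `η_i` be feature *i*'s
observation frequency (its carrier count across samples, or its row sum for
abundances).  A polynomial with non-negative values over the observed range,

    P(η) = a_0 + a_1 η + … + a_n η^n        (default: P(η) = η⁴)

is normalized into feature weights `w_i = P(η_i) / Σ_k P(η_k)`, and the
*correction matrix* `D̄[i,·] = w_i · D[i,·]` rescales every feature row, so
recurrent (high-frequency) features dominate the sample-to-sample distances.
Samples are then clustered by Ward agglomeration (`ward.D2` convention) on
Euclidean distances between columns of `D̄`.

The number of clusters is chosen by Monti-style consensus resampling: for
each candidate `k`, `H` subsamples of a fraction `f` of the samples are
clustered, the consensus matrix `C(i,j) = Σ_h M^h(i,j) / Σ_h U^h(i,j)`
(co-clustered over co-selected counts) is assembled, and its CDF is
summarized by the proportion of ambiguous clustering
`PAC = F(u₂) − F(u₁)` (defaults `u₁ = 0.1`, `u₂ = 0.9`) and by the relative
change in area under successive CDF curves.  Low PAC = stable `k`.
Partitions are scored by entropy `−Σ p_k ln p_k` of the cluster sizes and by
the Calinski–Harabasz index `(tr B / tr W) · (n − k)/(k − 1)`, both against
an unweighted Euclidean-Ward baseline, and interpreted through per-cluster
feature occurrence ("most valuable biomarker") reports.

See `vignettes/pwsc-methods.Rmd` for assumptions, defaults and limitations.

## Worked example

```r
library(pwsc)

spec <- synthetic_spec(m = 120, n = 90, k_true = 3, n_signature = 10,
                       p_signature = 0.7, p_background = 0.08, seed = 42)
sim <- generate_planted(spec)
sim$matrix
#> sparse_data_matrix: 120 features x 90 samples, density 0.1343

plan <- resampling_plan(n_iterations = 200, sample_fraction = 0.8, seed = 42)
res  <- run_consensus(sim$matrix, 2:6, plan)
sel  <- select_optimal_k(lapply(res, consensus_cdf))
print(sel$table, digits = 3)
#>     k   pac  area delta_area
#> k=2 2 0.785 0.461     0.4614
#> k=3 3 0.344 0.667     0.4462
#> k=4 4 0.340 0.723     0.0839
#> k=5 5 0.328 0.764     0.0569
#> k=6 6 0.333 0.793     0.0374
```

PAC is nearly flat from `k = 3` on (0.344 vs 0.328), so the argmin alone
would over-split; the delta-area curve collapses after `k = 3` and
`select_optimal_k(..., criterion = "delta_area")` picks 3 — the planted
truth.  At that `k`:

```r
a <- pwsc_cluster(sim$matrix, 3)
a
#> cluster assignment: 90 samples in 3 clusters (sizes 30/29/31)
mclust::adjustedRandIndex(a$labels, sim$labels)
#> [1] 0.9664753

head(subset(most_valuable(occurrence_counts(sim$matrix, a),
                          tau = 0.6)$table, flagged), 4)
#>   cluster cluster_size  feature_id count prevalence flagged
#> 1       1           30 feature_005    23  0.7666667    TRUE
#> 2       1           30 feature_009    22  0.7333333    TRUE
#> 3       1           30 feature_010    22  0.7333333    TRUE
#> 4       1           30 feature_003    21  0.7000000    TRUE
```

The flagged features are exactly cluster 1's planted signature block, each
present in ≥70% of its samples.  The metric sweep
(`metrics_sweep(sim$matrix, 2:6)`) shows the weighted algorithm roughly
tripling the baseline's Calinski–Harabasz index at every `k` on this data
(e.g. 30.8 vs 11.7 at `k = 3`) at essentially equal entropy.

The same workflow runs from the shell via the installed `exec/pwsc` script
(`simulate`, `weights`, `cluster`, `consensus`, `metrics`, `biomarkers`,
`full`), e.g.

```sh
pwsc full --input matrix.tsv --kmin 2 --kmax 15 --reps 1000 --seed 7 --out run/
```

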