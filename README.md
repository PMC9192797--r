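# lccaselect

Latent Class Cluster Analysis (LCCA) with an extended strategy for
selecting the number of clusters.

LCCA clusters categorical/ordinal data — Likert items, diagnostic codes,
survey batteries — by fitting a finite mixture of products of multinomial
distributions: class `k` has prior probability `π_k`, and given the class,
item `j` takes category `h` with probability `α_kjh`. The latent class is
the cluster label. Choosing the number of classes `K` from a fit index
alone is fragile, so this package computes and visualises three families
of evidence side by side:

* **model fit** — log-likelihood, BIC `= -2ℓ + ν log n` and the
  entropy-penalised ICL `= BIC + 2·EN(τ)` over `K = 1..10`, with a
  formalised elbow heuristic on the BIC curve;
* **cluster separation** — the average silhouette width (ASW) of the MAP
  partition on a simple-matching (normalised Hamming) dissimilarity;
* **stability of partitions** — bootstrap resampling: refit on each
  resample, classify the full sample, and compare against the reference
  partition with the adjusted Rand index and the Jaccard coefficient.

Around that core it provides the preprocessing a real analysis needs
(missingness exploration, one-way ICC screen for multilevel structure,
chained random-forest imputation, category-frequency reports), a seeded
latent-Gaussian generator for ordinal clustered data with controllable
separation (including six preset designs with known separable-cluster
counts), post-selection diagnostics (population shares, per-item
discriminative power, item-probability / silhouette / PCA figures), and a
command-line interface. It is aimed at applied researchers in psychology,
education and epidemiology, and at methodologists who want a transparent,
fully seeded test bed for cluster-number selection.

## Worked example

Simulate ordinal data with three clusters of unequal size, sweep the
criteria, then check stability of the indicated solution:

```r
library(lccaselect)

spec <- simulation_spec(K = 3, n_total = 600, J = 6, m = 4,
                        weights = c(0.5, 0.3, 0.2), separation = 2,
                        within_sd = 0.8, seed = 42)
sim <- simulate_ordinal_clusters(spec)

sel <- selection_table(sim$data, k_min = 1, k_max = 6, restarts = 10, seed = 1)
sel
#> Cluster-number selection table
#>  K   loglik  nu      bic   entropy      icl      asw
#>  1 -4990.66  18 10096.46   0.00000 10096.46       NA
#>  2 -3743.55  37  7723.80   4.88432  7733.56 0.379424
#>  3 -3407.79  56  7173.80  10.71389  7195.23 0.428539
#>  4 -3388.76  75  7257.28  21.62267  7300.53 0.356473
#>  5 -3376.10  94  7353.51 161.04368  7675.60 0.305337
#>  6 -3359.03 113  7440.91 190.95876  7822.83 0.305424
#> minimal BIC at K = 3; minimal ICL at K = 3; max ASW at K = 3; BIC elbow at K = 3
```

Every criterion points at `K = 3`: the BIC and ICL are smallest there, the
silhouette peaks there (0.43 — moderate separation), and the BIC curve
flattens after 3. `selection_plot(sel)` draws the two-panel figure with
the min-BIC/min-ICL lines and the elbow marker.

```r
st <- bootstrap_stability(sim$data, K = 3, B = 20, seed = 1, restarts = 10)
st
#> Bootstrap stability for K = 3 (20 replicates)
#> mean ARI: 0.988   mean Jaccard: 0.985
```

Partitions refitted on resamples agree with the reference partition almost
perfectly (means near 1), so the 3-cluster solution is not an artefact of
this particular sample. Finally, the post-selection report:

```r
cluster_report(sim$data, sel$fits[[3]])
#> Cluster report for K = 3
#> population shares:
#>  cluster count     share flagged
#>        1   301 0.5016667   FALSE
#>        2   180 0.3000000   FALSE
#>        3   119 0.1983333   FALSE
#> ASW: 0.429
#> discriminative power (descending):
#>   item6   item4   item5   item3   item2   item1
#> 375.411 349.624 349.521 348.996 346.011 342.567
```

Shares match the generating weights (0.5/0.3/0.2), none is small enough
to be flagged, and all six items carry comparable (large, positive)
discriminative power — as they should, since all six were generated to
separate the clusters.

Real data enter through `read_lcca_csv()` / `lcca_data()` (integer codes
or string levels; empty cells and `NA` are missing), typically followed by
`missingness_summary()`, `drop_empty_rows()` and `impute_missing()`
before fitting.

## Command line

```sh
Rscript inst/cli/lcca.R simulate --preset C --seed 1 --out c
Rscript inst/cli/lcca.R select --input c_data.csv --kmin 1 --kmax 10 \
    --restarts 20 --seed 1 --out-table selection.csv --plot selection.png
Rscript inst/cli/lcca.R stability --input c_data.csv --k 4 --bootstrap 100 --seed 1
Rscript inst/cli/lcca.R report --input c_data.csv --k 4 --out-dir report
```

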