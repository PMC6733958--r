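# specnet

Weighted correlation networks and spectral decomposition for comparing small
groups of athletes — built around the analysis of Olympic 50 m freestyle
finals, where each edition's 8 finalists split into 3 medalists and 5
non-medalists.

## The science

For each (edition, group) cell, six per-athlete variables — age, weight,
height, BMI, number of Olympic medals, reaction time — become the nodes of a
complete weighted graph. The link weight between nodes *i* and *j* is the
Pearson correlation of the two variables across the group's athletes,
rendered as a percentage (r = 0.56 → a 56% link) and, by default, taken in
absolute value so the connection matrix **C** is non-negative. Race time and
velocity are deliberately *not* nodes: they directly determine the finish
order and would bias the network.

The headline statistic is the **spectral radius** (SR), the largest
eigenvalue θ₀ of the symmetric connection matrix **C**. For non-negative
symmetric **C**, Perron–Frobenius theory guarantees θ₀ is real, dominates
every eigenvalue in magnitude (|θ| ≤ θ₀), has a non-negative eigenvector
(the Perron vector, whose components are eigenvector-centrality scores), is
simple when the network is irreducible, and never increases when edges are
removed. A higher SR means stronger overall coupling among the variables;
the empirical finding this package operationalises is that medalist groups
show systematically higher SR than non-medalists.

Because the underlying per-athlete data are not public beyond group
means/SDs, the package ships a synthetic cohort generator: a single latent
factor *F* per athlete with per-variable loadings λ,

```
x_v = μ_v + σ_v (λ_v F + sqrt(1 − λ_v²) ε_v),
```

calibrated so marginals match the published per-edition tables, with BMI
derived deterministically from weight and height. Loadings (default 0.85
medalist vs 0.45 non-medalist) control group-wise correlation strength.

Groups are compared by one-way ANOVA + Tukey HSD on link weights (per
edition) and on SR (across editions), plus a permutation test on the SR
difference that re-partitions athletes into groups of 3/5 — an extension
added because n = 3 vs 5 makes F-distribution assumptions fragile.

## Worked example

```r
library(specnet)
report <- run_pipeline(pipeline_config(seed = 42))
print(report)
```

prints (output from an actual run):

```
<pipeline_report> 10 networks, 60 nodes, 300 directed links
   edition        group spectral_radius mean_node_eigen_score
1   Sydney     medalist          4.8688                4.8149
2   Sydney non_medalist          2.2975                1.9488
3   Athens     medalist          4.7817                4.7043
4   Athens non_medalist          2.7565                2.3183
5  Beijing     medalist          2.9874                2.6284
6  Beijing non_medalist          2.4038                1.8345
7   London     medalist          4.2419                3.9499
8   London non_medalist          2.8907                2.4316
9      Rio     medalist          3.2596                2.8327
10     Rio non_medalist          1.8895                1.2658
<comparison_result> spectral_radius
         group n   mean     sd
1     medalist 5 4.0279 0.8652
2 non_medalist 5 2.4476 0.3961
  ANOVA: F(1, 8) = 13.7905, p = 0.005926
  direction: medalist mean SR (4.028) >= non_medalist (2.448)
  medalist SR higher in 5/5 editions
warnings:
 - zero-SD variable(s) generated as constants in Rio/non_medalist: olympic_medals
 - Rio/non_medalist: 5 degenerate (zero-variance) pair(s) kept as weight-0 links
```

Reading it: 5 editions × 2 groups give 10 six-node networks (60 nodes, 300
directed links). Every medalist network has a higher spectral radius than
its non-medalist counterpart, and the across-edition ANOVA on the 5-vs-5 SR
values is significant (F(1,8) = 13.79, p ≈ 0.006). The Rio non-medalist
group has a zero-variance medal count, so its five links involving that node
are kept with weight 0 and flagged — which is why its SR is lowest.

Lower-level pieces compose freely:

```r
cohort <- synthesize_cohorts(synthetic_config(seed = 42))
groups <- split_by_medal(cohort[cohort$edition == "Sydney", ])
net    <- build_network(groups$medalist)      # 6 nodes, 15 weighted links
s      <- eigen_system(net)                   # SR, spectrum, Perron vector
node_eigen_scores(s)                          # ranked centrality table
write_report(run_pipeline(pipeline_config(seed = 42)), "results/")
```

A CLI wraps the same pipeline:

```sh
Rscript -e 'specnet::specnet_cli()' synthesize --seed 42 --out cohort.csv
Rscript -e 'specnet::specnet_cli()' analyze --input cohort.csv --out results/
Rscript -e 'specnet::specnet_cli()' all --seed 42 --out results/
```

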