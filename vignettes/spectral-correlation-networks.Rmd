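---
title: "Spectral correlation networks for small athlete groups: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral correlation networks for small athlete groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specnet)
```

## The model

specnet analyses groups of athletes through weighted complete correlation
networks. Six per-athlete variables — age (years), weight (kg), height (cm),
BMI (kg/m², derived), Olympic medal count, reaction time (s) — are the nodes
of a graph whose link weight between nodes $i$ and $j$ is the Pearson
correlation $r_{ij}$ of the two variables across the group's athletes. Each
group's connection matrix $C$ is symmetric with zero diagonal, and every one
of the $p(p-1)/2 = 15$ pairs receives a link: correlations are never
thresholded, so all networks share a single complete topology and stay
directly comparable. Links are bidirectional, so a 6-node network is reported
as 30 directed links.

The summary statistic is the spectral radius $\theta_0$, the largest
eigenvalue of $C$. With non-negative weights (the default; see below),
Perron–Frobenius theory gives the properties the analysis relies on:
$\theta_0$ is real and dominates every eigenvalue in magnitude; its
eigenvector (the Perron vector $v$) can be chosen non-negative; $\theta_0$ is
simple when the support graph is connected; and zeroing any edge never
increases $\theta_0$. Useful bounds follow for symmetric non-negative $C$:
mean weighted degree $\le \theta_0 \le$ max weighted degree, and for the
uniform complete network with common weight $w$, $\theta_0 = (p-1)w$ — so a
6-node network with SR 3.75 corresponds to a mean absolute correlation of
about 0.75.

### Assumptions

* Groups are small (3 medalists, 5 non-medalists): correlations from 3–5
  observations are extremely noisy, which is precisely why the comparison
  operates at the level of whole-network summaries and why a permutation test
  supplements the ANOVA.
* Variables enter on equal footing; no causal direction is implied by a link.
* Race time and velocity are excluded as nodes by default because they
  directly determine finish order; requesting them raises an error unless
  explicitly overridden.

## Tunable parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `weight_mode` | `"absolute"` | absolute / signed | Perron–Frobenius needs non-negative $C$; reports quote weights as positive percentages. Signed spectra are computed on request with a warning, since the guarantees lapse. |
| `medalist_loading` | 0.85 | $[0,1]$ | Latent-factor loading; induces pairwise population correlation $\lambda_i\lambda_j \approx 0.72$, reproducing the observed strong medalist coupling (SR band ≥ 2.91). |
| `non_medalist_loading` | 0.45 | $[0,1]$ | Population correlation $\approx 0.20$, the weak-coupling regime (SR band ≤ 2.51). |
| `n_permutations` | 199 | ≥ 99 | Permutation resolution: smallest attainable $p$ is $1/(B+1)$ = 0.005. |
| `seed` | 42 | 32-bit integer | Every stochastic step derives child seeds from it; a fixed configuration reproduces results bit-identically. |
| `alpha` | 0.05 | $(0,1)$ | Two-sided throughout; no multiple-edition correction is applied, matching the source analyses. |

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws each athlete's variables from a single-latent-factor
Gaussian model,
$$x_{v} = \mu_v + \sigma_v\,(\lambda_v F + \sqrt{1-\lambda_v^2}\,\varepsilon_v),$$
with one shared $F\sim N(0,1)$ per athlete. Means and SDs default to the
published per-edition, per-group tables (5 editions × 2 groups), so marginals
are calibrated to the real finals; the loading is the single interpretable
knob for correlation strength. Medal counts are rounded to a non-negative
integer; BMI is always recomputed as weight/(height/100)² — it is
functionally determined in reality, and deriving it builds in the realistic
strong BMI–weight correlation the analysis must tolerate. Velocity is derived
as 50 m / race time. Finish ranks are assigned within each group by race time
(medalists 1–3, non-medalists 4–8).

Limitations a green test does **not** paper over:

* Real athletes are not Gaussian draws, and a single factor cannot produce
  the heterogeneous signed correlation patterns of real groups — only the
  overall coupling level. Generator-based tests establish that the pipeline
  recovers a known coupling contrast, not that the published SR values are
  reproduced (the per-athlete data needed for that are not printed anywhere).
* Rounding and clipping medal counts at zero biases that variable's moments
  when $\mu$ is small relative to $\sigma$ (e.g. a group at $1.8 \pm 2.88$);
  marginal-calibration checks therefore cover the continuous variables. The
  rounded-Gaussian choice (rather than Poisson) was kept because the source
  tables publish means and SDs, not rates, and rounding preserves the
  latent-factor coupling.
* With unit loadings the continuous variables are exact affine images of the
  latent factor, hence pairwise $|r| = 1$ exactly; the rounded medal count is
  a step function of $F$ and is exempt from that exactness.

## Numerical choices

* **Eigen-solver.** `eigen(symmetric = TRUE)` (LAPACK) on the validated
  symmetric matrix. Its SR is property-tested to $10^{-8}$ against an
  independent oracle: characteristic-polynomial coefficients from the
  Faddeev–LeVerrier recursion rooted by `polyroot` (Jenkins–Traub) — a route
  that shares no code with the solver.
* **Degenerate correlations.** A zero-variance variable (e.g. a group where
  nobody holds a medal) makes its correlations undefined; these become
  weight-0 links, recorded per pair and surfaced as warnings, rather than
  dropped nodes — keeping all networks on the same 6-node topology.
* **Perron-vector orientation.** The principal eigenvector is flipped so its
  largest-magnitude entry is positive, then unit-normalised; for a
  non-negative irreducible matrix this is the Perron vector.
* **Per-node scores.** "An eigenvalue per node" is not standard linear
  algebra; the implemented per-node quantity is the eigenvector-centrality
  score $\theta_0 v_i / \max_j v_j$, so the most central node scores exactly
  $\theta_0$. The network-level companion, `mean_node_eigen_score`, is the
  mean of these scores — *not* the mean of the spectrum, which is identically
  zero for any zero-diagonal matrix and therefore cannot be a useful axis.
* **Ties.** Node rankings break ties stably by node-label order.
* **Permutation p.** $p = (1 + \#\{|\Delta_{perm}| \ge |\Delta_{obs}|\})/(B+1)$
  over random re-partitions into groups of the original sizes; valid for any
  $B$, two-sided, deterministic under a seed. Shuffles on which the statistic
  is undefined are redrawn (at most 10 times) and counted. Note the smallest
  attainable $p$ exceeds $1/(B+1)$ in practice whenever the pool is small
  enough that resampling can redraw the observed partition — with 8 athletes
  split 3/5 there are only 56 partitions, and a redraw counts in the
  numerator.
* **ANOVA degeneracy.** All-zero within-group variance is an error (F is
  0/0), as is any group with fewer than 2 observations.

## Design choices that were genuinely open

* **Absolute vs signed weights.** The source analyses report weights as
  positive percentages and lean on Perron–Frobenius properties, which demand
  non-negativity, but display signed correlation heat maps. Default:
  absolute weights for all spectral work, with the raw signed matrix retained
  on every network and a signed mode available end to end.
* **Per-edition vs pooled link-weight ANOVA.** The source is ambiguous
  (significance is quoted per edition); specnet runs the link-weight
  comparison per edition, and the SR comparison pools editions as a separate
  operation — the two units of analysis are never conflated.
* **Permutation supplement.** Not part of the source analyses; added and
  clearly labelled because 15 correlated link weights and 3-vs-5 athlete
  groups strain the independence assumptions behind the F distribution.

## Known limitations

Single-factor synthesis cannot calibrate individual link weights (the source
figures print no per-pair numbers, only SR values); conclusions from
synthetic runs are about orderings and recovery rates, not about matching
published SRs. The ANOVA on 15 link weights treats correlated quantities as
exchangeable observations — inherited from the source design and the reason
the permutation test exists. No Laplacian spectrum, spectral clustering,
partial correlations or time-lagged coupling: the method is a static
between-group comparison of correlation structure.
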