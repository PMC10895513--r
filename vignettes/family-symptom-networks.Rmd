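---
title: "Family symptom networks: models, estimation and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family symptom networks: models, estimation and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Depression symptoms in mothers and fathers of young children co-occur, and
both are linked to later emotional difficulties in their children. famnet
analyses this co-occurrence at the *symptom* level: each parent's ten
Edinburgh Postnatal Depression Scale (EPDS) items and a child
emotional-difficulties factor are nodes of an undirected network whose
edges are partial correlations — the association between two symptoms after
conditioning on every other symptom in the network. Symptoms whose
remaining associations cross the mother/father boundary ("bridge
symptoms") are candidate transmission points for within-family symptom
reinforcement.

The cohort data such an analysis is usually run on are access-restricted,
so the package ships a synthetic family generator with a *known* network.
Every stage of the pipeline — estimation, centrality, stability,
replication — is then testable by parameter recovery against that truth.

## Model and estimation

### Gaussian graphical model

For standardized variables with concentration (inverse covariance) matrix
$K$, the edge weight between nodes $i$ and $j$ is the partial correlation

$$ w_{ij} = -\frac{K_{ij}}{\sqrt{K_{ii} K_{jj}}}, $$

and $w_{ij} = 0$ exactly when the symptoms are conditionally independent
(given Gaussianity). Because symptom items are ordinal (1–4) and
right-skewed, the input correlation matrix is Spearman's rank correlation
on complete rows, computed as the product-moment correlation of
average-rank-transformed columns. Rank-correlation matrices can be
indefinite; they are repaired by clipping eigenvalues at $10^{-6}$ and
re-standardizing to unit diagonal.

### Constrained maximum likelihood

Given a candidate edge set, the maximum-likelihood concentration matrix
with zeros on all non-edges is fitted by iterative proportional scaling
(IPS): cycling over edge cliques, each $2 \times 2$ block of $K$ is
updated so the implied covariance matches the sample correlation on that
block; isolated vertices get the analogous scalar update. Convergence is
declared when the largest entrywise change in one sweep falls below
$10^{-8}$ (measured relative to the magnitude of $K$, so fits on repaired,
nearly singular matrices terminate; the saturated model is closed-form,
$K = S^{-1}$). The profile log-likelihood is
$\tfrac{n}{2}(\log\det K - \operatorname{tr}(S K))$ up to a constant fixed
across models.

### Stepwise BIC model selection

Model search is greedy and unregularised: starting from a graph, all
single-edge additions and removals are evaluated by refitting and scored
with

$$ \mathrm{BIC} = -2\,\ell + m \log n, $$

where $m$ counts edges only (the diagonal is common to all models and
cannot change rankings). The change with the largest BIC decrease is
applied; the search stops at a local BIC minimum. Ties within $10^{-10}$
break toward removal, then lexicographic edge order, making the search
deterministic. The default start graph keeps the edges whose
saturated-model partial correlations pass a Fisher-z test at
$\alpha = 0.01$; this start typically lands within a few changes of the
BIC optimum and is switchable to the empty graph. On problems small
enough to enumerate (3 nodes, all 8 graphs), the stepwise search attains
the exhaustive-search BIC minimum in at least 95% of random datasets — one
of the package's acceptance checks.

### Centrality and bridges

Strength is the absolute sum of a node's incident edge weights; expected
influence is the signed sum, and the two coincide on all-positive
networks. Bridge strength restricts the sum to edges crossing community
boundaries (mother vs father vs child). The top 30% of parent symptoms by
bridge strength are flagged as bridges; the flag count uses
$\lceil 0.3\,p \rceil$ with inclusive ties, because the endpoints of a
single cross-parent edge tie *exactly* and excluding one of them would be
arbitrary. When the child factor node is present it is excluded from the
flagging denominator (the analysis flags *parent* bridge symptoms), which
is switchable.

### Stability and replication

* **Edge bootstrap** — nonparametric row resampling; every replicate
  re-runs the *full* pipeline (Spearman, repair, stepwise selection), so
  the intervals reflect model-search variability, not just weight noise.
  Intervals are percentile 2.5/97.5%; an edge absent from a replicate
  contributes weight zero. A consequence worth knowing: for a borderline
  edge selected in under 2.5% of replicates, the percentile interval can
  be $[0, 0]$ while the bootstrap mean is a small positive number, so the
  interval does not always bracket the mean.
* **Case-dropping bootstrap and CS** — for each drop proportion in
  $\{0.05, 0.15, \dots, 0.75\}$, subsamples without replacement are
  re-estimated and the correlation of subsample centralities with the
  full-sample ones recorded. The CS coefficient is the largest tested
  proportion at which at least 95% of subsamples correlate $\ge 0.7$;
  above 0.25 counts as stable, above 0.5 preferred.
* **Network comparison test (NCT)** — two groups are compared on global
  strength (sum of absolute edge weights) and structure (maximum absolute
  edge-weight difference). The null distribution reassigns rows to groups
  of the original sizes and re-estimates both networks per permutation;
  p-values use the add-one formula $(1 + \#\{perm \ge obs\})/(1 + B)$ and
  are never exactly zero. Split-half replication halves the sample at
  random (sizes within one) and runs the NCT on the halves.

## The synthetic generator

`build_true_network()` draws within-parent edges at a configurable
density with uniform weights, places cross-parent edges exactly at the
designated bridge pairs, and (optionally) links a child factor node to
named parent symptoms. If the implied precision $I - P$ is not positive
definite, all off-diagonals are shrunk by 0.95 per step (at most 100
steps) until its smallest eigenvalue reaches $10^{-6}$ — deterministic and
sparsity-preserving. `partial_to_covariance()` inverts the GGM identity
and is round-trip tested against a regression-residual (Schur-complement)
oracle.

`sample_family_data()` draws latent vectors from the implied multivariate
normal and discretizes parent nodes at cutpoints on the latent scale.
Calibration choices, made once and exposed as arguments:

* **Cutpoints (0.25, 1.0, 1.9)** produce right-skewed endorsement
  (roughly 60/24/13/3% across the four categories), the typical shape of
  postnatal depression items in community cohorts, where item-level
  endorsement tables are not available to copy.
* **Study truth** (`family_truth()`): nine symptoms per parent,
  within-parent density $55/72$, within weights uniform on 0.04–0.41 (the
  published edge-magnitude band), six same-symptom cross-parent bridge
  edges on 0.04–0.09 (the published cross-parent band), child links to
  mother guilt/anhedonia/panic/sadness and father overwhelm. The
  positive-definiteness shrinkage contracts these nominal bands by about
  0.6 at this density, and a uniform weight distribution has a larger
  mean than the heavily right-skewed empirical one — the emulation targets
  the *structure* (node count, communities, bridge placement, magnitude
  range), not every printed summary.
* **Child waves**: three wave scores $\mathrm{round}(1.5 + 2(\lambda z +
  \varepsilon))$ clipped to $[0, 10]$, with loadings $\lambda = 0.75$ and
  noise SD 0.6. On the latent scale this puts inter-wave correlations at
  $0.5625/(0.5625 + 0.36) \approx 0.61$; rounding and clipping of the
  0–10 scale attenuate the observed rank correlations by roughly 0.88, to
  about 0.54 — inside the published 0.49–0.59 band — and yield a
  three-wave KMO near 0.70. Cronbach's alpha across
  the three wave totals is about 0.77; this is *not* comparable to a
  published within-wave item alpha (a different item set).
* **Demographics**: an optional Bernoulli child-sex column with
  probability $2204/4492 \approx 0.491$, the cohort's share of girls.
* `ordinal_thresholds = NULL` keeps parent nodes continuous (the latent
  scale). This mode exists because discretisation attenuates the
  estimand itself: rank correlations of ordinalized items estimate a
  shrunken version of the latent correlation, so experiments that probe
  the *bootstrap's* calibration (does a 95% interval cover the true edge
  95% of the time?) are run on the latent scale. Relatedly, the
  estimation drivers resolve their correlation method from the table's
  scale (`corr_method = "auto"`): Spearman for ordinal symptom tables —
  the rank transform is what the ordinal, skewed data call for — but
  plain product-moment correlation when every column is continuous,
  where ranking has no justification and only injects the
  $(6/\pi)\arcsin(\rho/2)$ bias into an otherwise unbiased estimand.
  Both can be forced explicitly.

What the generator does **not** emulate: item-level missingness and
imputation, response styles and local item dependence, sampling biases of
cohort attrition, and genetic confounding. Passing recovery tests
therefore show the *estimator* works under the stated model, not that the
model captures every feature of real cohort data.

## Numerical and design choices

* Complete-case rows for all correlation work (imputation is out of
  scope; the emulated cohort is a complete-data subsample by design).
* Redundancy screening defaults: candidate pairs at Spearman
  $r \ge 0.50$ within a parent community, dependent-correlation tests
  (Hittner back-transformed-average variant by default, Steiger's plain
  average switchable) against the remaining items of that community, flag
  when under 25% of tests reject at $\alpha = 0.05$. The published
  analysis resolved flagged pairs by expert review; that step is
  represented by the `drop_items` configuration list, not automated.
* Child factor scores use the regression method (Bartlett switchable);
  the one-factor ML fit is just-identified for three indicators, and a
  Heywood solution clamps the uniqueness at $10^{-6}$ with a warning.
* The NCT counts permutations $\ge$ observed with a $10^{-12}$ slack so
  that exactly tied statistics (e.g. identical groups) give $p = 1$.
* All randomness flows from one integer seed per entry point;
  sub-streams (latent draw, child noise, demographics, bootstrap,
  permutations) use small fixed offsets from it.

## Problem sizes used in tests and the acceptance script

Every replicate of a bootstrap or permutation re-runs the full selection,
so simulation sizes are chosen at desk scale: the cohort emulation runs
once at $n = 4492$ with 18/19 nodes; edge-recovery benchmarks use an
18-node strong-signal truth (all $|w| \ge 0.15$, within-density 0.25) at
$n = 4000$ over 20 seeds; NCT calibration uses 6 nodes, two groups of
250, 200 permutations and 200 simulations; bootstrap coverage uses 6
continuous nodes at $n = 2000$ with $B = 200$ over 20 simulations; the
case-dropping benchmark uses a 10-node strong-signal truth at $n = 4000$
with $B = 100$ per drop proportion. The split-half replication of the
full 18-node cohort emulation uses 100–200 permutations (the analysis
scripts note the runtime).

## Known limitations

* Spearman-based estimation on ordinal items is consistent for the
  rank-metric network, which is attenuated relative to the generating
  latent network; recovery benchmarks therefore test the *sparsity
  pattern* and approximate magnitudes, not exact weights.
* Greedy stepwise search finds a local BIC minimum; the exhaustive
  equivalence is verified only where enumeration is feasible.
* IPS converges slowly on repaired, nearly singular correlation
  matrices; candidate fits that fail to converge are skipped during the
  search rather than aborting it (the saturated fit is closed-form).
* The CS coefficient is quantized to the tested grid and capped at its
  maximum (0.75 by default).
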