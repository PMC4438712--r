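---
title: "Maximum-flow reliability, education, and subnetwork inference: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-flow reliability, education, and subnetwork inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowreserve)
```

## The model

flowreserve analyzes structural brain networks through the lens of *network
reliability*. A subject's white-matter connectome is an undirected binary
graph $G = (V, E)$: nodes are parcellated brain regions (90 under the AAL
atlas), and an edge connects two regions when tractography finds a fiber
bundle of at least three streamlines between them (the `binarize()`
threshold; three is the conventional cutoff that suppresses false-positive
connections from tractography noise).

For a binary graph the maximum flow between nodes $i$ and $j$ equals, by
Menger's theorem, the number of pairwise **edge-disjoint paths** between
them. It measures route redundancy: how many independent channels remain if
individual connections fail. `pairwise_flow()` computes this value for every
pair of regions; the cognitive-reserve hypothesis is then operationalized as
a statistical association between these per-pair flow values and the
subject's years of education.

The analysis has two stages:

1. **Edgewise association.** For every node pair, the partial Pearson
   correlation between education (years, 0--22) and the subjects' flow
   values for that pair, residualizing both on the adjusted covariates (age
   and sex; additionally CDR-SOB, the Clinical Dementia Rating Sum of
   Boxes, in a dementia group so that the education effect is not
   confounded with clinical severity). This yields a $V \times V$
   correlation matrix (`education_flow_correlation()`).

2. **Suprathreshold cluster-size inference.** Node pairs whose correlation
   exceeds a threshold $r_0$ (strictly greater for the positive direction;
   strictly smaller than a negative $r_0$ for the negative direction) form
   a subgraph; two surviving pairs are adjacent when they share a region,
   and each connected component is a cluster whose *size* is its edge
   count. The maximum cluster size is the test statistic. Its null
   distribution comes from $M$ random permutations of the education vector
   across subjects — covariates and flow matrices stay bound to their
   subjects — and the familywise-error-corrected p-value is
   $p = (1 + \#\{\text{null} \ge \text{observed}\})/(M+1)$
   (`cluster_size_test()`).

Because the maximum cluster size is a single familywise statistic, a
significant result identifies the whole cluster as the
education-associated subnetwork; the procedure controls the probability of
reporting any subnetwork under the null.

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| fiber threshold | 3 | streamlines | conventional rule: an edge needs a bundle of three or more tracts |
| `r_threshold` | 0.32 positive / −0.30 negative | correlation | working values for the two directions; always explored with `threshold_sweep()` because cluster inference is threshold-dependent |
| `n_permutations` (M) | 5000 | count | at M = 5000 a p-value near 0.026 carries a parametric 95% half-width of about 0.004; the interval is `p ± 1.96·sqrt(p(1−p)/M)` |
| `alpha` | 0.05 | — | familywise level |
| covariates | age, sex (+ cdr_sob for an AD-labelled group) | — | education must not proxy demographics or disease severity |
| subsample `fraction` | 0.9 | — | leave-10%-out reproducibility |

The threshold sweep reports the Jaccard overlap of the subnetworks at
consecutive thresholds; a threshold is trustworthy when neighbouring
choices return essentially the same edge set. Too low a threshold lets
chance clusters grow large under permutation and costs power; too high a
threshold drops genuinely associated pairs.

## The synthetic cohort generator

No imaging data ship with the package; `generate_cohort()` produces cohorts
with the statistical structure the analysis assumes, so every stage is
testable end to end.

* **Anatomy** (shared by all subjects of a cohort, drawn from
  `structure_seed`): a modular backbone on $V = 90$ nodes — 6 modules, 5:1
  within:between edge density, overall density 0.17 giving mean degree
  about 15 — plus the *planted machinery*: a hub node (index 63, the left
  supramarginal gyrus slot, when $V = 90$), 8 hub--partner pairs, and 2
  dedicated relay nodes per pair. Two cohorts given the same
  `structure_seed` share their anatomy, which is the setting in which
  group comparisons are meaningful.
* **Subjects**: independent edge flips at rate $\varepsilon = 0.05$ per
  cell outside the machinery; education drawn as a rounded normal clipped
  to 0--22 (NC-like preset mean 11.33, sd 4.77; AD-like 10.18, 5.41); age,
  sex, CDR-SOB drawn independently of education and redrawn (bounded
  retries) while their sample correlation with education reaches 0.2, the
  analogue of recruiting groups whose education is not confounded with
  demographics. Education itself is never redrawn.
* **Planted effect**: for each pair (hub $h$, partner $j$) and each of its
  relays $r$, the 2-path $h\!-\!r\!-\!j$ is present with probability
  $\mathrm{logistic}(\alpha_0 + \beta z_s)$, where $z_s$ is the subject's
  standardized education, $\alpha_0 = 0$ (baseline inclusion 0.5) and
  $\beta$ = `effect_beta` sets direction and strength. Each present relay
  path is one more edge-disjoint route, so hub-pair maximum flow is
  stochastically increasing (or, for $\beta < 0$, decreasing) in
  education.
* **Hub anchoring**: the hub participates in the backbone only through 2
  fixed anchor edges. Its min-cut toward any well-connected region is
  therefore carried by the relay routes, concentrating the education
  effect on the hub's node pairs. Without this, degree fluctuations of
  partners and relays broadcast the correlation across the whole graph
  and no single region emerges as the subnetwork's hub. A consequence is
  that the mechanism needs the backbone degree to exceed the hub's
  expected degree ($2 + \text{pairs}\times\text{relays}\times 0.5 \approx
  10 < 15$); at much smaller $V$ choose a higher `base_density`
  accordingly.
* **Calibration**: `effect_beta = 0.26` is fixed so that the mean planted-
  pair partial correlation at $n = 80$ is about 0.44, a realistic
  within-subnetwork effect size for this design; `effect_beta = 0` is the
  null generator (`null_cohort()`), used for familywise-error calibration.
* **Fiber counts**: every synthetic edge carries exactly 3 streamlines, so
  binarization at the default threshold is the identity; with
  `graded_fibers = TRUE` counts are dispersed (machinery ≥ 5, other edges
  1 + Poisson(2.5)) so fiber-threshold sweeps become informative.

**What the generator does not emulate.** Spatial geometry and tract
anatomy, distance-dependent connection probabilities, realistic FA values
(the optional FA matrix is a constant 0.4), disease-related topology
change, and any direct effect of age or sex on the network. Passing tests
therefore show that the statistics behave correctly on networks with
planted flow-education structure — not that the pipeline recovers effects
in real diffusion MRI, where confounds, registration error, and
tractography biases add failure modes the simulation does not contain.

## Numerical and algorithmic choices

* **Max flow** is computed on the directed graph with two opposite unit
  arcs per undirected edge, by BFS augmenting paths; results are exact
  integers. All-pairs values use Gusfield's flow-equivalent tree ($V-1$
  max-flow computations instead of $\binom{V}{2}$); the equivalence is
  enforced in the test suite against a brute-force minimum-cut oracle
  (exhaustive on 5-node graphs, random $G(8, 0.4)$ ensembles).
* **Partial correlation** residualizes via QR decomposition. A pair whose
  flow residuals are numerically constant (tolerance `1e-8` relative)
  carries no statistic: it is masked, not set to 0, and masked pairs can
  never enter a suprathreshold set — constant-flow pairs would otherwise
  seed spurious clusters.
* **Permutation scheme**: only education is permuted; covariates stay with
  their subjects, and the flow-side residuals are precomputed once per
  test. The add-one p-value convention never returns 0 and is mildly
  conservative.
* **Strict inequality** at the correlation threshold in both directions.
* **Tie-breaking**: equally large clusters are resolved in favour of the
  cluster containing the lexicographically smallest node pair; ranked flow
  tables break ties by region label; hub metrics report ties as lists and
  never break them silently.
* **Group comparison of correlations** uses Fisher's z with effective
  sample size $n - 3 - k$, subtracting the $k$ adjusted covariates since
  the inputs are partial correlations. A correlation of $\pm 1$ gives an
  infinite z, reported as p = 0.
* **Edgewise ANCOVA** is one linear model per pair,
  `flow ~ group + covariates`, equivalent to classical one-way ANCOVA with
  one between-group degree of freedom; "generalized linear regression" of
  the summary measures is the Gaussian identity-link model, appropriate
  for continuous sums.
* **Bonferroni** multiplies by the number of *valid* pairs only.
* **Sub-seeds**: threshold sweeps, fiber sweeps and subsample replicates
  derive their seed as `seed + index`, so any row can be reproduced in
  isolation.
* **Betweenness** is raw (unnormalized) shortest-path betweenness with
  fractional credit across tied shortest paths; closeness is
  $(N-1)/\sum d$. Rankings — the use made of hubs — are unaffected by
  normalization choices.

## Design decisions where the design was open

* The ranking of node pairs by flow aggregates across subjects by the
  group mean (median by option).
* Subsample balance ("no significant education-demographics correlation in
  the subgroup") is achieved by test-and-redraw with a bounded retry
  count, not by constrained sampling.
* The per-subject "average flow" in the group comparison averages over all
  $\binom{V}{2}$ pairs by default; an edges-only variant is a flag.
* The AAL-90 label table ships in `inst/extdata/`; input matrices must
  follow that row order for region names in reports to be meaningful.
  Other dimensions get generic labels `R001...`.

## Problem sizes used by the test suite

The suite exercises the full study scale where it matters and smaller
ensembles elsewhere: planted-effect recovery runs 25 replicate cohorts of
80 subjects by 90 nodes (plus a 10-replicate negative-direction mirror) at
M = 500; familywise-error calibration uses 200 null cohorts of 40 subjects
by 30 nodes at M = 500; the exhaustive-permutation check enumerates all
5040 orderings of a 7-subject cohort; oracle comparisons cover all 1024
graphs on 5 nodes and 200 random 8-node graphs. `scripts/acceptance.R`
reports quantities averaged over 5 replicate cohorts per direction.

## Known limitations

* Binary networks only: fiber-count or FA-weighted capacities are read and
  summarized but not used as flow capacities.
* The permutation test assumes exchangeability of education across
  subjects given the covariates; it does not re-residualize under
  permutation (no Freedman–Lane step), matching the plain
  permute-the-predictor scheme.
* Cross-group application of a subnetwork reuses the edge set, not the
  threshold machinery; its mean correlation is descriptive, without a
  p-value.
* The generator's planted effect is concentrated on one hub by
  construction; analyses of real data should expect more diffuse effects
  and correspondingly lower recall of any single region.
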