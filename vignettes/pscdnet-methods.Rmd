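---
title: "Methods: network and imaging-biomarker analysis of delayed post-stroke cognitive decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network and imaging-biomarker analysis of delayed post-stroke cognitive decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

A minority of patients who remain cognitively normal for a year or more
after a mild stroke later develop progressive cognitive decline. Studying
this delayed-onset group leads to a nested case-control design: decliners
are identified from longitudinal MMSE trajectories inside a stroke
registry, matched with non-declining patients on age and initial stroke
severity, and characterized with resting-state fMRI (functional network
architecture), amyloid PET (subthreshold tracer retention) and FLAIR MRI
(white-matter hyperintensity burden). `pscdnet` implements the
quantitative stages of that workflow — everything downstream of spatial
normalization — as seed-deterministic, tested functions, together with a
synthetic cohort generator so the full pipeline can be exercised and
validated without access to patient data.

## Functional connectivity and graph attributes

Regional BOLD time series (time × region matrices) are correlated
pairwise (`compute_fc()`) and, where a within/between-network contrast is
needed, Fisher z-transformed (`fisher_z()`), with |r| clipped at
1 − 10⁻⁷ so that duplicated signals produce a large finite z rather than
an infinity that would poison means. The diagonal is stored (1 on the r
scale, 0 on the z scale) but excluded from every aggregate.

Graphs are built by proportional density thresholding
(`threshold_by_density()`): the ⌊d·n(n−1)/2⌋ strongest positive
correlations become unweighted edges, so subjects contribute graphs of
identical size at each density d ∈ {0.05, 0.10, 0.15, 0.20}. Three
choices here were genuinely open and are worth stating:

* **Binarization.** Attributes are computed on binary graphs, the
  convention of the brain-connectivity-toolbox lineage this analysis
  follows; weighted variants are out of scope.
* **Negative correlations** are never edge candidates: ordering edge
  strength across mixed signs is ill-defined, and the segregation
  literature the pipeline builds on uses positive weights.
* **Ties** are broken by lexicographic node-index order, making the edge
  set a pure function of the input (and the density-nesting property
  `edges(d₁) ⊆ edges(d₂)` for `d₁ ≤ d₂` exactly testable).

Five conventional attributes are computed per density: characteristic
path length and global efficiency (integration), and modularity
(Louvain), mean clustering coefficient and transitivity (segregation).
Thresholded functional graphs at low density are routinely disconnected,
so path length averages over *reachable* ordered pairs only and
efficiency counts unreachable pairs as zero — the standard conventions
that keep both defined; an edgeless graph still fails path length loudly.
A node of degree < 2 contributes a clustering coefficient of 0.

Each attribute is normalized against a null distribution from 100 (by
default) degree-preserving double-edge-swap rewirings
(`rewire_null()`, ~10 accepted swaps per edge), as
`normalized = raw / mean(null)`. Characteristic path length is inverted
so that lower values represent worse function; its normalized value is
`mean(null CPL) / raw CPL`, which makes all five normalized attributes
point the same way (larger = more favourable topology). The ensemble
*mean* (not median) is the normalizer; the null SD is retained for
diagnostics. Graphs with no valid swap (stars) yield a degenerate
ensemble of copies, flagged rather than hidden.

Louvain is run with 10 randomized-order restarts (seeded), keeping the
highest-Q partition, because the greedy algorithm is order-dependent.
One known limitation follows from the algorithm itself: greedy
aggregation from singletons cannot reach every partition, so on a small
fraction of graphs the returned Q is strictly below the exhaustive
optimum no matter how many restarts are used. The test suite documents
one such 7-node graph; for 265-node functional graphs the restart scheme
is the practical mitigation.

## System segregation

For a canonical partition of nodes into the seven cortical resting-state
networks (VN, SMN, DAN, VAN, LN, FPN, DMN), system segregation of a
module is

$$\mathrm{SysSeg} = \frac{\bar{Z}_w - \bar{Z}_b}{\bar{Z}_w}$$

with $\bar{Z}_w$ the mean Fisher-z connectivity over within-module pairs
and $\bar{Z}_b$ over pairs linking the module to the other analysis
networks. It is computed on the full z matrix — no thresholding.
Decisions (each exposed as an argument):

* **Negative z values are excluded** from both means by default,
  following the segregation literature; retention is a flag.
* **Non-analysis pools** (subcortical, cerebellum, brainstem) stay out of
  the between-network means by default, since the analysis networks are
  the seven cortical systems.
* **The overall value pools pairs** across networks (every cross-network
  pair counted once) rather than averaging per-network ratios; the
  alternative is available via `overall_method = "mean_networks"`.

A module whose within-mean is non-positive reports `NA` with the reason,
never a spurious ratio.

## Spring-embedded layout

`spring_layout()` is a Fruchterman–Reingold iteration: seeded uniform
start on the unit square, repulsion k²/d between all pairs, attraction
d²/k along edges, k = 1/√n, displacement capped by a temperature cooling
linearly from 0.1 to 0 over the budget (default 500 iterations), with an
early stop when the largest step falls below 10⁻⁴. The update is a
capped gradient descent on the potential
Σ_edges d³/(3k) − Σ_pairs k² ln d, whose trace is returned so
convergence ("energy non-increasing over the final stretch") is a
testable property rather than a claim. Isolated nodes receive
coordinates like any other node and render as dots without lines.
Figure rendering defaults to reporting the layout density in a caption
line; a sparser density (0.025) than the metric densities is the usual
choice for legible plots.

## PET SUVR and WMH quantification

All voxel operations assume volumes already live on one grid, enforced
by a `space_tag` plus shape check. Regional SUVR is the region's mean
intensity divided by the reference-region mean (cerebellar gray matter
in this design, supplied as an explicit label — no segmentation is
performed). The global SUVR averages four composites (frontal,
cingulate, lateral parietal, lateral temporal), each the *unweighted*
mean of its member regions' SUVRs — the composite map names regions, not
voxels — with volume weighting available by flag. WMH burden is
100 × lesion voxels / brain voxels, and `lesion_frequency_map()`
accumulates per-voxel lesion counts across subjects with the pooled
proportion relative to total brain volume.

## Clinical classification and statistics

Decliners show a decline of ≥ 3 MMSE points annually
(annualized as 12·Δ/months) or an absolute drop of ≥ 5 points;
non-decliners decline at most 1 point per year *and* fewer than 3 points
absolutely; everything else is indeterminate. Controls are matched
greedily in seeded random order within ±3 years of age and ±2 NIHSS
points, nearest by |Δage| + |ΔNIHSS|, never force-paired.

Group comparisons use Student's t or the Wilcoxon rank-sum test for
continuous variables — the source analysis used both without stating a
rule, so the default policy is rank-sum whenever either group has fewer
than 15 observations, overridable — and χ² with a Fisher-exact fallback
(any expected cell < 5) for categorical ones. Associations default to
Spearman's ρ (how they are reported in this literature) with Pearson
behind a flag. The group-specific WMH effect is tested by OLS with a
group × WMH interaction. The voxel-wise amyloid model is a per-voxel
logistic regression, group (decliner = 1) on age, sex, education and
voxel SUVR, reporting the Wald statistic and two-sided p for the SUVR
term; voxels with non-convergence or complete separation are flagged and
excluded from the p < 0.05 mask, which is deliberately uncorrected
(exploratory convention; an FDR flag exists but is off by default).

## The synthetic cohort generator

`generate_cohort()` emulates exactly the statistical structure the
analysis assumes, nothing more:

* **BOLD**: multivariate-normal draws from a two-value block correlation
  matrix — `r_within` (default 0.5) inside networks, `r_between`
  (default 0.1) across, typical resting-state magnitudes. Decliners have
  `r_within` reduced by `segregation_shift` (default 0.15) and a
  `mixing_fraction` (default 0.2) of nodes reassigned to random other
  modules before covariance construction, emulating intermingled
  canonical modules. The target matrix is repaired to PSD by clipping
  eigenvalues at 10⁻¹⁰ and renormalizing the diagonal when needed (the
  two-value family is PSD for 0 ≤ r_b ≤ r_w < 1, so repair is a
  safety net). Default T = 240 timepoints, an 8-minute run at TR = 2 s.
* **Ground truth**: each subject's `generating_segregation` is the
  closed-form pooled SysSeg of the generating z matrix under the
  canonical partition (computed from pair counts, so it is exact).
* **Volumes**: an ellipsoidal brain (~10⁴ voxels at the default 32³
  grid), eight cortical label regions plus a reference region, PET
  intensity flat at the subject's target SUVR relative to reference, and
  a lesion mask of 2³-voxel blobs whose count is chosen to hit the
  subject's target WMH fraction (granularity ~0.08 %). The recorded
  WMH fraction and global SUVR are *re-derived from the generated
  volumes* through the package's own quantification functions, so
  record and image never disagree.
* **Clinical records**: age, sex, education, NIHSS, baseline MMSE,
  evaluation interval, APOE e4 and the WMH/SUVR target distributions are
  drawn per group from the published cohort's Table-1 summaries
  (e.g. decliner age 69.2 ± 3.6, WMH lognormal with median 0.58 % vs
  0.52 % — deliberately *near-identical* across groups, because the
  published groups did not differ in WMH level, only in its coupling to
  cognition). MMSE change is linear in generating segregation, WMH
  fraction and global SUVR plus N(0, noise_sd²) noise, with the WMH
  coefficient applied per group (defaults −6 in decliners, 0 in
  non-decliners). The intercept and slopes are calibrated so expected
  change is ≈ −6 points in decliners and ≈ 0 in non-decliners — the
  published medians. The effect sizes themselves are free parameters of
  the generator, not calibrated claims: the source study reports no
  coefficients linking the three substrates to MMSE decline.
* **Consistency contract**: subjects whose simulated trajectory fails
  the classification rule for their intended group get their MMSE noise
  redrawn (bounded retries); below 90 % agreement the cohort
  specification is reported unsatisfiable. Null configurations (zero coefficients) legitimately
  carry no group signal and disable the contract via
  `enforce_classification = FALSE`.
* **Determinism**: one master seed drives everything; per-subject
  network streams are keyed by the *within-group index only*, so a null
  configuration gives decliner j and non-decliner j identical network
  parameters — group-mean comparisons under the null are exact, not
  approximate.

What the generator does **not** emulate — hemodynamics, scanner noise,
spatial autocorrelation, realistic anatomy, registration error —
bounds what passing tests show: they validate the estimators and the
pipeline's contracts, not robustness to real acquisition artifacts.

## Problem sizes used by the tests and acceptance script

Chosen as desk-scale versions of the study conditions: oracle
equivalence uses 200 random graphs of ≤ 7 nodes; the null-normalization
check a 100-node random matrix with 100 rewirings; gap recovery a
10-point grid at T = 2000 on 70 nodes; the cohort-level comparison 15
decliners vs 15 non-decliners at the full 265-node parcellation with 20
rewirings and 5 Louvain restarts per graph (null means have SDs in the
third decimal, so the smaller ensemble does not move them); interaction
power 200 record-level replicates at 30/30; the voxel-wise type-I
simulation 1000 voxels × 30 subjects.

## Known limitations

* **Normalized global efficiency cannot mirror the other four
  attributes in this generator family.** Degree-preserving rewiring
  shortens paths of any modular graph, so the *more* segregated group
  (non-decliners) always sits further below its null on efficiency than
  the less segregated group. On synthetic cohorts the decliner group is
  therefore numerically *higher* on normalized efficiency while lower on
  the other four attributes — the empirical finding of lower efficiency
  in decliners presumably reflects features (regional disconnection,
  noise structure) that a pure block-covariance generator does not
  carry. The test suite records this openly rather than masking it.
* Louvain's greedy aggregation can miss the global modularity optimum on
  specific small graphs (documented above).
* The annualization rule (12·Δ/months) and the matching algorithm
  (greedy nearest within tolerance) are the package's own choices where
  the source design is silent; both are flagged at the call sites.
* BAPL visual scores are carried as recorded fields only; nothing
  computes them.
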