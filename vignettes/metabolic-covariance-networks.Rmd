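---
title: "Metabolic covariance brain networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance brain networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metcovnet)
```

## The model

A metabolic brain network describes how regional glucose metabolism
covaries **across subjects** within a group. Given a group's subjects-by-ROIs
table of FDG-PET standardized uptake value ratios (SUVR; tracer uptake
normalized to a reference region, dimensionless and typically between 0.5
and 2.0), the edge between ROIs $i$ and $j$ is the sample Pearson
correlation $r_{ij}$ of their SUVR columns. This yields a fully weighted,
symmetric $R \times R$ adjacency matrix per group — the same construction
used for cortical-thickness covariance networks, applied to metabolism. A
positive edge means the two regions rise and fall together across people;
a negative edge means they trade off; an edge near zero means their
relative levels are inconsistent across people.

Edges are kept **signed and fully weighted**: we deliberately do not
threshold into binary graphs, because the quantity of interest is the
strength of covariation itself, and sparsification discards exactly that
information.

### Strength on the Fisher-Z scale

Every aggregate of correlations — global, per-ROI ("regional"), restricted
to long-distance edges, or within/between intrinsic connectivity networks —
is computed by averaging Fisher-Z transformed values
$z_{ij} = \operatorname{artanh}(r_{ij})$ and transforming the average back:

$$\bar r = \tanh\!\Big(\tfrac{1}{|E|}\sum_{(i,j) \in E} \operatorname{artanh}(r_{ij})\Big).$$

The Z transform is variance-stabilizing, and averaging on that scale is
not the same as averaging raw correlations:
$\tanh\big((\operatorname{artanh} 0 + \operatorname{artanh} 0.5)/2\big) \approx 0.268$,
not $0.25$.

```{r}
tanh(mean(fisher_z(c(0, 0.5))))
```

All aggregation uses the **strict upper triangle**: an 80-ROI parcellation
has $\binom{80}{2} = 3160$ unique undirected edges. (Descriptions of this
design sometimes quote $80 \cdot 81/2 = 3240$, which counts self-pairs;
the error degrees of freedom of the edge-level ANOVA below are consistent
only with 3160, so the package treats 3160 as the edge count everywhere
and the diagonal as undefined.)

The Z matrix diagonal is stored as `NA` and never aggregated. Correlations
within $10^{-12}$ of $\pm 1$ are clamped before `atanh` to keep aggregates
finite; every clamp is counted on the network object and surfaced in the
pipeline log.

## Cohort machinery

The motivating study design crosses amyloid burden with genetic risk in
cognitively normal older adults, alongside young and Alzheimer's-disease
reference groups. The package implements that workflow:

* **PIB index** (`pib_index`): the mean amyloid-tracer distribution volume
  ratio (DVR) over four cortical composites (prefrontal, lateral temporal,
  parietal, cingulate).
* **Amyloid dichotomization** (`classify_amyloid`): PIB+ iff index
  $\geq 1.08$ DVR — the boundary is inclusive. The 1.08 cutoff is a
  published threshold validated against post-mortem amyloid burden; it is
  a tunable argument with that default.
* **Stratification** (`stratify`): old subjects are partitioned into the
  four cells of PIB status × ApoE ε4 carriage; young and AD groups pass
  through. Subjects with unresolved status are an error, except that a
  missing index may be allowed under an explicit visual-read override
  (mirroring clinical practice for incomplete scans).
* **Demographic matching** (`match_subgroups`): the design calls for
  subgroups matched on age, sex and education but does not define an
  algorithm. Our choice: z-score age and education over the union of
  reference and pool, score each candidate by the mean absolute deviation
  from the reference-group mean z-scores plus a sex-mismatch penalty
  (deviation of the candidate's female indicator from the reference female
  fraction), and take the `k` cheapest candidates, ties broken by subject
  identifier. Because the cost is additive per candidate, this greedy
  selection is exactly the minimum-cost `k`-subset, which the test suite
  verifies against exhaustive enumeration.
* **Demographic balance tests** (`demographics_tests`): one-way ANOVA +
  Tukey HSD for continuous features; omnibus chi-squared (no continuity
  correction) followed by Bonferroni-adjusted pairwise chi-squared for
  dichotomous ones. Pairwise contrasts are only flagged under a
  significant omnibus test (protected testing), keeping the per-feature
  family-wise error at the nominal rate. A pairwise table with a zero
  expected count falls back to Fisher's exact test and is flagged as such.

## Group comparison

### Edge-level ANOVA and Tukey HSD

`edge_anova` stacks each group's 3160 edge-Z values as observations in a
one-way fixed-effects ANOVA: $k$ groups give $df_\text{between} = k - 1$
and $df_\text{error} = kE - k$, i.e. 12,636 for four 80-ROI groups and
18,954 for six. `tukey_hsd_edges` follows with Tukey–Kramer simultaneous
intervals at a family-wise error rate of 0.05.

A caveat worth stating plainly: edges of one network share subjects, so
they are not independent observations, and the nominal error df overstates
the effective information. This is inherent to the edge-level ANOVA design
the package implements; the permutation test below does not share the
problem and is the primary significance machinery for regional contrasts.

### Permutation test of regional strength

`permutation_regional_diff` compares two groups' per-ROI strengths. The
observed statistic is the difference of mean regional Z values (A − B),
transformed back with `tanh` at the reporting boundary. The null is built
by pooling the subjects, randomly reassigning $n_A$ of them to group A
(the rest to B), rebuilding both networks and recording the same
statistic; the default is 100,000 reassignments drawn uniformly **with
replacement** across repetitions. A region is significant when its
observed difference lies outside the central 95% interval of its null
distribution; an add-one two-sided empirical p-value
$(1 + \#\{|t^\ast| \geq |t|\})/(B + 1)$ is reported alongside,
uncorrected across ROIs (corrections across regions are deliberately out
of scope, matching the design this implements).

Two numerical decisions:

* **Interval bounds are inverse-ECDF (order-statistic) percentiles**, not
  linearly interpolated ones. On a continuous null with $10^5$ draws the
  two are indistinguishable; on the *discrete* null of an exhaustive
  enumeration (e.g. all $\binom{6}{3} = 20$ assignments of a 3+3 pool),
  interpolation places the upper bound strictly below the largest atom and
  flags an observation whose one-sided rank p-value is 0.05 — a decision
  inconsistent with the rank logic of permutation testing, and one a large
  sampled null never reproduces. Order-statistic bounds make sampled and
  exhaustive decisions agree.
* A reassignment that produces a zero-variance ROI column (correlation
  undefined) is redrawn, counted, and hard-capped; the observed tables
  themselves must be non-degenerate.

`exhaustive = TRUE` enumerates all assignments instead of sampling, which
the test suite uses to check the sampler against a from-scratch
enumeration oracle.

## Distance control

Spatially close regions can show inflated correlation for uninteresting
reasons (shared partial-volume effects of atrophy), so the package can
restrict strength comparisons to long-distance edges.

* **Geodesic** (`grey_matter_geodesic`): the distance between two voxels
  is the length of the shortest path through the grey-matter mask where
  one step moves to any of the 26 adjacent voxels — the Chebyshev
  neighborhood, whose unit ball is exactly that 26-neighborhood. Length is
  counted as steps (voxels visited minus one): adjacent voxels, including
  diagonal neighbors, are at distance 1 and a voxel is at distance 0 from
  itself. (The alternative convention of counting voxels shifts every
  distance by one and cannot change a median split.) On an open mask this
  reduces to $\max(|\Delta x|, |\Delta y|, |\Delta z|)$. Implemented as a
  level-synchronous breadth-first search; the test suite verifies it
  against an independent shortest-path oracle on random masks.
* **ROI centers** (`roi_center_of_mass`): the ROI voxel minimizing the
  *sum* of geodesics to all other ROI voxels (rather than the maximum),
  ties broken lexicographically on coordinates.
* **Median split** (`pairwise_distance_matrix`): an edge is long-distance
  when its center-to-center step count is **strictly greater** than the
  median of all pairwise distances (mean of the two middle order
  statistics for even counts). Edges at the median count as short; the
  `long_rule = "inclusive"` flag flips that reading. With heavy ties at
  the median the two rules can classify far fewer or more than half the
  edges as long — on real parcellations the long-edge count need not be
  $E/2$.
* `long_distance_strength` and `distance_correlation` then give the
  restricted strength average and the edge-wise Pearson correlation
  between Z value and step count (a strongly negative value indicates
  decay of metabolic coupling with anatomical distance).

The package accepts any labeled volume plus mask (plain-text voxel lists,
or NIfTI via the optional RNifti backend); no real brain atlas is bundled.

## Intrinsic connectivity networks

With an ROI → ICN membership table (`icn_membership`), `icn_matrix`
aggregates a network built on the functional parcellation into an
ICN × ICN matrix: within-ICN strength on the diagonal (Z-mean over member
pairs; undefined for singleton ICNs), between-ICN strength off the
diagonal (Z-mean over cross pairs). Z-scale averaging is applied uniformly
to both. Because the cells partition the edge set, the pair-count-weighted
Z-mean of the matrix equals the network's overall mean strength — an exact
conservation identity the tests check to $10^{-9}$. The reference
functional atlas structure (84 ROIs, 14 ICNs: dDMN, vDMN, Prec, lECN,
rECN, aSal, pSal, SM, VS, hVis, pVis, Lang, Aud, BG) ships only as a
synthetic stand-in membership (`synthetic_icn_membership()`); its real
geometry is not distributed with the package, so analyses of real data
must supply their own membership file.

## The synthetic cohort generator

No subject-level data are distributed with the design this package
implements, so every downstream stage is exercised on seeded synthetic
cohorts (`cohort_spec`, `generate_cohort`). Subjects are drawn from a
multivariate normal on the SUVR scale — the simplest generative family
carrying the needed correlation structure, and consistent with the linear
dependence the Pearson machinery assumes — with a planted correlation
matrix from one of four regimes:

| regime | construction | emulates |
|---|---|---|
| `heterogeneous` | one-factor Gram matrix $\lambda\lambda^\top + \operatorname{diag}(1-\lambda^2)$, loadings scattered around $\sqrt{\text{target}}$ | young-adult-like diversity with mixed-sign edges |
| `homogeneous_high` | equicorrelation at `target` | old-age amyloid-negative metabolic homogeneity |
| `intermediate` | equicorrelation at `target` with small jitter | dampened homogeneity under dual risk factors |
| `long_range_decayed` | $r_{ij} = \text{base} \cdot e^{-\text{decay} \cdot d_{ij}}$ | disease-like collapse of long-range coupling with preserved short-range edges |

The one-factor construction for the heterogeneous regime is positive
semi-definite by design. (An earlier draft drew independent Gaussian
off-diagonals, but such matrices are so far from PSD at $R = 80$ that the
repair step dragged the planted mean far below its target; the factor
construction keeps the planted mean honest.) User-supplied or jittered
targets that are not PSD are repaired deterministically by eigenvalue
clipping at $10^{-8}$ and renormalization to unit diagonal. The
`long_range_decayed` regime accepts an explicit distance matrix so the
planted decay can use the same distances analyzed downstream; its default
is ROI index distance, a one-dimensional proxy.

Subject records carry simulated age, sex, education (from the published
group means and SDs, used only to exercise the demographics machinery),
ApoE ε4 status drawn at `apoe4_fraction`, and four regional DVR
composites whose mean is exactly the subject's PIB index, drawn from a
truncated normal inside the group's published range.
`study_cohort_specs()` packages the six study-shaped groups (17 young, 22
AD, four old subgroups of 16) with their published PIB distributions.

**All regime correlation levels are illustrative.** The source design
describes the group covariance structures only qualitatively, so the
defaults are qualitative stand-ins, not estimates of any cohort. What a
passing test suite shows is that the *pipeline* recovers planted structure
of realistic shape and size — not that real FDG-PET data look like the
generator. In particular the generator omits voxel-level PET noise,
partial-volume effects, scanner differences and longitudinal change.

### Calibration experiments in the test suite

Three simulation experiments anchor the statistics, with sizes chosen to
estimate rates precisely while keeping a default test run in minutes:

* **Type-I calibration**: two groups of 16 drawn from one generator with
  an *identity* planted correlation (independent ROIs), 80 ROIs, 2,000
  reassignments, 200 replicates; the ROI flag rate over all 16,000
  decisions must fall in the 99% binomial band around 0.05. The
  independent-ROI null matters: the binomial band presumes approximately
  independent ROI decisions, which planted cross-ROI correlation would
  violate by construction.
* **Regime-ordering recovery**: four cohorts of 16 with planted mean
  correlations 0.88 / 0.57 / 0.27 / 0.05 (homogeneous-high >
  intermediate > heterogeneous > long-range-decayed; all separations
  ≥ 0.15). At $n = 16$ the group mean-strength estimator has a standard
  deviation of roughly 0.05–0.09 — shared-subject covariance between
  edges, irreducible at this group size — so the separations are set
  comfortably above the estimator noise; recovery (descending order, all
  Tukey contrasts significant) is required in ≥ 95% of 100 replicates.
* **Exhaustive-oracle equivalence**: 3+3 pooled groups, all 20
  assignments enumerated from scratch and compared to the sampler.

## Known limitations

* The edge-level ANOVA treats dependent edges as independent observations
  (see above); its printed df are a convention of the design, not an
  effective sample size.
* Geodesic distances are voxel-graph shortest paths; surface-based mesh
  geodesics and partial-volume correction are out of scope.
* The permutation test is two-group; multi-group regional inference should
  combine pooling (`pool_groups`) with pairwise runs.
* BFS-based center-of-mass search evaluates a full BFS per candidate
  voxel, which is meant for parcellation-scale ROIs (up to a few thousand
  voxels), not whole-hemisphere masks.
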