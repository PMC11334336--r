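---
title: "Methods: trophic associations and abiotic drivers along gradients"
author: "trophgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trophic associations and abiotic drivers along gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophgrad)
```

## The scientific problem

Soil bacterial communities along large environmental gradients are shaped
jointly by abiotic filtering (climate, soil chemistry) and by putative
trophic interactions — grazing by protists and lysis by bacteriophages.
Marker-gene surveys observe all three guilds (16S for bacteria, 18S for
protists, the g23 major-capsid gene for T4-like phages) at the same sites,
which makes it possible to ask how much of the bacterial community's
variation is attributable to climate, to soil, and to predator–prey
association structure, and how those contributions shift along the
gradient. `trophgrad` implements that analysis chain end to end:

1. ASV-table handling: rarefaction, prevalence filtering, relative
   abundance (`core_data`);
2. a synthetic-data generator with planted gradients and planted
   predator–prey links, so every downstream stage is testable without any
   sequencing download (`synthetic_data`);
3. alpha/beta diversity: richness trends, Bray–Curtis/Jaccard, NMDS,
   ANOSIM, Mantel, distance–decay (`diversity`);
4. bipartite predator–prey co-occurrence networks with a random-matrix-
   theory (RMT) correlation threshold and per-site subnetwork metrics
   (`trophic_networks`);
5. a normalized stochasticity ratio (NST) with an occupancy-proportional
   fixed-richness null model (`assembly_stochasticity`);
6. distance-based redundancy analysis (dbRDA), hierarchical and variation
   partitioning, and a moving-window scan along the gradient
   (`gradient_partitioning`);
7. Procrustes/PROTEST congruence of ordinations with residual–gradient
   trends (`congruence`);
8. AIC-selected linear/quadratic trend fits and standardized best-subset
   OLS (`trend_models`);
9. a pipeline and CLI orchestrating the survey arm and a microcosm arm
   where temperature or soil water content replaces latitude
   (`pipeline_cli`).

## The synthetic world

The generator states one fixed world; its defaults are not tuned to make
tests pass.

* **Sites.** 73 sites spanning 19.27–47.41°N (the span is pinned at both
  ends). Mean annual temperature falls 0.75 °C per degree of latitude with
  2 °C noise (r ≈ −0.95); precipitation falls with latitude; soil water
  content is generated from precipitation so their correlation targets
  ≈ 0.66; pH and C:N carry weak positive latitude trends; the remaining
  edaphic variables are gradient-independent.
* **Communities.** Each ASV has a log-normal baseline abundance
  (sdlog = 1) and a Gaussian niche on the driver gradient (tolerance 6
  gradient units, niche optima drawn one tolerance beyond both ends so
  edge sites are not artificially depauperate). Occupancy is Bernoulli
  with probability `base(kingdom, position) × ((1 − w) + w · niche)`;
  the filter weight `w` defaults to 0.5 — strong but not deterministic
  environmental filtering. The kingdom base curves encode the observed
  richness shapes: bacteria decline toward high latitude, protists peak
  near 32°N, viruses rise weakly. Counts are multinomial at depth 10⁴,
  emulating even sequencing effort before rarefaction.
* **Planted links.** A planted predator copies its prey's occupancy with
  probability ρ (the link strength, default 0.9) and, where present, its
  log-latent abundance is `ρ·z_prey + sqrt(1 − ρ²)·ε`. Links are planted on
  the latent scale, before multinomial sampling, so sequencing noise
  attenuates but cannot erase them; at ρ = 1 the planted pair is an exact
  monotone copy (Spearman 1), at ρ = 0 it is exchangeable with background.
* **Microcosm.** The design is fixed: five temperatures (5–25 °C) × 8
  replicates at 13.7 % soil water content plus four moisture levels
  (10–25 %) × 8 replicates at 20 °C — 72 units. The niche filter acts on
  temperature; the protist–bacteria link strength follows a quadratic
  profile peaking at 15 °C, emulating mid-temperature intensification of
  grazing.

What the generator does **not** emulate: compositional bias, PCR/chimera
artefacts, taxonomic mis-assignment, spatial autocorrelation beyond the
gradient itself, and abundance–occupancy relationships richer than the
log-normal × niche model. A green test therefore establishes that the
statistics recover structure of the planted kind at realistic sample sizes
— not that they would recover every structure present in field data.

## Statistical definitions fixed by this package

Several operations the source literature delegates to packages are given
one explicit definition here.

**NST.** On presence/absence after rarefaction, with observed pairwise
Jaccard dissimilarity `D` and null mean `E` (1000 nulls by default; the
null preserves each sample's richness exactly and draws taxa with
probability proportional to observed occupancy):
`ST = E/D` if `D ≥ E` else `D/E` (1 when both are 0), and with maximum
dissimilarity 1 as normalizer `NST = (1 − D)/(1 − E)` capped at 1 when
`D ≥ E`, else `D/E`. Both are averaged over pairs; determinism is
`1 − NST` with 0.5 the conventional boundary. Bit-compatibility with any
external NST implementation is not claimed; tests assert only the limit
and ordering properties any faithful variant satisfies (null-generated
communities score near 1, convergent communities score 0, stronger
filtering lowers NST).

**RMT threshold.** Candidate cutoffs 0.30–0.98 (step 0.01) are scanned.
At each cutoff the predator × prey Spearman block is hard-thresholded on
|ρ| and embedded as the off-diagonal blocks of a symmetric matrix. The
spectrum is taken on the *active* subnetwork (ASVs with at least one
surviving entry) and **includes its exact zero modes**: odd components
such as predator stars contribute degenerate zeros, and that level
clustering is precisely what distinguishes a residual noise tangle from a
clean set of predator–prey pairs. The spectrum is unfolded with a cubic
smoothing spline (10 knots) on the empirical cumulative density — the
main numerical sensitivity, with an average-rank fallback for degenerate
spectra — and the nearest-neighbour spacings are scored against Poisson
`e^{-u}` and Wigner–Dyson `(πu/2)e^{-πu²/4}` by a chi-square over 40 bins
on [0, 3] **plus an overflow bin** (large unfolded gaps are evidence, not
discards), pooling sparse bins to expected counts ≥ 5. The chosen
threshold St prefers the *stable* Poisson region — the smallest consistent
cutoff with no rejection above it — and falls back to the first
consistent cutoff when sporadic rejections on very small spectra leave no
stable region. A threshold is evaluable while the spectrum has ≥ 30
levels: the conventional floor of 50 would make a clean 20-pair network
(40 levels) permanently unevaluable and the scan could never terminate on
exactly the data it is meant to find. The `(π/2)e^{-π/4} ≈ 0.7162` Wigner
reference value is asserted in the tests.

**Networks.** Edges are `|ρ| ≥ St` by default (association presence, both
signs; `positive_only` restricts to positive co-occurrence). Isolated
nodes are excluded from the node count `N`; connectance is `C = E/N²`.
Per-site subnetworks are induced on ASVs with rarefied count > 0, with no
relative-abundance floor.

**dbRDA and partitioning.** Principal coordinates of the dissimilarity
matrix are computed with negative eigenvalues dropped and the discarded
inertia fraction reported (no Cailliez/Lingoes correction); R² is the
constrained fraction of retained inertia, adjusted by Ezekiel's formula;
significance uses unrestricted row permutations of the predictors
(999 by default). Hierarchical partitioning is the Shapley decomposition
over all non-empty subsets of predictor groups: each group's independent
effect is the average over entry orders of its incremental adjusted R²,
and the effects sum to the full-model adjusted R² identically. With
orthogonal groups each effect equals its marginal adjusted R² up to the
(O(k/n)) asymmetry of the Ezekiel penalty across subset sizes — exact in
raw R², not in adjusted R², which is why the test asserts it at n = 200
with an absolute 0.01 band. Variation partitioning over three groups is
inclusion–exclusion over the seven subset adjusted R² values; slightly
negative fractions are reported as-is.

**Moving window.** Sites are sorted by the gradient and windows are
contiguous runs of `w` sites stepping by one (`n − w + 1` windows), so
the low-gradient group transitions smoothly into the high-gradient group.
The default `w` is the size of the initial low-gradient group under the
configured split (32°N for the survey, matching the conventional
low/high division), clamped below by the minimum viable size
(total predictors + 5). Predictor significance filtering is applied once
on the full dataset, not per window, to keep the series comparable.

**Procrustes/PROTEST.** Symmetric Procrustes on the first two NMDS axes:
both configurations centered and scaled to unit sum of squares, optimal
rotation (reflections allowed) from the SVD of the cross-product,
`m² = 1 − (Σσ)²`, `R² = 1 − m²`; pointwise residuals are distances between
matched rows after transformation, and their sum of squares equals `m²`.
PROTEST permutes the second configuration's rows (1000 by default,
one-sided, add-one corrected; exhaustive below n = 8).

**Trend models and OLS.** AIC uses the full Gaussian constant
(`stats::AIC`); selection depends only on differences. Linear and
quadratic candidates are compared; overall p > .05 flags a nonsignificant
trend. Best-subset OLS standardizes response and predictors (so a simple
regression's β equals the Pearson correlation), searches all subsets up to
10 candidates and falls back to backward elimination beyond; exact
collinearity (condition number > 1e10) is rejected with a pointer to VIF
pruning. Plain OLS is used throughout; no spatial autocorrelation
correction is applied, because no specific method is identifiable from the
source material — a documented limitation.

**Permutation tests.** All permutation p-values use the add-one
correction, guaranteeing `p ≥ 1/(n_perm + 1)`, and every stochastic stage
of the pipeline derives its own seed from the master seed and the stage
name, so stages are individually reproducible.

## Design choices that were genuinely open

* **Rarefaction** is a single seeded multivariate-hypergeometric draw
  (not averaged over draws); samples under the depth are dropped with a
  warning, mirroring the 73-of-76 retention pattern typical of such
  surveys.
* **"Detected over 30 % of sites"** is a strict `>` on the sample count.
* **Negative correlations** count as edges by default because the binary
  network encodes association presence; `positive_only` is provided.
* **DDR distances** are untransformed kilometers (haversine, Earth radius
  6371 km); the pairwise non-independence of the slope-difference
  interaction test is acknowledged, and within-group pairs only are used.
* **The pipeline's RMT fallback:** strongly structured data can reject
  Poisson at every evaluable cutoff; `rmt_threshold()` then errors with
  its diagnostic scan (the contract), while `run_survey()` catches that
  error and uses the best-fitting cutoff with a warning so a survey run
  remains auditable end to end.

## Known limitations

* Co-occurrence edges are statistical associations, not demonstrated
  interactions; the planted-link recovery tests quantify sensitivity only
  for the planted kind of association.
* NST here is one fixed, documented variant; numerical parity with other
  implementations' edge-case handling is out of scope.
* The RMT transition is intrinsically information-limited at small
  spectra: once only isolated dyads remain, residual noise dyads are
  spectrally indistinguishable from true pairs, so precision near the
  transition is bounded by how many noise edges survive — the acceptance
  test's planted world sits close to that bound.
* The microcosm arm reuses the survey machinery with per-level summaries;
  with ≤ 5 gradient levels the moving window is not meaningful and is
  replaced accordingly.
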