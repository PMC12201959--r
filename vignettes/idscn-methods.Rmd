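---
title: "Individualized differential structural covariance networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individualized differential structural covariance networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idscn)
```

## The model

A structural covariance network (SCN) summarizes how regional grey-matter
volumes (GMV) co-vary across subjects: entry $(a, b)$ is the Pearson
correlation between the volumes of regions $a$ and $b$, computed over a
sample after removing age, sex, education and scanning-site effects.
A group-level SCN says nothing about any one patient. The individualized
differential SCN (IDSCN) recovers a per-patient quantity by perturbation:

1. build the **reference network** (rSCN) from the $n$ controls alone;
2. add one patient to the controls and rebuild the network on the $n+1$
   subjects, with the covariate design refit on the combined sample — the
   **perturbed network** (pSCN);
3. take the difference $\mathrm{dSCN} = \mathrm{pSCN} - \mathrm{rSCN}$;
4. scale each edge to a Z-statistic:

$$Z_{ab} \;=\; \frac{\mathrm{pSCN}_{ab} - \mathrm{rSCN}_{ab}}
{\bigl(1 - \mathrm{rSCN}_{ab}^2\bigr) / (n - 1)}.$$

One added subject moves a correlation of $n$ subjects by $O(1/n)$, and the
influence of a single observation on a Pearson correlation has asymptotic
variance $(1-r^2)^2/n$; the denominator above rescales the $O(1/n)$
difference accordingly, so that under the null (the patient exchangeable
with the controls) $Z$ has approximately unit variance. `idscnZ()` uses
$n$ = the number of reference controls; the constant is configurable
through the sample sizes recorded on the network objects.

**Calibration caveat.** Unit variance does not imply normality. The
single-subject influence term behaves like a product of two standardized
deviates, so the null distribution of $Z$ has a sharper peak and heavier
tails than the standard normal. The package's null-scenario test computes
the empirical rejection rate at raw $p<0.05$ and documents that it exceeds
the nominal level (the two-sided $p$-values are computed from the normal,
as the method prescribes). At the operating point that actually matters for
the pipeline — the Bonferroni-corrected cutoff $|Z| \gtrsim 5.4$ — the
heavy tail means a patient typically shows a few dozen "significant" edges
under pure noise rather than none; the prevalence rule below is what makes
the feature selection robust to this, because those noise edges scatter
across the $13{,}695$-edge family instead of concentrating on any single
edge. The same behaviour is visible in published applications of the
statistic, where most edges are significant in at least one patient.

## From individual networks to subtypes

Per patient, an edge is **significantly altered** when its two-tailed
normal $p$ satisfies $p \cdot m < \alpha$ with family size
$m = \binom{R}{2}$ (13,695 for a 166-region atlas) and $\alpha = 0.001$.
Both are `pipelineConfig()` fields; the correction is the plain Bonferroni
product, and the reading "corrected $p < 0.001$" (raw
$p < 0.001/13{,}695$, $|Z| \gtrsim 5.38$) is the default.

**Edge prevalence** counts, per edge, the patients whose mask marks it.
Edges prevalent in at least `prevalenceFraction` (default 5%, rounded half
away from zero, floor 1 — 8 of 164 patients) become clustering features.
The feature matrix holds the **raw Z-scores** of the selected edges: the Z
transform already places edges on a common scale, so no per-column
re-standardization is applied (and none is stated by the method this
package operationalizes).

K-means runs on the feature rows with Euclidean distance for every
$k = 2,\dots,10$; each $k$ gets 100 restarts with initial centers drawn
uniformly from the data rows, run to convergence. Each restart is scored by
the mean silhouette width (Euclidean, same metric as the clustering;
singleton clusters score 0); per $k$ the best restart wins, ties broken by
smaller within-cluster sum of squares; across $k$ the maximum mean
silhouette wins, ties to the smaller $k$. Restarts that error or produce an
empty cluster are redrawn (bounded retries). Labels are renumbered so
cluster sizes are non-increasing — subtype 1 is always the largest cluster.
Distance choice and feature scaling were genuinely open design points; both
defaults are the simplest reading and the distance is fixed in code rather
than exposed, because the silhouette-based selection is only comparable
within a single metric.

**Characterization** compares the discovered subtypes on
(i) each selected edge's Z (covariate-adjusted two-group $t$, i.e. the
group-dummy coefficient of a least-squares fit on intercept + group +
age + sex + education + site, Bonferroni over the selected edges at 0.05);
(ii) regional GMV (same test per region, Bonferroni over all regions —
a region-level surrogate, *not* a voxel-wise cluster inference);
(iii) Pearson correlations between edge Z-scores and the clinical totals
(HAMD-17, HAMA-14), pooled across patients; and (iv) demographics
(chi-square for sex without continuity correction by default, classical
pooled-variance $t$ for age, education and the clinical totals).
The $t > 0$ direction convention is "first-sorted group larger", and a
label swap negates every $t$ while preserving every $p$ — a property the
test suite asserts.

## What the synthetic generator emulates

`generateCohort()` produces cohorts with the statistical structure the
analysis assumes: 164 patients (ground-truth subtypes of 117 and 47) and
164 controls over a 166-region atlas by default, spread round-robin over 6
sites.

Regional volumes are built on a unit-variance latent scale and then
stretched per region:

* **Covariance**: one global factor (variance share 0.30, loadings jittered
  ±10%) plus 11 idiosyncratic factors (0.35 jointly) plus independent noise
  (`baselineNoiseSd` = $\sqrt{0.35}$), giving a mean off-diagonal
  correlation near 0.3 with realistic spread. A latent-factor construction
  was preferred over a fixed target matrix: it is cheap, full-rank by
  construction, and yields block-like structure.
* **Covariates**: per-region coefficients for age and education (per
  decade), sex, and site are drawn at SD `covariateEffectScale` (0.3).
* **Region scale and mean**: scales U(0.5, 0.9), means U(5, 9) in arbitrary
  volume units; the matrix is floor-shifted if any value would be
  non-positive.

**Planted edge perturbations** are the ground truth the pipeline must
recover. Each planted pair is simulated as its own two-region factor block
with baseline correlation $-0.9$, uncorrelated with all other regions; a
carrier's residual at the pair is *replaced* by $(u\delta,\; u\,s\,\delta)$
with a per-carrier sign $u$ and magnitude $\delta \sim U(0.85, 1.15)$.
A same-sign co-deviation against a strongly negative baseline violates the
pair's covariance by roughly $\delta^2 (1-r)/(1-r^2) \approx 10\,\delta^2$
Z-units while each region's marginal deviation stays near one SD. This
construction is deliberate: single-subject edge detection at baseline
$r \approx 0$ would require $|z_a z_b| \gtrsim 5.6$ and hence marginal
outliers of 2.5+ SD, and such outliers unavoidably drag *every* edge
incident to the planted regions (and every cross-pair of planted regions)
over the significance cutoff once a hundred carriers share them. The
anti-correlated-pair device confines the perturbation to exactly the
planted edges, which is what a ground-truth generator is for.

The default `paper_like` scenario plants nine disjoint edges carried by all
117 subtype-1 patients and one distant edge carried by every patient of
both subtypes ("carried equally" realized as equal 100% proportion, so the
edge cannot differentiate the subtypes). By construction the pipeline
should select exactly these 10 edges, find 9 of them subtype-differential
with subtype 1 stronger, and split the patients 117/47 at $k = 2$.

Three further ground-truth effects: a **volume deficit** of 1.2 residual
SDs in three regions of subtype-1 patients, implanted as a homogeneous
shift with the residual spread tightened (×0.3) so the group-level effect
is reliably detectable without turning each patient into a marginal outlier
whose z-score would bleed into edge significances; **anxiety coupling**
(HAMA-14 = 18 + γ·mean planted deviation + N(0, 4), γ = 5, clipped to
0–56 and rounded), so subtype 1 has higher expected anxiety and planted-edge
Z correlates positively with HAMA; and **HAMD-17** drawn from one common
N(22, 5) for all patients — no planted depression-severity difference.
Clinical score distributions are arbitrary defaults (the source cohort's
tables are not reproduced anywhere the package can see); only their
*coupling structure* is meaningful.

What the generator does **not** emulate: neuroanatomical covariance
topography, site-specific scanner distributions, score distributions of any
real cohort, voxel-level data, and — by design — carriers whose planted
deviations are marginal outliers. Passing tests therefore demonstrate that
the pipeline recovers the structure the generator plants under its
idealized geometry, not that the method is calibrated or powerful on real
morphometric data.

## Numerical choices and degenerate inputs

* Edges are canonicalized as upper-triangle $(i < j)$ pairs; user-facing
  files use 1-based region indices.
* `prevalenceThreshold()` rounds half away from zero (`floor(x + 0.5)`),
  minimum 1.
* Feature-edge ordering: descending prevalence, ties by ascending $(i, j)$.
* A reference correlation of exactly ±1 makes the Z denominator vanish and
  is rejected naming the edge; a region with zero residual variance is
  rejected naming the region; constant age/sex/education are rejected
  naming the column; a patient whose site has no controls is rejected (the
  site effect cannot be estimated).
* A feature matrix with all rows identical has no defined silhouette and is
  rejected.
* Single-site cohorts simply drop the site dummies.

## Problem sizes in the test suite

The suite exercises the full study geometry: 20 paper-like cohorts and 20
null cohorts at 328 × 166, each with all 164 leave-one-in recomputations
and (for the paper-like sweep) the full 9 × 100 k-means model selection;
brute-force oracle comparisons run on 8-region toys at tolerance 1e-10,
and the Monte-Carlo calibration of the adjusted t uses 4,000 null
replicates. These sizes were chosen so the whole suite completes in a few
minutes while keeping every Monte-Carlo check at the study's own sample
sizes.

## Known limitations

* The Z statistic's null tails are heavier than normal (see above); its
  nominal per-edge $p$-values are anti-conservative at moderate levels.
  The pipeline's conclusions ride on prevalence across patients, which the
  null sweep shows stays far below the 8-patient threshold (max observed 6
  across 20 cohorts at the study size).
* The covariate adjustment is linear residualization; nonlinear age
  effects would leak into the correlations.
* The group comparison assumes homoscedastic residuals across subtypes;
  the generator's tightened-deficit device mildly violates this in the
  three deficit regions, in the direction that makes the pooled test
  conservative for the larger group.
* Pearson edge–symptom correlations are computed across all patients
  pooled; with strong subtype separation they are dominated by the
  between-subtype contrast (per-subtype correlations are a one-line
  variation the API permits but does not default to).
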