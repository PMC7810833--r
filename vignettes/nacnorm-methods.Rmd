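---
title: "Normative alpha-centrality analysis: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative alpha-centrality analysis: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nacnorm` turns region-level resting-state BOLD time series into per-subject
maps of abnormally central brain regions. This vignette is the package's own
account of the method: the model at each stage, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical decisions taken where the design was genuinely open.

## 1. From time series to a graph

Each subject contributes up to `n_sessions` runs of a region × time matrix
(388 regions, 101 volumes at TR = 3 s in the reference configuration).

**Motion QC.** A session is excluded when any volume's displacement from
the *first* volume reaches 2 mm on a translation axis or 0.02 rad on a
rotation axis (both limits inclusive). Measuring displacement against the
first volume matches the convention of realignment-parameter (`rp_*.txt`)
files; frame-to-frame displacement would be an alternative reading, and the
choice is recorded in the pipeline manifest.

**Band-pass filter.** `bandpass()` removes the constant offset, the linear
trend, and all frequencies outside 0.01–0.1 Hz in a single step: each
region's series is projected onto the orthogonal complement of the span of
{intercept, linear ramp, out-of-band discrete Fourier modes}. A projection
was chosen deliberately over the more common detrend-then-FFT-mask recipe:
the two-step recipe is not idempotent (the masked signal re-acquires a
small trend component, of order 10⁻³ of signal scale on a second pass),
whereas a projection filter applied twice is exactly the filter applied
once. The retained band is identical up to the leakage handling.

**Connectivity.** For every region pair, Pearson's r is converted to
`t = r √((N_eff − 2)/(1 − r²))`, with the effective sample size correcting
for temporal autocorrelation:

\[ N_\mathrm{eff} = n \frac{1 - \rho_i \rho_j}{1 + \rho_i \rho_j}, \]

where ρ are the lag-1 autocorrelations of the two series. The estimator
family is standard but not unique; the lag-1 form is the default and a
full-lag-sum variant `n / (1 + 2 Σ_k ρ_i(k) ρ_j(k))` is available as
`ess_mode = "full"`. The mode in force is written into every manifest.
`N_eff` is floored at 4 (so the t distribution keeps ≥ 2 df; the floor is
rare and only matters for pathologically autocorrelated pairs), and values
above `n` from opposite-signed autocorrelations are kept as computed.

t is mapped to Z by quantile matching on the signed tail, computed through
log-tail probabilities so |t| up to ~40 does not overflow; degenerate
|r| = 1 returns a capped Z = 40 with a warning. This construction preserves
the correspondence p < 0.05 ⇔ |Z| > 1.96. Session Z maps are averaged over
the sessions that passed QC, and the adjacency matrix keeps edges with
**Z strictly > 1.96**.

## 2. Normalized α-centrality

With adjacency matrix A, the package evaluates the partial series

\[ C_{\alpha n} = A + \alpha A^2 + \alpha^2 A^3 + \dots + \alpha^n A^{n+1},
\qquad n = 20, \]

normalizes by the sum of all elements of C, and scores region i by the row
sum of the normalized matrix. Two α values are kept per subject: α = 0
(`nac0`) and α = 1/λ (`nac1`), λ the largest eigenvalue of A.

Three decisions here were open and are worth recording:

* **Score reduction.** The normalized C is a matrix; the per-region score
  is its row sum. This is the unique linear reduction making the α = 0
  score exactly degree/Σdegree, i.e. exactly proportional to degree
  centrality — which is what `nac0` is meant to be.
* **Dual scales.** Statistics all use the canonical sum-to-1 scale. A
  max-rescaled copy (score / max score, so the maximum is 1) is also
  emitted, for distribution histograms on [0, 1]: on a 388-region sum-to-1
  scale every score is ≈ 1/388 and a histogram axis in tenths would be
  unreadable. The normative model accepts only the canonical scale and
  rejects mixed-scale input (the mean + 2 SD rule is not scale-free).
* **α = 1/λ exactly.** At the upper end of the admissible range the series
  terms stop decaying; the *normalized* quantity still converges, which is
  what matters.

**Convergence at α = 1/λ is O(1/n), not geometric.** Writing A in its
eigenbasis, the k-th term of the series is λ v₁v₁ᵀ plus contributions
decaying like (λ₂/λ₁)ᵏ; the partial sums therefore grow linearly in the
dominant direction while the subdominant contributions approach a
*constant* matrix B. After normalization the deviation from the eigenvector
limit is ≈ B/(n+1) — a Cesàro 1/n rate whose constant depends on how far
the early terms (degree profile) sit from the eigenvector profile. In
practice, at order 20: a few ×10⁻⁴ on sparse 50-node random graphs, ~10⁻⁵
on 388-node graphs at connectome density, and up to 10⁻³ on strongly
modular graphs whose community blocks produce near-degenerate top
eigenvalues. Order 20 is kept as the default because the *ranking* of
regions — all the downstream method uses — is stable well before the
absolute values settle (eigenvector correlation > 0.999 in the test suite),
but claims of convergence below ~10⁻⁴ per score at this order are not
supported by the mathematics and the package does not make them.

The pipeline computes `nac1` row sums by the vector recursion
`u₀ = A·1, u_k = α A u_{k−1}` (identical algebra, O(n²) per term); equality
with the explicit matrix series is covered by a unit test. Disconnected
graphs are analysed whole (λ from the full spectrum) and flagged in the
manifest; an edgeless graph yields NA scores and excludes the subject from
`nac1`-based statistics.

## 3. The normative model

Controls are split by sex. Per region and measure, scores are OLS-regressed
on age (the mean line). For the dispersion the package regresses the
absolute residuals, scaled by √(π/2) (which makes E|e|·√(π/2) = σ for
Gaussian residuals), on age — so the SD is itself a linear function of age
(`sd_mode = "age_regressed"`). A homoscedastic pooled-SD variant is one
flag away (`sd_mode = "pooled"`); the age-regressed form is the default
because the mean *and* SD are both described as age-resolved quantities,
and the pooled form is nested within it (slope 0). Predicted SDs are
floored at 10% of the pooled residual SD, preventing zero-width normal
ranges on near-deterministic synthetic fixtures.

A region enters aR₀ (or aR₁) when its canonical score strictly exceeds
mean + 2·SD at the subject's age and sex. Under a Gaussian null this flags
2.28% of region-tests (one-sided 2 SD tail); the test suite verifies the
rate on subjects drawn from the fitted model. Two caveats are inherent and
worth knowing:

* Graph-derived scores are right-skewed rather than Gaussian, so the
  absolute-residual SD estimate is slightly conservative on real profiles:
  held-out *graph-based* controls are flagged at ~1.3% per region rather
  than 2.28% in the synthetic cohort.
* Age matching is continuous (regression prediction at the subject's age),
  never binned; ages outside the fitted range are extrapolated and
  flagged.

## 4. Downstream statistics

All statistics are implemented to the specific variants the method calls
for, and each is unit-tested against an independent brute-force oracle:

* **Distribution χ²** between a subject's max-rescaled score histogram
  (0.05-wide bins on [0, 1]) and a matched-control reference: same-sex
  controls within ±5 years, mean bin proportions; below 10 matches the
  per-bin proportions are OLS-regressed on age and predicted at the
  subject's age (clipped, renormalized). Adjacent bins are merged —
  smallest expected count into its smaller neighbour, deterministically —
  until every expected count is ≥ 5; df = bins − 1.
* **Wilcoxon rank-sum** with tie-corrected normal approximation and *no*
  continuity correction (z is reported, matching a plain normal
  approximation).
* **Spearman / partial Spearman**: Pearson on mid-ranks; the partial form
  rank-transforms all three variables and partials the covariate out of
  the rank correlation, t-test with df = n − 3. Used with age as the
  nuisance covariate for duration of illness, which is confounded with
  age.
* **Cohen's κ** from marginal products; two identical constant labelings
  are defined as κ = 1.
* **Connection percentage** `100 · edges within aR₀ / C(|aR₀|, 2)`,
  undefined (NA) below 2 regions.
* **DMN enrichment**: goodness-of-fit χ² (df = 1) of the in/out-DMN split
  of a subject's abnormal regions against the atlas proportion (100/388 =
  25.8% at the reference atlas).
* **Edge-count ANCOVA**: partial F for group given age in the additive
  model, and for the group × age interaction.

No multiple-testing adjustment is applied (the per-test p-values are
reported raw); the clinical correlation table carries the number of tests
as an attribute.

## 5. The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not fMRI physics. Defaults (all in `cohort_config()`):

| parameter | default | rationale |
|---|---|---|
| `n_controls` / `n_patients` | 300 / 10 | large normative cohort, desk-scale runtime |
| `n_regions`, `n_dmn` | 388, 100 | reference atlas geometry (368 cerebral + 20 cerebellar; 100 DMN) |
| `n_sessions`, `n_volumes`, `tr_seconds` | 3, 101, 3 | reference acquisition (three runs, 101 analysed volumes, TR 3 s) |
| `age_range`, `sex_ratio` | 18–84, 0.62 | control cohort span; ~62% female |
| `ar1_coeff` | 0.3 | moderate BOLD-like temporal autocorrelation |
| `n_communities` | 8 | large-scale network count of common parcellations |
| `base_within_corr` / `base_between_corr` | 0.30 / 0.05 | within-network coupling well above, between-network near, the edge threshold at N ≈ 100 |
| `age_slope` | −0.001/yr | mild connectivity decline with age, makes the age regression non-vacuous |
| `sex_shift` | +0.02 (M) | makes per-sex fitting non-vacuous |
| `n_hubs` / `hub_corr_boost` | 5 / 0.3 | injected patient abnormality for recovery testing |

Each session is a stationary AR(1) process whose innovations carry a
community-block latent correlation matrix (repaired to positive definite by
eigenvalue clipping at 10⁻⁸ and rescaling to unit diagonal, when hub boosts
push it outside the cone). Motion traces are small Gaussian random walks
anchored at zero, with an optional injected violation for QC tests. All
randomness flows from a single seed; regeneration is bit-identical.

Synthetic sessions are generated at the analysed volume count directly;
dummy-scan discard and slice-time bookkeeping are voxel-level acquisition
steps the generator does not emulate (`discard_initial_volumes()` exists
and is tested, but the pipeline applies k = 0 to synthetic cohorts).

**What passing tests do and do not show.** The generator produces
Gaussian, stationary, community-structured signals with homogeneous
temporal autocorrelation. Real BOLD is non-Gaussian, nonstationary, has
spatially varying autocorrelation, physiological noise, and motion
artefacts correlated with the signal. Tests passing on this cohort
demonstrate that the *pipeline machinery* is correct and calibrated under
its own assumptions — not that those assumptions hold for any scanner.

**Hub injection is zero-sum under canonical normalization.** Because
scores sum to 1, boosting five hub regions necessarily *lowers* every
other region's score (by the share the hubs absorb, roughly 0.3–0.5
control-SD at the default boost). Injected hubs are recovered in aR₀
essentially always, but the patients' *total* abnormal-region count is not
elevated relative to held-out controls: the guaranteed hub flags displace
about as many baseline-tail flags. A patient-vs-control count contrast like
the one seen in real cohorts requires genuine network reorganization, which
this deliberately minimal stand-in does not model. The count-contrast check
in the acceptance suite documents this honestly rather than passing by
construction.

Similarly, session averaging shrinks the null Z variance (mean of 3
independent Z scores has SD 1/√3), so the ~2.5% per-pair null edge rate
holds for single-session subjects; with 3 sessions the null edge rate is
far lower, which is the intended benefit of averaging.

## 6. Problem sizes and determinism

The unit suite runs on small graphs (≤ 50 nodes) and small cohorts (30–60
subjects, 30–100 regions, 1–2 sessions of 20–80 volumes), sizes at which
every oracle (eigendecomposition, brute-force matrix powers, normal
equations, rank arithmetic) is exact and fast. The acceptance checks and
`scripts/acceptance.R` use the full default cohort — 300 controls + 10
patients at 388 regions, 3 × 101 volumes — with 500 model-drawn held-out
subjects for the flag-rate calibration and 1000 draws each for the
distribution-χ² and DMN-enrichment null rates (50-region sets for the
latter, where the df = 1 χ² approximation is comfortable). The whole
pipeline is deterministic given the seed: two runs on the same on-disk
cohort produce byte-identical outputs, and the manifest (config, package
version, design-decision flags) suffices to reproduce any subject.

## 7. Known limitations

* Starts at region × time matrices: no spatial preprocessing, no NIfTI
  ingestion, no nuisance regression beyond the band-pass projection.
* The effective-sample-size estimator family is under-determined; both
  implemented variants are approximations and the choice is surfaced in
  every output rather than hidden.
* Normative SDs assume residual Gaussianity up to a scale factor;
  heavy-tailed score distributions make the flag rate conservative.
* Weighted graphs, path-length/clustering statistics, nonlinear age
  models, and site harmonization are out of scope.
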