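---
title: "Methods: isotope partitioning, GAM selection and model assessment in soilcmin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isotope partitioning, GAM selection and model assessment in soilcmin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`soilcmin` implements a statistical pipeline for soil incubation
experiments that ask how soil properties — in particular bacterial and
fungal diversity indexes — relate to the mineralisation of different
carbon pools. The experimental template is a microcosm incubation of
soils from two land uses (cropland, grassland), with and without
incorporation of ^13^C-labelled plant residue, respired CO~2~ being
accumulated over a fixed schedule of sampling intervals (by default days
0–3, 3–7, …, 60–80).

This vignette documents the models, the algorithmic choices and the
numerical conventions, in enough detail that every reported number can be
traced to a formula.

## Isotope partitioning and responses

For an amended microcosm the total respired CO~2~ over an interval,
$R_t$, mixes soil-derived ($R_s$) and residue-derived ($R_r$) carbon.
With ^13^C abundances $A^{13}_s$ (native soil C), $A^{13}_r$ (labelled
residue) and $A^{13}_t$ (respired CO~2~), mass balance gives

$$R_s + R_r = R_t, \qquad
  R_s A^{13}_s + R_r A^{13}_r = R_t A^{13}_t$$

solved as $R_r = R_t\,(A^{13}_t - A^{13}_s)/(A^{13}_r - A^{13}_s)$ and
$R_s = R_t - R_r$. Any consistent abundance scale works; the package
does not convert between atom % and δ-notation. Measurement noise can
push $A^{13}_t$ slightly outside the endmember interval, producing a
negative component: the package clamps it to zero, rescales the pair to
preserve $R_t$, and flags the cell (`clamped`), rather than failing or
silently dropping data. Cells are only excluded (with a count in the QC
attributes) where a logarithm would be undefined.

The priming effect is the ratio
$PE = R_{s,\mathrm{amended}} / R_{s,\mathrm{control}}$, which stays
positive and so supports the log transformation applied to all
responses. Replicate pairing for $PE$ is by index (amended replicate
*u* over control replicate *u*); a replicate-mean denominator is
available via `pe_pairing = "mean"`. The pairing convention is a
genuine free choice — index pairing was chosen because it is
deterministic and keeps replicate-level dispersion in the response.

Responses are interval rates, amount divided by interval length
(µg C-CO~2~ g^-1^ soil day^-1^), modelled on the natural-log scale:
`log_rs_control`, `log_rs_amended`, `log_rr`, `log_pe`.

## Diversity indexes

From per-sample OTU counts with relative abundances $p_i$: richness
$S$ (OTUs with positive count), Shannon $H' = -\sum p_i \ln p_i$,
evenness $J' = H'/\ln S$ (undefined and reported `NA` at $S = 1$), and
inverse Simpson $1/D = 1/\sum p_i^2$. Natural logarithms are the
default (`base` is exposed). Zero-count OTUs are excluded everywhere;
no rarefaction or depth normalisation is applied — sequencing depth is
carried only for QC. Index computation delegates to `vegan`.

## The additive model

Each candidate model for a log response $Y$ has the form

$$Y = \alpha + b_{\mathrm{time}} + [\,\beta_{\mathrm{land\,use}}\,] +
      f_1(x_1) + \dots + f_p(x_p) + \varepsilon$$

with Gaussian errors and identity link (the log transformation having
stabilised the variance). Each $f_j$ is one of: identity (I),
orthogonal polynomial of degree 2 or 3 (P2, P3), or a penalized cubic
regression spline (s), optionally interacted with land use so the two
land uses get separate relationships. Orthogonal rather than raw
polynomial columns are used purely for conditioning; fitted values are
identical.

Sampling day enters every model as a categorical *random* factor
$b_{\mathrm{time}}$: one intercept per date shrunk by a ridge penalty
(`mgcv`'s `s(time_f, bs = "re")`), the standard penalized-regression
representation of a random intercept for temporal pseudo-replication.
Fitting is penalized least squares via `mgcv::gam`; smoothing
parameters are chosen by GCV by default (`method = "REML"` optional).

Choices the data could not dictate, fixed as follows:

* **Spline basis dimension** `k = 5` per smooth. Site covariates take
  only ~20 distinct values, so a larger basis invites overfitting;
  `k` is exposed.
* **Standardization.** Covariates are z-scored on the training data
  before basis construction (per cross-validation fold, so no
  leakage); predictions and reports are on the original scale.
* **Land-use main effect.** Whenever any term interacts with land use,
  the land-use indicator is included as a main effect — interactions
  without main effects are ill-posed.
* **Unseen dates** at prediction time get a random-factor contribution
  of zero (the shrinkage prediction for an unobserved level), with a
  warning.

Per-term significance uses F tests (`anova.gam`): exact tests on
coefficients for parametric terms, approximate effective-df tests for
smooths. For a by-land-use smooth, which `mgcv` fits as one smooth per
level, the reported p-value is the smaller of the per-level tests.
Codes: `***` < 0.001 < `**` < 0.01 < `*` < 0.05 < `°` < 0.1 < `ns`.

## Stepwise selection by cross-validated MSEP

Model search starts from the mandatory intercept + random-time model
and is driven by the leave-one-soil-out mean squared error of
prediction,

$$\mathrm{MSEP} = \frac{1}{N}\sum_{i,t,u}
   \left(y_{itu} - \hat y_{-i,tu}\right)^2,$$

where $\hat y_{-i,tu}$ is predicted by the model calibrated without
*any* row of soil $i$ — the fold unit is the whole soil, covering all
its times and replicates, and smoothing parameters are re-estimated in
every fold. Each iteration:

1. computes the current model's MSEP;
2. pre-screens the not-yet-selected covariates by variance inflation
   factor — an OLS regression of each candidate (raw scale, one row per
   soil) on the already-selected covariates; candidates with
   $\mathrm{VIF} = 1/(1-R^2) > 4$ are set aside for this iteration.
   VIF is computed on covariates, not on their transformed terms;
3. enumerates all add moves (admissible covariate × functional form ×
   land-use-interaction flag) and all remove moves (drop one selected
   term); by default each candidate is enumerated both with and without
   the interaction (`interaction_mode = "both"` — the alternatives
   `always`/`never` restrict the search space);
4. scores every candidate model by LOSO-MSEP;
5. accepts the best move if its MSEP is *strictly* smaller than the
   current one, else stops.

A removed covariate returns to the pool and may re-enter. The
procedure is fully deterministic: candidates are enumerated covariates
first (configured order), then forms (I, P2, P3, s), then interaction
flag; exact MSEP ties break by smaller effective degrees of freedom,
then enumeration order. The trace records every accepted move with the
MSEP before/after, the number of candidates scored and the number
VIF-excluded.

### A note on selection liberality

Strict-improvement CV selection carries no complexity margin (no
one-standard-error rule), and grouped CV estimates of MSEP are noisy:
for a site-level noise covariate the change in LOSO-MSEP has a positive
mean but a standard deviation of the same order, so each spurious
candidate has an appreciable chance of appearing to improve prediction,
and the chance that *some* candidate does grows with the size of the
search space. The test suite quantifies this with a null simulation
(all candidates pure noise): the time-only model is returned in roughly
half of replicates at the suite's settings, not the large majority one
might hope for. Users should read a selected marginal covariate with
corresponding caution; the per-term F tests and relative importances in
the assessment report are the intended guard-rails.

## Model assessment

* **Explained deviance** $\% \mathrm{Dev} = 100(1 -
  \mathrm{RSS}/\mathrm{TSS})$ for these Gaussian identity models.
* **RPIQ** $= \mathrm{IQR}(y)/\sqrt{\mathrm{MSEP}}$, with
  linear-interpolation quartiles (R's default type 7; the convention
  matters at $n = 20$ soils and is therefore fixed and documented).
* **Relative importance.** Each component of the linear predictor (the
  random time factor first, then the land-use main effect if present,
  then covariate terms in selection order; interaction halves summed
  per covariate) is extracted and the response is regressed on the
  component matrix — redundancy analysis with a single response reduces
  to OLS, and per-component contributions are the sequential (type I)
  sums of squares as a share of the total sum of squares, in percent.
  Shared variance not attributable to a single component is reported as
  a remainder, which can be slightly negative because the ordination
  re-estimates component coefficients and thereby undoes a little
  penalization shrinkage. A `marginal` attribution mode (drop in RSS
  when entered last) is provided for sensitivity analysis.
* **BIC** uses the Gaussian profile form
  $n\ln(\mathrm{RSS}/n) + \mathrm{edf}\,\ln n$ with the penalized
  model's total effective degrees of freedom in place of a parameter
  count — a heuristic consistent with reporting fractional df, intended
  for ordering model families, not as an absolute criterion.
* **Kinetics ANOVA.** `value ~ land_use * time` with land use fixed and
  time random: land-use and time F ratios are formed against the
  interaction mean square, the interaction against the residual.
  Tukey HSD comparisons give compact-letter groupings across sampling
  times and per-time significance codes for the cropland–grassland
  contrast.

## The synthetic-data generator

The generator reproduces the design the analysis assumes — 10 cropland
+ 10 grassland soils × 2 treatments × 3 replicates × sampling days
3, 7, 14, 21, 28, 44, 60, 80 — and provides ground truth for
inverse-problem tests. Its defaults are the package's statement of a
realistic study:

* **Covariates** drawn per land use from normal distributions with
  field-plausible means (e.g. SOC 14 ± 4 g kg^-1^ cropland vs
  24 ± 8 g kg^-1^ grassland); texture closes to 1000 g kg^-1^ exactly
  (sand is the complement) and clay + fine silt is derived from clay
  and silt. The four bacterial indexes (and the four fungal ones) are
  drawn as a correlated block, r = 0.8 by default, mirroring the strong
  intercorrelation of diversity indexes in real communities; grassland
  bacterial 1/D is higher than cropland on average, the clearest
  land-use contrast in such data. Draws are projected onto the index
  invariants (J′ ∈ [0,1], 1/D ∈ [1, S], H′ ≤ ln S).
* **Kinetics.** Soil- and residue-derived respiration each follow
  two-pool (fast + slow) first-order decay; defaults give a basal rate
  near 15 µg C g^-1^ day^-1^ declining monotonically, and roughly half
  of a ~2000 µg C g^-1^ residue amendment mineralised over 80 days.
  Interval amounts are exact integrals of the rate curves.
* **Effects.** Configurable covariate effects multiply the rates by
  $\exp(a\,g(z))$ with $z$ the standardized covariate and $g$ linear,
  centered-quadratic, cubic or a bounded smooth shape; effects can be
  land-use-specific (separate amplitude per land use). Effects
  targeting the control-soil response act on soil-derived respiration
  in both treatments; priming-targeted effects multiply the amended
  soil-derived flux only.
* **Noise.** One lognormal factor per microcosm-interval (σ = 0.15 on
  the log scale by default) multiplies both carbon sources of that
  interval, so the ^13^C mixture abundance remains *exactly* consistent
  with the underlying partition — the forward model is invertible by
  construction, which the recovery tests exploit.
* **Endmembers** default to natural-abundance soil C (1.08 atom %) and
  enriched residue (3.0 atom %).
* **OTU tables** for diversity-module tests follow geometric-series
  abundance profiles whose decay parameter is solved by root finding to
  hit a target evenness, sampled multinomially at a configurable depth.

What the generator deliberately does **not** emulate: site-level random
effects beyond the covariate effects, temporal autocorrelation of the
noise, covariate measurement error, isotope fractionation, or any
mechanistic microbial dynamics. Passing recovery tests therefore
demonstrates correctness of the estimation machinery under the stated
stochastic model, not robustness to real-data pathologies such as
confounded land-use/diversity gradients — which, as the assessment
report's interaction terms make visible, cannot be resolved
statistically at n = 20 soils anyway.

## Problem sizes used by the test suite and acceptance script

Simulation-based checks are sized so a complete run stays comfortable
on one CPU: the selection power/null studies use 20 soils, 5 candidate
covariates, forms {I, s} without interactions and 50 replicates; the
exhaustive-search equivalence check uses 3 identity-form covariates
(2^3 models) over 20 seeds; calibration checks use 1000 seeds. The
acceptance script runs the full pipeline — all four responses, a
12-covariate menu spanning texture, chemistry, biomass and both
organisms' diversity indexes, all four forms, interactions enumerated
both ways — on one default-configuration dataset. These sizes are the
package's definition of its standard validation experiment and are
stated here so they can be scaled up deliberately.

## Known limitations

* With 20 soils, land-use-interacted relationships rest on 10 soils per
  curve; the spline basis (k = 5) is accordingly small, and selected
  nonlinear shapes should be inspected, not trusted blindly.
* The selection optimises a noisy criterion greedily; results can be
  local minima, and near-ties between models are common (the trace
  makes the margins auditable).
* BIC on effective degrees of freedom and the min-p summary of
  by-land-use smooths are pragmatic conventions, not exact theory.
* The kinetics ANOVA assumes a balanced two-way layout; unbalanced
  designs fall back to the same sums of squares with a warning rather
  than a full mixed-model treatment.
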