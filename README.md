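# soilcmin

Statistical pipeline for soil incubation experiments that link soil
properties — especially bacterial and fungal **diversity indexes** — to
the mineralisation of different soil carbon pools. It is written for
soil ecologists and biogeochemists who run ¹³C-labelled residue
incubations and want a reproducible, cross-validated way to ask *which
soil properties explain the respiration kinetics*.

## What it computes

**Isotope partitioning.** For amended microcosms, total respired CO₂
(*R*ₜ) is split into soil-derived (*R*ₛ) and residue-derived (*R*ᵣ)
fluxes by two-endmember ¹³C mass balance:

    Rs + Rr = Rt
    Rs·A¹³s + Rr·A¹³r = Rt·A¹³t
    ⇒  Rr = Rt · (A¹³t − A¹³s) / (A¹³r − A¹³s)

The priming effect is the ratio PE = Rₛ,amended / Rₛ,control, and all
responses are interval rates (µg C-CO₂ g⁻¹ soil day⁻¹) modelled on the
natural-log scale.

**Diversity indexes.** Per-sample richness, Shannon H′ = −Σ pᵢ ln pᵢ,
evenness J′ = H′/ln S and inverse Simpson 1/D = 1/Σ pᵢ² from OTU count
tables.

**Covariate selection.** For each response, additive models

    Y = α + random(time) + f₁(x₁) + … + fₚ(xₚ) + ε

are searched stepwise, where each fⱼ is identity, a degree-2/3
polynomial or a penalized cubic regression spline, optionally
interacted with land use, and time (sampling day) is a mandatory
random factor. Moves are scored by **leave-one-soil-out cross-validated
MSEP** (the fold unit is an entire soil), candidates are pre-screened by
variance inflation factor (threshold 4), and the search stops when no
move strictly reduces the MSEP.

**Assessment.** Explained deviance (%Dev), RPIQ (IQR/√MSEP), per-term
F tests, relative importance by sequential variance partitioning of the
linear-predictor components (redundancy analysis), BIC on effective
degrees of freedom, and a two-way kinetics ANOVA (land use fixed, time
random) with Tukey letter groupings.

A seeded synthetic-data generator reproduces the study design
(20 soils × 2 treatments × 3 replicates × 8 sampling days) with known
ground truth, so the whole pipeline is testable as an inverse problem.
See `vignettes/soilcmin-methods.Rmd` for the full methods account.

## Worked example

```r
library(soilcmin)

sim   <- simulate_dataset(seed = 42)   # synthetic incubation study
frame <- model_frame(sim$dataset)      # partition -> log-rate responses

sel <- stepwise_select(frame, "log_rs_control",
                       candidates = c("bacterial_j", "sand", "cn_ratio"),
                       forms = c("I", "poly2"), interaction_mode = "both")
assess_model(sel)
```

```
Model assessment: log_rs_control
  %Dev = 94.5, MSEP = 0.0224, RPIQ = 5.71, df = 16.99, BIC = -1764.7
   covariate interaction relation significance relative_importance
        time          NO       RF          ***         69.62375538
    land_use          NO        I           ns          0.08823478
 bacterial_j         YES       P2          ***         24.64725210
    cn_ratio         YES       P2            *          0.16391069
  unattributed remainder: -0.00%
```

Reading this: the selected control-soil model keeps the mandatory
random time factor (70% of the response variance — respiration declines
sharply over the 80-day incubation), and recovers the land-use-specific
polynomial dependence on bacterial evenness that the generator injected
(25% of variance, p < 0.001). The cross-validated MSEP of 0.0224
(ln-units²) gives RPIQ = 5.7: the response's spread is ~5.7 times the
model's prediction error. `sel$trace` records every accepted add/remove
move with its MSEP margin.

Real data enter through `read_dataset()` (CSV tables of sites,
respiration intervals and isotope endmembers, with an optional
column-name mapping), and `run_pipeline()` chains
partitioning → selection → assessment for all four responses and
writes a combined report via `write_report()`.

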