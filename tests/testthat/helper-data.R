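# Shared fixtures, built in code.

# Small complete dataset: 4 soils, 2 replicates, 2 sampling days.
small_config <- function(...) {
  generator_config(n_per_land_use = c(cropland = 2L, grassland = 2L),
                   n_replicates = 2L,
                   schedule = c(3, 7),
                   ...)
}

small_dataset <- function(seed = 42, ...) {
  simulate_dataset(small_config(...), seed = seed)$dataset
}

# Model frame for selection studies: 20 soils, independent covariates,
# optional single linear effect of pH on the control-soil log rate.
selection_frame <- function(seed, effect_amplitude = 0, sigma = 0.3) {
  effects <- if (effect_amplitude != 0) {
    list(list(covariate = "ph", response = "rs_control",
              shape = "linear", amplitude = effect_amplitude,
              by_land_use = FALSE))
  } else list()
  cfg <- generator_config(diversity_correlation = 0,
                          effects = effects,
                          noise_sigma = sigma)
  model_frame(simulate_dataset(cfg, seed = seed)$dataset)
}

# Candidate covariates used in the selection studies (site-level,
# mutually ~independent under diversity_correlation = 0).
SIM_CANDIDATES <- c("ph", "soc", "cn_ratio", "molecular_biomass", "clay")

selected_covariates <- function(selection) {
  vapply(selection$spec$terms, function(t) t$covariate, character(1))
}

# Exhaustive LOSO-MSEP search over identity-only subsets of covariates.
exhaustive_best_msep <- function(frame, response, covariates) {
  subsets <- unlist(lapply(0:length(covariates), function(m)
    combn(covariates, m, simplify = FALSE)), recursive = FALSE)
  vals <- vapply(subsets, function(cs) {
    sp <- model_spec(response, lapply(cs, model_term, form = "I"))
    as.numeric(suppressWarnings(loso_msep(sp, frame)))
  }, numeric(1))
  list(msep = min(vals), all = vals, subsets = subsets)
}
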