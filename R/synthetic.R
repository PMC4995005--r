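# Seeded synthetic-data generator emulating the incubation study design:
# 20 soils split between cropland and grassland, 2 treatments (control /
# 13C-residue-amended) x 3 replicates x 8 sampling dates, intercorrelated
# diversity covariates, double-pool exponential decay kinetics modulated
# by configurable covariate effects, multiplicative lognormal noise on
# interval amounts, and two-endmember 13C mixing of the respired CO2.

#' Generator configuration with study-design defaults
#'
#' Defaults reproduce the experimental design the analysis assumes: 10
#' cropland + 10 grassland soils, control and amended treatments, 3
#' replicates, sampling days 3-80. Soil- and residue-carbon mineralisation
#' follow two-pool (fast + slow) first-order decay; pool sizes are in ug C
#' per g soil and rates in 1/day, chosen so that basal respiration starts
#' near 15 ug C/g/day and declines monotonically, and roughly half the
#' added residue C (about 2000 ug C/g for a 5 mg/g amendment) mineralises
#' over 80 days. Covariates are drawn per land use from normal
#' distributions with the four bacterial (and fungal) diversity indexes
#' intercorrelated (default r = 0.8); grassland bacterial 1/D exceeds the
#' cropland mean, the strongest land-use contrast in this kind of data.
#' Interval amounts receive multiplicative lognormal noise (sigma on the
#' log scale). Endmembers default to natural-abundance soil C (1.08
#' atom %) and enriched residue (3.0 atom %).
#'
#' @param ... overrides for any default element (see the function body
#'   for the full list); unknown names are an error.
#' @return a list of generator settings.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_per_land_use = c(cropland = 10L, grassland = 10L),
    n_replicates = 3L,
    schedule = default_schedule(),
    covariate_params = default_covariate_params(),
    diversity_correlation = 0.8,
    effects = list(
      list(covariate = "bacterial_j", response = "rs_control",
           shape = "poly2", amplitude = -0.35, by_land_use = TRUE,
           amplitude_grassland = 0.2),
      list(covariate = "soc", response = "rs_amended",
           shape = "linear", amplitude = 0.3, by_land_use = FALSE),
      list(covariate = "ph", response = "pe",
           shape = "linear", amplitude = 0.25, by_land_use = FALSE)),
    kinetics = list(
      soil_fast = c(size = 150, rate = 0.12),
      soil_slow = c(size = 4500, rate = 0.0012),
      residue_fast = c(size = 900, rate = 0.10),
      residue_slow = c(size = 900, rate = 0.004)),
    pe_multiplier = 1.3,
    noise_sigma = 0.15,
    a13_soil = 1.08,
    a13_residue = 3.0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    cmin_abort(sprintf("unknown generator setting(s): %s",
                       paste(unknown, collapse = ", ")), "config")
  cfg[names(dots)] <- dots
  if (cfg$noise_sigma < 0)
    cmin_abort("noise_sigma must be nonnegative", "config")
  cfg
}

# Per-land-use means and standard deviations for the site covariates.
# Texture closes to 1000 g/kg by construction (sand = 1000 - clay - silt)
# and clay + fine silt is derived as clay + 0.6 * silt.
default_covariate_params <- function() {
  p <- list(
    clay               = list(cropland = c(220, 60), grassland = c(260, 70)),
    silt               = list(cropland = c(380, 80), grassland = c(360, 80)),
    soc                = list(cropland = c(14, 4),   grassland = c(24, 8)),
    cn_ratio           = list(cropland = c(9.5, 1),  grassland = c(10.5, 1.3)),
    ph                 = list(cropland = c(6.6, 0.9), grassland = c(6.2, 0.8)),
    molecular_biomass  = list(cropland = c(18, 7),   grassland = c(30, 10)),
    bacterial_richness = list(cropland = c(1100, 180), grassland = c(1200, 200)),
    bacterial_h        = list(cropland = c(6.1, 0.25), grassland = c(6.3, 0.25)),
    bacterial_j        = list(cropland = c(0.84, 0.03), grassland = c(0.87, 0.03)),
    bacterial_invd     = list(cropland = c(100, 40), grassland = c(180, 60)),
    fungal_richness    = list(cropland = c(320, 80), grassland = c(360, 90)),
    fungal_h           = list(cropland = c(3.4, 0.5), grassland = c(3.6, 0.5)),
    fungal_j           = list(cropland = c(0.60, 0.07), grassland = c(0.63, 0.07)),
    fungal_invd        = list(cropland = c(12, 6), grassland = c(16, 7)))
  p
}

#' Generate the per-soil covariate table
#'
#' Diversity-index blocks (the four bacterial indexes; the four fungal
#' indexes) are drawn from a multivariate normal with constant
#' within-block correlation, then projected onto their invariants:
#' evenness clipped to \[0, 1\], inverse Simpson to \[1, richness\], Shannon
#' H' to \[0, ln(richness)\].
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return data frame of site records (see `SITE_COLUMNS`).
#' @export
generate_sites <- function(config = generator_config(), seed = 1) {
  set.seed(seed)
  n <- config$n_per_land_use
  land_use <- rep(names(n), n)
  ns <- sum(n)
  sites <- data.frame(site_id = sprintf("S%02d", seq_len(ns)),
                      land_use = land_use)
  cp <- config$covariate_params
  draw <- function(cov) {
    out <- numeric(ns)
    for (lu in names(n)) {
      i <- land_use == lu
      out[i] <- stats::rnorm(sum(i), cp[[cov]][[lu]][1], cp[[cov]][[lu]][2])
    }
    out
  }
  draw_block <- function(covs) {
    rho <- config$diversity_correlation
    p <- length(covs)
    sigma <- matrix(rho, p, p); diag(sigma) <- 1
    z <- MASS::mvrnorm(ns, mu = rep(0, p), Sigma = sigma)
    out <- matrix(0, ns, p, dimnames = list(NULL, covs))
    for (j in seq_len(p)) {
      for (lu in names(n)) {
        i <- land_use == lu
        out[i, j] <- cp[[covs[j]]][[lu]][1] + z[i, j] * cp[[covs[j]]][[lu]][2]
      }
    }
    out
  }
  sites$clay <- pmax(draw("clay"), 10)
  sites$silt <- pmax(draw("silt"), 10)
  # texture closes to 1000 g/kg exactly
  over <- sites$clay + sites$silt > 980
  sc <- ifelse(over, 980 / (sites$clay + sites$silt), 1)
  sites$clay <- sites$clay * sc
  sites$silt <- sites$silt * sc
  sites$sand <- 1000 - sites$clay - sites$silt
  sites$clay_fine_silt <- sites$clay + 0.6 * sites$silt
  sites$soc <- pmax(draw("soc"), 2)
  sites$cn_ratio <- pmax(draw("cn_ratio"), 5)
  sites$ph <- pmin(pmax(draw("ph"), 3.8), 8.7)
  sites$molecular_biomass <- pmax(draw("molecular_biomass"), 1)

  for (org in c("bacterial", "fungal")) {
    covs <- paste0(org, c("_richness", "_h", "_j", "_invd"))
    b <- draw_block(covs)
    rich <- pmax(round(b[, 1]), 5)
    j <- pmin(pmax(b[, 3], 0.05), 1)
    h <- pmin(pmax(b[, 2], 0), log(rich))
    invd <- pmin(pmax(b[, 4], 1), rich)
    sites[[covs[1]]] <- rich
    sites[[covs[2]]] <- h
    sites[[covs[3]]] <- j
    sites[[covs[4]]] <- invd
  }
  sites
}

effect_shape <- function(shape) {
  switch(shape,
         linear = function(z) z,
         poly2 = ,
         quadratic = function(z) z^2 - 1,
         poly3 = ,
         cubic = function(z) z^3,
         smooth = function(z) sin(1.5 * z),
         cmin_abort(paste("unknown effect shape:", shape), "config"))
}

# log-scale effect totals per site for one response target
effect_log_terms <- function(sites, config, target) {
  total <- numeric(nrow(sites))
  for (eff in config$effects) {
    if (eff$response != target) next
    if (!eff$covariate %in% names(sites))
      cmin_abort(sprintf("effect covariate '%s' not in site table",
                         eff$covariate), "config")
    x <- sites[[eff$covariate]]
    z <- (x - mean(x)) / stats::sd(x)
    f <- effect_shape(eff$shape)(z)
    amp <- rep(eff$amplitude, nrow(sites))
    if (isTRUE(eff$by_land_use)) {
      amp[sites$land_use == "grassland"] <-
        eff$amplitude_grassland %||% -eff$amplitude
    }
    total <- total + amp * f
  }
  total
}

two_pool_interval <- function(pools, t0, t1) {
  f <- pools[[1]]; s <- pools[[2]]
  f["size"] * (exp(-f["rate"] * t0) - exp(-f["rate"] * t1)) +
    s["size"] * (exp(-s["rate"] * t0) - exp(-s["rate"] * t1))
}

#' Generate respiration records and ground truth for a site table
#'
#' Soil-derived respiration follows the two-pool decay scaled by
#' exp(covariate effects targeting `rs_control`) in both treatments;
#' amended microcosms multiply the soil-derived flux by the priming
#' multiplier, exp(effects targeting `pe`) and exp(effects targeting
#' `rs_amended`), and add residue-derived decay scaled by exp(effects
#' targeting `rr`). One lognormal noise factor per microcosm-interval
#' multiplies both components so the 13C mixture abundance stays exactly
#' consistent with the underlying partition.
#'
#' @param sites site table from [generate_sites()].
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return list with `respiration` (record table), `endmembers`, and
#'   `truth`: realized per-cell soil/residue amounts (`rs`, `rr`), the
#'   deterministic priming multiplier per site, and the sampled effect
#'   functions (`effect_grid`).
#' @export
generate_respiration <- function(sites, config = generator_config(),
                                 seed = 1) {
  set.seed(seed + 1L)
  sched <- config$schedule
  t0 <- c(0, utils::head(sched, -1))
  ns <- nrow(sites)
  soil_base <- two_pool_interval(config$kinetics[c("soil_fast", "soil_slow")],
                                 t0, sched)
  res_base <- two_pool_interval(config$kinetics[c("residue_fast",
                                                  "residue_slow")],
                                t0, sched)
  e_ctrl <- exp(effect_log_terms(sites, config, "rs_control"))
  e_amd <- exp(effect_log_terms(sites, config, "rs_amended"))
  e_pe <- exp(effect_log_terms(sites, config, "pe"))
  e_rr <- exp(effect_log_terms(sites, config, "rr"))
  pe_mult <- config$pe_multiplier * e_pe * e_amd

  grid <- expand.grid(interval = seq_along(sched),
                      replicate = seq_len(config$n_replicates),
                      treatment = c("control", "amended"),
                      site = seq_len(ns), stringsAsFactors = FALSE)
  noise <- exp(stats::rnorm(nrow(grid), 0, config$noise_sigma))
  i <- grid$site; itv <- grid$interval
  amended <- grid$treatment == "amended"
  rs <- soil_base[itv] * e_ctrl[i] *
    ifelse(amended, pe_mult[i], 1) * noise
  rr <- ifelse(amended, res_base[itv] * e_rr[i] * noise, 0)
  rt <- rs + rr
  a13 <- ifelse(amended,
                (rs * config$a13_soil + rr * config$a13_residue) / rt,
                NA_real_)
  respiration <- data.frame(site_id = sites$site_id[i],
                            treatment = grid$treatment,
                            replicate = grid$replicate,
                            t_start = t0[itv], t_end = sched[itv],
                            co2_interval = rt,
                            a13_total = a13)
  endmembers <- data.frame(site_id = sites$site_id,
                           a13_soil = config$a13_soil,
                           a13_residue = config$a13_residue)
  zg <- seq(-2, 2, length.out = 41)
  effect_grid <- lapply(config$effects, function(eff)
    list(covariate = eff$covariate, response = eff$response,
         z = zg, f = eff$amplitude * effect_shape(eff$shape)(zg)))
  truth <- list(cells = data.frame(site_id = sites$site_id[i],
                                   treatment = grid$treatment,
                                   replicate = grid$replicate,
                                   t_start = t0[itv], t_end = sched[itv],
                                   rs = rs, rr = rr),
                pe_multiplier = stats::setNames(pe_mult, sites$site_id),
                effect_grid = effect_grid)
  list(respiration = respiration, endmembers = endmembers, truth = truth)
}

#' Generate a complete synthetic incubation dataset
#'
#' @param config a [generator_config()].
#' @param seed integer seed governing all randomness.
#' @return list with `dataset` (a validated `cmin_dataset`) and `truth`
#'   (see [generate_respiration()]).
#' @export
simulate_dataset <- function(config = generator_config(), seed = 1) {
  sites <- generate_sites(config, seed)
  resp <- generate_respiration(sites, config, seed)
  ds <- cmin_dataset(sites, resp$respiration, resp$endmembers,
                     schedule = config$schedule)
  list(dataset = ds, truth = resp$truth)
}

#' Generate an OTU count table matching target diversity profiles
#'
#' Per sample, relative OTU abundances follow a geometric series whose
#' decay parameter is tuned (by root finding) so that the evenness of the
#' expected composition matches the target; counts are then drawn
#' multinomially at the given sequencing depth. With `depth = Inf` the
#' exact expected composition is returned (scaled to sum to 1), removing
#' sampling noise.
#'
#' @param targets data frame with columns `sample_id`, `richness`,
#'   `evenness_j` (targets; evenness in (0, 1]).
#' @param depth reads per sample (default 5000), or `Inf`.
#' @param seed integer seed.
#' @return matrix, samples in rows, OTUs in columns.
#' @export
generate_otu_table <- function(targets, depth = 5000, seed = 1) {
  set.seed(seed + 2L)
  smax <- max(targets$richness)
  out <- matrix(0, nrow(targets), smax,
                dimnames = list(targets$sample_id,
                                paste0("OTU", seq_len(smax))))
  for (r in seq_len(nrow(targets))) {
    s <- targets$richness[r]
    jt <- targets$evenness_j[r]
    if (s < 1 || jt <= 0 || jt > 1)
      cmin_abort("unreachable (richness, evenness) target", "target")
    p <- geometric_composition(s, jt)
    if (is.infinite(depth)) out[r, seq_len(s)] <- p
    else out[r, seq_len(s)] <- stats::rmultinom(1, depth, p)[, 1]
  }
  out
}

# relative abundances p_i proportional to theta^(i-1) with theta chosen so
# that the expected-composition evenness equals the target
geometric_composition <- function(s, j_target) {
  if (s == 1) return(1)
  comp_of <- function(theta) {
    # log-space evaluation; ranks far down the series may underflow to
    # exactly zero, which the entropy treats as 0 * log 0 = 0
    lp <- (seq_len(s) - 1) * log(theta)
    p <- exp(lp - max(lp))
    p / sum(p)
  }
  even_of <- function(theta) {
    p <- comp_of(theta)
    p <- p[p > 0]
    -sum(p * log(p)) / log(s)
  }
  if (j_target >= 1 - 1e-12) return(rep(1 / s, s))
  lo <- 1e-8
  if (even_of(lo) > j_target)
    cmin_abort(sprintf("evenness target %.3f unreachable with richness %d",
                       j_target, s), "target")
  theta <- stats::uniroot(function(th) even_of(th) - j_target,
                          c(lo, 1 - 1e-12), tol = 1e-12)$root
  comp_of(theta)
}
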