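# Two-endmember 13C mass-balance partitioning of respired CO2, the
# priming-effect ratio, and construction of the log-rate response table.
#
# For an amended microcosm the total respired CO2 (Rt) mixes soil-derived
# (Rs) and residue-derived (Rr) carbon:
#     Rs + Rr = Rt
#     Rs * A13s + Rr * A13r = Rt * A13t
# which solves to Rr = Rt * (A13t - A13s) / (A13r - A13s), Rs = Rt - Rr.

#' Partition total respiration into soil- and residue-derived fluxes
#'
#' Solves the two-endmember 13C mass balance for each observation.
#' Solutions with a (slightly) negative component, as produced by
#' measurement noise pushing the mixture abundance outside the endmember
#' interval, are clamped to zero with the complementary flux rescaled to
#' preserve the total, and flagged.
#'
#' @param rt total respired C-CO2 (ug C per g soil), nonnegative.
#' @param a13_total 13C abundance of the respired CO2 (same scale as the
#'   endmembers, e.g. atom %).
#' @param a13_soil,a13_residue endmember 13C abundances (recycled).
#' @param endmember_tol minimum |a13_residue - a13_soil| below which the
#'   mixing problem is degenerate.
#' @param mixture_tol tolerance, as a fraction of the endmember separation,
#'   by which `a13_total` may fall outside the endmember interval before a
#'   warning is raised (the component is clamped either way).
#' @return data frame with columns `rs`, `rr`, `clamped`.
#' @export
#' @examples
#' partition_respiration(100, 2.05, 1.1, 3.0) # 50/50 split
partition_respiration <- function(rt, a13_total, a13_soil, a13_residue,
                                  endmember_tol = 1e-6,
                                  mixture_tol = 0.05) {
  n <- length(rt)
  a13_soil <- rep_len(a13_soil, n)
  a13_residue <- rep_len(a13_residue, n)
  sep <- a13_residue - a13_soil
  if (any(abs(sep) <= endmember_tol))
    cmin_abort("endmember 13C abundances are too close to partition",
               "degenerate_mixing")
  if (any(rt < 0, na.rm = TRUE))
    cmin_abort("total respiration must be nonnegative", "data")

  frac <- (a13_total - a13_soil) / sep
  out_of_range <- !is.na(frac) & (frac < -mixture_tol | frac > 1 + mixture_tol)
  if (any(out_of_range))
    cmin_warn(sprintf(
      "%d mixture abundance(s) fall outside the endmember interval; clamped",
      sum(out_of_range)), "mixture_range")

  rr <- rt * frac
  rs <- rt - rr
  clamped <- !is.na(rr) & (rr < 0 | rs < 0)
  rr <- pmin(pmax(rr, 0), rt)
  rs <- rt - rr
  data.frame(rs = rs, rr = rr, clamped = clamped)
}

#' Priming-effect ratio
#'
#' The priming effect is the ratio of soil-derived respiration in the
#' amended microcosm to that in the matched control, a strictly positive
#' quantity whose logarithm is used as a model response.
#'
#' @param rs_amended,rs_control soil-derived respiration (same units).
#' @return numeric vector of ratios; entries with a nonpositive control are
#'   `NA` with attribute `n_undefined` counting them.
#' @export
priming_effect <- function(rs_amended, rs_control) {
  stopifnot(length(rs_amended) == length(rs_control))
  bad <- !is.na(rs_control) & rs_control <= 0
  pe <- rs_amended / rs_control
  pe[bad] <- NA_real_
  if (any(bad))
    cmin_warn(sprintf("priming effect undefined for %d cell(s) with nonpositive control respiration",
                      sum(bad)), "undefined_pe")
  attr(pe, "n_undefined") <- sum(bad)
  pe
}

# Interval start for each respiration row given the schedule.
interval_starts <- function(schedule) {
  stats::setNames(c(0, utils::head(schedule, -1)), schedule)
}

#' Build the log-rate response table
#'
#' Partitions every amended interval, converts interval amounts to rates
#' (amount divided by interval length, ug C-CO2 per g soil per day), pairs
#' amended with control replicates to form the priming-effect ratio, and
#' returns natural-log responses ready for model fitting. Cells with a
#' nonpositive rate are excluded from the corresponding log response and
#' counted in the attached QC attributes.
#'
#' @param ds a validated `cmin_dataset`.
#' @param pe_pairing `"replicate"` (amended replicate u over control
#'   replicate u, the default) or `"mean"` (amended replicate over the
#'   control replicate mean).
#' @return data frame with one row per (site, replicate, sampling day):
#'   columns `site_id`, `replicate`, `time`, the rates `rate_rs_control`,
#'   `rate_rs_amended`, `rate_rr`, `pe`, and log responses `log_rs_control`,
#'   `log_rs_amended`, `log_rr`, `log_pe`. Attributes `n_excluded` (cells
#'   dropped from log responses) and `n_clamped` (partition clamps).
#' @export
build_responses <- function(ds, pe_pairing = c("replicate", "mean")) {
  pe_pairing <- match.arg(pe_pairing)
  r <- ds$respiration
  r$dt <- r$t_end - r$t_start

  em <- ds$endmembers[match(r$site_id, ds$endmembers$site_id), ]
  amended <- r$treatment == "amended"
  part <- partition_respiration(r$co2_interval[amended],
                                r$a13_total[amended],
                                em$a13_soil[amended],
                                em$a13_residue[amended])
  r$rs <- ifelse(amended, NA_real_, r$co2_interval)
  r$rr <- 0
  r$rs[amended] <- part$rs
  r$rr[amended] <- part$rr
  n_clamped <- sum(part$clamped)

  ctrl <- r[r$treatment == "control", ]
  amd <- r[amended, ]
  key <- function(d) paste(d$site_id, d$replicate, d$t_end, sep = "|")
  base <- ctrl[c("site_id", "replicate", "t_end", "dt")]
  names(base)[3] <- "time"
  base$rate_rs_control <- ctrl$rs / ctrl$dt
  i <- match(key(ctrl), key(amd))
  base$rate_rs_amended <- amd$rs[i] / amd$dt[i]
  base$rate_rr <- amd$rr[i] / amd$dt[i]

  if (pe_pairing == "replicate") {
    base$pe <- as.numeric(priming_effect(base$rate_rs_amended,
                                         base$rate_rs_control))
  } else {
    agg <- stats::aggregate(rate_rs_control ~ site_id + time, base, mean)
    j <- match(paste(base$site_id, base$time),
               paste(agg$site_id, agg$time))
    base$pe <- as.numeric(priming_effect(base$rate_rs_amended,
                                         agg$rate_rs_control[j]))
  }

  safe_log <- function(x) ifelse(!is.na(x) & x > 0, log(x), NA_real_)
  base$log_rs_control <- safe_log(base$rate_rs_control)
  base$log_rs_amended <- safe_log(base$rate_rs_amended)
  base$log_rr <- safe_log(base$rate_rr)
  base$log_pe <- safe_log(base$pe)

  n_excluded <- sum(is.na(base[c("log_rs_control", "log_rs_amended",
                                 "log_rr", "log_pe")]))
  base$dt <- NULL
  rownames(base) <- NULL
  attr(base, "n_excluded") <- n_excluded
  attr(base, "n_clamped") <- n_clamped
  base
}

#' Model frame joining responses with site covariates
#'
#' @param ds a `cmin_dataset`.
#' @param responses a response table from [build_responses()]; computed if
#'   omitted.
#' @return data frame with the response columns plus `land_use` and all
#'   site covariates, one row per (site, replicate, sampling day).
#' @export
model_frame <- function(ds, responses = build_responses(ds)) {
  out <- merge(responses, ds$sites, by = "site_id", sort = FALSE)
  out$land_use <- factor(out$land_use, levels = c("cropland", "grassland"))
  out[order(out$site_id, out$replicate, out$time), , drop = FALSE]
}
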