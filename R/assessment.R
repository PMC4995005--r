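# Post-selection model assessment: RPIQ, variance-partitioning relative
# importance of the linear-predictor components, BIC for model-family
# comparison, and the two-way kinetics ANOVA with Tukey groupings.

#' Ratio of performance to inter-quartile range (RPIQ)
#'
#' The inter-quartile range of the response divided by the root MSEP;
#' higher values indicate better predictive quality. Quartiles use the
#' linear-interpolation convention (R's default, type 7).
#'
#' @param y response values (at least 4).
#' @param msep cross-validated mean squared error of prediction, > 0.
#' @return a single dimensionless number.
#' @export
#' @examples
#' rpiq(c(1, 2, 3, 4, 5), msep = 4) # IQR 2 / sqrt(4) = 1
rpiq <- function(y, msep) {
  y <- y[!is.na(y)]
  if (length(y) < 4) cmin_abort("RPIQ needs at least 4 response values",
                                "data")
  if (!is.finite(msep) || msep <= 0)
    cmin_abort("RPIQ undefined: MSEP must be positive (a zero MSEP means perfect prediction)",
               "perfect_prediction")
  as.numeric(diff(stats::quantile(y, c(0.25, 0.75), type = 7))) / sqrt(msep)
}

#' Sequential variance attribution over component columns
#'
#' Redundancy analysis of a single response on a set of linear-predictor
#' components reduces to ordinary least squares; the per-component
#' contributions are the sequential (type I) sums of squares in the given
#' order, as fractions of the total response sum of squares. The marginal
#' mode instead charges each component with its drop in residual sum of
#' squares when added last.
#'
#' @param y response values.
#' @param comps numeric matrix of component columns (named).
#' @param attribution `"sequential"` (default) or `"marginal"`.
#' @return data frame with `component`, `ss` and `pct` (share of total
#'   response sum of squares, in percent).
#' @export
sequential_importance <- function(y, comps,
                                  attribution = c("sequential",
                                                  "marginal")) {
  attribution <- match.arg(attribution)
  comps <- as.matrix(comps)
  tss <- sum((y - mean(y))^2)
  if (tss <= 0) cmin_abort("response has zero variance",
                           "degenerate_response")
  df <- data.frame(y = y, comps, check.names = FALSE)
  nm <- colnames(comps)
  qnm <- paste0("`", nm, "`")
  if (attribution == "sequential") {
    fit <- stats::lm(stats::reformulate(qnm, "y"), data = df)
    a <- stats::anova(fit)
    ss <- a[nm, "Sum Sq"]
  } else {
    full <- stats::lm(stats::reformulate(qnm, "y"), data = df)
    rss_full <- sum(stats::residuals(full)^2)
    ss <- vapply(seq_along(nm), function(i) {
      red <- stats::lm(stats::reformulate(qnm[-i], "y"), data = df)
      sum(stats::residuals(red)^2) - rss_full
    }, numeric(1))
  }
  data.frame(component = nm, ss = ss, pct = 100 * ss / tss,
             row.names = NULL)
}

#' Relative importance of model components
#'
#' Extracts the linear-predictor components of a fitted model (random time
#' factor first, then land-use main effect if present, then covariate
#' terms in selection order) and partitions the response variance among
#' them by constrained-ordination sums of squares (see
#' [sequential_importance()]). The share of explained deviance not
#' attributed to any single component is reported as the remainder; it can
#' be slightly negative because the ordination re-estimates component
#' coefficients, undoing a little of the penalization shrinkage.
#'
#' @param object a `cmin_gam`.
#' @param attribution `"sequential"` (default) or `"marginal"`.
#' @return data frame of per-component `pct` importances; attribute
#'   `remainder` holds `%Dev - sum(pct)`.
#' @export
relative_importance <- function(object,
                                attribution = c("sequential", "marginal")) {
  attribution <- match.arg(attribution)
  comps <- component_matrix(object)
  y <- object$train[[object$spec$response]]
  qr_c <- qr(cbind(1, comps))
  if (qr_c$rank < ncol(comps) + 1)
    cmin_warn("component matrix is rank deficient; attribution is not unique",
              "attribution")
  imp <- sequential_importance(y, comps, attribution)
  attr(imp, "remainder") <- explained_deviance(object) - sum(imp$pct)
  imp
}

#' Bayesian information criterion of a penalized Gaussian fit
#'
#' Gaussian profile form `n log(RSS/n) + edf log(n)` with the model's
#' total effective degrees of freedom playing the role of the parameter
#' count, consistent with reporting fractional df for penalized fits.
#'
#' @param object a `cmin_gam`, or a list with elements `n`, `rss`, `edf`.
#' @return BIC value.
#' @export
#' @examples
#' bic_gam(list(n = 100, rss = 100, edf = 3)) # 3 * log(100)
bic_gam <- function(object) {
  if (inherits(object, "cmin_gam")) {
    n <- length(stats::fitted(object$gam))
    rss <- object$gam$deviance
    edf <- edf_total(object)
  } else {
    n <- object$n; rss <- object$rss; edf <- object$edf
  }
  if (rss <= 0)
    cmin_abort("zero residual sum of squares; likelihood degenerate",
               "degenerate_likelihood")
  n * log(rss / n) + edf * log(n)
}

#' Two-way ANOVA of a mineralisation kinetic with Tukey groupings
#'
#' Fits `value ~ land_use * time` with land use fixed and time treated as
#' a random factor: the land-use and time F ratios are formed against the
#' interaction mean square (the appropriate denominator for a mixed
#' two-way layout), the interaction against the residual. Post-hoc Tukey
#' honest-significant-difference comparisons give letter groupings across
#' sampling times and a significance code for the cropland-grassland
#' contrast at each time.
#'
#' @param data data frame with columns `value`, `land_use`, `time` (and
#'   replication within cells).
#' @param alpha significance level for the time letter groupings.
#' @return a `cmin_kinetics_anova`: list with `anova` (effect table),
#'   `time_letters` (letters per sampling time, shared letter = not
#'   significantly different) and `land_use_by_time` (per-time contrast
#'   p-values and codes).
#' @export
kinetics_anova <- function(data, alpha = 0.05) {
  data$land_use <- factor(data$land_use)
  data$time_f <- factor(data$time)
  if (nlevels(data$land_use) < 2 || nlevels(data$time_f) < 2)
    cmin_abort("need at least two levels of land use and time", "data")
  fit <- stats::aov(value ~ land_use * time_f, data = data)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  ms <- tab[, "Mean Sq"]; dfs <- tab[, "Df"]
  i_lu <- which(rn == "land_use"); i_t <- which(rn == "time_f")
  i_int <- which(rn == "land_use:time_f"); i_res <- which(rn == "Residuals")
  f_lu <- ms[i_lu] / ms[i_int]
  f_t <- ms[i_t] / ms[i_int]
  f_int <- ms[i_int] / ms[i_res]
  eff <- data.frame(
    effect = c("land_use", "time", "land_use:time"),
    df = dfs[c(i_lu, i_t, i_int)],
    df_denom = c(dfs[i_int], dfs[i_int], dfs[i_res]),
    statistic = c(f_lu, f_t, f_int))
  eff$p_value <- stats::pf(eff$statistic, eff$df, eff$df_denom,
                           lower.tail = FALSE)
  eff$code <- sig_code(eff$p_value)

  tk <- stats::TukeyHSD(fit)
  tt <- tk$time_f
  lev <- levels(data$time_f)
  diff_mat <- matrix(FALSE, length(lev), length(lev),
                     dimnames = list(lev, lev))
  pairs <- do.call(rbind, strsplit(rownames(tt), "-", fixed = TRUE))
  for (r in seq_len(nrow(tt))) {
    if (tt[r, "p adj"] < alpha) {
      diff_mat[pairs[r, 1], pairs[r, 2]] <- TRUE
      diff_mat[pairs[r, 2], pairs[r, 1]] <- TRUE
    }
  }
  means <- tapply(data$value, data$time_f, mean)
  time_letters <- data.frame(time = lev, mean = as.numeric(means[lev]),
                             letters = compact_letters(diff_mat, means))

  ti <- tk$`land_use:time_f`
  lu <- levels(data$land_use)
  cmp <- do.call(rbind, strsplit(rownames(ti), "-", fixed = TRUE))
  part <- function(x) do.call(rbind, strsplit(x, ":", fixed = TRUE))
  a <- part(cmp[, 1]); b <- part(cmp[, 2])
  same_time <- a[, 2] == b[, 2] & a[, 1] != b[, 1]
  lu_time <- data.frame(time = a[same_time, 2],
                        p_value = ti[same_time, "p adj"])
  lu_time <- lu_time[order(as.numeric(lu_time$time)), ]
  lu_time$code <- sig_code(lu_time$p_value)
  rownames(lu_time) <- NULL

  structure(list(anova = eff, time_letters = time_letters,
                 land_use_by_time = lu_time),
            class = "cmin_kinetics_anova")
}

#' @export
print.cmin_kinetics_anova <- function(x, ...) {
  cat("Two-way kinetics ANOVA (land use fixed, time random)\n")
  print(x$anova, row.names = FALSE)
  cat("Tukey time groupings:\n")
  print(x$time_letters, row.names = FALSE)
  invisible(x)
}

#' Assemble the assessment report for one selected model
#'
#' @param selection a `cmin_selection` from [stepwise_select()].
#' @param attribution variance-attribution mode for
#'   [relative_importance()].
#' @return a `cmin_assessment`: list with scalar summaries (`response`,
#'   `pct_deviance`, `msep`, `rpiq`, `edf`, `bic`) and a per-component
#'   `terms` table with relation type, interaction flag, significance code
#'   and relative importance (%), plus the unattributed `remainder`.
#' @export
assess_model <- function(selection,
                         attribution = c("sequential", "marginal")) {
  fit <- selection$fit
  y <- fit$train[[fit$spec$response]]
  sig <- term_significance(fit)
  imp <- relative_importance(fit, attribution)
  tab <- merge(sig, imp[c("component", "pct")], by = "component",
               sort = FALSE)
  relation <- ifelse(tab$component == "time", "RF",
                     c(I = "I", poly2 = "P2", poly3 = "P3",
                       s = "s")[tab$form])
  terms <- data.frame(covariate = tab$component,
                      interaction = ifelse(tab$by_land_use, "YES", "NO"),
                      relation = relation,
                      significance = tab$code,
                      relative_importance = tab$pct)
  structure(list(response = fit$spec$response,
                 pct_deviance = explained_deviance(fit),
                 msep = selection$msep,
                 rpiq = rpiq(y, selection$msep),
                 edf = edf_total(fit),
                 bic = bic_gam(fit),
                 terms = terms,
                 remainder = attr(imp, "remainder")),
            class = "cmin_assessment")
}

#' @export
print.cmin_assessment <- function(x, ...) {
  cat(sprintf("Model assessment: %s\n", x$response))
  cat(sprintf("  %%Dev = %.1f, MSEP = %.4f, RPIQ = %.2f, df = %.2f, BIC = %.1f\n",
              x$pct_deviance, x$msep, x$rpiq, x$edf, x$bic))
  print(x$terms, row.names = FALSE)
  cat(sprintf("  unattributed remainder: %.2f%%\n", x$remainder))
  invisible(x)
}
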