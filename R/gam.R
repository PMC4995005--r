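# Additive-model engine for the mineralisation responses.
#
# Every candidate model has the form
#   y = intercept + random(time) [+ land_use] + f1(x1) + f2(x2) + ...
# where each f_j is one of: identity (I), orthogonal polynomial of degree
# 2 or 3 (poly2, poly3), or a penalized cubic regression spline (s), each
# optionally interacted with land use so that croplands and grasslands get
# their own relationship. Time (sampling day, categorical) is mandatory
# and modelled as a random factor: per-date intercepts shrunk by a ridge
# penalty, mgcv's s(time_f, bs = "re"). Responses are Gaussian on the log
# scale with identity link. Fitting is penalized least squares via mgcv,
# with smoothing parameters chosen by GCV by default (REML optional).
# Covariates are standardized (z-score) on the training data before basis
# construction; the scaling is stored so predictions and reports are on
# the original scale.

FORM_LEVELS <- c("I", "poly2", "poly3", "s")

#' Construct a model term
#'
#' @param covariate name of a site covariate.
#' @param form functional form: `"I"` (linear), `"poly2"`, `"poly3"`
#'   (orthogonal polynomials) or `"s"` (penalized cubic regression spline).
#' @param by_land_use if `TRUE` the relationship is estimated separately
#'   for cropland and grassland.
#' @return a `cmin_term`.
#' @export
model_term <- function(covariate, form = "I", by_land_use = FALSE) {
  form <- match.arg(form, FORM_LEVELS)
  structure(list(covariate = covariate, form = form,
                 by_land_use = isTRUE(by_land_use)),
            class = "cmin_term")
}

#' Construct a model specification
#'
#' The specification always contains the intercept and the random time
#' factor; `terms` lists the covariate terms in order. A land-use main
#' effect is included automatically whenever any term interacts with land
#' use (interactions without main effects are ill-posed).
#'
#' @param response name of the response column in the model frame (e.g.
#'   `"log_rs_control"`).
#' @param terms list of [model_term()] objects; empty list for the initial
#'   intercept + time model.
#' @return a `cmin_spec`.
#' @export
model_spec <- function(response, terms = list()) {
  covs <- vapply(terms, function(t) t$covariate, character(1))
  if (anyDuplicated(covs))
    cmin_abort("a covariate appears in more than one term", "spec")
  structure(list(response = response, terms = terms,
                 includes_land_use_main =
                   any(vapply(terms, function(t) t$by_land_use, logical(1)))),
            class = "cmin_spec")
}

# both orderings of an interaction label, as R may list the factor first
with_land_use <- function(base) {
  c(paste0(base, ":land_use"), paste0("land_use:", base))
}

term_label <- function(t) {
  sprintf("%s(%s%s)", t$form, t$covariate,
          if (t$by_land_use) " by land_use" else "")
}

#' @export
print.cmin_spec <- function(x, ...) {
  cat(sprintf("%s ~ intercept + random(time)%s%s\n", x$response,
              if (x$includes_land_use_main) " + land_use" else "",
              if (length(x$terms))
                paste0(" + ", paste(vapply(x$terms, term_label,
                                           character(1)), collapse = " + "))
              else ""))
  invisible(x)
}

# mgcv formula fragment for one term (on the standardized covariate).
term_formula <- function(t, k) {
  base <- switch(t$form,
                 I = t$covariate,
                 poly2 = sprintf("poly(%s, 2)", t$covariate),
                 poly3 = sprintf("poly(%s, 3)", t$covariate),
                 s = sprintf('s(%s, bs = "cr", k = %d', t$covariate, k))
  if (t$form == "s") {
    if (t$by_land_use) paste0(base, ", by = land_use)") else paste0(base, ")")
  } else {
    if (t$by_land_use) paste0(base, ":land_use") else base
  }
}

spec_formula <- function(spec, k) {
  rhs <- 's(time_f, bs = "re")'
  if (spec$includes_land_use_main) rhs <- c(rhs, "land_use")
  rhs <- c(rhs, vapply(spec$terms, term_formula, character(1), k = k))
  stats::reformulate(rhs, response = spec$response)
}

prepare_frame <- function(spec, data, scaling = NULL, k = 5,
                          time_levels = NULL) {
  needed <- c(spec$response, "time",
              vapply(spec$terms, function(t) t$covariate, character(1)))
  if (spec$includes_land_use_main) needed <- c(needed, "land_use")
  missing <- setdiff(needed, names(data))
  if (length(missing))
    cmin_abort(sprintf("model frame is missing column(s): %s",
                       paste(missing, collapse = ", ")), "spec")
  df <- data
  df$time_f <- if (is.null(time_levels)) factor(df$time)
               else factor(df$time, levels = time_levels)
  if ("land_use" %in% names(df)) df$land_use <- factor(df$land_use)
  if (is.null(scaling)) {
    scaling <- lapply(spec$terms, function(t) {
      x <- df[[t$covariate]]
      if (length(unique(x)) < 2)
        cmin_abort(sprintf("covariate '%s' is constant", t$covariate),
                   "basis")
      if (t$form == "s" && length(unique(x)) < k)
        cmin_abort(sprintf(
          "covariate '%s' has fewer than k = %d distinct values; reduce the basis dimension",
          t$covariate, k), "basis")
      c(center = mean(x), scale = stats::sd(x))
    })
    names(scaling) <- vapply(spec$terms, function(t) t$covariate,
                             character(1))
  }
  for (cov in names(scaling)) {
    df[[cov]] <- (df[[cov]] - scaling[[cov]]["center"]) /
      scaling[[cov]]["scale"]
  }
  list(df = df, scaling = scaling)
}

#' Fit an additive model
#'
#' @param spec a [model_spec()].
#' @param data model frame (see [model_frame()]) containing the response,
#'   `time`, `land_use` and every covariate named by the spec. Rows with a
#'   missing response are dropped.
#' @param k basis dimension for spline terms (default 5, suited to ~20
#'   distinct site values).
#' @param method smoothing-parameter criterion, `"GCV.Cp"` (default) or
#'   `"REML"`.
#' @return a `cmin_gam`: list holding the mgcv fit (`$gam`), the spec, the
#'   covariate scaling, and the training time levels.
#' @export
fit_gam <- function(spec, data, k = 5, method = c("GCV.Cp", "REML")) {
  method <- match.arg(method)
  data <- data[!is.na(data[[spec$response]]), , drop = FALSE]
  prep <- prepare_frame(spec, data, k = k)
  fml <- spec_formula(spec, k)
  fit <- tryCatch(
    mgcv::gam(fml, data = prep$df, method = method),
    error = function(e)
      cmin_abort(sprintf("model fit failed for %s: %s",
                         paste(deparse(fml), collapse = ""),
                         conditionMessage(e)), "fit"))
  structure(list(gam = fit, spec = spec, k = k, method = method,
                 scaling = prep$scaling,
                 time_levels = levels(prep$df$time_f),
                 train = prep$df),
            class = "cmin_gam")
}

#' Predict from a fitted additive model
#'
#' Evaluates the linear predictor on new data. Sampling days never seen in
#' training get a random-factor contribution of zero (with a warning), the
#' natural prediction for an unobserved level of a shrunk factor.
#'
#' @param object a `cmin_gam`.
#' @param newdata data frame with `time`, `land_use` (if used) and the
#'   covariates, on the original scale.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.cmin_gam <- function(object, newdata, ...) {
  spec <- object$spec
  nd <- newdata
  nd$time_f <- factor(nd$time, levels = object$time_levels)
  unseen <- is.na(nd$time_f) & !is.na(nd$time)
  if (any(unseen)) {
    cmin_warn(sprintf("%d row(s) at sampling days unseen in training; time effect set to 0",
                      sum(unseen)), "unseen_level")
    nd$time_f[unseen] <- object$time_levels[1]
  }
  if ("land_use" %in% names(nd)) nd$land_use <- factor(nd$land_use)
  for (cov in names(object$scaling)) {
    nd[[cov]] <- (nd[[cov]] - object$scaling[[cov]]["center"]) /
      object$scaling[[cov]]["scale"]
  }
  tm <- stats::predict(object$gam, newdata = nd, type = "terms")
  time_col <- grep("^s\\(time_f\\)", colnames(tm))
  if (any(unseen)) tm[unseen, time_col] <- 0
  as.numeric(rowSums(tm) + attr(tm, "constant"))
}

#' @export
fitted.cmin_gam <- function(object, ...) as.numeric(stats::fitted(object$gam))

#' @export
residuals.cmin_gam <- function(object, ...)
  as.numeric(stats::residuals(object$gam))

#' Per-component columns of the linear predictor
#'
#' Extracts one column per model component — the random time factor, the
#' land-use main effect when present, and each covariate term (land-use
#' interaction halves summed into a single column) — such that intercept +
#' row sums reproduce the linear predictor.
#'
#' @param object a `cmin_gam`.
#' @param newdata optional data frame (original scale); training data by
#'   default.
#' @return numeric matrix, one named column per component, each centered
#'   to mean zero over the training rows (the means are absorbed into the
#'   `intercept` attribute).
#' @export
component_matrix <- function(object, newdata = NULL) {
  train <- raw_components(object, object$train)
  if (is.null(newdata)) {
    m <- train$m
  } else {
    nd <- newdata
    nd$time_f <- factor(nd$time, levels = object$time_levels)
    if ("land_use" %in% names(nd)) nd$land_use <- factor(nd$land_use)
    for (cov in names(object$scaling))
      nd[[cov]] <- (nd[[cov]] - object$scaling[[cov]]["center"]) /
        object$scaling[[cov]]["scale"]
    m <- raw_components(object, nd)$m
  }
  mu <- colMeans(train$m)
  m <- sweep(m, 2, mu)
  attr(m, "intercept") <- train$intercept + sum(mu)
  m
}

# grouped (uncentered) term columns; `nd` already on the internal scale
raw_components <- function(object, nd) {
  spec <- object$spec
  tm <- stats::predict(object$gam, newdata = nd, type = "terms")
  cols <- colnames(tm)
  take <- function(labels) {
    idx <- which(cols %in% labels | cols %in% unlist(labels))
    if (!length(idx))
      cmin_abort(sprintf("component column(s) not found: %s",
                         paste(unlist(labels), collapse = ", ")),
                 "internal")
    rowSums(tm[, idx, drop = FALSE])
  }
  out <- list(time = take("s(time_f)"))
  if (spec$includes_land_use_main) out$land_use <- take("land_use")
  for (t in spec$terms) {
    labels <- switch(t$form,
                     I = if (t$by_land_use) with_land_use(t$covariate)
                         else t$covariate,
                     poly2 = ,
                     poly3 = {
                       deg <- if (t$form == "poly2") 2 else 3
                       b <- sprintf("poly(%s, %d)", t$covariate, deg)
                       if (t$by_land_use) with_land_use(b) else b
                     },
                     s = {
                       b <- sprintf("s(%s)", t$covariate)
                       if (t$by_land_use)
                         cols[startsWith(cols, paste0(b, ":land_use"))]
                       else b
                     })
    out[[t$covariate]] <- take(labels)
  }
  list(m = do.call(cbind, out), intercept = attr(tm, "constant"))
}

#' Percentage of deviance explained
#'
#' For the Gaussian identity models used here this is
#' 100 * (1 - RSS / TSS).
#'
#' @param object a `cmin_gam`.
#' @return percentage in \[0, 100\].
#' @export
explained_deviance <- function(object) {
  d <- object$gam$deviance
  d0 <- object$gam$null.deviance
  if (d0 <= 0)
    cmin_abort("null deviance is zero; response is degenerate",
               "degenerate_response")
  100 * (1 - d / d0)
}

#' Percentage of deviance from raw observed/fitted values
#'
#' @param y observed values.
#' @param fitted fitted values.
#' @return 100 * (1 - RSS / TSS) with TSS centered on `mean(y)`.
#' @export
#' @examples
#' pct_deviance(c(0, 1, 2), c(0.5, 1, 1.5)) # 75
pct_deviance <- function(y, fitted) {
  tss <- sum((y - mean(y))^2)
  if (tss <= 0)
    cmin_abort("response has zero variance", "degenerate_response")
  100 * (1 - sum((y - fitted)^2) / tss)
}

#' Total effective degrees of freedom of a fit
#'
#' @param object a `cmin_gam`.
#' @return sum of per-coefficient effective degrees of freedom (includes
#'   the intercept).
#' @export
edf_total <- function(object) sum(object$gam$edf)

#' Per-term significance tests
#'
#' F tests per model component: parametric terms are tested on their
#' coefficients, smooth terms (including the random time factor) by the
#' approximate F test on effective degrees of freedom, as produced by
#' `anova.gam`. For a spline interacted with land use the per-level smooth
#' with the smallest p-value is reported.
#'
#' @param object a `cmin_gam`.
#' @return data frame with one row per component: `component`, `covariate`,
#'   `form` (`RF` for the random time factor), `by_land_use`, `statistic`,
#'   `p_value` and the significance `code` (see [sig_code()]).
#' @export
term_significance <- function(object) {
  a <- stats::anova(object$gam)
  pt <- a$pTerms.table
  st <- a$s.table
  get_param <- function(labels) {
    hit <- intersect(labels, rownames(pt))
    if (is.null(pt) || !length(hit))
      cmin_abort(paste("no test for parametric term",
                       paste(labels, collapse = "/")), "internal")
    c(stat = pt[hit[1], "F"], p = pt[hit[1], "p-value"])
  }
  get_smooth <- function(labels) {
    idx <- rownames(st) %in% labels
    if (!any(idx))
      cmin_abort(paste("no test for smooth term(s):",
                       paste(labels, collapse = ", ")), "internal")
    sub <- st[idx, , drop = FALSE]
    best <- which.min(sub[, "p-value"])
    c(stat = sub[best, "F"], p = sub[best, "p-value"])
  }
  rows <- list(data.frame(component = "time", covariate = "time",
                          form = "RF", by_land_use = FALSE,
                          t(get_smooth("s(time_f)"))))
  if (object$spec$includes_land_use_main)
    rows <- c(rows, list(data.frame(component = "land_use",
                                    covariate = "land_use", form = "I",
                                    by_land_use = FALSE,
                                    t(get_param("land_use")))))
  for (t in object$spec$terms) {
    res <- if (t$form == "s") {
      b <- sprintf("s(%s)", t$covariate)
      labels <- if (t$by_land_use)
        rownames(st)[startsWith(rownames(st), paste0(b, ":land_use"))]
      else b
      get_smooth(labels)
    } else {
      deg <- switch(t$form, I = NULL, poly2 = 2, poly3 = 3)
      b <- if (is.null(deg)) t$covariate
           else sprintf("poly(%s, %d)", t$covariate, deg)
      get_param(if (t$by_land_use) with_land_use(b) else b)
    }
    rows <- c(rows, list(data.frame(component = t$covariate,
                                    covariate = t$covariate, form = t$form,
                                    by_land_use = t$by_land_use, t(res))))
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "stat"] <- "statistic"
  names(out)[names(out) == "p"] <- "p_value"
  out$code <- sig_code(out$p_value)
  rownames(out) <- NULL
  out
}

#' @export
print.cmin_gam <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  n = %d, edf = %.2f, %%Dev = %.1f, criterion = %s\n",
              length(stats::fitted(x$gam)), edf_total(x),
              explained_deviance(x), x$method))
  invisible(x)
}
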