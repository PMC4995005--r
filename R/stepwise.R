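# Stepwise covariate selection driven by leave-one-soil-out
# cross-validated prediction error (MSEP).
#
# Starting from the intercept + random-time model, each iteration:
#   1. screens the not-yet-selected covariates for collinearity with the
#      selected ones (variance inflation factor on the site-level table,
#      threshold 4);
#   2. enumerates every add move (admissible covariate x functional form x
#      land-use-interaction flag) and every remove move (drop one selected
#      term);
#   3. scores each candidate model by leave-one-soil-out MSEP, where the
#      fold unit is an entire soil: the model is refit without any row of
#      soil i and predicts all of soil i's times and replicates;
#   4. accepts the candidate with the smallest MSEP if it is strictly
#      below the current model's, otherwise stops.
# The procedure is deterministic: candidates are enumerated covariates
# first (in the order given), then forms (I, poly2, poly3, s), then
# interaction flag; exact MSEP ties are broken by the smaller effective
# degrees of freedom, then by enumeration order.

#' Leave-one-soil-out cross-validated MSEP of a model specification
#'
#' For each soil the model is calibrated on all other soils and predicts
#' every (time, replicate) row of the held-out soil; MSEP is the mean
#' squared prediction error over all held-out rows. A fold whose model
#' cannot be fitted is skipped with a warning and the denominator adjusted.
#'
#' @param spec a [model_spec()].
#' @param data model frame with a `site_id` column.
#' @param k,method passed to [fit_gam()].
#' @return MSEP (squared response units); attributes `n` (rows scored) and
#'   `failed_folds` (soils whose fold failed).
#' @export
loso_msep <- function(spec, data, k = 5, method = "GCV.Cp") {
  data <- data[!is.na(data[[spec$response]]), , drop = FALSE]
  soils <- unique(data$site_id)
  if (length(soils) < 3)
    cmin_abort("leave-one-soil-out needs at least 3 soils", "data")
  pred <- rep(NA_real_, nrow(data))
  failed <- character(0)
  for (s in soils) {
    hold <- data$site_id == s
    f <- tryCatch(fit_gam(spec, data[!hold, , drop = FALSE],
                          k = k, method = method),
                  error = function(e) e)
    if (inherits(f, "error")) { failed <- c(failed, s); next }
    p <- tryCatch(suppressWarnings(predict(f, data[hold, , drop = FALSE])),
                  error = function(e) e)
    if (inherits(p, "error")) { failed <- c(failed, s); next }
    pred[hold] <- p
  }
  if (length(failed) == length(soils))
    cmin_abort("every cross-validation fold failed", "fit")
  if (length(failed))
    cmin_warn(sprintf("%d fold(s) skipped: %s", length(failed),
                      paste(failed, collapse = ", ")), "fold")
  out <- msep_values(data[[spec$response]], pred)
  attr(out, "failed_folds") <- failed
  attr(out, "predictions") <- stats::setNames(pred, data$site_id)
  out
}

#' Variance-inflation-factor pre-screening of candidate covariates
#'
#' Each candidate is regressed (ordinary least squares, site level, raw
#' covariate scale) on the already-selected covariates; its VIF is
#' 1 / (1 - R^2). Candidates with VIF above the threshold are excluded
#' from the add moves of the current iteration. With nothing selected all
#' candidates are admissible.
#'
#' @param candidates character vector of candidate covariate names.
#' @param selected character vector of already-selected covariate names.
#' @param site_data one row per soil with the covariate columns.
#' @param threshold VIF threshold (default 4).
#' @return data frame with columns `covariate`, `vif`, `admissible`; exact
#'   collinearity is reported as `Inf`.
#' @export
vif_prescreen <- function(candidates, selected, site_data, threshold = 4) {
  vif <- vapply(candidates, function(cand) {
    if (!length(selected)) return(1)
    fml <- stats::reformulate(selected, response = cand)
    # summary.lm warns on an essentially perfect fit; that case is exactly
    # the exact-collinearity exclusion handled below
    r2 <- suppressWarnings(
      summary(stats::lm(fml, data = site_data))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(covariate = candidates, vif = unname(vif),
             admissible = unname(vif) <= threshold,
             row.names = NULL)
}

enumerate_moves <- function(state_terms, admissible, forms,
                            interaction_mode) {
  flags <- switch(interaction_mode,
                  both = c(FALSE, TRUE),
                  always = TRUE,
                  never = FALSE)
  moves <- list()
  for (cov in admissible)
    for (form in forms)
      for (fl in flags)
        moves <- c(moves, list(list(type = "add",
                                    term = model_term(cov, form, fl))))
  for (i in seq_along(state_terms))
    moves <- c(moves, list(list(type = "remove", index = i,
                                term = state_terms[[i]])))
  moves
}

apply_move <- function(terms, move) {
  if (move$type == "add") c(terms, list(move$term))
  else terms[-move$index]
}

#' Stepwise covariate selection by cross-validated MSEP
#'
#' Runs the full selection loop (see the module description at the top of
#' this file) and refits the final specification on all data.
#'
#' @param data model frame from [model_frame()] (or compatible) with
#'   `site_id`, `time`, `land_use`, the response and all candidate
#'   covariates.
#' @param response response column name.
#' @param candidates candidate covariate names, in enumeration order.
#' @param forms functional-form menu (subset of `I`, `poly2`, `poly3`,
#'   `s`), in enumeration order.
#' @param interaction_mode `"both"` (each candidate enumerated with and
#'   without the land-use interaction; default), `"always"` or `"never"`.
#' @param k,method passed to [fit_gam()].
#' @param vif_threshold collinearity threshold for [vif_prescreen()].
#' @param max_iter iteration cap; reaching it raises a
#'   `soilcmin_cap_error` carrying the trace so far.
#' @param verbose print per-iteration progress.
#' @return a `cmin_selection`: list with the final `spec`, the full-data
#'   refit `fit`, final `msep`, and `trace` (one row per step: move,
#'   term, MSEP before/after, number of candidates evaluated, number
#'   VIF-excluded).
#' @export
stepwise_select <- function(data, response, candidates,
                            forms = FORM_LEVELS,
                            interaction_mode = c("both", "always", "never"),
                            k = 5, method = "GCV.Cp", vif_threshold = 4,
                            max_iter = 50, verbose = FALSE) {
  interaction_mode <- match.arg(interaction_mode)
  forms <- match.arg(forms, FORM_LEVELS, several.ok = TRUE)
  missing <- setdiff(candidates, names(data))
  if (length(missing))
    cmin_abort(sprintf("unknown candidate covariate(s): %s",
                       paste(missing, collapse = ", ")), "config")
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  site_data <- data[!duplicated(data$site_id),
                    c("site_id", candidates), drop = FALSE]

  terms <- list()
  cur_msep <- loso_msep(model_spec(response, terms), data,
                        k = k, method = method)
  trace <- list()
  stopped <- FALSE

  for (iter in seq_len(max_iter)) {
    sel_covs <- vapply(terms, function(t) t$covariate, character(1))
    pool <- setdiff(candidates, sel_covs)
    vif <- vif_prescreen(pool, sel_covs, site_data, vif_threshold)
    admissible <- vif$covariate[vif$admissible]
    moves <- enumerate_moves(terms, admissible, forms, interaction_mode)

    msep_j <- vapply(moves, function(mv) {
      sp <- tryCatch(model_spec(response, apply_move(terms, mv)),
                     error = function(e) NULL)
      if (is.null(sp)) return(Inf)
      val <- tryCatch(suppressWarnings(
        loso_msep(sp, data, k = k, method = method)),
        error = function(e) Inf)
      as.numeric(val)
    }, numeric(1))

    best <- Inf; best_idx <- NA_integer_
    if (length(moves)) {
      best <- min(msep_j)
      ties <- which(msep_j == best)
      if (length(ties) > 1) {
        edfs <- vapply(ties, function(i) {
          f <- tryCatch(fit_gam(model_spec(response,
                                           apply_move(terms, moves[[i]])),
                                data, k = k, method = method),
                        error = function(e) NULL)
          if (is.null(f)) Inf else edf_total(f)
        }, numeric(1))
        ties <- ties[edfs == min(edfs)]
      }
      best_idx <- ties[1]
    }

    accepted <- is.finite(best) && best < cur_msep
    mv <- if (accepted) moves[[best_idx]] else NULL
    trace <- c(trace, list(data.frame(
      iteration = iter,
      move = if (accepted) mv$type else "stop",
      covariate = if (accepted) mv$term$covariate else NA_character_,
      form = if (accepted) mv$term$form else NA_character_,
      by_land_use = if (accepted) mv$term$by_land_use else NA,
      msep_before = cur_msep,
      msep_after = if (accepted) best else cur_msep,
      n_candidates = length(moves),
      n_vif_excluded = sum(!vif$admissible))))
    if (verbose)
      message(sprintf("iter %d: %s%s  MSEP %.5f -> %.5f", iter,
                      if (accepted) mv$type else "stop",
                      if (accepted) paste0(" ", term_label(mv$term)) else "",
                      cur_msep, if (accepted) best else cur_msep))
    if (!accepted) { stopped <- TRUE; break }
    terms <- apply_move(terms, mv)
    cur_msep <- best
  }
  trace <- do.call(rbind, trace)
  if (!stopped)
    cmin_abort(sprintf("selection did not converge within %d iterations",
                       max_iter), "cap", trace = trace)

  final_spec <- model_spec(response, terms)
  structure(list(spec = final_spec,
                 fit = fit_gam(final_spec, data, k = k, method = method),
                 msep = as.numeric(cur_msep),
                 trace = trace,
                 k = k, method = method),
            class = "cmin_selection")
}

#' @export
print.cmin_selection <- function(x, ...) {
  cat("Stepwise selection result\n  ")
  print(x$spec)
  cat(sprintf("  LOSO-MSEP = %.5f after %d accepted move(s)\n",
              x$msep, sum(x$trace$move != "stop")))
  invisible(x)
}
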