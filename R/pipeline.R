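# End-to-end pipeline: partition -> log rates -> stepwise selection (one
# run per mineralisation response) -> assessment -> report files.
# The functions here are also the programmatic command-line surface: a
# shell user drives them through a short Rscript (see the package README).

RESPONSE_COLUMNS <- c(rs_control = "log_rs_control",
                      rs_amended = "log_rs_amended",
                      rr = "log_rr",
                      pe = "log_pe")

#' Default candidate covariates for selection
#'
#' The abiotic soil properties commonly carried by SOM models (texture
#' fractions, SOC, C:N, pH), molecular microbial biomass, and the eight
#' bacterial/fungal diversity indexes.
#'
#' @return character vector of covariate names.
#' @export
default_candidates <- function() {
  c("clay", "silt", "sand", "clay_fine_silt", "soc", "cn_ratio", "ph",
    "molecular_biomass",
    "bacterial_richness", "bacterial_h", "bacterial_j", "bacterial_invd",
    "fungal_richness", "fungal_h", "fungal_j", "fungal_invd")
}

#' Run the full analysis pipeline on a dataset
#'
#' Partitions respiration, builds the log-rate responses, runs the
#' stepwise MSEP selection independently for each requested response, and
#' assesses every selected model.
#'
#' @param ds a validated `cmin_dataset`.
#' @param responses subset of `rs_control`, `rs_amended`, `rr`, `pe`.
#' @param candidates candidate covariates (must exist in the site table).
#' @param forms,interaction_mode,k,method,vif_threshold,max_iter passed to
#'   [stepwise_select()].
#' @param attribution passed to [assess_model()].
#' @param verbose print selection progress.
#' @return a `cmin_run`: list with the model frame (`frame`), and per
#'   response the `selections` and `assessments`.
#' @export
run_pipeline <- function(ds,
                         responses = c("rs_control", "rs_amended",
                                       "rr", "pe"),
                         candidates = default_candidates(),
                         forms = FORM_LEVELS,
                         interaction_mode = "both",
                         k = 5, method = "GCV.Cp", vif_threshold = 4,
                         max_iter = 50,
                         attribution = "sequential",
                         verbose = FALSE) {
  responses <- match.arg(responses, names(RESPONSE_COLUMNS),
                         several.ok = TRUE)
  unknown <- setdiff(candidates, names(ds$sites))
  if (length(unknown))
    cmin_abort(sprintf("unknown candidate covariate(s): %s",
                       paste(unknown, collapse = ", ")), "config")
  frame <- model_frame(ds)
  selections <- list(); assessments <- list()
  for (resp in responses) {
    if (verbose) message("selecting model for ", resp)
    sel <- stepwise_select(frame, RESPONSE_COLUMNS[[resp]], candidates,
                           forms = forms,
                           interaction_mode = interaction_mode,
                           k = k, method = method,
                           vif_threshold = vif_threshold,
                           max_iter = max_iter, verbose = verbose)
    selections[[resp]] <- sel
    assessments[[resp]] <- assess_model(sel, attribution = attribution)
  }
  structure(list(frame = frame, selections = selections,
                 assessments = assessments),
            class = "cmin_run")
}

#' Write the assessment report to CSV and JSON
#'
#' One CSV row per selected covariate per response, mirroring the usual
#' model-report layout (covariate, interaction, relation type,
#' significance, relative importance), plus per-response summary columns;
#' the JSON file carries the same content plus the selection traces.
#'
#' @param run a `cmin_run` (or a named list of `cmin_assessment`).
#' @param path output path without extension; `<path>.csv` and
#'   `<path>.json` are written.
#' @return invisible character vector of the files written.
#' @export
write_report <- function(run, path) {
  assessments <- if (inherits(run, "cmin_run")) run$assessments else run
  if (!length(assessments))
    cmin_abort("nothing to report: no assessed model", "data")
  rows <- lapply(names(assessments), function(resp) {
    a <- assessments[[resp]]
    cbind(data.frame(response = resp,
                     pct_deviance = a$pct_deviance,
                     msep = a$msep, rpiq = a$rpiq, df = a$edf,
                     bic = a$bic),
          a$terms)
  })
  tab <- do.call(rbind, rows)
  dir <- dirname(path)
  if (nzchar(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv <- paste0(path, ".csv"); json <- paste0(path, ".json")
  ok <- tryCatch({
    utils::write.csv(tab, csv, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) cmin_abort(paste("cannot write report to", csv), "io")
  payload <- lapply(names(assessments), function(resp) {
    a <- assessments[[resp]]
    out <- list(response = resp, pct_deviance = a$pct_deviance,
                msep = a$msep, rpiq = a$rpiq, df = a$edf, bic = a$bic,
                remainder = a$remainder, terms = a$terms)
    if (inherits(run, "cmin_run"))
      out$trace <- run$selections[[resp]]$trace
    out
  })
  names(payload) <- names(assessments)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(csv, json))
}

#' Serialize a model specification to JSON
#'
#' @param spec a `cmin_spec`.
#' @param path optional file; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
spec_to_json <- function(spec, path = NULL) {
  obj <- list(response = spec$response,
              terms = lapply(spec$terms, function(t)
                list(covariate = t$covariate, form = t$form,
                     by_land_use = t$by_land_use)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
print.cmin_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d response model(s)\n",
              length(x$assessments)))
  for (a in x$assessments) print(a)
  invisible(x)
}
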