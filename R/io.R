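# Data model and delimited-text readers/writers for the incubation dataset.
#
# A dataset bundles three tables:
#   sites       - one row per soil: land use plus abiotic and microbial
#                 covariates measured before incubation
#   respiration - one row per microcosm sampling interval: accumulated
#                 C-CO2 and, for amended microcosms, the 13C abundance of
#                 the respired CO2
#   endmembers  - per soil, the 13C abundance of native soil C and of the
#                 labelled residue, used by the mixing model
# plus the ordered sampling schedule (days; the first interval opens at 0).

SITE_COLUMNS <- c("site_id", "land_use", "clay", "silt", "sand",
                  "clay_fine_silt", "soc", "cn_ratio", "ph",
                  "molecular_biomass",
                  "bacterial_richness", "fungal_richness",
                  "bacterial_h", "fungal_h",
                  "bacterial_j", "fungal_j",
                  "bacterial_invd", "fungal_invd")

RESPIRATION_COLUMNS <- c("site_id", "treatment", "replicate",
                         "t_start", "t_end", "co2_interval", "a13_total")

ENDMEMBER_COLUMNS <- c("site_id", "a13_soil", "a13_residue")

#' Default incubation sampling schedule (days)
#'
#' Respired CO2 is accumulated over consecutive intervals ending at these
#' days; the first interval starts at day 0.
#'
#' @return integer vector of sampling days.
#' @export
default_schedule <- function() c(3L, 7L, 14L, 21L, 28L, 44L, 60L, 80L)

#' Assemble an incubation dataset from its component tables
#'
#' Validates the experimental-design structure (see Details) and returns a
#' `cmin_dataset` object consumed by the rest of the pipeline.
#'
#' @details Validation enforces: all required columns present; no duplicated
#' (site, treatment, replicate, interval) design cell; every respiration row
#' referring to a known site; texture fractions nonnegative with
#' clay + silt + sand not exceeding 1000 g/kg (within `texture_tol`);
#' evenness in \[0, 1\]; inverse Simpson in \[1, richness\]; Shannon H' in
#' \[0, ln(richness)\]; intervals with `t_end > t_start >= 0` and ends on the
#' schedule; distinct isotopic endmembers; and a 13C abundance present for
#' every amended interval. Control microcosms may omit `a13_total`.
#'
#' @param sites data frame of per-soil covariates (see `SITE_COLUMNS`).
#' @param respiration data frame of per-interval CO2 measurements.
#' @param endmembers data frame of per-soil endmember 13C abundances.
#' @param schedule ordered sampling days; default [default_schedule()].
#' @param texture_tol slack (g/kg) allowed on the texture closure sum.
#' @return a `cmin_dataset`: list with elements `sites`, `respiration`,
#'   `endmembers`, `schedule`.
#' @seealso [read_dataset()], [design_completeness()]
#' @export
cmin_dataset <- function(sites, respiration, endmembers,
                         schedule = default_schedule(),
                         texture_tol = 5) {
  ds <- structure(list(sites = as.data.frame(sites),
                       respiration = as.data.frame(respiration),
                       endmembers = as.data.frame(endmembers),
                       schedule = sort(as.numeric(schedule))),
                  class = "cmin_dataset")
  validate_dataset(ds, texture_tol = texture_tol)
  ds
}

check_columns <- function(df, required, table) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    cmin_abort(sprintf("table '%s' is missing column(s): %s", table,
                       paste(missing, collapse = ", ")),
               "schema", columns = missing, table = table)
  }
}

#' Validate an incubation dataset
#'
#' @param ds a `cmin_dataset`.
#' @param texture_tol slack (g/kg) on the texture closure sum.
#' @return `ds`, invisibly, if valid; otherwise a classed error
#'   (`soilcmin_schema_error`, `soilcmin_integrity_error`,
#'   `soilcmin_referential_error` or `soilcmin_data_error`).
#' @export
validate_dataset <- function(ds, texture_tol = 5) {
  s <- ds$sites; r <- ds$respiration; e <- ds$endmembers
  check_columns(s, SITE_COLUMNS, "sites")
  check_columns(r, setdiff(RESPIRATION_COLUMNS, "a13_total"), "respiration")
  check_columns(e, ENDMEMBER_COLUMNS, "endmembers")
  if (!"a13_total" %in% names(r)) r$a13_total <- NA_real_

  if (anyDuplicated(s$site_id))
    cmin_abort("duplicated site_id in sites table", "integrity")
  if (!all(s$land_use %in% c("cropland", "grassland")))
    cmin_abort("land_use must be 'cropland' or 'grassland'", "data")

  tex <- c("clay", "silt", "sand", "clay_fine_silt")
  if (any(as.matrix(s[tex]) < 0, na.rm = TRUE))
    cmin_abort("negative texture fraction", "data")
  closure <- s$clay + s$silt + s$sand
  if (any(closure > 1000 + texture_tol, na.rm = TRUE))
    cmin_abort("clay + silt + sand exceeds 1000 g/kg", "data")
  if (any(s$bacterial_j < -1e-9 | s$bacterial_j > 1 + 1e-9, na.rm = TRUE) ||
      any(s$fungal_j < -1e-9 | s$fungal_j > 1 + 1e-9, na.rm = TRUE))
    cmin_abort("evenness J' outside [0, 1]", "data")
  if (any(s$bacterial_invd < 1 - 1e-9, na.rm = TRUE) ||
      any(s$fungal_invd < 1 - 1e-9, na.rm = TRUE))
    cmin_abort("inverse Simpson index below 1", "data")
  if (any(s$bacterial_invd > s$bacterial_richness + 1e-9, na.rm = TRUE) ||
      any(s$fungal_invd > s$fungal_richness + 1e-9, na.rm = TRUE))
    cmin_abort("inverse Simpson index exceeds richness", "data")
  if (any(s$bacterial_h < -1e-9, na.rm = TRUE) ||
      any(s$bacterial_h > log(s$bacterial_richness) + 1e-9, na.rm = TRUE) ||
      any(s$fungal_h < -1e-9, na.rm = TRUE) ||
      any(s$fungal_h > log(s$fungal_richness) + 1e-9, na.rm = TRUE))
    cmin_abort("Shannon H' outside [0, ln(richness)]", "data")

  if (!all(r$treatment %in% c("control", "amended")))
    cmin_abort("treatment must be 'control' or 'amended'", "data")
  if (any(r$t_start < 0) || any(r$t_end <= r$t_start))
    cmin_abort("intervals must satisfy t_end > t_start >= 0", "data")
  if (any(r$co2_interval < 0, na.rm = TRUE))
    cmin_abort("negative accumulated CO2", "data")
  off <- setdiff(unique(r$t_end), ds$schedule)
  if (length(off))
    cmin_abort(sprintf("interval end day(s) not on the schedule: %s",
                       paste(off, collapse = ", ")), "data")

  key <- paste(r$site_id, r$treatment, r$replicate, r$t_start, r$t_end,
               sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    cmin_abort(sprintf("duplicated design cell (site|treatment|replicate|t_start|t_end): %s",
                       dup), "integrity", cell = dup)
  }

  orphans <- setdiff(unique(r$site_id), s$site_id)
  if (length(orphans))
    cmin_abort(sprintf("respiration rows refer to unknown site(s): %s",
                       paste(orphans, collapse = ", ")),
               "referential", sites = orphans)
  miss_em <- setdiff(unique(r$site_id[r$treatment == "amended"]), e$site_id)
  if (length(miss_em))
    cmin_abort(sprintf("no isotope endmembers for amended site(s): %s",
                       paste(miss_em, collapse = ", ")),
               "referential", sites = miss_em)

  if (any(e$a13_soil <= 0) || any(e$a13_residue <= 0) ||
      any(e$a13_residue == e$a13_soil))
    cmin_abort("endmember abundances must be positive and distinct", "data")

  amended_missing <- r$treatment == "amended" & !is.finite(r$a13_total)
  if (any(amended_missing))
    cmin_abort(sprintf("%d amended interval(s) lack a13_total",
                       sum(amended_missing)), "integrity")
  invisible(ds)
}

#' Read an incubation dataset from delimited text files
#'
#' Reads the three CSV tables (UTF-8, header row), optionally renaming file
#' headers to internal names through `schema`, and validates the assembled
#' dataset.
#'
#' @param paths named list or vector with elements `sites`, `respiration`,
#'   `endmembers` giving file paths, or a single directory containing
#'   `sites.csv`, `respiration.csv`, `endmembers.csv`.
#' @param schema optional named list with elements `sites`, `respiration`,
#'   `endmembers`; each a named character vector mapping internal column
#'   names to the headers used in that file.
#' @param schedule sampling days; default [default_schedule()].
#' @return a validated `cmin_dataset`.
#' @export
read_dataset <- function(paths, schema = NULL,
                         schedule = default_schedule()) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths)) {
    paths <- list(sites = file.path(paths, "sites.csv"),
                  respiration = file.path(paths, "respiration.csv"),
                  endmembers = file.path(paths, "endmembers.csv"))
  }
  read_one <- function(what) {
    p <- paths[[what]]
    if (is.null(p) || !file.exists(p))
      cmin_abort(sprintf("input file for '%s' not found: %s", what,
                         p %||% "<missing>"), "io")
    df <- utils::read.csv(p, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
    map <- schema[[what]]
    if (!is.null(map)) {
      for (internal in names(map)) {
        if (!map[[internal]] %in% names(df))
          cmin_abort(sprintf("table '%s' is missing column(s): %s", what,
                             map[[internal]]), "schema",
                     columns = map[[internal]], table = what)
        names(df)[names(df) == map[[internal]]] <- internal
      }
    }
    df
  }
  cmin_dataset(read_one("sites"), read_one("respiration"),
               read_one("endmembers"), schedule = schedule)
}

#' Write an incubation dataset to CSV files
#'
#' Numeric columns are written with 15 significant digits so that a
#' read/write cycle round-trips values to at least 12 significant digits.
#'
#' @param ds a `cmin_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) format(x, digits = 15,
                                                  scientific = FALSE,
                                                  trim = TRUE))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  }
  w(ds$sites, "sites.csv")
  w(ds$respiration, "respiration.csv")
  w(ds$endmembers, "endmembers.csv")
  invisible(dir)
}

#' Missing design cells of an incubation dataset
#'
#' A complete design has one respiration row for every combination of site,
#' treatment, replicate and schedule interval.
#'
#' @param ds a `cmin_dataset`.
#' @param n_replicates replicates expected per microcosm (default 3).
#' @return data frame of the missing (site_id, treatment, replicate,
#'   t_start, t_end) cells; zero rows when the design is complete.
#' @export
design_completeness <- function(ds, n_replicates = 3) {
  sched <- ds$schedule
  starts <- c(0, utils::head(sched, -1))
  expected <- expand.grid(site_id = ds$sites$site_id,
                          treatment = c("control", "amended"),
                          replicate = seq_len(n_replicates),
                          interval = seq_along(sched),
                          stringsAsFactors = FALSE)
  expected$t_start <- starts[expected$interval]
  expected$t_end <- sched[expected$interval]
  expected$interval <- NULL
  key <- function(d) paste(d$site_id, d$treatment, d$replicate,
                           d$t_start, d$t_end, sep = "|")
  missing <- expected[!(key(expected) %in% key(ds$respiration)), ]
  rownames(missing) <- NULL
  missing
}

#' @export
print.cmin_dataset <- function(x, ...) {
  cat("Incubation dataset\n")
  cat(sprintf("  soils:       %d (%s)\n", nrow(x$sites),
              paste(sprintf("%s: %d", names(table(x$sites$land_use)),
                            table(x$sites$land_use)), collapse = ", ")))
  cat(sprintf("  respiration: %d interval records\n", nrow(x$respiration)))
  cat(sprintf("  schedule:    days %s\n",
              paste(x$schedule, collapse = ", ")))
  miss <- design_completeness(x)
  if (nrow(miss) == 0) cat("  design:      complete\n")
  else cat(sprintf("  design:      %d missing cell(s)\n", nrow(miss)))
  invisible(x)
}
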