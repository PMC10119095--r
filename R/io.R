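## Delimited-table and parameter-file I/O. One canonical schema: CSV, UTF-8,
## header row, ISO-8601 dates, empty field = missing.

DATE_COLUMNS <- c("baseline_date", "event_date", "survey_date", "end_date",
                  "censor_date")

#' Write a cohort (or any results) table as canonical CSV
#'
#' @param df data.frame
#' @param path output file
#' @return the path, invisibly
#' @export
write_cohort <- function(df, path) {
  out <- df
  for (cl in names(out)) {
    if (inherits(out[[cl]], "Date")) out[[cl]] <- format(out[[cl]], "%Y-%m-%d")
    if (is.logical(out[[cl]])) out[[cl]] <- as.integer(out[[cl]])
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a canonical CSV cohort table
#'
#' Date columns (by canonical name) are parsed as `Date`; empty fields become
#' `NA`; ICD code-list columns stay character.
#'
#' @param path CSV file
#' @return data.frame
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  for (cl in intersect(DATE_COLUMNS, names(df))) {
    df[[cl]] <- as.Date(df[[cl]])
  }
  for (cl in intersect(c("icd_baseline", "icd_followup"), names(df))) {
    df[[cl]] <- ifelse(is.na(df[[cl]]), "", as.character(df[[cl]]))
  }
  df
}

#' Write trained KDM parameters as a keyed text file
#'
#' Long CSV: one row per (sex, biomarker) with q, k, s, plus one `s_ba` row
#' per sex and an `sba_method` row.
#'
#' @param params `kdm_parameters` from [fit_kdm()]
#' @param path output file
#' @return the path, invisibly
#' @export
write_kdm_params <- function(params, path) {
  stopifnot(inherits(params, "kdm_parameters"))
  rows <- list()
  for (sx in c("male", "female")) {
    p <- params[[sx]]
    rows[[sx]] <- data.frame(sex = sx, biomarker = names(p$q),
                             q = unname(p$q), k = unname(p$k),
                             s = unname(p$s), s_ba = p$s_ba)
  }
  out <- do.call(rbind, rows)
  out$sba_method <- params$sba_method
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read KDM parameters written by [write_kdm_params()]
#'
#' @param path CSV file
#' @return a `kdm_parameters` object
#' @export
read_kdm_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  assert_columns(df, c("sex", "biomarker", "q", "k", "s", "s_ba"),
                 "KDM parameter file")
  out <- list(sba_method = if ("sba_method" %in% names(df))
    df$sba_method[1] else "explained_variance")
  for (sx in c("male", "female")) {
    d <- df[df$sex == sx, , drop = FALSE]
    out[[sx]] <- list(q = stats::setNames(d$q, d$biomarker),
                      k = stats::setNames(d$k, d$biomarker),
                      s = stats::setNames(d$s, d$biomarker),
                      s_ba = d$s_ba[1])
  }
  class(out) <- "kdm_parameters"
  out
}

#' Write a provenance sidecar for a pipeline run
#'
#' Records the seed, the package version, the R version, row counts and an
#' md5 digest of the serialized configuration, as JSON next to the outputs.
#'
#' @param path sidecar file path (JSON)
#' @param seed integer seed of the run
#' @param config the run configuration (list)
#' @param tables named integer vector of row counts
#' @return the path, invisibly
#' @export
write_provenance <- function(path, seed, config, tables = integer()) {
  cfg_file <- tempfile(fileext = ".json")
  on.exit(unlink(cfg_file))
  jsonlite::write_json(config_to_list(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  side <- list(
    seed = seed,
    package = "bioagemh",
    package_version = as.character(utils::packageVersion("bioagemh")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = unname(tools::md5sum(cfg_file)),
    tables = as.list(tables))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_to_list <- function(config) {
  x <- unclass(config)
  lapply(x, function(v) {
    if (inherits(v, "Date")) format(v, "%Y-%m-%d")
    else if (is.data.frame(v)) as.list(v)
    else v
  })
}

#' Read a cohort configuration from a JSON file
#'
#' The file holds any subset of [cohort_config()] arguments; unspecified
#' fields keep their defaults. Dates are ISO-8601 strings.
#'
#' @param path JSON config file
#' @return a `cohort_config`
#' @export
read_cohort_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_bioagemh(sprintf("unknown config field(s): %s",
                          paste(unknown, collapse = ", ")),
                  "bioagemh_config_error")
  }
  for (nm in intersect(c("baseline_window", "survey_window", "censor_date"),
                       names(raw))) {
    raw[[nm]] <- as.Date(unlist(raw[[nm]]))
  }
  if ("biomarker_params" %in% names(raw)) {
    raw$biomarker_params <- as.data.frame(raw$biomarker_params)
  }
  if ("covariates" %in% names(raw)) {
    raw$covariates <- lapply(raw$covariates, unlist)
  }
  do.call(cohort_config, raw)
}
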