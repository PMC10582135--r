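sex_levels <- c("male", "female")
imdc_levels <- c("favorable", "intermediate", "poor")
histology_levels <- c("clear_cell", "non_clear_cell")
regimen_levels <- c("IO_IO", "IO_TKI")

require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("schema error in ", file, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

check_enum <- function(values, allowed, col, file) {
  bad <- which(!(values %in% allowed))
  if (length(bad))
    stop("value error in ", file, ", row ", bad[1], ": '", values[bad[1]],
         "' is not a valid ", col, " (allowed: ",
         paste(allowed, collapse = ", "), ")", call. = FALSE)
}

check_numeric <- function(values, col, file, min = -Inf, strict_min = FALSE,
                          integer = FALSE) {
  v <- suppressWarnings(as.numeric(values))
  bad <- which(!is.finite(v) | (if (strict_min) v <= min else v < min) |
                 (integer & v != round(v)))
  if (length(bad))
    stop("value error in ", file, ", row ", bad[1], ": '", values[bad[1]],
         "' is not a valid ", col, call. = FALSE)
  v
}

check_logical <- function(values, col, file) {
  v <- values
  if (is.character(v)) v <- toupper(trimws(v))
  out <- ifelse(v %in% c("TRUE", "T", "1", 1, TRUE), TRUE,
                ifelse(v %in% c("FALSE", "F", "0", 0, FALSE), FALSE, NA))
  bad <- which(is.na(out))
  if (length(bad))
    stop("value error in ", file, ", row ", bad[1], ": '", values[bad[1]],
         "' is not a valid ", col, call. = FALSE)
  out
}

#' Read and validate the three cohort tables
#'
#' Reads the longitudinal CRP table, the adverse-event table and the
#' baseline/outcome table from CSV, validates schemas, enum literals and
#' invariants (errors name the file, column and row), enforces referential
#' integrity (every CRP/TRAE record must belong to a patient in the outcome
#' table) and returns the records sorted by patient and time.
#'
#' Expected columns:
#' * `crp.csv`: `patient_id, time_weeks, crp_mg_per_l`
#' * `trae.csv`: `patient_id, onset_weeks, category, ctcae_grade`
#' * `outcomes.csv`: `patient_id, age_years, sex, ecog, imdc, histology,
#'   regimen, response, pfs_weeks, pfs_event[, os_weeks, os_event]`
#'
#' @param crp_path,trae_path,outcome_path CSV file paths.
#' @param time_unit `"weeks"` (default) or `"days"`; days are divided by 7 on
#'   input (applies to CRP times, TRAE onsets and PFS/OS times).
#' @param crp_unit `"mg_per_l"` (default) or `"mg_per_dl"` (multiplied by 10).
#' @return Object of class `rcc_cohort`: data frames `crp`, `trae`,
#'   `outcomes`, plus `n_patients` and per-table record counts.
#' @export
read_cohort <- function(crp_path, trae_path, outcome_path,
                        time_unit = c("weeks", "days"),
                        crp_unit = c("mg_per_l", "mg_per_dl")) {
  time_unit <- match.arg(time_unit)
  crp_unit <- match.arg(crp_unit)
  for (p in c(crp_path, trae_path, outcome_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tdiv <- if (time_unit == "days") 7 else 1
  cmul <- if (crp_unit == "mg_per_dl") 10 else 1

  crp <- utils::read.csv(crp_path, stringsAsFactors = FALSE)
  require_columns(crp, c("patient_id", "time_weeks", "crp_mg_per_l"), crp_path)
  crp$patient_id <- as.character(crp$patient_id)
  crp$time_weeks <- check_numeric(crp$time_weeks, "time_weeks", crp_path) / tdiv
  crp$crp_mg_per_l <- cmul *
    check_numeric(crp$crp_mg_per_l, "crp_mg_per_l (>= 0)", crp_path, min = 0)

  trae <- utils::read.csv(trae_path, stringsAsFactors = FALSE)
  require_columns(trae, c("patient_id", "onset_weeks", "category",
                          "ctcae_grade"), trae_path)
  trae$patient_id <- as.character(trae$patient_id)
  trae$onset_weeks <- check_numeric(trae$onset_weeks, "onset_weeks (>= 0)",
                                    trae_path, min = 0) / tdiv
  check_enum(trae$category, trae_categories, "category", trae_path)
  trae$ctcae_grade <- as.integer(
    check_numeric(trae$ctcae_grade, "ctcae_grade", trae_path, integer = TRUE))
  check_enum(trae$ctcae_grade, 1:5, "ctcae_grade", trae_path)

  out <- utils::read.csv(outcome_path, stringsAsFactors = FALSE)
  require_columns(out, c("patient_id", "age_years", "sex", "ecog", "imdc",
                         "histology", "regimen", "response", "pfs_weeks",
                         "pfs_event"), outcome_path)
  out$patient_id <- as.character(out$patient_id)
  if (anyDuplicated(out$patient_id))
    stop("value error in ", outcome_path, ": duplicated patient_id '",
         out$patient_id[anyDuplicated(out$patient_id)], "'", call. = FALSE)
  out$age_years <- as.integer(check_numeric(out$age_years, "age_years",
                                            outcome_path, min = 0,
                                            strict_min = TRUE, integer = TRUE))
  check_enum(out$sex, sex_levels, "sex", outcome_path)
  out$ecog <- as.integer(check_numeric(out$ecog, "ecog (>= 0)", outcome_path,
                                       min = 0, integer = TRUE))
  check_enum(out$imdc, imdc_levels, "imdc", outcome_path)
  check_enum(out$histology, histology_levels, "histology", outcome_path)
  check_enum(out$regimen, regimen_levels, "regimen", outcome_path)
  check_enum(out$response, response_levels, "response", outcome_path)
  out$pfs_weeks <- check_numeric(out$pfs_weeks, "pfs_weeks (> 0)",
                                 outcome_path, min = 0, strict_min = TRUE) / tdiv
  out$pfs_event <- check_logical(out$pfs_event, "pfs_event", outcome_path)
  if ("os_weeks" %in% names(out)) {
    out$os_weeks <- check_numeric(out$os_weeks, "os_weeks (> 0)", outcome_path,
                                  min = 0, strict_min = TRUE) / tdiv
    out$os_event <- check_logical(out$os_event, "os_event", outcome_path)
  }

  ids <- out$patient_id
  for (nm in c("crp", "trae")) {
    df <- get(nm)
    orphan <- which(!(df$patient_id %in% ids))
    if (length(orphan))
      stop("referential-integrity error: ", nm, " row ", orphan[1],
           " references unknown patient '", df$patient_id[orphan[1]], "'",
           call. = FALSE)
  }
  crp <- crp[order(match(crp$patient_id, ids), crp$time_weeks), , drop = FALSE]
  trae <- trae[order(match(trae$patient_id, ids), trae$onset_weeks), ,
               drop = FALSE]
  rownames(crp) <- rownames(trae) <- rownames(out) <- NULL
  new_cohort(crp, trae, out)
}

new_cohort <- function(crp, trae, outcomes) {
  structure(list(crp = crp, trae = trae, outcomes = outcomes,
                 n_patients = nrow(outcomes),
                 n_records = c(crp = nrow(crp), trae = nrow(trae),
                               outcomes = nrow(outcomes))),
            class = "rcc_cohort")
}

#' @export
print.rcc_cohort <- function(x, ...) {
  cat(sprintf("aRCC cohort: %d patients, %d CRP measurements, %d TRAE records\n",
              x$n_patients, nrow(x$crp), nrow(x$trae)))
  invisible(x)
}

#' Write a cohort back to the three CSV files
#'
#' Inverse of [read_cohort()]; writing then reading reproduces every field.
#'
#' @param cohort an `rcc_cohort` (or [generate_cohort()] result).
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("crp.csv", "trae.csv", "outcomes.csv"))
  utils::write.csv(cohort$crp, paths[1], row.names = FALSE)
  utils::write.csv(cohort$trae, paths[2], row.names = FALSE)
  utils::write.csv(cohort$outcomes, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Write an analysis report to JSON
#'
#' Serialises a report produced by [run_pipeline()] (or any nested list of
#' numeric/character results) to JSON. Undefined statistics (`NA`, e.g. an
#' unreached survival median) are written as JSON `null`; numbers are not
#' rounded, so re-reading yields identical values.
#'
#' @param results nested list of results.
#' @param path output path.
#' @export
write_report <- function(results, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON analysis report
#'
#' @param path path written by [write_report()].
#' @return Nested list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
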