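trae_categories <- c("general", "cutaneous", "cardiovascular",
                     "gastrointestinal", "pulmonary", "neurological",
                     "endocrine", "urinary")

#' First treatment-related adverse event of one patient
#'
#' Reduces a patient's adverse-event records to the first onset and the
#' binary early-onset factor (`first_onset_weeks <= threshold_weeks`). All
#' CTCAE grades count toward onset. Ties at the earliest onset report every
#' tied category and the maximum grade among them. A patient without events
#' is valid: the onset is `NA` and the early flag `FALSE`.
#'
#' @param events data frame of adverse events for one patient with columns
#'   `onset_weeks`, `category`, `ctcae_grade` (zero rows allowed).
#' @param threshold_weeks early-onset cutoff in weeks (default 4; an onset
#'   exactly at the threshold counts as early).
#' @return List of class `trae_onset` with `first_onset_weeks`, `early_trae`,
#'   `first_category` (all tied categories), `max_grade_at_onset`.
#' @export
first_trae_onset <- function(events, threshold_weeks = 4) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L)
    return(structure(list(first_onset_weeks = NA_real_, early_trae = FALSE,
                          first_category = character(0),
                          max_grade_at_onset = NA_integer_),
                     class = "trae_onset"))
  stopifnot(all(c("onset_weeks", "category", "ctcae_grade") %in% names(events)),
            all(events$onset_weeks >= 0))
  t0 <- min(events$onset_weeks)
  at <- events$onset_weeks == t0
  structure(list(first_onset_weeks = t0,
                 early_trae = t0 <= threshold_weeks,
                 first_category = unique(events$category[at]),
                 max_grade_at_onset = max(events$ctcae_grade[at])),
            class = "trae_onset")
}

#' @export
print.trae_onset <- function(x, ...) {
  if (is.na(x$first_onset_weeks)) {
    cat("No treatment-related adverse events recorded\n")
  } else {
    cat(sprintf("First TRAE at %.1f weeks (%s, grade %d)%s\n",
                x$first_onset_weeks, paste(x$first_category, collapse = "/"),
                x$max_grade_at_onset, if (x$early_trae) " [early]" else ""))
  }
  invisible(x)
}

split_events <- function(trae, ids) {
  idx <- split(seq_len(nrow(trae)), factor(trae$patient_id, levels = ids))
  lapply(idx, function(i) trae[i, , drop = FALSE])
}

#' Mean time to the first adverse event across a cohort
#'
#' Arithmetic mean (with range) of per-patient first onsets. In cohorts where
#' every patient has at least one event this is the statistic used to choose
#' the early-onset threshold; `skip_event_free = TRUE` drops event-free
#' patients instead of raising an error.
#'
#' @param cohort cohort object with a `trae` data frame and an `outcomes`
#'   data frame listing all patients.
#' @param skip_event_free drop patients without events (default requires
#'   every patient to have one).
#' @return List with `mean_weeks`, `min_weeks`, `max_weeks`, `n`.
#' @export
mean_time_to_first_trae <- function(cohort, skip_event_free = FALSE) {
  ids <- unique(cohort$outcomes$patient_id)
  onsets <- vapply(split_events(cohort$trae, ids),
                   function(ev) if (nrow(ev)) min(ev$onset_weeks) else NA_real_,
                   numeric(1))
  if (anyNA(onsets)) {
    if (!skip_event_free)
      stop(sum(is.na(onsets)), " patient(s) without adverse events; set ",
           "skip_event_free = TRUE to average over patients with events",
           call. = FALSE)
    onsets <- onsets[!is.na(onsets)]
  }
  if (!length(onsets))
    stop("undefined statistic: no adverse-event onsets in the cohort",
         call. = FALSE)
  list(mean_weeks = mean(onsets), min_weeks = min(onsets),
       max_weeks = max(onsets), n = length(onsets))
}

#' Early-onset flags for a cohort
#'
#' Applies [first_trae_onset()] per patient and summarises the binary factor.
#'
#' @inheritParams mean_time_to_first_trae
#' @param threshold_weeks early-onset cutoff in weeks.
#' @return List of class `trae_cohort`: `onsets` data frame (`patient_id`,
#'   `first_onset_weeks`, `early_trae`, `first_category`,
#'   `max_grade_at_onset`), `n_early`, `n_late`.
#' @export
flag_early_cohort <- function(cohort, threshold_weeks = 4) {
  ids <- unique(cohort$outcomes$patient_id)
  per <- lapply(split_events(cohort$trae, ids), first_trae_onset,
                threshold_weeks = threshold_weeks)
  onsets <- data.frame(
    patient_id = ids,
    first_onset_weeks = vapply(per, `[[`, numeric(1), "first_onset_weeks"),
    early_trae = vapply(per, `[[`, logical(1), "early_trae"),
    first_category = vapply(per, function(x)
      paste(x$first_category, collapse = "/"), character(1)),
    max_grade_at_onset = vapply(per, `[[`, integer(1), "max_grade_at_onset"),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(onsets = onsets,
                 n_early = sum(onsets$early_trae),
                 n_late = sum(!onsets$early_trae),
                 threshold_weeks = threshold_weeks),
            class = "trae_cohort")
}

#' @export
print.trae_cohort <- function(x, ...) {
  cat(sprintf("TRAE onset (threshold %.1f weeks): %d early, %d late\n",
              x$threshold_weeks, x$n_early, x$n_late))
  invisible(x)
}
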