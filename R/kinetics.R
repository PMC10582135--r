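#' Parameters of the CRP kinetics classification
#'
#' The on-treatment CRP kinetics rule set distinguishes three trajectory
#' classes over the first three months of therapy:
#'
#' * **flare-response** — CRP at least doubles over baseline within the first
#'   month, then falls below baseline at least once within three months;
#' * **response** — CRP falls to at most 70% of baseline (a >= 30% decrease)
#'   within three months, with no prior flare-window doubling;
#' * **non-response** — everything else.
#'
#' All thresholds are weak inequalities on the named side: a value exactly at
#' `doubling_factor * baseline` counts as a doubling and a value exactly at
#' `response_fraction * baseline` counts as a response; the post-flare drop is
#' strictly below baseline. Windows are half-open intervals `(0, w]` in weeks.
#'
#' @param doubling_factor fold-change over baseline that counts as a flare
#'   doubling (default 2).
#' @param response_fraction fraction of baseline at or below which a
#'   measurement qualifies as a response (default 0.70, i.e. a 30% decrease).
#' @param flare_window_weeks window for the qualifying doubling ("first
#'   month", default 4 weeks).
#' @param assessment_window_weeks window for the whole classification
#'   ("within three months", default 12 weeks).
#' @param baseline_lookback_weeks how far before treatment start a baseline
#'   draw may lie (default 4 weeks).
#' @param detection_floor_mg_per_l lower clamp for the baseline so that
#'   fold-changes stay defined for undetectable baselines (default 1 mg/L).
#' @return A validated list of class `kinetics_params`.
#' @export
kinetics_params <- function(doubling_factor = 2.0,
                            response_fraction = 0.70,
                            flare_window_weeks = 4,
                            assessment_window_weeks = 12,
                            baseline_lookback_weeks = 4,
                            detection_floor_mg_per_l = 1.0) {
  stopifnot(doubling_factor > 1,
            response_fraction > 0, response_fraction < 1,
            flare_window_weeks > 0,
            flare_window_weeks <= assessment_window_weeks,
            baseline_lookback_weeks > 0,
            detection_floor_mg_per_l >= 0)
  structure(list(doubling_factor = doubling_factor,
                 response_fraction = response_fraction,
                 flare_window_weeks = flare_window_weeks,
                 assessment_window_weeks = assessment_window_weeks,
                 baseline_lookback_weeks = baseline_lookback_weeks,
                 detection_floor_mg_per_l = detection_floor_mg_per_l),
            class = "kinetics_params")
}

crp_classes <- c("flare_response", "response", "non_response")

# collapse duplicate measurement times to their maximum value
# (conservative for flare detection)
dedupe_series <- function(time, value) {
  if (anyDuplicated(time)) {
    value <- vapply(split(value, time), max, numeric(1))
    time <- as.numeric(names(value))
  }
  o <- order(time)
  list(time = time[o], value = unname(value)[o])
}

#' Baseline CRP of one patient
#'
#' The baseline is the pre-treatment measurement closest to treatment start
#' (largest `time_weeks <= 0`) within the lookback window, clamped from below
#' at the detection floor. Duplicate draws at the same time resolve to their
#' maximum.
#'
#' @param series data frame with columns `time_weeks` and `crp_mg_per_l` for
#'   one patient (pre-treatment times are non-positive).
#' @param params a [kinetics_params()] object.
#' @return Baseline CRP in mg/L.
#' @export
compute_baseline <- function(series, params = kinetics_params()) {
  stopifnot(is.data.frame(series),
            all(c("time_weeks", "crp_mg_per_l") %in% names(series)))
  pre <- series$time_weeks <= 0 &
    series$time_weeks >= -params$baseline_lookback_weeks
  if (!any(pre))
    stop("missing baseline: no pre-treatment CRP within ",
         params$baseline_lookback_weeks, " weeks before start", call. = FALSE)
  s <- dedupe_series(series$time_weeks[pre], series$crp_mg_per_l[pre])
  max(s$value[length(s$value)], params$detection_floor_mg_per_l)
}

#' Classify one patient's on-treatment CRP trajectory
#'
#' Applies the three-class kinetics rule (see [kinetics_params()]) to the
#' on-treatment measurements in `(0, assessment_window_weeks]`. Availability
#' requirements mirror the clinical minimum: at least one measurement within
#' the flare window and at least three within the assessment window overall.
#'
#' @param series data frame with columns `time_weeks`, `crp_mg_per_l`.
#' @param baseline baseline CRP in mg/L (see [compute_baseline()]).
#' @param params a [kinetics_params()] object.
#' @return List of class `kinetics_classification` with `crp_class` (one of
#'   `"flare_response"`, `"response"`, `"non_response"`), `baseline_crp`,
#'   `flare_time_weeks` (earliest qualifying doubling, `NA` otherwise),
#'   `response_time_weeks` (earliest qualifying drop, `NA` otherwise) and
#'   `n_measurements_used`.
#' @examples
#' s <- data.frame(time_weeks = c(-1, 2, 6, 10),
#'                 crp_mg_per_l = c(50, 110, 30, 25))
#' classify_patient(s, baseline = 50)$crp_class  # flare_response
#' @export
classify_patient <- function(series, baseline, params = kinetics_params()) {
  stopifnot(is.data.frame(series), is.numeric(baseline), baseline > 0)
  on_tx <- series$time_weeks > 0 &
    series$time_weeks <= params$assessment_window_weeks
  s <- dedupe_series(series$time_weeks[on_tx], series$crp_mg_per_l[on_tx])
  t <- s$time; v <- s$value
  in_flare_win <- t <= params$flare_window_weeks
  if (!any(in_flare_win))
    stop("insufficient data: no on-treatment CRP within the first ",
         params$flare_window_weeks, " weeks", call. = FALSE)
  if (length(t) < 3L)
    stop("insufficient data: fewer than 3 on-treatment CRP values within ",
         params$assessment_window_weeks, " weeks", call. = FALSE)

  doubling <- in_flare_win & v >= params$doubling_factor * baseline
  flare_time <- NA_real_; resp_time <- NA_real_
  cls <- "non_response"
  if (any(doubling)) {
    t1 <- min(t[doubling])
    post_drop <- t > t1 & v < baseline
    if (any(post_drop)) {
      cls <- "flare_response"
      flare_time <- t1
      resp_time <- min(t[post_drop])
    }
    # a flare-window doubling without the later drop blocks "response"
  } else {
    resp <- v <= params$response_fraction * baseline
    if (any(resp)) {
      cls <- "response"
      resp_time <- min(t[resp])
    }
  }
  structure(list(crp_class = cls, baseline_crp = baseline,
                 flare_time_weeks = flare_time,
                 response_time_weeks = resp_time,
                 n_measurements_used = length(t)),
            class = "kinetics_classification")
}

#' @export
print.kinetics_classification <- function(x, ...) {
  cat("CRP kinetics: ", x$crp_class,
      " (baseline ", format(x$baseline_crp, digits = 4), " mg/L, ",
      x$n_measurements_used, " on-treatment values)\n", sep = "")
  invisible(x)
}

#' Classify every patient in a cohort
#'
#' Runs [compute_baseline()] and [classify_patient()] per patient over the
#' cohort's longitudinal CRP table. Per-patient failures are collected and
#' reported together, with patient ids, rather than stopping at the first.
#'
#' @param cohort a cohort object from [read_cohort()] or [generate_cohort()],
#'   or any list with a `crp` data frame
#'   (`patient_id`, `time_weeks`, `crp_mg_per_l`).
#' @param params a [kinetics_params()] object.
#' @return List of class `kinetics_cohort`: `classifications` (data frame
#'   `patient_id`, `crp_class`, `baseline_crp`, `flare_time_weeks`,
#'   `response_time_weeks`), `counts` (named integer vector over the three
#'   classes) and `proportions`.
#' @export
classify_cohort <- function(cohort, params = kinetics_params()) {
  crp <- cohort$crp
  stopifnot(is.data.frame(crp),
            all(c("patient_id", "time_weeks", "crp_mg_per_l") %in% names(crp)))
  ids <- unique(crp$patient_id)
  by_patient <- split(seq_len(nrow(crp)),
                      factor(crp$patient_id, levels = ids))
  rows <- vector("list", length(ids))
  failures <- character(0)
  for (k in seq_along(ids)) {
    s <- crp[by_patient[[k]], , drop = FALSE]
    res <- tryCatch({
      b <- compute_baseline(s, params)
      cl <- classify_patient(s, b, params)
      data.frame(patient_id = ids[k], crp_class = cl$crp_class,
                 baseline_crp = cl$baseline_crp,
                 flare_time_weeks = cl$flare_time_weeks,
                 response_time_weeks = cl$response_time_weeks,
                 stringsAsFactors = FALSE)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <- c(failures, sprintf("%s: %s", ids[k], res))
    } else rows[[k]] <- res
  }
  if (length(failures))
    stop("classification failed for ", length(failures), " patient(s):\n  ",
         paste(failures, collapse = "\n  "), call. = FALSE)
  cls <- do.call(rbind, rows)
  if (is.null(cls))
    cls <- data.frame(patient_id = character(0), crp_class = character(0),
                      baseline_crp = numeric(0), flare_time_weeks = numeric(0),
                      response_time_weeks = numeric(0))
  counts <- vapply(crp_classes, function(cl) sum(cls$crp_class == cl), integer(1))
  structure(list(classifications = cls, counts = counts,
                 proportions = if (length(ids)) counts / length(ids)
                               else counts * NA_real_),
            class = "kinetics_cohort")
}

#' @export
print.kinetics_cohort <- function(x, ...) {
  cat("CRP kinetics over", sum(x$counts), "patients:\n")
  print(x$counts)
  invisible(x)
}
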