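#' Expand a printed cross-tabulation into patient-level records
#'
#' Materialises an r x c table of counts as one record per patient, with the
#' row and column labels as factor columns. Re-tabulating the records
#' reproduces the counts exactly, which makes published cross-tabs usable as
#' pipeline inputs.
#'
#' @param table matrix of counts or [contingency_table()].
#' @param row_var,col_var names of the output columns.
#' @return Data frame with `patient_id`, `row_var` and `col_var` columns.
#' @examples
#' kin <- matrix(c(1, 1, 7, 1, 7, 14, 8, 10, 8), 3, 3, byrow = TRUE,
#'               dimnames = list(c("flare", "response", "non_response"),
#'                               c("PD", "SD", "PR/CR")))
#' nrow(tables_from_counts(kin))  # 57
#' @export
tables_from_counts <- function(table, row_var = "row", col_var = "col") {
  m <- as_count_matrix(table)
  if (is.null(rownames(m))) rownames(m) <- paste0("R", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("C", seq_len(ncol(m)))
  idx <- which(m >= 0, arr.ind = TRUE)
  rows <- rep(rownames(m)[idx[, 1]], m[idx])
  cols <- rep(colnames(m)[idx[, 2]], m[idx])
  out <- data.frame(patient_id = sprintf("E%04d", seq_along(rows)),
                    row = factor(rows, levels = rownames(m)),
                    col = factor(cols, levels = colnames(m)),
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- c(row_var, col_var)
  out
}

#' Pipeline configuration
#'
#' Exactly one of `input_paths` (named list/vector with `crp`, `trae`,
#' `outcomes`) or `simulation` (a [simulation_config()]) must be given.
#'
#' @param input_paths paths to the three cohort CSVs, or `NULL`.
#' @param simulation a [simulation_config()], or `NULL`.
#' @param kinetics a [kinetics_params()].
#' @param trae_threshold_weeks early-onset cutoff in weeks.
#' @param seed integer seed for the simulation and any Monte-Carlo test.
#' @param out_dir optional output directory for the JSON report and CSVs.
#' @param exact_max_tables enumeration cap before the exact test falls back
#'   to Monte Carlo.
#' @param mc_B Monte-Carlo sample size for the fallback.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(input_paths = NULL, simulation = NULL,
                            kinetics = kinetics_params(),
                            trae_threshold_weeks = 4, seed = 1,
                            out_dir = NULL, exact_max_tables = 2e6,
                            mc_B = 10000) {
  if (is.null(input_paths) == is.null(simulation))
    stop("config error: exactly one of input_paths and simulation must be set",
         call. = FALSE)
  if (!is.null(input_paths) &&
      !all(c("crp", "trae", "outcomes") %in% names(input_paths)))
    stop("config error: input_paths needs elements crp, trae, outcomes",
         call. = FALSE)
  structure(list(input_paths = input_paths, simulation = simulation,
                 kinetics = kinetics,
                 trae_threshold_weeks = trae_threshold_weeks, seed = seed,
                 out_dir = out_dir, exact_max_tables = exact_max_tables,
                 mc_B = mc_B),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `inputs:` (`crp`, `trae`, `outcomes`), `simulation:`
#' (arguments of [simulation_config()]), `crp_kinetics:` (arguments of
#' [kinetics_params()]), `trae: threshold_weeks`, `seed`, `out_dir`.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulation))
    do.call(simulation_config, y$simulation) else NULL
  kin <- if (!is.null(y$crp_kinetics))
    do.call(kinetics_params, y$crp_kinetics) else kinetics_params()
  pipeline_config(
    input_paths = y$inputs, simulation = sim, kinetics = kin,
    trae_threshold_weeks = y$trae$threshold_weeks %||% 4,
    seed = y$seed %||% 1, out_dir = y$out_dir)
}

exact_or_mc <- function(tab, config) {
  freeman_halton_exact(tab, max_tables = config$exact_max_tables,
                       monte_carlo = TRUE, B = config$mc_B,
                       mc_seed = config$seed + 1L)
}

test_summary <- function(ex, lr) {
  list(exact_p = ex$p_value, exact_method = ex$method,
       exact_n_tables = ex$n_tables_enumerated,
       mc_se = if (!is.null(ex$monte_carlo)) ex$monte_carlo$se else NULL,
       lr_chisq = lr$statistic, lr_df = lr$df, lr_p = lr$p_value)
}

#' Run the end-to-end on-treatment risk analysis
#'
#' Reads or simulates the cohort, classifies CRP kinetics, derives the
#' early-TRAE factor, assigns risk groups, cross-tabulates against the
#' primary treatment response, runs the association tests (Freeman-Halton
#' exact with Monte-Carlo fallback, likelihood-ratio chi-square, logistic
#' model of both factors against objective response), and fits the survival
#' analyses (Kaplan-Meier per risk group, Gehan-Breslow Wilcoxon comparison,
#' univariable Cox for both factors). If `out_dir` is set, writes the JSON
#' report and the derived CSVs (classifications, onsets, risk assignments,
#' per-group Kaplan-Meier curves).
#'
#' @param config a [pipeline_config()].
#' @return Nested list of class `pipeline_report` (see sections `cohort`,
#'   `kinetics`, `trae`, `risk`, `associations`, `survival`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$simulation)) {
    generate_cohort(config$simulation, seed = config$seed)
  } else {
    read_cohort(config$input_paths[["crp"]], config$input_paths[["trae"]],
                config$input_paths[["outcomes"]])
  }

  kin <- classify_cohort(cohort, config$kinetics)
  trae <- flag_early_cohort(cohort, config$trae_threshold_weeks)
  assign <- risk_assignments(kin, trae)
  strata <- stratify_cohort(assign, cohort$outcomes)
  onset_stats <- mean_time_to_first_trae(cohort, skip_event_free = TRUE)

  out <- cohort$outcomes[match(assign$patient_id, cohort$outcomes$patient_id), ]
  pooled <- pool_response(out$response)

  kin_tab <- contingency_table(table(
    factor(assign$crp_class, levels = crp_classes), pooled))
  trae_tab <- contingency_table(table(
    factor(ifelse(assign$trae_factor, "early", "late"),
           levels = c("early", "late")), pooled))
  risk_tab <- strata$cross_tab

  orr <- objective_response_indicator(out$response)
  logit <- tryCatch(
    logistic_fit(orr, data.frame(
      crp_class = factor(assign$crp_class,
                         levels = c("non_response", "flare_response",
                                    "response")),
      early_trae = factor(ifelse(assign$trae_factor, "early", "late"),
                          levels = c("late", "early")))),
    error = function(e) list(error = conditionMessage(e)))

  surv_rec <- data.frame(time_weeks = out$pfs_weeks, event = out$pfs_event)
  grp <- factor(assign$risk_group, levels = risk_groups)
  km <- lapply(stats::setNames(risk_groups, risk_groups), function(g) {
    r <- surv_rec[grp == g, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    est <- km_estimate(r)
    list(n = est$n, events = sum(est$n_event), median = est$median,
         median_ci = est$median_ci, curve = est)
  })
  gehan <- if (nlevels(droplevels(grp)) >= 2 && any(surv_rec$event))
    gehan_wilcoxon_test(surv_rec, droplevels(grp)) else NULL
  cox_crp <- tryCatch(
    cox_univariable(surv_rec, factor(assign$crp_factor,
                                     levels = c(FALSE, TRUE),
                                     labels = c("no_crp_factor", "crp_factor"))),
    error = function(e) list(error = conditionMessage(e)))
  cox_trae <- tryCatch(
    cox_univariable(surv_rec, factor(assign$trae_factor,
                                     levels = c(FALSE, TRUE),
                                     labels = c("late", "early"))),
    error = function(e) list(error = conditionMessage(e)))

  report <- structure(list(
    cohort = list(n_patients = cohort$n_patients,
                  n_crp_records = nrow(cohort$crp),
                  n_trae_records = nrow(cohort$trae),
                  source = if (is.null(config$simulation)) "files"
                           else "simulation",
                  seed = config$seed),
    kinetics = list(counts = as.list(kin$counts),
                    proportions = as.list(kin$proportions)),
    trae = list(n_early = trae$n_early, n_late = trae$n_late,
                threshold_weeks = config$trae_threshold_weeks,
                mean_onset_weeks = onset_stats$mean_weeks,
                min_onset_weeks = onset_stats$min_weeks,
                max_onset_weeks = onset_stats$max_weeks),
    risk = c(list(group_counts = as.list(strata$group_counts),
                  group_labels = as.list(risk_group_synonyms),
                  cross_tab = unclass(risk_tab$counts)),
             test_summary(exact_or_mc(risk_tab, config),
                          lr_chisq_test(risk_tab))),
    associations = list(
      kinetics_vs_response = c(list(table = unclass(kin_tab$counts)),
                               test_summary(exact_or_mc(kin_tab, config),
                                            lr_chisq_test(kin_tab))),
      trae_vs_response = c(list(table = unclass(trae_tab$counts)),
                           test_summary(exact_or_mc(trae_tab, config),
                                        lr_chisq_test(trae_tab))),
      logistic_orr = if (!is.null(logit$error)) logit else list(
        odds_ratios = logit$odds_ratios,
        lr_chisq = logit$lr_chisq, lr_df = logit$lr_df, lr_p = logit$lr_p,
        nagelkerke_r2 = logit$nagelkerke_r2)),
    survival = list(
      km_by_group = lapply(km, function(x) if (is.null(x)) NULL else
        list(n = x$n, events = x$events, median_weeks = x$median,
             median_ci = x$median_ci)),
      gehan_wilcoxon = if (is.null(gehan)) NULL else
        list(statistic = gehan$statistic, df = gehan$df,
             p_value = gehan$p_value),
      cox_crp_factor = if (!is.null(cox_crp$error)) cox_crp else
        cox_crp$hazard_ratios,
      cox_trae_factor = if (!is.null(cox_trae$error)) cox_trae else
        cox_trae$hazard_ratios)),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    d <- config$out_dir
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
    write_report(unclass(report), file.path(d, "report.json"))
    utils::write.csv(kin$classifications,
                     file.path(d, "crp_classification.csv"), row.names = FALSE)
    utils::write.csv(trae$onsets, file.path(d, "trae_onsets.csv"),
                     row.names = FALSE)
    utils::write.csv(assign, file.path(d, "risk_assignments.csv"),
                     row.names = FALSE)
    km_rows <- do.call(rbind, lapply(risk_groups, function(g) {
      x <- km[[g]]
      if (is.null(x)) return(NULL)
      data.frame(risk_group = g, time = x$curve$time, n_risk = x$curve$n_risk,
                 survival = x$curve$surv, ci_low = x$curve$ci_low,
                 ci_high = x$curve$ci_high)
    }))
    if (!is.null(km_rows))
      utils::write.csv(km_rows, file.path(d, "km_curves.csv"),
                       row.names = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("On-treatment risk pipeline report\n")
  cat(sprintf("  cohort: %d patients (%s)\n", x$cohort$n_patients,
              x$cohort$source))
  cat("  CRP kinetics:", paste(names(x$kinetics$counts),
                               unlist(x$kinetics$counts), collapse = ", "), "\n")
  cat(sprintf("  early TRAE: %d / %d\n", x$trae$n_early,
              x$trae$n_early + x$trae$n_late))
  cat("  risk groups:", paste(names(x$risk$group_counts),
                              unlist(x$risk$group_counts), collapse = ", "), "\n")
  cat(sprintf("  risk model vs response: exact p = %.4g, LR p = %.4g\n",
              x$risk$exact_p, x$risk$lr_p))
  invisible(x)
}
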