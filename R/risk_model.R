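risk_groups <- c("low", "intermediate", "high")
response_levels <- c("PD", "SD", "PR", "CR")

# the paper-style synonyms used in printed reports
risk_group_synonyms <- c(low = "favorable", intermediate = "intermediate",
                         high = "poor")

#' Assign the on-treatment risk group from the two binary factors
#'
#' The three-tier on-treatment risk model combines (1) the CRP factor —
#' kinetics class flare-response or response — and (2) the early-TRAE factor:
#' both present gives the low (favorable) risk group, exactly one the
#' intermediate group, neither the high (poor) group.
#'
#' @param crp_class kinetics class (`"flare_response"`, `"response"`,
#'   `"non_response"`), or a logical CRP factor directly.
#' @param early_trae logical early-onset TRAE factor.
#' @return List of class `risk_assignment` with `crp_factor`, `trae_factor`,
#'   `risk_group`.
#' @examples
#' assign_risk_group("flare_response", TRUE)$risk_group   # "low"
#' assign_risk_group("non_response", FALSE)$risk_group    # "high"
#' @export
assign_risk_group <- function(crp_class, early_trae) {
  crp_factor <- if (is.logical(crp_class)) crp_class else {
    stopifnot(crp_class %in% crp_classes)
    crp_class %in% c("flare_response", "response")
  }
  stopifnot(is.logical(early_trae), !is.na(early_trae), !is.na(crp_factor))
  group <- c("high", "intermediate", "low")[crp_factor + early_trae + 1L]
  structure(list(crp_factor = crp_factor, trae_factor = early_trae,
                 risk_group = group),
            class = "risk_assignment")
}

#' @export
print.risk_assignment <- function(x, ...) {
  cat(sprintf("Risk group: %s (%s) [CRP factor: %s, early TRAE: %s]\n",
              x$risk_group, risk_group_synonyms[[x$risk_group]],
              x$crp_factor, x$trae_factor))
  invisible(x)
}

#' Objective response indicator
#'
#' The objective response rate pools partial and complete responses; the
#' indicator is `TRUE` for RECIST class PR or CR.
#'
#' @param response RECIST response labels (`"PD"`, `"SD"`, `"PR"`, `"CR"`).
#' @return Logical vector.
#' @export
objective_response_indicator <- function(response) {
  stopifnot(all(response %in% response_levels))
  response %in% c("PR", "CR")
}

#' Risk assignments for every patient
#'
#' Joins per-patient kinetics classes and early-TRAE flags into risk
#' assignments.
#'
#' @param kinetics a [classify_cohort()] result.
#' @param trae a [flag_early_cohort()] result.
#' @return Data frame `patient_id`, `crp_class`, `crp_factor`, `trae_factor`,
#'   `risk_group`.
#' @export
risk_assignments <- function(kinetics, trae) {
  k <- kinetics$classifications
  t <- trae$onsets
  if (!setequal(k$patient_id, t$patient_id))
    stop("kinetics and TRAE tables cover different patients", call. = FALSE)
  t <- t[match(k$patient_id, t$patient_id), ]
  grp <- mapply(function(cl, et) assign_risk_group(cl, et)$risk_group,
                k$crp_class, t$early_trae, USE.NAMES = FALSE)
  data.frame(patient_id = k$patient_id,
             crp_class = k$crp_class,
             crp_factor = k$crp_class %in% c("flare_response", "response"),
             trae_factor = t$early_trae,
             risk_group = grp,
             stringsAsFactors = FALSE)
}

pool_response <- function(response) {
  factor(ifelse(response %in% c("PR", "CR"), "PR/CR", response),
         levels = c("PD", "SD", "PR/CR"))
}

#' Stratify a cohort by risk group and cross-tabulate against outcome
#'
#' Counts patients per risk group and builds the 3 x 3 cross-tabulation of
#' risk group against primary treatment response with PR and CR pooled.
#'
#' @param assignments data frame from [risk_assignments()] (columns
#'   `patient_id`, `risk_group`).
#' @param outcomes data frame with `patient_id` and `response`.
#' @return List of class `risk_strata`: `group_counts` (named vector over
#'   low/intermediate/high), `cross_tab` (a [contingency_table()] of risk
#'   group x {PD, SD, PR/CR}), `n`.
#' @export
stratify_cohort <- function(assignments, outcomes) {
  if (!setequal(assignments$patient_id, outcomes$patient_id))
    stop("assignments and outcomes cover different patients", call. = FALSE)
  o <- outcomes[match(assignments$patient_id, outcomes$patient_id), ]
  grp <- factor(assignments$risk_group, levels = risk_groups)
  counts <- table(grp)
  xt <- table(grp, pool_response(o$response))
  structure(list(group_counts = stats::setNames(as.integer(counts), risk_groups),
                 cross_tab = contingency_table(
                   matrix(as.integer(xt), nrow = 3,
                          dimnames = dimnames(xt))),
                 n = nrow(assignments)),
            class = "risk_strata")
}

#' @export
print.risk_strata <- function(x, ...) {
  cat("On-treatment risk model (n =", x$n, ")\n")
  lab <- sprintf("%s (%s)", names(x$group_counts),
                 risk_group_synonyms[names(x$group_counts)])
  print(stats::setNames(x$group_counts, lab))
  cat("\nCross-tabulation against primary treatment response:\n")
  print(x$cross_tab$counts)
  invisible(x)
}
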