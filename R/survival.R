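as_survival_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time_weeks", "event") %in% names(records)))
  if (any(!is.finite(records$time_weeks)) || any(records$time_weeks <= 0))
    stop("survival times must be positive and finite", call. = FALSE)
  records$event <- as.logical(records$event)
  records
}

#' Kaplan-Meier estimate with median confidence interval
#'
#' Product-limit estimator via [survival::survfit()]. Censored times tied
#' with event times are handled in the usual convention (censoring occurs
#' just after the event). The median is the smallest time at which the
#' survival curve reaches 0.5 or less; its 95% interval inverts the
#' log-log-transformed pointwise confidence band (Brookmeyer-Crowley). Both
#' are `NA` when the curve never reaches 0.5.
#'
#' @param records data frame with columns `time_weeks` (positive) and
#'   `event` (logical/0-1; `TRUE` = progression or death observed).
#' @param conf_level confidence level of the band (default 0.95).
#' @return Object of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `ci_low`, `ci_high`, `median`, `median_ci`
#'   (length-2 vector), `n`.
#' @examples
#' km_estimate(data.frame(time_weeks = 1:5, event = TRUE))$median  # 3
#' @export
km_estimate <- function(records, conf_level = 0.95) {
  records <- as_survival_records(records)
  if (nrow(records) == 0L) stop("no survival records", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time_weeks, event) ~ 1,
    data = records, conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 n_censor = fit$n.censor, surv = fit$surv,
                 ci_low = fit$lower, ci_high = fit$upper,
                 median = unname(tab["median"]),
                 median_ci = unname(c(tab["0.95LCL"], tab["0.95UCL"])),
                 n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate over %d records (%d events)\n",
              x$n, sum(x$n_event)))
  cat(sprintf("  median: %s weeks (95%% CI %s-%s)\n",
              format(x$median, digits = 4),
              format(x$median_ci[1], digits = 4),
              format(x$median_ci[2], digits = 4)))
  invisible(x)
}

#' Gehan-Breslow generalized Wilcoxon test for censored groups
#'
#' Weighted logrank test with weight equal to the total number at risk at
#' each distinct event time (the Gehan-Breslow weighting, the censored-data
#' Wilcoxon of the SPSS family). At each event time the per-group
#' observed-minus-expected event counts are accumulated with weight `n_j`,
#' the covariance uses the standard multivariate-hypergeometric form, and
#' the statistic `U' V^{-1} U` (first k-1 groups) is referred to chi-square
#' with k-1 degrees of freedom.
#'
#' @param records data frame with columns `time_weeks`, `event`.
#' @param group vector of group labels, one per record (k >= 2 groups).
#' @return List of class `gehan_test`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected_weighted` per group.
#' @export
gehan_wilcoxon_test <- function(records, group) {
  records <- as_survival_records(records)
  group <- factor(group)
  stopifnot(length(group) == nrow(records), nlevels(group) >= 2)
  if (!any(records$event))
    stop("undefined test: no events in any group", call. = FALSE)
  k <- nlevels(group)
  tt <- records$time_weeks; ev <- records$event
  event_times <- sort(unique(tt[ev]))
  U <- numeric(k); V <- matrix(0, k, k); Ow <- numeric(k)
  for (t in event_times) {
    at_risk <- tt >= t
    n_j <- sum(at_risk)
    d_j <- sum(ev & tt == t)
    if (n_j < 1 || d_j < 1) next
    n_ij <- tabulate(group[at_risk], nbins = k)
    d_ij <- tabulate(group[ev & tt == t], nbins = k)
    w <- n_j                                  # Gehan-Breslow weight
    U <- U + w * (d_ij - n_ij * d_j / n_j)
    Ow <- Ow + w * d_ij
    if (n_j > 1) {
      p_i <- n_ij / n_j
      vcov_t <- (diag(p_i, k) - tcrossprod(p_i)) *
        d_j * (n_j - d_j) / (n_j - 1)
      V <- V + w^2 * vcov_t
    }
  }
  idx <- seq_len(k - 1L)
  Vsub <- V[idx, idx, drop = FALSE]
  stat <- if (all(abs(U[idx]) < 1e-12)) 0 else {
    sol <- tryCatch(solve(Vsub, U[idx]), error = function(e) NULL)
    if (is.null(sol)) {
      # singular covariance: generalized inverse via eigendecomposition
      eg <- eigen(Vsub, symmetric = TRUE)
      pos <- eg$values > max(eg$values) * 1e-10
      sol <- eg$vectors[, pos, drop = FALSE] %*%
        ((t(eg$vectors[, pos, drop = FALSE]) %*% U[idx]) / eg$values[pos])
    }
    drop(U[idx] %*% sol)
  }
  structure(list(statistic = stat, df = k - 1L,
                 p_value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(Ow, levels(group)),
                 score = stats::setNames(U, levels(group))),
            class = "gehan_test")
}

#' @export
print.gehan_test <- function(x, ...) {
  cat(sprintf("Gehan-Breslow generalized Wilcoxon: chi2(%d) = %.4f, p = %.4g\n",
              x$df, x$statistic, x$p_value))
  invisible(x)
}

#' Univariable Cox proportional-hazards regression
#'
#' Partial-likelihood fit via [survival::coxph()] with Breslow tie handling
#' (Efron available through `ties`). Returns hazard ratios with Wald
#' confidence intervals and p-values. A constant covariate is rejected;
#' monotone likelihood (the censored-data analogue of separation) is
#' reported via the `separation` flag when coefficients diverge.
#'
#' @param records data frame with columns `time_weeks`, `event`.
#' @param covariate per-record covariate: numeric, logical, or factor
#'   (dummy-coded against its first level).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param conf_level confidence level for the Wald intervals.
#' @return Object of class `cox_fit`: `hazard_ratios` (data frame `term`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`), `coefficients`,
#'   `loglik`, `separation`, `n`, `n_events`, `fit`.
#' @export
cox_univariable <- function(records, covariate, ties = c("breslow", "efron"),
                            conf_level = 0.95) {
  ties <- match.arg(ties)
  records <- as_survival_records(records)
  stopifnot(length(covariate) == nrow(records))
  if (length(unique(covariate)) < 2L)
    stop("degenerate covariate: constant across patients", call. = FALSE)
  if (!any(records$event)) stop("no events observed", call. = FALSE)
  dat <- data.frame(time_weeks = records$time_weeks,
                    event = records$event, x = covariate)
  fit <- suppressWarnings(survival::coxph(
    survival::Surv(time_weeks, event) ~ x, data = dat, ties = ties,
    control = survival::coxph.control(eps = 1e-12, iter.max = 100)))
  co <- stats::coef(fit)
  sm <- summary(fit)$coefficients
  separation <- any(!is.finite(co)) || any(abs(co) > 12)
  if (separation)
    warning("monotone partial likelihood (separation); estimates are bounded ",
            "only by the iteration limit", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  hr <- data.frame(term = rownames(sm),
                   hazard_ratio = exp(sm[, "coef"]),
                   ci_low = exp(sm[, "coef"] - z * sm[, "se(coef)"]),
                   ci_high = exp(sm[, "coef"] + z * sm[, "se(coef)"]),
                   p_value = sm[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(list(hazard_ratios = hr, coefficients = sm,
                 loglik = fit$loglik, separation = separation, ties = ties,
                 n = nrow(records), n_events = sum(records$event), fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties; n = %d, events = %d)%s\n",
              x$ties, x$n, x$n_events,
              if (x$separation) " [monotone likelihood]" else ""))
  hr <- x$hazard_ratios
  hr[-1] <- lapply(hr[-1], signif, 4)
  print(hr, row.names = FALSE)
  invisible(x)
}
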