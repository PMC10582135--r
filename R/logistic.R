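#' Binomial logistic regression with odds ratios and Nagelkerke R-squared
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()], convergence tightened to a deviance tolerance of 1e-12,
#' at most 100 iterations) with the summaries conventional in clinical
#' association tables: Wald standard errors and p-values, odds ratios with
#' 95% Wald intervals, the likelihood-ratio chi-square against the
#' intercept-only model, and Nagelkerke's pseudo R-squared
#' \deqn{R^2_N = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}.}
#'
#' Complete (or quasi-complete) separation is detected from diverging
#' coefficients and reported as an error naming the offending predictor:
#' Wald summaries are meaningless there.
#'
#' @param outcome logical or 0/1 vector.
#' @param predictors data frame of predictors; factors are dummy-coded
#'   against their first level (set the reference by releveling).
#' @param conf_level confidence level for the odds-ratio intervals.
#' @return Object of class `logistic_fit`: `coefficients` (matrix with
#'   estimate, se, z, p), `odds_ratios` (data frame `term`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_value`), `loglik_null`, `loglik_fitted`,
#'   `lr_chisq`, `lr_df`, `lr_p`, `nagelkerke_r2`, `n`, `fit` (the glm).
#' @examples
#' set.seed(1)
#' x <- rbinom(100, 1, 0.5)
#' y <- rbinom(100, 1, stats::plogis(-0.5 + x))
#' logistic_fit(y, data.frame(x = factor(x)))
#' @export
logistic_fit <- function(outcome, predictors, conf_level = 0.95) {
  outcome <- as.integer(outcome)
  stopifnot(all(outcome %in% 0:1), is.data.frame(predictors),
            nrow(predictors) == length(outcome))
  dat <- cbind(.y = outcome, predictors)
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged)
    stop("logistic fit did not converge within 100 iterations", call. = FALSE)
  co <- stats::coef(fit)
  if (length(co) > length(outcome))
    stop("more parameters than observations", call. = FALSE)
  big <- which(abs(co[-1]) > 12)
  if (length(big))
    stop("separation detected for predictor(s): ",
         paste(names(co[-1])[big], collapse = ", "), call. = FALSE)
  sm <- summary(fit)$coefficients
  ll1 <- as.numeric(stats::logLik(fit))
  fit0 <- stats::glm(outcome ~ 1, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(fit0))
  n <- length(outcome)
  lr <- max(0, 2 * (ll1 - ll0))
  lr_df <- length(co) - 1L
  r2_cs <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_n <- if (lr_df > 0) r2_cs / (1 - exp(2 * ll0 / n)) else 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- rownames(sm)[-1]
  ors <- data.frame(term = terms,
                    odds_ratio = exp(sm[-1, 1]),
                    ci_low = exp(sm[-1, 1] - z * sm[-1, 2]),
                    ci_high = exp(sm[-1, 1] + z * sm[-1, 2]),
                    p_value = sm[-1, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = sm, odds_ratios = ors,
                 loglik_null = ll0, loglik_fitted = ll1,
                 lr_chisq = lr, lr_df = lr_df,
                 lr_p = stats::pchisq(lr, max(lr_df, 1), lower.tail = FALSE),
                 nagelkerke_r2 = min(max(r2_n, 0), 1),
                 n = n, fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "Logistic regression (n = %d): LR chi2(%d) = %.3f, p = %.4g, Nagelkerke R2 = %.3f\n",
    x$n, x$lr_df, x$lr_chisq, x$lr_p, x$nagelkerke_r2))
  if (nrow(x$odds_ratios)) {
    or <- x$odds_ratios
    or[-1] <- lapply(or[-1], signif, 4)
    print(or, row.names = FALSE)
  }
  invisible(x)
}

block_lr_p <- function(outcome, base_cols, add_col, predictors) {
  f1 <- logistic_quiet(outcome, predictors[, c(base_cols, add_col), drop = FALSE])
  f0 <- if (length(base_cols))
    logistic_quiet(outcome, predictors[, base_cols, drop = FALSE])
  else NULL
  ll0 <- if (is.null(f0)) {
    as.numeric(stats::logLik(stats::glm(outcome ~ 1, family = stats::binomial())))
  } else as.numeric(stats::logLik(f0))
  ll1 <- as.numeric(stats::logLik(f1))
  df <- attr(stats::logLik(f1), "df") -
    if (is.null(f0)) 1L else attr(stats::logLik(f0), "df")
  stats::pchisq(max(0, 2 * (ll1 - ll0)), max(df, 1), lower.tail = FALSE)
}

logistic_quiet <- function(outcome, predictors) {
  dat <- cbind(.y = as.integer(outcome), predictors)
  suppressWarnings(stats::glm(.y ~ ., data = dat, family = stats::binomial(),
                              control = stats::glm.control(epsilon = 1e-12,
                                                           maxit = 100)))
}

#' Stepwise predictor selection by likelihood-ratio tests
#'
#' Forward selection with backward elimination over predictor blocks
#' (each data-frame column is one block; a factor enters or leaves with all
#' its dummies). Forward steps add the block with the smallest
#' likelihood-ratio p-value below `alpha_enter`; backward steps drop any
#' included block whose removal p-value exceeds `alpha_remove`. A removed
#' block may re-enter only with a strictly smaller p-value than when it was
#' removed, which guarantees termination.
#'
#' @param outcome logical or 0/1 vector.
#' @param candidates data frame of candidate predictor blocks.
#' @param alpha_enter forward entry threshold (default 0.05).
#' @param alpha_remove backward removal threshold (default 0.10).
#' @return List with `selected` (character vector of column names, possibly
#'   empty), `trace` (data frame of steps) and `fit` (the [logistic_fit()]
#'   on the selected blocks, `NULL` when none selected).
#' @export
stepwise_select <- function(outcome, candidates,
                            alpha_enter = 0.05, alpha_remove = 0.10) {
  stopifnot(is.data.frame(candidates), alpha_enter <= alpha_remove)
  outcome <- as.integer(outcome)
  pool <- names(candidates)
  selected <- character(0)
  removed_at <- numeric(0)  # name -> p at removal; bars re-entry unless improved
  trace <- list()
  repeat {
    changed <- FALSE
    # forward
    avail <- setdiff(pool, selected)
    if (length(avail)) {
      pv <- vapply(avail, function(nm)
        block_lr_p(outcome, selected, nm, candidates), numeric(1))
      prev <- removed_at[avail]    # NA for blocks never removed
      ok <- pv < alpha_enter & (is.na(prev) | pv < prev - 1e-12)
      if (any(ok, na.rm = TRUE)) {
        best <- avail[ok][which.min(pv[ok])]
        selected <- c(selected, best)
        trace[[length(trace) + 1L]] <-
          data.frame(step = "add", term = best, p_value = min(pv[ok]))
        changed <- TRUE
      }
    }
    # backward
    if (length(selected) > 0L) {
      pv <- vapply(selected, function(nm)
        block_lr_p(outcome, setdiff(selected, nm), nm, candidates), numeric(1))
      worst <- which.max(pv)
      if (pv[worst] > alpha_remove) {
        nm <- selected[worst]
        removed_at[nm] <- pv[worst]
        selected <- setdiff(selected, nm)
        trace[[length(trace) + 1L]] <-
          data.frame(step = "drop", term = nm, p_value = pv[worst])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit <- if (length(selected))
    logistic_fit(outcome, candidates[, selected, drop = FALSE]) else NULL
  list(selected = selected,
       trace = if (length(trace)) do.call(rbind, trace)
               else data.frame(step = character(0), term = character(0),
                               p_value = numeric(0)),
       fit = fit)
}
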