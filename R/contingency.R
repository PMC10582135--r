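#' Labeled contingency table of non-negative integer counts
#'
#' Light container for an r x c cross-tabulation. All exact-test and
#' odds-ratio functions accept either a plain integer matrix or an object
#' built here; labels are carried through to printed output and reports.
#'
#' @param counts r x c matrix of non-negative integers, r >= 2, c >= 2.
#' @param row_labels,col_labels optional character vectors; default to the
#'   dimnames of `counts` or `R1..Rr` / `C1..Cc`.
#' @return An object of class `contingency_table`.
#' @examples
#' contingency_table(matrix(c(7, 2, 8, 18), 2, 2, byrow = TRUE),
#'                   row_labels = c("flare", "non_response"),
#'                   col_labels = c("ORR", "no_ORR"))
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be finite non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(row_labels)) row_labels <- rownames(counts)
  if (is.null(col_labels)) col_labels <- colnames(counts)
  if (is.null(row_labels)) row_labels <- paste0("R", seq_len(nrow(counts)))
  if (is.null(col_labels)) col_labels <- paste0("C", seq_len(ncol(counts)))
  dimnames(counts) <- list(row_labels, col_labels)
  structure(list(counts = counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("Contingency table (", nrow(x$counts), "x", ncol(x$counts),
      ", n = ", sum(x$counts), ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

as_count_matrix <- function(table) {
  if (inherits(table, "contingency_table")) return(table$counts)
  m <- as.matrix(table)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be finite non-negative integers", call. = FALSE)
  m
}

# log multivariate hypergeometric probability constant for fixed margins:
# P(T) = prod(rs!) prod(cs!) / (n! prod(cells!))
fm_log_const <- function(rs, cs) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1)
}

# Enumerate every table with the given margins, invoking visit(log_prob)
# once per table. Rows are filled left to right; the final cell of each row
# and the whole final row are forced by the margins, which keeps the
# recursion depth at (r-1) * (c-1) free cells. Feasibility bounds from the
# remaining margins prune dead branches. Stops with a resource condition
# once more than `cap` tables have been visited.
fm_enumerate <- function(rs, cs, visit, cap = 5e7) {
  r <- length(rs); cc <- length(cs)
  # cheap upper bound on the enumeration size: each free cell ranges over at
  # most min(row, column) + 1 values; skip the recursion when it cannot fit
  bound <- prod(outer(rs[-r], cs[-cc], pmin) + 1)
  if (is.finite(bound) && bound > cap || !is.finite(bound))
    stop(structure(class = c("crpflare_enumeration_cap", "error", "condition"),
                   list(message = sprintf(
                     "more than %g fixed-margin tables; use the Monte-Carlo fallback", cap),
                     call = NULL)))
  const <- fm_log_const(rs, cs)
  n_seen <- 0L
  recurse <- function(i, j, rowrem, colrem, lfac_sum) {
    if (i == r) {
      # last row forced by the remaining column margins
      if (any(colrem < 0)) return()
      n_seen <<- n_seen + 1L
      if (n_seen > cap)
        stop(structure(class = c("crpflare_enumeration_cap", "error", "condition"),
                       list(message = sprintf(
                         "more than %g fixed-margin tables; use the Monte-Carlo fallback", cap),
                         call = NULL)))
      visit(const - lfac_sum - sum(lgamma(colrem + 1)))
      return()
    }
    if (j == cc) {                       # last cell of row i forced
      v <- rowrem
      if (v < 0 || v > colrem[j]) return()
      colrem[j] <- colrem[j] - v
      recurse(i + 1L, 1L, if (i + 1L <= r) rs[i + 1L] else 0L,
              colrem, lfac_sum + lgamma(v + 1))
      return()
    }
    lo <- max(0L, rowrem - sum(colrem[(j + 1L):cc]))
    hi <- min(rowrem, colrem[j])
    if (lo > hi) return()
    for (v in lo:hi) {
      cr <- colrem; cr[j] <- cr[j] - v
      recurse(i, j + 1L, rowrem - v, cr, lfac_sum + lgamma(v + 1))
    }
  }
  recurse(1L, 1L, rs[1L], cs, 0)
  invisible(n_seen)
}

exact_test_result <- function(p_value, n_tables, observed_prob, method,
                              total_prob = NA_real_, mc = NULL) {
  structure(list(p_value = min(1, p_value), n_tables_enumerated = n_tables,
                 observed_prob = observed_prob, method = method,
                 total_prob = total_prob, monte_carlo = mc),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(x$method, "\n  p-value: ", format(x$p_value, digits = 6), sep = "")
  if (!is.null(x$monte_carlo))
    cat(sprintf("  (Monte Carlo, B = %d, se = %.2g, seed = %s)",
                x$monte_carlo$B, x$monte_carlo$se,
                format(x$monte_carlo$seed)))
  cat("\n  tables: ", x$n_tables_enumerated,
      ", observed table probability: ", format(x$observed_prob, digits = 6),
      "\n", sep = "")
  invisible(x)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided exact test conditioning on both margins. The p-value sums the
#' hypergeometric probabilities of every table with the observed margins
#' whose probability does not exceed the observed table's probability
#' (within relative tolerance `tol`, so that floating-point ties are kept).
#' This is the two-sided convention of SPSS and of `stats::fisher.test`.
#'
#' @param table 2 x 2 matrix of non-negative integer counts or a
#'   [contingency_table()].
#' @param tol relative tolerance used when comparing table probabilities.
#' @return An `exact_test` object with elements `p_value`,
#'   `n_tables_enumerated`, `observed_prob`.
#' @examples
#' fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, 2))$p_value  # 2/252
#' @export
fisher_exact_2x2 <- function(table, tol = 1e-9) {
  m <- as_count_matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2 x 2 table", call. = FALSE)
  if (sum(m) < 1) stop("grand total must be positive", call. = FALSE)
  freeman_halton_exact(m, tol = tol, method_label = "Fisher exact test (2 x 2)")
}

#' Freeman-Halton exact test for an r x c table
#'
#' Exact generalization of Fisher's 2 x 2 test: conditional on both margins,
#' the two-sided p-value is the total multivariate-hypergeometric probability
#' of all tables whose probability is at most the observed table's (relative
#' tolerance `tol`). Enumeration is exhaustive over the fixed-margin set; when
#' the number of tables exceeds `max_tables`, a Monte-Carlo estimate over
#' random fixed-margin tables (Patefield's algorithm via [stats::r2dtable()])
#' is used if `monte_carlo = TRUE`, otherwise a resource error is raised.
#'
#' Note that published cross-tabulations captioned "Fisher's exact test" do
#' not always carry this statistic: SPSS prints the exact test next to the
#' Pearson and likelihood-ratio chi-squares, and the rows are easily
#' transposed in reporting. [lr_chisq_test()] computes the likelihood-ratio
#' companion so both can be compared.
#'
#' @param table r x c matrix of non-negative integer counts (r, c >= 2) or a
#'   [contingency_table()].
#' @param tol relative tolerance for probability comparisons.
#' @param max_tables enumeration cap before the Monte-Carlo fallback.
#' @param monte_carlo logical; permit the Monte-Carlo fallback.
#' @param B number of Monte-Carlo tables when the fallback runs.
#' @param mc_seed optional integer seed for the fallback (recorded in the
#'   result); when `NULL` the current RNG stream is used.
#' @param method_label label carried into the printed result (internal use).
#' @return An `exact_test` object; under the fallback it carries a
#'   `monte_carlo` element with `B`, the standard error and the seed.
#' @examples
#' kin <- matrix(c(1, 1, 7, 1, 7, 14, 8, 10, 8), 3, 3, byrow = TRUE)
#' freeman_halton_exact(kin)$p_value
#' @export
freeman_halton_exact <- function(table, tol = 1e-9, max_tables = 5e7,
                                 monte_carlo = FALSE, B = 10000,
                                 mc_seed = NULL, method_label = NULL) {
  m <- as_count_matrix(table)
  rs <- unname(rowSums(m)); cs <- unname(colSums(m))
  if (any(rs == 0) || any(cs == 0))
    stop("every margin used by the exact test must be positive", call. = FALSE)
  lp_obs <- fm_log_const(rs, cs) - sum(lgamma(m + 1))
  p_obs <- exp(lp_obs)
  cut <- lp_obs + log1p(tol)
  p_sum <- 0; total <- 0; n_tab <- 0L
  res <- tryCatch({
    n_tab <- fm_enumerate(rs, cs, cap = max_tables, visit = function(lp) {
      pr <- exp(lp)
      total <<- total + pr
      if (lp <= cut) p_sum <<- p_sum + pr
    })
    exact_test_result(p_sum, n_tab, p_obs,
                      method = method_label %||% "Freeman-Halton exact test",
                      total_prob = total)
  }, crpflare_enumeration_cap = function(e) e)
  if (!inherits(res, "condition")) return(res)
  if (!monte_carlo) stop(conditionMessage(res), call. = FALSE)
  if (!is.null(mc_seed)) set.seed(mc_seed)
  draws <- stats::r2dtable(B, rs, cs)
  const <- fm_log_const(rs, cs)
  hits <- vapply(draws, function(t) (const - sum(lgamma(t + 1))) <= cut, logical(1))
  # observed table included in the reference set (add-one estimator)
  p_hat <- (1 + sum(hits)) / (B + 1)
  se <- sqrt(p_hat * (1 - p_hat) / (B + 1))
  exact_test_result(p_hat, B, p_obs,
                    method = "Freeman-Halton exact test (Monte Carlo)",
                    mc = list(B = as.integer(B), se = se,
                              seed = if (is.null(mc_seed)) NA_integer_ else mc_seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Likelihood-ratio chi-square test for an r x c table
#'
#' The G-squared statistic `2 * sum(O * log(O / E))` with
#' `(r - 1)(c - 1)` degrees of freedom and an asymptotic chi-square p-value
#' (zero cells contribute zero). This is the "Likelihood Ratio" row of the
#' SPSS crosstabs output and the asymptotic companion of the exact tests.
#'
#' @inheritParams freeman_halton_exact
#' @return A list of class `chisq_test` with `statistic`, `df`, `p_value`.
#' @export
lr_chisq_test <- function(table) {
  m <- as_count_matrix(table)
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (n < 1) stop("grand total must be positive", call. = FALSE)
  e <- outer(rs, cs) / n
  g2 <- 2 * sum(ifelse(m > 0, m * log(m / e), 0))
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  structure(list(statistic = g2, df = df,
                 p_value = stats::pchisq(g2, df, lower.tail = FALSE)),
            class = "chisq_test")
}

#' @export
print.chisq_test <- function(x, ...) {
  cat(sprintf("Likelihood-ratio chi-square: G2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Odds ratio of a 2 x 2 table with Woolf confidence interval
#'
#' Crude odds ratio `(a d) / (b c)` for a table `[[a, b], [c, d]]` with the
#' Woolf (log-scale Wald) 95% interval
#' `exp(log(OR) +- z * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell makes the
#' crude OR degenerate; with `correction = TRUE` the Haldane-Anscombe
#' continuity correction (0.5 added to every cell) is applied instead of
#' raising an error.
#'
#' @param table 2 x 2 counts.
#' @param correction apply the Haldane-Anscombe 0.5 correction.
#' @param conf_level confidence level for the Woolf interval.
#' @return List with `odds_ratio`, `ci_low`, `ci_high`, `log_or`, `se_log_or`.
#' @examples
#' odds_ratio_2x2(matrix(c(7, 2, 8, 18), 2, 2, byrow = TRUE))  # 7.875
#' @export
odds_ratio_2x2 <- function(table, correction = FALSE, conf_level = 0.95) {
  m <- as_count_matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2 x 2 table", call. = FALSE)
  m <- m + 0  # numeric
  if (any(m == 0)) {
    if (!correction)
      stop("zero cell makes the odds ratio degenerate; set correction = TRUE ",
           "for the Haldane-Anscombe correction", call. = FALSE)
    m <- m + 0.5
  } else if (correction) {
    m <- m + 0.5
  }
  log_or <- log(m[1, 1]) + log(m[2, 2]) - log(m[1, 2]) - log(m[2, 1])
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(odds_ratio = exp(log_or),
       ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se),
       log_or = log_or, se_log_or = se)
}
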