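test_that("KM with no censoring is the empirical survival function", {
  est <- km_estimate(data.frame(time_weeks = 1:5, event = TRUE))
  expect_equal(est$surv, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(est$median, 3)
  set.seed(9)
  tt <- rexp(50, 0.1)
  est <- km_estimate(data.frame(time_weeks = tt, event = TRUE))
  emp <- vapply(est$time, function(t0) mean(tt > t0), numeric(1))
  expect_equal(est$surv, emp, tolerance = 1e-12)
})

test_that("fully censored data leave the curve at 1 with undefined median", {
  est <- km_estimate(data.frame(time_weeks = c(3, 7, 11), event = FALSE))
  expect_true(all(est$surv == 1))
  expect_true(is.na(est$median))
  expect_true(all(is.na(est$median_ci)))
  expect_error(km_estimate(data.frame(time_weeks = numeric(0),
                                      event = logical(0))), "no survival")
  expect_error(km_estimate(data.frame(time_weeks = c(1, -2),
                                      event = c(TRUE, TRUE))), "positive")
})

test_that("KM median recovers an exponential median within 10% at n = 400", {
  set.seed(49)
  n <- 400
  true_median <- 49
  tt <- rexp(n, log(2) / true_median)
  cens <- rexp(n, log(2) / true_median / 4)    # ~20% censoring
  est <- km_estimate(data.frame(time_weeks = pmin(tt, cens),
                                event = tt <= cens))
  expect_lt(abs(est$median - true_median) / true_median, 0.10)
  expect_lt(est$median_ci[1], true_median)
  expect_gt(est$median_ci[2], true_median)
})

test_that("Gehan-Breslow statistic is zero for exchangeable groups and symmetric", {
  rec <- data.frame(time_weeks = c(2, 5, 7, 9, 12, 15),
                    event = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  both <- rbind(rec, rec)
  g <- rep(c("a", "b"), each = nrow(rec))
  res <- gehan_wilcoxon_test(both, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # label swap leaves the statistic unchanged
  set.seed(31)
  rec2 <- data.frame(time_weeks = rexp(30, 0.1) + 0.1,
                     event = runif(30) < 0.8)
  g2 <- sample(c("a", "b"), 30, TRUE)
  s1 <- gehan_wilcoxon_test(rec2, g2)$statistic
  s2 <- gehan_wilcoxon_test(rec2, ifelse(g2 == "a", "b", "a"))$statistic
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_error(gehan_wilcoxon_test(
    data.frame(time_weeks = c(1, 2), event = FALSE), c("a", "b")),
    "no events")
})

test_that("two-group statistic matches the naive implementation and its permutation p", {
  set.seed(77)
  n <- 40
  tt <- c(rexp(n / 2, 0.05), rexp(n / 2, 0.12)) + 0.01
  ev <- runif(n) < 0.85
  g <- rep(c("a", "b"), each = n / 2)
  rec <- data.frame(time_weeks = tt, event = ev)
  ours <- gehan_wilcoxon_test(rec, g)
  expect_equal(ours$statistic, naive_gehan_stat(tt, ev, g), tolerance = 1e-10)
  # permutation reference distribution for the chi-square approximation
  B <- 2000
  perm <- replicate(B, naive_gehan_stat(tt, ev, sample(g)))
  p_perm <- (1 + sum(perm >= ours$statistic - 1e-12)) / (B + 1)
  se <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(ours$p_value - p_perm), 0.05 + 3 * se)
})

test_that("three-group Gehan test has 2 degrees of freedom and detects separation of scales", {
  set.seed(78)
  rec <- data.frame(
    time_weeks = c(rexp(60, log(2) / 49), rexp(60, log(2) / 101),
                   rexp(60, log(2) / 21)) + 0.01,
    event = TRUE)
  g <- rep(c("low", "intermediate", "high"), each = 60)
  res <- gehan_wilcoxon_test(rec, g)
  expect_equal(res$df, 2L)
  expect_lt(res$p_value, 0.01)
})

test_that("Cox fit: label swap inverts the hazard ratio", {
  set.seed(90)
  rec <- data.frame(time_weeks = rexp(80, 0.05) + 0.01,
                    event = runif(80) < 0.8)
  x <- factor(sample(c("a", "b"), 80, TRUE))
  hr1 <- cox_univariable(rec, x)$hazard_ratios$hazard_ratio
  hr2 <- cox_univariable(rec, stats::relevel(x, "b"))$hazard_ratios$hazard_ratio
  expect_equal(hr1, 1 / hr2, tolerance = 1e-8)
})

test_that("Cox fit recovers a true hazard ratio of 2 within its Wald interval", {
  set.seed(1000)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.02 * 2^x)
  cens <- runif(n, 0, 100)
  rec <- data.frame(time_weeks = pmin(tt, cens) + 1e-9, event = tt <= cens)
  fit <- cox_univariable(rec, factor(x))
  expect_lt(fit$hazard_ratios$ci_low, 2)
  expect_gt(fit$hazard_ratios$ci_high, 2)
  expect_lt(abs(log(fit$hazard_ratios$hazard_ratio) - log(2)), 0.3)
})

test_that("Cox coefficient is invariant to covariate shift and equivariant to scale", {
  set.seed(91)
  rec <- data.frame(time_weeks = rexp(120, 0.05) + 0.01,
                    event = runif(120) < 0.8)
  x <- rnorm(120)
  b0 <- cox_univariable(rec, x)$coefficients[1, "coef"]
  expect_equal(cox_univariable(rec, x + 5)$coefficients[1, "coef"], b0,
               tolerance = 1e-6)
  expect_equal(cox_univariable(rec, 2 * x)$coefficients[1, "coef"], b0 / 2,
               tolerance = 1e-6)
})

test_that("degenerate covariates and monotone likelihood are reported", {
  rec <- data.frame(time_weeks = c(1, 2, 3, 4), event = TRUE)
  expect_error(cox_univariable(rec, rep(1, 4)), "degenerate")
  # all events in one group strictly precede the other: monotone likelihood
  rec2 <- data.frame(time_weeks = c(1, 2, 3, 10, 11, 12), event = TRUE)
  expect_warning(cox_univariable(rec2, factor(rep(c("a", "b"), each = 3))),
                 "separation|monotone")
})

test_that("null calibration: Wald p-values are approximately uniform", {
  set.seed(92)
  reps <- 500
  pv <- numeric(reps)
  for (i in seq_len(reps)) {
    rec <- data.frame(time_weeks = rexp(60, 0.05) + 0.01,
                      event = runif(60) < 0.85)
    pv[i] <- cox_univariable(rec,
                             factor(rep(c("a", "b"), 30)))$hazard_ratios$p_value
  }
  rej <- mean(pv < 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.001)
})
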