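archetype <- function(values, times = c(2, 6, 10), pre = -1, baseline = 50) {
  data.frame(time_weeks = c(pre, times),
             crp_mg_per_l = c(baseline, values))
}

test_that("baseline is the latest pre-treatment value, floor-clamped", {
  s <- data.frame(time_weeks = c(-3, -1), crp_mg_per_l = c(40, 50))
  expect_equal(compute_baseline(s), 50)
  expect_equal(compute_baseline(
    data.frame(time_weeks = -1, crp_mg_per_l = 0.2)), 1.0)
  expect_error(compute_baseline(
    data.frame(time_weeks = c(1, 2), crp_mg_per_l = c(5, 5))),
    "missing baseline")
  # outside the lookback window does not count
  expect_error(compute_baseline(
    data.frame(time_weeks = -6, crp_mg_per_l = 30)), "missing baseline")
})

test_that("the three archetype trajectories classify as defined", {
  fl <- classify_patient(archetype(c(110, 30, 25)), 50)
  expect_equal(fl$crp_class, "flare_response")
  expect_equal(fl$flare_time_weeks, 2)
  expect_equal(fl$response_time_weeks, 6)

  rs <- classify_patient(archetype(c(40, 34, 36)), 50)
  expect_equal(rs$crp_class, "response")
  expect_equal(rs$response_time_weeks, 6)   # 34 <= 0.7 * 50

  expect_equal(classify_patient(archetype(c(60, 55, 52)), 50)$crp_class,
               "non_response")
  # doubling without any later drop below baseline blocks both other classes
  expect_equal(classify_patient(archetype(c(110, 55, 52)), 50)$crp_class,
               "non_response")
})

test_that("threshold boundaries are weak on the named side", {
  # exactly doubled, later drop strictly below baseline
  expect_equal(classify_patient(archetype(c(100, 49, 60)), 50)$crp_class,
               "flare_response")
  # drop exactly at baseline is not a drop
  expect_equal(classify_patient(archetype(c(100, 50, 50)), 50)$crp_class,
               "non_response")
  # exactly 30% decrease counts as response
  expect_equal(classify_patient(archetype(c(40, 35, 36)), 50)$crp_class,
               "response")
  # doubling exactly at the flare-window edge still counts
  expect_equal(classify_patient(archetype(c(100, 30, 40), times = c(4, 6, 10)),
                                50)$crp_class, "flare_response")
})

test_that("insufficient availability raises located errors", {
  expect_error(classify_patient(
    data.frame(time_weeks = c(-1, 6, 8, 10),
               crp_mg_per_l = c(50, 40, 30, 20)), 50), "first 4 weeks")
  expect_error(classify_patient(
    data.frame(time_weeks = c(-1, 2), crp_mg_per_l = c(50, 40)), 50),
    "fewer than 3")
})

test_that("classifier matches the pairwise brute-force oracle and partitions", {
  set.seed(515)
  for (i in 1:1000) {
    s <- random_series()
    b <- compute_baseline(s)
    cl <- classify_patient(s, b)
    expect_true(cl$crp_class %in% c("flare_response", "response",
                                    "non_response"))
    expect_identical(cl$crp_class,
                     oracle_classify(s$time_weeks, s$crp_mg_per_l, b))
  }
})

test_that("classification is invariant to rescaling baseline and values together", {
  set.seed(616)
  for (i in 1:200) {
    s <- random_series()
    b <- compute_baseline(s)
    cl0 <- classify_patient(s, b)$crp_class
    for (k in c(0.25, 3.7)) {
      s2 <- s; s2$crp_mg_per_l <- s2$crp_mg_per_l * k
      expect_identical(classify_patient(s2, b * k)$crp_class, cl0)
    }
  }
})

test_that("scaling a non-response trajectory up never creates a response", {
  set.seed(717)
  n_checked <- 0
  while (n_checked < 200) {
    s <- random_series()
    b <- compute_baseline(s)
    if (classify_patient(s, b)$crp_class != "non_response") next
    n_checked <- n_checked + 1
    for (k in c(1, 1.3, 2.5)) {
      s2 <- s
      on <- s2$time_weeks > 0
      s2$crp_mg_per_l[on] <- s2$crp_mg_per_l[on] * k
      expect_true(classify_patient(s2, b)$crp_class != "response")
    }
  }
})

test_that("upscaling can convert non-response to flare only via a new doubling", {
  # near-doubling plus a sub-baseline value: scaling by 1.06 creates the
  # doubling while the later value stays below baseline
  s <- archetype(c(95, 35.5, 45))        # baseline 50: 1.9x, 0.71x, 0.9x
  expect_equal(classify_patient(s, 50)$crp_class, "non_response")
  s2 <- s; on <- s2$time_weeks > 0
  s2$crp_mg_per_l[on] <- s2$crp_mg_per_l[on] * 1.06
  expect_equal(classify_patient(s2, 50)$crp_class, "flare_response")
})

test_that("duplicate measurement times resolve to the maximum value", {
  s <- data.frame(time_weeks = c(-1, 2, 2, 6, 10),
                  crp_mg_per_l = c(50, 80, 110, 30, 40))
  expect_equal(classify_patient(s, 50)$crp_class, "flare_response")
})

test_that("cohort classification counts, proportions and error collection", {
  crp <- rbind(cbind(patient_id = "A", archetype(c(110, 30, 25))),
               cbind(patient_id = "B", archetype(c(40, 34, 36))),
               cbind(patient_id = "C", archetype(c(60, 55, 52))))
  res <- classify_cohort(list(crp = crp))
  expect_equal(unname(res$counts), c(1L, 1L, 1L))
  expect_equal(sum(res$counts), 3L)
  expect_equal(unname(res$proportions), rep(1 / 3, 3))

  empty <- classify_cohort(list(crp = crp[0, ]))
  expect_equal(unname(empty$counts), c(0L, 0L, 0L))

  bad <- rbind(crp, data.frame(patient_id = "D", time_weeks = 2,
                               crp_mg_per_l = 10))
  err <- tryCatch(classify_cohort(list(crp = bad)), error = conditionMessage)
  expect_match(err, "D:")
})
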