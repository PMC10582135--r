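test_that("configuration blocks are validated", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(joint_factor_probs = c(
    both = 0.5, crp_only = 0.3, trae_only = 0.3, neither = 0.1)), "sum to 1")
  expect_error(simulation_config(visit_weeks = c(-1, 2, 6)), "on-treatment")
  expect_error(simulation_config(n_patients = 0))
  # default joint factor probabilities imply the anchor margins
  p <- simulation_config()$joint_factor_probs
  expect_equal(unname(p[["both"]] + p[["crp_only"]]), 31 / 57)
  expect_equal(unname(p[["both"]] + p[["trae_only"]]), 31 / 57)
  expect_equal(unname(p[["both"]]), 15 / 57)
  expect_equal(unname(p[["neither"]]), 10 / 57)
})

test_that("default outcome strata reproduce all anchor cross-tab margins", {
  q <- default_response_probs()
  for (cl in names(q)) for (st in c("early", "late")) {
    expect_true(all(q[[cl]][[st]] >= -1e-12))
    expect_equal(sum(q[[cl]][[st]]), 1, tolerance = 1e-12)
  }
  p_early <- 15 / 31
  flare_row <- p_early * q$flare_response$early +
    (1 - p_early) * q$flare_response$late
  resp_row <- p_early * q$response$early + (1 - p_early) * q$response$late
  non_row <- (16 / 26) * q$non_response$early + (10 / 26) * q$non_response$late
  expect_equal(flare_row, c(1, 1, 7) / 9)
  expect_equal(resp_row, c(1, 7, 14) / 22)
  expect_equal(non_row, c(8, 10, 8) / 26)
  low_row <- (9 / 31) * q$flare_response$early + (22 / 31) * q$response$early
  expect_equal(low_row, c(0, 5, 10) / 15)
  expect_equal(q$non_response$late, c(6, 0, 4) / 10)
})

test_that("generation is deterministic given the seed", {
  a <- generate_cohort(simulation_config(n_patients = 30), seed = 123)
  b <- generate_cohort(simulation_config(n_patients = 30), seed = 123)
  c <- generate_cohort(simulation_config(n_patients = 30), seed = 124)
  expect_identical(a$crp, b$crp)
  expect_identical(a$trae, b$trae)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_false(identical(a$crp, c$crp))
})

test_that("noise-free archetypes classify as constructed, for every class", {
  cfg <- simulation_config(noise_sd = 0)
  for (cl in c("flare_response", "response", "non_response")) {
    for (b in c(2, 30, 300)) {
      tr <- generate_crp_trajectory(cl, b, cfg, noise_sd = 0)
      expect_identical(classify_patient(tr, compute_baseline(tr))$crp_class, cl)
    }
  }
})

test_that("a zero-noise cohort is recovered perfectly by the pipeline", {
  cfg <- simulation_config(n_patients = 57, noise_sd = 0)
  coh <- generate_cohort(cfg, seed = 7)
  kin <- classify_cohort(coh)
  expect_identical(kin$classifications$crp_class, coh$ground_truth$crp_class)
  fl <- flag_early_cohort(coh)
  expect_identical(fl$onsets$early_trae, coh$ground_truth$early_trae)
  asg <- risk_assignments(kin, fl)
  expect_identical(asg$risk_group, coh$ground_truth$risk_group)
})

test_that("large-cohort factor proportions match the configured joint law", {
  coh <- generate_cohort(simulation_config(n_patients = 5700), seed = 13)
  gt <- coh$ground_truth
  props <- c(mean(gt$risk_group == "low"),
             mean(gt$risk_group == "intermediate"),
             mean(gt$risk_group == "high"))
  expect_true(all(abs(props - c(15, 32, 10) / 57) < 0.02))
  expect_lt(abs(mean(gt$crp_class == "flare_response") - 9 / 57), 0.02)
  expect_lt(abs(mean(gt$crp_class == "response") - 22 / 57), 0.02)
})

test_that("trajectory misclassification is non-decreasing in noise", {
  cfg0 <- simulation_config()
  rate_at <- function(sd) {
    set.seed(400 + round(sd * 10))
    n_per <- 300
    wrong <- 0
    for (cl in c("flare_response", "response", "non_response")) {
      for (i in seq_len(n_per)) {
        b <- rlnorm(1, cfg0$baseline_meanlog, cfg0$baseline_sdlog)
        tr <- generate_crp_trajectory(cl, b, cfg0, noise_sd = sd)
        got <- classify_patient(tr, compute_baseline(tr))$crp_class
        if (got != cl) wrong <- wrong + 1
      }
    }
    wrong / (3 * n_per)
  }
  rates <- vapply(c(0, 0.1, 0.3, 0.5), rate_at, numeric(1))
  expect_equal(rates[1], 0)
  expect_true(all(diff(rates) >= -0.01))   # monotone up to MC error
  expect_gt(rates[4], rates[1])
})

test_that("PFS draws respect the configured group medians and censoring horizon", {
  coh <- generate_cohort(simulation_config(n_patients = 5700), seed = 17)
  gt <- coh$ground_truth
  out <- coh$outcomes
  expect_true(all(out$pfs_weeks <= 178))
  expect_true(all(out$pfs_weeks > 0))
  for (g in c("low", "intermediate", "high")) {
    med <- c(low = 49, intermediate = 101, high = 21)[[g]]
    est <- km_estimate(data.frame(
      time_weeks = out$pfs_weeks[gt$risk_group == g],
      event = out$pfs_event[gt$risk_group == g]))
    expect_lt(abs(est$median - med) / med, 0.15)
  }
})
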