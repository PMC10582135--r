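write_demo_cohort <- function(dir, mutate = identity) {
  crp <- data.frame(
    patient_id = rep(c("p1", "p2"), each = 4),
    time_weeks = rep(c(-1, 2, 6, 10), 2),
    crp_mg_per_l = c(50, 110, 30, 25, 20, 14, 12, 10))
  trae <- data.frame(patient_id = c("p1", "p2"),
                     onset_weeks = c(2, 6),
                     category = c("cutaneous", "endocrine"),
                     ctcae_grade = c(2L, 1L))
  out <- data.frame(patient_id = c("p1", "p2"), age_years = c(64L, 71L),
                    sex = c("male", "female"), ecog = c(0L, 1L),
                    imdc = c("favorable", "poor"),
                    histology = c("clear_cell", "non_clear_cell"),
                    regimen = c("IO_TKI", "IO_IO"),
                    response = c("PR", "SD"),
                    pfs_weeks = c(49.5, 21.25), pfs_event = c(TRUE, FALSE))
  tabs <- mutate(list(crp = crp, trae = trae, outcomes = out))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tabs$crp, file.path(dir, "crp.csv"), row.names = FALSE)
  write.csv(tabs$trae, file.path(dir, "trae.csv"), row.names = FALSE)
  write.csv(tabs$outcomes, file.path(dir, "outcomes.csv"), row.names = FALSE)
  file.path(dir, c("crp.csv", "trae.csv", "outcomes.csv"))
}

read_demo <- function(paths) read_cohort(paths[1], paths[2], paths[3])

test_that("well-formed files load, sorted by patient then time", {
  d <- withr::local_tempdir()
  coh <- read_demo(write_demo_cohort(d, function(tabs) {
    tabs$crp <- tabs$crp[sample(nrow(tabs$crp)), ]   # shuffle on disk
    tabs
  }))
  expect_equal(coh$n_patients, 2L)
  expect_equal(coh$n_records[["crp"]], 8L)
  by_patient <- split(coh$crp$time_weeks, coh$crp$patient_id)
  expect_true(all(vapply(by_patient, function(x) !is.unsorted(x), logical(1))))
})

test_that("schema, enum and referential errors are located", {
  d <- withr::local_tempdir()
  p <- write_demo_cohort(d, function(tabs) {
    tabs$outcomes$response <- NULL
    tabs
  })
  expect_error(read_demo(p), "missing column.*response")

  p <- write_demo_cohort(d, function(tabs) {
    tabs$outcomes$response[2] <- "XX"
    tabs
  })
  expect_error(read_demo(p), "row 2.*'XX'")

  p <- write_demo_cohort(d, function(tabs) {
    tabs$crp$patient_id[3] <- "ghost"
    tabs
  })
  expect_error(read_demo(p), "referential-integrity.*ghost")

  p <- write_demo_cohort(d, function(tabs) {
    tabs$trae$ctcae_grade[1] <- 7
    tabs
  })
  expect_error(read_demo(p), "ctcae_grade")

  p <- write_demo_cohort(d, function(tabs) {
    tabs$crp$crp_mg_per_l[1] <- -4
    tabs
  })
  expect_error(read_demo(p), "crp_mg_per_l")
})

test_that("day-based and mg/dL inputs are converted on read", {
  d <- withr::local_tempdir()
  p <- write_demo_cohort(d, function(tabs) {
    tabs$crp$time_weeks <- tabs$crp$time_weeks * 7
    tabs$trae$onset_weeks <- tabs$trae$onset_weeks * 7
    tabs$outcomes$pfs_weeks <- tabs$outcomes$pfs_weeks * 7
    tabs
  })
  coh <- read_cohort(p[1], p[2], p[3], time_unit = "days")
  expect_equal(coh$crp$time_weeks[1:4], c(-1, 2, 6, 10))
  expect_equal(coh$outcomes$pfs_weeks, c(49.5, 21.25))

  p <- write_demo_cohort(d, function(tabs) {
    tabs$crp$crp_mg_per_l <- tabs$crp$crp_mg_per_l / 10
    tabs
  })
  coh <- read_cohort(p[1], p[2], p[3], crp_unit = "mg_per_dl")
  expect_equal(coh$crp$crp_mg_per_l[1], 50)
})

test_that("cohort round-trips through write_cohort and read_cohort", {
  coh <- generate_cohort(simulation_config(n_patients = 12), seed = 5)
  d <- withr::local_tempdir()
  paths <- write_cohort(coh, d)
  back <- read_demo(paths)
  expect_equal(back$crp$crp_mg_per_l, coh$crp$crp_mg_per_l)
  expect_equal(back$crp$time_weeks, coh$crp$time_weeks)
  expect_equal(back$trae$onset_weeks, coh$trae$onset_weeks)
  expect_equal(back$outcomes, coh$outcomes)
})

test_that("reports round-trip through JSON with nulls for undefined medians", {
  res <- list(counts = list(flare_response = 9L, response = 22L),
              exact = list(p_value = 0.0295674),
              survival = list(median = NA_real_))
  d <- withr::local_tempdir()
  path <- write_report(res, file.path(d, "report.json"))
  back <- read_report(path)
  expect_equal(back$exact$p_value, res$exact$p_value)
  expect_equal(back$counts$response, 22)
  expect_null(back$survival$median)
  blocker <- file.path(d, "blocker")
  file.create(blocker)
  expect_error(suppressWarnings(
    write_report(res, file.path(blocker, "report.json"))))
})
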