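#' Default outcome distributions per (kinetics class x TRAE) stratum
#'
#' Conditional probabilities over (PD, SD, PR/CR) for each of the six
#' (kinetics class x early/late TRAE) strata, derived so that the generator
#' reproduces, in expectation, all three outcome cross-tabs of the anchor
#' cohort at once: kinetics rows (1,1,7)/9, (1,7,14)/22, (8,10,8)/26; TRAE
#' rows (2,15,14)/31, (8,3,15)/26; and risk-group rows (0,5,10)/15,
#' (4,13,15)/32, (6,0,4)/10. Assuming the TRAE factor is independent of the
#' kinetics class within the CRP-factor stratum (split 9/31 flare, 22/31
#' response; 15/31 early), the low-risk row's zero progression count forces
#' zero progression probability in both early CRP-factor strata, and the
#' remaining cells follow by solving the margin equations; the one free
#' parameter (how the low-risk stable-disease mass splits between early
#' flare and early response patients) is set to the boundary solution that
#' gives early flare patients a certain objective response. All six vectors
#' are non-negative and the system is exactly consistent.
#'
#' @return Nested list `[[class]][[c("early", "late")]]` of length-3
#'   probability vectors over (PD, SD, PR/CR).
#' @export
default_response_probs <- function() {
  q_flare_early <- c(0, 0, 1)
  q_resp_early <- (31 / 22) * (c(0, 5, 10) / 15 - (9 / 31) * q_flare_early)
  q_flare_late <- (31 / 16) * (c(1, 1, 7) / 9 - (15 / 31) * q_flare_early)
  q_resp_late <- (31 / 16) * (c(1, 7, 14) / 22 - (15 / 31) * q_resp_early)
  list(flare_response = list(early = q_flare_early, late = q_flare_late),
       response = list(early = q_resp_early, late = q_resp_late),
       non_response = list(early = c(2, 10, 4) / 16, late = c(6, 0, 4) / 10))
}

#' Configuration of the synthetic aRCC cohort generator
#'
#' The generator emulates the statistical structure of an on-treatment
#' biomarker study in advanced renal cell carcinoma: per-patient CRP
#' trajectories realizing a chosen kinetics class under multiplicative
#' lognormal measurement noise and a fixed visit schedule; adverse-event
#' onsets from a truncated lognormal centred so the cohort mean sits near
#' 4 weeks; RECIST outcome drawn conditionally on the kinetics class; and
#' exponential progression-free survival per risk group with administrative
#' censoring.
#'
#' The default joint distribution of the two risk factors is the unique one
#' consistent with the anchor cohort's margins (31/57 with the CRP factor,
#' 31/57 with early TRAE) and risk-group sizes 15/32/10: both = 15/57,
#' neither = 10/57, and the 32 single-factor patients split 16/16 — the
#' symmetric split, which the margins do not determine and which is
#' therefore configurable.
#'
#' The RECIST outcome is drawn conditionally on the joint (kinetics class x
#' early-TRAE) stratum. The default conditional distributions are derived in
#' [default_response_probs()]: they are the (essentially unique) set
#' simultaneously consistent with the anchor cohort's kinetics-by-outcome,
#' TRAE-by-outcome and risk-group-by-outcome cross-tabs, so all three
#' printed margins are reproduced in expectation — in particular a 60%
#' progression probability in the high-risk stratum and none in the
#' low-risk stratum.
#'
#' @param n_patients cohort size (default 57).
#' @param joint_factor_probs named probabilities `both`, `crp_only`,
#'   `trae_only`, `neither` over the (CRP factor x early-TRAE) cells.
#' @param kinetic_split named probabilities `flare`, `response`: the split of
#'   CRP-factor patients between flare-response and response (default
#'   9/31, 22/31).
#' @param response_probs nested list `response_probs[[class]][[stratum]]` of
#'   probability vectors over (PD, SD, PR/CR), with `class` one of the three
#'   kinetics classes and `stratum` `"early"`/`"late"` (the TRAE factor);
#'   default [default_response_probs()].
#' @param baseline_meanlog,baseline_sdlog lognormal baseline CRP (mg/L);
#'   defaults `log(30)`, `0.8`.
#' @param visit_weeks visit schedule in weeks relative to treatment start;
#'   must contain at least one pre-treatment and three on-treatment visits
#'   (default `c(-1, 2, 6, 10)`).
#' @param flare_peak_fold noise-free flare peak as a multiple of baseline
#'   (default 3).
#' @param post_drop_fraction noise-free post-flare level as a fraction of
#'   baseline (default 0.5).
#' @param response_start_fraction,response_nadir_fraction noise-free start
#'   and nadir of the response archetype (defaults 0.85 and 0.5).
#' @param nonresponse_range noise-free band of the non-response archetype as
#'   fractions of baseline (default `c(1.0, 1.3)`, inside the rule margins).
#' @param noise_sd standard deviation of the multiplicative lognormal
#'   measurement noise on every CRP draw (default 0.1).
#' @param trae_meanlog,trae_sdlog lognormal first-onset distribution in
#'   weeks, truncated to `(0, trae_max_weeks]`; defaults give an
#'   untruncated mean of 4 weeks.
#' @param trae_max_weeks onset truncation (default 28).
#' @param early_threshold_weeks early-onset cutoff used to condition onsets
#'   on the TRAE factor (default 4).
#' @param mean_extra_events Poisson mean of additional (later) adverse
#'   events per patient (default 1).
#' @param pfs_median_weeks named exponential PFS medians per risk group
#'   (defaults low 49, intermediate 101, high 21 weeks).
#' @param censor_horizon_weeks administrative censoring horizon (default
#'   178 weeks, about 41 months of follow-up).
#' @param pr_fraction_within_orr probability that a pooled PR/CR outcome is
#'   a PR rather than a CR (default 28/29).
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 57,
    joint_factor_probs = c(both = 15, crp_only = 16, trae_only = 16,
                           neither = 10) / 57,
    kinetic_split = c(flare = 9, response = 22) / 31,
    response_probs = default_response_probs(),
    baseline_meanlog = log(30), baseline_sdlog = 0.8,
    visit_weeks = c(-1, 2, 6, 10),
    flare_peak_fold = 3.0, post_drop_fraction = 0.5,
    response_start_fraction = 0.85, response_nadir_fraction = 0.5,
    nonresponse_range = c(1.0, 1.3),
    noise_sd = 0.1,
    trae_meanlog = log(4) - 0.9^2 / 2, trae_sdlog = 0.9,
    trae_max_weeks = 28, early_threshold_weeks = 4,
    mean_extra_events = 1,
    pfs_median_weeks = c(low = 49, intermediate = 101, high = 21),
    censor_horizon_weeks = 178,
    pr_fraction_within_orr = 28 / 29) {
  stopifnot(n_patients >= 1, n_patients == round(n_patients))
  check_probs <- function(p, what, nms = NULL) {
    if (!is.null(nms) && !setequal(names(p), nms))
      stop("config error: ", what, " must have names ",
           paste(nms, collapse = ", "), call. = FALSE)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12)
      stop("config error: ", what, " must be non-negative and sum to 1",
           call. = FALSE)
  }
  check_probs(joint_factor_probs, "joint_factor_probs",
              c("both", "crp_only", "trae_only", "neither"))
  check_probs(kinetic_split, "kinetic_split", c("flare", "response"))
  stopifnot(setequal(names(response_probs), crp_classes))
  for (nm in names(response_probs)) {
    stopifnot(setequal(names(response_probs[[nm]]), c("early", "late")))
    for (st in c("early", "late"))
      check_probs(response_probs[[nm]][[st]],
                  paste0("response_probs$", nm, "$", st))
  }
  if (sum(visit_weeks <= 0) < 1 || sum(visit_weeks > 0) < 3)
    stop("config error: visit_weeks needs >= 1 pre-treatment and >= 3 ",
         "on-treatment visits", call. = FALSE)
  stopifnot(flare_peak_fold >= 2, post_drop_fraction < 1,
            response_nadir_fraction <= 0.7,
            nonresponse_range[1] > 0.7, nonresponse_range[2] < 2,
            noise_sd >= 0, trae_max_weeks > early_threshold_weeks,
            all(pfs_median_weeks > 0),
            setequal(names(pfs_median_weeks), risk_groups),
            censor_horizon_weeks > 0,
            pr_fraction_within_orr >= 0, pr_fraction_within_orr <= 1)
  structure(as.list(environment())[setdiff(names(formals(simulation_config)),
                                           "")],
            class = "simulation_config")
}

#' Noise-free (or noisy) CRP trajectory realizing a kinetics class
#'
#' Builds a trajectory over the visit schedule whose noise-free version is
#' classified as `class` by [classify_patient()] by construction: the flare
#' archetype peaks at `flare_peak_fold` x baseline at the first on-treatment
#' visit inside the flare window and then settles below baseline; the
#' response archetype declines from `response_start_fraction` to
#' `response_nadir_fraction` of baseline; the non-response archetype stays
#' inside `nonresponse_range`. Multiplicative lognormal noise is applied
#' afterwards to every value, including the pre-treatment one.
#'
#' @param class kinetics class to realize.
#' @param baseline true baseline CRP in mg/L.
#' @param config a [simulation_config()] (schedule, archetype shape, noise).
#' @param noise_sd noise level; defaults to the config value.
#' @return Data frame `time_weeks`, `crp_mg_per_l`.
#' @export
generate_crp_trajectory <- function(class, baseline,
                                    config = simulation_config(),
                                    noise_sd = config$noise_sd) {
  stopifnot(class %in% crp_classes, baseline > 0)
  t <- sort(config$visit_weeks)
  pre <- t <= 0
  on <- !pre
  k <- sum(on)
  mult <- numeric(length(t))
  mult[pre] <- 1
  if (class == "flare_response") {
    on_t <- t[on]
    peak_at <- which.min(on_t)  # earliest on-treatment visit
    if (on_t[peak_at] > 4)
      stop("config error: no on-treatment visit inside the flare window",
           call. = FALSE)
    m <- seq(config$post_drop_fraction, min(0.9, config$post_drop_fraction + 0.2),
             length.out = k - 1)
    mult[on] <- append(m, config$flare_peak_fold, after = peak_at - 1)
  } else if (class == "response") {
    mult[on] <- seq(config$response_start_fraction,
                    config$response_nadir_fraction, length.out = k)
  } else {
    mult[on] <- seq(config$nonresponse_range[2], config$nonresponse_range[1],
                    length.out = k)
  }
  v <- baseline * mult
  if (noise_sd > 0)
    v <- v * exp(stats::rnorm(length(v), 0, noise_sd))
  data.frame(time_weeks = t, crp_mg_per_l = v)
}

r_trunc_lnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, plo, phi), meanlog, sdlog)
}

#' Generate a complete synthetic cohort
#'
#' Draws the two risk factors from their joint distribution, the kinetics
#' class within the CRP factor, the CRP trajectory realizing that class, the
#' adverse-event records conditioned on the early-TRAE factor, the RECIST
#' outcome conditionally on the kinetics class, and exponential PFS per
#' (ground-truth) risk group with administrative censoring. The returned
#' object is a valid cohort for the full pipeline plus a ground-truth table.
#' Output is deterministic given `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return Object of class `rcc_cohort` with an extra `ground_truth` data
#'   frame (`patient_id`, `crp_class`, `early_trae`, `risk_group`,
#'   `response`) and the `config`/`seed` attached.
#' @examples
#' coh <- generate_cohort(simulation_config(n_patients = 20), seed = 7)
#' table(coh$ground_truth$risk_group)
#' @export
generate_cohort <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  n <- config$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  cell <- sample(names(config$joint_factor_probs), n, replace = TRUE,
                 prob = config$joint_factor_probs)
  crp_factor <- cell %in% c("both", "crp_only")
  trae_factor <- cell %in% c("both", "trae_only")
  crp_class <- ifelse(!crp_factor, "non_response",
                      ifelse(stats::runif(n) < config$kinetic_split[["flare"]],
                             "flare_response", "response"))
  risk_group <- ifelse(crp_factor & trae_factor, "low",
                       ifelse(crp_factor | trae_factor, "intermediate", "high"))

  # longitudinal CRP
  baseline <- stats::rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  crp <- do.call(rbind, lapply(seq_len(n), function(i) {
    tr <- generate_crp_trajectory(crp_class[i], baseline[i], config)
    cbind(patient_id = ids[i], tr)
  }))

  # adverse events: first onset conditioned on the early flag, later extras
  thr <- config$early_threshold_weeks
  onset <- numeric(n)
  onset[trae_factor] <- r_trunc_lnorm(sum(trae_factor), config$trae_meanlog,
                                      config$trae_sdlog, 0, thr)
  onset[!trae_factor] <- r_trunc_lnorm(sum(!trae_factor), config$trae_meanlog,
                                       config$trae_sdlog, thr,
                                       config$trae_max_weeks)
  grade_w <- c(21, 30, 11)
  trae <- do.call(rbind, lapply(seq_len(n), function(i) {
    n_extra <- stats::rpois(1, config$mean_extra_events)
    t_ev <- c(onset[i],
              stats::runif(n_extra, onset[i], config$trae_max_weeks))
    data.frame(patient_id = ids[i], onset_weeks = t_ev,
               category = sample(trae_categories, n_extra + 1, replace = TRUE,
                                 prob = c(8, 8, 5, 4, 1, 1, 1, 1)),
               ctcae_grade = sample(1:3, n_extra + 1, replace = TRUE,
                                    prob = grade_w))
  }))
  trae <- trae[order(match(trae$patient_id, ids), trae$onset_weeks), ,
               drop = FALSE]
  rownames(trae) <- NULL

  # RECIST outcome conditional on the (kinetics class x TRAE) stratum;
  # PR/CR split within the pooled objective-response column
  stratum <- ifelse(trae_factor, "early", "late")
  pooled <- vapply(seq_len(n), function(i)
    sample(c("PD", "SD", "PR/CR"), 1,
           prob = config$response_probs[[crp_class[i]]][[stratum[i]]]),
    character(1), USE.NAMES = FALSE)
  response <- ifelse(pooled != "PR/CR", pooled,
                     ifelse(stats::runif(n) < config$pr_fraction_within_orr,
                            "PR", "CR"))

  # PFS: exponential per risk group, administrative censoring
  rate <- log(2) / config$pfs_median_weeks[risk_group]
  t_raw <- stats::rexp(n, rate)
  pfs_weeks <- pmin(t_raw, config$censor_horizon_weeks)
  pfs_event <- t_raw <= config$censor_horizon_weeks

  outcomes <- data.frame(
    patient_id = ids,
    age_years = as.integer(pmin(90, pmax(40, round(stats::rnorm(n, 67, 9))))),
    sex = sample(sex_levels, n, replace = TRUE, prob = c(39, 18)),
    ecog = sample(0:1, n, replace = TRUE, prob = c(32, 25)),
    imdc = sample(imdc_levels, n, replace = TRUE, prob = c(13, 28, 16)),
    histology = sample(histology_levels, n, replace = TRUE, prob = c(48, 9)),
    regimen = sample(regimen_levels, n, replace = TRUE, prob = c(9, 48)),
    response = response,
    pfs_weeks = pfs_weeks,
    pfs_event = pfs_event,
    stringsAsFactors = FALSE)

  cohort <- new_cohort(crp, trae, outcomes)
  cohort$ground_truth <- data.frame(
    patient_id = ids, crp_class = crp_class, early_trae = trae_factor,
    risk_group = risk_group, response = response, baseline_crp = baseline,
    first_onset_weeks = onset, stringsAsFactors = FALSE)
  cohort$config <- config
  cohort$seed <- seed
  class(cohort) <- c("synthetic_cohort", class(cohort))
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic aRCC cohort (seed %s): %d patients, %d CRP rows, %d TRAE rows\n",
    format(x$seed), x$n_patients, nrow(x$crp), nrow(x$trae)))
  print(table(x$ground_truth$risk_group))
  invisible(x)
}
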