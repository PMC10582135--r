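# Independent oracles used by the test suite. These deliberately share no
# code with the package: probabilities come from direct factorial products
# over expand.grid enumerations, and the trajectory oracle tests all
# measurement pairs explicitly.

# Brute-force two-sided exact p for an r x c table: enumerate the free
# (r-1) x (c-1) block over a full grid, reconstruct the forced cells, and
# sum probabilities <= the observed table's.
oracle_exact_p <- function(tab, tol = 1e-9) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  r <- nrow(tab); cc <- ncol(tab)
  prob_of <- function(m) {
    exp(sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
          sum(lfactorial(m)))
  }
  free <- expand.grid(rep(list(0:max(rs)), (r - 1) * (cc - 1)))
  probs <- apply(free, 1, function(v) {
    m <- matrix(0, r, cc)
    m[seq_len(r - 1), seq_len(cc - 1)] <- matrix(v, r - 1, cc - 1)
    m[seq_len(r - 1), cc] <- rs[seq_len(r - 1)] - rowSums(m[, seq_len(cc - 1),
                                                            drop = FALSE])[seq_len(r - 1)]
    m[r, ] <- cs - colSums(m[seq_len(r - 1), , drop = FALSE])
    if (any(m < 0)) return(NA_real_)
    prob_of(m)
  })
  probs <- probs[!is.na(probs)]
  p_obs <- prob_of(tab)
  list(p = sum(probs[probs <= p_obs * (1 + tol)]), total = sum(probs),
       n_tables = length(probs))
}

# random small table with margins <= max_margin and no zero margin
random_small_table <- function(r, cc, max_margin = 12) {
  repeat {
    m <- matrix(rpois(r * cc, 1.5), r, cc)
    if (all(rowSums(m) >= 1) && all(colSums(m) >= 1) &&
        all(rowSums(m) <= max_margin) && all(colSums(m) <= max_margin))
      return(m)
  }
}

# Pairwise brute-force CRP kinetics oracle (distinct measurement times).
oracle_classify <- function(time, value, baseline, doubling = 2,
                            resp_frac = 0.7, flare_win = 4, assess_win = 12) {
  on <- time > 0 & time <= assess_win
  t <- time[on]; v <- value[on]
  flare <- FALSE
  for (i in seq_along(t)) for (j in seq_along(t)) {
    if (t[i] <= flare_win && v[i] >= doubling * baseline &&
        t[j] > t[i] && v[j] < baseline) flare <- TRUE
  }
  if (flare) return("flare_response")
  any_doubling <- any(t <= flare_win & v >= doubling * baseline)
  if (!any_doubling && any(v <= resp_frac * baseline)) return("response")
  "non_response"
}

# random CRP series meeting the availability preconditions, distinct times
random_series <- function() {
  n_pre <- sample(1:2, 1)
  n_on <- sample(3:6, 1)
  repeat {
    t_pre <- round(runif(n_pre, -4, 0), 3)
    t_on <- round(c(runif(1, 0.1, 4), runif(n_on - 1, 0.1, 12)), 3)
    tt <- c(t_pre, t_on)
    if (!anyDuplicated(tt)) break
  }
  baseline_true <- rlnorm(1, log(30), 0.8)
  v <- baseline_true * exp(rnorm(n_pre + n_on, 0, 0.7))
  data.frame(time_weeks = tt, crp_mg_per_l = v)
}

# Gehan-Breslow statistic recomputed naively for the permutation oracle
naive_gehan_stat <- function(time, event, group) {
  g <- as.integer(factor(group))
  ut <- sort(unique(time[event]))
  U <- 0; V <- 0
  for (t0 in ut) {
    at <- time >= t0
    nj <- sum(at); dj <- sum(event & time == t0)
    n1 <- sum(at & g == 1); d1 <- sum(event & time == t0 & g == 1)
    U <- U + nj * (d1 - n1 * dj / nj)
    if (nj > 1)
      V <- V + nj^2 * dj * (nj - dj) / (nj - 1) * (n1 / nj) * (1 - n1 / nj)
  }
  if (V <= 0) 0 else U^2 / V
}

table1_tables <- function() {
  list(
    crp_kinetics = matrix(c(1, 1, 7, 1, 7, 14, 8, 10, 8), 3, 3, byrow = TRUE,
                          dimnames = list(c("flare_response", "response",
                                            "non_response"),
                                          c("PD", "SD", "PR/CR"))),
    trae_timing = matrix(c(2, 15, 14, 8, 3, 15), 2, 3, byrow = TRUE,
                         dimnames = list(c("early", "late"),
                                         c("PD", "SD", "PR/CR"))),
    risk_model = matrix(c(0, 5, 10, 4, 13, 15, 6, 0, 4), 3, 3, byrow = TRUE,
                        dimnames = list(c("low", "intermediate", "high"),
                                        c("PD", "SD", "PR/CR"))),
    sex = matrix(c(5, 17, 17, 5, 1, 12), 2, 3, byrow = TRUE,
                 dimnames = list(c("male", "female"), c("PD", "SD", "PR/CR"))),
    regimen = matrix(c(5, 3, 1, 5, 15, 28), 2, 3, byrow = TRUE,
                     dimnames = list(c("IO_IO", "IO_TKI"),
                                     c("PD", "SD", "PR/CR"))),
    ecog = matrix(c(5, 8, 19, 5, 10, 10), 2, 3, byrow = TRUE,
                  dimnames = list(c("ecog0", "ecog1plus"),
                                  c("PD", "SD", "PR/CR"))),
    imdc = matrix(c(1, 2, 10, 6, 10, 12, 3, 6, 7), 3, 3, byrow = TRUE,
                  dimnames = list(c("favorable", "intermediate", "poor"),
                                  c("PD", "SD", "PR/CR"))),
    histology = matrix(c(8, 15, 25, 2, 3, 4), 2, 3, byrow = TRUE,
                       dimnames = list(c("clear_cell", "non_clear_cell"),
                                       c("PD", "SD", "PR/CR"))))
}

table1_printed_p <- c(crp_kinetics = 0.022, trae_timing = 0.002,
                      risk_model = 0.001,  # printed as "< 0.001"
                      sex = 0.006, regimen = 0.004, ecog = 0.333,
                      imdc = 0.305, histology = 0.893)
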