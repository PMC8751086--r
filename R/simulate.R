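# Synthetic cohort generator. Emulates the two-table schema of the nutrition
# survey database (admission table + patient-day intake table) under a known
# ground-truth hazard structure, so that every downstream stage (intake
# classification, PED split, window construction, penalized fitting, diet
# contrasts) can be validated against configured truth.

#' Simulation configuration
#'
#' Defines the data-generating process for [simulate_cohort()]: a first-order
#' Markov chain over intake levels I/II/III (initialized at its stationary
#' distribution), uniform g/kg draws inside each level's range, per-cause
#' piece-wise constant baseline hazards on daily intervals from day 4 to
#' day 60, phase-specific per-day cumulative log-hazard effects for level II
#' and III days (relative to level I), Gaussian ICU random intercepts, an
#' independent daily Bernoulli process for live ICU discharge before day 11
#' (which triggers the imputation path downstream), and 60-day censoring.
#'
#' @param n_patients Number of patients.
#' @param n_icus Number of ICUs; each patient is assigned uniformly and ICU
#'   random intercepts are shared by all patients of an ICU.
#' @param seed Integer seed; fully determines the cohort.
#' @param transition 3x3 row-stochastic transition matrix of the intake-level
#'   Markov chain (rows/cols ordered I, II, III). The default is persistent
#'   day-to-day with stationary distribution (44.5, 31.7, 23.8)%, matching
#'   the observed day-level mix of intake categories.
#' @param level_ranges 3x2 matrix of uniform sampling ranges (g/kg) per
#'   level; defaults have medians 0.49, 0.99, 1.41 g/kg inside the category
#'   bounds.
#' @param base_log_hazard List with elements `death` and `discharge`, each a
#'   vector of length 56 (intervals (4,5], ..., (59,60]) of baseline
#'   log-hazards per day, or a single value recycled. Defaults give roughly
#'   25% in-hospital death, 69% live discharge and 6% censoring by day 60.
#' @param effects Per-day cumulative log-hazard increments: a list with
#'   elements `death` and `discharge`, each a 2x2 matrix with rows `II`,
#'   `III` and columns `early` (days on diet #1--#4) and `late` (#5--#11).
#'   A day on diet at level II/III inside a follow-up interval's lag-lead
#'   window adds the corresponding increment to that interval's log-hazard.
#' @param icu_sd Standard deviation of the per-cause ICU random intercepts.
#' @param icu_discharge_prob Daily probability of live ICU discharge on days
#'   5--10 (discharge before day 11 triggers intake imputation downstream).
#' @param oral_prob Probability that a day on diet is exclusively oral
#'   (no EN/PN, hence level I and no medical nutrition therapy).
#' @param en_only_prob Probability that a fed day is exclusively enteral;
#'   otherwise the day's protein is split between EN and PN.
#' @param window_mode Window geometry generating the true cumulative
#'   effects: `"dynamic"` (lead = twice cumulative MNT days) or `"static"`
#'   (lead 60 days).
#' @param scenario `"default"` (confounders independent of intake and
#'   hazard) or `"indication_bias"` (a latent severity lowers intake level
#'   and raises the death hazard, the confounding structure the 4-day lag
#'   is meant to mitigate).
#' @param severity_coef Log-hazard coefficient of latent severity in the
#'   `indication_bias` scenario (death: `+severity_coef`, discharge:
#'   `-severity_coef`).
#' @param censor_day Administrative censoring day (60).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       n_icus = 20,
                       seed = 1L,
                       transition = matrix(c(0.74, 0.19, 0.07,
                                             0.29, 0.53, 0.18,
                                             0.10, 0.27, 0.63),
                                           3, 3, byrow = TRUE),
                       level_ranges = matrix(c(0.18, 0.80,
                                               0.80, 1.18,
                                               1.21, 1.61),
                                             3, 2, byrow = TRUE),
                       base_log_hazard = list(
                         death = log(0.013),
                         discharge = log(c(rep(0.02, 4), rep(0.055, 13),
                                           rep(0.04, 20), rep(0.025, 19)))
                       ),
                       effects = list(
                         death = matrix(c(0, log(0.75) / 7,
                                          0, log(0.75) / 7),
                                        2, 2, byrow = TRUE,
                                        dimnames = list(c("II", "III"),
                                                        c("early", "late"))),
                         discharge = matrix(c(0, log(1.5) / 7,
                                              log(0.8) / 4, 0),
                                            2, 2, byrow = TRUE,
                                            dimnames = list(c("II", "III"),
                                                            c("early", "late")))
                       ),
                       icu_sd = 0.25,
                       icu_discharge_prob = 0.08,
                       oral_prob = 0.03,
                       en_only_prob = 0.85,
                       window_mode = c("dynamic", "static"),
                       scenario = c("default", "indication_bias"),
                       severity_coef = 0.3,
                       censor_day = 60) {
  window_mode <- match.arg(window_mode)
  scenario <- match.arg(scenario)
  stopifnot(n_patients >= 0, n_icus >= 1, censor_day == 60)
  if (!is.matrix(transition) || !all(dim(transition) == c(3, 3)) ||
      any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("`transition` must be a 3x3 row-stochastic matrix", call. = FALSE)
  }
  n_int <- censor_day - 4L
  blh <- lapply(base_log_hazard, function(x) {
    x <- rep_len(x, n_int)
    if (any(!is.finite(exp(x))) || any(exp(x) < 0)) {
      stop("baseline hazards must be non-negative and finite", call. = FALSE)
    }
    x
  })
  for (k in c("death", "discharge")) {
    ef <- effects[[k]]
    stopifnot(is.matrix(ef), all(dim(ef) == c(2, 2)))
    dimnames(effects[[k]]) <- list(c("II", "III"), c("early", "late"))
  }
  structure(list(
    n_patients = as.integer(n_patients), n_icus = as.integer(n_icus),
    seed = as.integer(seed), transition = transition,
    level_ranges = level_ranges, base_log_hazard = blh, effects = effects,
    icu_sd = icu_sd, icu_discharge_prob = icu_discharge_prob,
    oral_prob = oral_prob, en_only_prob = en_only_prob,
    window_mode = window_mode, scenario = scenario,
    severity_coef = severity_coef, censor_day = censor_day
  ), class = "sim_config")
}

# Stationary distribution of a row-stochastic matrix.
stationary_dist <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Sample one competing-risks event time from daily piece-wise hazards
#'
#' Draws an event (cause and continuous time) from the discrete-hazard
#' scheme implied by the piece-wise exponential model: within the daily
#' interval (a, a+1], the probability of any event is
#' `1 - exp(-(h_death + h_discharge))`; given an event, the cause is chosen
#' with probability proportional to its hazard, and the time inside the
#' interval by inverting the truncated exponential CDF. Consumes the current
#' RNG stream.
#'
#' @param haz_death,haz_discharge Non-negative per-interval hazards (per
#'   day), one value per daily interval starting at `t_start`.
#' @param t_start Left endpoint of the first interval (days).
#' @return List with `cause` (`"hospital_death"`, `"live_discharge"` or
#'   `"censored"`) and `time` (days; end of follow-up when censored).
#' @export
daily_event_sampler <- function(haz_death, haz_discharge, t_start = 4) {
  if (length(haz_death) != length(haz_discharge)) {
    stop("hazard vectors must have equal length", call. = FALSE)
  }
  if (any(haz_death < 0) || any(haz_discharge < 0)) {
    stop("hazards must be non-negative", call. = FALSE)
  }
  n <- length(haz_death)
  lam <- haz_death + haz_discharge
  p_event <- 1 - exp(-lam)
  u <- stats::runif(n)
  j <- which(u < p_event)
  if (!length(j)) {
    return(list(cause = "censored", time = t_start + n))
  }
  j <- j[1L]
  cause <- if (stats::runif(1) < haz_death[j] / lam[j]) "hospital_death" else "live_discharge"
  w <- stats::runif(1)
  dt <- -log(1 - w * (1 - exp(-lam[j]))) / lam[j]
  list(cause = cause, time = t_start + (j - 1) + dt)
}

#' Simulate a synthetic ICU nutrition cohort
#'
#' Generates `cfg$n_patients` patient records under the configured
#' ground-truth hazard structure. Intake levels follow the Markov chain; the
#' hazard of each daily interval is the configured baseline plus the ICU
#' random intercept plus the cumulative contribution of all days on diet
#' whose lag-lead window covers the interval (using the hospital-mode
#' trajectory: recorded intake up to ICU discharge, standard-intake
#' imputation afterwards, so the hospital-outcome model is correctly
#' specified). Event times are continuous within days.
#'
#' @param cfg A [sim_config()].
#' @return Object of class `protein_cohort`: a list with `patients` (one
#'   admission-level row per patient) and `diet_days` (one row per recorded
#'   patient-day), plus the config and, as attribute `truth`, the latent
#'   quantities (ICU intercepts, effective 11-day level matrix) used by
#'   validation tests.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_patients
  grid <- interval_grid(4:cfg$censor_day)
  n_int <- grid$n
  levels3 <- c("I", "II", "III")
  pi0 <- stationary_dist(cfg$transition)
  years <- c(2007L, 2008L, 2009L, 2011L, 2013L, 2014L)

  b_death <- stats::rnorm(cfg$n_icus, 0, cfg$icu_sd)
  b_disch <- stats::rnorm(cfg$n_icus, 0, cfg$icu_sd)

  patients <- vector("list", n)
  diet_rows <- vector("list", n)
  truth_levels <- matrix(NA_character_, n, 11)

  for (i in seq_len(n)) {
    icu <- sample.int(cfg$n_icus, 1)
    severity <- stats::rnorm(1)
    age <- round(pmin(pmax(stats::rnorm(1, 62, 16), 18), 95), 1)
    bmi <- round(pmax(stats::rlnorm(1, log(27), 0.2), 14), 1)
    apache2 <- as.integer(pmin(pmax(round(stats::rnorm(1, 17, 6)), 0), 50))
    sex <- sample(c("female", "male"), 1, prob = c(0.4, 0.6))
    adm <- sample(c("medical", "elective_surgery", "emergency_surgery"), 1,
                  prob = c(0.6, 0.2, 0.2))
    dx <- sample(paste0("dx", 1:9), 1)
    year <- sample(years, 1)
    days_mv <- sample(1:3, 1)
    days_propofol <- sample(0:3, 1)

    # Intake level chain (the underlying feeding regime).
    p_init <- pi0
    if (cfg$scenario == "indication_bias") {
      # sicker patients start (and tend to stay) lower
      shift <- stats::plogis(severity)
      p_init <- pi0 * c(0.5 + shift, 1, 1.5 - shift)
      p_init <- p_init / sum(p_init)
    }
    state <- integer(11)
    state[1] <- sample.int(3, 1, prob = p_init)
    for (d in 2:11) state[d] <- sample.int(3, 1, prob = cfg$transition[state[d - 1], ])

    oral <- stats::runif(11) < cfg$oral_prob
    gkg <- stats::runif(11, cfg$level_ranges[state, 1], cfg$level_ranges[state, 2])
    gkg[oral] <- 0
    en <- numeric(11); pn <- numeric(11)
    fed <- !oral
    en_only <- stats::runif(11) < cfg$en_only_prob
    frac <- stats::runif(11)
    en[fed] <- ifelse(en_only[fed], gkg[fed], frac[fed] * gkg[fed])
    pn[fed] <- ifelse(en_only[fed], 0, (1 - frac[fed]) * gkg[fed] / PN_TO_PROTEIN)

    obs_level <- ifelse(oral, "I", levels3[state])

    # Live ICU discharge process on days 5..10 (before day 11).
    dd <- stats::runif(6) < cfg$icu_discharge_prob
    icu_dis <- if (any(dd)) 4L + which(dd)[1L] else NA_integer_

    # Effective (hospital-mode) trajectory driving the true hazard:
    # recorded levels up to ICU discharge, level II (MNT) afterwards.
    eff_level <- obs_level
    eff_mnt <- !oral
    if (!is.na(icu_dis)) {
      after <- seq_len(11) > icu_dis
      eff_level[after] <- "II"
      eff_mnt[after] <- TRUE
    }
    truth_levels[i, ] <- eff_level

    W <- lag_lead_window(eff_mnt, grid, mode = cfg$window_mode)$W
    phase <- ifelse(seq_len(11) <= 4, "early", "late")
    loghaz <- matrix(0, 2, n_int)
    for (k in 1:2) {
      cause <- c("death", "discharge")[k]
      lh <- cfg$base_log_hazard[[cause]] +
        (if (cause == "death") b_death[icu] else b_disch[icu])
      if (cfg$scenario == "indication_bias") {
        lh <- lh + (if (cause == "death") 1 else -1) * cfg$severity_coef * severity
      }
      ef <- cfg$effects[[cause]]
      inc <- numeric(11)
      hi <- eff_level != "I"
      inc[hi] <- ef[cbind(eff_level[hi], phase[hi])]
      lh <- lh + as.numeric(crossprod(W, inc))
      loghaz[k, ] <- lh
    }
    ev <- daily_event_sampler(exp(loghaz[1, ]), exp(loghaz[2, ]), t_start = 4)
    outcome <- ev$cause
    outcome_time <- ev$time
    if (!is.na(icu_dis) && outcome_time <= icu_dis) icu_dis <- NA_integer_

    reg_end <- min(11, floor(outcome_time))
    if (!is.na(icu_dis)) reg_end <- min(reg_end, icu_dis)
    rec <- seq_len(reg_end)

    # calorie intake fraction of target, correlated with early intake level
    lev_score <- mean(match(obs_level[1:3], levels3)) / 3
    calorie_fraction <- round(pmax(stats::rnorm(1, 0.15 + 0.75 * lev_score, 0.18), 0), 3)

    patients[[i]] <- data.frame(
      patient_id = i, icu_id = icu, apache2 = apache2, age = age, bmi = bmi,
      sex = sex, admission_category = adm, diagnosis = dx, year = year,
      days_mv = days_mv,
      days_pn = sum(pn[1:3] > 0),
      days_oral = sum(oral[1:3]),
      days_propofol = days_propofol,
      days_mnt = sum(!oral[1:3]),
      calorie_fraction = calorie_fraction,
      icu_discharge_day = icu_dis,
      outcome = outcome, outcome_time = outcome_time
    )
    diet_rows[[i]] <- data.frame(
      patient_id = i, day_index = rec,
      en_protein = round(en[rec], 4), pn_amino_acids = round(pn[rec], 4),
      oral_only = oral[rec]
    )
  }

  patients <- do.call(rbind, patients)
  diet_days <- do.call(rbind, diet_rows)
  if (n == 0) {
    patients <- data.frame(patient_id = integer(), icu_id = integer(),
                           apache2 = integer(), age = numeric(), bmi = numeric(),
                           sex = character(), admission_category = character(),
                           diagnosis = character(), year = integer(),
                           days_mv = integer(), days_pn = integer(),
                           days_oral = integer(), days_propofol = integer(),
                           days_mnt = integer(), calorie_fraction = numeric(),
                           icu_discharge_day = integer(), outcome = character(),
                           outcome_time = numeric())
    diet_days <- data.frame(patient_id = integer(), day_index = integer(),
                            en_protein = numeric(), pn_amino_acids = numeric(),
                            oral_only = logical())
  }
  structure(
    list(patients = patients, diet_days = diet_days, config = cfg),
    class = "protein_cohort",
    truth = list(b_death = b_death, b_discharge = b_disch,
                 eff_levels = truth_levels)
  )
}

#' @export
print.protein_cohort <- function(x, ...) {
  cat("<protein_cohort>", nrow(x$patients), "patients,",
      nrow(x$diet_days), "patient-days\n")
  if (nrow(x$patients)) print(table(x$patients$outcome))
  invisible(x)
}

#' Ground-truth hazard-ratio curve for a diet contrast
#'
#' Computes the exact per-interval hazard ratio implied by the configured
#' cumulative effect surface for two fully specified 11-day diets, by direct
#' summation of the per-day effects over the lag-lead window of a patient on
#' medical nutrition therapy on all 11 days. This is the oracle against
#' which fitted [hr_curve()]s are checked in parameter-recovery studies.
#'
#' @param cfg A [sim_config()].
#' @param ref,alt Character vectors of length 11 with levels I/II/III
#'   (reference and comparison diet).
#' @param cause `"death"` or `"discharge"`.
#' @param window_mode Window geometry; defaults to the config's.
#' @return Data frame with `t_start`, `t_end`, `hr`.
#' @export
ground_truth_hr <- function(cfg, ref, alt, cause = c("death", "discharge"),
                            window_mode = cfg$window_mode) {
  cause <- match.arg(cause)
  stopifnot(length(ref) == 11, length(alt) == 11)
  grid <- interval_grid(4:cfg$censor_day)
  W <- lag_lead_window(rep(TRUE, 11), grid, mode = window_mode)$W
  ef <- cfg$effects[[cause]]
  phase <- ifelse(seq_len(11) <= 4, "early", "late")
  per_day <- function(lv) {
    out <- numeric(11)
    hi <- lv != "I"
    out[hi] <- ef[cbind(lv[hi], phase[hi])]
    out
  }
  delta <- per_day(as.character(alt)) - per_day(as.character(ref))
  data.frame(t_start = grid$t_start, t_end = grid$t_end,
             hr = exp(as.numeric(crossprod(W, delta))))
}
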