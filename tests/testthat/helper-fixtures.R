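# Fixtures are built in code: a hand-constructed 5-patient cohort with known
# outcome times, and thin wrappers around the synthetic generator.

tiny_patients <- function() {
  data.frame(
    patient_id = 1:5,
    icu_id = c(1L, 1L, 2L, 2L, 1L),
    apache2 = c(12L, 20L, 9L, 30L, 17L),
    age = c(55, 70, 44, 63, 51),
    bmi = c(24, 31, 22, 28, 35),
    sex = c("female", "male", "male", "female", "male"),
    admission_category = c("medical", "elective_surgery", "medical",
                           "emergency_surgery", "medical"),
    diagnosis = c("dx1", "dx2", "dx1", "dx3", "dx2"),
    year = c(2007L, 2008L, 2013L, 2014L, 2009L),
    days_mv = c(2L, 3L, 1L, 2L, 3L),
    days_pn = c(0L, 1L, 0L, 2L, 0L),
    days_oral = c(0L, 0L, 1L, 0L, 0L),
    days_propofol = c(1L, 0L, 2L, 3L, 1L),
    days_mnt = c(3L, 3L, 2L, 3L, 3L),
    calorie_fraction = c(0.2, 0.5, 0.8, 0.4, 0.6),
    icu_discharge_day = c(NA, NA, NA, 6L, 8L),
    outcome = c("hospital_death", "censored", "live_discharge",
                "hospital_death", "censored"),
    outcome_time = c(6.5, 60, 9.3, 20.2, 60)
  )
}

tiny_diet_days <- function() {
  # per-patient constant EN intake; recorded up to
  # min(11, floor(outcome_time), icu_discharge_day)
  en <- c(0.5, 1.0, 1.3, 0.9, 0.5)
  ndays <- c(6, 11, 9, 6, 8)
  do.call(rbind, lapply(1:5, function(i) {
    data.frame(patient_id = i, day_index = seq_len(ndays[i]),
               en_protein = en[i], pn_amino_acids = 0, oral_only = FALSE)
  }))
}

tiny_cohort <- function() {
  structure(list(patients = tiny_patients(), diet_days = tiny_diet_days(),
                 config = NULL),
            class = "protein_cohort")
}

quick_cohort <- function(n = 80, seed = 42, ...) {
  simulate_cohort(sim_config(n_patients = n, seed = seed, ...))
}

# model spec without the confounder block (validation fits)
bare_spec <- function(cause, ...) {
  model_spec(cause, smooth_confounders = character(0),
             factor_confounders = character(0),
             linear_confounders = character(0), ...)
}

# known-truth scenario: the only non-zero effect is a per-day log-hazard of
# log(0.75) for level-II days in the late acute phase, on the death cause
recovery_effects <- function() {
  z <- matrix(0, 2, 2, dimnames = list(c("II", "III"), c("early", "late")))
  d <- z; d["II", "late"] <- log(0.75)
  list(death = d, discharge = z)
}
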