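test_that("cohort simulation is deterministic and honours degenerate configs", {
  cfg <- sim_config(n_patients = 40, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$diet_days, b$diet_days)

  expect_equal(nrow(simulate_cohort(sim_config(n_patients = 0))$patients), 0)

  no_events <- sim_config(n_patients = 25, seed = 5,
                          base_log_hazard = list(death = -Inf, discharge = -Inf))
  co <- simulate_cohort(no_events)
  expect_true(all(co$patients$outcome == "censored"))
  expect_true(all(co$patients$outcome_time == 60))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(transition = matrix(1, 3, 3)), "stochastic")
  expect_error(daily_event_sampler(c(-0.1), c(0)), "non-negative")
  expect_error(daily_event_sampler(c(0.1, 0.2), c(0.1)), "equal length")
})

test_that("the event sampler matches the closed-form interval probabilities", {
  # single interval, total hazard log 2: P(event) = 1 - exp(-log 2) = 0.5
  set.seed(77)
  n <- 1e5
  draws <- replicate(n, daily_event_sampler(log(2), 0, t_start = 4)$cause)
  expect_equal(mean(draws == "hospital_death"), 0.5, tolerance = 0.01)

  # equal cause-specific hazards: P(death | event) = 0.5
  set.seed(78)
  out <- replicate(n / 10, {
    d <- daily_event_sampler(0.4, 0.4, t_start = 4)
    d$cause
  })
  ev <- out[out != "censored"]
  # ~3 sigma binomial band around 1/2
  expect_lt(abs(mean(ev == "hospital_death") - 0.5), 3 * 0.5 / sqrt(length(ev)))

  # no hazard: censored at the end of follow-up
  expect_equal(daily_event_sampler(rep(0, 56), rep(0, 56)),
               list(cause = "censored", time = 60))
})

test_that("empirical event rates converge to the configured hazards", {
  lam_d <- 0.012; lam_l <- 0.03
  cfg <- sim_config(
    n_patients = 1500, seed = 31, icu_sd = 0,
    base_log_hazard = list(death = log(lam_d), discharge = log(lam_l)),
    effects = list(death = matrix(0, 2, 2), discharge = matrix(0, 2, 2))
  )
  co <- simulate_cohort(cfg)
  pt <- sum(pmin(co$patients$outcome_time, 60) - 4)
  rate_d <- sum(co$patients$outcome == "hospital_death") / pt
  rate_l <- sum(co$patients$outcome == "live_discharge") / pt
  # ~3 sigma Poisson bands around the configured rates
  expect_lt(abs(rate_d - lam_d), 3 * sqrt(lam_d / pt))
  expect_lt(abs(rate_l - lam_l), 3 * sqrt(lam_l / pt))
})

test_that("intake level mix stays near the chain's stationary distribution", {
  co <- quick_cohort(n = 400, seed = 99)
  tot <- total_protein(co$diet_days$en_protein, co$diet_days$pn_amino_acids,
                       co$diet_days$oral_only)
  lv <- classify_intake(tot, co$diet_days$oral_only)
  mix <- as.numeric(prop.table(table(lv)))
  # stationary (0.445, 0.317, 0.238); oral-only days add a little mass to I
  expect_lt(max(abs(mix - c(0.445, 0.317, 0.238))), 0.05)
})

test_that("ground-truth hazard ratios follow the window contents exactly", {
  cfg <- sim_config()
  # identical diets and null surfaces give HR = 1 everywhere
  same <- ground_truth_hr(cfg, rep("II", 11), rep("II", 11), "death")
  expect_true(all(same$hr == 1))
  null_cfg <- sim_config(effects = list(death = matrix(0, 2, 2),
                                        discharge = matrix(0, 2, 2)))
  expect_true(all(ground_truth_hr(null_cfg, rep("I", 11), rep("III", 11),
                                  "death")$hr == 1))

  # a single exposed level-II day (#5, per-day effect log 0.75) affects
  # exactly the intervals whose window holds day #5: t_start in [9, 19)
  cfg2 <- sim_config(effects = recovery_effects())
  alt <- rep("I", 11); alt[5] <- "II"
  gt <- ground_truth_hr(cfg2, rep("I", 11), alt, "death")
  inside <- gt$t_start >= 9 & gt$t_start < 19
  expect_equal(gt$hr[inside], rep(0.75, sum(inside)))
  expect_equal(gt$hr[!inside], rep(1, sum(!inside)))
})

test_that("the indication-bias scenario links low intake to higher death rates", {
  co_b <- simulate_cohort(sim_config(n_patients = 600, seed = 55,
                                     scenario = "indication_bias",
                                     severity_coef = 0.6))
  # per-patient mean intake level vs death: under indication bias, patients
  # who die received less protein on average than survivors
  lv <- classify_intake(
    total_protein(co_b$diet_days$en_protein, co_b$diet_days$pn_amino_acids,
                  co_b$diet_days$oral_only),
    co_b$diet_days$oral_only)
  mean_lv <- tapply(as.integer(lv), co_b$diet_days$patient_id, mean)
  died <- co_b$patients$outcome == "hospital_death"
  m <- mean_lv[as.character(co_b$patients$patient_id)]
  expect_lt(mean(m[died]), mean(m[!died]))
})
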