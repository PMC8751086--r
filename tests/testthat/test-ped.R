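test_that("PED split yields one row per interval at risk with correct offsets", {
  p <- tiny_patients()
  ped <- split_to_ped(p, interval_grid(4:60))

  # death at 6.5: rows (4,5], (5,6], (6,6.5]
  r1 <- ped[ped$patient_id == 1, ]
  expect_equal(nrow(r1), 3)
  expect_equal(r1$offset, log(c(1, 1, 0.5)))
  expect_equal(r1$death, c(0, 0, 1))
  expect_equal(r1$discharge, c(0, 0, 0))

  # censored at 60: 56 rows, no events
  r2 <- ped[ped$patient_id == 2, ]
  expect_equal(nrow(r2), 56)
  expect_true(all(r2$death == 0) && all(r2$discharge == 0))

  # live discharge at 9.3: event indicator on the discharge cause only
  r3 <- ped[ped$patient_id == 3, ]
  expect_equal(sum(r3$discharge), 1)
  expect_equal(r3$discharge[nrow(r3)], 1)
  expect_equal(sum(r3$death), 0)
})

test_that("total exposure is conserved and events appear exactly once", {
  co <- quick_cohort(n = 60, seed = 3)
  ped <- split_to_ped(co$patients, interval_grid(4:60))
  agg <- tapply(exp(ped$offset), ped$patient_id, sum)
  expect_equal(as.numeric(agg[as.character(co$patients$patient_id)]),
               pmin(co$patients$outcome_time, 60) - 4, tolerance = 1e-12)
  ev <- tapply(ped$death + ped$discharge, ped$patient_id, sum)
  expected <- as.numeric(co$patients$outcome != "censored")
  expect_equal(as.numeric(ev[as.character(co$patients$patient_id)]), expected)
})

test_that("PED split under the ICU outcome set recodes post-discharge deaths", {
  p <- tiny_patients()
  ped <- split_to_ped(p, interval_grid(4:60), cause_set = "icu")
  # patient 4 died in hospital at 20.2 but left the ICU alive on day 6:
  # ICU outcome is live ICU discharge at day 6
  r4 <- ped[ped$patient_id == 4, ]
  expect_equal(nrow(r4), 2)
  expect_equal(r4$discharge, c(0, 1))
  expect_equal(sum(r4$death), 0)
})

test_that("follow-up requires surviving past the first cut point", {
  p <- tiny_patients()[1, ]
  p$outcome_time <- 3.5
  expect_error(split_to_ped(p, interval_grid(4:60)), "inclusion")
  expect_error(interval_grid(c(3, 5, 10)), ">= 4")
})

test_that("the lag-lead window respects the 4-day lag and dynamic lead", {
  grid <- interval_grid(4:60)
  # MNT on day #1 only: lead 2 days, so day #1 affects t_start in [5, 7);
  # the cumulative MNT count stays 1, so e.g. day #2 spans [6, 8)
  w <- lag_lead_window(c(TRUE, rep(FALSE, 10)), grid, mode = "dynamic")
  expect_equal(which(w$W[1, ] == 1), which(grid$t_start %in% c(5, 6)))
  expect_equal(which(w$W[2, ] == 1), which(grid$t_start %in% c(6, 7)))
  # with no MNT at all, no lead accrues and no day has a window
  expect_true(all(lag_lead_window(rep(FALSE, 11), grid)$W == 0))
  # nothing can affect the first interval (4,5]
  w_full <- lag_lead_window(rep(TRUE, 11), grid, mode = "dynamic")
  expect_true(all(w_full$W[, grid$t_start == 4] == 0))
  # static mode: day #11 affects all intervals starting in [15, 60)
  w_st <- lag_lead_window(rep(TRUE, 11), grid, mode = "static")
  expect_equal(which(w_st$W[11, ] == 1), which(grid$t_start >= 15))
})

test_that("cumulative design counts window days by level and phase", {
  grid <- interval_grid(4:60)
  w <- lag_lead_window(rep(TRUE, 11), grid, mode = "dynamic")
  traj <- data.frame(day_index = 1:11,
                     level = factor(c(rep("I", 4), rep("II", 7)),
                                    levels = c("I", "II", "III")))
  cd <- build_cumulative_design(w, traj, "phase")
  # reference-level days contribute nothing
  all_I <- data.frame(day_index = 1:11,
                      level = factor(rep("I", 11), levels = c("I", "II", "III")))
  expect_true(all(build_cumulative_design(w, all_I, "phase") == 0))
  # at t_start = 10, dynamic window (full MNT) holds days t_z in 3..6, of
  # which the late level-II days are #5, #6
  j <- which(grid$t_start == 10)
  expect_equal(cd$cum_II_late[j], 2)
  expect_equal(cd$cum_II_early[j], 0)
  # at t_start in [15, 19) all seven late days are in the window
  expect_equal(cd$cum_II_late[grid$t_start %in% 15:18], rep(7, 4))
})

test_that("surface and phase designs agree on per-dummy totals", {
  grid <- interval_grid(4:60)
  set.seed(9)
  for (rep in 1:5) {
    mnt <- stats::runif(11) < 0.9
    w <- lag_lead_window(mnt, grid, mode = "dynamic")
    traj <- data.frame(day_index = 1:11,
                       level = factor(sample(c("I", "II", "III"), 11, TRUE),
                                      levels = c("I", "II", "III")))
    ph <- build_cumulative_design(w, traj, "phase")
    su <- build_cumulative_design(w, traj, "surface")
    expect_equal(rowSums(su[, paste0("cumII_tz", 1:11)]),
                 ph$cum_II_early + ph$cum_II_late)
    expect_equal(rowSums(su[, paste0("cumIII_tz", 1:11)]),
                 ph$cum_III_early + ph$cum_III_late)
  }
})

test_that("diet pairs identical inside all windows give identical designs", {
  grid <- interval_grid(4:60)
  w <- lag_lead_window(rep(TRUE, 11), grid, mode = "dynamic")
  set.seed(11)
  for (rep in 1:10) {
    lv <- sample(c("I", "II", "III"), 11, TRUE)
    lv2 <- lv
    day <- sample(11, 1)
    lv2[day] <- sample(setdiff(c("I", "II", "III"), lv[day]), 1)
    t1 <- data.frame(day_index = 1:11, level = factor(lv, levels = c("I", "II", "III")))
    t2 <- data.frame(day_index = 1:11, level = factor(lv2, levels = c("I", "II", "III")))
    d1 <- as.matrix(build_cumulative_design(w, t1, "phase"))
    d2 <- as.matrix(build_cumulative_design(w, t2, "phase"))
    affected <- w$W[day, ] == 1
    expect_true(all(d1[!affected, ] == d2[!affected, ]))
    expect_true(any(d1[affected, ] != d2[affected, ]))
  }
})

test_that("make_ped flags missing intake inside the window", {
  co <- tiny_cohort()
  # drop a needed recorded day: patient 2 is censored at 60 and in the ICU
  # beyond day 11, so all 11 days are required
  co$diet_days <- co$diet_days[!(co$diet_days$patient_id == 2 &
                                   co$diet_days$day_index >= 7), ]
  expect_error(make_ped(co), "missing")
})
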