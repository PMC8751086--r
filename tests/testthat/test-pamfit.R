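# Dual-route checks of the penalized Poisson fitter: closed-form
# occurrence/exposure rates, base glm() on an identical design, and
# mgcv REML on an identical design-and-penalty setup.

coarse_ped <- function(co, cuts = c(4, 8, 15, 30, 60)) {
  ped <- split_to_ped(co$patients, interval_grid(cuts))
  attr(ped, "basis_mode") <- "phase"
  ped
}

test_that("the unpenalized covariate-free fit reproduces occurrence/exposure rates", {
  co <- quick_cohort(n = 50, seed = 21)
  ped <- coarse_ped(co)
  spec <- bare_spec("death", baseline = "factor", random_icu = FALSE,
                    cumulative = FALSE, smoothing = "fixed", lambda = 0)
  fit <- fit_pamm(ped, spec)
  ev <- tapply(ped$death, ped$interval, sum)
  ex <- tapply(exp(ped$offset), ped$interval, sum)
  expect_true(all(ev > 0))  # fixture has deaths in every coarse interval
  rate <- unname(ev / ex)
  est <- unname(exp(fit$coefficients))
  expect_lt(max(abs(est - rate) / rate), 1e-6)
})

test_that("the fitter agrees with glm() on an unpenalized design", {
  co <- quick_cohort(n = 50, seed = 21)
  ped <- coarse_ped(co)
  spec <- model_spec("discharge", baseline = "factor",
                     smooth_confounders = character(0),
                     factor_confounders = "sex",
                     linear_confounders = "age",
                     random_icu = FALSE, cumulative = FALSE,
                     smoothing = "fixed", lambda = 0)
  fit <- fit_pamm(ped, spec)
  g <- stats::glm(discharge ~ 0 + factor(interval) + sex + age,
                  family = stats::poisson(), data = ped,
                  offset = ped$offset)
  eta_mine <- predict_log_hazard(fit, ped)$eta
  eta_glm <- stats::predict(g, type = "link") - ped$offset
  expect_lt(max(abs(eta_mine - eta_glm)), 1e-6)
})

test_that("duplicating PED rows while halving exposure leaves the MLE unchanged", {
  # seed/grid with deaths in every coarse interval, so the saturated MLE is finite
  co <- quick_cohort(n = 50, seed = 21)
  ped <- coarse_ped(co)
  spec <- bare_spec("death", baseline = "factor", random_icu = FALSE,
                    cumulative = FALSE, smoothing = "fixed", lambda = 0)
  fit1 <- fit_pamm(ped, spec)
  # split every row into two half-exposure copies, event kept on one copy:
  # the piece-wise exponential likelihood is invariant to such refinements
  first <- ped; first$death <- 0L; first$discharge <- 0L
  ped2 <- rbind(first, ped)
  ped2$offset <- ped2$offset - log(2)
  attr(ped2, "grid") <- attr(ped, "grid")
  attr(ped2, "basis_mode") <- "phase"
  fit2 <- fit_pamm(ped2, spec)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-6)
  expect_equal(loglik_pamm(fit1, ped2), loglik_pamm(fit2, ped2), tolerance = 1e-8)
})

test_that("the PED Poisson log-likelihood equals the survival log-likelihood up to a constant", {
  co <- tiny_cohort()
  ped <- make_ped(co)
  spec <- bare_spec("death", smoothing = "fixed", lambda = 1, random_icu = FALSE)
  fit <- fit_pamm(ped, spec)

  surv_ll <- function(beta) {
    m <- fit; m$coefficients <- beta
    eta <- predict_log_hazard(m, ped, exclude_random = FALSE)$eta
    sum(ped$death * eta) - sum(exp(eta + ped$offset))
  }
  beta1 <- fit$coefficients
  set.seed(4); beta2 <- beta1 + stats::rnorm(length(beta1), 0, 0.3)
  const1 <- loglik_pamm(fit, ped, beta1) - surv_ll(beta1)
  const2 <- loglik_pamm(fit, ped, beta2) - surv_ll(beta2)
  expect_equal(const1, const2, tolerance = 1e-9)
  expect_equal(const1, sum(ped$death * ped$offset), tolerance = 1e-9)
})

test_that("less penalization weakly increases the unpenalized log-likelihood", {
  co <- quick_cohort(n = 60, seed = 13)
  ped <- make_ped(co)
  lls <- vapply(c(50, 5, 0.5), function(l) {
    f <- fit_pamm(ped, bare_spec("death", smoothing = "fixed", lambda = l))
    loglik_pamm(f, ped)
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("predictions are additive in the diet terms and have valid SEs", {
  co <- quick_cohort(n = 60, seed = 13)
  ped <- make_ped(co)
  fit <- fit_pamm(ped, model_spec("death", smoothing = "fixed", lambda = 5))
  nd <- ped[rep(10, 4), ]
  nd$cum_II_late <- c(0, 3, 0, 3)
  nd$age <- c(40, 40, 80, 80)          # different confounder level in rows 3:4
  pr <- predict_log_hazard(fit, nd)
  expect_true(all(pr$se >= 0))
  # diet contrast is the same whatever the confounder values
  expect_equal(pr$eta[2] - pr$eta[1], pr$eta[4] - pr$eta[3], tolerance = 1e-10)
  # unseen factor levels are refused
  nd_bad <- ped[10, ]; nd_bad$sex <- "other"
  expect_error(predict_log_hazard(fit, nd_bad), "unseen")
})

test_that("REML smoothing matches mgcv on an identical design and penalties", {
  skip_if_not_installed("mgcv")
  co <- quick_cohort(n = 150, seed = 17)
  ped <- make_ped(co)
  spec <- bare_spec("discharge", cumulative = FALSE, smoothing = "reml")
  fit <- fit_pamm(ped, spec)

  dm <- protpamm:::build_pamm_design(ped, spec, attr(ped, "grid"), "phase")
  dat <- list(y = ped$discharge, off = ped$offset)
  paraPen <- list(); rhs <- character()
  for (lab in names(dm$cols)) {
    nm <- gsub("[^a-zA-Z0-9]", "_", lab)
    dat[[nm]] <- dm$X[, dm$cols[[lab]], drop = FALSE]
    rhs <- c(rhs, nm)
    tm <- dm$info$terms[[lab]]
    if (tm$penalized) paraPen[[nm]] <- tm$penalties
  }
  g <- mgcv::gam(stats::as.formula(paste("y ~ -1 +", paste(rhs, collapse = "+"))),
                 family = stats::poisson(), offset = off,
                 paraPen = paraPen, method = "REML", data = dat)
  eta_mine <- drop(dm$X %*% fit$coefficients)
  eta_mgcv <- drop(dm$X %*% stats::coef(g))
  expect_lt(max(abs(eta_mine - eta_mgcv)), 0.05)
  expect_equal(fit$edf_total, sum(g$edf), tolerance = 0.05)
})

test_that("non-convergence raises an informative error", {
  co <- quick_cohort(n = 30, seed = 2)
  ped <- make_ped(co)
  spec <- bare_spec("death", smoothing = "fixed", lambda = 1, max_iter = 1)
  expect_error(fit_pamm(ped, spec), "converge")
})

test_that("fitted models survive a JSON round trip", {
  co <- quick_cohort(n = 40, seed = 6)
  ped <- make_ped(co)
  fit <- fit_pamm(ped, bare_spec("death", smoothing = "fixed", lambda = 5))
  path <- tempfile(fileext = ".json")
  write_pamm_json(fit, path)
  back <- read_pamm_json(path)
  expect_equal(back$coefficients, fit$coefficients)
  cmp <- make_comparisons()[[1]]
  expect_equal(hr_curve(back, cmp)$hr, hr_curve(fit, cmp)$hr, tolerance = 1e-12)
})

test_that("the tensor-surface cumulative basis fits and keeps the lag structure", {
  co <- quick_cohort(n = 100, seed = 27)
  ped <- make_ped(co, basis_mode = "surface")
  fit <- fit_pamm(ped, bare_spec("death", smoothing = "fixed", lambda = 10))
  cmp <- make_comparisons()[[1]]
  hr <- hr_curve(fit, cmp)
  expect_identical(hr$hr[hr$t_start == 4], 1)
  expect_true(all(hr$hr > 0))
  # surface and phase fits agree on which intervals are structurally unaffected
  ped_ph <- make_ped(co, basis_mode = "phase")
  fit_ph <- fit_pamm(ped_ph, bare_spec("death", smoothing = "fixed", lambda = 10))
  hr_ph <- hr_curve(fit_ph, cmp)
  expect_identical(hr$ci_lower == hr$ci_upper, hr_ph$ci_lower == hr_ph$ci_upper)
})
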