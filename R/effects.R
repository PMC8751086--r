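# Hypothetical-diet contrasts: time-varying cause-specific hazard-ratio
# curves with delta-method confidence bands, and cumulative incidence
# functions from the pair of cause-specific models.

# PED-like rows for a hypothetical diet at the population-average profile:
# confounders at their reference/median, ICU random intercept at zero, and
# the cumulative design of a patient on MNT on all 11 days under the
# model's window mode.
diet_newdata <- function(model, levels11) {
  stopifnot(length(levels11) == 11)
  grid <- model$grid
  nd <- data.frame(interval = seq_len(grid$n),
                   t_start = grid$t_start, t_end = grid$t_end,
                   tmid = grid$tmid)
  for (v in names(model$info$profile)) nd[[v]] <- model$info$profile[[v]]
  win <- lag_lead_window(rep(TRUE, 11), grid, mode = model$window_mode)
  traj <- data.frame(day_index = 1:11,
                     level = factor(levels11, levels = c("I", "II", "III")))
  cum <- build_cumulative_design(win, traj, model$basis_mode)
  cbind(nd, cum)
}

#' Time-varying hazard-ratio curve between two hypothetical diets
#'
#' Computes, per follow-up interval, the cause-specific hazard ratio of the
#' comparison diet versus the reference diet under the ceteris paribus
#' assumption: all confounders and the ICU random effect cancel, so the log
#' hazard ratio is the difference of the cumulative-effect linear-predictor
#' contributions. The 95% confidence band uses the delta method on the
#' contrast vector and the posterior covariance of the penalized fit. On
#' intervals where the two diets are identical inside every contributing
#' lag-lead window (in particular the first interval (4,5], which no day on
#' diet can reach through the 4-day lag), the HR is exactly 1 with a
#' degenerate confidence interval.
#'
#' @param model A [fit_pamm()] object.
#' @param ref,alt Reference and comparison diets: character vectors of
#'   length 11 with levels I/II/III. Alternatively pass a single comparison
#'   element from [make_comparisons()] as `ref`.
#' @param conf_level Confidence level of the band (0.95; z = 1.96).
#' @return Data frame of class `hr_curve`: `t_start`, `t_end`, `hr`,
#'   `ci_lower`, `ci_upper`, `cause`, `reference`, `comparison`.
#' @export
hr_curve <- function(model, ref, alt = NULL, conf_level = 0.95) {
  ref_name <- "reference"; alt_name <- "comparison"
  if (is.list(ref) && !is.null(ref$ref) && is.null(alt)) {
    cmp <- ref
    ref <- cmp$ref; alt <- cmp$alt
    ref_name <- cmp$ref_name; alt_name <- cmp$alt_name
  }
  if (length(ref) != 11 || length(alt) != 11) {
    stop("diets must specify 11 days on diet", call. = FALSE)
  }
  if (anyNA(ref) || anyNA(alt)) {
    stop("diets must be fully resolved (no NA days); see make_comparisons()",
         call. = FALSE)
  }
  nd_ref <- diet_newdata(model, ref)
  nd_alt <- diet_newdata(model, alt)
  dX <- build_pamm_design(nd_alt, model$spec, model$grid, model$basis_mode,
                          info = model$info, exclude_random = TRUE)$X -
        build_pamm_design(nd_ref, model$spec, model$grid, model$basis_mode,
                          info = model$info, exclude_random = TRUE)$X
  d_eta <- drop(dX %*% model$coefficients)
  se <- sqrt(pmax(rowSums((dX %*% model$V) * dX), 0))
  null_row <- rowSums(abs(dX)) == 0
  d_eta[null_row] <- 0
  se[null_row] <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    t_start = model$grid$t_start, t_end = model$grid$t_end,
    hr = exp(d_eta),
    ci_lower = exp(d_eta - z * se),
    ci_upper = exp(d_eta + z * se),
    cause = model$spec$cause,
    reference = ref_name, comparison = alt_name
  )
  class(out) <- c("hr_curve", "data.frame")
  out
}

#' Cumulative incidence from per-interval cause-specific hazards
#'
#' Closed-form CIF of the piece-wise exponential model with constant
#' hazards inside intervals: with total hazard `lam = h_death + h_discharge`
#' and widths `w`, overall survival is `S(j) = exp(-sum(lam * w))` and
#' `CIF_k(j) = sum_i S(i-1) * h_k(i)/lam(i) * (1 - exp(-lam(i) w(i)))`
#' (proportional within-interval cause allocation, exact for constant
#' hazards). The identity `CIF_death + CIF_discharge + S = 1` holds by
#' telescoping.
#'
#' @param h_death,h_discharge Non-negative per-interval hazards (per day).
#' @param width Interval widths in days.
#' @return Data frame with `surv`, `cif_death`, `cif_discharge` at each
#'   interval end.
#' @export
cif_from_hazards <- function(h_death, h_discharge, width = 1) {
  n <- length(h_death)
  stopifnot(length(h_discharge) == n)
  if (any(h_death < 0) || any(h_discharge < 0)) {
    stop("hazards must be non-negative", call. = FALSE)
  }
  width <- rep_len(width, n)
  lam <- h_death + h_discharge
  S <- exp(-cumsum(lam * width))
  S_prev <- c(1, S[-n])
  q <- 1 - exp(-lam * width)
  share_d <- ifelse(lam > 0, h_death / lam, 0)
  share_l <- ifelse(lam > 0, h_discharge / lam, 0)
  data.frame(
    surv = S,
    cif_death = cumsum(S_prev * share_d * q),
    cif_discharge = cumsum(S_prev * share_l * q)
  )
}

#' Cumulative incidence curves for a hypothetical diet
#'
#' Predicts the per-interval cause-specific hazards of both fitted models
#' for a hypothetical diet at the population-average covariate profile and
#' converts them to absolute risks (CIFs) and overall survival.
#'
#' @param model_death,model_discharge The two cause-specific [fit_pamm()]
#'   models, fitted on the same interval grid.
#' @param diet Character vector of length 11 with levels I/II/III.
#' @return Data frame of class `cif_curve`: `t_start`, `t_end`, `surv`,
#'   `cif_death`, `cif_discharge`.
#' @export
cif_curve <- function(model_death, model_discharge, diet) {
  if (model_death$spec$cause != "death" || model_discharge$spec$cause != "discharge") {
    stop("pass the death model first and the discharge model second", call. = FALSE)
  }
  if (!same_grid(model_death$grid, model_discharge$grid)) {
    stop("the two cause-specific models must share one interval grid", call. = FALSE)
  }
  h_d <- exp(predict_log_hazard(model_death, diet_newdata(model_death, diet))$eta)
  h_l <- exp(predict_log_hazard(model_discharge, diet_newdata(model_discharge, diet))$eta)
  grid <- model_death$grid
  out <- cbind(data.frame(t_start = grid$t_start, t_end = grid$t_end),
               cif_from_hazards(h_d, h_l, grid$width))
  class(out) <- c("cif_curve", "data.frame")
  out
}

#' Step/ribbon plot of a hazard-ratio curve
#'
#' @param hr An [hr_curve()] data frame (possibly several row-bound curves
#'   with distinct `cause`/`comparison` values; the plot facets by them).
#' @return A ggplot object.
#' @export
plot_hr_curve <- function(hr) {
  ggplot2::ggplot(hr, ggplot2::aes(x = t_start + (t_end - t_start) / 2)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lower, ymax = ci_upper),
                         alpha = 0.2) +
    ggplot2::geom_step(ggplot2::aes(x = t_start, y = hr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(cause ~ paste(comparison, "vs", reference)) +
    ggplot2::labs(x = "days after ICU admission", y = "hazard ratio")
}

#' Plot cumulative incidence curves
#'
#' @param cif A [cif_curve()] data frame.
#' @return A ggplot object.
#' @export
plot_cif_curve <- function(cif) {
  long <- rbind(
    data.frame(t = cif$t_end, p = cif$cif_death, what = "in-hospital death"),
    data.frame(t = cif$t_end, p = cif$cif_discharge, what = "live discharge"),
    data.frame(t = cif$t_end, p = cif$surv, what = "still in hospital")
  )
  ggplot2::ggplot(long, ggplot2::aes(t, p, colour = what)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "days after ICU admission", y = "probability",
                  colour = NULL) +
    ggplot2::ylim(0, 1)
}
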