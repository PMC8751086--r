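# Piece-wise exponential data (PED): one pseudo-observation per patient and
# follow-up interval, with log person-time offset and cause-specific event
# indicators, plus the lag-lead cumulative-effect design.

#' Follow-up interval grid
#'
#' Half-open intervals (a, b] on the days-after-ICU-admission scale. The
#' default is daily from day 4 (follow-up conditions on 96-h survival) to
#' day 60 (administrative censoring).
#'
#' @param cuts Strictly increasing cut points; first cut must be >= 4.
#' @return Object of class `interval_grid` with `cuts`, `t_start`, `t_end`,
#'   `tmid`, `width` and `n`.
#' @export
interval_grid <- function(cuts = 4:60) {
  cuts <- as.numeric(cuts)
  if (length(cuts) < 2 || any(diff(cuts) <= 0)) {
    stop("`cuts` must be strictly increasing", call. = FALSE)
  }
  if (cuts[1] < 4) {
    stop("first cut point must be >= 4 (follow-up conditions on 96-h survival)",
         call. = FALSE)
  }
  n <- length(cuts) - 1L
  structure(list(cuts = cuts,
                 t_start = cuts[-length(cuts)], t_end = cuts[-1],
                 tmid = (cuts[-length(cuts)] + cuts[-1]) / 2,
                 width = diff(cuts), n = n),
            class = "interval_grid")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$cuts, b$cuts))
}

#' Split patient records into piece-wise exponential pseudo-data
#'
#' Expands each patient into one row per follow-up interval at risk, with
#' offset `log(min(outcome_time, t_end) - t_start)` and competing-risk event
#' indicators `death` and `discharge` that are 1 only in the final row of a
#' patient experiencing that cause. With `cause_set = "icu"`, events are
#' redefined as in-ICU death and live ICU discharge (the sensitivity
#' analysis): a patient discharged alive from the ICU before their hospital
#' outcome has a live-ICU-discharge event at the ICU discharge day.
#'
#' @param patients Admission-level data frame (as in
#'   [simulate_cohort()]`$patients`).
#' @param grid An [interval_grid()].
#' @param cause_set `"hospital"` or `"icu"`.
#' @return Data frame with one row per patient-interval: `patient_id`,
#'   `interval`, `t_start`, `t_end`, `tmid`, `offset`, `death`, `discharge`
#'   plus all admission covariates.
#' @export
split_to_ped <- function(patients, grid = interval_grid(),
                         cause_set = c("hospital", "icu")) {
  cause_set <- match.arg(cause_set)
  time <- patients$outcome_time
  outcome <- patients$outcome
  if (cause_set == "icu") {
    dis <- patients$icu_discharge_day
    early_out <- !is.na(dis) & dis < time
    time <- ifelse(early_out, dis, time)
    outcome <- ifelse(early_out, "live_discharge", outcome)
  }
  if (any(time <= grid$cuts[1])) {
    stop("outcome_time <= first cut point violates the inclusion criteria",
         call. = FALSE)
  }
  # number of intervals with t_start < time
  n_j <- vapply(time, function(tt) sum(grid$t_start < tt), integer(1))
  idx <- rep(seq_len(nrow(patients)), times = n_j)
  j <- sequence(n_j)
  t_start <- grid$t_start[j]
  t_end <- grid$t_end[j]
  exposure <- pmin(time[idx], t_end) - t_start
  last <- c(diff(idx) != 0, TRUE)
  ped <- data.frame(
    patient_id = patients$patient_id[idx],
    interval = j,
    t_start = t_start, t_end = t_end, tmid = grid$tmid[j],
    offset = log(exposure),
    death = as.integer(last & outcome[idx] == "hospital_death"),
    discharge = as.integer(last & outcome[idx] == "live_discharge")
  )
  covars <- setdiff(names(patients),
                    c("patient_id", "outcome", "outcome_time"))
  ped <- cbind(ped, patients[idx, covars, drop = FALSE])
  rownames(ped) <- NULL
  attr(ped, "grid") <- grid
  attr(ped, "cause_set") <- cause_set
  ped
}

#' Lag-lead window of a patient's days on diet
#'
#' Builds the indicator `W[t_z, j]` saying whether intake on day on diet
#' `t_z` (1..11) may affect the hazard of follow-up interval `j`. A day's
#' influence starts after a 4-day lag and lasts for a lead time of twice the
#' cumulative number of days with medical nutrition therapy up to and
#' including that day (`dynamic` mode) or 60 days (`static` mode):
#' `W = 1` iff `t_start >= t_z + 4` and `t_start < t_z + 4 + lead(t_z)`,
#' using the interval's left endpoint. No day can affect the first interval
#' (4,5], which is why hazard ratios between diets are 1 there.
#'
#' @param mnt Logical vector of length 11: day with any EN/PN intake
#'   (imputed standard-intake days count as MNT days).
#' @param grid An [interval_grid()].
#' @param mode `"dynamic"` or `"static"`.
#' @param lag Lag in days (4).
#' @return Object of class `lag_lead_window` with the 11 x `grid$n` binary
#'   matrix `W`, `mode` and `lead`.
#' @export
lag_lead_window <- function(mnt, grid = interval_grid(),
                            mode = c("dynamic", "static"), lag = 4) {
  mode <- match.arg(mode)
  stopifnot(length(mnt) == 11, is.logical(mnt))
  lead <- if (mode == "dynamic") 2 * cumsum(mnt) else rep(60, 11)
  tz <- seq_len(11)
  W <- outer(tz, grid$t_start, function(z, s) {
    (s >= z + lag) & (s < z + lag + lead[z])
  })
  storage.mode(W) <- "integer"
  structure(list(W = W, mode = mode, lag = lag, lead = lead),
            class = "lag_lead_window")
}

#' Per-interval cumulative-effect design entries
#'
#' Aggregates a patient's intake trajectory over the lag-lead window into
#' the quantities the hazard model consumes. In `phase` mode these are four
#' scalars per interval: the number of level II (resp. III) days on diet in
#' the early acute phase (days #1--#4) and in the late acute phase
#' (#5--#11) inside the interval's window. In `surface` mode they are the
#' per-day indicators `W[t_z, j] * 1{level(t_z) = d}` for each day on diet,
#' which the fitter combines with a tensor-product spline basis over
#' (interval time, day on diet). Level I is the reference and contributes
#' nothing. Entries needing a day beyond the available trajectory are `NA`
#' (a missing-data error is raised when such a row enters a model).
#'
#' @param window A [lag_lead_window()].
#' @param trajectory Data frame from [build_trajectory()].
#' @param basis_mode `"phase"` or `"surface"`.
#' @return Data frame with one row per grid interval: columns
#'   `cum_II_early`, `cum_II_late`, `cum_III_early`, `cum_III_late`
#'   (phase mode) or `cumII_tz1..11`, `cumIII_tz1..11` (surface mode).
#' @export
build_cumulative_design <- function(window, trajectory,
                                    basis_mode = c("phase", "surface")) {
  basis_mode <- match.arg(basis_mode)
  W <- window$W
  n_int <- ncol(W)
  lv <- rep(NA_character_, 11)
  lv[trajectory$day_index] <- as.character(trajectory$level)
  ind <- function(level) {
    x <- as.numeric(lv == level)          # NA where day unavailable
    M <- W * matrix(x, nrow = 11, ncol = n_int)
    M[W == 0] <- 0                        # unavailable days outside window: 0
    M
  }
  A_II <- ind("II"); A_III <- ind("III")
  if (basis_mode == "phase") {
    early <- 1:4; late <- 5:11
    out <- data.frame(
      cum_II_early = colSums(A_II[early, , drop = FALSE]),
      cum_II_late = colSums(A_II[late, , drop = FALSE]),
      cum_III_early = colSums(A_III[early, , drop = FALSE]),
      cum_III_late = colSums(A_III[late, , drop = FALSE])
    )
  } else {
    out <- as.data.frame(cbind(t(A_II), t(A_III)))
    names(out) <- c(paste0("cumII_tz", 1:11), paste0("cumIII_tz", 1:11))
  }
  out
}

cum_col_names <- function(basis_mode) {
  if (basis_mode == "phase") {
    c("cum_II_early", "cum_II_late", "cum_III_early", "cum_III_late")
  } else {
    c(paste0("cumII_tz", 1:11), paste0("cumIII_tz", 1:11))
  }
}

#' Assemble the full model-ready PED for a cohort
#'
#' Runs [build_trajectory()], [lag_lead_window()], [split_to_ped()] and
#' [build_cumulative_design()] for every patient and binds the
#' cumulative-effect columns onto the PED rows. Factor covariates are set up
#' with the analysis reference categories (female, medical admission,
#' earliest survey year, diagnosis `dx1`).
#'
#' @param cohort A `protein_cohort` (or any list with `patients` and
#'   `diet_days` in the documented two-table schema).
#' @param grid An [interval_grid()].
#' @param outcome_set `"hospital"` (with post-ICU-discharge imputation) or
#'   `"icu"` (sensitivity analysis; truncated trajectories, no imputation).
#' @param window_mode `"dynamic"` or `"static"`.
#' @param basis_mode `"phase"` or `"surface"`.
#' @return PED data frame with cumulative design columns; attributes
#'   `grid`, `window_mode`, `basis_mode`, `outcome_set`.
#' @export
make_ped <- function(cohort, grid = interval_grid(),
                     outcome_set = c("hospital", "icu"),
                     window_mode = c("dynamic", "static"),
                     basis_mode = c("phase", "surface")) {
  outcome_set <- match.arg(outcome_set)
  window_mode <- match.arg(window_mode)
  basis_mode <- match.arg(basis_mode)
  patients <- cohort$patients
  ped <- split_to_ped(patients, grid, cause_set = outcome_set)

  dd_split <- split(cohort$diet_days, cohort$diet_days$patient_id)
  traj_mode <- if (outcome_set == "hospital") "hospital" else "icu"
  cum_names <- cum_col_names(basis_mode)
  cum_list <- vector("list", nrow(patients))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    traj <- build_trajectory(dd_split[[as.character(p$patient_id)]],
                             p$icu_discharge_day, p$outcome, p$outcome_time,
                             mode = traj_mode)
    mnt <- rep(FALSE, 11)
    mnt[traj$day_index] <- traj$mnt
    win <- lag_lead_window(mnt, grid, mode = window_mode)
    cum_list[[i]] <- build_cumulative_design(win, traj, basis_mode)
  }
  rows_by_pat <- split(seq_len(nrow(ped)),
                       factor(ped$patient_id, levels = patients$patient_id))
  cum <- do.call(rbind, lapply(seq_along(cum_list), function(i) {
    cum_list[[i]][ped$interval[rows_by_pat[[i]]], , drop = FALSE]
  }))
  # split_to_ped emits rows in patient order, so cum rows align with ped rows
  ped[cum_names] <- cum
  bad <- !stats::complete.cases(ped[cum_names])
  if (any(bad)) {
    stop(sprintf(
      "missing intake data inside the lag-lead window for patient(s) %s",
      paste(unique(ped$patient_id[bad]), collapse = ", ")), call. = FALSE)
  }
  ped$sex <- factor(ped$sex, levels = c("female", "male"))
  ped$admission_category <- factor(ped$admission_category,
                                   levels = c("medical", "elective_surgery",
                                              "emergency_surgery"))
  ped$diagnosis <- factor(ped$diagnosis,
                          levels = paste0("dx", 1:9)[paste0("dx", 1:9) %in%
                                                       unique(ped$diagnosis)])
  ped$year <- factor(ped$year, levels = sort(unique(ped$year)))
  attr(ped, "grid") <- grid
  attr(ped, "window_mode") <- window_mode
  attr(ped, "basis_mode") <- basis_mode
  attr(ped, "outcome_set") <- outcome_set
  ped
}

#' Write piece-wise exponential data to CSV
#'
#' Long-format export (one row per patient-interval) for inspection or for
#' cross-fitting with external GAM software.
#'
#' @param ped PED data frame from [make_ped()] or [split_to_ped()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ped_csv <- function(ped, path) {
  utils::write.csv(ped, path, row.names = FALSE)
  invisible(path)
}
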