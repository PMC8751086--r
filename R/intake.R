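#' @keywords internal
"_PACKAGE"

# Conversion factor from parenteral amino acids to protein equivalents.
PN_TO_PROTEIN <- 0.83

# Category bounds in g protein / kg body weight per day:
# level I (low) [0, 0.8), level II (standard) [0.8, 1.2], level III (high)
# (1.2, Inf). Both printed bounds belong to level II.
LEVEL_LOW_BOUND <- 0.8
LEVEL_HIGH_BOUND <- 1.2

# Within-category medians of daily intake (g/kg) used as numeric placeholders
# for categorical diets; the hazard model itself only consumes categories.
LEVEL_MEDIANS <- c(I = 0.49, II = 0.99, III = 1.41)

#' Intake level definitions
#'
#' Daily protein intake (g per kg body weight) is classified into three
#' levels: level I (low, < 0.8), level II (standard, 0.8--1.2, both bounds
#' included), and level III (high, > 1.2). Days with exclusively oral intake
#' are ranked into the lowest level regardless of the amount.
#'
#' @return A data frame with one row per level: `level`, `lower`, `upper`,
#'   `lower_closed`, `upper_closed`, `median` (g/kg).
#' @export
#' @examples
#' intake_levels()
intake_levels <- function() {
  data.frame(
    level = c("I", "II", "III"),
    lower = c(0, LEVEL_LOW_BOUND, LEVEL_HIGH_BOUND),
    upper = c(LEVEL_LOW_BOUND, LEVEL_HIGH_BOUND, Inf),
    lower_closed = c(TRUE, TRUE, FALSE),
    upper_closed = c(FALSE, TRUE, NA),
    median = unname(LEVEL_MEDIANS)
  )
}

#' Total daily protein intake in protein equivalents
#'
#' Sums enteral protein and parenteral amino acids for one day on diet,
#' converting amino acids to protein equivalents with the factor 0.83.
#' Exclusively oral days contribute no EN/PN intake and return 0.
#'
#' @param en_protein Enteral protein, g/kg. Non-negative.
#' @param pn_amino_acids Parenteral amino acids, g/kg. Non-negative.
#' @param oral_only Logical; day with exclusively oral intake.
#' @return Total protein-equivalent intake, g/kg. Vectorized.
#' @export
#' @examples
#' total_protein(0, 1.0)     # 0.83
#' total_protein(0.5, 0.6)   # 0.998
total_protein <- function(en_protein, pn_amino_acids, oral_only = FALSE) {
  if (any(en_protein < 0, na.rm = TRUE) || any(pn_amino_acids < 0, na.rm = TRUE)) {
    stop("negative intake values are not allowed", call. = FALSE)
  }
  n <- max(length(en_protein), length(pn_amino_acids), length(oral_only))
  en <- rep_len(en_protein, n)
  pn <- rep_len(pn_amino_acids, n)
  oo <- rep_len(as.logical(oral_only), n)
  out <- en + PN_TO_PROTEIN * pn
  out[oo] <- 0
  out
}

#' Classify a day's protein intake into level I/II/III
#'
#' @param total Total protein-equivalent intake, g/kg (see [total_protein()]).
#' @param oral_only Logical; exclusively oral days are level I by definition.
#' @return Factor with levels `I`, `II`, `III`. Vectorized.
#' @export
#' @examples
#' classify_intake(c(0.49, 0.8, 0.99, 1.2, 1.41))
classify_intake <- function(total, oral_only = FALSE) {
  if (any(total < 0, na.rm = TRUE)) {
    stop("negative intake values are not allowed", call. = FALSE)
  }
  n <- max(length(total), length(oral_only))
  total <- rep_len(total, n)
  oo <- rep_len(as.logical(oral_only), n)
  lev <- ifelse(total < LEVEL_LOW_BOUND, "I",
         ifelse(total <= LEVEL_HIGH_BOUND, "II", "III"))
  lev[oo] <- "I"
  factor(lev, levels = c("I", "II", "III"))
}

#' Build the 11-day intake trajectory for one patient
#'
#' Converts the recorded patient-days of one patient into the day-on-diet
#' trajectory the hazard model consumes. In `hospital` mode, days between a
#' live ICU discharge and day on diet #11 are imputed as standard-intake
#' (level II) days, because the hospital-outcome model needs intake on all
#' 11 days for patients still in hospital. In `icu` mode (the sensitivity
#' analysis on ICU outcomes) the trajectory is truncated at ICU discharge
#' and nothing is imputed. Days after death are never filled.
#'
#' @param diet_days Data frame with columns `day_index` (1..11),
#'   `en_protein`, `pn_amino_acids`, `oral_only` for one patient.
#' @param icu_discharge_day Day after ICU admission of live ICU discharge,
#'   or `NA` if the patient was not discharged alive from the ICU before the
#'   end of intake registration.
#' @param outcome One of `"hospital_death"`, `"live_discharge"`, `"censored"`.
#' @param outcome_time Event/censoring time in days after ICU admission.
#' @param mode `"hospital"` (impute after live ICU discharge) or `"icu"`
#'   (truncate, no imputation).
#' @return Data frame with columns `day_index`, `total_protein`, `level`,
#'   `imputed`, `mnt` (day with medical nutrition therapy).
#' @export
build_trajectory <- function(diet_days, icu_discharge_day, outcome, outcome_time,
                             mode = c("hospital", "icu")) {
  mode <- match.arg(mode)
  outcome <- match.arg(outcome, c("hospital_death", "live_discharge", "censored"))
  diet_days <- diet_days[order(diet_days$day_index), , drop = FALSE]
  rec_days <- diet_days$day_index

  # End of the window in which intake could have been registered.
  reg_end <- min(11, floor(outcome_time))
  if (!is.na(icu_discharge_day)) reg_end <- min(reg_end, floor(icu_discharge_day))
  if (length(rec_days)) {
    if (!identical(as.integer(rec_days), seq_len(length(rec_days)))) {
      stop("missing or non-contiguous days on diet before end of registration",
           call. = FALSE)
    }
    if (max(rec_days) < reg_end) {
      stop(sprintf("missing days on diet %d..%d before end of registration",
                   max(rec_days) + 1L, reg_end), call. = FALSE)
    }
  } else if (reg_end >= 1) {
    stop("no recorded days on diet", call. = FALSE)
  }

  total <- total_protein(diet_days$en_protein, diet_days$pn_amino_acids,
                         diet_days$oral_only)
  traj <- data.frame(
    day_index = diet_days$day_index,
    total_protein = total,
    level = classify_intake(total, diet_days$oral_only),
    imputed = FALSE,
    mnt = !diet_days$oral_only
  )

  # discharged alive from the ICU before the (hospital) outcome: intake after
  # ICU discharge is unknown and must be imputed in hospital mode, whatever
  # happens later in hospital (including death after day #11)
  discharged_alive_from_icu <- !is.na(icu_discharge_day) &&
    icu_discharge_day < outcome_time

  if (mode == "icu") {
    if (!is.na(icu_discharge_day)) {
      traj <- traj[traj$day_index <= floor(icu_discharge_day), , drop = FALSE]
    }
    return(traj)
  }

  # hospital mode: impute level-II days between live ICU discharge and day 11,
  # but never beyond death and only while the patient is still in follow-up.
  if (discharged_alive_from_icu) {
    last_needed <- min(11, floor(outcome_time))
    fill <- setdiff(seq_len(last_needed), traj$day_index)
    fill <- fill[fill > floor(icu_discharge_day)]
    if (length(fill)) {
      traj <- rbind(traj, data.frame(
        day_index = fill,
        total_protein = unname(LEVEL_MEDIANS["II"]),
        level = factor("II", levels = c("I", "II", "III")),
        imputed = TRUE,
        mnt = TRUE
      ))
      traj <- traj[order(traj$day_index), , drop = FALSE]
    }
  }
  rownames(traj) <- NULL
  traj
}
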