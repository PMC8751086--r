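# End-to-end orchestration: configuration, inclusion filtering, sensitivity
# and subgroup variants, artifact output with provenance.

#' Analysis configuration
#'
#' Single configuration object driving [run_analysis()]: data source
#' (in-memory cohort, two CSV paths, or a synthetic scenario), outcome set,
#' window geometry, cumulative-effect basis, subgroup, smoothing mode and
#' seed. Defaults reproduce the primary analysis (hospital outcomes,
#' dynamic window, phase basis, REML smoothing).
#'
#' @param cohort A `protein_cohort`, or `NULL` to simulate.
#' @param patients_csv,diet_days_csv Paths to the two-table CSV schema
#'   (admission table, patient-day table); used when `cohort` is `NULL`
#'   and both are given.
#' @param scenario Synthetic scenario (`"default"` or `"indication_bias"`)
#'   used when no data are supplied.
#' @param n_patients,n_icus Synthetic cohort size.
#' @param seed Integer seed for all randomness.
#' @param outcome_set `"hospital"` or `"icu"` (sensitivity analysis without
#'   post-ICU-discharge imputation).
#' @param window_mode `"dynamic"` or `"static"` (sensitivity analysis with
#'   lag 4 / lead 60).
#' @param basis_mode `"phase"` or `"surface"`.
#' @param subgroup `"all"`, `"bmi_gt_30"`, or calorie-intake strata
#'   `"calorie_low"` (< 30% of target), `"calorie_moderate"` (30--70%),
#'   `"calorie_high"` (> 70%); the fraction-of-target is an input column.
#' @param smoothing `"reml"` or `"fixed"` (bit-for-bit reproducible).
#' @param lambda Fixed/initial smoothing parameter(s).
#' @param grid_cuts Interval cut points (default daily, day 4 to 60).
#' @param confounders Include the confounder model? (Disabled only for
#'   reduced validation fits.)
#' @param outdir Output directory for artifacts, or `NULL` for none.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = NULL,
                            patients_csv = NULL, diet_days_csv = NULL,
                            scenario = "default",
                            n_patients = 500, n_icus = 20, seed = 1L,
                            outcome_set = c("hospital", "icu"),
                            window_mode = c("dynamic", "static"),
                            basis_mode = c("phase", "surface"),
                            subgroup = c("all", "bmi_gt_30", "calorie_low",
                                         "calorie_moderate", "calorie_high"),
                            smoothing = c("reml", "fixed"),
                            lambda = 10,
                            grid_cuts = 4:60,
                            confounders = TRUE,
                            outdir = NULL) {
  structure(list(
    cohort = cohort, patients_csv = patients_csv, diet_days_csv = diet_days_csv,
    scenario = scenario, n_patients = n_patients, n_icus = n_icus,
    seed = as.integer(seed),
    outcome_set = match.arg(outcome_set),
    window_mode = match.arg(window_mode),
    basis_mode = match.arg(basis_mode),
    subgroup = match.arg(subgroup),
    smoothing = match.arg(smoothing),
    lambda = lambda, grid_cuts = grid_cuts,
    confounders = isTRUE(confounders), outdir = outdir
  ), class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [analysis_config()].
#' @return An `analysis_config`.
#' @export
analysis_config_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  do.call(analysis_config, vals)
}

# FNV-1a hash of the serialized configuration, for artifact provenance.
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Apply the inclusion criteria with an exclusion tally
#'
#' Filters a cohort to patients who were at least 18 years old, had
#' BMI > 13 kg/m2 (strict), were treated in the ICU for at least 96 h, and
#' received medical nutrition therapy and mechanical ventilation on at
#' least one day during the first days on diet. Exclusions are tallied in
#' flow-chart order; a patient is counted under the first criterion that
#' excludes them.
#'
#' @param cohort A `protein_cohort` (or list with `patients`, `diet_days`).
#' @return List with the filtered `cohort`, the `tally` (named integer
#'   vector: `age`, `bmi`, `icu_96h`, `mnt_mv`), `n_in` and `n_kept`.
#' @export
apply_inclusion <- function(cohort) {
  p <- cohort$patients
  icu_days <- pmin(ifelse(is.na(p$icu_discharge_day), Inf, p$icu_discharge_day),
                   p$outcome_time)
  mnt_any <- if ("days_mnt" %in% names(p)) {
    p$days_mnt >= 1
  } else {
    dd <- cohort$diet_days
    early <- dd[dd$day_index <= 3 & !dd$oral_only &
                  (dd$en_protein + dd$pn_amino_acids) > 0, ]
    p$patient_id %in% early$patient_id
  }
  fail_age <- p$age < 18
  fail_bmi <- !fail_age & p$bmi <= 13
  fail_icu <- !fail_age & !fail_bmi & icu_days < 4
  fail_mnt <- !fail_age & !fail_bmi & !fail_icu & !(p$days_mv >= 1 & mnt_any)
  keep <- !(fail_age | fail_bmi | fail_icu | fail_mnt)
  kept <- p[keep, , drop = FALSE]
  out <- list(
    cohort = structure(list(
      patients = kept,
      diet_days = cohort$diet_days[cohort$diet_days$patient_id %in%
                                     kept$patient_id, , drop = FALSE],
      config = cohort$config
    ), class = "protein_cohort"),
    tally = c(age = sum(fail_age), bmi = sum(fail_bmi),
              icu_96h = sum(fail_icu), mnt_mv = sum(fail_mnt)),
    n_in = nrow(p), n_kept = nrow(kept)
  )
  out
}

subgroup_filter <- function(cohort, subgroup) {
  p <- cohort$patients
  keep <- switch(subgroup,
    all = rep(TRUE, nrow(p)),
    bmi_gt_30 = p$bmi > 30,
    calorie_low = p$calorie_fraction < 0.3,
    calorie_moderate = p$calorie_fraction >= 0.3 & p$calorie_fraction <= 0.7,
    calorie_high = p$calorie_fraction > 0.7
  )
  if (subgroup != "all" && !"calorie_fraction" %in% names(p) &&
      startsWith(subgroup, "calorie")) {
    stop("calorie subgroup requires a `calorie_fraction` column", call. = FALSE)
  }
  kept <- p[keep, , drop = FALSE]
  structure(list(
    patients = kept,
    diet_days = cohort$diet_days[cohort$diet_days$patient_id %in%
                                   kept$patient_id, , drop = FALSE],
    config = cohort$config
  ), class = "protein_cohort")
}

#' Run the end-to-end analysis
#'
#' Loads or simulates the cohort, applies the inclusion filter and subgroup
#' selection, builds the PED with the configured window and basis, fits
#' both cause-specific hazard models, and computes the six pairwise diet
#' hazard-ratio curves and the cumulative incidence functions for every
#' resolved diet of every comparison. Deterministic given the seed (bit for
#' bit in fixed-smoothing mode). If `config$outdir` is set, all artifacts
#' are written there with the configuration hash in a structured log.
#'
#' @param config An [analysis_config()].
#' @return Object of class `pamm_analysis`: `config`, `hash`, `inclusion`
#'   (tally), `n_patients`, `fits` (death, discharge), `hr_curves` (one
#'   long data frame, 6 comparisons x 2 causes), `cifs` (long data frame
#'   per comparison and diet role), `log` (character).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  hash <- config_hash(config[setdiff(names(config), "cohort")])
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  say("config hash %s", hash)
  set.seed(config$seed)

  cohort <- config$cohort
  if (is.null(cohort) && !is.null(config$patients_csv)) {
    cohort <- read_cohort_csv(config$patients_csv, config$diet_days_csv)
    say("read cohort from %s (%d patients)", config$patients_csv,
        nrow(cohort$patients))
  }
  if (is.null(cohort)) {
    cohort <- simulate_cohort(sim_config(n_patients = config$n_patients,
                                         n_icus = config$n_icus,
                                         seed = config$seed,
                                         scenario = config$scenario,
                                         window_mode = config$window_mode))
    say("simulated scenario '%s' cohort of %d patients (seed %d)",
        config$scenario, config$n_patients, config$seed)
  }

  incl <- apply_inclusion(cohort)
  say("inclusion: kept %d of %d (excluded: %s)", incl$n_kept, incl$n_in,
      paste(names(incl$tally), incl$tally, sep = "=", collapse = ", "))
  cohort <- subgroup_filter(incl$cohort, config$subgroup)
  say("subgroup '%s': %d patients", config$subgroup, nrow(cohort$patients))
  if (nrow(cohort$patients) == 0) {
    stop("no patients remain after inclusion/subgroup filtering", call. = FALSE)
  }

  grid <- interval_grid(config$grid_cuts)
  ped <- make_ped(cohort, grid, outcome_set = config$outcome_set,
                  window_mode = config$window_mode,
                  basis_mode = config$basis_mode)
  say("PED: %d rows, %d deaths, %d discharges", nrow(ped),
      sum(ped$death), sum(ped$discharge))

  mk_spec <- function(cause) {
    if (config$confounders) {
      model_spec(cause = cause,
                 smoothing = config$smoothing, lambda = config$lambda)
    } else {
      model_spec(cause = cause, smooth_confounders = character(0),
                 factor_confounders = character(0),
                 linear_confounders = character(0),
                 smoothing = config$smoothing, lambda = config$lambda)
    }
  }
  fits <- list(death = fit_pamm(ped, mk_spec("death")),
               discharge = fit_pamm(ped, mk_spec("discharge")))
  say("fitted death model: edf %.1f; discharge model: edf %.1f",
      fits$death$edf_total, fits$discharge$edf_total)

  comparisons <- make_comparisons()
  hr_curves <- do.call(rbind, unlist(lapply(comparisons, function(cmp) {
    lapply(fits, function(f) hr_curve(f, cmp))
  }), recursive = FALSE))
  rownames(hr_curves) <- NULL

  cifs <- do.call(rbind, lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    rbind(
      cbind(comparison = nm, diet = cmp$ref_name,
            cif_curve(fits$death, fits$discharge, cmp$ref)),
      cbind(comparison = nm, diet = cmp$alt_name,
            cif_curve(fits$death, fits$discharge, cmp$alt))
    )
  }))
  rownames(cifs) <- NULL

  res <- structure(list(
    config = config, hash = hash, inclusion = incl$tally,
    n_patients = nrow(cohort$patients),
    fits = fits, hr_curves = hr_curves, cifs = cifs, log = log
  ), class = "pamm_analysis")

  if (!is.null(config$outdir)) write_analysis(res, config$outdir)
  res
}

write_analysis <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tag <- res$hash
  utils::write.csv(res$hr_curves,
                   file.path(outdir, sprintf("hr_curves_%s.csv", tag)),
                   row.names = FALSE)
  utils::write.csv(res$cifs,
                   file.path(outdir, sprintf("cifs_%s.csv", tag)),
                   row.names = FALSE)
  write_pamm_json(res$fits$death,
                  file.path(outdir, sprintf("model_death_%s.json", tag)))
  write_pamm_json(res$fits$discharge,
                  file.path(outdir, sprintf("model_discharge_%s.json", tag)))
  writeLines(jsonlite::toJSON(
    list(hash = res$hash, log = res$log, inclusion = as.list(res$inclusion)),
    auto_unbox = TRUE, pretty = TRUE),
    file.path(outdir, sprintf("log_%s.json", tag)))
  invisible(outdir)
}

#' @export
print.pamm_analysis <- function(x, ...) {
  cat("<pamm_analysis>", x$n_patients, "patients | hash", x$hash, "\n")
  cat("  outcome set:", x$config$outcome_set,
      "| window:", x$config$window_mode,
      "| basis:", x$config$basis_mode,
      "| subgroup:", x$config$subgroup, "\n")
  cat("  HR curves:", nrow(x$hr_curves), "rows;",
      "CIFs:", nrow(x$cifs), "rows\n")
  invisible(x)
}

#' Write / read the two-table cohort CSV schema
#'
#' The admission table has one row per patient (ids, APACHE II, age, sex,
#' BMI, admission and diagnosis category, survey year, first-3-day therapy
#' counts, ICU discharge day, outcome and outcome time); the patient-day
#' table has one row per recorded day on diet (EN protein and PN amino
#' acids in g/kg, oral-only flag). Schema version `protein-cohort-1`.
#'
#' @param cohort A `protein_cohort`.
#' @param patients_path,diet_days_path CSV paths.
#' @return Paths (write) or a `protein_cohort` (read).
#' @export
write_cohort_csv <- function(cohort, patients_path, diet_days_path) {
  utils::write.csv(cohort$patients, patients_path, row.names = FALSE)
  utils::write.csv(cohort$diet_days, diet_days_path, row.names = FALSE)
  invisible(c(patients_path, diet_days_path))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(patients_path, diet_days_path) {
  patients <- utils::read.csv(patients_path)
  diet_days <- utils::read.csv(diet_days_path)
  need_p <- c("patient_id", "icu_id", "apache2", "age", "bmi", "sex",
              "admission_category", "diagnosis", "year", "days_mv",
              "days_pn", "days_oral", "days_propofol",
              "icu_discharge_day", "outcome", "outcome_time")
  need_d <- c("patient_id", "day_index", "en_protein", "pn_amino_acids",
              "oral_only")
  miss <- c(setdiff(need_p, names(patients)), setdiff(need_d, names(diet_days)))
  if (length(miss)) {
    stop(sprintf("cohort CSV schema violation; missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!(diet_days$en_protein >= 0 & diet_days$pn_amino_acids >= 0))
  if (length(bad)) {
    stop(sprintf("malformed patient-day rows (negative intake): rows %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  structure(list(patients = patients, diet_days = diet_days, config = NULL),
            class = "protein_cohort")
}
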