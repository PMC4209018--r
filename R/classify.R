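#' Evaluate the four CDS components on check-up records
#'
#' Adds one logical column per component (`comp_overweight`,
#' `comp_hypertension`, `comp_dyslipidemia`, `comp_hyperglycemia`) and a
#' completeness flag. A record is complete when BMI, SBP, DBP, TG, HDL and
#' FPG are all non-missing; the 2-h post-meal glucose is optional and only
#' contributes when present. Prior-diagnosis flags for hypertension and
#' hyperglycemia are each sufficient alone for their component.
#'
#' @param records Data frame with the cohort schema (see
#'   [cohort_schema()]).
#' @param cuts A [cds_thresholds()] object.
#' @return `records` as a tibble with component columns, `n_components`
#'   and `complete` added. Component columns are `NA` for incomplete
#'   records.
#' @export
evaluate_components <- function(records, cuts = cds_thresholds()) {
  stopifnot(inherits(cuts, "cds_thresholds"))
  records <- tibble::as_tibble(records)
  needed <- c("bmi", "sbp", "dbp", "tg", "hdl", "fpg")
  missing_cols <- setdiff(c(needed, "dx_hypertension", "dx_hyperglycemia"),
                          names(records))
  if (length(missing_cols) > 0) {
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"pg2h" %in% names(records)) records$pg2h <- NA_real_

  complete <- !Reduce(`|`, lapply(records[needed], is.na))

  pg_hit <- !is.na(records$pg2h) & records$pg2h >= cuts$pg2h
  out <- dplyr::mutate(
    records,
    complete = complete,
    comp_overweight    = .data$bmi >= cuts$bmi,
    comp_hypertension  = .data$sbp >= cuts$sbp | .data$dbp >= cuts$dbp |
      as.logical(.data$dx_hypertension),
    comp_dyslipidemia  = .data$tg >= cuts$tg | .data$hdl < cuts$hdl,
    comp_hyperglycemia = .data$fpg >= cuts$fpg | pg_hit |
      as.logical(.data$dx_hyperglycemia)
  )
  comp_cols <- paste0("comp_", ms_components())
  out[!out$complete, comp_cols] <- NA
  out$n_components <- rowSums(out[comp_cols])
  out
}

#' Map a component profile to a metabolic state
#'
#' Zero components map to `no_component`; exactly one maps to the matching
#' isolated state; exactly two to `two_component`; three or four to `ms`.
#' The function is total over the 16 possible profiles.
#'
#' @param overweight,hypertension,dyslipidemia,hyperglycemia Logical
#'   vectors (recycled to a common length) giving component presence.
#' @return Character vector of state names (see [ms_states()]); `NA` where
#'   any input component is `NA`.
#' @export
#' @examples
#' assign_state(FALSE, FALSE, FALSE, FALSE)
#' assign_state(TRUE, FALSE, TRUE, FALSE)   # any 2 components
#' assign_state(TRUE, TRUE, TRUE, FALSE)    # >= 3 components = MS
assign_state <- function(overweight, hypertension, dyslipidemia,
                         hyperglycemia) {
  prof <- cbind(overweight, hypertension, dyslipidemia, hyperglycemia)
  n <- rowSums(prof)
  states <- ms_states()
  out <- rep(NA_character_, nrow(prof))
  out[n == 0] <- states[1]
  one <- which(n == 1)
  if (length(one) > 0) {
    # isolated states follow component order: columns 1..4 -> states 2..5
    out[one] <- states[1 + max.col(prof[one, , drop = FALSE])]
  }
  out[n == 2] <- states[6]
  out[n >= 3] <- states[7]
  out
}

#' Remove excluded subjects and log the reasons
#'
#' Mirrors the study's sample-selection rules: a subject is removed
#' entirely (all visits) when any visit carries a history of coronary heart
#' disease, type-1 diabetes or familial hyperlipidemia, when any visit is
#' missing a mandatory measurement, or when any visit has age below 18.
#'
#' @param records Cohort data frame (see [cohort_schema()]).
#' @return List with `records` (the retained tibble) and `log` (a tibble
#'   with one row per exclusion reason: `reason`, `n_subjects`).
#' @export
apply_exclusions <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(list(records = records,
                log = tibble::tibble(reason = character(),
                                     n_subjects = integer())))
  }
  mand <- c("bmi", "sbp", "dbp", "tg", "hdl", "fpg")
  flag_subjects <- function(bad_row) unique(records$subject_id[bad_row])

  excl <- list(
    history_chd          = flag_subjects(as.logical(records$hx_chd) %in% TRUE),
    history_t1dm         = flag_subjects(as.logical(records$hx_t1dm) %in% TRUE),
    history_fam_hyperlip = flag_subjects(
      as.logical(records$hx_fam_hyperlipidemia) %in% TRUE),
    incomplete_information = flag_subjects(
      Reduce(`|`, lapply(records[mand], is.na))),
    age_below_18         = flag_subjects((records$age < 18) %in% TRUE)
  )
  # attribute each subject to the first reason that applies
  seen <- character(0)
  log <- tibble::tibble(reason = names(excl),
                        n_subjects = vapply(names(excl), function(r) {
                          new <- setdiff(excl[[r]], seen)
                          seen <<- union(seen, excl[[r]])
                          length(new)
                        }, integer(1), USE.NAMES = FALSE))
  keep <- !(records$subject_id %in% seen)
  list(records = records[keep, ], log = log)
}

#' Classify a cohort into metabolic states and strata
#'
#' Runs the full classification stage: exclusions, component evaluation,
#' state assignment, and sex/age stratification. Follow-up year is derived
#' per subject as `visit_year` minus the subject's first (baseline) year.
#'
#' @param records Cohort data frame (see [cohort_schema()]).
#' @param cuts A [cds_thresholds()] object.
#' @return List with `records` (classified tibble, gaining `complete`,
#'   component flags, `n_components`, `state`, `state_index`, `age_group`,
#'   `stratum`, `follow_up`) and `exclusion_log`.
#' @export
classify_cohort <- function(records, cuts = cds_thresholds()) {
  filtered <- apply_exclusions(records)
  out <- evaluate_components(filtered$records, cuts)
  if (nrow(out) > 0) {
    out$state <- assign_state(out$comp_overweight, out$comp_hypertension,
                              out$comp_dyslipidemia, out$comp_hyperglycemia)
    out$state_index <- state_index(out$state)
    out$age_group <- assign_age_group(out$age)
    out$stratum <- stratum_label(out$sex, out$age_group)
    out <- out |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::mutate(follow_up = .data$visit_year - min(.data$visit_year)) |>
      dplyr::ungroup()
  } else {
    out$state <- character(0)
    out$state_index <- integer(0)
    out$age_group <- character(0)
    out$stratum <- character(0)
    out$follow_up <- integer(0)
  }
  list(records = out, exclusion_log = filtered$log)
}

#' Cohort CSV schema
#'
#' @return Tibble describing the column names and types of the cohort CSV
#'   exchanged between the simulator and the classifier.
#' @export
cohort_schema <- function() {
  tibble::tribble(
    ~column,                 ~type,      ~description,
    "subject_id",            "character", "unique subject identifier",
    "visit_year",            "integer",   "calendar year of the check-up",
    "age",                   "numeric",   "age in years at the visit",
    "sex",                   "character", "M or F",
    "bmi",                   "numeric",   "body-mass index, kg/m^2",
    "sbp",                   "numeric",   "systolic blood pressure, mmHg",
    "dbp",                   "numeric",   "diastolic blood pressure, mmHg",
    "tg",                    "numeric",   "fasting triglyceride, mmol/L",
    "hdl",                   "numeric",   "HDL cholesterol, mmol/L",
    "fpg",                   "numeric",   "fasting plasma glucose, mmol/L",
    "pg2h",                  "numeric",   "2-h post-meal glucose, mmol/L (optional)",
    "dx_hypertension",       "integer",   "prior hypertension diagnosis (0/1)",
    "dx_hyperglycemia",      "integer",   "prior hyperglycemia diagnosis (0/1)",
    "hx_chd",                "integer",   "history of coronary heart disease (0/1)",
    "hx_t1dm",               "integer",   "history of type-1 diabetes (0/1)",
    "hx_fam_hyperlipidemia", "integer",   "history of familial hyperlipidemia (0/1)"
  )
}
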