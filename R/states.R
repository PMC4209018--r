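#' The 7-state metabolic state space
#'
#' The model classifies every check-up into exactly one of seven mutually
#' exclusive, collectively exhaustive states built from the four CDS risk
#' components (overweight/obesity, hypertension, dyslipidemia,
#' hyperglycemia): no component, four isolated single-component states, an
#' any-2-component state, and metabolic syndrome (MS, >= 3 components).
#' The order returned here is the fixed row/column order used by every
#' transition matrix and occupancy vector in the package.
#'
#' @return Character vector of the 7 state names, in canonical index order.
#' @export
#' @examples
#' ms_states()
ms_states <- function() {
  c("no_component",
    "iso_overweight",
    "iso_hypertension",
    "iso_dyslipidemia",
    "iso_hyperglycemia",
    "two_component",
    "ms")
}

#' Human-readable state labels
#'
#' @return Named character vector mapping state names to display labels.
#' @export
ms_state_labels <- function() {
  c(no_component      = "No component",
    iso_overweight    = "Isolated overweight or obesity",
    iso_hypertension  = "Isolated hypertension",
    iso_dyslipidemia  = "Isolated dyslipidemia",
    iso_hyperglycemia = "Isolated hyperglycemia",
    two_component     = "2 components",
    ms                = "MS")
}

#' The four metabolic risk components
#'
#' @return Character vector of component names, in the order used by
#'   component-profile columns (`comp_overweight`, `comp_hypertension`,
#'   `comp_dyslipidemia`, `comp_hyperglycemia`).
#' @export
ms_components <- function() {
  c("overweight", "hypertension", "dyslipidemia", "hyperglycemia")
}

#' Sex by age-group strata
#'
#' Transition matrices are estimated separately within 8 strata: two sexes
#' crossed with four age groups. Age groups partition \[18, Inf) as
#' \[18,40), \[40,50), \[50,60), \[60,Inf); the half-open convention gives a
#' single-valued mapping at the overlapping printed boundaries.
#'
#' @return Character vector of the 4 age-group labels.
#' @export
ms_age_groups <- function() {
  c("18_40", "40_49", "50_59", "60plus")
}

#' Map age in years to its age group
#'
#' @param age Numeric vector of ages in years.
#' @return Character vector of age-group labels; `NA` for ages below 18.
#' @export
#' @examples
#' assign_age_group(c(39.9, 40, 60, 17))
assign_age_group <- function(age) {
  stopifnot(is.numeric(age))
  cut(age,
      breaks = c(18, 40, 50, 60, Inf),
      labels = ms_age_groups(),
      right = FALSE) |>
    as.character()
}

#' Stratum labels
#'
#' @param sex Character vector, "M" or "F".
#' @param age_group Character vector of age-group labels (see
#'   [ms_age_groups()]).
#' @return Character stratum labels such as `"men_18_40"`; `NA` where either
#'   input is `NA`.
#' @export
stratum_label <- function(sex, age_group) {
  stopifnot(all(sex %in% c("M", "F") | is.na(sex)))
  bad <- !(age_group %in% ms_age_groups() | is.na(age_group))
  if (any(bad)) {
    stop("unknown age group(s): ", paste(unique(age_group[bad]), collapse = ", "))
  }
  out <- ifelse(sex == "M", "men", "women")
  out <- paste(out, age_group, sep = "_")
  out[is.na(sex) | is.na(age_group)] <- NA_character_
  out
}

#' All 8 stratum labels in canonical order
#'
#' @return Character vector of stratum labels, youngest age group first,
#'   men before women within each age group (the order the stratum tables
#'   are conventionally presented in).
#' @export
ms_strata <- function() {
  as.vector(outer(c("men", "women"), ms_age_groups(), paste, sep = "_"))
}

# internal: integer index of a state name (1-based), with validation
state_index <- function(state) {
  idx <- match(state, ms_states())
  if (anyNA(idx)) {
    stop("unknown state(s): ", paste(unique(state[is.na(idx)]), collapse = ", "))
  }
  idx
}
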