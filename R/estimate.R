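# Estimation of annual transition matrices: tabulate state transitions
# between consecutive calendar years within each sex/age stratum, convert
# to row-conditional incidence-rate matrices, and average the year-pair
# matrices into one annual transition matrix per stratum.

#' Extract consecutive-year transition events
#'
#' For every subject, each pair of visits in adjacent calendar years
#' (y, y+1) yields one event; visits separated by a gap of more than one
#' year contribute no event across the gap. The stratum of an event is, by
#' default, determined by the subject's age in the first year of the pair
#' ("per-pair" mode); `"baseline"` mode freezes the stratum at the
#' subject's first visit instead.
#'
#' @param classified Classified cohort tibble from [classify_cohort()].
#' @param stratum_mode `"per_pair"` (default) or `"baseline"`.
#' @return Tibble of events: `subject_id`, `stratum`, `year_from`,
#'   `state_from`, `state_to`.
#' @export
pair_consecutive_visits <- function(classified,
                                    stratum_mode = c("per_pair", "baseline")) {
  stratum_mode <- match.arg(stratum_mode)
  df <- tibble::as_tibble(classified)
  if (nrow(df) == 0) {
    return(tibble::tibble(subject_id = character(), stratum = character(),
                          year_from = integer(), state_from = character(),
                          state_to = character()))
  }
  dup <- df |>
    dplyr::count(.data$subject_id, .data$visit_year) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate subject-year rows for subject(s): ",
         paste(utils::head(unique(dup$subject_id), 5), collapse = ", "))
  }
  df <- df |>
    dplyr::arrange(.data$subject_id, .data$visit_year) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(
      next_year = dplyr::lead(.data$visit_year),
      state_to = dplyr::lead(.data$state),
      baseline_stratum = .data$stratum[1]
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$next_year),
                  .data$next_year == .data$visit_year + 1L)
  tibble::tibble(
    subject_id = df$subject_id,
    stratum = if (stratum_mode == "per_pair") df$stratum
              else df$baseline_stratum,
    year_from = as.integer(df$visit_year),
    state_from = df$state,
    state_to = df$state_to
  )
}

#' Tabulate transition counts per stratum and year-pair
#'
#' @param events Tibble from [pair_consecutive_visits()].
#' @return Tibble with one row per (stratum, year_from): `stratum`,
#'   `year_from`, and a list-column `counts` of 7x7 integer matrices
#'   n(i -> j).
#' @export
count_transitions <- function(events) {
  states <- ms_states()
  tab <- function(from, to) {
    m <- table(factor(from, levels = states), factor(to, levels = states))
    matrix(as.integer(m), 7, 7, dimnames = list(states, states))
  }
  events |>
    dplyr::group_by(.data$stratum, .data$year_from) |>
    dplyr::summarise(counts = list(tab(.data$state_from, .data$state_to)),
                     n_events = dplyr::n(), .groups = "drop")
}

#' Convert a count matrix to an annual incidence-rate matrix (percent)
#'
#' rate(i -> j) = 100 * n(i -> j) / n(i) for rows with n(i) > 0; rows with
#' no observed starting state are returned as `NA` (unobserved), never
#' zero-filled.
#'
#' @param counts 7x7 integer count matrix.
#' @return 7x7 numeric matrix in percent with `NA` rows where n(i) = 0.
#' @export
annual_rate_matrix <- function(counts) {
  stopifnot(all(dim(counts) == c(7, 7)), all(counts >= 0, na.rm = TRUE))
  n_i <- rowSums(counts)
  rate <- 100 * counts / n_i
  rate[n_i == 0, ] <- NA_real_
  dimnames(rate) <- list(ms_states(), ms_states())
  rate
}

#' Average year-pair incidence-rate matrices into one annual matrix
#'
#' Cell-wise unweighted mean over the year-pairs in which the row's
#' starting state was observed (the primary estimator); rows are
#' renormalized to sum to 100 afterwards. `"pooled"` mode instead pools
#' counts across year-pairs before conditioning, as a sensitivity
#' alternative; the two coincide when row denominators are equal across
#' year-pairs.
#'
#' @param rate_matrices List of 7x7 percent matrices (with possible `NA`
#'   rows) from [annual_rate_matrix()]. Required for `"unweighted"`.
#' @param count_matrices List of 7x7 count matrices (same year-pair order);
#'   required for `"pooled"`.
#' @param stratum Optional stratum label attached to the result.
#' @param mode `"unweighted"` (default) or `"pooled"`.
#' @return A [ms_tmatrix()] with provenance `"estimated"`; rows never
#'   observed in any year-pair are `NA`, and the per-row number of
#'   contributing year-pairs is recorded in the `n_pairs` attribute.
#' @export
average_annual_matrices <- function(rate_matrices = NULL,
                                    count_matrices = NULL,
                                    stratum = NULL,
                                    mode = c("unweighted", "pooled")) {
  mode <- match.arg(mode)
  if (mode == "unweighted") {
    stopifnot(length(rate_matrices) >= 1)
    arr <- array(unlist(rate_matrices),
                 dim = c(7, 7, length(rate_matrices)))
    mean_mat <- apply(arr, c(1, 2), mean, na.rm = TRUE)
    mean_mat[is.nan(mean_mat)] <- NA_real_
    # a row is fully NA or fully observed within a year-pair, so one
    # column suffices to count contributing year-pairs
    n_pairs <- rowSums(!is.na(arr[, 1, , drop = FALSE]), dims = 1)
  } else {
    stopifnot(length(count_matrices) >= 1)
    pooled <- Reduce(`+`, count_matrices)
    mean_mat <- annual_rate_matrix(pooled)
    n_pairs <- vapply(seq_len(7), function(i) {
      sum(vapply(count_matrices, function(m) sum(m[i, ]) > 0, logical(1)))
    }, integer(1))
  }
  observed <- !apply(mean_mat, 1, function(r) all(is.na(r)))
  out <- mean_mat
  out[observed, ] <- 100 * out[observed, , drop = FALSE] /
    rowSums(out[observed, , drop = FALSE])
  ms_tmatrix(out, stratum = stratum, provenance = "estimated",
             n_pairs = stats::setNames(as.integer(n_pairs), ms_states()))
}

#' Estimate per-stratum annual transition matrices from a classified cohort
#'
#' The full estimation stage: consecutive-year events, per-year-pair
#' counts and incidence rates, then the across-year-pair average, for every
#' stratum present in the data.
#'
#' @inheritParams pair_consecutive_visits
#' @param averaging `"unweighted"` (mean of year-pair rates, the primary
#'   estimator) or `"pooled"` (count-weighted).
#' @return Named list of [ms_tmatrix()] keyed by stratum label, with a
#'   `counts` attribute holding the per-(stratum, year-pair) count tibble.
#' @export
estimate_transition_matrices <- function(classified,
                                         stratum_mode = c("per_pair",
                                                          "baseline"),
                                         averaging = c("unweighted",
                                                       "pooled")) {
  stratum_mode <- match.arg(stratum_mode)
  averaging <- match.arg(averaging)
  events <- pair_consecutive_visits(classified, stratum_mode)
  counted <- count_transitions(events)
  strata <- sort(unique(counted$stratum))
  out <- lapply(strata, function(st) {
    rows <- counted[counted$stratum == st, ]
    average_annual_matrices(
      rate_matrices = lapply(rows$counts, annual_rate_matrix),
      count_matrices = rows$counts,
      stratum = st, mode = averaging)
  })
  names(out) <- strata
  attr(out, "counts") <- counted
  out
}

#' Descriptive summary per follow-up year
#'
#' Cohort size, mean age, percent male, and the prevalence (%) of each
#' component and of MS, by follow-up year (0 = each subject's first
#' enrolled year).
#'
#' @param classified Classified cohort tibble from [classify_cohort()].
#' @return Tibble with one row per follow-up year.
#' @export
descriptive_summary <- function(classified) {
  df <- tibble::as_tibble(classified)
  if (nrow(df) == 0) {
    return(tibble::tibble(follow_up = integer(), n = integer(),
                          mean_age = numeric(), pct_male = numeric(),
                          pct_overweight = numeric(),
                          pct_hypertension = numeric(),
                          pct_dyslipidemia = numeric(),
                          pct_hyperglycemia = numeric(), pct_ms = numeric()))
  }
  df |>
    dplyr::group_by(follow_up = .data$follow_up) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_age = mean(.data$age),
      pct_male = 100 * mean(.data$sex == "M"),
      pct_overweight = 100 * mean(.data$comp_overweight),
      pct_hypertension = 100 * mean(.data$comp_hypertension),
      pct_dyslipidemia = 100 * mean(.data$comp_dyslipidemia),
      pct_hyperglycemia = 100 * mean(.data$comp_hyperglycemia),
      pct_ms = 100 * mean(.data$state == "ms"),
      .groups = "drop") |>
    dplyr::arrange(.data$follow_up)
}
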