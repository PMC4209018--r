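# Occupancy projection through an annual transition matrix, its
# microsimulation oracle, and validation against observed prevalence.

# resolve a starting specification into a length-7 occupancy vector
as_occupancy <- function(start) {
  if (is.character(start)) {
    v <- rep(0, 7)
    v[state_index(start)] <- 1
  } else {
    v <- as.numeric(start)
    if (length(v) != 7 || any(v < 0) || abs(sum(v) - 1) > 1e-9) {
      stop("start must be a state name or a length-7 occupancy vector ",
           "summing to 1")
    }
  }
  stats::setNames(v, ms_states())
}

#' Project state occupancy through annual Markov cycles
#'
#' Propagates an occupancy vector pi through pi_{t+1} = pi_t P, where P is
#' the annual transition matrix (entries percent/100), for `cycles` annual
#' steps. The chain is time-homogeneous: the same matrix is applied at
#' every cycle, and no age-group migration occurs during projection.
#'
#' @param m A [ms_tmatrix()].
#' @param start A state name (unit starting vector) or a length-7
#'   occupancy vector summing to 1.
#' @param cycles Number of annual cycles (>= 0).
#' @param renormalize If `TRUE` (default), rows are rescaled to sum to
#'   exactly 100 before propagation, which keeps occupancy conserved to
#'   1e-9 over many cycles. Use `FALSE` to read printed table rows back
#'   verbatim in a one-cycle projection.
#' @return An `ms_trajectory`: a `(cycles+1) x 7` matrix of occupancies
#'   (rows = cycles 0..T), with `start` and matrix metadata attached.
#' @export
#' @examples
#' m <- fixture_matrix("men_18_40")
#' tr <- project(m, "no_component", 10)
#' round(100 * tr[, "ms"], 2) # percent in MS at each cycle
project <- function(m, start, cycles = 10, renormalize = TRUE) {
  stopifnot(inherits(m, "ms_tmatrix"))
  if (!is.numeric(cycles) || length(cycles) != 1 || cycles < 0) {
    stop("cycles must be a single non-negative number")
  }
  cycles <- as.integer(cycles)
  pi0 <- as_occupancy(start)
  if (renormalize) m <- renormalize_rows(m)
  P <- unclass(m) / 100
  obs <- observed_rows(m)
  P[!obs, ] <- 0  # guarded below: never reached with positive probability

  out <- matrix(0, cycles + 1, 7, dimnames = list(0:cycles, ms_states()))
  out[1, ] <- pi0
  pi_t <- pi0
  for (t in seq_len(cycles)) {
    bad <- !obs & pi_t > 1e-15
    if (any(bad)) {
      stop("projection reaches unobserved row(s) with positive ",
           "probability at cycle ", t, ": ",
           paste(ms_states()[bad], collapse = ", "))
    }
    pi_t <- as.vector(pi_t %*% P)
    out[t + 1, ] <- pi_t
  }
  structure(out, class = c("ms_trajectory", "matrix", "array"),
            start = start, stratum = attr(m, "stratum"),
            provenance = attr(m, "provenance"))
}

#' @export
print.ms_trajectory <- function(x, digits = 4, ...) {
  cat(sprintf("Occupancy trajectory%s, %d cycles, start: %s\n",
              if (!is.null(attr(x, "stratum")))
                paste0(" [", attr(x, "stratum"), "]") else "",
              nrow(x) - 1,
              paste(format(attr(x, "start")), collapse = " ")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Trajectories from every starting state
#'
#' One projection per starting state (all 7 by default; the published
#' figures plot the 6 non-MS starts).
#'
#' @param m A [ms_tmatrix()].
#' @param horizon Number of annual cycles.
#' @param states Starting states (character vector).
#' @param renormalize Passed to [project()].
#' @return Named list of `ms_trajectory`, keyed by starting state.
#' @export
predict_by_initial_state <- function(m, horizon = 10,
                                     states = ms_states(),
                                     renormalize = TRUE) {
  out <- lapply(states, function(s) project(m, s, horizon, renormalize))
  names(out) <- states
  out
}

#' Tidy a set of trajectories
#'
#' @param trajectories Named list from [predict_by_initial_state()], or a
#'   single `ms_trajectory`.
#' @return Tidy tibble: `stratum`, `start_state`, `cycle`, `state`,
#'   `occupancy` (fraction).
#' @export
trajectories_tidy <- function(trajectories) {
  if (inherits(trajectories, "ms_trajectory")) {
    trajectories <- list(trajectories)
    names(trajectories) <- paste(attr(trajectories[[1]], "start"),
                                 collapse = "+")
  }
  dplyr::bind_rows(lapply(names(trajectories), function(s) {
    tr <- trajectories[[s]]
    tibble::tibble(
      stratum = attr(tr, "stratum") %||% NA_character_,
      start_state = s,
      cycle = rep(0:(nrow(tr) - 1), times = 7),
      state = rep(colnames(tr), each = nrow(tr)),
      occupancy = as.vector(unclass(tr))
    )
  }))
}

#' Plot MS occupancy against cycle for each starting state
#'
#' @param trajectories Named list from [predict_by_initial_state()].
#' @param percent Plot occupancy in percent (default) rather than as a
#'   fraction.
#' @return A ggplot object.
#' @export
plot_ms_trajectories <- function(trajectories, percent = TRUE) {
  tidy <- trajectories_tidy(trajectories) |>
    dplyr::filter(.data$state == "ms")
  if (percent) tidy$occupancy <- 100 * tidy$occupancy
  labs <- ms_state_labels()
  tidy$start_state <- factor(labs[tidy$start_state],
                             levels = unname(labs))
  ggplot2::ggplot(tidy, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                     colour = .data$start_state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Years from start",
                  y = if (percent) "MS occupancy (%)" else "MS occupancy",
                  colour = "Starting state",
                  title = attr(trajectories[[1]], "stratum")) +
    ggplot2::theme_minimal()
}

#' Microsimulation oracle for occupancy projection
#'
#' Steps `n` independent subjects through the chain and reports the
#' empirical state distribution at every cycle. This is a brute-force
#' counterpart to [project()], used to cross-check the matrix-power
#' propagation within Monte-Carlo error.
#'
#' @param m A [ms_tmatrix()].
#' @param start Starting state name or occupancy vector.
#' @param cycles Number of annual cycles.
#' @param n Number of simulated chains.
#' @param seed Optional integer seed.
#' @return `(cycles+1) x 7` matrix of empirical occupancies.
#' @export
microsimulation_oracle <- function(m, start, cycles = 10, n = 100000,
                                   seed = NULL) {
  stopifnot(inherits(m, "ms_tmatrix"))
  if (!is.null(seed)) set.seed(seed)
  P <- unclass(renormalize_rows(m)) / 100
  pi0 <- as_occupancy(start)
  cur <- sample.int(7, n, replace = TRUE, prob = pi0)
  out <- matrix(0, cycles + 1, 7, dimnames = list(0:cycles, ms_states()))
  out[1, ] <- tabulate(cur, 7) / n
  for (t in seq_len(cycles)) {
    nxt <- integer(n)
    for (i in 1:7) {
      idx <- which(cur == i)
      if (length(idx) > 0) {
        if (all(is.na(P[i, ]))) {
          stop("microsimulation reaches unobserved row: ", ms_states()[i])
        }
        nxt[idx] <- sample.int(7, length(idx), replace = TRUE, prob = P[i, ])
      }
    }
    cur <- nxt
    out[t + 1, ] <- tabulate(cur, 7) / n
  }
  out
}

#' Validate projected MS prevalence against the observed cohort
#'
#' For each stratum, projects the stratum's baseline occupancy forward
#' `horizon` cycles under the estimated (or supplied) matrix, and compares
#' the projected MS occupancy with the observed MS prevalence among the
#' subjects actually seen at that follow-up year. The report is
#' descriptive; no pass/fail threshold is applied.
#'
#' @param matrices Named list of [ms_tmatrix()] keyed by stratum.
#' @param classified Classified cohort tibble ([classify_cohort()]);
#'   strata are defined by each subject's baseline visit here.
#' @param horizon Follow-up year to validate at (default 5).
#' @return Tibble per stratum: baseline size, projected and observed MS
#'   prevalence (%) at the horizon, their absolute difference, and the
#'   number of subjects observed at the horizon (`NA` prevalence marks a
#'   stratum that cannot be validated).
#' @export
validate_against_empiric <- function(matrices, classified, horizon = 5) {
  df <- tibble::as_tibble(classified) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(baseline_stratum = .data$stratum[
      which.min(.data$visit_year)]) |>
    dplyr::ungroup()
  base <- df |> dplyr::filter(.data$follow_up == 0)
  at_h <- df |> dplyr::filter(.data$follow_up == horizon)
  strata <- sort(unique(base$baseline_stratum))
  rows <- lapply(strata, function(st) {
    b <- base[base$baseline_stratum == st, ]
    pi0 <- tabulate(b$state_index, 7) / nrow(b)
    proj <- if (!is.null(matrices[[st]])) {
      tr <- project(matrices[[st]], pi0, horizon)
      100 * tr[horizon + 1, "ms"]
    } else NA_real_
    o <- at_h[at_h$baseline_stratum == st, ]
    obs <- if (nrow(o) > 0) 100 * mean(o$state == "ms") else NA_real_
    tibble::tibble(stratum = st, n_baseline = nrow(b),
                   n_at_horizon = nrow(o),
                   projected_ms_pct = proj, observed_ms_pct = obs,
                   abs_diff_pct = abs(proj - obs))
  })
  dplyr::bind_rows(rows)
}

#' Spread of MS occupancy across starting states
#'
#' The maximum pairwise difference in MS occupancy at each cycle across
#' trajectories started from every state. For an irreducible aperiodic
#' annual matrix this spread shrinks with the horizon, which is the
#' numerical counterpart of all starting states reaching a similar MS
#' occupancy after 10 years.
#'
#' @param m A [ms_tmatrix()].
#' @param horizon Number of annual cycles.
#' @param states Starting states to compare.
#' @return Tibble: `cycle`, `spread` (max minus min MS occupancy, in
#'   percent).
#' @export
ms_occupancy_spread <- function(m, horizon = 10, states = ms_states()) {
  trajs <- predict_by_initial_state(m, horizon, states)
  ms_curves <- vapply(trajs, function(tr) 100 * tr[, "ms"],
                      numeric(horizon + 1))
  tibble::tibble(cycle = 0:horizon,
                 spread = apply(ms_curves, 1, max) -
                   apply(ms_curves, 1, min))
}
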