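# Synthetic check-up cohorts. Latent 7-state dynamics follow a specified
# per-stratum annual transition matrix; clinical measurements are rendered
# on the correct side of each CDS threshold so that classification
# round-trips to the latent state exactly.

#' Specify a ground-truth cohort model
#'
#' Bundles everything the simulator needs: one 7x7 annual transition matrix
#' per stratum (in percent; rows are renormalized on load and rejected if
#' negative or unnormalizable), an initial state distribution, cohort sizes,
#' the visit schedule and the dropout mechanism.
#'
#' @param matrices Named list (stratum label -> 7x7 matrix in percent, or
#'   [ms_tmatrix()]).
#' @param initial Length-7 probability vector over [ms_states()] used for
#'   every stratum, or a named list of such vectors per stratum. Default
#'   spreads mass over all 7 states so every matrix row is exercised.
#' @param n_per_stratum Subjects per stratum: a single count or a named
#'   vector per stratum.
#' @param n_visits Maximum number of annual visits per subject (2-6).
#' @param dropout Per-visit probability of dropping out, applied
#'   independently before each visit after the second; every subject keeps
#'   at least 2 visits. The default 0.30 gives a mean of about 3.7 visits.
#' @param baseline_year First calendar year of follow-up.
#' @param seed Integer seed governing all stochastic draws.
#' @return An object of class `gt_model`.
#' @export
ground_truth_model <- function(matrices,
                               initial = c(0.40, 0.12, 0.10, 0.10,
                                           0.04, 0.14, 0.10),
                               n_per_stratum = 2000,
                               n_visits = 6,
                               dropout = 0.30,
                               baseline_year = 2006,
                               seed = 1L) {
  stopifnot(is.list(matrices), length(matrices) > 0,
            !is.null(names(matrices)))
  mats <- lapply(names(matrices), function(nm) {
    m <- matrices[[nm]]
    mat <- if (inherits(m, "ms_tmatrix")) unclass(m) else as.matrix(m)
    if (anyNA(mat)) {
      bad <- ms_states()[apply(mat, 1, anyNA)]
      stop("stratum ", nm, ": matrix has missing entries in row(s): ",
           paste(bad, collapse = ", "))
    }
    ms_tmatrix(mat, stratum = nm, provenance = "constructed",
               normalize = TRUE)
  })
  names(mats) <- names(matrices)

  if (!is.list(initial)) initial <- stats::setNames(
    rep(list(initial), length(mats)), names(mats))
  for (nm in names(mats)) {
    p0 <- initial[[nm]]
    if (is.null(p0) || length(p0) != 7 || any(p0 < 0) ||
        abs(sum(p0) - 1) > 1e-8) {
      stop("stratum ", nm,
           ": initial distribution must be a length-7 simplex vector")
    }
  }
  if (length(n_per_stratum) == 1 && is.null(names(n_per_stratum))) {
    n_per_stratum <- stats::setNames(rep(n_per_stratum, length(mats)),
                                     names(mats))
  }
  stopifnot(all(names(mats) %in% names(n_per_stratum)),
            all(n_per_stratum >= 1))
  if (!(n_visits >= 2 && n_visits <= 6)) {
    stop("n_visits must be between 2 and 6")
  }
  stopifnot(dropout >= 0, dropout <= 1)
  structure(list(matrices = mats, initial = initial[names(mats)],
                 n_per_stratum = n_per_stratum[names(mats)],
                 n_visits = as.integer(n_visits), dropout = dropout,
                 baseline_year = as.integer(baseline_year),
                 seed = as.integer(seed)),
            class = "gt_model")
}

#' Demo ground-truth model built from the packaged matrices
#'
#' @param n_per_stratum Subjects per stratum.
#' @param seed Integer seed.
#' @param ... Passed on to [ground_truth_model()].
#' @return A `gt_model` covering all 8 strata.
#' @export
default_gt_model <- function(n_per_stratum = 2000, seed = 1L, ...) {
  ground_truth_model(fixture_matrices(), n_per_stratum = n_per_stratum,
                     seed = seed, ...)
}

#' @export
print.gt_model <- function(x, ...) {
  cat("Ground-truth cohort model:", length(x$matrices), "strata,",
      sum(x$n_per_stratum), "subjects,", x$n_visits,
      "annual visits from", x$baseline_year,
      sprintf("(dropout %.2f/visit, seed %d)\n", x$dropout, x$seed))
  invisible(x)
}

# age interval sampled at baseline for each age group; the upper ends of
# the open-ended groups are a simulation choice, not a classification rule
age_interval <- function(age_group) {
  switch(age_group,
         "18_40" = c(18, 40), "40_49" = c(40, 50),
         "50_59" = c(50, 60), "60plus" = c(60, 75),
         stop("unknown age group: ", age_group))
}

#' Sample latent state trajectories
#'
#' Draws, for every synthetic subject, a baseline state from the stratum's
#' initial distribution and then one state per year from the row of the
#' stratum matrix corresponding to the current state. Dropout truncates the
#' sequence (independent Bernoulli before each visit after the second), so
#' every subject retains at least two visits.
#'
#' @param model A [ground_truth_model()].
#' @return Tibble with one row per subject-visit: `subject_id`, `stratum`,
#'   `sex`, `visit_year`, `visit_index`, `age`, `state`.
#' @export
sample_trajectories <- function(model) {
  stopifnot(inherits(model, "gt_model"))
  set.seed(model$seed)
  states <- ms_states()
  out <- vector("list", length(model$matrices))
  for (k in seq_along(model$matrices)) {
    nm <- names(model$matrices)[k]
    P <- unclass(model$matrices[[nm]]) / 100
    n <- model$n_per_stratum[[nm]]
    nv <- model$n_visits

    lat <- matrix(0L, n, nv)
    lat[, 1] <- sample.int(7, n, replace = TRUE, prob = model$initial[[nm]])
    for (t in seq_len(nv - 1)) {
      cur <- lat[, t]
      nxt <- integer(n)
      for (i in 1:7) {
        idx <- which(cur == i)
        if (length(idx) > 0) {
          nxt[idx] <- sample.int(7, length(idx), replace = TRUE,
                                 prob = P[i, ])
        }
      }
      lat[, t + 1] <- nxt
    }

    # visits kept: 2 guaranteed, then independent Bernoulli continuation
    keep <- matrix(TRUE, n, nv)
    if (nv > 2) {
      attend <- rep(TRUE, n)
      for (j in 3:nv) {
        attend <- attend & (stats::runif(n) >= model$dropout)
        keep[, j] <- attend
      }
    }

    sex <- if (grepl("^men_", nm)) "M" else "F"
    ag <- sub("^(men|women)_", "", nm)
    iv <- age_interval(ag)
    age0 <- stats::runif(n, iv[1], iv[2])

    keep_vec <- as.vector(t(keep))
    out[[k]] <- tibble::tibble(
      subject_id = rep(sprintf("%s_%06d", nm, seq_len(n)), each = nv),
      stratum = nm,
      sex = sex,
      visit_index = rep(seq_len(nv), n),
      visit_year = model$baseline_year + rep(seq_len(nv), n) - 1L,
      age = rep(age0, each = nv) + rep(seq_len(nv), n) - 1,
      state = states[as.vector(t(lat))]
    )[keep_vec, ]
  }
  dplyr::bind_rows(out)
}

#' Configure the measurement renderer
#'
#' Defines, for each CDS component, the value ranges used on the positive
#' and negative side of its threshold and the probabilities of the
#' alternative ways a component can be triggered (elevated measurement,
#' 2-h glucose, or a prior-diagnosis flag). Ranges are validated against
#' the thresholds: a configuration whose ranges straddle a cut is rejected,
#' which is what guarantees the classify-after-render round trip.
#'
#' @param cuts The [cds_thresholds()] the cohort will be classified with.
#' @param bmi_pos,bmi_neg BMI ranges (kg/m^2) when overweight is
#'   present/absent.
#' @param sbp_pos,sbp_neg,dbp_pos,dbp_neg Blood-pressure ranges (mmHg).
#' @param tg_pos,tg_neg Triglyceride ranges (mmol/L).
#' @param hdl_low,hdl_normal HDL ranges (mmol/L); `hdl_low` is the
#'   dyslipidemic side (below the cut).
#' @param fpg_pos,fpg_neg Fasting-glucose ranges (mmol/L).
#' @param pg2h_pos,pg2h_neg 2-h post-meal glucose ranges (mmol/L).
#' @param p_ht_dx_only Probability a hypertensive record is flagged by
#'   prior diagnosis with normal measured blood pressure.
#' @param p_ht_dx_extra Probability the diagnosis flag accompanies elevated
#'   blood pressure.
#' @param p_dys_via_hdl Probability dyslipidemia is expressed as low HDL
#'   rather than high TG.
#' @param p_hg_via_pg Probability hyperglycemia is expressed only in the
#'   2-h glucose.
#' @param p_hg_dx_only Probability a hyperglycemic record is flagged by
#'   prior diagnosis with normal glucose values.
#' @param p_hg_dx_extra Probability the diagnosis flag accompanies elevated
#'   fasting glucose.
#' @param p_pg_measured Probability the optional 2-h glucose is measured on
#'   a non-hyperglycemic record.
#' @return An object of class `measurement_renderer`.
#' @export
measurement_renderer <- function(cuts = cds_thresholds(),
                                 bmi_pos = c(25.0, 32.0),
                                 bmi_neg = c(19.0, 24.8),
                                 sbp_pos = c(140, 180),
                                 sbp_neg = c(100, 138),
                                 dbp_pos = c(90, 110),
                                 dbp_neg = c(62, 88),
                                 tg_pos = c(1.70, 4.50),
                                 tg_neg = c(0.50, 1.65),
                                 hdl_low = c(0.55, 0.88),
                                 hdl_normal = c(0.95, 2.00),
                                 fpg_pos = c(6.1, 10.0),
                                 fpg_neg = c(4.0, 6.0),
                                 pg2h_pos = c(7.8, 13.0),
                                 pg2h_neg = c(4.5, 7.6),
                                 p_ht_dx_only = 0.15,
                                 p_ht_dx_extra = 0.25,
                                 p_dys_via_hdl = 0.30,
                                 p_hg_via_pg = 0.15,
                                 p_hg_dx_only = 0.10,
                                 p_hg_dx_extra = 0.15,
                                 p_pg_measured = 0.30) {
  stopifnot(inherits(cuts, "cds_thresholds"))
  ranges <- list(bmi_pos = bmi_pos, bmi_neg = bmi_neg, sbp_pos = sbp_pos,
                 sbp_neg = sbp_neg, dbp_pos = dbp_pos, dbp_neg = dbp_neg,
                 tg_pos = tg_pos, tg_neg = tg_neg, hdl_low = hdl_low,
                 hdl_normal = hdl_normal, fpg_pos = fpg_pos,
                 fpg_neg = fpg_neg, pg2h_pos = pg2h_pos,
                 pg2h_neg = pg2h_neg)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop("range ", nm, " must be c(lo, hi) with lo <= hi")
    }
  }
  # each range must sit entirely on its side of the threshold
  check <- function(nm, ok, cut) {
    if (!ok) stop("renderer range ", nm, " straddles its threshold (",
                  cut, "); rendered values would not classify back to the ",
                  "latent state")
  }
  check("bmi_pos", bmi_pos[1] >= cuts$bmi, cuts$bmi)
  check("bmi_neg", bmi_neg[2] < cuts$bmi, cuts$bmi)
  check("sbp_pos", sbp_pos[1] >= cuts$sbp, cuts$sbp)
  check("sbp_neg", sbp_neg[2] < cuts$sbp, cuts$sbp)
  check("dbp_pos", dbp_pos[1] >= cuts$dbp, cuts$dbp)
  check("dbp_neg", dbp_neg[2] < cuts$dbp, cuts$dbp)
  check("tg_pos", tg_pos[1] >= cuts$tg, cuts$tg)
  check("tg_neg", tg_neg[2] < cuts$tg, cuts$tg)
  check("hdl_low", hdl_low[2] < cuts$hdl, cuts$hdl)
  check("hdl_normal", hdl_normal[1] >= cuts$hdl, cuts$hdl)
  check("fpg_pos", fpg_pos[1] >= cuts$fpg, cuts$fpg)
  check("fpg_neg", fpg_neg[2] < cuts$fpg, cuts$fpg)
  check("pg2h_pos", pg2h_pos[1] >= cuts$pg2h, cuts$pg2h)
  check("pg2h_neg", pg2h_neg[2] < cuts$pg2h, cuts$pg2h)

  probs <- list(p_ht_dx_only = p_ht_dx_only, p_ht_dx_extra = p_ht_dx_extra,
                p_dys_via_hdl = p_dys_via_hdl, p_hg_via_pg = p_hg_via_pg,
                p_hg_dx_only = p_hg_dx_only, p_hg_dx_extra = p_hg_dx_extra,
                p_pg_measured = p_pg_measured)
  stopifnot(all(unlist(probs) >= 0), all(unlist(probs) <= 1))
  structure(c(list(cuts = cuts), ranges, probs),
            class = "measurement_renderer")
}

# uniform draw within a range, vectorized over n
runif_range <- function(n, r) stats::runif(n, r[1], r[2])

# component profiles for composite states: the 6 pairs and the 5 ways to
# have >= 3 of 4 components (4 triples + the quadruple)
component_pairs <- function() utils::combn(4, 2)
component_triples_plus <- function() {
  c(utils::combn(4, 3, simplify = FALSE), list(1:4))
}

#' Render clinical measurements for latent state sequences
#'
#' Expands each latent state into a component profile (composite states
#' pick uniformly among their valid component combinations) and draws
#' measurement values on the correct side of every threshold, so that
#' [classify_cohort()] recovers exactly the latent state.
#'
#' @param trajectories Output of [sample_trajectories()].
#' @param renderer A [measurement_renderer()].
#' @param seed Optional integer; when `NULL` the current RNG stream is
#'   used (so a single model seed governs the whole simulation).
#' @return Tibble following [cohort_schema()], plus the `stratum` and
#'   latent `state` columns for reference.
#' @export
render_measurements <- function(trajectories,
                                renderer = measurement_renderer(),
                                seed = NULL) {
  stopifnot(inherits(renderer, "measurement_renderer"))
  if (!is.null(seed)) set.seed(seed)
  tr <- tibble::as_tibble(trajectories)
  n <- nrow(tr)
  sidx <- state_index(tr$state)

  comp <- matrix(FALSE, n, 4)
  comp[sidx >= 2 & sidx <= 5, ] <-
    diag(4)[sidx[sidx >= 2 & sidx <= 5] - 1, ] > 0
  two <- which(sidx == 6)
  if (length(two) > 0) {
    pairs <- component_pairs()
    pick <- sample.int(ncol(pairs), length(two), replace = TRUE)
    for (j in seq_len(ncol(pairs))) {
      rows <- two[pick == j]
      comp[rows, pairs[, j]] <- TRUE
    }
  }
  msi <- which(sidx == 7)
  if (length(msi) > 0) {
    combos <- component_triples_plus()
    pick <- sample.int(5, length(msi), replace = TRUE)
    for (j in 1:5) {
      rows <- msi[pick == j]
      comp[rows, combos[[j]]] <- TRUE
    }
  }
  ow <- comp[, 1]; ht <- comp[, 2]; dys <- comp[, 3]; hg <- comp[, 4]
  r <- renderer

  bmi <- ifelse(ow, runif_range(n, r$bmi_pos), runif_range(n, r$bmi_neg))

  ht_dx_only <- ht & stats::runif(n) < r$p_ht_dx_only
  ht_elev <- ht & !ht_dx_only
  sbp <- ifelse(ht_elev, runif_range(n, r$sbp_pos), runif_range(n, r$sbp_neg))
  dbp <- ifelse(ht_elev, runif_range(n, r$dbp_pos), runif_range(n, r$dbp_neg))
  dx_ht <- as.integer(ht_dx_only | (ht_elev & stats::runif(n) < r$p_ht_dx_extra))

  via_hdl <- dys & stats::runif(n) < r$p_dys_via_hdl
  tg <- ifelse(dys & !via_hdl, runif_range(n, r$tg_pos),
               runif_range(n, r$tg_neg))
  hdl <- ifelse(via_hdl, runif_range(n, r$hdl_low),
                runif_range(n, r$hdl_normal))

  u_mech <- stats::runif(n)
  hg_via_pg <- hg & u_mech < r$p_hg_via_pg
  hg_dx_only <- hg & !hg_via_pg & u_mech < r$p_hg_via_pg + r$p_hg_dx_only
  hg_fpg <- hg & !hg_via_pg & !hg_dx_only
  fpg <- ifelse(hg_fpg, runif_range(n, r$fpg_pos), runif_range(n, r$fpg_neg))
  pg_measured_neg <- stats::runif(n) < r$p_pg_measured
  pg2h <- rep(NA_real_, n)
  pg2h[hg_via_pg] <- runif_range(sum(hg_via_pg), r$pg2h_pos)
  idle <- !hg_via_pg & pg_measured_neg & !hg
  pg2h[idle] <- runif_range(sum(idle), r$pg2h_neg)
  dx_hg <- as.integer(hg_dx_only | (hg_fpg & stats::runif(n) < r$p_hg_dx_extra))

  tibble::tibble(
    subject_id = tr$subject_id,
    visit_year = tr$visit_year,
    age = tr$age,
    sex = tr$sex,
    bmi = bmi, sbp = sbp, dbp = dbp, tg = tg, hdl = hdl, fpg = fpg,
    pg2h = pg2h,
    dx_hypertension = dx_ht,
    dx_hyperglycemia = dx_hg,
    hx_chd = 0L, hx_t1dm = 0L, hx_fam_hyperlipidemia = 0L,
    stratum = tr$stratum,
    state = tr$state
  )
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: [sample_trajectories()] then
#' [render_measurements()], all driven by the model's single seed.
#'
#' @param model A [ground_truth_model()].
#' @param renderer A [measurement_renderer()].
#' @return Tibble following [cohort_schema()] plus `stratum` and latent
#'   `state`.
#' @export
simulate_cohort <- function(model, renderer = measurement_renderer()) {
  traj <- sample_trajectories(model)  # sets the seed
  render_measurements(traj, renderer)  # continues the same RNG stream
}

#' Write a cohort to CSV
#'
#' Only the schema columns are written (the latent state, when present, is
#' dropped, since it is not observable in real data). Output is
#' byte-stable for a given input.
#'
#' @param records Cohort tibble.
#' @param path Output path.
#' @param keep_latent If `TRUE`, also write `stratum` and latent `state`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path, keep_latent = FALSE) {
  cols <- cohort_schema()$column
  if (keep_latent) cols <- c(cols, intersect(c("stratum", "state"),
                                             names(records)))
  readr::write_csv(records[, cols], path)
  invisible(path)
}

#' Read a cohort CSV
#'
#' @param path CSV path following [cohort_schema()].
#' @return Cohort tibble.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    visit_year = readr::col_integer(),
                    sex = readr::col_character(),
                    .default = readr::col_double()))
}
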