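# End-to-end pipeline: simulate (or read) a cohort, classify, estimate,
# project, validate, summarise, and write a reproducible artifact bundle.

#' Pipeline configuration
#'
#' @param out_dir Output directory for the artifact bundle.
#' @param model A [ground_truth_model()] to simulate from, or `NULL` when
#'   `cohort_csv` is supplied.
#' @param cohort_csv Path to an existing cohort CSV (see
#'   [cohort_schema()]); ignored when `model` is given.
#' @param matrices Named list of [ms_tmatrix()] per stratum for a
#'   projection-only run (no cohort, no estimation), e.g.
#'   [fixture_matrices()].
#' @param cuts [cds_thresholds()] used for classification.
#' @param renderer [measurement_renderer()] used for simulation.
#' @param stratum_mode `"per_pair"` or `"baseline"` stratum assignment for
#'   transition events.
#' @param averaging `"unweighted"` or `"pooled"` year-pair averaging.
#' @param horizon Projection horizon in annual cycles.
#' @param validation_horizon Follow-up year for the validation report.
#' @param seed Integer seed overriding the model's seed (optional).
#' @param write_plots Write per-stratum MS-trajectory plots (PNG).
#' @return An object of class `ms_pipeline_config`.
#' @export
ms_pipeline_config <- function(out_dir,
                               model = NULL,
                               cohort_csv = NULL,
                               matrices = NULL,
                               cuts = cds_thresholds(),
                               renderer = measurement_renderer(cuts),
                               stratum_mode = c("per_pair", "baseline"),
                               averaging = c("unweighted", "pooled"),
                               horizon = 10,
                               validation_horizon = 5,
                               seed = NULL,
                               write_plots = TRUE) {
  stratum_mode <- match.arg(stratum_mode)
  averaging <- match.arg(averaging)
  if (is.null(model) && is.null(cohort_csv) && is.null(matrices)) {
    stop("provide a ground-truth model to simulate from, a cohort CSV, ",
         "or matrices for a projection-only run")
  }
  if (!is.null(model)) stopifnot(inherits(model, "gt_model"))
  if (!is.null(seed) && !is.null(model)) model$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, model = model, cohort_csv = cohort_csv,
                 matrices = matrices, cuts = cuts, renderer = renderer,
                 stratum_mode = stratum_mode, averaging = averaging,
                 horizon = horizon,
                 validation_horizon = validation_horizon,
                 seed = seed, write_plots = write_plots),
            class = "ms_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or read) the cohort; classify records into states and
#' strata; estimate per-stratum annual transition matrices; project MS
#' development from every starting state; validate projected MS prevalence
#' against the observed cohort; write the descriptive summary and a run
#' log. All outputs land in `config$out_dir`.
#'
#' @param config A [ms_pipeline_config()].
#' @return The artifact bundle, invisibly: a list with `cohort`,
#'   `classified`, `exclusion_log`, `matrices`, `trajectories`,
#'   `validation`, `summary`, and the paths written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "ms_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("msmarkov pipeline run %s",
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("stratum_mode=%s averaging=%s horizon=%d",
                         config$stratum_mode, config$averaging,
                         config$horizon))

  projection_only <- is.null(config$model) && is.null(config$cohort_csv)
  if (projection_only) {
    cohort <- NULL
    cls <- NULL
    matrices <- config$matrices
    log_lines <- c(log_lines,
                   sprintf("projection-only run over %d supplied matrices",
                           length(matrices)))
  } else {
    if (!is.null(config$model)) {
      cohort <- simulate_cohort(config$model, config$renderer)
      log_lines <- c(log_lines,
                     sprintf("simulated cohort: %d records, %d subjects, seed %d",
                             nrow(cohort),
                             length(unique(cohort$subject_id)),
                             config$model$seed))
    } else {
      cohort <- read_cohort(config$cohort_csv)
      log_lines <- c(log_lines, sprintf("read cohort from %s: %d records",
                                        config$cohort_csv, nrow(cohort)))
    }
    write_cohort(cohort, file.path(config$out_dir, "cohort.csv"))

    cls <- classify_cohort(cohort, config$cuts)
    readr::write_csv(cls$records, file.path(config$out_dir,
                                            "classified_cohort.csv"))
    for (i in seq_len(nrow(cls$exclusion_log))) {
      log_lines <- c(log_lines, sprintf("excluded (%s): %d subjects",
                                        cls$exclusion_log$reason[i],
                                        cls$exclusion_log$n_subjects[i]))
    }

    matrices <- estimate_transition_matrices(cls$records,
                                             config$stratum_mode,
                                             config$averaging)
    counts <- attr(matrices, "counts")
    for (i in seq_len(nrow(counts))) {
      log_lines <- c(log_lines,
                     sprintf("events %s %d->%d: %d", counts$stratum[i],
                             counts$year_from[i], counts$year_from[i] + 1,
                             counts$n_events[i]))
    }
  }
  mat_dir <- file.path(config$out_dir, "matrices")
  dir.create(mat_dir, showWarnings = FALSE)
  for (st in names(matrices)) {
    write_tmatrix_csv(matrices[[st]], file.path(mat_dir,
                                                paste0(st, ".csv")))
    write_tmatrix_json(matrices[[st]], file.path(mat_dir,
                                                 paste0(st, ".json")))
  }

  trajectories <- list()
  traj_rows <- list()
  for (st in names(matrices)) {
    m <- matrices[[st]]
    ok <- tryCatch({
      trajectories[[st]] <- predict_by_initial_state(m, config$horizon)
      TRUE
    }, error = function(e) {
      log_lines <<- c(log_lines, sprintf(
        "projection skipped for %s: %s", st, conditionMessage(e)))
      FALSE
    })
    if (ok) traj_rows[[st]] <- trajectories_tidy(trajectories[[st]])
  }
  traj_tidy <- dplyr::bind_rows(traj_rows)
  readr::write_csv(traj_tidy, file.path(config$out_dir,
                                        "trajectories.csv"))
  if (config$write_plots && length(trajectories) > 0) {
    plot_dir <- file.path(config$out_dir, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    for (st in names(trajectories)) {
      p <- plot_ms_trajectories(trajectories[[st]])
      ggplot2::ggsave(file.path(plot_dir, paste0(st, "_ms.png")), p,
                      device = grDevices::png, width = 7, height = 4.5,
                      dpi = 150, units = "in")
    }
  }

  if (!projection_only) {
    validation <- validate_against_empiric(matrices, cls$records,
                                           config$validation_horizon)
    jsonlite::write_json(validation, file.path(config$out_dir,
                                               "validation.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    summary_tbl <- descriptive_summary(cls$records)
    readr::write_csv(summary_tbl, file.path(config$out_dir,
                                            "descriptive_summary.csv"))
  } else {
    validation <- NULL
    summary_tbl <- NULL
  }

  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, classified = cls$records,
                 exclusion_log = cls$exclusion_log, matrices = matrices,
                 trajectories = trajectories, validation = validation,
                 summary = summary_tbl, out_dir = config$out_dir,
                 config = config))
}

#' Render a human-readable report from a pipeline bundle
#'
#' Writes a plain-text report with the descriptive summary, the estimated
#' per-stratum matrices (in the canonical row/column order), MS-occupancy
#' projections per starting state, and the validation table.
#'
#' @param bundle List returned by [run_pipeline()].
#' @param path Output path (default `report.txt` inside the bundle's
#'   output directory).
#' @return `path`, invisibly.
#' @export
render_report <- function(bundle, path = file.path(bundle$out_dir,
                                                   "report.txt")) {
  fmt_mat <- function(m) {
    utils::capture.output(print(m, digits = 2))
  }
  lines <- c("Metabolic-syndrome progression report",
             strrep("=", 38), "")
  if (!is.null(bundle$summary)) {
    lines <- c(lines, "Descriptive summary by follow-up year:",
               utils::capture.output(print(as.data.frame(
                 bundle$summary), digits = 4, row.names = FALSE)), "")
  }
  for (st in names(bundle$matrices)) {
    lines <- c(lines, strrep("-", 38), paste("Stratum:", st), "",
               fmt_mat(bundle$matrices[[st]]), "")
    if (!is.null(bundle$trajectories[[st]])) {
      ms_curve <- vapply(bundle$trajectories[[st]],
                         function(tr) 100 * tr[nrow(tr), "ms"], numeric(1))
      lines <- c(lines,
                 sprintf("MS occupancy (%%) after %d cycles by starting state:",
                         nrow(bundle$trajectories[[st]][[1]]) - 1),
                 utils::capture.output(print(round(ms_curve, 2))), "")
    } else {
      lines <- c(lines, "insufficient data: projection not available", "")
    }
  }
  if (!is.null(bundle$validation)) {
    lines <- c(lines, strrep("-", 38),
               "Validation (projected vs observed MS %):",
               utils::capture.output(print(as.data.frame(bundle$validation),
                                           digits = 4, row.names = FALSE)))
  }
  writeLines(lines, path)
  invisible(path)
}
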