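#' Write a ground-truth model to YAML
#'
#' @param model A [ground_truth_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gt_model <- function(model, path) {
  stopifnot(inherits(model, "gt_model"))
  payload <- list(
    states = ms_states(),
    n_visits = model$n_visits,
    dropout = model$dropout,
    baseline_year = model$baseline_year,
    seed = model$seed,
    strata = lapply(stats::setNames(names(model$matrices),
                                    names(model$matrices)), function(nm) {
      m <- unclass(model$matrices[[nm]])
      list(matrix_percent = lapply(seq_len(nrow(m)),
                                   function(i) as.numeric(m[i, ])),
           initial = as.numeric(model$initial[[nm]]),
           n = as.integer(model$n_per_stratum[[nm]]))
    })
  )
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' Read a ground-truth model from YAML
#'
#' @param path YAML written by [write_gt_model()] (or hand-authored with
#'   the same layout).
#' @return A [ground_truth_model()].
#' @export
read_gt_model <- function(path) {
  y <- yaml::read_yaml(path)
  mats <- lapply(y$strata, function(s) {
    do.call(rbind, s$matrix_percent)
  })
  init <- lapply(y$strata, function(s) as.numeric(s$initial))
  n <- vapply(y$strata, function(s) as.integer(s$n), integer(1))
  ground_truth_model(matrices = mats, initial = init, n_per_stratum = n,
                     n_visits = y$n_visits, dropout = y$dropout,
                     baseline_year = y$baseline_year, seed = y$seed)
}
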