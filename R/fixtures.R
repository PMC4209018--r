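#' Names of the packaged per-stratum transition matrices
#'
#' Five strata (men/women 18-40, men/women 40-49, men 50-59) ship the
#' published annual transition-probability tables verbatim (in percent, as
#' printed; rows carry rounding drift of up to 0.01 percentage points).
#' The remaining three strata (women 50-59, men/women >=60) were published
#' only in supplementary material that is not redistributable here, so the
#' package ships hand-constructed *synthetic* stand-ins, flagged by the
#' `_synthetic` suffix and `provenance = "synthetic"`. The stand-ins follow
#' the qualitative structure of the published elderly strata (higher
#' transitions into hypertension and the 2-component state) but are not
#' estimates of any real cohort.
#'
#' @return Character vector of fixture names accepted by
#'   [fixture_matrix()].
#' @export
#' @examples
#' fixture_names()
fixture_names <- function() {
  c("men_18_40", "women_18_40", "men_40_49", "women_40_49", "men_50_59",
    "women_50_59_synthetic", "men_60plus_synthetic", "women_60plus_synthetic")
}

#' Load a packaged transition matrix
#'
#' @param name One of [fixture_names()]; the stratum label (e.g.
#'   `"women_50_59"`) is also accepted for the synthetic strata.
#' @param normalize If `TRUE`, renormalize rows to sum to exactly 100
#'   (required before multi-cycle projection); if `FALSE` (default) the
#'   values are returned verbatim as printed.
#' @return A [ms_tmatrix()] with provenance `"fixture"` or `"synthetic"`.
#' @export
#' @examples
#' m <- fixture_matrix("men_18_40")
#' m["no_component", "ms"] # percent chance of developing MS in one year
fixture_matrix <- function(name, normalize = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  avail <- fixture_names()
  if (!name %in% avail) {
    synth <- paste0(name, "_synthetic")
    if (synth %in% avail) name <- synth
    else stop("unknown fixture '", name, "'; available: ",
              paste(avail, collapse = ", "))
  }
  path <- system.file("extdata", "matrices", paste0(name, ".csv"),
                      package = "msmarkov", mustWork = TRUE)
  synthetic <- grepl("_synthetic$", name)
  read_tmatrix_csv(path,
                   stratum = sub("_synthetic$", "", name),
                   provenance = if (synthetic) "synthetic" else "fixture",
                   normalize = normalize)
}

#' Load all packaged matrices as a named list
#'
#' @inheritParams fixture_matrix
#' @return Named list of [ms_tmatrix()], one per stratum, keyed by stratum
#'   label.
#' @export
fixture_matrices <- function(normalize = FALSE) {
  out <- lapply(fixture_names(), fixture_matrix, normalize = normalize)
  names(out) <- vapply(out, function(m) attr(m, "stratum"), character(1))
  out
}
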