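#' Construct an annual transition matrix
#'
#' A `ms_tmatrix` is a 7x7 matrix of annual transition probabilities in
#' percent, rows = starting state, columns = state after one annual cycle,
#' both in the canonical [ms_states()] order. Rows that were never observed
#' in the data may be entirely `NA` ("unobserved"); observed rows must be
#' non-negative and sum to 100 within `tol` (or be renormalizable via
#' `normalize = TRUE`).
#'
#' @param mat Numeric 7x7 matrix in percent. Dimnames, if present, must
#'   match [ms_states()].
#' @param stratum Optional stratum label (see [ms_strata()]).
#' @param provenance One of "estimated", "fixture", "synthetic",
#'   "constructed".
#' @param n_pairs Optional integer vector of length 7: number of year-pair
#'   incidence matrices contributing to each row of an estimated matrix.
#' @param normalize If `TRUE`, rescale each observed row to sum to exactly
#'   100 (printed tables are subject to rounding drift).
#' @param tol Row-sum tolerance (percentage points) applied when
#'   `normalize = FALSE`.
#' @return An object of class `ms_tmatrix`.
#' @export
ms_tmatrix <- function(mat, stratum = NULL,
                       provenance = c("constructed", "estimated",
                                      "fixture", "synthetic"),
                       n_pairs = NULL, normalize = FALSE, tol = 0.5) {
  provenance <- match.arg(provenance)
  mat <- as.matrix(mat)
  if (!all(dim(mat) == c(7, 7))) {
    stop("transition matrix must be 7x7, got ",
         paste(dim(mat), collapse = "x"))
  }
  dimnames(mat) <- list(ms_states(), ms_states())
  observed <- !apply(mat, 1, function(r) all(is.na(r)))
  if (any(is.na(mat[observed, ]))) {
    stop("rows must be fully observed or fully NA")
  }
  if (any(mat[observed, ] < 0)) {
    bad <- ms_states()[observed][apply(mat[observed, , drop = FALSE], 1,
                                       function(r) any(r < 0))]
    stop("negative transition probabilities in row(s): ",
         paste(bad, collapse = ", "))
  }
  sums <- rowSums(mat)
  if (normalize) {
    zero <- observed & sums == 0
    if (any(zero)) {
      stop("cannot normalize all-zero row(s): ",
           paste(ms_states()[zero], collapse = ", "))
    }
    mat[observed, ] <- 100 * mat[observed, , drop = FALSE] / sums[observed]
  } else {
    bad <- observed & abs(sums - 100) > tol
    if (any(bad)) {
      stop("row(s) not stochastic (sum != 100 within tolerance ", tol, "): ",
           paste(sprintf("%s (%.2f)", ms_states()[bad], sums[bad]),
                 collapse = ", "))
    }
  }
  structure(mat, class = c("ms_tmatrix", "matrix", "array"),
            stratum = stratum, provenance = provenance,
            n_pairs = n_pairs)
}

#' Renormalize the rows of a transition matrix to sum to exactly 100
#'
#' Printed tables carry rounding drift of up to a few hundredths of a
#' percentage point per row; multi-cycle projection requires exact
#' stochasticity, so rows are rescaled before propagation.
#'
#' @param m A [ms_tmatrix()].
#' @return A `ms_tmatrix` whose observed rows sum to 100 exactly (to
#'   floating precision).
#' @export
renormalize_rows <- function(m) {
  stopifnot(inherits(m, "ms_tmatrix"))
  ms_tmatrix(unclass(m), stratum = attr(m, "stratum"),
             provenance = attr(m, "provenance"),
             n_pairs = attr(m, "n_pairs"), normalize = TRUE)
}

#' Which rows of a transition matrix are observed?
#'
#' @param m A [ms_tmatrix()].
#' @return Named logical vector over the 7 states.
#' @export
observed_rows <- function(m) {
  stopifnot(inherits(m, "ms_tmatrix"))
  !apply(unclass(m), 1, function(r) all(is.na(r)))
}

#' @export
print.ms_tmatrix <- function(x, digits = 2, ...) {
  cat(sprintf("Annual transition probabilities (%%)%s [%s]\n",
              if (!is.null(attr(x, "stratum")))
                paste0(" - ", attr(x, "stratum")) else "",
              attr(x, "provenance")))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Write a transition matrix to CSV (percent, 2 decimals)
#'
#' @param m A [ms_tmatrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tmatrix_csv <- function(m, path) {
  stopifnot(inherits(m, "ms_tmatrix"))
  df <- tibble::as_tibble(round(unclass(m), 2), rownames = "starting_state")
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a transition matrix from CSV
#'
#' @param path CSV with a `starting_state` column and one column per state.
#' @param ... Passed to [ms_tmatrix()] (e.g. `stratum`, `provenance`,
#'   `normalize`).
#' @return A [ms_tmatrix()].
#' @export
read_tmatrix_csv <- function(path, ...) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, ms_states()])
  rownames(mat) <- df$starting_state
  mat <- mat[ms_states(), ]
  ms_tmatrix(mat, ...)
}

#' Write a transition matrix (full precision, with provenance) to JSON
#'
#' @param m A [ms_tmatrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tmatrix_json <- function(m, path) {
  stopifnot(inherits(m, "ms_tmatrix"))
  payload <- list(states = ms_states(),
                  stratum = attr(m, "stratum"),
                  provenance = attr(m, "provenance"),
                  n_pairs = attr(m, "n_pairs"),
                  percent = unname(unclass(m)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
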