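# shared fixtures, all built in code

# one check-up record with healthy defaults; override any field
toy_record <- function(...) {
  rec <- tibble::tibble(
    subject_id = "s1", visit_year = 2007L, age = 30, sex = "M",
    bmi = 22, sbp = 115, dbp = 70, tg = 1.0, hdl = 1.3, fpg = 5.0,
    pg2h = NA_real_, dx_hypertension = 0L, dx_hyperglycemia = 0L,
    hx_chd = 0L, hx_t1dm = 0L, hx_fam_hyperlipidemia = 0L)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

toy_cohort <- function(...) dplyr::bind_rows(...)

# minimal classified records sufficient for the estimation stage
toy_classified <- function(subject_id, visit_year, state,
                           stratum = "men_18_40") {
  tibble::tibble(subject_id = subject_id,
                 visit_year = as.integer(visit_year),
                 state = state, stratum = stratum)
}

# a deterministic 7x7 percent matrix concentrated on a cycle through all
# states (irreducible, aperiodic thanks to self-loops)
cyclic_test_matrix <- function(self = 40) {
  m <- matrix(0, 7, 7)
  for (i in 1:7) {
    m[i, i] <- self
    m[i, i %% 7 + 1] <- 100 - self
  }
  ms_tmatrix(m)
}

# all 16 component profiles as a logical matrix
all_profiles <- function() {
  as.matrix(expand.grid(overweight = c(FALSE, TRUE),
                        hypertension = c(FALSE, TRUE),
                        dyslipidemia = c(FALSE, TRUE),
                        hyperglycemia = c(FALSE, TRUE)))
}
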