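# state classification: CDS component rules, state assignment,
# exclusions, stratification

test_that("component evaluation follows the CDS rules, including boundary semantics", {
  cases <- list(
    # record overrides, then expected (ow, ht, dys, hg)
    list(toy_record(bmi = 26.0, sbp = 120, dbp = 75, tg = 1.2, hdl = 1.1,
                    fpg = 5.0),
         c(TRUE, FALSE, FALSE, FALSE)),
    # boundary values at >= cuts count as present; DBP alone triggers
    list(toy_record(bmi = 24.0, sbp = 138, dbp = 92, tg = 1.7, hdl = 1.0,
                    fpg = 6.1),
         c(FALSE, TRUE, TRUE, TRUE)),
    # HDL strictly below its cut; 2-h glucose >= cut counts
    list(toy_record(bmi = 24.9, sbp = 130, dbp = 80, tg = 1.0, hdl = 0.89,
                    fpg = 5.5, pg2h = 8.0),
         c(FALSE, FALSE, TRUE, TRUE)),
    # prior-diagnosis flags are sufficient alone
    list(toy_record(dx_hypertension = 1L, dx_hyperglycemia = 1L),
         c(FALSE, TRUE, FALSE, TRUE)),
    # HDL exactly at the cut is NOT dyslipidemic (strict <)
    list(toy_record(hdl = 0.9), c(FALSE, FALSE, FALSE, FALSE))
  )
  for (cs in cases) {
    out <- evaluate_components(cs[[1]])
    got <- unlist(out[1, paste0("comp_", ms_components())])
    expect_equal(unname(got), cs[[2]])
  }
})

test_that("incomplete records are flagged and never classified", {
  out <- evaluate_components(toy_record(tg = NA_real_))
  expect_false(out$complete)
  expect_true(is.na(out$comp_dyslipidemia))
  expect_true(is.na(out$n_components))
  # missing pg2h alone does not make a record incomplete
  expect_true(evaluate_components(toy_record(pg2h = NA_real_))$complete)
})

test_that("state assignment is total over the 16 profiles with multiplicities 1/4/6/5", {
  prof <- all_profiles()
  states <- assign_state(prof[, 1], prof[, 2], prof[, 3], prof[, 4])
  expect_false(anyNA(states))
  expect_setequal(unique(states), ms_states())
  counts <- table(factor(states, levels = ms_states()))
  expect_equal(unname(counts[["no_component"]]), 1)
  expect_equal(sum(counts[paste0("iso_", c("overweight", "hypertension",
                                           "dyslipidemia",
                                           "hyperglycemia"))]), 4)
  expect_equal(unname(counts[["two_component"]]), 6)
  expect_equal(unname(counts[["ms"]]), 5)
  # each isolated state matches its component
  expect_equal(assign_state(TRUE, FALSE, FALSE, FALSE), "iso_overweight")
  expect_equal(assign_state(FALSE, FALSE, FALSE, TRUE), "iso_hyperglycemia")
})

test_that("raising a measurement that appears only in >= clauses never removes a component", {
  set.seed(11)
  base <- dplyr::bind_rows(lapply(1:50, function(i) {
    toy_record(subject_id = paste0("s", i),
               bmi = runif(1, 18, 35), sbp = runif(1, 100, 180),
               dbp = runif(1, 60, 110), tg = runif(1, 0.5, 4),
               hdl = runif(1, 0.5, 2), fpg = runif(1, 4, 9))
  }))
  n0 <- evaluate_components(base)$n_components
  for (col in c("bmi", "sbp", "dbp", "tg", "fpg")) {
    bumped <- base
    bumped[[col]] <- bumped[[col]] + 5
    expect_true(all(evaluate_components(bumped)$n_components >= n0),
                label = paste("monotonicity in", col))
  }
  # lowering HDL can only add the dyslipidemia component
  lowered <- base
  lowered$hdl <- lowered$hdl - 0.5
  expect_true(all(evaluate_components(lowered)$n_components >= n0))
})

test_that("classification ignores pg2h when FPG or the flag already triggers hyperglycemia", {
  with_pg <- evaluate_components(toy_record(fpg = 7.0, pg2h = 5.0))
  without <- evaluate_components(toy_record(fpg = 7.0, pg2h = NA_real_))
  expect_true(with_pg$comp_hyperglycemia)
  expect_true(without$comp_hyperglycemia)
})

test_that("exclusions drop whole subjects and log each reason", {
  co <- toy_cohort(
    toy_record(subject_id = "a", visit_year = 2007L),
    toy_record(subject_id = "a", visit_year = 2008L, hx_t1dm = 1L),
    toy_record(subject_id = "b", visit_year = 2007L, tg = NA_real_),
    toy_record(subject_id = "b", visit_year = 2008L),
    toy_record(subject_id = "c", visit_year = 2007L),
    toy_record(subject_id = "d", visit_year = 2007L, age = 17)
  )
  out <- apply_exclusions(co)
  expect_equal(sort(unique(out$records$subject_id)), "c")
  lg <- out$log
  expect_equal(lg$n_subjects[lg$reason == "history_t1dm"], 1L)
  expect_equal(lg$n_subjects[lg$reason == "incomplete_information"], 1L)
  expect_equal(lg$n_subjects[lg$reason == "age_below_18"], 1L)
})

test_that("exclusions on an empty cohort give empty output and log", {
  out <- apply_exclusions(toy_record()[0, ])
  expect_equal(nrow(out$records), 0)
  expect_equal(sum(out$log$n_subjects), 0)
})

test_that("age groups use the half-open partition and strata combine sex and age", {
  expect_equal(assign_age_group(c(39.9, 40, 49.9, 50, 59.9, 60, 80)),
               c("18_40", "40_49", "40_49", "50_59", "50_59", "60plus",
                 "60plus"))
  expect_true(is.na(assign_age_group(17.9)))
  expect_equal(stratum_label("M", "18_40"), "men_18_40")
  expect_equal(stratum_label("F", "40_49"), "women_40_49")
  expect_length(ms_strata(), 8)
})

test_that("classify_cohort derives follow-up years from each subject's first visit", {
  co <- toy_cohort(
    toy_record(subject_id = "a", visit_year = 2008L),
    toy_record(subject_id = "a", visit_year = 2010L),
    toy_record(subject_id = "b", visit_year = 2007L)
  )
  out <- classify_cohort(co)$records
  expect_equal(out$follow_up[out$subject_id == "a"], c(0L, 2L))
  expect_equal(out$follow_up[out$subject_id == "b"], 0L)
  expect_true(all(out$state == "no_component"))
})
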