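# transition estimation: event pairing, counting, incidence rates,
# year-pair averaging, descriptive summary

test_that("consecutive-year pairing yields events only across adjacent years", {
  cls <- dplyr::bind_rows(
    toy_classified("a", 2007:2009, c("no_component", "iso_overweight", "ms")),
    toy_classified("b", c(2007, 2009), c("no_component", "ms")),
    toy_classified("c", 2008, "no_component")
  )
  ev <- pair_consecutive_visits(cls)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$state_from, c("no_component", "iso_overweight"))
  expect_equal(ev$state_to, c("iso_overweight", "ms"))
  expect_equal(ev$year_from, c(2007L, 2008L))
  expect_equal(nrow(pair_consecutive_visits(cls[0, ])), 0)
})

test_that("duplicate subject-year rows are rejected naming the subject", {
  cls <- toy_classified(c("a", "a"), c(2007, 2007), c("ms", "ms"))
  expect_error(pair_consecutive_visits(cls), "a")
})

test_that("baseline stratum mode freezes the stratum of the first visit", {
  cls <- dplyr::bind_rows(
    toy_classified("a", 2007:2009, rep("no_component", 3),
                   stratum = c("men_18_40", "men_40_49", "men_40_49")))
  per_pair <- pair_consecutive_visits(cls, "per_pair")
  expect_equal(per_pair$stratum, c("men_18_40", "men_40_49"))
  baseline <- pair_consecutive_visits(cls, "baseline")
  expect_equal(baseline$stratum, c("men_18_40", "men_18_40"))
})

test_that("transition counts match an independent hand tally on a toy cohort", {
  # hand-built: 2007->2008 has no->no (d), no->ow (a); 2008->2009 has
  # ow->ms (a), two->ms (e)
  cls <- dplyr::bind_rows(
    toy_classified("a", 2007:2009, c("no_component", "iso_overweight", "ms")),
    toy_classified("d", 2007:2008, c("no_component", "no_component")),
    toy_classified("e", 2008:2009, c("two_component", "ms"))
  )
  counted <- count_transitions(pair_consecutive_visits(cls))
  expect_equal(nrow(counted), 2)
  c78 <- counted$counts[[which(counted$year_from == 2007)]]
  expect_equal(sum(c78), 2)
  expect_equal(c78["no_component", "no_component"], 1L)
  expect_equal(c78["no_component", "iso_overweight"], 1L)
  c89 <- counted$counts[[which(counted$year_from == 2008)]]
  expect_equal(c89["iso_overweight", "ms"], 1L)
  expect_equal(c89["two_component", "ms"], 1L)
  expect_equal(sum(c89), 2)
})

test_that("incidence-rate rows are conditional percentages; empty rows stay unobserved", {
  counts <- matrix(0L, 7, 7)
  counts[1, ] <- c(8L, 1L, 0L, 1L, 0L, 0L, 0L)
  rate <- annual_rate_matrix(counts)
  expect_equal(unname(rate[1, ]), c(80, 10, 0, 10, 0, 0, 0))
  expect_true(all(is.na(rate[2:7, ])))
  expect_equal(sum(rate[1, ]), 100)
})

test_that("averaging five identical matrices returns the same matrix", {
  r <- annual_rate_matrix({
    m <- matrix(0L, 7, 7); m[1, ] <- c(6L, 1L, 1L, 1L, 1L, 0L, 0L)
    m[7, 7] <- 10L; m
  })
  avg <- average_annual_matrices(rep(list(r), 5))
  expect_equal(unclass(avg)[1, ], r[1, ], ignore_attr = TRUE)
  expect_equal(unclass(avg)[7, 7], 100)
  expect_equal(attr(avg, "n_pairs")[["no_component"]], 5L)
  expect_true(all(is.na(unclass(avg)[2:6, ])))
})

test_that("rows observed in only some year-pairs average over those pairs only", {
  r1 <- matrix(NA_real_, 7, 7); r1[1, ] <- c(100, 0, 0, 0, 0, 0, 0)
  r2 <- r1; r2[1, ] <- c(0, 100, 0, 0, 0, 0, 0)
  r_unobs <- matrix(NA_real_, 7, 7)
  avg <- average_annual_matrices(list(r1, r1, r1, r1, r2, r_unobs))
  expect_equal(unname(unclass(avg)[1, 1:2]), c(80, 20))
  expect_equal(attr(avg, "n_pairs")[["no_component"]], 5L)
})

test_that("unweighted averaging equals pooled counting when denominators are equal", {
  set.seed(8)
  counts <- lapply(1:5, function(i) {
    m <- matrix(0L, 7, 7)
    for (r in 1:7) m[r, ] <- as.integer(stats::rmultinom(1, 40, rep(1, 7)))
    m
  })
  rates <- lapply(counts, annual_rate_matrix)
  unw <- average_annual_matrices(rate_matrices = rates)
  pooled <- average_annual_matrices(count_matrices = counts,
                                    mode = "pooled")
  expect_equal(unclass(unw), unclass(pooled), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("estimates are invariant to subject row order", {
  model <- default_gt_model(n_per_stratum = 150, seed = 77)
  cls <- classify_cohort(simulate_cohort(model))$records
  m1 <- estimate_transition_matrices(cls)
  set.seed(1)
  m2 <- estimate_transition_matrices(cls[sample.int(nrow(cls)), ])
  for (st in names(m1)) {
    expect_equal(unclass(m1[[st]]), unclass(m2[[st]]), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("full-pipeline estimation recovers a known generating matrix", {
  truth <- fixture_matrix("women_18_40", normalize = TRUE)
  model <- ground_truth_model(list(women_18_40 = unclass(truth)),
                              n_per_stratum = 40000, seed = 31)
  cls <- classify_cohort(simulate_cohort(model))$records
  est <- estimate_transition_matrices(cls)[["women_18_40"]]
  # large, well-populated cell: persistence of the no-component state
  expect_lt(abs(unclass(est)["no_component", "no_component"] -
                  unclass(truth)["no_component", "no_component"]), 0.5)
  expect_equal(unname(rowSums(unclass(est))), rep(100, 7),
               tolerance = 1e-9)
})

test_that("descriptive summary matches hand-counted prevalences on a toy cohort", {
  co <- dplyr::bind_rows(
    toy_record(subject_id = "a", visit_year = 2007L, bmi = 27),   # iso ow
    toy_record(subject_id = "a", visit_year = 2008L, bmi = 27,
               sbp = 150, tg = 2.0),                              # ms
    toy_record(subject_id = "b", visit_year = 2007L, sex = "F"),  # none
    toy_record(subject_id = "b", visit_year = 2008L, sex = "F",
               fpg = 6.5)                                         # iso hg
  )
  s <- descriptive_summary(classify_cohort(co)$records)
  expect_equal(s$n, c(2L, 2L))
  expect_equal(s$pct_male, c(50, 50))
  expect_equal(s$pct_overweight, c(50, 50))
  expect_equal(s$pct_ms, c(0, 50))
  expect_equal(s$pct_hyperglycemia, c(0, 50))
  # a cohort where every record is MS shows 100% MS prevalence each year
  all_ms <- dplyr::bind_rows(
    toy_record(subject_id = "x", visit_year = 2007L, bmi = 27, sbp = 150,
               tg = 2.0),
    toy_record(subject_id = "x", visit_year = 2008L, bmi = 27, sbp = 150,
               tg = 2.0))
  s2 <- descriptive_summary(classify_cohort(all_ms)$records)
  expect_equal(s2$pct_ms, c(100, 100))
  expect_equal(nrow(descriptive_summary(classify_cohort(co[0, ])$records)), 0)
})
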