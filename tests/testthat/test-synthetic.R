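test_that("cohort demographics follow the configured distributions", {
  meds <- vapply(1:5, function(s)
    median(sample_cohort(26, seed = s)$weight), numeric(1))
  expect_true(all(meds > 60 & meds < 72))
  co <- sample_cohort(200, seed = 1)
  expect_true(all(co$weight >= 50 & co$weight <= 75))
  expect_true(all(co$ffm < co$weight))
  expect_gt(mean(co$sex == "female"), 0.75)
  # degenerate bounds pin the value
  cfg <- cohort_config(weight = list(mean = 67, sd = 5, min = 67, max = 67))
  expect_true(all(sample_cohort(3, cfg, seed = 2)$weight == 67))
  expect_error(sample_cohort(3, cohort_config(
    weight = list(mean = 67, sd = 5, min = 75, max = 50))), "bounds")
  expect_identical(sample_cohort(10, seed = 3), sample_cohort(10, seed = 3))
})

test_that("study design carries the published sampling schedule", {
  des <- ddi_study_design()
  expect_equal(lengths(des$plasma_times), c(9, 8, 8, 8))
  expect_equal(des$tau, c(24, 24, 12, 12))
  expect_equal(des$regimen, pk_regimens())
  expect_true(all(des$leadin_days >= 7))
  # PBMC troughs at visits 1, 3, 4 and a 12 h sample at visit 2
  expect_equal(unlist(des$pbmc_times), c(0, 12, 0, 0))
})

test_that("a 26-subject dataset has the nominal observation count and BLQ rate", {
  ds <- simulate_dataset(sample_cohort(26, seed = 11), ddi_study_design(),
                         atv$structural, atv$variability, atv$error,
                         seed = 12)
  plasma <- ds$evid == 0 & ds$cmt == 2
  expect_equal(sum(plasma), 858)   # 26 x (9 + 8 + 8 + 8)
  frac <- mean(ds$blq[plasma])
  expect_gt(frac, 0)
  expect_lt(frac, 0.10)
  # every visit's pre-dose sample is preceded by an unobserved-dose occasion
  for (v in 1:4) {
    sub <- ds[ds$id == 1 & ds$visit == v, ]
    t0 <- sub$time[sub$evid == 1 & sub$obsdose == 1]
    unobs <- sub[sub$evid == 1 & sub$obsdose == 0, ]
    expect_equal(nrow(unobs), 1)
    expect_lt(unobs$time, t0)
    expect_equal(unobs$ss, 1L)
  }
  validate_pk_dataset(ds)
})

test_that("zero variability and no error reproduce deterministic predictions", {
  co <- sample_cohort(2, seed = 21)
  ds <- simulate_dataset(co, ddi_study_design(), atv$structural,
                         variability_params(), err = NULL, seed = 22)
  obs <- ds[ds$evid == 0 & ds$id == 1 & ds$visit == 1 & ds$cmt == 2, ]
  p <- allometric_scale(atv$structural, co$ffm[1])
  man <- atvrpk:::visit_concentrations(p, 24, 300, obs$time - 7 * 24)
  expect_equal(obs$dv, man$plasma, tolerance = 1e-12)
  expect_false(any(ds$blq))
})

test_that("truth hooks expose the realised random effects", {
  ds <- small_dataset()
  tr <- attr(ds, "truth")
  expect_named(tr, c("drug", "dose", "params", "variability", "error",
                     "cohort", "draws"))
  expect_true(all(c("eta_cl_bsv", "eta_ka", "eta_f") %in% names(tr$draws)))
  expect_equal(nrow(tr$draws), 2 * 4 * 2)  # subjects x visits x occasions
  # occasion multipliers are strictly positive log-normals
  expect_true(all(tr$draws$f > 0 & tr$draws$ka > 0 & tr$draws$mtt > 0))
})
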