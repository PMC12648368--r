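test_that("a zero-variance model collapses the bands onto the prediction", {
  co <- sample_cohort(4, seed = 81)
  ds <- simulate_dataset(co, ddi_study_design(), atv$structural,
                         variability_params(), err = NULL, seed = 82)
  v <- vpc(ds, atv$structural, variability_params(), err = NULL,
           n_rep = 100, seed = 83)
  expect_true(all(abs(v$p50_hi - v$p50_lo) < 1e-10))
  expect_true(all(abs(v$obs_p50 - v$p50_lo) < 1e-10))
})

test_that("percentiles and bands are ordered", {
  ds <- simulate_dataset(sample_cohort(8, seed = 84), ddi_study_design(),
                         atv$structural, atv$variability, atv$error,
                         seed = 85)
  v <- vpc(ds, atv$structural, atv$variability, atv$error, n_rep = 100,
           seed = 86)
  expect_true(all(v$obs_p5 <= v$obs_p50 & v$obs_p50 <= v$obs_p95))
  expect_true(all(v$p5_lo <= v$p5_hi))
  expect_true(all(v$p50_lo <= v$p50_hi))
  expect_true(all(v$p95_lo <= v$p95_hi))
  expect_s3_class(autoplot(v), "ggplot")
  expect_error(vpc(ds, atv$structural, atv$variability, atv$error,
                   n_rep = 50), ">= 100")
})

test_that("data simulated from the model fall inside their own bands", {
  ds <- simulate_dataset(sample_cohort(26, seed = 87), ddi_study_design(),
                         atv$structural, atv$variability, atv$error,
                         seed = 88)
  v <- vpc(ds, atv$structural, atv$variability, atv$error, n_rep = 150,
           seed = 89)
  inside <- c(v$obs_p50 >= v$p50_lo & v$obs_p50 <= v$p50_hi,
              v$obs_p5 >= v$p5_lo & v$obs_p5 <= v$p5_hi,
              v$obs_p95 >= v$p95_lo & v$obs_p95 <= v$p95_hi)
  expect_gte(mean(inside), 0.9)
})

test_that("sparse bins are merged with a warning", {
  ds <- simulate_dataset(sample_cohort(4, seed = 90), ddi_study_design(),
                         atv$structural, atv$variability, atv$error,
                         seed = 91)
  # drop most of one plasma bin so it falls under the occupancy threshold
  drop <- which(ds$evid == 0 & ds$cmt == 2 & ds$visit == 1 &
                  ds$time == 7 * 24 + 0.5)[-1]
  expect_warning(vpc(ds[-drop, ], atv$structural, atv$variability,
                     atv$error, n_rep = 100, seed = 92), "merging")
})
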