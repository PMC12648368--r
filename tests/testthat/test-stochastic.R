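test_that("degenerate variances reproduce the typical values exactly", {
  d0 <- draw_individual(atv$structural, variability_params(), seed = 1)
  expect_true(all(d0$cl == atv$structural$cl))
  expect_true(all(d0$ka == atv$structural$ka))
  expect_true(all(d0$f == atv$structural$f))
})

test_that("log-scale SDs of the draws match the stated variabilities", {
  # subject-level clearance effect: 27.6% CV on the log scale
  withr::local_seed(42)
  etas <- vapply(1:2000, function(i)
    draw_individual(atv$structural, atv$variability,
                    n_visits = 1)$eta_cl_bsv[1], numeric(1))
  expect_lt(abs(100 * sd(etas) - 27.6), 1.5)
  # occasion effects: many occasions from a single realisation
  big <- draw_individual(atv$structural, atv$variability, n_visits = 4000,
                         occasions_per_visit = 2, seed = 7)
  sd_obs <- sd(big$eta_ka[!big$unobserved])
  sd_unobs <- sd(big$eta_ka[big$unobserved])
  expect_lt(abs(sd_obs - 0.979), 0.04)
  # unobserved doses carry 1.63-fold inflated BOV
  expect_lt(abs(sd_unobs / sd_obs - 1.63), 0.1)
  # log-normal multipliers have median 1
  expect_lt(abs(median(exp(big$eta_f[!big$unobserved])) - 1), 0.02)
  expect_lt(abs(median(big$f[!big$unobserved]) / atv$structural$f - 1), 0.02)
})

test_that("identical seeds give bit-identical realisations", {
  a <- draw_individual(atv$structural, atv$variability, seed = 99)
  b <- draw_individual(atv$structural, atv$variability, seed = 99)
  expect_identical(a, b)
  x <- apply_residual_error(rep(1, 10), atv$error, seed = 5)
  y <- apply_residual_error(rep(1, 10), atv$error, seed = 5)
  expect_identical(x, y)
})

test_that("combined residual error adds variances", {
  e0 <- list(prop = 0, add = 0, prop_pbmc = 0, add_pbmc = 0)
  expect_equal(apply_residual_error(c(0.5, 2), e0), c(0.5, 2))
  y <- apply_residual_error(rep(1, 20000), atv$error, seed = 3)
  expect_lt(abs(sd(y) - sqrt(0.198^2 + 0.006^2)), 0.005)
  # zero prediction: additive noise floored at zero
  y0 <- apply_residual_error(rep(0, 2000), atv$error, seed = 4)
  expect_true(all(y0 >= 0))
  expect_true(any(y0 == 0) && any(y0 > 0))
  expect_error(apply_residual_error(-1, atv$error), ">= 0")
})

test_that("BLQ censoring imputes LLOQ/2 below the strict threshold", {
  out <- censor_blq(c(0.010, 0.030, 0), lloq = 0.030)
  expect_equal(out$value, c(0.015, 0.030, 0.015))
  expect_equal(out$blq, c(TRUE, FALSE, TRUE))
  expect_error(censor_blq(1, 0), "> 0")
})
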