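test_that("fat-free mass matches hand-computed sex-specific values", {
  # female 67 kg / 1.59 m: 9270*67 / (8780 + 244*26.503) = 40.74
  expect_equal(compute_ffm(67, 1.59, "female"), 40.74, tolerance = 1e-3)
  # male 70 kg / 1.75 m: 9270*70 / (6680 + 216*22.857) = 55.86
  expect_equal(compute_ffm(70, 1.75, "male"), 55.86, tolerance = 1e-3)
  # consistent with the study's median fat-free mass of 41 kg
  expect_lt(abs(compute_ffm(67, 1.59, "female") - 41), 1)
})

test_that("fat-free mass is below weight, monotone in weight, deterministic", {
  w <- seq(40, 120, by = 5)
  ffm_f <- compute_ffm(w, 1.6, "female")
  ffm_m <- compute_ffm(w, 1.6, "male")
  expect_true(all(ffm_f < w))
  expect_true(all(ffm_m < w))
  expect_true(all(diff(ffm_f) > 0))
  expect_true(all(diff(ffm_m) > 0))
  expect_identical(compute_ffm(67, 1.59, "female"),
                   compute_ffm(67, 1.59, "female"))
})

test_that("ffm rejects bad inputs", {
  expect_error(compute_ffm(-1, 1.6, "female"), "positive")
  expect_error(compute_ffm(60, 0, "female"), "positive")
  expect_error(compute_ffm(60, 1.6, "unknown"), "sex")
})

test_that("allometric scaling uses exponents 0.75 and 1", {
  p <- atv$structural
  same <- allometric_scale(p, 42, 42)
  expect_equal(unclass(same), unclass(p))
  half <- allometric_scale(p, 21, 42)
  expect_equal(half$cl, 7.57 * 0.5^0.75, tolerance = 1e-10)
  expect_equal(half$cl, 4.5011, tolerance = 1e-4)
  expect_equal(half$v, 77.5 / 2)
  dbl <- allometric_scale(p, 84, 42)
  expect_equal(dbl$cl / p$cl, 2^0.75)
  expect_equal(dbl$q / p$q, 2^0.75)
  expect_equal(dbl$v / p$v, 2)
  expect_equal(dbl$vp / p$vp, 2)
  expect_equal(dbl$mtt, p$mtt)  # absorption untouched
  expect_error(allometric_scale(p, -1, 42), "positive")
})

test_that("regimen covariate effects reproduce the final-model multipliers", {
  p <- atv$structural
  qd_rif <- apply_regimen_effects(p, "ATVr_QD_RIF600")
  expect_equal(qd_rif$cl, 7.57 * 3.05, tolerance = 1e-10)
  expect_equal(qd_rif$f, 0.475)
  expect_equal(qd_rif$ka, 6 * 0.327)
  bid_rif <- apply_regimen_effects(p, "ATVr_BID_RIF600")
  expect_equal(bid_rif$cl / p$cl, 2.03)
  expect_equal(bid_rif$f, 1)  # bioavailability restored at BID
  expect_equal(bid_rif$ka / p$ka, 0.327)
  ref <- apply_regimen_effects(p, "ATVr_QD")
  expect_equal(unclass(ref), unclass(p))
  expect_error(apply_regimen_effects(p, "ATV_TID"), "unknown regimen")
  # ritonavir: single CL fold for all rifampicin regimens, F partially
  # restored at BID
  r <- regimen_effects("ritonavir")
  expect_equal(r$cl_fold[r$regimen == "ATVr_BID_RIF600"], 2.12)
  expect_equal(r$f_mult[r$regimen == "ATVr_QD_RIF600"], 0.312)
  expect_equal(r$f_mult[r$regimen == "ATVr_BID_RIF600"], 0.667)
})

test_that("parameter config round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_pk_config(atv, f)
  back <- read_pk_config(f)
  expect_equal(unclass(back$structural), unclass(atv$structural))
  expect_equal(unclass(back$variability), unclass(atv$variability))
  expect_equal(unclass(back$error), unclass(atv$error))
  expect_equal(back$dose, atv$dose)
  expect_equal(as.data.frame(back$regimen), as.data.frame(atv$regimen))
})

test_that("structural parameter invariants are enforced", {
  expect_error(structural_params(cl = -1, v = 50), "positive")
  expect_error(structural_params(cl = 5, v = 50, f = 1.6), "1.5")
  expect_error(structural_params(cl = 5, v = 50, nn = -1), "nn")
  expect_error(error_model(prop = 0.2, add = 0.001, lloq = 0.03), "20%")
  expect_error(variability_params(bsv_cl = -0.1), ">= 0")
})
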