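test_that("no doses yield zero concentrations", {
  p <- atv$structural
  pr <- predict_profile(p, data.frame(time = numeric(0), amount = numeric(0)),
                        0:10)
  expect_true(all(pr$plasma == 0))
  expect_true(all(pr$pbmc == 0))
})

test_that("one-compartment no-delay limit matches the Bateman closed form", {
  # q = 0, nn = 0, mtt -> 0: absorption is a single first-order step and the
  # plasma curve is (F D / V) ka/(ka-ke) (exp(-ke t) - exp(-ka t))
  for (ka in c(1, 100)) {
    p <- structural_params(cl = 7.57, v = 77.5, q = 0, vp = 1, f = 1,
                           ka = ka, mtt = 1e-3, nn = 0, teq = 1, ppc = 1)
    tt <- seq(0.5, 48, by = 0.5)
    pr <- predict_profile(p, data.frame(time = 0, amount = 300), tt)
    ke <- 7.57 / 77.5
    bateman <- (300 / 77.5) * ka / (ka - ke) * (exp(-ke * tt) - exp(-ka * tt))
    expect_lt(max(abs(pr$plasma - bateman) / bateman), 0.005)
  }
})

test_that("analytic gamma input agrees with the explicit transit chain", {
  for (nn in c(1, 5, 10)) {
    p <- structural_params(cl = 7.57, v = 77.5, q = 3.13, vp = 42.1,
                           ka = 6, mtt = 0.5, nn = nn, teq = 0.963,
                           ppc = 0.653)
    tt <- seq(0.25, 36, by = 0.25)
    doses <- data.frame(time = 0, amount = 300)
    a <- predict_profile(p, doses, tt)
    o <- predict_profile(p, doses, tt, method = "transit_chain")
    keep <- a$plasma > 1e-5
    expect_lt(max(abs(a$plasma - o$plasma)[keep] / a$plasma[keep]), 0.005)
    keep <- a$pbmc > 1e-5
    expect_lt(max(abs(a$pbmc - o$pbmc)[keep] / a$pbmc[keep]), 0.005)
  }
})

test_that("multiple doses superpose linearly", {
  p <- atv$structural
  doses <- data.frame(time = c(0, 24, 48), amount = c(300, 300, 150))
  tt <- seq(0, 96, by = 1)
  total <- predict_profile(p, doses, tt)
  parts <- lapply(seq_len(nrow(doses)), function(i)
    predict_profile(p, doses[i, ], tt))
  sum_p <- Reduce(`+`, lapply(parts, function(x) x$plasma))
  sum_e <- Reduce(`+`, lapply(parts, function(x) x$pbmc))
  keep <- total$plasma > 1e-8
  expect_lt(max(abs(total$plasma - sum_p)[keep] / total$plasma[keep]), 0.001)
  keep <- total$pbmc > 1e-8
  expect_lt(max(abs(total$pbmc - sum_e)[keep] / total$pbmc[keep]), 0.001)
})

test_that("profiles are non-negative and finite across extreme draws", {
  withr::local_seed(7)
  for (i in 1:20) {
    p <- structural_params(cl = exp(rnorm(1, log(7.6), 1)),
                           v = exp(rnorm(1, log(77), 1)),
                           q = exp(rnorm(1, log(3), 1)),
                           vp = exp(rnorm(1, log(42), 1)),
                           ka = exp(rnorm(1, log(6), 1.5)),
                           mtt = exp(rnorm(1, log(0.5), 1)),
                           nn = sample(c(0, 1, 5.5, 10, 12.3), 1),
                           teq = exp(rnorm(1, 0, 1)),
                           ppc = exp(rnorm(1, 0, 0.7)))
    pr <- predict_profile(p, data.frame(time = c(0, 24), amount = 300),
                          seq(0, 48, by = 0.5))
    expect_true(all(is.finite(pr$plasma)) && all(pr$plasma >= 0))
    expect_true(all(is.finite(pr$pbmc)) && all(pr$pbmc >= 0))
    sv <- atvrpk:::visit_concentrations(p, 24, 300, c(0, 1, 6, 12, 24))
    expect_true(all(is.finite(sv$plasma)) && all(sv$plasma >= 0))
  }
})

test_that("dose and time preconditions are enforced", {
  p <- atv$structural
  expect_error(predict_profile(p, data.frame(time = -1, amount = 300), 0:2),
               ">= 0")
  expect_error(predict_profile(p, data.frame(time = 0, amount = 0), 0:2),
               "> 0")
  expect_error(predict_profile(p, data.frame(time = 0, amount = 300),
                               c(2, 1)), "sorted")
})
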