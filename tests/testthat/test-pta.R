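test_that("target attainment proportions behave as probabilities", {
  co <- sample_cohort(150, seed = 51)
  pta <- simulate_pta(co, "ATVr_QD", thresholds = c(0, 0.014, 0.15, 1),
                      seed = 52)
  expect_equal(pta$prop[pta$threshold == 0], 1)  # threshold 0 attains always
  props <- pta$prop[order(pta$threshold)]
  expect_true(all(diff(props) <= 0))  # monotone non-increasing in threshold
  expect_true(all(pta$prop >= 0 & pta$prop <= 1))
  expect_true(all(pta$n == 150))
  bands <- attr(pta, "bands")
  tot <- bands |>
    dplyr::filter(.data$threshold == 0) |>
    dplyr::summarise(n = sum(.data$n))
  expect_equal(tot$n, 150)  # weight bands partition the cohort
})

test_that("the three scenarios rank as expected and BID matches at both rifampicin doses", {
  co <- sample_cohort(200, seed = 53)
  pta <- simulate_pta(co, "all", seed = 54)
  p15 <- function(rg) pta$prop[pta$regimen == rg & pta$threshold == 0.15]
  expect_lt(p15("ATVr_QD_RIF600"), p15("ATVr_QD"))
  expect_gt(p15("ATVr_BID_RIF600"), p15("ATVr_QD_RIF600"))
  a <- simulate_pta(co, "ATVr_BID_RIF600", seed = 55)
  b <- simulate_pta(co, "ATVr_BID_RIF1200", seed = 55)
  expect_equal(a$prop, b$prop)  # same final-model parameters
})

test_that("a 12-h trough read for QD regimens sits above the 24-h trough", {
  co <- sample_cohort(80, seed = 56)
  t24 <- simulate_pta(co, "ATVr_QD_RIF600", seed = 57)
  t12 <- simulate_pta(co, "ATVr_QD_RIF600", trough_time = 12, seed = 57)
  expect_gt(mean(attr(t12, "troughs")$ctrough),
            mean(attr(t24, "troughs")$ctrough))
})

test_that("Monte Carlo error shrinks with cohort size", {
  p_small <- vapply(1:8, function(s)
    simulate_pta(sample_cohort(120, seed = 60 + s), "ATVr_QD",
                 thresholds = 0.15, seed = 80 + s)$prop, numeric(1))
  p_big <- vapply(1:8, function(s)
    simulate_pta(sample_cohort(480, seed = 160 + s), "ATVr_QD",
                 thresholds = 0.15, seed = 180 + s)$prop, numeric(1))
  # quadrupling n roughly halves the SE; allow wide slack for 10 replicates
  expect_lt(sd(p_big), sd(p_small))
})

test_that("single-draw occasion handling widens the trough distribution", {
  co <- sample_cohort(300, seed = 58)
  a <- simulate_pta(co, "ATVr_QD", occasion = "per_dose", seed = 59)
  b <- simulate_pta(co, "ATVr_QD", occasion = "single_draw", seed = 59)
  expect_gt(sd(log(attr(b, "troughs")$ctrough)),
            sd(log(attr(a, "troughs")$ctrough)))
})
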