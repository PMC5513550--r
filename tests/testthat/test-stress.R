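test_that("stress accumulation matches the brute-force oracle", {
  expect_equal(stress_accumulate(rep(0, 52), 0.01), 0)
  # persistent mild stress: rate 0.008, exceedance 0.1, n_w = w
  expect_equal(stress_accumulate(rep(0.1, 52), 0.008),
               100 * min(1, 0.0008 * (52 * 53 / 2)))
  set.seed(99)
  for (i in 1:200) {
    exceed <- ifelse(runif(52) < runif(1, 0.2, 0.9), runif(52, 0, 2), 0)
    rate <- runif(1, 0, 0.02)
    expect_equal(stress_accumulate(exceed, rate),
                 oracle_accumulate(exceed, rate))
  }
  # wrapped run across the year boundary
  exceed <- c(rep(1, 5), rep(0, 40), rep(1, 7))
  expect_equal(stress_accumulate(exceed, 0.001),
               oracle_accumulate(exceed, 0.001))
})

test_that("cold stress activates below the degree-day threshold", {
  p <- preset_params("current")
  warm <- ecoclimex:::weekly_degree_days(rep(20, 52), p$DVCS)   # 94.5/wk
  expect_equal(cold_stress(warm, p), 0)
  expect_equal(cold_stress(rep(10, 52), p), 0)      # exactly at DTCS
  cold <- ecoclimex:::weekly_degree_days(rep(6.5, 52), p$DVCS)  # 0/wk
  expect_equal(cold_stress(cold, p), 100)           # capped accumulation
})

test_that("heat stress threshold is strict at TTHS", {
  p <- preset_params("current")
  expect_equal(heat_stress(rep(20, 52), p), 0)
  expect_equal(heat_stress(rep(33, 52), p), 0)      # at threshold: none
  expect_equal(heat_stress(rep(35, 52), p), 100)
})

test_that("dry stress threshold is strict at SMDS", {
  p <- preset_params("current")
  expect_equal(dry_stress(rep(0.25, 52), p), 0)
  expect_equal(dry_stress(rep(0.2, 52), p), 0)
  expect_equal(dry_stress(rep(0.1, 52), p), 100)
})

test_that("wet stress is disabled when its rate is zero, active otherwise", {
  cur <- preset_params("current")
  expect_equal(wet_stress(rep(4.0, 52), cur), 0)    # mechanism off
  sm <- preset_params("spradbery_maywald")
  expect_equal(wet_stress(rep(2.5, 52), sm), 0)     # at SMWS boundary
  expect_equal(wet_stress(rep(3.0, 52), sm), 100)
})

test_that("hot-wet stress needs both legs of the joint condition", {
  p <- preset_params("current")
  expect_equal(hot_wet_stress(rep(20, 52), rep(2.0, 52), p), 0)  # cool
  expect_equal(hot_wet_stress(rep(25, 52), rep(0.3, 52), p), 0)  # dry
  expect_equal(hot_wet_stress(rep(25, 52), rep(0.6, 52), p), 100)
  # mechanism disabled where unparameterised
  tr <- preset_params("tribe_richardson")
  expect_equal(hot_wet_stress(rep(30, 52), rep(2, 52), tr), 0)
})

test_that("each stress is monotone in its exceedance series", {
  p <- preset_params("current")
  set.seed(17)
  for (i in 1:20) {
    e1 <- ifelse(runif(52) < 0.5, runif(52, 0, 1), 0)
    e2 <- e1 + ifelse(e1 > 0, runif(52, 0, 0.5), 0)
    expect_gte(stress_accumulate(e2, 0.005), stress_accumulate(e1, 0.005))
    # dry stress never increases when soil gets wetter
    sm1 <- runif(52, 0, 0.5)
    sm2 <- sm1 + runif(52, 0, 0.3)
    expect_lte(dry_stress(sm2, p), dry_stress(sm1, p))
  }
})

test_that("stresses combine multiplicatively; interactions stay inactive", {
  expect_equal(stress_result()$combined_factor, 1)
  expect_equal(stress_result(cold = 100)$combined_factor, 0)
  expect_equal(stress_result(cold = 50, dry = 50)$combined_factor, 0.25)
  s <- stress_result(cold = 20, heat = 10)
  expect_equal(combine_stresses(s), 0.8 * 0.9)
  # unparameterised interaction stresses are structurally present, zero
  expect_identical(c(s$cold_dry, s$cold_wet, s$hot_dry), c(0, 0, 0))
  expect_error(stress_result(cold = 120), "\\[0,100\\]")
})
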