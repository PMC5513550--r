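test_that("summer top-up raises rainfall to the 7*rate floor", {
  p <- rep(2, 52)
  out <- apply_irrigation(p, lat = -41, irrigation_scenario(2.5))
  expect_equal(out[1], 17.5)                   # January, austral summer
  expect_equal(out[30], 2)                     # July, austral winter
  # already-wet weeks are untouched (top-up, not additive)
  wet <- rep(30, 52)
  expect_equal(apply_irrigation(wet, -41, irrigation_scenario(2.5)), wet)
  # northern site irrigates the other half-year
  out_n <- apply_irrigation(p, lat = 48, irrigation_scenario(2.5))
  expect_equal(out_n[30], 17.5)
  expect_equal(out_n[1], 2)
  expect_error(irrigation_scenario(rate = -1), "non-negative")
})

test_that("irrigated rainfall never falls below the natural input", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(52, 0, 40)
    lat <- runif(1, -60, 60)
    out <- apply_irrigation(p, lat, irrigation_scenario(runif(1, 0, 5)))
    expect_true(all(out >= p))
  }
})

test_that("evaporative demand is zero when cold or saturated", {
  expect_equal(potential_et(-5, 0.3), 0)
  expect_equal(potential_et(20, 1.0), 0)
  expect_equal(potential_et(20, 0.5, k_et = 0.6), 42)
  expect_error(potential_et(20, 1.2), "rh")
})

test_that("bucket arithmetic matches the one-step update", {
  step <- ecoclimex:::bucket_pass(0.5, precip = 35, et_pot = 14,
                                  capacity = 100, sm_cap = 5)
  expect_equal(step$et, 14 * 0.5)
  expect_equal(step$sm, 0.5 + (35 - 7) / 100)   # 0.78
})

test_that("bucket fixed points: no flux holds, pure demand drains", {
  none <- run_bucket(rep(0, 52), rep(0, 52), sm_init = 0.5)
  expect_equal(none$sm, rep(0.5, 52))
  dry <- run_bucket(rep(0, 52), rep(10, 52), sm_init = 0.9)
  expect_equal(dry$sm, rep(0, 52), tolerance = 1e-6)
})

test_that("soil moisture is monotone in rainfall and spin-up forgets its start", {
  set.seed(23)
  for (i in 1:10) {
    ep <- runif(52, 0, 40)
    p1 <- runif(52, 0, 30)
    p2 <- p1 + runif(52, 0, 10)          # pointwise-wetter input
    sm1 <- run_bucket(p1, ep)$sm
    sm2 <- run_bucket(p2, ep)$sm
    expect_true(all(sm2 >= sm1 - 1e-9))
    # fixed point independent of the initial state
    alt <- run_bucket(p1, ep, sm_init = runif(1, 0, 5))$sm
    expect_equal(alt, sm1, tolerance = 1e-4)
  }
})

test_that("irrigation never lowers weekly soil moisture", {
  set.seed(31)
  for (i in 1:5) {
    s <- random_site(paste0("s", i), lat = -40)
    wk <- monthly_to_weekly(s)
    ep <- potential_et(wk$tavg, wk$rh)
    nat <- run_bucket(wk$precip, ep)$sm
    irr <- run_bucket(apply_irrigation(wk$precip, s$lat,
                                       irrigation_scenario()), ep)$sm
    expect_true(all(irr >= nat - 1e-9))
  }
})
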