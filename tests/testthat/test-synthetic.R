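test_that("generation is deterministic in the seed and varies across seeds", {
  for (prof in climate_profiles()) {
    a <- make_site(prof, seed = 1)
    b <- make_site(prof, seed = 1)
    expect_equal(unclass(a), unclass(b), info = prof)
  }
  a <- make_site("patagonia_xeric", seed = 1)
  b <- make_site("patagonia_xeric", seed = 2)
  expect_false(isTRUE(all.equal(a$precip, b$precip)))
})

test_that("generated sites honour their profile contracts", {
  p <- preset_params("current")
  for (s in 1:3) {
    pat <- make_site("patagonia_xeric", s)
    tavg <- (pat$tmin + pat$tmax) / 2
    expect_lt(pat$lat, 0)
    expect_lt(sum(pat$precip), 250)
    expect_gt(sum(pat$precip[6:8]), sum(pat$precip[c(12, 1, 2)]))
    expect_lt(mean(tavg[6:8]), 5)
    st <- mean(tavg[c(12, 1, 2)])
    expect_true(st >= 12 && st <= 22)

    trop <- make_site("tropical_hot_wet", s)
    expect_gt(min((trop$tmin + trop$tmax) / 2), 24)
    expect_gt(sum(trop$precip), 1800)
    expect_gt(mean(c(trop$rh09, trop$rh15)), 0.7)
    # persistent hot-wet conditions cap the joint stress; EI collapses
    res <- run_location(trop, p)
    expect_equal(res$stresses$hot_wet, 100)
    expect_equal(res$ei, 0)

    alp <- make_site("alpine_cold", s)
    expect_lt(max((alp$tmin + alp$tmax) / 2), 6)
    expect_equal(run_location(alp, p)$ei, 0)

    opt <- make_site("optimal_constant", s)
    sm <- run_location(opt, p)$weekly$sm
    expect_true(all(sm >= 0.8 & sm <= 1.2))

    med <- make_site("mediterranean", s)
    tavg <- (med$tmin + med$tmax) / 2
    expect_true(min(tavg) >= 8 && max(tavg) <= 24)
  }
})

test_that("every generated site passes the climate-table validators", {
  path <- withr::local_tempfile(fileext = ".csv")
  sites <- lapply(climate_profiles(), make_site, seed = 6)
  write_climate_table(sites, path)
  expect_length(read_climate_table(path), length(sites))
})

test_that("synthetic grids span the gradients and validate everywhere", {
  g <- make_grid(10, 10, seed = 8)
  expect_length(g$sites, 100)
  expect_true(any(g$mask) && !all(g$mask))
  profs <- unique(sub("^cell_r\\d+_c\\d+_", "", names(g$sites)))
  expect_setequal(profs, climate_profiles())
  for (s in g$sites[seq(1, 100, by = 7)]) {
    expect_silent(ecoclimex:::validate_location_climate(s))
  }
  # determinism
  g2 <- make_grid(10, 10, seed = 8)
  expect_equal(g$mask, g2$mask)
  expect_equal(unclass(g$sites[[5]]), unclass(g2$sites[[5]]))
})

test_that("masked arid cells gain (or keep) suitability under the composite", {
  p <- preset_params("current")
  g <- make_grid(6, 4, seed = 12)
  rg <- run_grid(g, p)
  m <- rg[rg$irrigated_mask, ]
  expect_gt(nrow(m), 0)
  expect_true(all(m$ei_composite >= m$ei_natural))
})
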