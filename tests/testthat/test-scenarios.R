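test_that("pipeline extremes: constant optimum scores 100, cold scores 0", {
  p <- preset_params("current")
  opt <- make_site("optimal_constant", seed = 4)
  expect_equal(run_location(opt, p)$ei, 100)
  cold <- constant_site(tmin = 0, tmax = 8)   # tavg 4, below DV0
  res <- run_location(cold, p)
  expect_equal(res$ei, 0)
  expect_equal(res$gi_a, 0)
  expect_lt(res$dd_annual, p$PDD)
  expect_equal(res$ei_class, "unsuitable")
})

test_that("runs are deterministic and irrigation relieves dry stress", {
  p <- preset_params("current")
  site <- make_site("patagonia_xeric", seed = 2)
  a <- run_location(site, p, irrigation_scenario())
  b <- run_location(site, p, irrigation_scenario())
  expect_identical(a, b)
  nat <- run_location(site, p)
  expect_lte(a$stresses$dry, nat$stresses$dry)
  expect_gte(a$ei, nat$ei)
})

test_that("composite mapping follows the per-cell mask rule", {
  p <- preset_params("current")
  sites <- list(make_site("patagonia_xeric", 1),
                make_site("mediterranean", 1),
                make_site("optimal_constant", 1))
  all_off <- run_grid(sites, p, mask = rep(FALSE, 3))
  expect_equal(all_off$ei_composite, all_off$ei_natural)
  all_on <- run_grid(sites, p, mask = rep(TRUE, 3))
  expect_equal(all_on$ei_composite, all_on$ei_irrigated)
  mixed <- run_grid(sites, p, mask = c(TRUE, FALSE, TRUE))
  expect_equal(mixed$ei_composite,
               ifelse(mixed$irrigated_mask, mixed$ei_irrigated,
                      mixed$ei_natural))
  expect_error(run_grid(list(), p), "empty grid")
  expect_error(run_grid(sites, p, mask = c(TRUE, FALSE)), "mask length")
})

test_that("a 1-cell grid agrees with run_location", {
  p <- preset_params("current")
  site <- make_site("mediterranean", seed = 9)
  g <- run_grid(list(site), p, mask = TRUE)
  expect_equal(g$ei_natural, run_location(site, p)$ei)
  expect_equal(g$ei_irrigated,
               run_location(site, p, irrigation_scenario())$ei)
})

test_that("risk grids round-trip through CSV with the rule intact", {
  p <- preset_params("current")
  g <- make_grid(4, 3, seed = 5)
  rg <- run_grid(g, p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_risk_grid(rg, path)
  back <- read_risk_grid(path)
  expect_equal(as.data.frame(back), as.data.frame(rg))
  expect_identical(attr(back, "nrow"), attr(rg, "nrow"))
  # composite layer recomputable from the other two plus the mask
  expect_equal(back$ei_composite,
               ifelse(back$irrigated_mask, back$ei_irrigated,
                      back$ei_natural))
})

test_that("phenology tables capture the seasonal contrast", {
  p <- preset_params("current")
  opt <- make_site("optimal_constant", seed = 3)
  ph <- phenology(opt, p)
  expect_equal(nrow(ph), 52)
  expect_equal(ph$gi_natural, rep(1, 52))
  expect_equal(ph$gi_irrigated, rep(1, 52))

  pat <- make_site("patagonia_xeric", seed = 3)
  ph <- phenology(pat, p)
  expect_equal(ph$gi_natural, rep(0, 52))       # no growth on rainfall alone
  expect_gt(max(ph$gi_irrigated), 0)
  peak <- which.max(ph$gi_irrigated)
  expect_true(peak >= 9 && peak <= 13)          # austral late summer

  path <- withr::local_tempfile(fileext = ".csv")
  write_phenology(ph, path)
  expect_equal(utils::read.csv(path)$gi_irrigated, ph$gi_irrigated)
})
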