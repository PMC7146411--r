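test_that("the analytic crop coefficient tracks canopy development", {
  sites <- tiny_sites()
  wx <- sim_weather(tiny_clim(), irrigation_season(2014), seed = 71)
  kc_lo <- crop_coefficient(wx, constant_canopy(lai = 0.5, albedo = 0.15),
                            sites, on_undefined = "drop")
  kc_hi <- crop_coefficient(wx, constant_canopy(lai = 5, albedo = 0.20),
                            sites, on_undefined = "drop")
  # early-season sparse canopy sits around half the reference demand,
  # a dense mid-season canopy a little above it
  expect_gt(median(kc_lo$kc), 0.35)
  expect_lt(median(kc_lo$kc), 0.75)
  expect_gt(median(kc_hi$kc), 1.0)
  expect_lt(median(kc_hi$kc), 1.35)
  expect_true(all(kc_hi$kc > kc_lo$kc))
  expect_true(all(kc_lo$canopy_date == as.Date("2014-05-20")))
})

test_that("grass-parameter canopy yields a crop coefficient of one", {
  sites <- tiny_sites()
  wx <- sim_weather(tiny_clim(), irrigation_season(2014), seed = 72)
  et0 <- et0_penman_monteith(wx, sites)
  etc_ref <- etc_penman_monteith(wx, canopy = NULL, sites = sites, h_c = 0.12,
                                 rs_fixed = 70, albedo_fixed = 0.23)
  kc <- etc_ref$et_mm / et0$et_mm
  expect_true(all(abs(kc - 1) < 0.02))
})

test_that("near-zero reference ET makes the crop coefficient undefined", {
  wx <- fixed_weather_row()
  wx$rs_wm2 <- 0; wx$rh_mean <- 100; wx$ws10 <- 0
  wx$t_max <- 10; wx$t_min <- 10; wx$t_mean <- 10
  expect_error(
    suppressWarnings(crop_coefficient(wx, constant_canopy(), tiny_sites())),
    "undefined"
  )
  dropped <- suppressWarnings(
    crop_coefficient(wx, constant_canopy(), tiny_sites(), on_undefined = "drop")
  )
  expect_equal(nrow(dropped), 0)
})

test_that("ETc forecasts follow Kc linearity and lead structure", {
  sites <- tiny_sites()[1, ]
  wx <- sim_weather(tiny_clim()[1, ], irrigation_season(2014), seed = 73)
  canopy <- constant_canopy(lai = 3, albedo = 0.18)
  fc <- forecasts_from_obs(wx)
  kc <- crop_coefficient(wx, canopy, sites, on_undefined = "drop")

  out <- forecast_etc(kc, fc, sites, canopy = canopy, k_hs = 0.85)
  expect_true(all(out$lead %in% 1:5))
  expect_true(all(out$etc_hs_mm >= 0))

  # zero crop coefficient zeroes the temperature-only path
  kc0 <- dplyr::mutate(kc, kc = 0)
  out0 <- forecast_etc(kc0, fc, sites, canopy = canopy, method = "hs")
  expect_equal(out0$etc_hs_mm, rep(0, nrow(out0)))

  # identical forecast temperatures across leads give identical daily ETc-HS
  fc_flat <- fc |>
    dplyr::group_by(site_id, issue_date) |>
    dplyr::mutate(t_mean = t_mean[1], t_max = t_max[1], t_min = t_min[1]) |>
    dplyr::ungroup()
  # neutralise the date-dependence of extraterrestrial radiation as well:
  # all leads of one issue share a valid-day window of five days, so compare
  # consecutive leads only through the Kc-free ratio
  out_flat <- forecast_etc(kc, fc_flat, sites, canopy = canopy, method = "hs")
  one <- out_flat[out_flat$issue_date == out_flat$issue_date[1], ]
  ra <- extraterrestrial_radiation(
    sites$lat, as.integer(strftime(one$issue_date + one$lead, "%j"))
  )
  expect_equal(one$etc_hs_mm / ra, rep(one$etc_hs_mm[1] / ra[1], 5),
               tolerance = 1e-12)
})

test_that("a perfect forecast reproduces the best estimate exactly", {
  sites <- tiny_sites()
  wx <- sim_weather(tiny_clim(), irrigation_season(2014), seed = 74)
  canopy <- constant_canopy(lai = 3.5, albedo = 0.19)
  fc <- forecasts_from_obs(wx)
  kc <- crop_coefficient(wx, canopy, sites, on_undefined = "drop")
  out <- forecast_etc(kc, fc, sites, canopy = canopy, method = "pm") |>
    dplyr::mutate(valid_date = issue_date + lead)
  best <- etc_penman_monteith(wx, canopy, sites) |>
    dplyr::select(site_id, date, best_mm = et_mm)
  joined <- dplyr::inner_join(out, best,
                              by = c("site_id", "valid_date" = "date"))
  expect_equal(joined$etc_pm_mm, joined$best_mm, tolerance = 1e-12)
})

test_that("missing forecast variables are refused per method", {
  sites <- tiny_sites()[1, ]
  wx <- sim_weather(tiny_clim()[1, ], irrigation_season(2014), seed = 75)
  canopy <- constant_canopy()
  fc <- forecasts_from_obs(wx)
  kc <- crop_coefficient(wx, canopy, sites, on_undefined = "drop")
  fc_na <- dplyr::mutate(fc, rh_mean = NA_real_)
  expect_error(forecast_etc(kc, fc_na, sites, canopy = canopy, method = "pm"),
               "complete set")
  out_hs <- forecast_etc(kc, fc_na, sites, canopy = canopy, method = "hs")
  expect_true(all(is.finite(out_hs$etc_hs_mm)))
  fc_nat <- dplyr::mutate(fc, t_max = NA_real_)
  expect_error(forecast_etc(kc, fc_nat, sites, canopy = canopy, method = "hs"),
               "t_mean, t_max, t_min|finite")
})

test_that("horizon accumulation forms monotone partial sums", {
  fc <- tidyr::expand_grid(site_id = "s", issue_date = as.Date("2014-07-01"),
                           lead = 1:5) |>
    dplyr::mutate(etc_hs_mm = 1, etc_pm_mm = 2)
  acc <- accumulate_horizons(fc)
  expect_equal(acc$etc_hs_mm_acc, c(1, 3, 5))
  expect_equal(acc$etc_pm_mm_acc, c(2, 6, 10))
  zero <- dplyr::mutate(fc, etc_hs_mm = 0, etc_pm_mm = 0)
  expect_true(all(accumulate_horizons(zero)$etc_hs_mm_acc == 0))
  withr::with_seed(76, {
    rnd <- dplyr::mutate(fc, etc_hs_mm = runif(5, 0, 8))
    a <- accumulate_horizons(rnd, cols = "etc_hs_mm")
    expect_true(all(diff(a$etc_hs_mm_acc) >= 0))
  })
  expect_error(accumulate_horizons(fc[fc$lead != 4, ]), "Missing lead")
})
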