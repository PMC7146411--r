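# Frozen expected values come from an independent evaluation of the FAO-56
# worked procedure (high-precision scalar arithmetic outside this package).

test_that("vapour pressures follow the FAO-56 closures", {
  vp <- vapor_pressures(20, 20, 100)
  expect_equal(vp$e_s, 2.338281, tolerance = 1e-6)
  expect_equal(vp$e_a, vp$e_s) # saturated air
  expect_equal(vapor_pressures(25, 15, 0)$e_a, 0)
  vp2 <- vapor_pressures(10, 10, 50)
  expect_equal(vp2$e_a, vp2$e_s / 2)
  expect_gt(vp$delta, 0)
})

test_that("actual vapour pressure is linear in relative humidity", {
  withr::with_seed(4, {
    t_min <- runif(50, -5, 25)
    t_max <- t_min + runif(50, 0, 15)
    rh <- runif(50, 0, 100)
    vp <- vapor_pressures(t_max, t_min, rh)
    expect_equal(vp$e_a / vp$e_s, rh / 100)
    expect_true(all(vp$e_a >= 0 & vp$e_a <= vp$e_s))
  })
})

test_that("vapour pressure rejects invalid humidity and inverted extremes", {
  expect_error(vapor_pressures(20, 25, 50), "t_min")
  expect_error(vapor_pressures(25, 15, 101), "rh_mean")
  expect_error(vapor_pressures(25, 15, -1), "rh_mean")
})

test_that("air constants reproduce the barometric closure", {
  ac <- air_constants(0, 20)
  expect_equal(ac$pressure, 101.3, tolerance = 1e-6)
  expect_equal(ac$gamma, 0.0673645, tolerance = 1e-6)
  expect_equal(ac$lam, 2.45)
  expect_lt(air_constants(848, 20)$pressure, 101.3)
  # measured pressure overrides the elevation estimate
  expect_equal(air_constants(848, 20, pressure = 101.3)$gamma, 0.0673645,
               tolerance = 1e-6)
  # air density stays physical across the elevation/temperature envelope
  grid <- expand.grid(z = c(0, 400, 848), t = c(0, 20, 35))
  rho <- air_constants(grid$z, grid$t)$rho_air
  expect_true(all(rho > 0.7 & rho < 1.5))
  expect_error(air_constants(Inf, 20), "finite")
})

test_that("10 m to 2 m wind conversion is the constant log-profile factor", {
  expect_equal(round(wind_2m_from_10m(1), 2), 0.75)
  expect_equal(wind_2m_from_10m(1), 4.87 / log(67.8 * 10 - 5.42))
  expect_equal(wind_2m_from_10m(0), 0)
  expect_equal(wind_2m_from_10m(4.4), 4.4 * 0.7479511, tolerance = 1e-6)
  ws <- c(0.3, 1, 2.7, 8)
  expect_equal(wind_2m_from_10m(ws) / ws, rep(wind_2m_from_10m(1), 4))
  expect_error(wind_2m_from_10m(-1), "non-negative")
})

test_that("extraterrestrial radiation matches FAO-56 solar geometry", {
  expect_equal(extraterrestrial_radiation(40, 196), 40.79948, tolerance = 1e-5)
  expect_equal(extraterrestrial_radiation(70, 355), 0) # polar night
  grid <- expand.grid(lat = seq(-90, 90, by = 15), doy = seq(1, 366, by = 10))
  ra <- extraterrestrial_radiation(grid$lat, grid$doy)
  expect_true(all(ra >= 0))
  expect_error(extraterrestrial_radiation(95, 100), "latitude")
  expect_error(extraterrestrial_radiation(40, 0), "day_of_year")
  expect_error(extraterrestrial_radiation(40, 367), "day_of_year")
})

test_that("hemispheric Ra symmetry is exact once eccentricity is removed", {
  # half a (365-day) year later the declination flips sign exactly, so the
  # only asymmetry between hemispheres is the inverse-distance factor dr
  dr <- function(doy) 1 + 0.033 * cos(2 * pi / 365 * doy)
  for (lat in c(15, 35, 55)) {
    for (doy in c(15, 100, 180)) {
      doy2 <- ((doy + 182.5 - 1) %% 365) + 1
      a <- extraterrestrial_radiation(lat, doy) / dr(doy)
      b <- extraterrestrial_radiation(-lat, doy2) / dr(doy2)
      expect_equal(a, b, tolerance = 1e-9)
      # and the raw values differ by at most the dr ratio (about 7%)
      expect_lt(abs(extraterrestrial_radiation(lat, doy) -
                      extraterrestrial_radiation(-lat, doy2)) /
                  extraterrestrial_radiation(lat, doy), 0.07)
    }
  }
})

test_that("net radiation reproduces the FAO-56 worksheet value", {
  expect_equal(net_radiation(25, 0.23, 30, 18, 2.0, 40, 0), 15.032012,
               tolerance = 1e-6)
})

test_that("net radiation respects the shortwave bound and its guards", {
  withr::with_seed(9, {
    n <- 200
    t_min <- runif(n, 0, 25); t_max <- t_min + runif(n, 0, 15)
    alb <- runif(n, 0, 0.4)
    ra <- runif(n, 5, 42)
    rs <- runif(n, 0, 1) * 0.8 * ra
    e_a <- runif(n, 0.1, 4)
    rn <- net_radiation(rs, alb, t_max, t_min, e_a, ra, 100)
    # longwave loss is non-negative under the clamp
    expect_true(all(rn <= (1 - alb) * rs + 1e-12))
  })
  # fully reflective surface: no shortwave absorption, only longwave loss
  expect_lt(net_radiation(25, 0.99, 30, 18, 2, 40, 0), 0.26 * 25)
  expect_error(net_radiation(25, 1, 30, 18, 2, 40, 0), "albedo")
  # zero Ra with positive rs: ratio guard keeps the result finite
  expect_true(is.finite(net_radiation(5, 0.23, 10, 2, 1, 0, 0)))
})
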