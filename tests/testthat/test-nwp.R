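test_that("triangle interpolation honours barycentric identities", {
  site <- list(lat = 0.5, lon = 0.5)
  nodes <- tibble::tibble(lat = c(0.5, 1.5, 1.5), lon = c(0.5, 0.2, 0.9),
                          value = c(7, 1, 3))
  # site coincident with a node
  expect_equal(interpolate_to_site(nodes, site), 7)
  # constant field is reproduced anywhere
  flat <- nodes; flat$value <- rep(4.2, 3)
  expect_equal(interpolate_to_site(flat, list(lat = 0.9, lon = 0.55)), 4.2)
  # centroid of a triangle at tiny latitude (planar limit): equal weights
  eq <- tibble::tibble(lat = c(0, 0, sqrt(3) / 2) / 100,
                       lon = c(-0.5, 0.5, 0) / 100,
                       value = c(3, 6, 9))
  centroid <- list(lat = mean(eq$lat), lon = mean(eq$lon))
  expect_equal(interpolate_to_site(eq, centroid), 6, tolerance = 1e-6)
})

test_that("degenerate node geometry falls back or clips", {
  # collinear nodes: inverse-distance fallback, announced
  coll <- tibble::tibble(lat = c(0, 0, 0), lon = c(-1, 0, 1), value = c(1, 2, 3))
  expect_message(v <- interpolate_to_site(coll, list(lat = 0, lon = 0.5)),
                 "Collinear")
  expect_true(v >= 1 && v <= 3)
  # site far beyond one vertex: clipped to the nearest edge end
  tri <- tibble::tibble(lat = c(0, 0, 0.5) / 10, lon = c(0, 1, 0.5) / 10,
                        value = c(10, 20, 30))
  expect_equal(interpolate_to_site(tri, list(lat = 0, lon = -5)), 10)
  expect_error(interpolate_to_site(tri[1:2, ], list(lat = 0, lon = 0)), "three")
})

test_that("ensemble reduction: median across members, then daily mean", {
  wx <- sim_weather(tiny_clim()[1, ], irrigation_season(2014)[1:8], seed = 41)
  m1 <- sim_forecast_members(wx, forecast_error_model(members = 2), seed = 6,
                             leads = 1:2)
  red <- reduce_daily(m1)
  expect_named(red, c("site_id", "issue_date", "lead", "t_mean", "t_max",
                      "t_min", "rh_mean", "ws10", "rs_wm2", "pressure_kpa"))
  expect_true(all(red$lead %in% 1:2))
  expect_true(all(red$t_min <= red$t_mean & red$t_mean <= red$t_max))

  # single member: the daily value is the plain mean of its 8 steps
  base <- tidyr::expand_grid(
    member_id = 1L, variable = "T",
    valid_time = as.POSIXct("2014-06-02", tz = "UTC") + seq(0, 21, 3) * 3600
  ) |>
    dplyr::mutate(site_id = "s1",
                  issue_time = as.POSIXct("2014-06-01", tz = "UTC"),
                  value = 1:8)
  expect_equal(reduce_daily(base)$t_mean, mean(1:8))
  expect_equal(reduce_daily(base)$t_max, 8)

  # majority: median of {a, a, b} is a at every step
  trio <- dplyr::bind_rows(
    dplyr::mutate(base, member_id = 1L, value = 10),
    dplyr::mutate(base, member_id = 2L, value = 10),
    dplyr::mutate(base, member_id = 3L, value = 99)
  )
  expect_equal(reduce_daily(trio)$t_mean, 10)

  # permuting member labels changes nothing
  perm <- m1 |> dplyr::mutate(member_id = 3L - member_id)
  expect_equal(reduce_daily(perm), red)

  # shift equivariance: adding a constant to every member shifts the output
  shifted <- m1 |>
    dplyr::mutate(value = value + ifelse(variable == "T", 2.5, 0))
  red_s <- reduce_daily(shifted)
  expect_equal(red_s$t_mean, red$t_mean + 2.5, tolerance = 1e-12)
  expect_equal(red_s$rh_mean, red$rh_mean, tolerance = 1e-12)
})

test_that("incomplete forecast days are flagged and excluded", {
  base <- tidyr::expand_grid(
    member_id = 1L, variable = "T",
    valid_time = as.POSIXct("2014-06-02", tz = "UTC") + seq(0, 21, 3) * 3600
  ) |>
    dplyr::mutate(site_id = "s1",
                  issue_time = as.POSIXct("2014-06-01", tz = "UTC"),
                  value = 15)
  expect_warning(red <- reduce_daily(base[-3, ]), "fewer than 8")
  expect_equal(nrow(red), 0)
  expect_error(reduce_daily(dplyr::mutate(base, variable = "TX")), "Unknown")
})

test_that("mean-bias fitting and removal follow the algebra of the mean", {
  wx <- sim_weather(tiny_clim(), irrigation_season(2010:2013), seed = 51)
  fc <- forecasts_from_obs(wx, leads = 1:3)
  # constant offset is recovered exactly
  fc_off <- dplyr::mutate(fc, t_mean = t_mean + 1, t_max = t_max + 1,
                          t_min = t_min + 1)
  bt <- fit_mean_bias(fc_off, wx, "T")
  expect_equal(bt$mean_bias, rep(1, nrow(bt)), tolerance = 1e-12)
  expect_equal(fit_mean_bias(fc, wx, "T")$mean_bias, rep(0, nrow(bt)),
               tolerance = 1e-12)

  # fit then apply on the fitting sample: residual bias zero, and the RMSE
  # decomposition rmse_raw^2 = rmse_corrected^2 + bias^2 holds exactly
  noisy <- fc |>
    dplyr::mutate(err = withr::with_seed(8, rnorm(dplyr::n(), -0.68, 1)),
                  t_mean = t_mean + err, t_max = t_max + err,
                  t_min = t_min + err) |>
    dplyr::select(-err)
  bt2 <- fit_mean_bias(noisy, wx, "T")
  corr <- apply_bias_correction(noisy, bt2)
  paired <- function(f) {
    f |>
      dplyr::mutate(valid_date = issue_date + lead) |>
      dplyr::inner_join(dplyr::select(wx, site_id, date, obs = t_mean),
                        by = c("site_id", "valid_date" = "date")) |>
      dplyr::group_by(site_id, lead) |>
      dplyr::summarise(bias = mean(t_mean - obs),
                       rmse = sqrt(mean((t_mean - obs)^2)), .groups = "drop")
  }
  raw_s <- paired(noisy); cor_s <- paired(corr)
  expect_equal(cor_s$bias, rep(0, nrow(cor_s)), tolerance = 1e-9)
  expect_equal(cor_s$rmse^2, raw_s$rmse^2 - raw_s$bias^2, tolerance = 1e-9)

  # only the variables present in the table are touched
  expect_equal(corr$rh_mean, noisy$rh_mean)
  expect_equal(corr$ws10, noisy$ws10)
})

test_that("bias table coverage is enforced as configured", {
  wx <- sim_weather(tiny_clim(), irrigation_season(2010:2013), seed = 52)
  fc <- forecasts_from_obs(wx, leads = 1:2)
  bt <- fit_mean_bias(fc, wx, "T")
  expect_error(fit_mean_bias(fc[fc$lead == 1, ][1:10, ], wx, "T"),
               "Insufficient")
  # strict mode errors on a missing entry, lax mode passes through
  part <- bt[bt$site_id == "aws_a", ]
  expect_warning(out <- apply_bias_correction(fc, part), "without a bias-table")
  expect_equal(out$t_mean[out$site_id == "aws_b"],
               fc$t_mean[fc$site_id == "aws_b"])
  expect_error(apply_bias_correction(fc, part, strict = TRUE), "without")
})

test_that("bias tables survive a JSON round trip", {
  wx <- sim_weather(tiny_clim(), irrigation_season(2010:2013), seed = 53)
  fc <- forecasts_from_obs(wx, leads = 1:2) |>
    dplyr::mutate(t_mean = t_mean - 0.68)
  bt <- fit_mean_bias(fc, wx, "T")
  path <- withr::local_tempfile(fileext = ".json")
  write_bias_table(bt, path)
  expect_equal(read_bias_table(path), bt)
})
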