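# daily wide column carrying each forecast variable
variable_columns <- c(
  T = "t_mean", RH = "rh_mean", WS10 = "ws10", RS = "rs_wm2", P = "pressure_kpa"
)

#' Triangle-based interpolation of gridded values to a site
#'
#' Bilinear (barycentric) interpolation from the three numerical grid nodes
#' closest to a site, on a local planar projection centred on the site
#' (longitude scaled by cos(latitude)). Inside the triangle the value is the
#' barycentric-weighted combination; outside, the site is projected onto the
#' nearest triangle edge and interpolated along it. Collinear nodes fall back
#' to inverse-distance weighting (with a message).
#'
#' @param nodes Data frame of exactly three rows with columns `lat`, `lon`,
#'   `value`.
#' @param site A one-row data frame or list with `lat` and `lon`.
#' @return Interpolated scalar value.
#' @export
interpolate_to_site <- function(nodes, site) {
  if (nrow(nodes) != 3) abort("`nodes` must contain exactly three grid points.")
  lat0 <- site$lat
  x <- (nodes$lon - site$lon) * cos(lat0 * pi / 180)
  y <- nodes$lat - lat0
  if (anyDuplicated(cbind(x, y)) > 0) abort("Grid nodes must be distinct.")
  # site sits at the origin of the local frame
  det2 <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
  scale2 <- max(abs(c(x, y)))^2
  if (abs(det2) < 1e-12 * max(scale2, 1e-12)) {
    inform("Collinear grid nodes: falling back to inverse-distance weighting.")
    d <- sqrt(x^2 + y^2)
    if (any(d == 0)) return(nodes$value[which(d == 0)[1]])
    w <- (1 / d) / sum(1 / d)
    return(sum(w * nodes$value))
  }
  l1 <- ((x[2] - 0) * (y[3] - 0) - (x[3] - 0) * (y[2] - 0)) / det2
  l2 <- ((x[3] - 0) * (y[1] - 0) - (x[1] - 0) * (y[3] - 0)) / det2
  l3 <- 1 - l1 - l2
  w <- c(l1, l2, l3)
  if (all(w >= -1e-12)) {
    w <- pmax(w, 0); w <- w / sum(w)
    return(sum(w * nodes$value))
  }
  # outside the triangle: nearest point on each edge, then linear along it
  best <- NULL
  for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
    i <- e[1]; j <- e[2]
    ex <- x[j] - x[i]; ey <- y[j] - y[i]
    t <- (-x[i] * ex - y[i] * ey) / (ex^2 + ey^2)
    t <- min(1, max(0, t))
    px <- x[i] + t * ex; py <- y[i] + t * ey
    d2 <- px^2 + py^2
    v <- (1 - t) * nodes$value[i] + t * nodes$value[j]
    if (is.null(best) || d2 < best$d2) best <- list(d2 = d2, v = v)
  }
  best$v
}

#' Reduce ensemble forecast steps to daily site values
#'
#' Collapses long-format 3-hourly ensemble output to one row per site, issue
#' date and lead day. In the default order the ensemble median is taken at
#' each 3-hourly step, then the eight step medians of each lead day are
#' averaged; the alternative order (`"daily_first"`) averages each member's
#' day first and takes the median across members. Daily temperature extremes
#' are the max/min of the eight reduced 3-hourly temperatures. Days with
#' fewer than eight steps for any variable are dropped with a warning.
#'
#' @param members Long tibble: `site_id, issue_time, member_id, variable,
#'   valid_time, value`, `variable` in T (degC), RH (%), WS10 (m s^-1),
#'   RS (W m^-2), P (kPa). `valid_time` hours 0,3,...,21 belong to that
#'   calendar day.
#' @param order `"median_first"` (default) or `"daily_first"`.
#' @return A tibble `site_id, issue_date, lead, t_mean, t_max, t_min,
#'   rh_mean, ws10, rs_wm2, pressure_kpa` (columns absent from the input stay
#'   `NA`), leads restricted to 1..5.
#' @export
reduce_daily <- function(members, order = c("median_first", "daily_first")) {
  order <- arg_match(order)
  required <- c("site_id", "issue_time", "member_id", "variable", "valid_time", "value")
  missing_cols <- setdiff(required, names(members))
  if (length(missing_cols) > 0) {
    abort(paste0("`members` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad <- setdiff(unique(members$variable), names(variable_columns))
  if (length(bad) > 0) {
    abort(paste0("Unknown forecast variable(s): ", paste(bad, collapse = ", ")))
  }
  m <- as_tibble(members) %>%
    mutate(
      issue_date = as.Date(.data$issue_time),
      valid_date = as.Date(.data$valid_time),
      lead = as.integer(.data$valid_date - .data$issue_date)
    ) %>%
    filter(.data$lead >= 1, .data$lead <= 5)

  if (order == "median_first") {
    steps <- m %>%
      group_by(.data$site_id, .data$issue_date, .data$variable,
               .data$valid_date, .data$lead, .data$valid_time) %>%
      summarise(med = median(.data$value), .groups = "drop")
    daily <- steps %>%
      group_by(.data$site_id, .data$issue_date, .data$variable,
               .data$valid_date, .data$lead) %>%
      summarise(
        n_steps = n(),
        mean_v = mean(.data$med),
        max_v = max(.data$med),
        min_v = min(.data$med),
        .groups = "drop"
      )
  } else {
    per_member <- m %>%
      group_by(.data$site_id, .data$issue_date, .data$variable,
               .data$valid_date, .data$lead, .data$member_id) %>%
      summarise(
        n_steps = n(),
        mean_v = mean(.data$value),
        max_v = max(.data$value),
        min_v = min(.data$value),
        .groups = "drop"
      )
    daily <- per_member %>%
      group_by(.data$site_id, .data$issue_date, .data$variable,
               .data$valid_date, .data$lead) %>%
      summarise(
        n_steps = min(.data$n_steps),
        mean_v = median(.data$mean_v),
        max_v = median(.data$max_v),
        min_v = median(.data$min_v),
        .groups = "drop"
      )
  }

  incomplete <- daily %>% filter(.data$n_steps < 8)
  if (nrow(incomplete) > 0) {
    warn(sprintf("Dropping %d site/issue/variable day(s) with fewer than 8 forecast steps.",
                 nrow(incomplete)))
    daily <- daily %>% filter(.data$n_steps >= 8)
  }

  out <- daily %>%
    mutate(col = unname(variable_columns[.data$variable])) %>%
    select(all_of(c("site_id", "issue_date", "lead", "col", "mean_v"))) %>%
    tidyr::pivot_wider(names_from = "col", values_from = "mean_v")
  extremes <- daily %>%
    filter(.data$variable == "T") %>%
    select(all_of(c("site_id", "issue_date", "lead")),
           t_max = "max_v", t_min = "min_v")
  out <- left_join(out, extremes, by = c("site_id", "issue_date", "lead"))
  for (col in c(unname(variable_columns), "t_max", "t_min")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  out %>%
    select(all_of(c("site_id", "issue_date", "lead", "t_mean", "t_max", "t_min",
                    "rh_mean", "ws10", "rs_wm2", "pressure_kpa"))) %>%
    arrange(.data$site_id, .data$issue_date, .data$lead)
}

#' Estimate the mean forecast bias over a reference period
#'
#' Mean of (forecast - observation) per site and lead time for one variable,
#' computed over a declared reference period (typically the irrigation
#' seasons of several past years). Pairs with a missing
#' forecast or observation are dropped.
#'
#' @param forecasts Daily site forecasts as produced by [reduce_daily()] (or
#'   [sim_forecast_daily()]).
#' @param obs Observed daily weather (`site_id, date, ...` with the column
#'   that carries `variable`).
#' @param variable One of `"T"`, `"RH"`, `"WS10"`, `"RS"`, `"P"`.
#' @param reference_period Optional `Date` vector; only forecast valid dates
#'   inside it are used.
#' @param min_pairs Minimum paired days per site x lead (default 30).
#' @return A bias table: tibble `site_id, variable, lead, mean_bias, n`.
#' @export
fit_mean_bias <- function(forecasts, obs, variable = "T",
                          reference_period = NULL, min_pairs = 30) {
  variable <- arg_match(variable, names(variable_columns))
  col <- unname(variable_columns[variable])
  fc <- as_tibble(forecasts) %>%
    mutate(valid_date = .data$issue_date + .data$lead)
  if (!is.null(reference_period)) {
    fc <- filter(fc, .data$valid_date %in% as.Date(reference_period))
  }
  obs <- as_tibble(obs)
  obs$date <- as.Date(obs$date)
  paired <- inner_join(
    fc %>% select(all_of(c("site_id", "valid_date", "lead")), fc_value = all_of(col)),
    obs %>% select(all_of(c("site_id", "date")), obs_value = all_of(col)),
    by = c("site_id", "valid_date" = "date")
  ) %>%
    filter(is.finite(.data$fc_value), is.finite(.data$obs_value))
  out <- paired %>%
    group_by(.data$site_id, .data$lead) %>%
    summarise(mean_bias = mean(.data$fc_value - .data$obs_value),
              n = n(), .groups = "drop") %>%
    mutate(variable = variable) %>%
    select(all_of(c("site_id", "variable", "lead", "mean_bias", "n")))
  short <- filter(out, .data$n < min_pairs)
  if (nrow(out) == 0 || nrow(short) > 0) {
    abort(sprintf(
      "Insufficient paired days to fit the mean bias (floor %d per site x lead).",
      min_pairs
    ))
  }
  out
}

#' Subtract the estimated mean bias from forecasts
#'
#' Corrected forecast = raw forecast - mean bias, per site, variable and lead
#' time. Only variables present in the bias table are touched; in the
#' standard configuration that is temperature only, whose correction shifts
#' `t_mean`, `t_max` and `t_min` alike. Site/lead combinations without a
#' table entry pass through with a warning (or error when `strict = TRUE`).
#'
#' @param forecasts Daily site forecasts ([reduce_daily()] output).
#' @param bias_table Output of [fit_mean_bias()] (rows for several variables
#'   may be stacked).
#' @param strict Error instead of warning on a missing table entry.
#' @return `forecasts` with corrected values.
#' @export
apply_bias_correction <- function(forecasts, bias_table, strict = FALSE) {
  fc <- as_tibble(forecasts)
  for (v in unique(bias_table$variable)) {
    tbl <- bias_table %>%
      filter(.data$variable == v) %>%
      select(all_of(c("site_id", "lead", "mean_bias")))
    fc <- left_join(fc, tbl, by = c("site_id", "lead"))
    missing_entry <- is.na(fc$mean_bias)
    if (any(missing_entry)) {
      msg <- sprintf("%d forecast row(s) without a bias-table entry for %s.",
                     sum(missing_entry), v)
      if (strict) abort(msg)
      warn(paste(msg, "Passed through uncorrected."))
      fc$mean_bias[missing_entry] <- 0
    }
    shift_cols <- if (v == "T") c("t_mean", "t_max", "t_min") else unname(variable_columns[v])
    for (col in shift_cols) {
      fc[[col]] <- fc[[col]] - fc$mean_bias
    }
    fc$mean_bias <- NULL
  }
  fc
}

#' Write or read a bias table as JSON
#'
#' Serialised as an object keyed `"site|variable|lead"`, each entry holding
#' `mean_bias` and `n`.
#'
#' @param bias_table Output of [fit_mean_bias()].
#' @param path File path.
#' @return `read_bias_table()` returns the tibble; `write_bias_table()` its
#'   path, invisibly.
#' @export
write_bias_table <- function(bias_table, path) {
  keys <- sprintf("%s|%s|%d", bias_table$site_id, bias_table$variable, bias_table$lead)
  entries <- purrr::map(seq_len(nrow(bias_table)), function(i) {
    list(mean_bias = bias_table$mean_bias[i], n = bias_table$n[i])
  })
  jsonlite::write_json(setNames(entries, keys), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(path) {
  raw <- jsonlite::read_json(path)
  parts <- strsplit(names(raw), "|", fixed = TRUE)
  tibble(
    site_id = purrr::map_chr(parts, 1),
    variable = purrr::map_chr(parts, 2),
    lead = as.integer(purrr::map_chr(parts, 3)),
    mean_bias = unname(purrr::map_dbl(raw, "mean_bias")),
    n = unname(purrr::map_int(raw, ~ as.integer(.x$n)))
  )
}
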