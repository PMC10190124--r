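#' Configuration of the synthetic study domain
#'
#' Defines a self-contained synthetic world with the statistical structure
#' the satellite-to-surface NO2 estimation chain assumes: a smooth surface
#' NO2 field with hotspots, a winter-peaking seasonal cycle and a
#' rise-then-fall long-term trend; satellite columns proportional to the
#' surface field through a smoothly varying scaling factor; cloud-driven
#' non-random missingness; sparse monitors preferentially sited in populous
#' cells; and provincial population/mortality tables. The defaults emulate
#' a 2005-2020 run at desk scale: a 60 x 60 fine grid at 0.05 degrees,
#' 0.25-degree satellite pixels, a trend peaking seven years in, and a
#' missingness level giving roughly 47% raw satellite coverage.
#'
#' @param seed Integer seed; fully determines the generated world.
#' @param n_years Number of simulated years (default 16).
#' @param fine_grid `grid_spec` of the fine modelling grid.
#' @param coarse_factor Fine cells per coarse satellite cell side (5, i.e.
#'   0.25 degrees from 0.05 degrees); must divide the fine dimensions.
#' @param n_monitors Number of ground stations (default 15, matching the
#'   real network's density of roughly one station per 250 fine cells).
#' @param n_hotspots Number of emission hotspots (default 5).
#' @param trend_peak_year_index 0-based year index at which the national
#'   trend peaks (default 7, emulating the 2011-2012 turning point).
#' @param missingness_target Long-run fraction of satellite pixel-days
#'   removed by the cloud rule (default 0.53, emulating 46.9% raw coverage).
#' @param monitor_siting_bias Exponent coupling station placement
#'   probability to population (placement prob proportional to
#'   pop^monitor_siting_bias; 0 = uniform).
#' @param days_per_month Days simulated per month (default 8); an idealised
#'   calendar keeping daily gap-filling affordable while preserving the
#'   daily-to-monthly aggregation structure.
#' @param start_year First calendar year (default 2005); timestamps use
#'   real dates so the pre-September-2018 reference-state correction has a
#'   concrete cutover.
#' @param seasonal_amplitude Relative amplitude of the winter-max seasonal
#'   cycle (default 0.35).
#' @param trend_amplitude Scales the rise-then-fall trend; 0 gives a flat
#'   trend (default 1).
#' @param retrieval_noise Lognormal sigma of multiplicative satellite
#'   retrieval noise (default 0.10; the real instrument's noise level is
#'   not pinned down, so this is exposed as a parameter).
#' @param station_bias_sd Lognormal sigma of per-station multiplicative
#'   siting bias (default 0.12), giving monitors a site-specific offset a
#'   model cannot learn for unmonitored locations.
#' @param month_anomaly_sd Lognormal sigma of a domain-wide monthly
#'   scaling-factor anomaly (default 0.06), meteorological variability not
#'   captured by the covariates.
#' @param day_factor_sd Lognormal sigma of the shared day-to-day column
#'   variation within a month (default 0.08).
#' @param hourly_noise_sd Additive sd of hourly monitor noise, ug/m3
#'   (default 3).
#' @param diurnal_amplitude Amplitude of the monitor diurnal cycle
#'   (default 0.25).
#' @param artifact_rate Fraction of station-days carrying an injected
#'   instrument artifact (default 0.02; half stuck-value runs of >= 8
#'   hours, half days truncated below 18 valid hours).
#' @param base_missing_rate Fraction of hours missing at random
#'   (default 0.01).
#' @param cloud_pollution_coupling Weight coupling cloudiness to column
#'   amount (default 0.35) so gaps concentrate in polluted cells.
#' @param cloud_ar Day-to-day AR(1) coefficient of the cloud field.
#' @param row_anomaly If `TRUE`, mask a fixed stripe of satellite columns
#'   from `row_anomaly_start_year` onward, emulating a detector row
#'   anomaly. Off by default.
#' @param row_anomaly_start_year 0-based year index at which the stripe
#'   starts (default 2).
#' @param lockdown_factor Multiplier applied to the surface field in
#'   `lockdown_months` of the final year (default 0.8, a 20% suppression).
#' @param lockdown_months Months of the final year suppressed (default 1:4).
#' @return A `world_config` list.
#' @export
world_config <- function(seed = 1L,
                         n_years = 16L,
                         fine_grid = grid_spec(20, 100, 0.05, 0.05, 60, 60),
                         coarse_factor = 5L,
                         n_monitors = 15L,
                         n_hotspots = 5L,
                         trend_peak_year_index = 7L,
                         missingness_target = 0.53,
                         monitor_siting_bias = 1,
                         days_per_month = 8L,
                         start_year = 2005L,
                         seasonal_amplitude = 0.35,
                         trend_amplitude = 1,
                         retrieval_noise = 0.10,
                         station_bias_sd = 0.12,
                         month_anomaly_sd = 0.06,
                         day_factor_sd = 0.08,
                         hourly_noise_sd = 3,
                         diurnal_amplitude = 0.25,
                         artifact_rate = 0.02,
                         base_missing_rate = 0.01,
                         cloud_pollution_coupling = 0.35,
                         cloud_ar = 0.6,
                         row_anomaly = FALSE,
                         row_anomaly_start_year = 2L,
                         lockdown_factor = 0.8,
                         lockdown_months = 1:4) {
  if (fine_grid$nrows %% coarse_factor != 0L ||
      fine_grid$ncols %% coarse_factor != 0L)
    stop("coarse_factor ", coarse_factor,
         " does not divide fine grid dimensions")
  stopifnot(missingness_target > 0, missingness_target < 1,
            monitor_siting_bias >= 0, n_years >= 1, days_per_month >= 2)
  cfg <- list(seed = as.integer(seed), n_years = as.integer(n_years),
              fine_grid = fine_grid, coarse_factor = as.integer(coarse_factor),
              n_monitors = as.integer(n_monitors),
              n_hotspots = as.integer(n_hotspots),
              trend_peak_year_index = as.integer(trend_peak_year_index),
              missingness_target = missingness_target,
              monitor_siting_bias = monitor_siting_bias,
              days_per_month = as.integer(days_per_month),
              start_year = as.integer(start_year),
              seasonal_amplitude = seasonal_amplitude,
              trend_amplitude = trend_amplitude,
              retrieval_noise = retrieval_noise,
              station_bias_sd = station_bias_sd,
              month_anomaly_sd = month_anomaly_sd,
              day_factor_sd = day_factor_sd,
              hourly_noise_sd = hourly_noise_sd,
              diurnal_amplitude = diurnal_amplitude,
              artifact_rate = artifact_rate,
              base_missing_rate = base_missing_rate,
              cloud_pollution_coupling = cloud_pollution_coupling,
              cloud_ar = cloud_ar,
              row_anomaly = isTRUE(row_anomaly),
              row_anomaly_start_year = as.integer(row_anomaly_start_year),
              lockdown_factor = lockdown_factor,
              lockdown_months = as.integer(lockdown_months))
  class(cfg) <- "world_config"
  cfg
}

#' Generate the synthetic world
#'
#' Builds all latent truth fields for a configuration: monthly fine-grid
#' surface NO2 (ug/m3), the true surface-to-column scaling factor, daily
#' coarse-grid column densities, daily cloud fraction, covariate stacks,
#' annual gridded population, province labels, and the provincial
#' demography table. Identical configurations give bit-identical worlds.
#'
#' The surface field is (smooth background + exponential-decay hotspots)
#' x seasonal sinusoid (winter max) x piecewise-linear rise-then-fall trend,
#' with a lockdown suppression in the final year's early months. Columns
#' are surface / S with S a smooth positive function of the boundary-layer
#' covariate times a domain-wide monthly anomaly, so the scaling-factor
#' regression is well-posed and recoverable. Daily columns are the monthly
#' column times a shared day factor normalised to mean one, so daily truth
#' averages exactly to monthly truth.
#'
#' @param config A [world_config()].
#' @return An object of class `no2_world`; a list holding the truth fields,
#'   calendars (`months`, `days` data frames), covariates, provinces and
#'   demography. Latent quantities needed for recovery tests (true scaling
#'   factors, monthly anomaly, lockdown factor) are retained.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  set.seed(config$seed)
  fg <- config$fine_grid
  cf <- config$coarse_factor
  cg <- grid_spec(fg$lat0 + (cf - 1) / 2 * fg$dlat,
                  fg$lon0 + (cf - 1) / 2 * fg$dlon,
                  fg$dlat * cf, fg$dlon * cf,
                  fg$nrows %/% cf, fg$ncols %/% cf)
  nr <- fg$nrows; nc <- fg$ncols
  ny <- config$n_years; nm <- ny * 12L
  dpm <- config$days_per_month; ndays <- nm * dpm

  months <- data.frame(month_index = seq_len(nm),
                       year_index = rep(0:(ny - 1L), each = 12L),
                       year = config$start_year + rep(0:(ny - 1L), each = 12L),
                       month = rep(1:12, times = ny))
  days <- data.frame(day_index = seq_len(ndays),
                     month_index = rep(seq_len(nm), each = dpm),
                     day = rep(seq_len(dpm), times = nm))
  days$year <- months$year[days$month_index]
  days$month <- months$month[days$month_index]
  days$doy <- (days$month - 1L) * dpm + days$day

  std <- function(m) (m - mean(m)) / stats::sd(m)

  ## static spatial structure
  elev_n <- std(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), 8))
  base_n <- std(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), 6))
  base <- pmax(14 + 6 * base_n, 2)
  hot <- matrix(0, nr, nc)
  if (config$n_hotspots > 0) {
    ci <- stats::runif(config$n_hotspots, 1, nr)
    cj <- stats::runif(config$n_hotspots, 1, nc)
    amp <- stats::runif(config$n_hotspots, 10, 30)
    rad <- stats::runif(config$n_hotspots, 2.5, 6)
    ii <- row(hot); jj <- col(hot)
    for (h in seq_len(config$n_hotspots))
      hot <- hot + amp[h] * exp(-((ii - ci[h])^2 + (jj - cj[h])^2) /
                                  (2 * rad[h]^2))
  }
  spatial <- base + hot

  pop_noise <- std(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), 4))
  pop_base <- exp(0.9 * std(spatial) + 0.7 * pop_noise)
  pop_base <- pop_base / sum(pop_base) * 5e7
  population <- array(0, c(nr, nc, ny))
  for (y in seq_len(ny))
    population[, , y] <- pop_base * 1.015^(y - 1L)

  emis_n <- std(spatial)

  ## monthly covariates and truth
  seas <- 1 + config$seasonal_amplitude * cos(2 * pi * (months$month - 1) / 12)
  peak <- config$trend_peak_year_index
  yi <- months$year_index
  tr_up <- if (peak > 0) 1 - 0.40 * config$trend_amplitude * (peak - yi) / peak else rep(1, nm)
  tr_dn <- if (peak < ny - 1L)
    1 - 0.32 * config$trend_amplitude * (yi - peak) / (ny - 1L - peak) else rep(1, nm)
  trend <- ifelse(yi <= peak, tr_up, tr_dn)
  m_anom <- exp(stats::rnorm(nm, 0, config$month_anomaly_sd) -
                  config$month_anomaly_sd^2 / 2)

  lat_n <- std(matrix(rep(grid_lat(fg), nc), nr, nc))
  temperature <- array(0, c(nr, nc, nm))
  blh <- array(0, c(nr, nc, nm))
  emission <- array(0, c(nr, nc, nm))
  surface <- array(0, c(nr, nc, nm))
  scaling_pre <- array(0, c(nr, nc, nm))
  lock_mul <- rep(1, nm)
  lock_sel <- months$year_index == ny - 1L & months$month %in% config$lockdown_months
  lock_mul[lock_sel] <- config$lockdown_factor
  for (m in seq_len(nm)) {
    mo <- months$month[m]
    temperature[, , m] <- 15 - 6 * lat_n + 10 * cos(2 * pi * (mo - 7) / 12) +
      1.5 * std(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), 5))
    blh[, , m] <- 0.6 * cos(2 * pi * (mo - 7) / 12) - 0.25 * lat_n +
      0.7 * std(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), 5))
    emission[, , m] <- emis_n * trend[m] +
      0.15 * std(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), 5))
    surface[, , m] <- spatial * seas[m] * trend[m] * lock_mul[m]
    scaling_pre[, , m] <- 20 * exp(-0.35 * blh[, , m]) * m_anom[m]
  }

  ## coarse monthly and daily columns; plus a reanalysis-column analog
  ## (the role CAMS simulated columns play for the real instrument): the
  ## true fine column with smooth multiplicative error
  vcd_monthly_coarse <- array(0, c(cg$nrows, cg$ncols, nm))
  cams_no2 <- array(0, c(nr, nc, nm))
  for (m in seq_len(nm)) {
    vfine <- surface[, , m] / scaling_pre[, , m]
    vcd_monthly_coarse[, , m] <- block_aggregate(vfine, cf)
    cams_no2[, , m] <- vfine *
      exp(0.15 * std(smooth_field(matrix(stats::rnorm(nr * nc), nr, nc), 4)))
  }
  day_factor <- numeric(ndays)
  for (m in seq_len(nm)) {
    f <- exp(stats::rnorm(dpm, 0, config$day_factor_sd))
    day_factor[days$month_index == m] <- f / mean(f)
  }
  vcd_daily <- array(0, c(cg$nrows, cg$ncols, ndays))
  for (d in seq_len(ndays))
    vcd_daily[, , d] <- vcd_monthly_coarse[, , days$month_index[d]] *
      day_factor[d]

  ## cloud fraction: temporally AR(1), spatially smooth, coupled to column
  ## amount so gaps concentrate where columns are high
  cc <- config$cloud_pollution_coupling
  z <- array(0, c(cg$nrows, cg$ncols, ndays))
  g_prev <- std(smooth_field(matrix(stats::rnorm(cg$nrows * cg$ncols),
                                    cg$nrows, cg$ncols), 2.5))
  for (d in seq_len(ndays)) {
    innov <- std(smooth_field(matrix(stats::rnorm(cg$nrows * cg$ncols),
                                     cg$nrows, cg$ncols), 2.5))
    g_prev <- config$cloud_ar * g_prev + sqrt(1 - config$cloud_ar^2) * innov
    pol <- std(log(vcd_monthly_coarse[, , days$month_index[d]]))
    z[, , d] <- (1 - cc) * g_prev + cc * pol
  }
  z <- (z - mean(z)) / stats::sd(z)
  delta <- stats::qnorm(1 - config$missingness_target) - stats::qnorm(0.30)
  cloud_fraction <- stats::pnorm(z - delta)

  ## true scaling factor consistent with the downstream regrid operator
  plan <- idw_plan(cg, fg)
  scaling_truth <- array(0, c(nr, nc, nm))
  for (m in seq_len(nm))
    scaling_truth[, , m] <- surface[, , m] /
      matrix(idw_apply(plan, as.vector(vcd_monthly_coarse[, , m])), nr, nc)

  ## provinces: 3 x 3 rectangular blocks
  pb_r <- max(1L, nr %/% 3L); pb_c <- max(1L, nc %/% 3L)
  provinces <- matrix(0L, nr, nc)
  provinces[] <- pmin((row(provinces) - 1L) %/% pb_r, 2L) * 3L +
    pmin((col(provinces) - 1L) %/% pb_c, 2L) + 1L

  ## demography: last simulated year unavailable (reporting lag), so
  ## downstream carry-forward is exercised
  demo_years <- config$start_year + 0:(max(ny - 2L, 0L))
  rate_p <- 0.007 * (1 + 0.1 * std(tapply(as.vector(pop_base),
                                          as.vector(provinces), sum)))
  mortality <- do.call(rbind, lapply(sort(unique(as.vector(provinces))),
    function(p) {
      sel <- provinces == p
      data.frame(province = p, year = demo_years,
                 population = vapply(seq_along(demo_years), function(y)
                   sum(population[, , y][sel]), 0),
                 mortality_rate = unname(rate_p[p]))
    }))

  w <- list(config = config, fine = fg, coarse = cg,
            months = months, days = days,
            surface_no2 = surface, scaling_truth = scaling_truth,
            vcd_monthly_coarse = vcd_monthly_coarse, vcd_daily = vcd_daily,
            day_factor = day_factor, month_anomaly = m_anom,
            cloud_fraction = cloud_fraction,
            covariates = list(temperature = temperature, blh = blh,
                              emission = emission, cams_no2 = cams_no2,
                              elevation = elev_n, population = population),
            population_base = pop_base, provinces = provinces,
            mortality = mortality, trend = trend,
            lockdown = list(factor = config$lockdown_factor,
                            months = config$lockdown_months,
                            month_index = which(lock_sel)))
  class(w) <- "no2_world"
  w
}

#' @export
print.no2_world <- function(x, ...) {
  cat(sprintf(paste0("Synthetic NO2 world: %d years (%d-%d), fine %dx%d @ %.2f deg, ",
                     "coarse %dx%d, %d days/month\n"),
              x$config$n_years, x$config$start_year,
              x$config$start_year + x$config$n_years - 1L,
              x$fine$nrows, x$fine$ncols, x$fine$dlat,
              x$coarse$nrows, x$coarse$ncols, x$config$days_per_month))
  cat(sprintf("  surface NO2 mean %.1f ug/m3; %d provinces; seed %d\n",
              mean(x$surface_no2), length(unique(as.vector(x$provinces))),
              x$config$seed))
  invisible(x)
}

#' National annual mean surface NO2 of a synthetic world
#'
#' Unweighted domain mean of the monthly truth field, averaged by year.
#'
#' @param world An `no2_world`.
#' @return Data frame (year, year_index, mean_no2).
#' @export
national_annual_mean <- function(world) {
  mm <- apply(world$surface_no2, 3, mean)
  agg <- tapply(mm, world$months$year_index, mean)
  data.frame(year_index = as.integer(names(agg)),
             year = world$config$start_year + as.integer(names(agg)),
             mean_no2 = as.numeric(agg), row.names = NULL)
}

#' Simulate satellite observation of the synthetic columns
#'
#' Applies multiplicative lognormal retrieval noise to the daily column
#' truth, then masks every pixel-day whose cloud fraction exceeds 0.30
#' (the quality-control rule applied to the real level-3 product) and,
#' optionally, a fixed stripe of columns emulating a detector row anomaly.
#' Missingness is therefore cloud-driven and non-random.
#'
#' @param world An `no2_world`.
#' @param config Configuration; defaults to the world's own.
#' @return A list of class `sat_obs`: `vcd` (coarse array, `NA` where
#'   masked), `missing_cloud`/`missing_anomaly` logical arrays, and the
#'   overall `coverage` fraction.
#' @export
observe_satellite <- function(world, config = world$config) {
  set.seed(config$seed + 7919L)
  dims <- dim(world$vcd_daily)
  noise <- exp(stats::rnorm(prod(dims), 0, config$retrieval_noise) -
                 config$retrieval_noise^2 / 2)
  vcd <- world$vcd_daily * array(noise, dims)
  miss_cloud <- world$cloud_fraction > 0.30
  miss_anom <- array(FALSE, dims)
  if (config$row_anomaly) {
    jband <- seq(max(1L, dims[2] %/% 2), min(dims[2], dims[2] %/% 2 + 1L))
    dsel <- world$days$month_index %in%
      which(world$months$year_index >= config$row_anomaly_start_year)
    miss_anom[, jband, dsel] <- TRUE
  }
  vcd[miss_cloud | miss_anom] <- NA_real_
  structure(list(vcd = vcd, missing_cloud = miss_cloud,
                 missing_anomaly = miss_anom,
                 coverage = mean(!is.na(vcd))),
            class = "sat_obs")
}

#' Simulate the hourly ground monitoring network
#'
#' Stations are placed in distinct fine cells with probability proportional
#' to population raised to `monitor_siting_bias`. Hourly values are the
#' local monthly surface truth times a station siting bias, a diurnal
#' cycle, and a day-level factor, plus additive noise. A configurable
#' fraction of station-days carries injected instrument artifacts -- runs
#' of at least eight identical values, or days truncated below 18 valid
#' hours -- whose exact positions are recorded so quality-control recovery
#' can be verified.
#'
#' @param world An `no2_world`.
#' @param config Configuration; defaults to the world's own.
#' @return A list of class `monitor_obs`: `stations` (station_id, lat, lon,
#'   cell indices, bias), `hourly` (station_id, timestamp, no2),
#'   and `artifacts` with elements `stuck` (station_id, timestamp of every
#'   injected stuck hour) and `short_days` (station_id, date).
#' @export
observe_monitors <- function(world, config = world$config) {
  fg <- world$fine
  ncell <- fg$nrows * fg$ncols
  if (config$n_monitors > ncell)
    stop("n_monitors (", config$n_monitors, ") exceeds number of grid cells (",
         ncell, ")")
  set.seed(config$seed + 104729L)
  prob <- as.vector(world$population_base)^config$monitor_siting_bias
  cells <- sample.int(ncell, config$n_monitors, prob = prob)
  ci <- (cells - 1L) %% fg$nrows + 1L
  cj <- (cells - 1L) %/% fg$nrows + 1L
  stations <- data.frame(
    station_id = sprintf("S%03d", seq_len(config$n_monitors)),
    lat = grid_lat(fg)[ci], lon = grid_lon(fg)[cj],
    row = ci, col = cj,
    bias = exp(stats::rnorm(config$n_monitors, 0, config$station_bias_sd) -
                 config$station_bias_sd^2 / 2))

  dpm <- config$days_per_month
  ndays <- nrow(world$days)
  hours <- 0:23
  diurnal <- 1 + config$diurnal_amplitude * cos(2 * pi * (hours - 7) / 24)
  day_start <- as.numeric(ISOdatetime(world$days$year, world$days$month,
                                      world$days$day, 0, 0, 0, tz = "UTC"))

  out <- vector("list", config$n_monitors)
  stuck_list <- list(); short_list <- list()
  for (s in seq_len(config$n_monitors)) {
    truth_m <- world$surface_no2[ci[s], cj[s], ]      # monthly truth at cell
    base_d <- truth_m[world$days$month_index] * stations$bias[s]
    v <- outer(diurnal, base_d) +
      matrix(stats::rnorm(24 * ndays, 0, config$hourly_noise_sd), 24, ndays)
    nz <- v <= 0
    v[nz] <- stats::runif(sum(nz), 0.05, 0.6)       # detection-limit floor
    keep <- matrix(stats::runif(24 * ndays) >= config$base_missing_rate,
                   24, ndays)

    art_day <- which(stats::runif(ndays) < config$artifact_rate)
    art_stuck <- art_day[seq_along(art_day) %% 2L == 1L]
    art_short <- setdiff(art_day, art_stuck)
    st_rows <- list()
    for (d in art_stuck) {
      len <- sample(8:12, 1)
      h0 <- sample.int(24 - len + 1L, 1)
      idx <- h0:(h0 + len - 1L)
      val <- v[h0, d]
      v[idx, d] <- val
      keep[idx, d] <- TRUE
      # keep bookkeeping exact: nudge neighbours that would round-match
      rv <- round(val, 3)
      if (h0 > 1L && round(v[h0 - 1L, d], 3) == rv) v[h0 - 1L, d] <- val + 0.019
      if (h0 + len <= 24L && round(v[h0 + len, d], 3) == rv)
        v[h0 + len, d] <- val + 0.019
      if (h0 == 1L && d > 1L && round(v[24, d - 1L], 3) == rv)
        v[24, d - 1L] <- val + 0.019
      if (h0 + len == 25L && d < ndays && round(v[1, d + 1L], 3) == rv)
        v[1, d + 1L] <- val + 0.019
      st_rows[[length(st_rows) + 1L]] <-
        data.frame(station_id = stations$station_id[s],
                   timestamp = day_start[d] + 3600 * (idx - 1L))
    }
    for (d in art_short) {
      nkeep <- sample(10:17, 1)
      kidx <- sort(sample.int(24, nkeep))
      keep[, d] <- FALSE
      keep[kidx, d] <- TRUE
      short_list[[length(short_list) + 1L]] <-
        data.frame(station_id = stations$station_id[s],
                   date = as.Date(as.POSIXct(day_start[d], tz = "UTC",
                                             origin = "1970-01-01")))
    }
    if (length(st_rows)) stuck_list[[length(stuck_list) + 1L]] <-
      do.call(rbind, st_rows)

    ts <- rep(day_start, each = 24) + 3600 * rep(hours, times = ndays)
    ok <- as.vector(keep)
    out[[s]] <- data.frame(station_id = stations$station_id[s],
                           timestamp = ts[ok], no2 = as.vector(v)[ok])
  }
  hourly <- do.call(rbind, out)
  hourly$timestamp <- as.POSIXct(hourly$timestamp, tz = "UTC",
                                 origin = "1970-01-01")
  stuck <- if (length(stuck_list)) do.call(rbind, stuck_list) else
    data.frame(station_id = character(), timestamp = numeric())
  if (nrow(stuck)) stuck$timestamp <- as.POSIXct(stuck$timestamp, tz = "UTC",
                                                 origin = "1970-01-01")
  short_days <- if (length(short_list)) do.call(rbind, short_list) else
    data.frame(station_id = character(), date = as.Date(character()))
  structure(list(stations = stations, hourly = hourly,
                 artifacts = list(stuck = stuck, short_days = short_days)),
            class = "monitor_obs")
}
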