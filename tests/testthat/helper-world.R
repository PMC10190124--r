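# Shared fixtures: the default synthetic world and the pipeline artifacts
# derived from it are expensive, so they are built once per test run and
# memoised here. Every fixture is a deterministic function of fixed seeds.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

default_world <- function() memo("world", generate_world(world_config(seed = 1)))

default_sat <- function() memo("sat", observe_satellite(default_world()))

default_monitors <- function() memo("monitors", observe_monitors(default_world()))

# months in the synthetic calendar have 8 days, so the monthly
# completeness rule scales to 6 valid days (75%, as for real months)
default_qc <- function() memo("qc",
  qc_monitors(default_monitors()$hourly, min_days = 6L))

default_gapfill <- function() memo("gapfill",
  gapfill_run(default_sat(), default_world(), seed = 1))

default_vcd_fine <- function() memo("vcd_fine",
  monthly_vcd_fine(default_gapfill(), default_world()))

default_table <- function() memo("table",
  build_training_table(default_qc(), default_monitors()$stations,
                       default_vcd_fine(), default_world()))

# training period emulates the monitored years; the final year is held
# out for external (hindcast) validation
train_table <- function() memo("train", {
  tab <- default_table()
  tab[tab$year >= 2014 & tab$year <= 2019, ]
})

final_year_table <- function() memo("final_year", {
  tab <- default_table()
  tab[tab$year == 2020, ]
})

default_fit <- function() memo("fit", fit_ensemble(train_table(), seed = 1))

insample_fit <- function() memo("fit_insample",
  fit_ensemble(train_table(), seed = 1, combiner = "insample"))

# small world for cheap unit tests
tiny_config <- function(...) {
  defaults <- list(seed = 42, n_years = 2L,
                   fine_grid = grid_spec(30, 110, 0.05, 0.05, 20, 20),
                   coarse_factor = 5L, n_monitors = 6L, n_hotspots = 2L,
                   trend_peak_year_index = 1L, days_per_month = 6L)
  do.call(world_config, utils::modifyList(defaults, list(...)))
}

tiny_world <- function() memo("tiny_world", generate_world(tiny_config()))

# truth scaling factor / surface value at each table row's cell
truth_at_rows <- function(tab, world, field = world$scaling_truth) {
  loc <- grid_locate(world$fine, tab$lat, tab$lon)
  field[cbind(loc[, 1], loc[, 2], tab$month_index)]
}

# a synthetic training table whose scaling factor is an exact linear
# function of one covariate
linear_table <- function(n = 400, seed = 11) {
  set.seed(seed)
  tab <- data.frame(
    station_id = sprintf("S%02d", rep(1:20, length.out = n)),
    year = rep(2014:2018, length.out = n),
    month = rep(1:12, length.out = n),
    vcd = runif(n, 0.5, 2),
    temperature = rnorm(n), blh = rnorm(n), emission = rnorm(n),
    cams_no2 = rnorm(n), elevation = rnorm(n), population = runif(n),
    lat = runif(n, 20, 23), lon = runif(n, 100, 103),
    year_index = 0L)
  tab$month_index <- (tab$year - 2014L) * 12L + tab$month
  tab$S <- 10 + 3 * tab$blh
  tab$mean_no2 <- tab$S * tab$vcd
  attr(tab, "predictors") <- c("vcd", "temperature", "blh", "emission",
                               "cams_no2", "elevation", "population",
                               "lat", "lon", "month", "year_index")
  class(tab) <- c("no2_table", class(tab))
  tab
}

# hourly fixture builder: one station, given dates and hours, constant or
# supplied values
make_hourly <- function(values, start = "2019-03-01 00:00:00",
                        station = "A") {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(station_id = station,
             timestamp = t0 + 3600 * (seq_along(values) - 1L),
             no2 = values)
}
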