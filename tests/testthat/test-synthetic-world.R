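test_that("identical configurations give bit-identical worlds and observations", {
  cfg <- tiny_config()
  w1 <- generate_world(cfg)
  w2 <- generate_world(cfg)
  expect_identical(w1, w2)
  expect_identical(observe_satellite(w1), observe_satellite(w2))
  expect_identical(observe_monitors(w1), observe_monitors(w2))
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(fine_grid = grid_spec(0, 0, 0.05, 0.05, 21, 20),
                            coarse_factor = 5),
               "does not divide")
  w <- tiny_world()
  expect_error(observe_monitors(w, modifyList(w$config,
                                              list(n_monitors = 10000L))),
               "exceeds number of grid cells")
})

test_that("degenerate generator gives a smooth stationary field", {
  w <- generate_world(tiny_config(n_hotspots = 0L, trend_amplitude = 0,
                                  lockdown_factor = 1))
  am <- national_annual_mean(w)
  expect_equal(diff(range(am$mean_no2)), 0, tolerance = 1e-9)
  # spatial smoothness: adjacent cells nearly identical
  f <- w$surface_no2[, , 1]
  expect_gt(cor(as.vector(f[-1, ]), as.vector(f[-nrow(f), ])), 0.95)
})

test_that("national trend peaks at the configured year and winter exceeds summer", {
  w <- default_world()
  am <- national_annual_mean(w)
  expect_equal(am$year_index[which.max(am$mean_no2)],
               w$config$trend_peak_year_index)
  mm <- apply(w$surface_no2, 3, mean)
  winter <- mean(mm[w$months$month %in% c(12, 1, 2)])
  summer <- mean(mm[w$months$month %in% 6:8])
  expect_gt(winter, summer)
})

test_that("daily column truth averages exactly to the monthly truth", {
  w <- tiny_world()
  for (m in seq_len(nrow(w$months))) {
    sel <- w$days$month_index == m
    dm <- apply(w$vcd_daily[, , sel, drop = FALSE], c(1, 2), mean)
    expect_equal(dm, w$vcd_monthly_coarse[, , m], tolerance = 1e-9)
  }
})

test_that("stored scaling factor is surface over the regridded monthly column", {
  w <- tiny_world()
  for (m in c(1, 13)) {
    vf <- idw_regrid(w$vcd_monthly_coarse[, , m], w$coarse, w$fine)
    expect_equal(w$scaling_truth[, , m], w$surface_no2[, , m] / vf,
                 tolerance = 1e-9)
  }
})

test_that("satellite missingness is exactly the cloud rule plus anomaly stripe", {
  w <- tiny_world()
  s <- observe_satellite(w)
  expect_identical(is.na(s$vcd),
                   w$cloud_fraction > 0.30 | s$missing_anomaly)
  expect_false(any(s$missing_anomaly))

  # all-clear skies: full coverage; overcast: none
  w0 <- w; w0$cloud_fraction[] <- 0
  expect_equal(observe_satellite(w0)$coverage, 1)
  w1 <- w; w1$cloud_fraction[] <- 1
  expect_equal(observe_satellite(w1)$coverage, 0)

  sa <- observe_satellite(w, modifyList(w$config,
                                        list(row_anomaly = TRUE,
                                             row_anomaly_start_year = 0L)))
  expect_true(any(sa$missing_anomaly))
  expect_true(all(is.na(sa$vcd[sa$missing_anomaly])))
  expect_lt(sa$coverage, s$coverage)
})

test_that("default-world raw coverage lands near the configured target", {
  s <- default_sat()
  expect_gte(s$coverage, 0.42)
  expect_lte(s$coverage, 0.52)
  cfg <- default_world()$config
  expect_lt(abs((1 - s$coverage) - cfg$missingness_target), 0.05)
})

test_that("unbiased monitor siting is uniform over the domain", {
  w <- tiny_world()
  cfg0 <- modifyList(w$config, list(monitor_siting_bias = 0))
  # pool placements over seeds, then chi-square against uniform quadrants
  counts <- matrix(0, 2, 2)
  for (s in 1:40) {
    cfg0$seed <- 1000L + s
    st <- observe_monitors(w, cfg0)$stations
    qi <- 1L + (st$row > w$fine$nrows / 2)
    qj <- 1L + (st$col > w$fine$ncols / 2)
    for (m in seq_len(nrow(st))) counts[qi[m], qj[m]] <- counts[qi[m], qj[m]] + 1
  }
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.01)
})

test_that("populous cells attract monitors under positive siting bias", {
  w <- tiny_world()
  pop_at <- function(st) mean(w$population_base[cbind(st$row, st$col)])
  biased <- numeric(20); unif <- numeric(20)
  for (s in 1:20) {
    cfg <- w$config; cfg$seed <- 2000L + s
    biased[s] <- pop_at(observe_monitors(w, modifyList(cfg,
      list(monitor_siting_bias = 2)))$stations)
    unif[s] <- pop_at(observe_monitors(w, modifyList(cfg,
      list(monitor_siting_bias = 0)))$stations)
  }
  expect_gt(mean(biased), mean(unif))
})
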