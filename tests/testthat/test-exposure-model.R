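test_that("training table joins stations to cells and computes the ratio target", {
  w <- tiny_world()
  monthly <- data.frame(station_id = c("A", "A", "B"),
                        year = 2005L, month = c(1L, 2L, 1L),
                        mean_no2 = c(30, 12, 18), n_valid_days = 6L)
  stations <- data.frame(station_id = c("A", "B"),
                         lat = grid_lat(w$fine)[c(3, 7)],
                         lon = grid_lon(w$fine)[c(4, 9)])
  vf <- array(rlnorm(prod(c(dim(w$surface_no2)[1:2], nrow(w$months)))),
              c(dim(w$surface_no2)[1:2], nrow(w$months)))
  vf[3, 4, 1] <- 10
  tab <- build_training_table(monthly, stations, vf, w)
  row1 <- tab[tab$station_id == "A" & tab$month == 1, ]
  expect_equal(row1$S, 3.0)
  expect_equal(tab$S, tab$mean_no2 / tab$vcd)

  # a zero column density cannot form a ratio: row excluded
  vf[3, 4, 1] <- 0
  tab0 <- build_training_table(monthly, stations, vf, w)
  expect_false(any(tab0$station_id == "A" & tab0$month == 1))
  expect_gte(attr(tab0, "n_dropped"), 1L)

  # stations outside the grid are dropped with a warning
  stations$lat[2] <- 89
  expect_warning(build_training_table(monthly, stations, vf, w),
                 "outside the grid")
})

test_that("observed scaling factors track the latent truth under low noise", {
  w <- generate_world(world_config(
    seed = 21, n_years = 2L, fine_grid = grid_spec(30, 110, 0.05, 0.05, 30, 30),
    coarse_factor = 5L, n_monitors = 8L, trend_peak_year_index = 1L,
    days_per_month = 6L, retrieval_noise = 0.02, station_bias_sd = 0,
    hourly_noise_sd = 0.5, artifact_rate = 0, missingness_target = 0.2,
    cloud_pollution_coupling = 0))
  sat <- observe_satellite(w)
  gf <- gapfill_run(sat, w, seed = 21)
  vf <- monthly_vcd_fine(gf, w)
  mo <- observe_monitors(w)
  qc <- qc_monitors(mo$hourly, min_days = 5L)
  tab <- build_training_table(qc, mo$stations, vf, w)
  expect_gt(cor(tab$S, truth_at_rows(tab, w)), 0.9)
})

test_that("a noiseless linear scaling law is learned almost exactly", {
  fit <- fit_ensemble(linear_table(), seed = 5, combiner = "insample")
  r2 <- fit$insample$r2[fit$insample$learner == "ensemble"]
  expect_gt(r2, 0.99)
})

test_that("the combined in-sample fit is at least as good as the best base learner", {
  fit <- insample_fit()
  rmse <- fit$insample$rmse
  expect_lte(rmse[fit$insample$learner == "ensemble"],
             min(rmse[fit$insample$learner != "ensemble"]) + 1e-9)
})

test_that("fits are deterministic and survive serialization", {
  tab <- linear_table(300, seed = 2)
  f1 <- fit_ensemble(tab, seed = 9, combiner = "insample")
  f2 <- fit_ensemble(tab, seed = 9, combiner = "insample")
  nd <- linear_table(80, seed = 3)
  expect_identical(predict(f1, nd), predict(f2, nd))

  tmp <- tempfile(fileext = ".rds")
  saveRDS(f1, tmp)
  f3 <- readRDS(tmp)
  expect_identical(as.numeric(predict(f1, nd)), as.numeric(predict(f3, nd)))
  unlink(tmp)
})

test_that("degenerate and undersized tables are rejected", {
  tab <- linear_table(150)
  expect_error(fit_ensemble(tab), "at least 200")
  tab2 <- linear_table(250)
  tab2$S <- 1
  tab2$mean_no2 <- tab2$vcd
  expect_error(fit_ensemble(tab2, combiner = "insample"), "degenerate")
})

test_that("the prediction pipeline is scaling times column density", {
  fit <- insample_fit()
  nd <- final_year_table()
  S <- predict(fit, nd, type = "scaling")
  base <- predict(fit, nd, type = "base_no2")
  expect_equal(base, S * nd$vcd)
  # doubling the column with scaling held fixed doubles base predictions
  expect_equal(S * (2 * nd$vcd), 2 * base)

  missing_cols <- nd[, setdiff(names(nd), "blh")]
  expect_error(predict(fit, missing_cols), "blh")
})

test_that("identity learners and combiner wire the column straight through", {
  w <- tiny_world()
  one <- function(X) rep(1, nrow(X))
  model <- structure(list(
    learners = list(rf = one, xgb = one, gbm = one),
    combiner = function(d) d$p_rf,
    combiner_mode = "insample", spec = ensemble_spec(), seed = 1L,
    predictors = c("vcd", "temperature", "blh", "emission", "cams_no2",
                   "elevation", "population", "lat", "lon", "month",
                   "year_index"),
    train_years = 2005L, n_train = 0L, insample = NULL),
    class = "no2_ensemble")
  vf <- monthly_vcd_fine(w$vcd_daily, w)
  pred <- predict_surface(model, vf, w, month_index = 2)
  expect_equal(unclass(pred), vf[, , 2], ignore_attr = TRUE)
})

test_that("surface predictions are complete, nonnegative and bounded", {
  fit <- default_fit()
  w <- default_world()
  vf <- default_vcd_fine()
  m <- which(w$months$year == 2020)[6]
  pred <- predict_surface(fit, vf, w, m)
  expect_false(anyNA(pred))
  expect_true(all(pred >= 0))
  expect_lt(max(pred), 3 * max(default_table()$mean_no2))
})
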