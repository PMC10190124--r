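test_that("stuck runs of eight or more identical hours are removed, shorter kept", {
  h8 <- make_hourly(c(12.1, rep(25.0, 8), 13.4, 14.2))
  out <- remove_stuck_runs(h8)
  expect_identical(which(is.na(out$no2)), 2:9)

  h7 <- make_hourly(c(12.1, rep(25.0, 7), 13.4))
  expect_false(anyNA(remove_stuck_runs(h7)$no2))

  inc <- make_hourly(seq(5, by = 0.5, length.out = 24))
  expect_identical(remove_stuck_runs(inc)$no2, inc$no2)
})

test_that("a missing hour breaks a stuck run", {
  # 5 identical + gap + 4 identical: neither segment reaches 8 consecutive
  h <- make_hourly(rep(25.0, 10))
  h <- h[-6, ]
  expect_false(anyNA(remove_stuck_runs(h)$no2))

  # 4 + gap + 8 identical: only the adjacent 8 are flagged
  h2 <- make_hourly(rep(30.0, 13))
  h2 <- h2[-5, ]
  out <- remove_stuck_runs(h2)
  expect_identical(which(is.na(out$no2)), 5:12)
})

test_that("daily completeness threshold is 'fewer than 18 hours excluded'", {
  v24 <- rnorm(24, 20, 2)
  full <- make_hourly(v24)
  d18 <- daily_means(full[1:18, ])
  expect_equal(nrow(d18), 1L)
  expect_equal(d18$mean_no2, mean(v24[1:18]))
  expect_equal(nrow(daily_means(full[1:17, ])), 0L)

  allten <- make_hourly(rep(10, 24))
  expect_equal(daily_means(allten)$mean_no2, 10)
})

test_that("monthly completeness threshold is 'fewer than 20 days removed'", {
  mk_days <- function(n) data.frame(
    station_id = "A",
    date = as.Date("2019-03-01") + seq_len(n) - 1L,
    mean_no2 = 12, n_valid_hours = 24L)
  expect_equal(monthly_means(mk_days(20))$mean_no2, 12)
  expect_equal(monthly_means(mk_days(20))$n_valid_days, 20L)
  expect_equal(nrow(monthly_means(mk_days(19))), 0L)
})

test_that("reference-state correction applies strictly before the cutover", {
  t_aug <- as.POSIXct("2018-08-31 23:00:00", tz = "UTC")
  t_sep <- as.POSIXct("2018-09-01 00:00:00", tz = "UTC")
  expect_equal(reference_state_correction(50, t_aug), 46)
  expect_equal(reference_state_correction(50, t_sep), 50)
  expect_equal(reference_state_correction(0, t_aug), 0)
})

test_that("flagged hours match injected artifacts exactly on the synthetic network", {
  mo <- default_monitors()
  qc <- default_qc()
  fl <- attr(qc, "flagged")
  got <- paste(fl$station_id, as.numeric(fl$timestamp))
  want <- paste(mo$artifacts$stuck$station_id,
                as.numeric(mo$artifacts$stuck$timestamp))
  expect_setequal(got, want)
  expect_equal(nrow(fl), nrow(mo$artifacts$stuck))
})

test_that("completeness rules are idempotent and monotone in thresholds", {
  mo <- default_monitors()
  sub <- mo$hourly[mo$hourly$station_id %in% c("S001", "S002"), ]
  once <- qc_monitors(sub, min_days = 6L)
  # re-running the rule chain on already-corrected data changes nothing
  corrected <- sub
  corrected$no2 <- reference_state_correction(corrected$no2,
                                              corrected$timestamp)
  twice <- qc_monitors(corrected, min_days = 6L, correction = FALSE)
  expect_equal(as.data.frame(once), as.data.frame(twice))

  strict <- qc_monitors(sub, min_days = 7L)
  key_strict <- paste(strict$station_id, strict$year, strict$month)
  key_loose <- paste(once$station_id, once$year, once$month)
  expect_true(all(key_strict %in% key_loose))
})

test_that("without injected artifacts only completeness rules remove data", {
  w <- tiny_world()
  mo <- observe_monitors(w, modifyList(w$config,
                                       list(artifact_rate = 0,
                                            base_missing_rate = 0)))
  expect_equal(nrow(mo$artifacts$stuck), 0L)
  qc <- qc_monitors(mo$hourly, min_days = 5L)
  expect_equal(nrow(attr(qc, "flagged")), 0L)
  # every station-month survives: all days have 24 valid hours
  expect_equal(nrow(qc), w$config$n_monitors * nrow(w$months))
})
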