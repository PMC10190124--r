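test_that("relative risk follows the log-linear exposure-response form", {
  er <- exposure_response()
  expect_identical(rr_at(10, er), 1.02)
  expect_identical(rr_at(er$ref, er), 1)
  expect_equal(rr_at(20, er), 1.02^2)
  expect_equal(rr_at(20, er), 1.0404)
  # below-reference exposures are clamped, never protective
  er5 <- exposure_response(ref = 5)
  expect_identical(rr_at(2, er5), 1)
  expect_identical(rr_at(c(0, 15), er5), c(1, 1.02))
  expect_equal(rr_at(10, er, "high"), 1.04)
})

test_that("attributable fraction is (RR-1)/RR, increasing, and guarded", {
  expect_equal(attributable_fraction(1), 0)
  expect_equal(attributable_fraction(2), 0.5)
  expect_equal(attributable_fraction(1.02), 0.0196078431372549)
  rr <- seq(1, 3, by = 0.1)
  expect_true(all(diff(attributable_fraction(rr)) > 0))
  expect_error(attributable_fraction(0.9), "below 1")
})

test_that("attributable deaths follow AF x Pop x I with hand-computable cases", {
  demo <- data.frame(province = 1, year = 2010,
                     population = 1000, mortality_rate = 0.01)
  # rr_per10 = 2 at C = 10 gives AF = 0.5, so AD = 0.5 * 1000 * 0.01 = 5
  er2 <- exposure_response(rr_per10 = 2, rr_low = 1.5, rr_high = 3)
  bt <- attributable_deaths(data.frame(province = 1, year = 2010, C = 10),
                            demo, er2)
  expect_equal(bt$AD, 5)
  expect_equal(bt$AD_per_100k, 500)

  # zero exposure at the counterfactual reference: no burden
  bt0 <- attributable_deaths(data.frame(province = 1, year = 2010, C = 0),
                             demo, exposure_response())
  expect_equal(bt0$AD, 0)
  expect_equal(bt0$AD_low, 0)

  # closed form at C = 30: AF = (1.02^3 - 1)/1.02^3
  demo6 <- data.frame(province = 1, year = 2010,
                      population = 1e6, mortality_rate = 0.007)
  bt3 <- attributable_deaths(data.frame(province = 1, year = 2010, C = 30),
                             demo6, exposure_response())
  rr3 <- 1.02^3
  expect_equal(bt3$AD, 1e6 * 0.007 * (rr3 - 1) / rr3)
  expect_lt(abs(bt3$AD - 403.8), 0.5)

  expect_error(attributable_deaths(
    data.frame(province = 2, year = 2010, C = 10), demo,
    carry_forward = FALSE), "no demography row")
})

test_that("confidence bounds bracket the estimate and burden is monotone", {
  demo <- data.frame(province = rep(1:3, each = 2),
                     year = rep(c(2010, 2011), 3),
                     population = rep(c(1e6, 2e6, 3e6), each = 2),
                     mortality_rate = rep(c(0.006, 0.007, 0.008), each = 2))
  expo <- expand.grid(province = 1:3, year = c(2010, 2011))
  expo$C <- c(10, 20, 30, 12, 22, 32)
  bt <- attributable_deaths(expo, demo)
  expect_true(all(bt$AD_low <= bt$AD & bt$AD <= bt$AD_high))
  # monotone in C, holding demography fixed
  b1 <- attributable_deaths(data.frame(province = 1, year = 2010, C = 10), demo)
  b2 <- attributable_deaths(data.frame(province = 1, year = 2010, C = 11), demo)
  expect_gt(b2$AD, b1$AD)
})

test_that("small exposures reduce to the log-linear limit within 1 percent", {
  er <- exposure_response()
  for (C in c(0.5, 1, 2, 4.9)) {
    af <- attributable_fraction(rr_at(C, er))
    approx <- log(1.02) * C / 10
    expect_lt(abs(af - approx) / af, 0.01)
  }
})

test_that("freezing demography isolates the exposure-driven trend", {
  demo <- data.frame(province = 1, year = 2005:2010,
                     population = 1e6 * 1.05^(0:5), mortality_rate = 0.007)
  expo <- data.frame(province = 1, year = 2005:2010, C = 25)
  grown <- attributable_deaths(expo, demo)
  frozen <- fixed_reference_population(expo, demo, reference_year = 2005)
  expect_true(all(diff(grown$AD) > 0))
  expect_equal(diff(range(frozen$AD)), 0, tolerance = 1e-12)
  # in the reference year itself the two agree
  expect_equal(frozen$AD[1], grown$AD[1])
  expect_error(fixed_reference_population(expo, demo, reference_year = 1990),
               "not present")
})

test_that("demography carry-forward covers reporting-lag years", {
  w <- default_world()
  ann <- annual_means(w$surface_no2, w$months)
  final <- dim(ann)[3]
  expo <- provincial_exposure(ann[, , final],
                              w$covariates$population[, , final],
                              w$provinces)
  expo$year <- max(w$months$year)          # year absent from demography
  expect_false(expo$year[1] %in% w$mortality$year)
  bt <- attributable_deaths(expo, w$mortality)
  last <- w$mortality[w$mortality$year == max(w$mortality$year), ]
  expect_equal(bt$AD / (bt$C |> rr_at() |> attributable_fraction()),
               last$population * last$mortality_rate)
})

test_that("provincial exposure aggregates like the shared weighted mean", {
  w <- tiny_world()
  ann <- annual_means(w$surface_no2, w$months)[, , 1]
  pop <- w$covariates$population[, , 1]
  pe <- provincial_exposure(ann, pop, w$provinces)
  for (p in pe$province)
    expect_equal(pe$C[pe$province == p],
                 population_weighted_mean(ann, pop, w$provinces == p))
  # uniform field: every province equals the field value
  u <- provincial_exposure(matrix(9, nrow(ann), ncol(ann)), pop, w$provinces)
  expect_equal(u$C, rep(9, nrow(u)))
  # province totals cover the whole grid exactly once
  expect_equal(sum(table(as.vector(w$provinces))),
               length(w$provinces))

  pop0 <- pop; pop0[w$provinces == 1] <- 0
  expect_warning(provincial_exposure(ann, pop0, w$provinces),
                 "zero population")
})

test_that("national burden is the exact sum of provincial burdens", {
  w <- tiny_world()
  ann <- annual_means(w$surface_no2, w$months)
  yrs <- as.integer(dimnames(ann)[[3]])
  expo <- do.call(rbind, lapply(seq_along(yrs), function(i) {
    pe <- provincial_exposure(ann[, , i], w$covariates$population[, , i],
                              w$provinces)
    pe$year <- yrs[i]
    pe
  }))
  bt <- attributable_deaths(expo, w$mortality)
  nat <- tapply(bt$AD, bt$year, sum)
  for (y in names(nat))
    expect_equal(unname(nat[y]), sum(bt$AD[bt$year == as.integer(y)]))
  expect_true(all(bt$AD >= 0))
})
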