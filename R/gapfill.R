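#' Gap-filling configuration
#'
#' Hyperparameters of the random-forest model imputing missing satellite
#' columns: 5 predictors tried per split and 500 trees, fitted on a rolling
#' three-day window (half-width 1) and predicting the middle day.
#'
#' @param mtry Predictors tried per split (default 5).
#' @param ntree Trees per forest (default 500).
#' @param window_halfwidth Days either side of the target day (default 1,
#'   i.e. a 3-day window; truncated at the record edges).
#' @param min_train Minimum observed pixel-days in the window needed to fit
#'   a forest; defaults to `max(10, mtry + 1)`. Days below it fall back to
#'   same-day spatial IDW, then per-pixel temporal interpolation.
#' @return A `gapfill_config` list.
#' @export
gapfill_config <- function(mtry = 5L, ntree = 500L, window_halfwidth = 1L,
                           min_train = NULL) {
  if (is.null(min_train)) min_train <- max(10L, mtry + 1L)
  structure(list(mtry = as.integer(mtry), ntree = as.integer(ntree),
                 window_halfwidth = as.integer(window_halfwidth),
                 min_train = as.integer(min_train)),
            class = "gapfill_config")
}

#' Fraction of valid satellite pixel-days
#'
#' @param vcd A coarse column-density array (pixels x pixels x days, `NA` =
#'   missing) or a `sat_obs` object.
#' @return Non-missing pixel-days divided by total pixel-days.
#' @export
coverage <- function(vcd) {
  if (inherits(vcd, "sat_obs")) vcd <- vcd$vcd
  if (length(vcd) == 0L) stop("empty field sequence")
  mean(!is.na(vcd))
}

# Coarse-resolution predictor stack used by the gap-filling forest:
# monthly column-related covariates aggregated to satellite pixels, plus
# static elevation, annual population, and spatiotemporal terms.
coarse_predictor_stack <- function(world) {
  cf <- world$config$coarse_factor
  nm <- nrow(world$months)
  agg <- function(arr) {
    out <- array(0, c(world$coarse$nrows, world$coarse$ncols, dim(arr)[3]))
    for (m in seq_len(dim(arr)[3])) out[, , m] <- block_aggregate(arr[, , m], cf)
    out
  }
  list(temperature = agg(world$covariates$temperature),
       blh = agg(world$covariates$blh),
       emission = agg(world$covariates$emission),
       cams_no2 = agg(world$covariates$cams_no2),
       elevation = block_aggregate(world$covariates$elevation, cf),
       population = agg(world$covariates$population),
       lat = matrix(rep(grid_lat(world$coarse), world$coarse$ncols),
                    world$coarse$nrows),
       lon = matrix(rep(grid_lon(world$coarse), each = world$coarse$nrows),
                    world$coarse$nrows))
}

# Assemble the model frame for a set of (pixel, day) entries. `cells` is a
# logical matrix pixel x day over `day_idx`.
gapfill_frame <- function(vcd, cloud, stack, world, day_idx, sel, target_day) {
  rows <- which(sel)
  npix <- dim(vcd)[1] * dim(vcd)[2]
  pix <- (rows - 1L) %% npix + 1L
  dd <- day_idx[(rows - 1L) %/% npix + 1L]
  mi <- world$days$month_index[dd]
  yi <- world$months$year_index[mi] + 1L
  mstride <- (mi - 1L) * npix
  ystride <- (yi - 1L) * npix
  data.frame(
    vcd = vcd[, , day_idx, drop = FALSE][sel],
    cloud = cloud[, , day_idx, drop = FALSE][sel],
    temperature = stack$temperature[pix + mstride],
    blh = stack$blh[pix + mstride],
    emission = stack$emission[pix + mstride],
    cams_no2 = stack$cams_no2[pix + mstride],
    elevation = as.vector(stack$elevation)[pix],
    population = stack$population[pix + ystride],
    lat = as.vector(stack$lat)[pix],
    lon = as.vector(stack$lon)[pix],
    rel_day = dd - target_day,
    doy = world$days$doy[dd])
}

#' Impute one day of satellite columns
#'
#' Fits a random forest on all observed pixel-days in the rolling window
#' centred on `day` and predicts the missing pixels of that day. Observed
#' pixels are never altered. Out-of-bag R-squared is taken from the
#' forest's own OOB predictions. With fewer than `min_train` observed
#' pixel-days in the window the day is flagged for fallback.
#'
#' @param day Day index into the record.
#' @param vcd Coarse column array (`NA` = missing), pixels x pixels x days.
#' @param world The `no2_world` providing covariates and the calendar.
#' @param config A [gapfill_config()].
#' @param seed Integer seed (per-day forest seed is `seed + day`).
#' @param stack Precomputed [coarse_predictor_stack()]; built on the fly
#'   when `NULL`.
#' @return List: `field` (the day's matrix, filled where possible),
#'   `imputed` (logical matrix), `oob_r2`, `n_train`, `method`
#'   (`"rf"`, `"fallback"` or `"complete"`), and `oob` (data frame of
#'   OOB predictions and observations).
#' @export
impute_day <- function(day, vcd, world, config = gapfill_config(),
                       seed = 1L, stack = NULL) {
  if (is.null(stack)) stack <- coarse_predictor_stack(world)
  nd <- dim(vcd)[3]
  w <- max(1L, day - config$window_halfwidth):min(nd, day + config$window_halfwidth)
  field <- vcd[, , day]
  miss <- is.na(field)
  if (!any(miss))
    return(list(field = field, imputed = miss, oob_r2 = NA_real_,
                n_train = 0L, method = "complete",
                oob = data.frame(obs = numeric(), pred = numeric())))
  win <- vcd[, , w, drop = FALSE]
  obs_sel <- !is.na(win)
  n_train <- sum(obs_sel)
  if (n_train < config$min_train)
    return(list(field = field, imputed = miss, oob_r2 = NA_real_,
                n_train = n_train, method = "fallback",
                oob = data.frame(obs = numeric(), pred = numeric())))
  train <- gapfill_frame(vcd, world$cloud_fraction, stack, world, w,
                         obs_sel, day)
  fit <- ranger::ranger(
    vcd ~ ., data = train,
    num.trees = config$ntree,
    mtry = min(config$mtry, ncol(train) - 1L),
    seed = seed + day, num.threads = 1L)
  tsel <- array(FALSE, dim(win))
  tsel[, , which(w == day)] <- miss
  newd <- gapfill_frame(vcd, world$cloud_fraction, stack, world, w, tsel, day)
  newd$vcd <- NULL
  field[miss] <- stats::predict(fit, newd, num.threads = 1L)$predictions
  keep <- !is.na(fit$predictions)
  list(field = field, imputed = miss, oob_r2 = fit$r.squared,
       n_train = n_train, method = "rf",
       oob = data.frame(obs = train$vcd[keep], pred = fit$predictions[keep]))
}

#' Gap-fill a full satellite record
#'
#' Runs [impute_day()] over every day, applies the fallback chain
#' (same-day spatial IDW, then per-pixel temporal interpolation) to days
#' with too little training data, and reports coverage before/after plus
#' per-day and pooled out-of-bag skill. After the run no pixel is missing.
#'
#' @param sat A `sat_obs` from [observe_satellite()] or a coarse column
#'   array with `NA` for missing.
#' @param world The generating `no2_world`.
#' @param config A [gapfill_config()].
#' @param seed Integer seed.
#' @param verbose Print progress every 200 days.
#' @return Object of class `gapfill_result`: `vcd` (complete array),
#'   `imputed` (logical array), and `report` with `coverage_before`,
#'   `coverage_after`, `oob_r2_daily`, `oob_r2_mean`, `oob_r2_pooled`,
#'   and `fallback_days`.
#' @export
gapfill_run <- function(sat, world, config = gapfill_config(), seed = 1L,
                        verbose = FALSE) {
  vcd <- if (inherits(sat, "sat_obs")) sat$vcd else sat
  stopifnot(length(dim(vcd)) == 3L)
  cov_before <- coverage(vcd)
  stack <- coarse_predictor_stack(world)
  nd <- dim(vcd)[3]
  out <- vcd
  imputed <- is.na(vcd)
  oob_daily <- rep(NA_real_, nd)
  fallback_days <- integer()
  oob_obs <- vector("list", nd); oob_pred <- vector("list", nd)
  for (d in seq_len(nd)) {
    res <- impute_day(d, vcd, world, config, seed = seed, stack = stack)
    oob_daily[d] <- res$oob_r2
    oob_obs[[d]] <- res$oob$obs; oob_pred[[d]] <- res$oob$pred
    if (res$method == "fallback") {
      fallback_days <- c(fallback_days, d)
      obs_day <- vcd[, , d]
      if (any(!is.na(obs_day))) {
        out[, , d] <- idw_regrid(obs_day, world$coarse, world$coarse)
      }                                  # else left for temporal pass
    } else {
      out[, , d] <- res$field
    }
    if (verbose && d %% 200L == 0L)
      message("gapfill: day ", d, "/", nd)
  }
  if (anyNA(out)) {                      # temporal interpolation, per pixel
    npix <- dim(out)[1] * dim(out)[2]
    for (p in seq_len(npix)) {
      i <- (p - 1L) %% dim(out)[1] + 1L; j <- (p - 1L) %/% dim(out)[1] + 1L
      s <- out[i, j, ]
      if (anyNA(s)) {
        ok <- which(!is.na(s))
        if (length(ok) == 0L) stop("pixel with no valid day anywhere")
        out[i, j, ] <- stats::approx(ok, s[ok], xout = seq_len(nd),
                                     rule = 2)$y
      }
    }
  }
  pooled_obs <- unlist(oob_obs); pooled_pred <- unlist(oob_pred)
  structure(list(
    vcd = out, imputed = imputed,
    report = list(coverage_before = cov_before,
                  coverage_after = coverage(out),
                  oob_r2_daily = oob_daily,
                  oob_r2_mean = mean(oob_daily, na.rm = TRUE),
                  oob_r2_pooled = if (length(pooled_obs))
                    r2_score(pooled_obs, pooled_pred) else NA_real_,
                  fallback_days = fallback_days)),
    class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("Gap-fill: coverage %.1f%% -> %.1f%%; mean OOB R2 %.3f (pooled %.3f); %d fallback day(s)\n",
              100 * r$coverage_before, 100 * r$coverage_after,
              r$oob_r2_mean, r$oob_r2_pooled, length(r$fallback_days)))
  invisible(x)
}

#' Monthly fine-grid column densities from gap-filled daily columns
#'
#' Averages the complete daily coarse columns within each month, then
#' moves each monthly field onto the fine grid by inverse distance
#' weighting (the aggregation order used throughout: fill, monthly mean,
#' then regrid).
#'
#' @param filled A `gapfill_result` or complete coarse daily array.
#' @param world The `no2_world`.
#' @param power,k IDW parameters (defaults 2 and 4).
#' @return Fine-grid array (nrows x ncols x months).
#' @export
monthly_vcd_fine <- function(filled, world, power = 2, k = 4) {
  vcd <- if (inherits(filled, "gapfill_result")) filled$vcd else filled
  nm <- nrow(world$months)
  fg <- world$fine
  plan <- idw_plan(world$coarse, fg, power = power, k = k)
  out <- array(0, c(fg$nrows, fg$ncols, nm))
  for (m in seq_len(nm)) {
    sel <- world$days$month_index == m
    cm <- apply(vcd[, , sel, drop = FALSE], c(1, 2), mean)
    out[, , m] <- matrix(idw_apply(plan, as.vector(cm)), fg$nrows, fg$ncols)
  }
  out
}
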