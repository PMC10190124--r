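#' Build the scaling-factor training table
#'
#' Joins each QC'd station-month to the column density and covariates of
#' its containing fine grid cell and computes the regression target
#' S = surface NO2 / column density. Rows whose column density falls at or
#' below a small threshold (the 1st percentile of positive values, where
#' the ratio is ill-conditioned) or with non-finite S are dropped and
#' counted; stations outside the grid are dropped with a warning.
#'
#' @param monthly Monthly station means from [qc_monitors()].
#' @param stations Station table with `station_id`, `lat`, `lon`.
#' @param vcd_fine Monthly fine-grid column array from [monthly_vcd_fine()].
#' @param world The `no2_world` supplying covariates and the calendar.
#' @return A data frame of class `no2_table` with the target `S`, observed
#'   `mean_no2`, and predictor columns (attribute `predictors`); dropped
#'   row counts are in attribute `n_dropped`.
#' @export
build_training_table <- function(monthly, stations, vcd_fine, world) {
  m <- merge(monthly, stations[, c("station_id", "lat", "lon")],
             by = "station_id")
  loc <- grid_locate(world$fine, m$lat, m$lon)
  outside <- is.na(loc[, 1]) | is.na(loc[, 2])
  if (any(outside)) {
    warning(sum(outside), " station-month row(s) outside the grid dropped")
    m <- m[!outside, , drop = FALSE]
    loc <- loc[!outside, , drop = FALSE]
  }
  mi <- match(paste(m$year, m$month),
              paste(world$months$year, world$months$month))
  keep <- !is.na(mi)
  m <- m[keep, , drop = FALSE]; loc <- loc[keep, , drop = FALSE]
  mi <- mi[keep]
  nrw <- world$fine$nrows
  pix <- loc[, 1] + (loc[, 2] - 1L) * nrw
  npix <- nrw * world$fine$ncols
  yi <- world$months$year_index[mi] + 1L
  tab <- data.frame(
    station_id = m$station_id, year = m$year, month = m$month,
    month_index = mi, mean_no2 = m$mean_no2,
    vcd = vcd_fine[pix + (mi - 1L) * npix],
    temperature = world$covariates$temperature[pix + (mi - 1L) * npix],
    blh = world$covariates$blh[pix + (mi - 1L) * npix],
    emission = world$covariates$emission[pix + (mi - 1L) * npix],
    cams_no2 = world$covariates$cams_no2[pix + (mi - 1L) * npix],
    elevation = as.vector(world$covariates$elevation)[pix],
    population = world$covariates$population[pix + (yi - 1L) * npix],
    lat = m$lat, lon = m$lon,
    year_index = world$months$year_index[mi])
  eps <- stats::quantile(tab$vcd[tab$vcd > 0], 0.01, names = FALSE)
  tab$S <- tab$mean_no2 / tab$vcd
  bad <- !(tab$vcd > eps) | !is.finite(tab$S)
  out <- tab[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "predictors") <- c("vcd", "temperature", "blh", "emission",
                               "cams_no2", "elevation", "population",
                               "lat", "lon", "month", "year_index")
  attr(out, "n_dropped") <- sum(bad)
  attr(out, "vcd_eps") <- eps
  class(out) <- c("no2_table", class(out))
  out
}

#' @export
`[.no2_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "predictors") <- attr(x, "predictors")
    attr(out, "vcd_eps") <- attr(x, "vcd_eps")
    class(out) <- class(x)
  }
  out
}

#' Hyperparameter set for the ensemble
#'
#' 500 trees for every base learner; 15 candidate variables per split for
#' the forest (capped at the number of predictors available); maximum tree
#' depth 10 for both gradient-boosted variants.
#'
#' @param ntree Trees per base learner.
#' @param mtry Forest variables per split.
#' @param max_depth Boosted-tree maximum depth.
#' @param eta,eta_slow Learning rates of the two boosted variants.
#' @param subsample Row subsampling of the slow boosted variant.
#' @param cv_combiner Combiner training mode used inside cross-validation
#'   folds (`"insample"` by default; see [fit_ensemble()]).
#' @return List of class `ensemble_spec`.
#' @export
ensemble_spec <- function(ntree = 500L, mtry = 15L, max_depth = 10L,
                          eta = 0.1, eta_slow = 0.05, subsample = 0.7,
                          cv_combiner = "insample") {
  structure(list(ntree = as.integer(ntree), mtry = as.integer(mtry),
                 max_depth = as.integer(max_depth), eta = eta,
                 eta_slow = eta_slow, subsample = subsample,
                 cv_combiner = cv_combiner),
            class = "ensemble_spec")
}

fit_base_learners <- function(X, y, spec, seed) {
  p <- ncol(X)
  rf <- ranger::ranger(x = X, y = y, num.trees = spec$ntree,
                       mtry = min(spec$mtry, p), seed = seed,
                       num.threads = 1L)
  mx <- as.matrix(X)
  set.seed(seed)
  xgb <- xgboost::xgb.train(
    params = list(max_depth = spec$max_depth, eta = spec$eta,
                  nthread = 1L, seed = seed),
    data = xgboost::xgb.DMatrix(mx, label = y),
    nrounds = spec$ntree, verbose = 0)
  set.seed(seed + 1L)
  gbm <- xgboost::xgb.train(
    params = list(max_depth = spec$max_depth, eta = spec$eta_slow,
                  subsample = spec$subsample, colsample_bytree = 0.8,
                  nthread = 1L, seed = seed + 1L),
    data = xgboost::xgb.DMatrix(mx, label = y),
    nrounds = spec$ntree, verbose = 0)
  list(rf = rf, xgb = xgboost::xgb.save.raw(xgb),
       gbm = xgboost::xgb.save.raw(gbm))
}

# Each learner is a fitted ranger, a raw-serialized xgboost booster, or a
# plain function(X) -> scaling-factor vector (the latter mainly for
# pipeline wiring checks).
predict_one_S <- function(l, X) {
  if (is.function(l)) return(l(X))
  if (is.raw(l)) return(stats::predict(xgboost::xgb.load.raw(l),
                                       as.matrix(X)))
  stats::predict(l, X, num.threads = 1L)$predictions
}

predict_base_S <- function(learners, X) {
  cbind(rf = predict_one_S(learners$rf, X),
        xgb = predict_one_S(learners$xgb, X),
        gbm = predict_one_S(learners$gbm, X))
}

#' Fit the scaling-factor ensemble exposure model
#'
#' Trains three tree-ensemble base learners -- a bagged random forest and
#' two gradient-boosted variants -- on the scaling factor S, converts each
#' learner's S prediction to a surface NO2 prediction by multiplying with
#' the column density, and combines the three NO2 predictions with a
#' generalized additive model (one smooth per base prediction; the
#' smooths' unpenalized null space spans the linear terms, so the combined
#' in-sample fit can never be worse than the best base learner).
#'
#' By default the combiner is trained on out-of-fold base predictions from
#' an internal 10-fold split, the standard stacking guard against
#' leakage; `combiner = "insample"` trains it on in-sample predictions
#' instead.
#'
#' @param table A training table from [build_training_table()].
#' @param seed Integer seed; fixes all stochastic fits.
#' @param spec An [ensemble_spec()].
#' @param combiner `"oof"` (default) or `"insample"`.
#' @param k Folds of the internal stacking split (default 10).
#' @return An object of class `no2_ensemble` with components `learners`,
#'   `combiner` (fitted `gam`), `predictors`, `train_years`, and
#'   `insample` (per-learner and ensemble in-sample RMSE/R2).
#' @export
fit_ensemble <- function(table, seed = 1L, spec = ensemble_spec(),
                         combiner = c("oof", "insample"), k = 10L) {
  combiner <- match.arg(combiner)
  if (nrow(table) < 200L)
    stop("training table has ", nrow(table), " rows; at least 200 required")
  preds <- attr(table, "predictors")
  X <- table[, preds, drop = FALSE]
  y <- table$S
  if (stats::sd(y) < 1e-12) stop("degenerate constant scaling-factor target")
  learners <- fit_base_learners(X, y, spec, seed)
  S_in <- predict_base_S(learners, X)
  no2_in <- S_in * table$vcd

  if (combiner == "oof") {
    folds <- make_folds(table, "sample", k = k, seed = seed)
    no2_comb <- matrix(NA_real_, nrow(table), 3,
                       dimnames = list(NULL, colnames(S_in)))
    for (f in seq_len(k)) {
      tr <- folds$fold != f; te <- !tr
      lf <- fit_base_learners(X[tr, , drop = FALSE], y[tr], spec,
                              seed + 37L * f)
      no2_comb[te, ] <- predict_base_S(lf, X[te, , drop = FALSE]) *
        table$vcd[te]
    }
  } else {
    no2_comb <- no2_in
  }
  cd <- data.frame(obs = table$mean_no2, p_rf = no2_comb[, "rf"],
                   p_xgb = no2_comb[, "xgb"], p_gbm = no2_comb[, "gbm"])
  gamfit <- mgcv::gam(obs ~ s(p_rf) + s(p_xgb) + s(p_gbm), data = cd)

  ens_in <- as.numeric(stats::predict(gamfit, data.frame(
    p_rf = no2_in[, "rf"], p_xgb = no2_in[, "xgb"], p_gbm = no2_in[, "gbm"])))
  insample <- data.frame(
    learner = c(colnames(no2_in), "ensemble"),
    rmse = c(apply(no2_in, 2, rmse_score, obs = table$mean_no2),
             rmse_score(table$mean_no2, ens_in)),
    r2 = c(apply(no2_in, 2, r2_score, obs = table$mean_no2),
           r2_score(table$mean_no2, ens_in)), row.names = NULL)

  structure(list(learners = learners, combiner = gamfit,
                 combiner_mode = combiner, spec = spec, seed = seed,
                 predictors = preds,
                 train_years = sort(unique(table$year)),
                 n_train = nrow(table), insample = insample),
            class = "no2_ensemble")
}

#' @export
print.no2_ensemble <- function(x, ...) {
  cat(sprintf("Scaling-factor ensemble (%d rows, years %s-%s, combiner: %s)\n",
              x$n_train, min(x$train_years), max(x$train_years),
              x$combiner_mode))
  cat("In-sample fit (NO2 scale):\n")
  print(x$insample, digits = 3)
  invisible(x)
}

#' @export
summary.no2_ensemble <- function(object, ...) {
  print(object)
  cat("\nCombiner (GAM) smooth terms:\n")
  print(summary(object$combiner)$s.table, digits = 3)
  invisible(object)
}

#' Predict surface NO2 for table rows
#'
#' @param object An `no2_ensemble`.
#' @param newdata Data frame holding the model's predictor columns
#'   (including `vcd`).
#' @param type `"response"` (combined surface NO2, clipped at zero),
#'   `"base_no2"` (matrix of the three base NO2 predictions), or
#'   `"scaling"` (matrix of base scaling-factor predictions).
#' @param ... Unused.
#' @return Numeric vector, or a matrix for the component types.
#' @export
predict.no2_ensemble <- function(object, newdata,
                                 type = c("response", "base_no2", "scaling"),
                                 ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$predictors, names(newdata))
  if (length(missing_cols))
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  S <- predict_base_S(object$learners,
                      newdata[, object$predictors, drop = FALSE])
  if (type == "scaling") return(S)
  no2 <- S * newdata$vcd
  if (type == "base_no2") return(no2)
  cd <- data.frame(p_rf = no2[, "rf"], p_xgb = no2[, "xgb"],
                   p_gbm = no2[, "gbm"])
  out <- if (is.function(object$combiner)) object$combiner(cd) else
    as.numeric(stats::predict(object$combiner, cd))
  res <- pmax(out, 0)
  attr(res, "n_negative") <- sum(out < 0)
  res
}

#' Predict a monthly surface NO2 field
#'
#' Applies the ensemble to every fine-grid cell of one month, multiplying
#' predicted scaling factors by the (gap-filled, regridded) column density
#' and combining. Negative combiner outputs are clipped to zero and
#' counted.
#'
#' @param model An `no2_ensemble`.
#' @param vcd_fine Monthly fine-grid column array from
#'   [monthly_vcd_fine()], or a single month's matrix.
#' @param world The `no2_world`.
#' @param month_index Month to predict (index into `world$months`).
#' @return Matrix of surface NO2 (ug/m3) with attribute `n_clipped`.
#' @export
predict_surface <- function(model, vcd_fine, world, month_index) {
  fg <- world$fine
  vm <- if (length(dim(vcd_fine)) == 3L) vcd_fine[, , month_index] else vcd_fine
  npix <- fg$nrows * fg$ncols
  yi <- world$months$year_index[month_index] + 1L
  newd <- data.frame(
    vcd = as.vector(vm),
    temperature = as.vector(world$covariates$temperature[, , month_index]),
    blh = as.vector(world$covariates$blh[, , month_index]),
    emission = as.vector(world$covariates$emission[, , month_index]),
    cams_no2 = as.vector(world$covariates$cams_no2[, , month_index]),
    elevation = as.vector(world$covariates$elevation),
    population = as.vector(world$covariates$population[, , yi]),
    lat = grid_centres(fg)[, "lat"], lon = grid_centres(fg)[, "lon"],
    month = world$months$month[month_index],
    year_index = world$months$year_index[month_index])
  raw <- stats::predict(model, newd)
  out <- matrix(raw, fg$nrows, fg$ncols)
  attr(out, "n_clipped") <- attr(raw, "n_negative")
  out
}
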