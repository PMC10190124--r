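#' Assign cross-validation folds
#'
#' Builds a unit-level random partition for one of the validation schemes:
#' `"sample"` partitions rows, `"spatial"` whole stations, `"temporal"`
#' whole calendar months (year x month of the run), and `"by_year"` uses
#' one fold per distinct year. Units are shuffled and dealt round-robin,
#' so fold sizes differ by at most one unit; the assignment is a
#' deterministic function of the seed.
#'
#' @param table A training table with `station_id`, `year`, `month`.
#' @param scheme One of `"sample"`, `"spatial"`, `"temporal"`, `"by_year"`.
#' @param k Number of folds (default 10; ignored for `"by_year"`, which
#'   uses the number of distinct years).
#' @param seed Integer seed.
#' @return Object of class `fold_assignment`: `scheme`, `k`, `seed`, and
#'   `fold`, an integer vector with one entry per table row.
#' @export
make_folds <- function(table, scheme = c("sample", "spatial", "temporal",
                                         "by_year"),
                       k = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  unit <- switch(scheme,
                 sample = as.character(seq_len(nrow(table))),
                 spatial = as.character(table$station_id),
                 temporal = paste(table$year, table$month, sep = "-"),
                 by_year = as.character(table$year))
  uu <- unique(unit)
  if (scheme == "by_year") k <- length(uu)
  if (length(uu) < k)
    stop("only ", length(uu), " distinct ", scheme,
         " unit(s); need at least k = ", k)
  set.seed(seed)
  perm <- sample(uu)
  fold_of_unit <- stats::setNames((seq_along(perm) - 1L) %% k + 1L, perm)
  structure(list(scheme = scheme, k = as.integer(k), seed = as.integer(seed),
                 fold = unname(fold_of_unit[unit])),
            class = "fold_assignment")
}

#' Cross-validate the exposure model
#'
#' Runs the requested scheme: in each round the model (base learners and
#' combiner) is refit on the training folds only and predicts the held-out
#' fold, so every row is predicted exactly once; R-squared
#' (1 - SS_res/SS_tot) and RMSE are computed on the pooled out-of-fold
#' predictions, with a per-fold breakdown attached. Within folds the
#' combiner is trained on in-sample base predictions (`spec$cv_combiner`),
#' which stays leakage-free across folds while avoiding a nested stacking
#' split.
#'
#' Custom models can be validated by supplying `fit_fun(train_table, seed)`
#' and `predict_fun(fit, test_table)`.
#'
#' @param table Training table ([build_training_table()]).
#' @param scheme Validation scheme, as in [make_folds()].
#' @param k Number of folds (default 10).
#' @param seed Integer seed (folds and model fits).
#' @param spec An [ensemble_spec()].
#' @param fit_fun,predict_fun Optional model override.
#' @return Object of class `no2_cv`: `scheme`, `r2`, `rmse`, `n`,
#'   `per_fold` data frame, and the pooled `predictions`.
#' @export
cross_validate <- function(table, scheme = "sample", k = 10L, seed = 1L,
                           spec = ensemble_spec(),
                           fit_fun = NULL, predict_fun = NULL) {
  folds <- make_folds(table, scheme, k = k, seed = seed)
  if (is.null(fit_fun))
    fit_fun <- function(tr, s) fit_ensemble(tr, seed = s, spec = spec,
                                            combiner = spec$cv_combiner)
  if (is.null(predict_fun))
    predict_fun <- function(fit, te) as.numeric(predict(fit, te))
  pred <- rep(NA_real_, nrow(table))
  per_fold <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    te <- folds$fold == f
    if (!any(te)) stop("fold ", f, " has no test rows")
    tr_tab <- table[!te, , drop = FALSE]
    attr(tr_tab, "predictors") <- attr(table, "predictors")
    fit <- fit_fun(tr_tab, seed + 1009L * f)
    te_tab <- table[te, , drop = FALSE]
    pred[te] <- predict_fun(fit, te_tab)
    per_fold[[f]] <- data.frame(
      fold = f, n = sum(te),
      r2 = r2_score(table$mean_no2[te], pred[te]),
      rmse = rmse_score(table$mean_no2[te], pred[te]))
  }
  structure(list(scheme = scheme, k = folds$k, seed = seed,
                 r2 = r2_score(table$mean_no2, pred),
                 rmse = rmse_score(table$mean_no2, pred),
                 n = nrow(table),
                 per_fold = do.call(rbind, per_fold),
                 predictions = data.frame(obs = table$mean_no2, pred = pred)),
            class = "no2_cv")
}

#' @export
print.no2_cv <- function(x, ...) {
  cat(sprintf("%s CV (k = %d, n = %d): R2 = %.3f, RMSE = %.2f ug/m3\n",
              x$scheme, x$k, x$n, x$r2, x$rmse))
  invisible(x)
}

#' External (separate-period) validation
#'
#' Evaluates a fitted model on a held-out period that took no part in
#' training, the hindcast-style check: metrics are computed on the test
#' rows only, and any overlap between training and test years is an error.
#'
#' @param model A fitted `no2_ensemble`.
#' @param test_table Table of held-out rows (e.g. the final year).
#' @return Object of class `no2_cv` with scheme `"external_year"`.
#' @export
external_validate <- function(model, test_table) {
  if (nrow(test_table) == 0L) stop("empty external test table")
  overlap <- intersect(model$train_years, unique(test_table$year))
  if (length(overlap))
    stop("training and test periods overlap in year(s): ",
         paste(overlap, collapse = ", "))
  pred <- as.numeric(stats::predict(model, test_table))
  structure(list(scheme = "external_year", k = 1L, seed = model$seed,
                 r2 = r2_score(test_table$mean_no2, pred),
                 rmse = rmse_score(test_table$mean_no2, pred),
                 n = nrow(test_table),
                 per_fold = data.frame(fold = 1L, n = nrow(test_table),
                                       r2 = r2_score(test_table$mean_no2, pred),
                                       rmse = rmse_score(test_table$mean_no2,
                                                         pred)),
                 predictions = data.frame(obs = test_table$mean_no2,
                                          pred = pred)),
            class = "no2_cv")
}
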