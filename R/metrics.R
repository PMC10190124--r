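#' Coefficient of determination
#'
#' Default definition is 1 - SS_res/SS_tot on the supplied (typically
#' pooled out-of-fold) predictions, which can be negative for predictors
#' worse than the observed mean; `method = "cor"` gives the squared
#' Pearson correlation instead.
#'
#' @param obs,pred Numeric vectors.
#' @param method `"ss"` (default) or `"cor"`.
#' @return Scalar R-squared.
#' @export
r2_score <- function(obs, pred, method = c("ss", "cor")) {
  method <- match.arg(method)
  ok <- is.finite(obs) & is.finite(pred)
  obs <- obs[ok]; pred <- pred[ok]
  if (method == "cor") return(stats::cor(obs, pred)^2)
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Root mean squared error
#' @param obs,pred Numeric vectors.
#' @return Scalar RMSE in the units of `obs`.
#' @export
rmse_score <- function(obs, pred) {
  ok <- is.finite(obs) & is.finite(pred)
  sqrt(mean((obs[ok] - pred[ok])^2))
}
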