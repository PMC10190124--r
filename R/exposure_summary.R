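#' Population-weighted mean exposure
#'
#' Sum(pop * no2) / Sum(pop) over the masked, non-missing cells. With
#' uniform population this reduces to the arithmetic mean.
#'
#' @param no2 Exposure matrix (ug/m3).
#' @param pop Population matrix, aligned with `no2`.
#' @param mask Optional logical matrix restricting the region.
#' @return Scalar ug/m3.
#' @export
population_weighted_mean <- function(no2, pop, mask = NULL) {
  stopifnot(all(dim(no2) == dim(pop)))
  sel <- !is.na(no2)
  if (!is.null(mask)) sel <- sel & mask
  w <- sum(pop[sel])
  if (!(w > 0)) stop("total population over the region is zero")
  sum(pop[sel] * no2[sel]) / w
}

#' Population fraction above an exposure threshold
#'
#' Fraction of the (masked) population living in cells whose annual mean
#' exposure strictly exceeds the threshold -- e.g. the 2021 WHO annual NO2
#' guideline of 10 ug/m3 or interim target 1 of 40 ug/m3.
#'
#' @param no2_annual Annual-mean exposure matrix.
#' @param pop Population matrix.
#' @param threshold Threshold in ug/m3.
#' @param mask Optional logical region mask.
#' @return Fraction in \[0, 1\].
#' @export
exceedance_fraction <- function(no2_annual, pop, threshold, mask = NULL) {
  stopifnot(all(dim(no2_annual) == dim(pop)))
  sel <- !is.na(no2_annual)
  if (!is.null(mask)) sel <- sel & mask
  w <- sum(pop[sel])
  if (!(w > 0)) stop("total population over the region is zero")
  sum(pop[sel & no2_annual > threshold]) / w
}

#' Annual mean fields from a monthly stack
#'
#' @param monthly Fine-grid array (rows x cols x months).
#' @param months Calendar data frame with `year` per layer.
#' @param require_complete Require all 12 months of a year (default TRUE;
#'   partial years are dropped with a warning).
#' @return Array (rows x cols x years) with `dimnames` on year.
#' @export
annual_means <- function(monthly, months, require_complete = TRUE) {
  yrs <- sort(unique(months$year))
  keep <- vapply(yrs, function(y) sum(months$year == y) == 12L, TRUE)
  if (require_complete && any(!keep)) {
    warning("dropping partial year(s): ", paste(yrs[!keep], collapse = ", "))
    yrs <- yrs[keep]
  }
  out <- array(0, c(dim(monthly)[1:2], length(yrs)),
               dimnames = list(NULL, NULL, yrs))
  for (i in seq_along(yrs))
    out[, , i] <- apply(monthly[, , months$year == yrs[i], drop = FALSE],
                        c(1, 2), mean)
  out
}

#' Seasonal mean fields
#'
#' Cellwise means over meteorological seasons across all years: DJF winter
#' (December counted toward the following winter), MAM spring, JJA summer,
#' SON autumn.
#'
#' @param monthly Fine-grid array (rows x cols x months).
#' @param months Calendar data frame with a `month` column per layer.
#' @return Named list of matrices (`winter`, `spring`, `summer`, `autumn`).
#' @export
seasonal_means <- function(monthly, months) {
  seas <- list(winter = c(12, 1, 2), spring = 3:5, summer = 6:8,
               autumn = 9:11)
  lapply(seas, function(ms) {
    sel <- months$month %in% ms
    if (!any(sel)) stop("no months available for this season")
    apply(monthly[, , sel, drop = FALSE], c(1, 2), mean)
  })
}

#' Relative change of population-weighted exposure between periods
#'
#' (pw_mean(a) - pw_mean(b)) / pw_mean(b), with b the baseline: the
#' statistic behind lockdown-period comparisons against the same months of
#' reference years.
#'
#' @param monthly Fine-grid array (rows x cols x months).
#' @param idx_a,idx_b Month-layer indices of the comparison and baseline
#'   periods.
#' @param pop Population matrix.
#' @param mask Optional logical region mask.
#' @return Signed fraction (e.g. -0.20 for a 20% decline).
#' @export
period_relative_change <- function(monthly, idx_a, idx_b, pop, mask = NULL) {
  if (!length(idx_a) || !length(idx_b)) stop("empty comparison period")
  pa <- population_weighted_mean(
    apply(monthly[, , idx_a, drop = FALSE], c(1, 2), mean), pop, mask)
  pb <- population_weighted_mean(
    apply(monthly[, , idx_b, drop = FALSE], c(1, 2), mean), pop, mask)
  if (abs(pb) < 1e-12) stop("zero baseline exposure")
  (pa - pb) / pb
}
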