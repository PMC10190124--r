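#' Exposure-response parameterization for all-cause mortality
#'
#' Log-linear relative risk per 10 ug/m3 of NO2. The defaults are the
#' WHO-recommended all-cause value of 1.02 (95% CI 1.01-1.04) per
#' 10 ug/m3 with a counterfactual zero reference (no threshold of safe
#' exposure is assumed).
#'
#' @param rr_per10 Relative risk per 10 ug/m3 (default 1.02).
#' @param rr_low,rr_high 95% confidence bounds (defaults 1.01, 1.04).
#' @param ref Counterfactual reference concentration, ug/m3 (default 0).
#' @return List of class `exposure_response`.
#' @export
exposure_response <- function(rr_per10 = 1.02, rr_low = 1.01,
                              rr_high = 1.04, ref = 0) {
  stopifnot(rr_low <= rr_per10, rr_per10 <= rr_high,
            rr_low > 0, ref >= 0)
  structure(list(rr_per10 = rr_per10, rr_low = rr_low, rr_high = rr_high,
                 ref = ref),
            class = "exposure_response")
}

#' Relative risk at a concentration
#'
#' RR_C = rr_per10^((C - ref) / 10). Concentrations below the reference
#' are clamped to RR = 1: no protective effect is extrapolated.
#'
#' @param C Concentration(s), ug/m3.
#' @param er An [exposure_response()].
#' @param which Use the central estimate (default), lower, or upper RR.
#' @return Relative risk, same length as `C`.
#' @export
rr_at <- function(C, er = exposure_response(),
                  which = c("central", "low", "high")) {
  which <- match.arg(which)
  rr <- switch(which, central = er$rr_per10, low = er$rr_low,
               high = er$rr_high)
  pmax(rr^((C - er$ref) / 10), 1)
}

#' Attributable fraction from a relative risk
#'
#' AF = (RR_C - 1) / RR_C, the share of baseline deaths attributable to
#' exposure above the counterfactual reference.
#'
#' @param rr_c Relative risk(s), each at least 1.
#' @return Fraction(s) in \[0, 1).
#' @export
attributable_fraction <- function(rr_c) {
  if (any(rr_c < 1)) stop("relative risk below 1; clamp exposures upstream")
  (rr_c - 1) / rr_c
}

# Align each (province, year) exposure row with a demography row,
# carrying the last available year forward when reporting lags leave the
# final year(s) without data.
match_demography <- function(exposure, demo, carry_forward = TRUE) {
  key <- paste(exposure$province, exposure$year)
  i <- match(key, paste(demo$province, demo$year))
  if (carry_forward && any(is.na(i))) {
    last <- tapply(demo$year, demo$province, max)
    miss <- which(is.na(i))
    fall <- paste(exposure$province[miss],
                  last[as.character(exposure$province[miss])])
    i[miss] <- match(fall, paste(demo$province, demo$year))
  }
  if (any(is.na(i))) {
    bad <- key[is.na(i)][1]
    stop("no demography row for (province year) = (", bad, ")")
  }
  demo[i, , drop = FALSE]
}

#' Attributable deaths per province and year
#'
#' AD_ij = AF(C_ij) x Pop_ij x I_ij, with confidence bounds computed by
#' substituting the lower and upper relative risks. Years missing from the
#' demography table use the last available year's population and mortality
#' rate (reporting-lag carry-forward) when `carry_forward = TRUE`.
#'
#' @param exposure Data frame (`province`, `year`, `C`) of annual
#'   population-weighted exposures, ug/m3.
#' @param demo Demography data frame (`province`, `year`, `population`,
#'   `mortality_rate` in deaths per person-year).
#' @param er An [exposure_response()].
#' @param carry_forward Carry the last demography year forward (default
#'   `TRUE`).
#' @return Data frame of class `burden_table`: province, year, C, AD,
#'   AD_low, AD_high, AD_per_100k.
#' @export
attributable_deaths <- function(exposure, demo, er = exposure_response(),
                                carry_forward = TRUE) {
  d <- match_demography(exposure, demo, carry_forward)
  base <- d$population * d$mortality_rate
  out <- data.frame(
    province = exposure$province, year = exposure$year, C = exposure$C,
    AD = attributable_fraction(rr_at(exposure$C, er)) * base,
    AD_low = attributable_fraction(rr_at(exposure$C, er, "low")) * base,
    AD_high = attributable_fraction(rr_at(exposure$C, er, "high")) * base)
  out$AD_per_100k <- out$AD / d$population * 1e5
  class(out) <- c("burden_table", class(out))
  out
}

#' Attributable deaths with demography frozen at a reference year
#'
#' Recomputes the burden using every province's population and mortality
#' rate from `reference_year` for all years, isolating the exposure-driven
#' component of the trend from population growth.
#'
#' @inheritParams attributable_deaths
#' @param reference_year Year whose demography is frozen (must be present
#'   for every province).
#' @return A `burden_table` as in [attributable_deaths()].
#' @export
fixed_reference_population <- function(exposure, demo,
                                       er = exposure_response(),
                                       reference_year) {
  ref <- demo[demo$year == reference_year, , drop = FALSE]
  if (nrow(ref) == 0L)
    stop("reference year ", reference_year, " not present in demography")
  frozen <- exposure
  frozen_demo <- ref[match(exposure$province, ref$province), , drop = FALSE]
  if (anyNA(frozen_demo$population))
    stop("reference year ", reference_year, " missing for some province")
  frozen_demo$year <- exposure$year
  attributable_deaths(exposure, frozen_demo, er, carry_forward = FALSE)
}

#' Annual provincial exposure from a gridded field
#'
#' Population-weighted mean of the annual exposure field over each
#' province's cells; a zero-population province falls back to the
#' unweighted mean with a warning.
#'
#' @param no2_annual Annual-mean exposure matrix.
#' @param pop Population matrix.
#' @param provinces Integer label matrix partitioning the grid.
#' @return Data frame (`province`, `C`).
#' @export
provincial_exposure <- function(no2_annual, pop, provinces) {
  stopifnot(all(dim(no2_annual) == dim(provinces)))
  provs <- sort(unique(as.vector(provinces)))
  C <- vapply(provs, function(p) {
    sel <- provinces == p
    if (sum(pop[sel]) > 0) {
      population_weighted_mean(no2_annual, pop, sel)
    } else {
      warning("province ", p, " has zero population; using unweighted mean")
      mean(no2_annual[sel], na.rm = TRUE)
    }
  }, 0)
  data.frame(province = provs, C = C)
}
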