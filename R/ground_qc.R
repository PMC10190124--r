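#' Reference-state correction of NO2 values
#'
#' Chinese gaseous-pollutant reporting switched from the standard
#' atmospheric state (273 K) to a reference state (298.15 K) in September
#' 2018; measurements timestamped strictly before 2018-09-01 00:00 UTC are
#' multiplied by 0.92 to put the whole record on the later convention.
#'
#' @param no2 Numeric vector of concentrations, ug/m3.
#' @param timestamp `POSIXct` vector, recycled against `no2`.
#' @param factor Correction factor (default 0.92).
#' @param cutover Cutover instant (default 2018-09-01 00:00 UTC).
#' @return Corrected numeric vector.
#' @export
reference_state_correction <- function(no2, timestamp, factor = 0.92,
                                       cutover = as.POSIXct("2018-09-01",
                                                            tz = "UTC")) {
  n <- max(length(no2), length(timestamp))
  no2 <- rep_len(no2, n); timestamp <- rep_len(timestamp, n)
  ifelse(timestamp < cutover, no2 * factor, no2)
}

#' Remove stuck-instrument runs from hourly series
#'
#' Every maximal run of at least `min_run` consecutive hours carrying an
#' identical value (equality judged after rounding to three decimals) is
#' set to missing; shorter runs are kept. "Consecutive" requires adjacent
#' hours: a missing hour or a timestamp gap breaks a run.
#'
#' @param hourly Data frame with columns `station_id`, `timestamp`
#'   (`POSIXct`, hourly), `no2`. Timestamps must be strictly increasing
#'   within a station.
#' @param min_run Minimum run length flagged (default 8).
#' @return The data frame with flagged values set `NA` and a logical
#'   attribute column `flagged_stuck` marking them.
#' @export
remove_stuck_runs <- function(hourly, min_run = 8L) {
  stopifnot(all(c("station_id", "timestamp", "no2") %in% names(hourly)))
  flag <- logical(nrow(hourly))
  idx <- split(seq_len(nrow(hourly)), hourly$station_id)
  for (rows in idx) {
    ts <- as.numeric(hourly$timestamp[rows])
    if (is.unsorted(ts, strictly = TRUE))
      stop("timestamps must be strictly increasing within a station")
    v <- round(hourly$no2[rows], 3)
    n <- length(v)
    if (n == 0L) next
    adjacent <- c(FALSE, diff(ts) == 3600)
    same <- c(FALSE, v[-1L] == v[-n] & !is.na(v[-1L]) & !is.na(v[-n]))
    newrun <- !(adjacent & same)
    grp <- cumsum(newrun)
    len <- stats::ave(grp, grp, FUN = length)
    flag[rows] <- len >= min_run & !is.na(v)
  }
  hourly$flagged_stuck <- flag
  hourly$no2[flag] <- NA_real_
  hourly
}

#' Daily means from QC'd hourly series
#'
#' A calendar day yields a mean only if it has at least `min_hours` valid
#' (non-missing) hourly values; the mean is the plain average of the valid
#' hours.
#'
#' @param hourly Data frame (`station_id`, `timestamp`, `no2`), stuck runs
#'   already removed.
#' @param min_hours Minimum valid hours per day (default 18, i.e. 75%).
#' @return Data frame (`station_id`, `date`, `mean_no2`, `n_valid_hours`).
#' @export
daily_means <- function(hourly, min_hours = 18L) {
  date <- as.Date(hourly$timestamp, tz = "UTC")
  ok <- !is.na(hourly$no2)
  key <- interaction(hourly$station_id, date, drop = TRUE)
  n_valid <- tapply(ok, key, sum)
  mean_no2 <- tapply(ifelse(ok, hourly$no2, 0), key, sum) / pmax(n_valid, 1)
  first <- !duplicated(key)
  out <- data.frame(station_id = hourly$station_id[first],
                    date = date[first],
                    mean_no2 = as.numeric(mean_no2[match(key[first], names(n_valid))]),
                    n_valid_hours = as.integer(n_valid[match(key[first],
                                                             names(n_valid))]))
  out <- out[out$n_valid_hours >= min_hours, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$station_id, out$date), ]
}

#' Monthly station means from daily means
#'
#' A station-month is emitted only if it has at least `min_days` valid
#' daily means; `mean_no2` is the average of those daily means.
#'
#' @param daily Output of [daily_means()].
#' @param min_days Minimum valid days per month (default 20).
#' @return Data frame (`station_id`, `year`, `month`, `mean_no2`,
#'   `n_valid_days`).
#' @export
monthly_means <- function(daily, min_days = 20L) {
  yr <- as.integer(format(daily$date, "%Y"))
  mo <- as.integer(format(daily$date, "%m"))
  key <- paste(daily$station_id, yr, mo, sep = "\r")
  n_days <- tapply(rep(1L, nrow(daily)), key, sum)
  mean_no2 <- tapply(daily$mean_no2, key, mean)
  parts <- do.call(rbind, strsplit(names(n_days), "\r", fixed = TRUE))
  out <- data.frame(station_id = parts[, 1],
                    year = as.integer(parts[, 2]),
                    month = as.integer(parts[, 3]),
                    mean_no2 = as.numeric(mean_no2),
                    n_valid_days = as.integer(n_days))
  out <- out[out$n_valid_days >= min_days, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$station_id, out$year, out$month), ]
}

#' Full ground-monitor quality-control chain
#'
#' Applies, in order: the reference-state correction, stuck-run removal,
#' daily completeness filtering, and monthly completeness filtering. The
#' multiplicative correction preserves identical-run structure, so the
#' fixed order does not change which hours are flagged; it makes outputs
#' reproducible.
#'
#' @param hourly Data frame (`station_id`, `timestamp`, `no2`).
#' @param min_run,min_hours,min_days QC thresholds; defaults 8 hours,
#'   18 hours/day, 20 days/month.
#' @param correction Apply the reference-state correction (default `TRUE`).
#' @return Monthly station means as from [monthly_means()], with the
#'   flagged hourly rows attached as attribute `flagged` and the surviving
#'   daily means as attribute `daily`.
#' @export
qc_monitors <- function(hourly, min_run = 8L, min_hours = 18L,
                        min_days = 20L, correction = TRUE) {
  if (correction)
    hourly$no2 <- reference_state_correction(hourly$no2, hourly$timestamp)
  hourly <- remove_stuck_runs(hourly, min_run = min_run)
  flagged <- hourly[hourly$flagged_stuck,
                    c("station_id", "timestamp"), drop = FALSE]
  daily <- daily_means(hourly, min_hours = min_hours)
  monthly <- monthly_means(daily, min_days = min_days)
  attr(monthly, "flagged") <- flagged
  attr(monthly, "daily") <- daily
  monthly
}
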