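## Phenology: chill/heat accumulation, sequential stage prediction and the
## derivation of the three analysis traits BB_CD, BB_GDH and Delta_GDH.

#' Growing-degree-hour model parameters
#'
#' Parameters of the cosine growing-degree-hour (GDH) response: heat
#' accumulation is zero at or below the base temperature `TB`, rises along a
#' cosine to a maximum of `F * (TU - TB)` at the optimum `TU`, and falls back
#' to zero at the critical temperature `TC`.
#'
#' @param TB base temperature, degrees C (default 4).
#' @param TU optimum temperature, degrees C (default 25).
#' @param TC critical temperature, degrees C (default 36).
#' @param F stress factor scaling the response (default 1).
#' @param form `"corrected"` (default) uses the continuous cosine response;
#'   `"as_printed"` reproduces a literal transcription of the equations as
#'   commonly printed in the horticultural literature, which is negative
#'   and discontinuous at `TU` and kept only for audit.
#' @return an object of class `gdh_params`.
#' @export
gdh_params <- function(TB = 4, TU = 25, TC = 36, F = 1,
                       form = c("corrected", "as_printed")) {
  form <- match.arg(form)
  stopifnot(TB < TU, TU < TC, F > 0)
  structure(list(TB = TB, TU = TU, TC = TC, F = F, form = form),
            class = "gdh_params")
}

#' Chilling-hour model parameters
#'
#' Plain chilling hours: an hour counts when the temperature lies in
#' `(lower, upper]`. Accumulation starts at `start` (a month-day string,
#' resolved within the series, or a full date).
#'
#' @param lower lower threshold, degrees C (default 0, exclusive).
#' @param upper upper threshold, degrees C (default 7.2, inclusive).
#' @param start accumulation start: `"MM-DD"` string (default `"09-01"`) or a
#'   `Date`.
#' @return an object of class `chill_params`.
#' @export
chill_params <- function(lower = 0, upper = 7.2, start = "09-01") {
  stopifnot(lower < upper)
  structure(list(lower = lower, upper = upper, start = start),
            class = "chill_params")
}

#' Construct an hourly temperature series
#'
#' @param site site identifier.
#' @param timestamp `POSIXct` vector, strictly increasing, hourly spacing.
#' @param temp_C temperatures, degrees C.
#' @return a `data.frame` of class `temperature_series` with columns
#'   `site`, `timestamp`, `temp_C`.
#' @export
temperature_series <- function(site, timestamp, temp_C) {
  stopifnot(length(timestamp) == length(temp_C), length(timestamp) >= 1L)
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  dt <- diff(as.numeric(timestamp))
  if (length(dt) && (any(dt <= 0) || any(abs(dt - 3600) > 1e-6)))
    pedqtl_stop("pedqtl_bad_series",
                "timestamps must be strictly increasing at hourly spacing")
  structure(data.frame(site = site, timestamp = timestamp, temp_C = temp_C,
                       stringsAsFactors = FALSE),
            class = c("temperature_series", "data.frame"))
}

#' Growing degree hours for one hour
#'
#' Cosine heat-accumulation response. With the default `"corrected"` form the
#' function is 0 for `TH <= TB` or `TH >= TC`, equals
#' `F*(TU-TB)/2*(1+cos(pi + pi*(TH-TB)/(TU-TB)))` on `[TB, TU]` and
#' `F*(TU-TB)*(1+cos(pi/2 + pi/2*(TH-TU)/(TC-TU)))/... ` scaled so that it is
#' continuous at `TU` (value `F*(TU-TB)`) and zero at `TC`.
#'
#' @param TH hourly temperature(s), degrees C; vectorized.
#' @param params a [gdh_params()] object.
#' @return growing degree hours accumulated in one hour at `TH`.
#' @examples
#' gdh_hour(25)  # 21 with defaults
#' @export
gdh_hour <- function(TH, params = gdh_params()) {
  stopifnot(inherits(params, "gdh_params"), all(is.finite(TH)))
  TB <- params$TB; TU <- params$TU; TC <- params$TC; F <- params$F
  out <- numeric(length(TH))
  if (params$form == "corrected") {
    lo <- TH > TB & TH <= TU
    hi <- TH > TU & TH < TC
    out[lo] <- F * (TU - TB) / 2 *
      (1 + cos(pi + pi * (TH[lo] - TB) / (TU - TB)))
    out[hi] <- F * (TU - TB) *
      (1 + cos(pi / 2 + pi / 2 * (TH[hi] - TU) / (TC - TU)))
  } else {
    ## literal transcription: (TB-TU)/2 in branch 1, denominator (TC-TB) in
    ## branch 2; negative and discontinuous -- retained for audit only
    lo <- TH <= TU
    hi <- TH > TU
    out[lo] <- F * (TB - TU) / 2 *
      (1 + cos(pi + pi * (TH[lo] - TB) / (TU - TB)))
    out[hi] <- (TB - TU) *
      (1 + cos(pi / 2 + pi / 2 * (TH[hi] - TU) / (TC - TB)))
  }
  out
}

## locate the integer index range of a half-open window [start, end)
series_window <- function(series, start, end) {
  start <- as.POSIXct(start, tz = "UTC"); end <- as.POSIXct(end, tz = "UTC")
  ts <- series$timestamp
  if (start > end)
    pedqtl_stop("pedqtl_bad_window", "window start is after end")
  if (start < ts[1L] - 1 || end > ts[length(ts)] + 3601)
    pedqtl_stop("pedqtl_bad_window", "window [%s, %s) outside series span",
                format(start), format(end))
  which(ts >= start & ts < end)
}

#' Accumulate growing degree hours over a window
#'
#' Sums [gdh_hour()] over all hours in the half-open window `[start, end)`.
#'
#' @param series a [temperature_series()].
#' @param start,end window bounds (coerced to `POSIXct`, UTC).
#' @param params a [gdh_params()] object.
#' @return total GDH, non-negative and additive over abutting windows.
#' @export
accumulate_gdh <- function(series, start, end, params = gdh_params()) {
  idx <- series_window(series, start, end)
  if (!length(idx)) return(0)
  sum(gdh_hour(series$temp_C[idx], params))
}

#' Count chilling hours over a window
#'
#' Number of hours in `[start, end)` whose temperature lies in
#' `(lower, upper]`.
#'
#' @inheritParams accumulate_gdh
#' @param params a [chill_params()] object.
#' @return integer count of chilling hours.
#' @export
chill_hours <- function(series, start, end, params = chill_params()) {
  idx <- series_window(series, start, end)
  if (!length(idx)) return(0L)
  th <- series$temp_C[idx]
  sum(th > params$lower & th <= params$upper)
}

## resolve the chill accumulation start within a series
chill_start <- function(series, params) {
  if (inherits(params$start, "Date") || inherits(params$start, "POSIXct"))
    return(as.POSIXct(params$start, tz = "UTC"))
  md <- format(series$timestamp, "%m-%d")
  hit <- which(md == params$start & format(series$timestamp, "%H") == "00")
  if (!length(hit)) hit <- which(md == params$start)
  if (!length(hit)) series$timestamp[1L] else series$timestamp[hit[1L]]
}

#' Predict dormancy-release and flowering dates sequentially
#'
#' Sequential chilling/heat model: (i) dormancy release is predicted at the
#' first hour at which cumulative chilling hours from the accumulation start
#' reach the chilling requirement `CR`; (ii) heat accumulation starts only
#' once `CR` is fulfilled; (iii) the stage (e.g. flowering) is predicted at
#' the first hour `t` at which `accumulate_gdh(release, t) >= HR`. The two
#' phases are strictly sequential and do not overlap.
#'
#' @param CR chilling requirement, chilling hours (> 0).
#' @param HR heat requirement, growing degree hours (> 0).
#' @param series a [temperature_series()] covering one dormancy season.
#' @param chill a [chill_params()] object.
#' @param gdh a [gdh_params()] object.
#' @return list with `release` and `flowering` (`POSIXct`), their `Date`
#'   counterparts, and `achieved_HR`, the cumulative GDH at the predicted
#'   stage hour (the first grid value at or above `HR`).
#' @export
predict_stage_dates <- function(CR, HR, series, chill = chill_params(),
                                gdh = gdh_params()) {
  stopifnot(CR > 0, HR > 0)
  ts <- series$timestamp
  t0 <- chill_start(series, chill)
  on <- ts >= t0
  th <- series$temp_C
  cum_chill <- cumsum(on & th > chill$lower & th <= chill$upper)
  i_rel <- which(cum_chill >= CR)[1L]
  if (is.na(i_rel))
    pedqtl_stop("pedqtl_unfulfilled",
                "chilling requirement %.0f not reached before series end", CR)
  g <- gdh_hour(th, gdh)
  ## stage at the first hour whose cumulative GDH from release (that hour
  ## included) fulfills HR; in the HR -> 0 limit the stage collapses onto
  ## the release hour
  cum_g <- cumsum(g * (seq_along(ts) >= i_rel))
  i_fl <- which(cum_g >= HR & seq_along(ts) >= i_rel)[1L]
  if (is.na(i_fl))
    pedqtl_stop("pedqtl_unfulfilled",
                "heat requirement %.0f not reached before series end", HR)
  list(release = ts[i_rel], flowering = ts[i_fl],
       release_date = as.Date(ts[i_rel], tz = "UTC"),
       flowering_date = as.Date(ts[i_fl], tz = "UTC"),
       achieved_HR = cum_g[i_fl])
}

#' Interpolate hourly temperatures from daily minima and maxima
#'
#' Half-sine day scheme: the daily minimum is placed at 05:00 and the maximum
#' at 14:00 with a quarter-sine rise in between; from 14:00 the temperature
#' decays linearly to the next day's minimum at 05:00. Daily extremes are
#' preserved exactly.
#'
#' @param daily `data.frame` with columns `site`, `date` (consecutive days),
#'   `tmin`, `tmax`.
#' @return a [temperature_series()] with 24 values per day.
#' @export
hourly_from_daily <- function(daily) {
  stopifnot(all(c("site", "date", "tmin", "tmax") %in% names(daily)))
  daily$date <- as.Date(daily$date)
  if (nrow(daily) > 1L && any(diff(daily$date) != 1))
    pedqtl_stop("pedqtl_missing_day", "daily series has missing days")
  if (any(daily$tmin > daily$tmax))
    pedqtl_stop("pedqtl_bad_series", "tmin exceeds tmax on some day")
  n <- nrow(daily)
  temp <- numeric(24 * n)
  for (d in seq_len(n)) {
    h <- 0:23
    v <- numeric(24)
    tmin <- daily$tmin[d]; tmax <- daily$tmax[d]
    tmin_next <- if (d < n) daily$tmin[d + 1L] else tmin
    ## 05:00 -> 14:00 quarter-sine rise
    rise <- h >= 5 & h <= 14
    v[rise] <- tmin + (tmax - tmin) * sin(pi / 2 * (h[rise] - 5) / 9)
    ## 14:00 -> next day's 05:00 linear decay (slots 15..23 here, 0..4 next)
    v[h > 14] <- tmax + (tmin_next - tmax) * (h[h > 14] - 14) / 15
    if (d == 1L) {
      v[h < 5] <- tmin
    } else {
      tmax_prev <- daily$tmax[d - 1L]
      v[h < 5] <- tmax_prev + (tmin - tmax_prev) * (h[h < 5] + 10) / 15
    }
    temp[(d - 1L) * 24 + 1:24] <- v
  }
  ts0 <- as.POSIXct(paste(daily$date[1L], "00:00:00"), tz = "UTC")
  temperature_series(daily$site[1L], ts0 + 3600 * (seq_len(24 * n) - 1L), temp)
}

#' Derive the analysis traits from observed stage dates
#'
#' For each tree-level observation, computes `BB_CD`, the budbreak date in
#' calendar days counted from 1 January (Jan 1 = 1); `BB_GDH`, the growing
#' degree hours accumulated between the site-year reference dormancy-release
#' date and the observed budbreak date; and `Delta_GDH`, the GDH accumulated
#' between budbreak and the beginning of flowering. The flowering date itself
#' is not carried forward as a trait.
#'
#' @param observations `data.frame` with columns `tree`, `genotype`, `site`,
#'   `year`, `budbreak_date`, `flowering_date` (`Date` or ISO-8601 strings).
#' @param reference_release `data.frame` with columns `site`, `year`,
#'   `release_date`: the reference cultivar's dormancy-release date per
#'   site-year.
#' @param series named list of [temperature_series()], one per site, each
#'   covering all site-years observed.
#' @param gdh a [gdh_params()] object.
#' @return a `data.frame` of class `trait_table` with columns `tree`,
#'   `genotype`, `site`, `year`, `BB_CD`, `BB_GDH`, `Delta_GDH` and a logical
#'   `bb_before_release` flag (budbreak observed before the reference
#'   release; `BB_GDH` is reported as 0 there, with a warning).
#' @export
derive_traits <- function(observations, reference_release, series,
                          gdh = gdh_params()) {
  obs <- observations
  need <- c("tree", "genotype", "site", "year", "budbreak_date",
            "flowering_date")
  stopifnot(all(need %in% names(obs)))
  obs$budbreak_date <- as.Date(obs$budbreak_date)
  obs$flowering_date <- as.Date(obs$flowering_date)
  key <- paste(reference_release$site, reference_release$year)
  rel <- setNames(as.Date(reference_release$release_date), key)
  n <- nrow(obs)
  BB_CD <- as.integer(format(obs$budbreak_date, "%j"))
  BB_GDH <- Delta_GDH <- numeric(n)
  flag <- logical(n)
  for (i in seq_len(n)) {
    sy <- paste(obs$site[i], obs$year[i])
    if (!sy %in% names(rel))
      pedqtl_stop("pedqtl_missing_reference",
                  "no reference release date for site-year %s", sy)
    sser <- series[[as.character(obs$site[i])]]
    if (is.null(sser))
      pedqtl_stop("pedqtl_missing_series", "no series for site %s",
                  obs$site[i])
    bb <- as.POSIXct(obs$budbreak_date[i], tz = "UTC")
    fl <- as.POSIXct(obs$flowering_date[i], tz = "UTC")
    r0 <- as.POSIXct(rel[[sy]], tz = "UTC")
    if (bb < r0) {
      flag[i] <- TRUE
      BB_GDH[i] <- 0
    } else {
      BB_GDH[i] <- accumulate_gdh(sser, r0, bb, gdh)
    }
    Delta_GDH[i] <- accumulate_gdh(sser, bb, fl, gdh)
  }
  if (any(flag))
    warning(sum(flag), " observation(s) with budbreak before the reference ",
            "release date; BB_GDH reported as 0 there")
  structure(data.frame(tree = obs$tree, genotype = obs$genotype,
                       site = obs$site, year = obs$year, BB_CD = BB_CD,
                       BB_GDH = BB_GDH, Delta_GDH = Delta_GDH,
                       bb_before_release = flag, stringsAsFactors = FALSE),
            class = c("trait_table", "data.frame"))
}
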