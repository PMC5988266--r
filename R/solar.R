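# Solar geometry (NOAA low-accuracy formulae), twilight detection from
# 10-min light logs, known-site calibration and threshold positioning.

#' Polar sentinels for day length
#'
#' `POLAR_DAY` (`Inf`) marks a latitude/date where the sun never reaches
#' the twilight zenith (continuous light); `POLAR_NIGHT` (`-Inf`) marks
#' continuous darkness with respect to that zenith.
#' @export
POLAR_DAY <- Inf

#' @rdname POLAR_DAY
#' @export
POLAR_NIGHT <- -Inf

#' Solar ephemeris (declination and equation of time)
#'
#' NOAA low-accuracy solar formulae, accurate to well under 0.1 degrees
#' over 1950--2050 — ample for a 10-minute light-sampling cadence.
#'
#' @param time POSIXct (UTC).
#' @return A list with `declination` (degrees) and `eqtime` (equation
#'   of time, minutes; positive when the true sun is ahead of the mean
#'   sun).
#' @export
solar_ephemeris <- function(time) {
  jd <- as.numeric(time) / 86400 + 2440587.5
  jc <- (jd - 2451545) / 36525
  gmls <- (280.46646 + jc * (36000.76983 + 0.0003032 * jc)) %% 360
  gmas <- 357.52911 + jc * (35999.05029 - 0.0001537 * jc)
  eeo <- 0.016708634 - jc * (0.000042037 + 0.0000001267 * jc)
  seqc <- sin(.deg2rad(gmas)) * (1.914602 - jc * (0.004817 + 0.000014 * jc)) +
    sin(.deg2rad(2 * gmas)) * (0.019993 - 0.000101 * jc) +
    sin(.deg2rad(3 * gmas)) * 0.000289
  stl <- gmls + seqc
  sal <- stl - 0.00569 - 0.00478 * sin(.deg2rad(125.04 - 1934.136 * jc))
  moe <- 23 + (26 + (21.448 - jc * (46.815 + jc * (0.00059 - jc * 0.001813))) / 60) / 60
  oc <- moe + 0.00256 * cos(.deg2rad(125.04 - 1934.136 * jc))
  declination <- .rad2deg(asin(sin(.deg2rad(oc)) * sin(.deg2rad(sal))))
  vary <- tan(.deg2rad(oc / 2))^2
  eqtime <- 4 * .rad2deg(
    vary * sin(2 * .deg2rad(gmls)) - 2 * eeo * sin(.deg2rad(gmas)) +
      4 * eeo * vary * sin(.deg2rad(gmas)) * cos(2 * .deg2rad(gmls)) -
      0.5 * vary^2 * sin(4 * .deg2rad(gmls)) -
      1.25 * eeo^2 * sin(2 * .deg2rad(gmas)))
  list(declination = declination, eqtime = eqtime)
}

#' Solar zenith angle
#'
#' @param time POSIXct (UTC), recycled with `lon`/`lat`.
#' @param lon,lat Position in decimal degrees.
#' @return Zenith angle in degrees (0 = overhead, 90 = horizon).
#' @export
solar_position <- function(time, lon, lat) {
  eph <- solar_ephemeris(time)
  mins <- (as.numeric(time) / 60) %% 1440
  tst <- (mins + eph$eqtime + 4 * lon) %% 1440
  ha <- tst / 4 - 180
  cz <- sin(.deg2rad(lat)) * sin(.deg2rad(eph$declination)) +
    cos(.deg2rad(lat)) * cos(.deg2rad(eph$declination)) * cos(.deg2rad(ha))
  .rad2deg(acos(pmin(1, pmax(-1, cz))))
}

#' Day length from the sunrise equation
#'
#' Solves cos(H) = (cos z - sin(lat) sin(dec)) / (cos(lat) cos(dec)) and
#' returns 2H expressed in hours; [POLAR_DAY] or [POLAR_NIGHT] when the
#' cosine argument leaves \[-1, 1\].
#'
#' @param lat Latitude, degrees.
#' @param declination Solar declination, degrees.
#' @param zenith_deg Twilight zenith angle defining "day", degrees.
#' @return Hours between the two zenith crossings, or a polar sentinel.
#' @export
daylength <- function(lat, declination, zenith_deg = 90) {
  num <- cos(.deg2rad(zenith_deg)) -
    sin(.deg2rad(lat)) * sin(.deg2rad(declination))
  den <- cos(.deg2rad(lat)) * cos(.deg2rad(declination))
  arg <- num / den
  out <- rep(NA_real_, length(arg))
  out[!is.na(arg) & arg < -1] <- POLAR_DAY
  out[!is.na(arg) & arg > 1] <- POLAR_NIGHT
  ok <- !is.na(arg) & arg >= -1 & arg <= 1
  out[ok] <- 2 * .rad2deg(acos(arg[ok])) / 15
  out
}

#' Predicted twilight time at a location
#'
#' Time on the civil (UTC) day of `day` at which the sun crosses
#' `zenith_deg` at (`lon`, `lat`), rising or setting. One ephemeris
#' refinement step is applied at the first-guess event time.
#'
#' @param day POSIXct or Date giving the civil day (UTC).
#' @param lon,lat Position in decimal degrees.
#' @param zenith_deg Twilight zenith angle, degrees.
#' @param rise Logical; `TRUE` for the morning crossing.
#' @return POSIXct event time (UTC); `NA` during polar day/night.
#' @export
predict_twilight <- function(day, lon, lat, zenith_deg, rise) {
  day0 <- as.POSIXct(trunc(as.POSIXct(day, tz = "UTC"), "days"), tz = "UTC")
  n <- max(length(day0), length(lon), length(lat), length(rise))
  day0 <- rep_len(day0, n)
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  sgn <- ifelse(rep_len(rise, n), -1, 1)
  guess <- day0 + 12 * 3600
  for (pass in 1:2) {
    eph <- solar_ephemeris(guess)
    half <- daylength(lat, eph$declination, zenith_deg) / 2
    noon_min <- 720 - 4 * lon - eph$eqtime
    ev_min <- noon_min + sgn * 60 * half
    ev_min[!is.finite(half)] <- NA_real_
    guess <- day0 + ev_min * 60
  }
  guess
}

#' Detect twilights in a 10-minute light log
#'
#' Classifies each record as light or dark against `threshold`, finds
#' the dark/light transitions, and linearly interpolates the crossing
#' time between the two bracketing windows. Short anomalous runs — a
#' dark spell embedded in the bright span of a day (sensor shading by a
#' hauled-out animal) or a bright blip at night — are flagged
#' `suspect_shading` and excluded from the `ok` twilights.
#'
#' @param lights data.frame with POSIXct `time` (UTC, window start) and
#'   numeric `light`, time-sorted on a regular 10-min cadence (gaps
#'   allowed).
#' @param threshold Light level defining twilight.
#' @param min_run_hours Minimum duration for a dark (or bright) run to
#'   count as genuine night (or day) rather than an artefact.
#' @param window_min Aggregation window length, minutes. Because each
#'   record is the *maximum* over the window starting at its timestamp,
#'   a rising light curve is represented by its value near the end of
#'   the window while a falling one is represented near the start;
#'   rise-crossing brackets are therefore shifted by `window_min` so
#'   sunrise and sunset are estimated without systematic offset.
#' @return data.frame with columns `time` (POSIXct), `rise` (logical)
#'   and `quality` (`"ok"` or `"suspect_shading"`).
#' @export
detect_twilights <- function(lights, threshold, min_run_hours = 4,
                             window_min = 10) {
  stopifnot(is.data.frame(lights), all(c("time", "light") %in% names(lights)))
  if (is.unsorted(as.numeric(lights$time), strictly = FALSE))
    stop("light records must be sorted by time")
  n <- nrow(lights)
  bright <- lights$light > threshold
  if (n < 2 || all(bright) || all(!bright)) {
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      rise = logical(), quality = character()))
  }
  r <- rle(bright)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  run_dur <- (as.numeric(lights$time[ends]) -
                as.numeric(lights$time[starts])) / 3600 + 1 / 6
  # interior runs shorter than min_run_hours are artefacts
  genuine <- run_dur >= min_run_hours
  genuine[c(1L, length(genuine))] <- TRUE  # edge runs kept as-is
  cross <- list()
  for (k in seq_len(length(r$lengths) - 1L)) {
    i <- ends[k]; j <- starts[k + 1L]
    l1 <- lights$light[i]; l2 <- lights$light[j]
    f <- if (l2 != l1) (threshold - l1) / (l2 - l1) else 0.5
    f <- min(1, max(0, f))
    is_rise <- r$values[k + 1L]  # transitioning into a bright run
    tc <- lights$time[i] + f * (as.numeric(lights$time[j]) -
                                  as.numeric(lights$time[i]))
    if (is_rise) tc <- tc + window_min * 60
    suspect <- !genuine[k] || !genuine[k + 1L]
    cross[[k]] <- data.frame(time = tc, rise = is_rise,
                             quality = if (suspect) "suspect_shading" else "ok")
  }
  out <- do.call(rbind, cross)
  attr(out, "n_suspect") <- sum(out$quality != "ok")
  out
}

#' Calibrate twilight zenith and light threshold at a known site
#'
#' Grid search over candidate zenith angles and light thresholds,
#' choosing the pair that minimises the root-mean-square discrepancy
#' between twilight times detected in the log and those predicted at
#' the known location.
#'
#' @param lights data.frame(`time`, `light`) from a logger fixed at a
#'   known site for at least 14 days.
#' @param known_lonlat Numeric length-2, c(lon, lat) degrees.
#' @param candidate_zeniths Zenith grid (degrees).
#' @param candidate_thresholds Threshold grid (light units).
#' @param min_run_hours Passed to [detect_twilights()].
#' @return A list of class `gls_calibration`: `zenith_deg`,
#'   `light_threshold`, `residual_spread` (RMS, minutes), and the full
#'   score grid.
#' @export
calibrate <- function(lights, known_lonlat,
                      candidate_zeniths = seq(88, 102, by = 0.25),
                      candidate_thresholds = 2:20,
                      min_run_hours = 4) {
  span_d <- diff(range(as.numeric(lights$time))) / 86400
  if (span_d < 14) stop("calibration requires at least 14 days of records")
  lon <- known_lonlat[1]; lat <- known_lonlat[2]
  best <- NULL
  scores <- matrix(NA_real_, length(candidate_thresholds),
                   length(candidate_zeniths),
                   dimnames = list(candidate_thresholds, candidate_zeniths))
  for (ti in seq_along(candidate_thresholds)) {
    tw <- detect_twilights(lights, candidate_thresholds[ti], min_run_hours)
    tw <- tw[tw$quality == "ok", , drop = FALSE]
    if (nrow(tw) < 4) next
    for (zi in seq_along(candidate_zeniths)) {
      pred <- predict_twilight(tw$time, lon, lat,
                               candidate_zeniths[zi], tw$rise)
      resid <- (as.numeric(tw$time) - as.numeric(pred)) / 60
      resid <- resid[is.finite(resid)]
      if (length(resid) < 4) next
      scores[ti, zi] <- sqrt(mean(resid^2))
    }
  }
  if (all(is.na(scores)))
    stop("calibration failed: no candidate produced usable twilights")
  ij <- which(scores == min(scores, na.rm = TRUE), arr.ind = TRUE)[1, ]
  structure(list(zenith_deg = candidate_zeniths[ij[2]],
                 light_threshold = candidate_thresholds[ij[1]],
                 residual_spread = scores[ij[1], ij[2]],
                 scores = scores),
            class = "gls_calibration")
}

#' @export
print.gls_calibration <- function(x, ...) {
  cat(sprintf(
    "GLS calibration: zenith %.2f deg, threshold %g, residual RMS %.1f min\n",
    x$zenith_deg, x$light_threshold, x$residual_spread))
  invisible(x)
}

#' Threshold-method position from one twilight pair
#'
#' Longitude from the midpoint of sunrise and sunset relative to solar
#' noon; latitude from the day length via the sunrise equation at the
#' mid-date declination. Within the equinox window (|declination| <
#' 4 degrees, about ten days either side of an equinox) day length is
#' nearly independent of latitude and the result is flagged.
#'
#' @param rise,set POSIXct twilight times (UTC); `rise` must precede
#'   `set` by less than 24 h.
#' @param zenith_deg Calibrated twilight zenith angle, degrees.
#' @param ref_lat Optional reference latitude. The sunrise equation can
#'   admit two latitude branches that reproduce the day length almost
#'   equally well near the equinoxes; when `ref_lat` is supplied the
#'   branch closer to it is taken (hemisphere disambiguation), otherwise
#'   the branch with the smaller day-length error wins.
#' @return list(`lon`, `lat`, `lat_quality`) with `lat_quality` one of
#'   `"ok"`, `"equinox_degenerate"`; `lat` is `NA` when the day length
#'   admits no solution at this zenith.
#' @export
threshold_position <- function(rise, set, zenith_deg, ref_lat = NULL) {
  rise <- as.POSIXct(rise, tz = "UTC"); set <- as.POSIXct(set, tz = "UTC")
  dt_s <- as.numeric(set) - as.numeric(rise)
  if (!is.finite(dt_s) || dt_s <= 0 || dt_s >= 86400)
    stop("rise must precede set within 24 h")
  tmid <- rise + dt_s / 2
  eph <- solar_ephemeris(tmid)
  mins <- (as.numeric(tmid) / 60) %% 1440
  lon <- wrap_lon((720 - eph$eqtime - mins) / 4)
  half_deg <- (dt_s / 3600) / 2 * 15  # half day length as hour angle, degrees
  # solve sin(lat) sin(dec) + cos(lat) cos(dec) cos(H) = cos(z) for lat
  A <- sin(.deg2rad(eph$declination))
  B <- cos(.deg2rad(eph$declination)) * cos(.deg2rad(half_deg))
  Rm <- sqrt(A^2 + B^2)
  c0 <- cos(.deg2rad(zenith_deg))
  if (abs(c0) > Rm) {
    lat <- NA_real_
  } else {
    alpha <- atan2(B, A)
    cand <- .rad2deg(c(asin(c0 / Rm) - alpha, pi - asin(c0 / Rm) - alpha))
    cand <- wrap_lon(cand)  # map into (-180, 180); latitudes must be in [-90, 90]
    cand <- cand[cand >= -90 & cand <= 90]
    if (!length(cand)) {
      lat <- NA_real_
    } else if (!is.null(ref_lat) && length(cand) > 1) {
      lat <- cand[which.min(abs(cand - ref_lat))]
    } else {
      err <- abs(daylength(cand, eph$declination, zenith_deg) - dt_s / 3600)
      lat <- cand[which.min(err)]
    }
  }
  quality <- if (abs(eph$declination) < 4) "equinox_degenerate" else "ok"
  list(lon = lon, lat = lat, lat_quality = quality)
}
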