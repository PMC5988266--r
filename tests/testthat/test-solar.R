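# Independent ephemeris oracle (Astronomical Almanac low-precision
# algorithm), coded from different formulae than the package's NOAA
# implementation.
almanac_zenith <- function(time, lon, lat) {
  rad <- pi / 180
  n <- as.numeric(time) / 86400 - 10957.5      # days from J2000.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- L + 1.915 * sin(g * rad) + 0.020 * sin(2 * g * rad)
  eps <- 23.439 - 0.0000004 * n
  alpha <- atan2(cos(eps * rad) * sin(lam * rad), cos(lam * rad)) / rad
  delta <- asin(sin(eps * rad) * sin(lam * rad)) / rad
  hour <- (as.numeric(time) %% 86400) / 3600
  gmst <- (6.697375 + 0.0657098242 * n + hour) %% 24
  lmst <- (gmst + lon / 15) %% 24
  ha <- (lmst * 15 - alpha) %% 360
  ha[ha > 180] <- ha[ha > 180] - 360
  cz <- sin(lat * rad) * sin(delta * rad) +
    cos(lat * rad) * cos(delta * rad) * cos(ha * rad)
  acos(pmin(1, pmax(-1, cz))) / rad
}

test_that("solar position matches an independent ephemeris to 0.2 degrees", {
  # subsolar point at an equinox noon
  z <- solar_position(as.POSIXct("2013-03-20 12:00:00", tz = "UTC"), 0, 0)
  expect_lt(z, 3)  # equation-of-time and declination slack
  # local solar midnight at mid-latitudes is dark
  z_mid <- solar_position(as.POSIXct("2012-08-15 02:32:00", tz = "UTC"),
                          -38.05, -54.01)  # ~solar midnight at 38 W
  expect_gt(z_mid, 90)
  set.seed(1)
  times <- as.POSIXct("2000-01-01", tz = "UTC") +
    runif(100, 0, 20 * 365.25 * 86400)
  lon <- runif(100, -180, 180); lat <- runif(100, -85, 85)
  dz <- abs(solar_position(times, lon, lat) - almanac_zenith(times, lon, lat))
  expect_lt(max(dz), 0.2)
})

test_that("day length follows the sunrise equation and its sentinels", {
  # equator: 12 h for any declination at the geometric horizon
  for (dec in c(-23, -10, 0, 17)) {
    expect_equal(daylength(0, dec, 90), 12, tolerance = 1e-9)
  }
  expect_identical(daylength(-80, -20, 90), POLAR_DAY)
  expect_identical(daylength(80, -20, 90), POLAR_NIGHT)
  # closed form vs brute-force zenith scan over the day
  brute_daylength <- function(lat, day, zen) {
    tt <- as.POSIXct(day, tz = "UTC") + seq(0, 86399, by = 30)
    below <- solar_position(tt, 0, lat) < zen
    sum(below) * 30 / 3600
  }
  grid <- expand.grid(lat = c(-65, -54.01, -30, 0, 40, 60),
                      day = c("2012-12-21", "2013-02-10", "2013-06-21",
                              "2013-09-01"))
  for (k in seq_len(nrow(grid))) {
    day <- as.POSIXct(paste(grid$day[k], "12:00:00"), tz = "UTC")
    eph <- solar_ephemeris(day)
    dl <- daylength(grid$lat[k], eph$declination, 96)
    if (!is.finite(dl)) next
    bf <- brute_daylength(grid$lat[k], grid$day[k], 96)
    expect_lt(abs(dl - bf), 1 / 60,
              label = sprintf("daylength lat %.2f %s", grid$lat[k],
                              grid$day[k]))
  }
  # the deployment-latitude winter case against the brute-force scan
  eph <- solar_ephemeris(as.POSIXct("2013-01-10 12:00:00", tz = "UTC"))
  expect_lt(abs(eph$declination - -22), 1.5)
  dl <- daylength(-54.01, -20, 96)
  tt <- as.POSIXct("2013-01-10", tz = "UTC") + seq(0, 86399, by = 20)
  # brute force at fixed declination -20: minimise |zenith - 96| directly
  ha <- seq(0, 180, by = 0.001)
  cz <- sin(-54.01 * pi / 180) * sin(-20 * pi / 180) +
    cos(-54.01 * pi / 180) * cos(-20 * pi / 180) * cos(ha * pi / 180)
  h_star <- ha[which.min(abs(acos(cz) * 180 / pi - 96))]
  expect_lt(abs(dl - 2 * h_star / 15), 1 / 60)
})

test_that("twilight detection recovers truth and flags shading", {
  tr <- stationary_track("2013-05-01", "2013-05-31")
  lt <- render_light(tr, zenith_deg = 96, threshold = 10)
  tw <- detect_twilights(lt, 10)
  ok <- tw[tw$quality == "ok", ]
  expect_equal(nrow(ok), 60)  # 30 days, one rise and one set each
  expect_true(all(ok$rise == rep(c(TRUE, FALSE), 30) |
                    ok$rise == rep(c(FALSE, TRUE), 30)))
  days <- as.Date(trunc(ok$time, "days"))
  pred_r <- predict_twilight(unique(days), BIRD_ISLAND[1], BIRD_ISLAND[2],
                             96, TRUE)
  pred_s <- predict_twilight(unique(days), BIRD_ISLAND[1], BIRD_ISLAND[2],
                             96, FALSE)
  truth <- sort(c(as.numeric(pred_r), as.numeric(pred_s)))
  obs <- sort(as.numeric(ok$time))
  expect_lt(max(abs(obs - truth)) / 60, 10)  # within one sampling window

  # constant bright light (polar day): no twilights
  lt_const <- data.frame(time = lt$time, light = 60)
  expect_equal(nrow(detect_twilights(lt_const, 10)), 0)

  # a 30-min midday shading bout is flagged, not emitted as twilight
  noon <- as.POSIXct("2013-05-10 14:30:00", tz = "UTC")
  shading <- data.frame(start = noon, end = noon + 1800)
  lt_sh <- render_light(tr, 96, 10, shading_bouts = shading)
  tw_sh <- detect_twilights(lt_sh, 10)
  expect_gt(sum(tw_sh$quality == "suspect_shading"), 0)
  expect_equal(nrow(tw_sh[tw_sh$quality == "ok", ]), 60)

  # unsorted input is rejected
  expect_error(detect_twilights(lt[c(2, 1, 3:nrow(lt)), ], 10), "sorted")
})

test_that("calibration recovers a photometrically consistent pair", {
  tr <- stationary_track("2013-05-01", "2013-05-31")
  lt <- render_light(tr, zenith_deg = 96, threshold = 10)
  cal <- calibrate(lt, BIRD_ISLAND)
  expect_s3_class(cal, "gls_calibration")
  expect_lt(cal$residual_spread, 5)
  # the recovered (zenith, threshold) pair must predict the generating
  # pair's twilights: the pairs are photometrically equivalent even
  # when they differ numerically (transfer-curve ridge)
  days <- seq(as.Date("2013-05-02"), as.Date("2013-05-29"), by = 1)
  t_gen <- predict_twilight(days, BIRD_ISLAND[1], BIRD_ISLAND[2], 96, TRUE)
  t_rec <- predict_twilight(days, BIRD_ISLAND[1], BIRD_ISLAND[2],
                            cal$zenith_deg, TRUE)
  tw <- detect_twilights(lt, cal$light_threshold)
  tw <- tw[tw$quality == "ok" & tw$rise, ]
  # recovered pair's detected dawns sit within 2 min of its predictions
  m <- match(as.Date(trunc(tw$time, "days")), days)
  resid <- (as.numeric(tw$time) - as.numeric(t_rec[m])) / 60
  expect_lt(stats::median(abs(resid), na.rm = TRUE), 2)
  # calibration window requirement and polar-day failure
  expect_error(calibrate(lt[1:(10 * 144), ], BIRD_ISLAND), "14 days")
  lt_polar <- data.frame(time = lt$time, light = 64)
  expect_error(calibrate(lt_polar, BIRD_ISLAND), "calibration failed")
})

test_that("threshold positioning recovers the site and flags the equinox", {
  # twilights symmetric about 12:00 UTC imply longitude ~ 0
  rise <- as.POSIXct("2013-05-10 07:00:00", tz = "UTC")
  set <- as.POSIXct("2013-05-10 17:00:00", tz = "UTC")
  pos <- threshold_position(rise, set, 96)
  expect_lt(abs(pos$lon), 1.2)  # equation-of-time slack
  # a noiseless month at the deployment site recovers its coordinates
  tr <- stationary_track("2013-05-01", "2013-05-31")
  lt <- render_light(tr, 96, 10)
  cal <- calibrate(lt, BIRD_ISLAND)
  tw <- detect_twilights(lt, cal$light_threshold)
  tw <- tw[tw$quality == "ok", ]
  days <- as.Date(trunc(tw$time, "days"))
  est <- t(vapply(unique(days), function(d) {
    r <- tw$time[days == d & tw$rise][1]
    s <- tw$time[days == d & !tw$rise][1]
    if (is.na(r) || is.na(s) || r >= s) return(c(NA_real_, NA_real_))
    p <- threshold_position(r, s, cal$zenith_deg)
    c(p$lon, p$lat)
  }, numeric(2)))
  expect_lt(abs(stats::median(est[, 1], na.rm = TRUE) - BIRD_ISLAND[1]), 0.25)
  expect_lt(abs(stats::median(est[, 2], na.rm = TRUE) - BIRD_ISLAND[2]), 0.5)
  # near-equinox day length is degenerate in latitude
  r_eq <- as.POSIXct("2013-03-21 06:00:00", tz = "UTC")
  s_eq <- as.POSIXct("2013-03-21 18:00:00", tz = "UTC")
  expect_equal(threshold_position(r_eq, s_eq, 90)$lat_quality,
               "equinox_degenerate")
  expect_error(threshold_position(set, rise, 96), "precede")
})
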