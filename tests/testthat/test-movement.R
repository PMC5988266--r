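test_that("speed prior has the stated moments, mode and scaling", {
  pr <- movement_prior(1, 0.9)
  # Monte-Carlo mean of speeds sampled from the prior: 1.0 +/- 3 SE
  set.seed(41)
  s <- rlnorm(1e5, pr$meanlog, pr$sdlog)
  expect_lt(abs(mean(s) - 1), 3 * 0.9 / sqrt(1e5))
  expect_lt(abs(sd(s) - 0.9), 0.02)
  # density is maximal at the distribution mode over distances at fixed dt
  mode <- exp(pr$meanlog - pr$sdlog^2)
  d_mode <- mode * 12  # km over 12 h
  p0 <- destination_point(-38, -54, 90, d_mode)
  lp_mode <- speed_log_prior(c(-38, -54), c(p0$lon, p0$lat), 12, pr)
  for (f in c(0.5, 0.8, 1.25, 2)) {
    pf <- destination_point(-38, -54, 90, d_mode * f)
    expect_lt(speed_log_prior(c(-38, -54), c(pf$lon, pf$lat), 12, pr),
              lp_mode)
  }
  # doubling dt at fixed distance halves the implied speed: the density
  # change matches direct recomputation from the log-normal
  p1 <- destination_point(-38, -54, 90, 24)
  lp12 <- speed_log_prior(c(-38, -54), c(p1$lon, p1$lat), 12, pr)
  lp24 <- speed_log_prior(c(-38, -54), c(p1$lon, p1$lat), 24, pr)
  expect_equal(lp24 - lp12,
               dlnorm(1, pr$meanlog, pr$sdlog, log = TRUE) -
                 dlnorm(2, pr$meanlog, pr$sdlog, log = TRUE),
               tolerance = 1e-6)
})

test_that("twilight likelihood is a proper density with the right support", {
  err <- twilight_error_model()
  day <- as.POSIXct("2012-08-10", tz = "UTC")
  pred <- predict_twilight(day, -38.05, -54.01, 96, TRUE)
  # numeric quadrature over observed time: integrates to 1
  offs <- seq(-err$shift + 1e-4, 120, by = 0.01)  # minutes around pred
  dens <- vapply(offs, function(o) {
    tw <- data.frame(time = pred + o * 60, rise = TRUE)
    exp(twilight_log_likelihood(tw, -38.05, -54.01, err, zenith_deg = 96))
  }, 0)
  expect_equal(sum(dens) * 0.01, 1, tolerance = 3e-3)
  # the mode sits at the error law's mode over observed-time offsets
  mode_x <- exp(log(err$scale) - err$sdlog^2)
  expect_equal(offs[which.max(dens)], mode_x - err$shift, tolerance = 0.1)
  # polar day at the location and date: impossible geometry
  tw <- data.frame(time = as.POSIXct("2013-01-05 10:00:00", tz = "UTC"),
                   rise = TRUE)
  expect_identical(
    twilight_log_likelihood(tw, 0, -75, err, zenith_deg = 96), -Inf)
  # but the sampler's soft variant is finite and decreasing poleward
  s1 <- twilight_log_likelihood(tw, 0, -72, err, zenith_deg = 96,
                                soft = TRUE)
  s2 <- twilight_log_likelihood(tw, 0, -80, err, zenith_deg = 96,
                                soft = TRUE)
  expect_true(is.finite(s1) && is.finite(s2) && s2 < s1)
})

test_that("initial path honours fixes and is always feasible", {
  fx <- residency_fixture(n_steps = 60, seed = 17)
  ip <- initial_path(fx$twilights, fx$fixes, movement_prior(), 96)
  expect_equal(nrow(ip), nrow(fx$twilights))
  # fixed twilights take the fix coordinates exactly
  expect_true(all(abs(ip$lon[ip$fixed] - fx$fixes$lon[1]) < 1e-9 |
                    abs(ip$lon[ip$fixed] - fx$fixes$lon[2]) < 1e-9))
  # finite posterior density everywhere under the soft likelihood
  ll <- twilight_log_likelihood(
    prepare_twilights(fx$twilights, 96), ip$lon, ip$lat, fx$err,
    soft = TRUE)
  expect_true(all(is.finite(ll)))
  # noiseless stationary record: within 1 degree of truth throughout
  tr <- stationary_track("2013-05-01", "2013-05-31")
  tw0 <- render_twilights(tr, 96, err = NULL)
  ip0 <- initial_path(tw0, NULL, movement_prior(), 96)
  expect_lt(max(abs(ip0$lon - BIRD_ISLAND[1])), 1)
  expect_lt(max(abs(ip0$lat - BIRD_ISLAND[2])), 1)
  expect_error(initial_path(tw0[0, ], NULL), "at least")
})

test_that("fully fixed days reproduce the fixes in every sample", {
  tr <- stationary_track("2012-08-01", "2012-08-10")
  tw <- render_twilights(tr, 96, err = twilight_error_model(), seed = 3)
  days <- unique(as.Date(trunc(tw$time, "days")))
  fixes <- data.frame(time = as.POSIXct(paste(days, "12:00:00"), tz = "UTC"),
                      lon = BIRD_ISLAND[1], lat = BIRD_ISLAND[2])
  ch <- sample_posterior(tw, fixes, n_chains = 2, n_iter = 200, seed = 1)
  for (cc in ch$chains) {
    expect_true(all(cc$lon == BIRD_ISLAND[1]))
    expect_true(all(cc$lat == BIRD_ISLAND[2]))
  }
})

test_that("chains are deterministic under a fixed seed", {
  fx <- residency_fixture(n_steps = 30, seed = 19)
  a <- sample_posterior(fx$twilights, fx$fixes, n_chains = 2, n_iter = 300,
                        seed = 9)
  b <- sample_posterior(fx$twilights, fx$fixes, n_chains = 2, n_iter = 300,
                        seed = 9)
  expect_identical(a$chains, b$chains)
  c2 <- sample_posterior(fx$twilights, fx$fixes, n_chains = 2, n_iter = 300,
                         seed = 10)
  expect_false(identical(a$chains, c2$chains))
})

test_that("MCMC marginal matches the brute-force grid posterior", {
  # collapsible case: one free location between two fixes, its twilight
  # likelihood plus the movement terms to both neighbours
  d1 <- as.POSIXct("2012-08-10", tz = "UTC")
  tws <- predict_twilight(c(d1, d1 + 86400, d1 + 2 * 86400),
                          c(-38, -38.3, -38.6), c(-54, -54.2, -54.4),
                          96, TRUE)
  tw <- data.frame(time = tws + c(0, 6 * 60, 0), rise = TRUE)
  fixes <- data.frame(time = tw$time[c(1, 3)],
                      lon = c(-38, -38.6), lat = c(-54, -54.4))
  ch <- sample_posterior(tw, fixes, n_chains = 4, n_iter = 6000, seed = 2)
  smp_lon <- unlist(lapply(ch$chains, function(c) c$lon[, 2]))
  smp_lat <- unlist(lapply(ch$chains, function(c) c$lat[, 2]))
  # independent dense-grid posterior for the middle location
  prep <- prepare_twilights(tw, 96)
  dt <- diff(as.numeric(tw$time)) / 3600
  pr <- movement_prior()
  err <- twilight_error_model()
  g <- expand.grid(lon = seq(-40.5, -36.5, by = 0.02),
                   lat = seq(-56.5, -52.5, by = 0.02))
  lp <- twilight_log_likelihood(prep[2, ], g$lon, g$lat, err, soft = TRUE) +
    hydrurga:::.step_log_prior(fixes$lon[1], fixes$lat[1], g$lon, g$lat,
                               dt[1], pr) +
    hydrurga:::.step_log_prior(g$lon, g$lat, fixes$lon[2], fixes$lat[2],
                               dt[2], pr)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  mean_lon <- sum(w * g$lon); mean_lat <- sum(w * g$lat)
  sd_lon <- sqrt(sum(w * (g$lon - mean_lon)^2))
  sd_lat <- sqrt(sum(w * (g$lat - mean_lat)^2))
  # sampled marginal mean within Monte-Carlo error of the grid mean
  expect_lt(abs(mean(smp_lon) - mean_lon), 4 * sd_lon / sqrt(50))
  expect_lt(abs(mean(smp_lat) - mean_lat), 4 * sd_lat / sqrt(50))
  expect_equal(sd(smp_lon), sd_lon, tolerance = 0.3)
  expect_equal(sd(smp_lat), sd_lat, tolerance = 0.3)
})

test_that("polar-day gaps are measured in days and pinned downstream", {
  # a seal in 24-h daylight between the two dates loses its twilights
  span <- as.POSIXct(c("2012-08-02", "2013-05-09"), tz = "UTC")
  days <- seq(as.Date("2012-08-02"), as.Date("2013-05-09"), by = 1)
  gap <- days >= as.Date("2012-11-20") & days < as.Date("2013-01-22")
  tw <- data.frame(time = as.POSIXct(paste(days[!gap], "10:00:00"),
                                     tz = "UTC"),
                   rise = TRUE)
  gaps <- handle_polar_day(tw, span)
  expect_equal(nrow(gaps), 1)
  expect_equal(gaps$start, as.Date("2012-11-20"))
  expect_equal(gaps$end, as.Date("2013-01-22"))
  expect_equal(gaps$duration_days, 63)
  # covariate locations during the run are pinned to the last estimate
  path <- data.frame(time = as.POSIXct(paste(days, "12:00:00"), tz = "UTC"),
                     lon = seq(-38, -45, length.out = length(days)),
                     lat = seq(-54, -61, length.out = length(days)))
  pinned <- pin_path(path, gaps)
  inside <- as.Date(trunc(pinned$time, "days")) >= gaps$start &
    as.Date(trunc(pinned$time, "days")) < gaps$end
  expect_equal(length(unique(pinned$lon[inside])), 1)
  expect_equal(length(unique(pinned$lat[inside])), 1)
  anchor <- max(which(as.Date(trunc(path$time, "days")) < gaps$start))
  expect_equal(unique(pinned$lon[inside]), path$lon[anchor])
  # a gap at the start of the record pins to the first fix after it
  tw2 <- tw[tw$time >= as.POSIXct("2012-09-01", tz = "UTC"), , drop = FALSE]
  gaps2 <- handle_polar_day(tw2, span)
  expect_equal(gaps2$start[1], as.Date("2012-08-02"))
  pinned2 <- pin_path(path, gaps2[1, ])
  first_in <- as.Date(trunc(pinned2$time, "days")) < gaps2$end[1]
  expect_equal(length(unique(pinned2$lon[first_in])), 1)
})

test_that("intermediate locations conserve time and lengthen paths", {
  times <- as.POSIXct("2013-01-01", tz = "UTC") + c(0, 12, 24, 36) * 3600
  lon <- c(-38, -39, -40.5, -41)
  lat <- c(-54, -54.5, -55.5, -56)
  # k = 1: great-circle midpoints
  d1 <- intermediate_locations(lon, lat, times, k = 1)
  m <- gc_interpolate(lon[1], lat[1], lon[2], lat[2], 0.5)
  expect_equal(d1$lon[1], m$lon, tolerance = 1e-9)
  expect_equal(d1$lat[1], m$lat, tolerance = 1e-9)
  # weights per segment sum to the segment duration
  d5 <- intermediate_locations(lon, lat, times, k = 5)
  expect_equal(sum(d5$weight_h), 36)
  expect_equal(as.numeric(tapply(d5$weight_h, rep(1:3, each = 5), sum)),
               rep(12, 3))
  # densified path (primary vertices plus intermediates) at least as
  # long as the primary chords
  dens <- 0
  for (i in 1:3) {
    seg <- d5[(i - 1) * 5 + 1:5, ]
    px <- c(lon[i], seg$lon, lon[i + 1])
    py <- c(lat[i], seg$lat, lat[i + 1])
    dens <- dens + sum(haversine_km(px[-7], py[-7], px[-1], py[-1]))
  }
  chord <- sum(haversine_km(lon[-4], lat[-4], lon[-1], lat[-1]))
  expect_gte(dens + 1e-9, chord)
})

test_that("time-spent grids normalize and localize a stationary animal", {
  tr <- stationary_track("2012-08-01", "2012-08-20")
  tw <- render_twilights(tr, 96, twilight_error_model(), seed = 5)
  fixes <- data.frame(time = tr$time, lon = tr$lon, lat = tr$lat)
  ch <- sample_posterior(tw, NULL, n_chains = 2, n_iter = 600, seed = 3)
  gs <- list(lon_range = c(-43, -33), lat_range = c(-58, -50),
             resolution = 0.5)
  tg <- time_spent_grid(ch, gs, n_simulations = 200, k = 5)
  expect_equal(sum(tg$density), 1, tolerance = 1e-9)
  expect_true(all(tg$density >= 0))
  # modal cell contains the true location
  ij <- which(tg$density == max(tg$density), arr.ind = TRUE)[1, ]
  lat_cell <- tg$lat[ij[1]] + c(0, gs$resolution)
  lon_cell <- tg$lon[ij[2]] + c(0, gs$resolution)
  expect_true(BIRD_ISLAND[2] >= lat_cell[1] - 0.5 &&
                BIRD_ISLAND[2] <= lat_cell[2] + 0.5)
  expect_true(BIRD_ISLAND[1] >= lon_cell[1] - 0.5 &&
                BIRD_ISLAND[1] <= lon_cell[2] + 0.5)
})

test_that("posterior recovers a noisy migratory fixture", {
  fx <- residency_fixture(n_steps = 160, seed = 23)
  ch <- sample_posterior(fx$twilights, fx$fixes, n_chains = 2,
                         n_iter = 6000, seed = 7)
  mp <- posterior_mean_path(ch)
  tru <- truth_at(fx$sim$track, mp$time)
  rmse <- sqrt(mean((mp$lon - tru$lon)^2 + (mp$lat - tru$lat)^2))
  expect_lt(rmse, 2)
  # central 95% envelopes cover the truth for >= 90% of time steps
  alllat <- do.call(rbind, lapply(ch$chains, function(c) c$lat))
  alllon <- do.call(rbind, lapply(ch$chains, function(c) c$lon))
  lo_a <- apply(alllat, 2, quantile, 0.025)
  hi_a <- apply(alllat, 2, quantile, 0.975)
  lo_o <- apply(alllon, 2, quantile, 0.025)
  hi_o <- apply(alllon, 2, quantile, 0.975)
  cov <- mean(tru$lat >= lo_a & tru$lat <= hi_a &
                tru$lon >= lo_o & tru$lon <= hi_o)
  expect_gte(cov, 0.9)
})
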