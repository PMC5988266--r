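# hourly states generated directly from a known bout process, with
# bout durations controlled per test
states_from_schedule <- function(days, sch, seed, start = "2013-01-01") {
  t0 <- as.POSIXct(start, tz = "UTC")
  tr <- data.frame(time = c(t0, t0 + days * 86400),
                   lon = -38.05, lat = -54.01)
  imm <- render_immersion(tr, sch, seed = seed)
  bouts <- detect_bouts(transform_immersion(imm$immersion))
  hourly_states(bouts, range(imm$immersion$time))
}

test_that("distance to land or ice handles substrate and monotonicity", {
  spec <- env_field_spec()
  poly <- spec$land_polygons[[1]]
  ice <- spec$ice_edge_latitude_by_month
  # a point on the polygon boundary is at distance zero
  expect_lt(distance_to_land_or_ice(poly$lon[1], poly$lat[1],
                                    spec$land_polygons, ice, 8), 1e-6)
  # poleward of the month's ice edge: inside the pack, distance zero
  expect_equal(distance_to_land_or_ice(-35, ice[8] - 1,
                                       spec$land_polygons, ice, 8), 0)
  # moving directly away from an isolated island increases the distance
  d <- vapply(seq(0.5, 4, by = 0.5), function(off)
    distance_to_land_or_ice(-38.05, -54.01 + off, spec$land_polygons,
                            ice, 8), 0)
  expect_true(all(diff(d) > 0))
  # brute-force nearest-densified-vertex oracle
  bd <- hydrurga:::densify_boundary(poly, 5)
  pts <- data.frame(lon = c(-37, -40, -36.2), lat = c(-53, -55.5, -54.6))
  for (i in seq_len(nrow(pts))) {
    want <- min(haversine_km(pts$lon[i], pts$lat[i], bd$lon, bd$lat))
    got <- distance_to_land_or_ice(pts$lon[i], pts$lat[i],
                                   spec$land_polygons, NULL, 8)
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_error(distance_to_land_or_ice(0, 0, NULL, NULL, 1), "at least")
})

test_that("design assembly produces lagged, binned, located rows", {
  sch <- haulout_schedule()
  states <- states_from_schedule(20, sch, seed = 31)
  path <- data.frame(time = states$hour_start,
                     lon = seq(-38, -39, length.out = nrow(states)),
                     lat = seq(-54, -55, length.out = nrow(states)))
  spec <- env_field_spec()
  d <- build_design(states, path, spec$land_polygons,
                    spec$ice_edge_latitude_by_month, n_lags = 3)
  # first k hours dropped (undefined lags)
  expect_equal(nrow(d), nrow(states) - 3)
  # lag1 equals the state shifted by one hour
  idx <- match(as.numeric(d$hour_start), as.numeric(states$hour_start))
  expect_equal(d$lag1, states$state[idx - 1])
  expect_equal(d$lag3, states$state[idx - 3])
  # hour binning convention: a row starting 23:00 has hour 23
  h23 <- d[strftime(d$hour_start, "%H") == "23", ]
  expect_true(all(h23$hour_of_day == 23))
  expect_true(all(d$distance_km >= 0))
  expect_error(build_design(states[1:5, ],
                            data.frame(time = path$time[100:110] + 9e7,
                                       lon = 0, lat = 0)),
               "overlap")
})

test_that("activity fits recover injected diel structure and lag effects", {
  # short bouts so the state peak tracks the start-hazard peak
  sch <- haulout_schedule(base_rate = 0.08, diel_amplitude = 1,
                          seasonal_amplitude = 0, persistence = 0.3)
  states <- states_from_schedule(300, sch, seed = 33)
  path <- data.frame(time = states$hour_start, lon = -38.05, lat = -54.01)
  d <- build_design(states, path, n_lags = 3)
  f <- fit_activity(d, smooths = list(smooth_spec("hour_of_day",
                                                  cyclic = TRUE,
                                                  period = 24)))
  expect_equal(f$link, "cloglog")
  peak <- smooth_peak(f, "s(hour_of_day)", period = 24)
  expect_lte(min(abs(peak - 12), 24 - abs(peak - 12)), 1)
  expect_gt(f$coefficients[["lag1"]], 0)

  # no diel structure: the hour smooth shrinks away
  sch0 <- haulout_schedule(base_rate = 0.10, diel_amplitude = 0,
                           seasonal_amplitude = 0, persistence = 0.3)
  states0 <- states_from_schedule(60, sch0, seed = 34)
  d0 <- build_design(states0, path[seq_len(nrow(states0)), , drop = FALSE],
                     n_lags = 1)
  f0 <- fit_activity(d0, smooths = list(smooth_spec("hour_of_day",
                                                    cyclic = TRUE,
                                                    period = 24)),
                     lags = "lag1")
  expect_lt(f0$term_table$edf[f0$term_table$type == "smooth"], 1.5)
})

test_that("two-hour bouts give a positive lag1 and negative lag3", {
  # bouts of ~2 h: being hauled out 3 h ago means the bout is ending
  sch <- haulout_schedule(base_rate = 0.12, diel_amplitude = 0,
                          seasonal_amplitude = 0, persistence = 0.15,
                          min_bout = 2, refractory_h = 5)
  states <- states_from_schedule(150, sch, seed = 35)
  path <- data.frame(time = states$hour_start, lon = -38.05, lat = -54.01)
  d <- build_design(states, path, n_lags = 3)
  f <- fit_activity(d, smooths = list(), lags = c("lag1", "lag2", "lag3"))
  expect_gt(f$coefficients[["lag1"]], 0)
  expect_lt(f$coefficients[["lag3"]], 0)
})

test_that("candidate selection ranks by AIC with stable tie-breaks", {
  sch <- haulout_schedule(base_rate = 0.10, diel_amplitude = 1,
                          seasonal_amplitude = 0, persistence = 0.3)
  states <- states_from_schedule(45, sch, seed = 36)
  path <- data.frame(time = states$hour_start, lon = -38.05, lat = -54.01)
  d <- build_design(states, path, n_lags = 3)
  sel <- select_activity_model(d)
  expect_gte(nrow(sel$ranking), 6)
  # the generating structure (a diel smooth) beats the week-only model
  expect_true(grepl("hour", sel$selected))
  aic_hour <- sel$ranking$aic[grepl("^hour \\+ week \\+ lag1-3$",
                                    sel$ranking$model)]
  aic_week <- sel$ranking$aic[sel$ranking$model == "week + lag1-3"]
  expect_lt(aic_hour, aic_week)
  # duplicate candidates: stable tie-break, no error
  f1 <- fit_activity(d, smooths = list(), lags = "lag1")
  tab <- pam_compare(list(a = f1, b = f1), "aic")
  expect_equal(nrow(tab), 2)
  expect_error(select_activity_model(d, candidates = list(x = list())),
               "two candidate")
})

test_that("diel and seasonal summaries aggregate states correctly", {
  hrs <- seq(as.POSIXct("2013-01-01", tz = "UTC"),
             as.POSIXct("2013-01-31 23:00:00", tz = "UTC"), by = 3600)
  st <- data.frame(hour_start = hrs, state = 0L)
  # haul-out only at hours 10-14 in January
  st$state[as.integer(strftime(hrs, "%H")) %in% 10:14] <- 1L
  ds <- diel_seasonal_summary(st)
  pr <- ds$hour_month$proportion
  expect_true(all(pr[as.character(10:14), "1"] == 1))
  expect_true(all(pr[as.character(c(0:9, 15:23)), "1"] == 0))
  expect_true(all(is.na(pr[, "6"])))
  # all-zero states: all proportions 0
  st0 <- data.frame(hour_start = hrs, state = 0L)
  ds0 <- diel_seasonal_summary(st0)
  expect_true(all(ds0$hour_month$proportion[, "1"] == 0))
  # proportions in [0, 1]; weighted cell means reproduce the overall rate
  p <- ds$hour_month$proportion; nn <- ds$hour_month$n
  expect_true(all(p[nn > 0] >= 0 & p[nn > 0] <= 1))
  expect_equal(sum(p * nn, na.rm = TRUE) / sum(nn), mean(st$state))
  # invariant to row order
  perm <- sample(nrow(st))
  ds_p <- diel_seasonal_summary(st[perm, ])
  expect_equal(ds_p$hour_month$proportion, ds$hour_month$proportion)
})
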