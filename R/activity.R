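# Hourly haul-out probability modelling: distance-to-land/ice and
# other covariates, design-table assembly with lagged states, cloglog
# penalized additive fits, candidate-model selection, and the
# hour-by-month / week-by-trip proportion summaries.

#' Distance to the nearest land polygon or monthly ice edge
#'
#' Minimum over the haversine distances to the densified boundary of
#' every land polygon and to the month's ice-edge line. Points inside
#' a land polygon, or poleward (south) of the month's ice edge, are at
#' their haul-out substrate and get distance 0.
#'
#' @param lon,lat Query coordinates (vectors).
#' @param land_polygons List of data.frame(`lon`, `lat`) polygons.
#' @param ice_edge_by_month Numeric length 12: ice-edge latitude per
#'   month.
#' @param month Month (1-12), recycled against the points.
#' @param spacing_km Boundary densification spacing.
#' @return Distance in km.
#' @export
distance_to_land_or_ice <- function(lon, lat, land_polygons,
                                    ice_edge_by_month, month,
                                    spacing_km = 5) {
  if ((is.null(land_polygons) || !length(land_polygons)) &&
      is.null(ice_edge_by_month))
    stop("need at least one land polygon or an ice edge")
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  month <- rep_len(month, n)
  d <- rep(Inf, n)
  if (!is.null(land_polygons)) {
    for (p in land_polygons) {
      bd <- densify_boundary(p, spacing_km)
      for (i in seq_len(n))
        d[i] <- min(d[i], min(haversine_km(lon[i], lat[i], bd$lon, bd$lat)))
      inside <- point_in_polygon(lon, lat, p)
      d[inside] <- 0
    }
  }
  if (!is.null(ice_edge_by_month)) {
    edge <- ice_edge_by_month[month]
    d_edge <- haversine_km(lon, lat, lon, edge)  # same meridian
    d <- pmin(d, d_edge)
    d[lat <= edge] <- 0  # inside the pack
  }
  d
}

#' Assemble the hourly design table for activity models
#'
#' One row per deployment hour: the binary haul-out state, time
#' covariates (hour of day, ISO week, month, Julian day), the location
#' interpolated from the posterior mean path, latitude, distance to
#' land or the monthly ice edge, and lagged states `lag1..lagk`. The
#' first `k` hours of each trip, whose lags are undefined, are
#' dropped.
#'
#' @param states data.frame(`hour_start`, `state`) from
#'   [hourly_states()].
#' @param mean_path data.frame(`time`, `lon`, `lat`).
#' @param land_polygons,ice_edge_by_month Passed to
#'   [distance_to_land_or_ice()].
#' @param tag_id,trip_id Deployment identifiers.
#' @param n_lags Number of lagged-state terms (default 3).
#' @return data.frame, one row per usable hour.
#' @export
build_design <- function(states, mean_path, land_polygons = NULL,
                         ice_edge_by_month = NULL,
                         tag_id = "tag1", trip_id = "trip1",
                         n_lags = 3) {
  t0 <- max(as.numeric(states$hour_start[1]), as.numeric(mean_path$time[1]))
  t1 <- min(as.numeric(states$hour_start[nrow(states)]),
            as.numeric(mean_path$time[nrow(mean_path)]))
  if (t0 >= t1) stop("states and locations do not overlap in time")
  keep <- as.numeric(states$hour_start) >= t0 &
    as.numeric(states$hour_start) <= t1
  st <- states[keep, , drop = FALSE]
  hrs <- st$hour_start
  lon <- stats::approx(as.numeric(mean_path$time), mean_path$lon,
                       as.numeric(hrs), rule = 2)$y
  lat <- stats::approx(as.numeric(mean_path$time), mean_path$lat,
                       as.numeric(hrs), rule = 2)$y
  mo <- as.integer(strftime(hrs, "%m"))
  dd <- if (is.null(land_polygons) && is.null(ice_edge_by_month)) 0
    else distance_to_land_or_ice(lon, lat, land_polygons,
                                 ice_edge_by_month, mo)
  out <- data.frame(
    tag_id = tag_id, trip_id = trip_id,
    hour_start = hrs, state = st$state,
    hour_of_day = as.integer(strftime(hrs, "%H")),
    week = pmin(53L, as.integer(strftime(hrs, "%V"))),
    month = mo,
    julian_day = as.integer(strftime(hrs, "%j")),
    latitude = lat, longitude = lon,
    distance_km = dd)
  for (k in seq_len(n_lags))
    out[[paste0("lag", k)]] <- c(rep(NA_integer_, k),
                                 utils::head(st$state, -k))
  out <- out[stats::complete.cases(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit an hourly haul-out model
#'
#' Penalized additive binomial fit with the complementary log-log link
#' (haul-out hours are the rarer outcome). `spec` describes the terms:
#' cyclic smooths for hour of day (period 24), week (period 52) or
#' Julian day (period 365), optionally grouped `by` a factor; linear
#' lag terms; and a tag/trip random intercept.
#'
#' @param design data.frame from [build_design()].
#' @param smooths List of [smooth_spec()]; default hour-of-day cyclic
#'   smooth plus week cyclic smooth.
#' @param lags Character vector of lag columns to include linearly.
#' @param random Grouping columns for random intercepts (`NULL` to
#'   omit; the single-deployment default omits them).
#' @param ... Passed to [pam_fit()].
#' @return A [pam_fit()] object.
#' @export
fit_activity <- function(design,
                         smooths = list(
                           smooth_spec("hour_of_day", cyclic = TRUE,
                                       period = 24),
                           smooth_spec("week", cyclic = TRUE,
                                       period = 52)),
                         lags = c("lag1", "lag2", "lag3"),
                         random = NULL, ...) {
  lags <- lags[lags %in% names(design)]
  pam_fit(design, "state", linear = lags, smooths = smooths,
          random = random, link = "cloglog", ...)
}

#' Fit and rank a family of candidate activity models
#'
#' @param design data.frame from [build_design()].
#' @param candidates Named list; each element is a list with elements
#'   `smooths`, `lags` (and optionally `random`) as accepted by
#'   [fit_activity()]. The default family varies the seasonal term
#'   (week vs month vs Julian day), drops lag3, and adds lag4 where
#'   present.
#' @param ... Passed to [pam_fit()].
#' @return list: `ranking` (by AIC, best first), `fits`, `selected`.
#' @export
select_activity_model <- function(design, candidates = NULL, ...) {
  if (is.null(candidates)) {
    hod <- function(...) smooth_spec("hour_of_day", cyclic = TRUE,
                                     period = 24, ...)
    wk <- function(...) smooth_spec("week", cyclic = TRUE, period = 52, ...)
    jd <- function(...) smooth_spec("julian_day", cyclic = TRUE,
                                    period = 365, ...)
    candidates <- list(
      "hour + week + lag1-3" = list(smooths = list(hod(), wk()),
                                    lags = c("lag1", "lag2", "lag3")),
      "hour + week + lag1-2" = list(smooths = list(hod(), wk()),
                                    lags = c("lag1", "lag2")),
      "hour + week + lag1" = list(smooths = list(hod(), wk()),
                                  lags = "lag1"),
      "hour + julian + lag1-3" = list(smooths = list(hod(), jd()),
                                      lags = c("lag1", "lag2", "lag3")),
      "hour + lag1-3" = list(smooths = list(hod()),
                             lags = c("lag1", "lag2", "lag3")),
      "week + lag1-3" = list(smooths = list(wk()),
                             lags = c("lag1", "lag2", "lag3")))
    if ("lag4" %in% names(design))
      candidates[["hour + week + lag1-4"]] <-
        list(smooths = list(hod(), wk()),
             lags = c("lag1", "lag2", "lag3", "lag4"))
  }
  if (length(candidates) < 2) stop("need at least two candidate models")
  fits <- lapply(candidates, function(cd)
    fit_activity(design, smooths = cd$smooths, lags = cd$lags,
                 random = cd$random, ...))
  ranking <- pam_compare(fits, criterion = "aic")
  list(ranking = ranking, fits = fits, selected = ranking$model[1])
}

#' Peak location of a fitted cyclic smooth
#'
#' The phase of the curve's first harmonic, a much more stable
#' estimator of "peak hour" (or week) than the curve's argmax when the
#' underlying cycle is broad: the argmax of a flat-topped diel profile
#' wanders by hours between replicates while the phase stays put.
#'
#' @param fit A [pam_fit()] object.
#' @param term Cyclic smooth block name.
#' @param period Cycle length in covariate units (24 for hours).
#' @param n Grid size for evaluating the smooth.
#' @return Peak position in covariate units, in \[0, period).
#' @export
smooth_peak <- function(fit, term, period = 24, n = 240) {
  grid <- seq(0, period, length.out = n + 1)[-(n + 1)]
  sv <- pam_smooth_values(fit, term, grid)
  w <- sv - mean(sv)
  ph <- atan2(sum(w * sin(2 * pi * grid / period)),
              sum(w * cos(2 * pi * grid / period)))
  (ph / (2 * pi) * period) %% period
}

#' Haul-out proportion summaries by hour x month and week x trip
#'
#' @param states data.frame with at least `hour_start` and `state`;
#'   a `trip_id` column is used for the weekly matrix when present.
#' @return list: `hour_month` and `week_trip`, each a list with
#'   `proportion` and `n` matrices.
#' @export
diel_seasonal_summary <- function(states) {
  hod <- as.integer(strftime(states$hour_start, "%H"))
  mo <- as.integer(strftime(states$hour_start, "%m"))
  wk <- pmin(53L, as.integer(strftime(states$hour_start, "%V")))
  trip <- if ("trip_id" %in% names(states)) as.character(states$trip_id)
    else rep("all", nrow(states))
  agg <- function(f1, l1, f2, l2) {
    pr <- matrix(NA_real_, length(l1), length(l2),
                 dimnames = list(l1, l2))
    nn <- matrix(0L, length(l1), length(l2), dimnames = list(l1, l2))
    tb_n <- table(factor(f1, levels = l1), factor(f2, levels = l2))
    tb_s <- tapply(states$state, list(factor(f1, levels = l1),
                                      factor(f2, levels = l2)), sum)
    nn[] <- tb_n
    pr[] <- ifelse(tb_n > 0, tb_s / tb_n, NA_real_)
    list(proportion = pr, n = nn)
  }
  list(hour_month = agg(hod, 0:23, mo, 1:12),
       week_trip = agg(wk, 1:53, trip, sort(unique(trip))))
}
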