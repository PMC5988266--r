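# Synthetic deployments: migratory central-place tracks with log-normal
# speeds, light curves driven by solar elevation, 0-200 immersion
# counts with diel/seasonal haul-out structure, and environmental
# grids. Every generator is deterministic under its seed and exports
# ground truth for downstream recovery tests.

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# arithmetic mean/sd on the natural scale -> log-normal meanlog/sdlog
lnorm_pars <- function(mean, sd) {
  if (sd <= 0) return(list(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Track simulation parameters
#'
#' Describes a migratory central-place movement: residency loops around
#' a central place followed by directed legs towards scheduled targets.
#' Per-step speeds are log-normal with the given arithmetic mean and SD
#' on the km/h scale; the defaults (1.0, 0.9) match the swim-speed
#' prior used by the track posterior.
#'
#' @param start_lonlat,central_place_lonlat c(lon, lat) degrees.
#' @param start_time POSIXct (UTC) of the first position.
#' @param mean_speed,speed_sd Arithmetic mean and SD of step speed,
#'   km/h. `mean_speed > 0`, `speed_sd >= 0`.
#' @param migration_schedule List of `list(date =, target =)` entries:
#'   from `date` onward the track heads towards `target` (c(lon, lat)).
#' @param residency_days Days of central-place residency before the
#'   first migration leg.
#' @param step_interval Hours between successive positions (> 0).
#' @param n_steps Number of movement steps; by default enough to cover
#'   the schedule plus 30 days.
#' @param heading_sd Heading noise SD, degrees.
#' @param loiter_radius_km Radius of residency loops, km.
#' @param seed Integer RNG seed.
#' @return A list of class `track_params`.
#' @export
track_params <- function(start_lonlat = c(-38.05, -54.01),
                         central_place_lonlat = start_lonlat,
                         start_time = as.POSIXct("2012-08-02 00:00:00", tz = "UTC"),
                         mean_speed = 1.0, speed_sd = 0.9,
                         migration_schedule = list(),
                         residency_days = 30L,
                         step_interval = 12,
                         n_steps = NULL,
                         heading_sd = 25,
                         loiter_radius_km = 40,
                         seed = 1L) {
  stopifnot(mean_speed > 0, speed_sd >= 0, step_interval > 0,
            residency_days >= 0)
  if (is.null(n_steps)) {
    end <- if (length(migration_schedule)) {
      max(vapply(migration_schedule,
                 function(s) as.numeric(as.POSIXct(s$date, tz = "UTC")), 0))
    } else as.numeric(start_time) + residency_days * 86400
    n_steps <- ceiling((end - as.numeric(start_time)) / 3600 /
                         step_interval) + ceiling(30 * 24 / step_interval)
  }
  structure(list(start_lonlat = start_lonlat,
                 central_place_lonlat = central_place_lonlat,
                 start_time = as.POSIXct(start_time, tz = "UTC"),
                 mean_speed = mean_speed, speed_sd = speed_sd,
                 migration_schedule = migration_schedule,
                 residency_days = as.integer(residency_days),
                 step_interval = step_interval,
                 n_steps = as.integer(n_steps),
                 heading_sd = heading_sd,
                 loiter_radius_km = loiter_radius_km,
                 seed = seed),
            class = "track_params")
}

#' Simulate a migratory central-place track
#'
#' Positions on a regular time grid. During residency the animal loops
#' within `loiter_radius_km` of the central place; during a migration
#' leg it heads towards the scheduled target with Gaussian heading
#' noise, loitering around the target after arrival. Step distances are
#' `speed * step_interval` with log-normal speeds.
#'
#' @param params A [track_params()] object.
#' @return list with `track` (data.frame `time`, `lon`, `lat`) and
#'   `truth` (generator echo including the drawn speeds).
#' @export
simulate_track <- function(params) {
  stopifnot(inherits(params, "track_params"))
  sched <- params$migration_schedule
  t0 <- as.numeric(params$start_time)
  if (length(sched)) {
    sd_t <- vapply(sched, function(s) as.numeric(as.POSIXct(s$date, tz = "UTC")), 0)
    t_end <- t0 + params$n_steps * params$step_interval * 3600
    if (any(sd_t < t0) || any(sd_t > t_end))
      stop("migration_schedule dates fall outside the simulated window")
    sched <- sched[order(sd_t)]
    sd_t <- sort(sd_t)
  } else sd_t <- numeric()
  n <- params$n_steps
  lp <- lnorm_pars(params$mean_speed, params$speed_sd)
  with_seed(params$seed, {
    speeds <- if (params$speed_sd == 0) rep(params$mean_speed, n)
      else stats::rlnorm(n, lp$meanlog, lp$sdlog)
    hnoise <- stats::rnorm(n, 0, params$heading_sd)
    uturn <- stats::runif(n, 0, 360)
    lon <- numeric(n + 1); lat <- numeric(n + 1)
    lon[1] <- params$start_lonlat[1]; lat[1] <- params$start_lonlat[2]
    times <- params$start_time + (0:n) * params$step_interval * 3600
    res_end <- t0 + params$residency_days * 86400
    for (i in seq_len(n)) {
      now <- as.numeric(times[i])
      k <- if (length(sd_t)) findInterval(now, sd_t) else 0L
      target <- if (k >= 1L) sched[[k]]$target else params$central_place_lonlat
      d_tar <- haversine_km(lon[i], lat[i], target[1], target[2])
      head_i <- if (d_tar > params$loiter_radius_km) {
        bearing_deg(lon[i], lat[i], target[1], target[2]) + hnoise[i]
      } else if (now < res_end || k >= 1L) {
        # loiter: random heading, biased back when drifting out
        uturn[i]
      } else uturn[i]
      p <- destination_point(lon[i], lat[i], head_i,
                             speeds[i] * params$step_interval)
      lon[i + 1] <- p$lon; lat[i + 1] <- p$lat
    }
    track <- data.frame(time = times, lon = lon, lat = lat)
    list(track = track,
         truth = list(true_track = track, speeds = speeds,
                      generator_params = params))
  })
}

#' Render a GLS light record along a track
#'
#' Ambient light is a logistic function of solar elevation, positioned
#' so that light equals `threshold` exactly when the solar zenith is
#' `zenith_deg`, scaled to an integer 0--`light_max` sensor scale.
#' Samples are drawn every 60 s at positions interpolated linearly in
#' time along the track and aggregated as the maximum per 10-minute
#' window, as archival GLS loggers record. During `shading_bouts` the
#' pre-noise light is attenuated to near zero, emulating an animal
#' shading the sensor while hauled out.
#'
#' @param track data.frame(`time`, `lon`, `lat`).
#' @param zenith_deg Zenith angle at which light crosses `threshold`.
#' @param threshold Light level at the twilight zenith.
#' @param noise_sd Per-sample Gaussian noise SD, light units.
#' @param shading_bouts data.frame(`start`, `end`) POSIXct intervals.
#' @param light_max Sensor full-scale value (default 64).
#' @param curve_width Logistic width in degrees of elevation.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return data.frame(`time`, `light`): 10-min window starts (UTC) and
#'   integer light maxima.
#' @export
render_light <- function(track, zenith_deg = 96, threshold = 10,
                         noise_sd = 0, shading_bouts = NULL,
                         light_max = 64, curve_width = 1.5, seed = 1L) {
  t0 <- as.numeric(track$time[1])
  t1 <- as.numeric(track$time[nrow(track)])
  tt <- seq(t0, t1, by = 60)
  lon <- stats::approx(as.numeric(track$time), track$lon, tt, rule = 2)$y
  lat <- stats::approx(as.numeric(track$time), track$lat, tt, rule = 2)$y
  elev <- 90 - solar_position(as.POSIXct(tt, tz = "UTC",
                                         origin = "1970-01-01"), lon, lat)
  e_thr <- 90 - zenith_deg
  e0 <- e_thr + curve_width * log(light_max / threshold - 1)
  light <- light_max * stats::plogis((elev - e0) / curve_width)
  if (!is.null(shading_bouts) && nrow(shading_bouts)) {
    for (b in seq_len(nrow(shading_bouts))) {
      sh <- tt >= as.numeric(shading_bouts$start[b]) &
        tt < as.numeric(shading_bouts$end[b])
      light[sh] <- light[sh] * 0.02
    }
  }
  if (noise_sd > 0)
    light <- with_seed(seed, light + stats::rnorm(length(light), 0, noise_sd))
  light <- round(pmin(light_max, pmax(0, light)))
  win <- (tt - t0) %/% 600
  mx <- tapply(light, win, max)
  data.frame(time = as.POSIXct(t0 + as.numeric(names(mx)) * 600,
                               tz = "UTC", origin = "1970-01-01"),
             light = as.numeric(mx))
}

#' Haul-out schedule parameters
#'
#' Hourly hazard of starting a haul-out bout combines a diel sinusoid
#' peaking at `diel_peak_hour`, a seasonal sinusoid peaking at
#' `seasonal_peak_week`, and hour-to-hour persistence once a bout has
#' started. Defaults give long (median several hours) bouts occupying
#' roughly a quarter of the deployment, with a midday diel peak —
#' the structure typical of phocid wet/dry records.
#'
#' @param base_rate Baseline bout-start probability per hour, in \[0,1\].
#' @param diel_peak_hour Hour of day (UTC) of peak starting hazard.
#' @param diel_amplitude,seasonal_amplitude Relative modulation depths.
#' @param seasonal_peak_week Week of year of the seasonal peak.
#' @param persistence Probability a bout continues one more hour
#'   (beyond `min_bout`), in \[0, 1).
#' @param min_bout Minimum bout duration, hours.
#' @param refractory_h Hours after a bout ends during which no new bout
#'   can start (the animal returns to sea to forage). Default 0.
#' @return list of class `haulout_schedule`.
#' @export
haulout_schedule <- function(base_rate = 0.06, diel_peak_hour = 12,
                             diel_amplitude = 0.8,
                             seasonal_amplitude = 0.5,
                             seasonal_peak_week = 2,
                             persistence = 0.8, min_bout = 1,
                             refractory_h = 0) {
  stopifnot(base_rate >= 0, base_rate <= 1,
            persistence >= 0, persistence < 1, min_bout > 0,
            refractory_h >= 0)
  structure(as.list(environment()), class = "haulout_schedule")
}

#' Render an immersion record with known haul-out bouts
#'
#' Simulates the bout process on an hourly grid over the track period,
#' then emits per-10-minute counts of positive salt-water tests at 3-s
#' sampling: 0 while hauled out (completely dry), near 200 at sea with
#' occasional surfacing-induced dips (never below 150).
#'
#' @param track data.frame(`time`, ...) giving the deployment span.
#' @param schedule A [haulout_schedule()].
#' @param seed RNG seed.
#' @return list with `immersion` (data.frame `time`, `wet_count`) and
#'   `bouts` (data.frame `start`, `end`, `duration_h` — the ground
#'   truth).
#' @export
render_immersion <- function(track, schedule, seed = 1L) {
  stopifnot(inherits(schedule, "haulout_schedule"))
  t0 <- as.numeric(track$time[1]); t1 <- as.numeric(track$time[nrow(track)])
  hours <- seq(t0, t1 - 3600, by = 3600)
  hod <- (hours %/% 3600) %% 24
  week <- as.numeric(strftime(as.POSIXct(hours, tz = "UTC",
                                         origin = "1970-01-01"), "%V"))
  with_seed(seed, {
    hazard <- schedule$base_rate *
      (1 + schedule$diel_amplitude *
         cos(2 * pi * (hod - schedule$diel_peak_hour) / 24)) *
      (1 + schedule$seasonal_amplitude *
         cos(2 * pi * (week - schedule$seasonal_peak_week) / 52))
    hazard <- pmin(1, pmax(0, hazard))
    state <- logical(length(hours))
    committed <- 0  # hours still owed to min_bout
    refr <- 0      # refractory hours left after the last bout
    for (i in seq_along(hours)) {
      if (i > 1 && state[i - 1]) {
        if (committed > 0) {
          state[i] <- TRUE; committed <- committed - 1
        } else state[i] <- stats::runif(1) < schedule$persistence
        if (!state[i]) refr <- schedule$refractory_h
      } else if (refr > 0) {
        refr <- refr - 1
      } else {
        state[i] <- stats::runif(1) < hazard[i]
        if (state[i]) committed <- ceiling(schedule$min_bout) - 1
      }
    }
    # truth bouts from the hourly state
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
    dry <- which(r$values)
    bouts <- data.frame(
      start = as.POSIXct(hours[starts[dry]], tz = "UTC", origin = "1970-01-01"),
      end = as.POSIXct(hours[ends[dry]] + 3600, tz = "UTC", origin = "1970-01-01"))
    bouts$duration_h <- as.numeric(bouts$end - bouts$start, units = "hours")
    wt <- seq(t0, t1 - 600, by = 600)
    hidx <- pmin(length(state), ((wt - t0) %/% 3600) + 1)
    n <- length(wt)
    base <- 200 - stats::rbinom(n, 8, 0.3)          # near-saturated wet
    dip <- stats::runif(n) < 0.05                    # surfacing dips
    base[dip] <- base[dip] - sample(0:42, sum(dip), replace = TRUE)
    wet <- ifelse(state[hidx], 0L, pmax(150L, pmin(200L, base)))
    list(immersion = data.frame(
           time = as.POSIXct(wt, tz = "UTC", origin = "1970-01-01"),
           wet_count = as.integer(wet)),
         bouts = bouts)
  })
}

#' Environmental field specification
#'
#' Synthetic stand-ins for a bathymetry grid, weekly/monthly
#' sea-surface temperature slices and monthly sea-ice concentration,
#' all sharing one lon/lat grid, plus land polygons for coastline
#' distances.
#'
#' @param lon_range,lat_range Grid bounds, degrees.
#' @param resolution Cell size, degrees (> 0).
#' @param depth_gradient Seafloor slope, metres per km offshore.
#' @param sst_base SST at the northern grid edge, deg C.
#' @param sst_lat_gradient Deg C per degree latitude (positive: warmer
#'   equatorward, i.e. northward in the southern hemisphere).
#' @param ice_edge_latitude_by_month Numeric length 12; the monthly
#'   latitude of the ice edge (concentration is zero equatorward of
#'   it). Must lie within `lat_range`.
#' @param land_polygons List of data.frame(`lon`, `lat`) polygons; the
#'   default is a small island at the central place used by
#'   [track_params()].
#' @return list of class `env_field_spec`.
#' @export
env_field_spec <- function(lon_range = c(-50, -20), lat_range = c(-70, -45),
                           resolution = 0.5,
                           depth_gradient = 15,
                           sst_base = 6, sst_lat_gradient = 0.5,
                           ice_edge_latitude_by_month =
                             c(-59, -58, -59, -60, -62, -64,
                               -66, -66, -65, -63, -61, -60),
                           land_polygons = NULL) {
  stopifnot(resolution > 0, length(ice_edge_latitude_by_month) == 12)
  if (any(ice_edge_latitude_by_month < lat_range[1] |
          ice_edge_latitude_by_month > lat_range[2]))
    stop("ice edge latitudes must lie within the grid extent")
  if (is.null(land_polygons)) {
    # ~40 km island centred on the default deployment site
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    land_polygons <- list(data.frame(lon = -38.05 + 0.35 * cos(th),
                                     lat = -54.01 + 0.20 * sin(th)))
  }
  structure(list(lon_range = lon_range, lat_range = lat_range,
                 resolution = resolution, depth_gradient = depth_gradient,
                 sst_base = sst_base, sst_lat_gradient = sst_lat_gradient,
                 ice_edge_latitude_by_month = ice_edge_latitude_by_month,
                 land_polygons = land_polygons),
            class = "env_field_spec")
}

#' Simulate environmental grids
#'
#' Builds the shared-grid rasters described by an [env_field_spec()]:
#' `depth` (negative below sea level, 0 on land/coast, deepening with
#' distance offshore), monthly and weekly SST (warming equatorward,
#' with a small seasonal cycle peaking in February), and monthly ice
#' concentration (0 equatorward of the month's edge, ramping to 100%
#' poleward of it).
#'
#' @param spec An [env_field_spec()].
#' @return list of class `env_grids`: `lon`, `lat` (cell centres),
#'   `depth` (matrix \[lat, lon\]), `sst_monthly` / `ice_monthly`
#'   (lists of 12 matrices), `sst_weekly` (list of 53 matrices),
#'   `land_polygons`, `ice_edge_latitude_by_month`, `spec`.
#' @export
simulate_environment <- function(spec) {
  stopifnot(inherits(spec, "env_field_spec"))
  lon <- seq(spec$lon_range[1] + spec$resolution / 2, spec$lon_range[2],
             by = spec$resolution)
  lat <- seq(spec$lat_range[1] + spec$resolution / 2, spec$lat_range[2],
             by = spec$resolution)
  G <- expand.grid(lon = lon, lat = lat)
  shore <- do.call(rbind, lapply(spec$land_polygons, densify_boundary,
                                 spacing_km = 5))
  dmin <- rep(Inf, nrow(G))
  for (i in seq_len(nrow(shore)))
    dmin <- pmin(dmin, haversine_km(G$lon, G$lat, shore$lon[i], shore$lat[i]))
  on_land <- rep(FALSE, nrow(G))
  for (p in spec$land_polygons)
    on_land <- on_land | point_in_polygon(G$lon, G$lat, p)
  # cells whose centre sits within half a cell diagonal of the shore
  # are coastal: depth 0, like the land cells themselves
  half_diag <- spec$resolution * 111.32 * 0.75
  depth_v <- -pmin(spec$depth_gradient * pmax(0, dmin - half_diag), 6000)
  depth_v[on_land | dmin <= half_diag] <- 0
  depth <- matrix(depth_v, nrow = length(lat), ncol = length(lon),
                  byrow = TRUE)
  sst_field <- function(seas) {
    matrix(rep(spec$sst_base +
                 spec$sst_lat_gradient * (lat - max(lat)), length(lon)) + seas,
           nrow = length(lat), ncol = length(lon))
  }
  sst_monthly <- lapply(1:12, function(m)
    sst_field(2 * cos(2 * pi * (m - 2) / 12)))
  sst_weekly <- lapply(1:53, function(w)
    sst_field(2 * cos(2 * pi * (w / 4.345 - 2) / 12)))
  ice_monthly <- lapply(1:12, function(m) {
    edge <- spec$ice_edge_latitude_by_month[m]
    conc <- pmin(100, pmax(0, 25 * (edge - lat)))
    matrix(rep(conc, length(lon)), nrow = length(lat), ncol = length(lon))
  })
  structure(list(lon = lon, lat = lat, depth = depth,
                 sst_monthly = sst_monthly, sst_weekly = sst_weekly,
                 ice_monthly = ice_monthly,
                 land_polygons = spec$land_polygons,
                 ice_edge_latitude_by_month = spec$ice_edge_latitude_by_month,
                 spec = spec),
            class = "env_grids")
}

#' Look up an environmental covariate
#'
#' Nearest-cell lookup on an [simulate_environment()] grid. SST uses
#' the weekly slice when present, falling back to the monthly mean when
#' that week's slice is missing (`NULL`).
#'
#' @param env An `env_grids` object.
#' @param var One of `"depth"`, `"sst"`, `"ice"`.
#' @param lon,lat Query coordinates (vectors).
#' @param week,month Week of year / month for the time-varying fields.
#' @return Numeric vector of values; `NA` outside the grid.
#' @export
env_extract <- function(env, var, lon, lat, week = NULL, month = NULL) {
  ii <- findInterval(lat, c(env$lat - env$spec$resolution / 2, Inf),
                     all.inside = FALSE)
  jj <- findInterval(lon, c(env$lon - env$spec$resolution / 2, Inf))
  ii[ii < 1 | ii > length(env$lat)] <- NA
  jj[jj < 1 | jj > length(env$lon)] <- NA
  pick <- function(M, i, j) ifelse(is.na(i) | is.na(j), NA_real_,
                                   M[cbind(pmin(i, nrow(M)), pmin(j, ncol(M)))])
  if (var == "depth") return(pick(env$depth, ii, jj))
  if (var == "ice") {
    stopifnot(!is.null(month))
    month <- rep_len(month, length(lon))
    out <- numeric(length(lon))
    for (m in unique(month)) {
      s <- month == m
      out[s] <- pick(env$ice_monthly[[m]], ii[s], jj[s])
    }
    return(out)
  }
  if (var == "sst") {
    stopifnot(!is.null(week), !is.null(month))
    week <- rep_len(week, length(lon)); month <- rep_len(month, length(lon))
    out <- rep(NA_real_, length(lon))
    for (w in unique(week)) {
      s <- week == w
      sl <- if (w >= 1 && w <= length(env$sst_weekly)) env$sst_weekly[[w]] else NULL
      if (is.null(sl)) {
        for (m in unique(month[s])) {
          sm <- s & month == m
          out[sm] <- pick(env$sst_monthly[[m]], ii[sm], jj[sm])
        }
      } else out[s] <- pick(sl, ii[s], jj[s])
    }
    return(out)
  }
  stop("unknown variable: ", var)
}
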