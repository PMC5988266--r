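# Bayesian posterior over the movement path: twilight-time likelihood,
# log-normal swim-speed prior, known-location fixes, and a vectorized
# Metropolis-within-Gibbs sampler with alternating forward/backward
# sweeps (red-black updating: locations of one parity are
# conditionally independent given the other). Downstream: intermediate
# locations and time-spent density grids.

#' Log-normal swim-speed prior
#'
#' Parameterized by the arithmetic mean and SD of speed on the km/h
#' scale (defaults 1.0 and 0.9, the values used for the tracked seals);
#' the log-scale parameters are derived internally.
#'
#' @param mean_speed,speed_sd Arithmetic mean and SD, km/h (> 0).
#' @return list of class `movement_prior` with `meanlog`, `sdlog`.
#' @export
movement_prior <- function(mean_speed = 1.0, speed_sd = 0.9) {
  stopifnot(mean_speed > 0, speed_sd > 0)
  lp <- lnorm_pars(mean_speed, speed_sd)
  structure(list(mean_speed = mean_speed, speed_sd = speed_sd,
                 meanlog = lp$meanlog, sdlog = lp$sdlog),
            class = "movement_prior")
}

#' Twilight-time error model
#'
#' Shifted log-normal on minutes: a sunrise is observed late and a
#' sunset early by `e` minutes where `e + shift` is log-normal with
#' median `scale` minutes, reflecting the one-sided bias that sensor
#' shading can only delay dawns and advance dusks. Equinox-flagged
#' twilights have `sdlog` multiplied by `equinox_inflation`.
#'
#' @param scale Median of the shifted error, minutes (> 0).
#' @param shift Allowed early margin, minutes.
#' @param sdlog Log-scale SD of the error law.
#' @param equinox_inflation Multiplier on `sdlog` near equinoxes.
#' @return list of class `twilight_error_model`.
#' @export
twilight_error_model <- function(scale = 8, shift = 2, sdlog = 0.6,
                                 equinox_inflation = 3) {
  stopifnot(scale > 0, sdlog > 0, equinox_inflation >= 1)
  structure(list(scale = scale, shift = shift, sdlog = sdlog,
                 equinox_inflation = equinox_inflation),
            class = "twilight_error_model")
}

#' Log-density of a speed under the movement prior
#'
#' Log-normal log-density of the great-circle speed implied by moving
#' between two locations in `dt_h` hours. Zero distances are floored at
#' 1e-8 km/h, the log-normal's limiting (vanishing) density as speed
#' approaches zero from above.
#'
#' @param loc_a,loc_b Two-column matrices (lon, lat) or length-2
#'   vectors.
#' @param dt_h Elapsed hours (> 0).
#' @param prior A [movement_prior()].
#' @return Log-density vector.
#' @export
speed_log_prior <- function(loc_a, loc_b, dt_h, prior) {
  stopifnot(all(dt_h > 0))
  a <- matrix(loc_a, ncol = 2); b <- matrix(loc_b, ncol = 2)
  sp <- haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]) / dt_h
  stats::dlnorm(pmax(sp, 1e-8), prior$meanlog, prior$sdlog, log = TRUE)
}

# Movement term used inside the MCMC target. A pairwise factor equal to
# the log-normal speed density *as a density in 2D position space*
# would induce step speeds distributed like s * dlnorm(s) (the polar
# area element contributes a factor s), inflating the induced mean
# speed to (mean^2 + sd^2)/mean. Dividing by the speed (subtracting
# log s) makes the induced distribution of implied speeds exactly the
# stated log-normal.
.step_log_prior <- function(lon_a, lat_a, lon_b, lat_b, dt_h, prior) {
  sp <- pmax(haversine_km(lon_a, lat_a, lon_b, lat_b) / dt_h, 1e-8)
  stats::dlnorm(sp, prior$meanlog, prior$sdlog, log = TRUE) - log(sp)
}

#' Precompute per-twilight solar quantities
#'
#' Caches, per twilight, the civil-day origin, the observed minute of
#' day, the solar declination and equation of time at the observed
#' time, and the equinox flag (|declination| < 4 degrees). With these
#' cached, the predicted twilight time at any trial location reduces to
#' closed-form trigonometry, which keeps the MCMC likelihood cheap.
#'
#' @param twilights data.frame(`time`, `rise`) (quality-filtered).
#' @param zenith_deg Calibrated twilight zenith, degrees.
#' @return data.frame used by [twilight_log_likelihood()].
#' @export
prepare_twilights <- function(twilights, zenith_deg) {
  eph <- solar_ephemeris(twilights$time)
  day0 <- as.numeric(trunc(twilights$time, "days"))
  data.frame(time = twilights$time, rise = twilights$rise,
             obs_min = (as.numeric(twilights$time) - day0) / 60,
             declination = eph$declination, eqtime = eph$eqtime,
             equinox = abs(eph$declination) < 4,
             zenith_deg = zenith_deg)
}

# predicted minute-of-day of each prepared twilight at (lon, lat);
# NA where the sun never crosses the zenith (polar day/night)
.predicted_minute <- function(prep, lon, lat) {
  num <- cos(.deg2rad(prep$zenith_deg)) -
    sin(.deg2rad(lat)) * sin(.deg2rad(prep$declination))
  den <- cos(.deg2rad(lat)) * cos(.deg2rad(prep$declination))
  arg <- num / den
  half_min <- 4 * .rad2deg(acos(pmin(1, pmax(-1, arg))))  # half daylength, min
  half_min[arg < -1 | arg > 1] <- NA_real_
  noon <- 720 - 4 * lon - prep$eqtime
  ifelse(prep$rise, noon - half_min, noon + half_min)
}

#' Twilight-time log-likelihood at trial locations
#'
#' Log-density of the observed twilight times given candidate
#' locations, under the shifted log-normal error model. Returns `-Inf`
#' where the location is in polar day or night at that date (no finite
#' predicted twilight) or where the signed error falls below `-shift`.
#'
#' @param prep data.frame from [prepare_twilights()] (or a
#'   data.frame(`time`, `rise`) plus `zenith_deg`).
#' @param lon,lat Candidate coordinates, recycled against `prep` rows.
#' @param err A [twilight_error_model()].
#' @param zenith_deg Needed only when `prep` is an unprepared twilight
#'   data.frame.
#' @param soft Logical. With the default `FALSE`, geometry outside the
#'   error law's support (polar day/night, or a predicted twilight
#'   later than an observed dawn can allow) returns `-Inf`. With
#'   `TRUE`, those regions instead return a steep finite penalty that
#'   decreases linearly with the size of the violation; the sampler
#'   uses this so that a chain started in an infeasible region is
#'   pulled back towards the support instead of being absorbed.
#' @return Log-likelihood vector, one element per twilight row.
#' @export
twilight_log_likelihood <- function(prep, lon, lat, err, zenith_deg = NULL,
                                    soft = FALSE) {
  if (is.null(prep$obs_min)) {
    if (is.null(zenith_deg)) stop("zenith_deg required for raw twilights")
    prep <- prepare_twilights(prep, zenith_deg)
  }
  n <- max(nrow(prep), length(lon), length(lat))
  prep <- prep[rep_len(seq_len(nrow(prep)), n), , drop = FALSE]
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  num <- cos(.deg2rad(prep$zenith_deg)) -
    sin(.deg2rad(lat)) * sin(.deg2rad(prep$declination))
  den <- cos(.deg2rad(lat)) * cos(.deg2rad(prep$declination))
  arg <- num / den
  half_min <- 4 * .rad2deg(acos(pmin(1, pmax(-1, arg))))
  polar <- arg < -1 | arg > 1
  noon <- 720 - 4 * lon - prep$eqtime
  pm <- ifelse(prep$rise, noon - half_min, noon + half_min)
  resid <- prep$obs_min - pm
  resid <- ((resid + 720) %% 1440) - 720     # wrap to (-720, 720]
  e <- ifelse(prep$rise, resid, -resid)      # late dawn / early dusk positive
  x <- e + err$shift
  sdl <- ifelse(prep$equinox, err$sdlog * err$equinox_inflation, err$sdlog)
  out <- rep(-Inf, length(x))
  ok <- !polar & !is.na(x) & x > 0
  out[ok] <- stats::dlnorm(x[ok], log(err$scale), sdl[ok], log = TRUE)
  if (soft) {
    x0 <- 0.1
    edge <- stats::dlnorm(x0, log(err$scale), sdl, log = TRUE)
    bad <- !polar & !is.na(x) & x <= 0
    out[bad] <- edge[bad] - 0.5 * (x0 - x[bad])
    # polar: penalty grows with the cosine-argument overshoot
    over <- pmax(arg - 1, -1 - arg)
    out[polar] <- -1000 - 1000 * pmin(2, over[polar])
  }
  out
}

#' Render noisy twilights along a track
#'
#' Ground-truth twilight times are computed at the track position
#' interpolated to each event, then perturbed with draws from the
#' twilight error model (late dawns, early dusks). Used to build
#' synthetic fixtures for the track posterior.
#'
#' @param track data.frame(`time`, `lon`, `lat`).
#' @param zenith_deg Twilight zenith angle.
#' @param err A [twilight_error_model()]; `NULL` for noiseless.
#' @param seed RNG seed.
#' @return data.frame(`time`, `rise`, `quality`) plus attribute
#'   `true_times`.
#' @export
render_twilights <- function(track, zenith_deg = 96, err = NULL, seed = 1L) {
  days <- seq(as.POSIXct(trunc(track$time[1], "days"), tz = "UTC"),
              track$time[nrow(track)], by = "1 day")
  tt <- as.numeric(track$time)
  out <- list()
  for (rise in c(TRUE, FALSE)) {
    ev <- days + 12 * 3600
    for (pass in 1:2) {
      at <- ifelse(is.na(ev), as.numeric(days) + 43200, as.numeric(ev))
      lon <- stats::approx(tt, track$lon, at, rule = 2)$y
      lat <- stats::approx(tt, track$lat, at, rule = 2)$y
      ev <- predict_twilight(days, lon, lat, zenith_deg, rise)
    }
    keep <- !is.na(ev) & as.numeric(ev) >= tt[1] &
      as.numeric(ev) <= tt[length(tt)]
    out[[length(out) + 1]] <- data.frame(true_time = ev[keep], rise = rise)
  }
  tw <- do.call(rbind, out)
  tw <- tw[order(tw$true_time), ]
  obs <- tw$true_time
  if (!is.null(err)) {
    obs <- with_seed(seed, {
      e <- stats::rlnorm(nrow(tw), log(err$scale), err$sdlog) - err$shift
      tw$true_time + ifelse(tw$rise, 60 * e, -60 * e)
    })
  }
  res <- data.frame(time = obs, rise = tw$rise, quality = "ok")
  attr(res, "true_times") <- tw$true_time
  res
}

#' Initial feasible path for the track posterior
#'
#' Per-day threshold positions from rise/set pairs, overlaid with
#' known-location fixes, gaps (polar periods, equinox-degenerate
#' latitudes, missing twilights) filled by linear interpolation in
#' time, then iteratively speed-capped so the movement prior assigns
#' finite density everywhere.
#'
#' @param twilights data.frame(`time`, `rise`) (quality-filtered).
#' @param fixes Optional data.frame(`time`, `lon`, `lat`) of known
#'   locations (e.g. days the animal was observed at the deployment
#'   site).
#' @param prior A [movement_prior()].
#' @param zenith_deg Calibrated zenith.
#' @return data.frame(`time`, `lon`, `lat`, `fixed`).
#' @export
initial_path <- function(twilights, fixes = NULL, prior = movement_prior(),
                         zenith_deg = 96) {
  if (nrow(twilights) < 2 && (is.null(fixes) || nrow(fixes) < 1))
    stop("need at least two twilights or one fix")
  n <- nrow(twilights)
  lon <- rep(NA_real_, n); lat <- rep(NA_real_, n)
  day <- as.Date(trunc(twilights$time, "days"))
  ref <- if (!is.null(fixes) && nrow(fixes)) fixes$lat[1] else NULL
  for (d in unique(day)) {
    idx <- which(day == d)
    r <- idx[twilights$rise[idx]][1]
    s <- idx[!twilights$rise[idx]]
    s <- s[s > r][1]
    if (is.na(r) || is.na(s)) next
    pos <- threshold_position(twilights$time[r], twilights$time[s],
                              zenith_deg, ref_lat = ref)
    lon[idx] <- pos$lon
    if (!is.na(pos$lat) && pos$lat_quality == "ok") {
      lat[idx] <- pos$lat
      ref <- pos$lat      # track the hemisphere along the record
    }
  }
  # discard residual gross latitude outliers before interpolation
  if (sum(!is.na(lat)) >= 9) {
    med <- stats::runmed(lat[!is.na(lat)], 9, endrule = "median")
    out <- abs(lat[!is.na(lat)] - med) > 10
    lat[!is.na(lat)][out] <- NA
  }
  fixed <- rep(FALSE, n)
  if (!is.null(fixes) && nrow(fixes)) {
    fday <- as.Date(trunc(as.POSIXct(fixes$time, tz = "UTC"), "days"))
    for (k in seq_len(nrow(fixes))) {
      idx <- which(day == fday[k])
      lon[idx] <- fixes$lon[k]; lat[idx] <- fixes$lat[k]
      fixed[idx] <- TRUE
    }
  }
  tt <- as.numeric(twilights$time)
  fill <- function(v) {
    if (all(is.na(v))) stop("no finite positions available for initial path")
    if (anyNA(v)) stats::approx(tt[!is.na(v)], v[!is.na(v)], tt, rule = 2)$y
    else v
  }
  lon <- fill(lon); lat <- fill(lat)
  # robust-smooth the raw threshold positions: per-twilight positions
  # carry degrees of noise (and occasional gross latitude outliers), and
  # starting the sampler on a jittery path leaves it far from the
  # posterior bulk
  if (n >= 9) {
    smooth1 <- function(v) {
      v <- stats::runmed(v, 9, endrule = "median")
      sm <- stats::filter(v, rep(1 / 7, 7), sides = 2)
      sm[is.na(sm)] <- v[is.na(sm)]
      as.numeric(sm)
    }
    lon <- ifelse(fixed, lon, smooth1(lon))
    lat <- ifelse(fixed, lat, smooth1(lat))
  }
  # speed capping: pull free locations toward neighbour midpoints until
  # the mean implied speed is at or below the prior mean. Starting the
  # sampler slightly smoother than the posterior bulk is deliberate:
  # local moves re-add small-scale wiggle quickly, whereas removing
  # large-scale jitter is the sampler's slowest direction.
  cap <- stats::qlnorm(0.95, prior$meanlog, prior$sdlog)
  dt <- pmax(diff(tt) / 3600, 1e-6)
  for (pass in 1:1000) {
    sp <- haversine_km(lon[-n], lat[-n], lon[-1], lat[-1]) / dt
    if (mean(sp) <= prior$mean_speed && max(sp) <= cap) break
    pull <- unique(pmin(n - 1, c(which(sp > cap) + 1L,
                                 if (mean(sp) > prior$mean_speed)
                                   2:(n - 1L))))
    for (i in pull) {
      if (fixed[i]) next
      j0 <- max(1, i - 1); j1 <- min(n, i + 1)
      lon[i] <- 0.7 * lon[i] + 0.15 * (lon[j0] + lon[j1])
      lat[i] <- 0.7 * lat[i] + 0.15 * (lat[j0] + lat[j1])
    }
  }
  data.frame(time = twilights$time, lon = lon, lat = lat, fixed = fixed)
}

#' Sample the movement-path posterior by MCMC
#'
#' Metropolis-within-Gibbs over per-twilight locations. Locations of
#' one parity are conditionally independent given the other, so each
#' pass makes two vectorized half-updates; passes alternate
#' forward (odd-first) and backward (even-first) sweep order. Proposals
#' are per-location bivariate Gaussians in km whose scales adapt during
#' burn-in to target 20--40% acceptance. Fixed locations are never
#' proposed. Chains are deterministic given `seed`.
#'
#' @param twilights data.frame(`time`, `rise`), quality-filtered and
#'   time-sorted.
#' @param fixes Optional data.frame(`time`, `lon`, `lat`).
#' @param prior A [movement_prior()].
#' @param err A [twilight_error_model()].
#' @param zenith_deg Calibrated zenith angle.
#' @param n_chains,n_iter,burn_in Chains, iterations per chain, and
#'   burn-in fraction.
#' @param thin Keep every `thin`-th post-burn-in iteration (default:
#'   at most 200 retained samples per chain).
#' @param seed Integer seed; chain c uses `seed + c - 1`.
#' @param init Optional initial path (default [initial_path()]).
#' @param proposal_km Initial proposal SD, km.
#' @return Object of class `posterior_chains`: per-chain arrays of
#'   sampled `lon`/`lat` (samples x locations), `times`, `fixed` mask,
#'   acceptance rates and the model ingredients.
#' @export
sample_posterior <- function(twilights, fixes = NULL,
                             prior = movement_prior(),
                             err = twilight_error_model(),
                             zenith_deg = 96,
                             n_chains = 4, n_iter = 2000, burn_in = 0.5,
                             thin = NULL, seed = 1L, init = NULL,
                             proposal_km = 30) {
  prep <- prepare_twilights(twilights, zenith_deg)
  n <- nrow(prep)
  if (is.null(init)) init <- initial_path(twilights, fixes, prior, zenith_deg)
  stopifnot(nrow(init) == n)
  fixed <- init$fixed
  tt <- as.numeric(twilights$time)
  dt <- pmax(diff(tt) / 3600, 1e-6)
  n_burn <- floor(n_iter * burn_in)
  n_keep_iter <- n_iter - n_burn
  if (is.null(thin)) thin <- max(1L, floor(n_keep_iter / 200))
  keep_at <- seq(n_burn + thin, n_iter, by = thin)
  ll_obs <- function(lon, lat, idx) {
    twilight_log_likelihood(prep[idx, , drop = FALSE], lon, lat, err,
                            soft = TRUE)
  }
  chains <- vector("list", n_chains)
  acc_all <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- with_seed(seed + ch - 1L, {
      lon <- init$lon + ifelse(fixed, 0, stats::rnorm(n, 0, 0.05))
      lat <- init$lat + ifelse(fixed, 0, stats::rnorm(n, 0, 0.05))
      ll <- ll_obs(lon, lat, seq_len(n))
      ll[fixed] <- 0   # fixes carry no twilight term
      sc <- rep(proposal_km, n)
      acc_n <- rep(0, n); acc_d <- rep(0, n)
      bsc <- proposal_km           # block-translation proposal scale, km
      bacc_n <- 0; bacc_d <- 0
      keep_lon <- matrix(NA_real_, length(keep_at), n)
      keep_lat <- matrix(NA_real_, length(keep_at), n)
      krow <- 0L
      parities <- list(which(seq_len(n) %% 2 == 1L & !fixed),
                       which(seq_len(n) %% 2 == 0L & !fixed))
      for (it in seq_len(n_iter)) {
        ord <- if (it %% 2 == 1L) 1:2 else 2:1  # forward / backward sweep
        for (pp in ord) {
          idx <- parities[[pp]]
          if (!length(idx)) next
          dlat <- stats::rnorm(length(idx), 0, sc[idx]) / 111.32
          dlon <- stats::rnorm(length(idx), 0, sc[idx]) /
            (111.32 * pmax(0.1, cos(.deg2rad(lat[idx]))))
          plon <- wrap_lon(lon[idx] + dlon)
          plat <- pmin(89.5, pmax(-89.5, lat[idx] + dlat))
          new_ll <- ll_obs(plon, plat, idx)
          delta <- new_ll - ll[idx]
          # movement terms to both neighbours
          im <- idx - 1L; ip <- idx + 1L
          has_m <- im >= 1L; has_p <- ip <= n
          if (any(has_m)) {
            d_old <- .step_log_prior(lon[im[has_m]], lat[im[has_m]],
                                     lon[idx[has_m]], lat[idx[has_m]],
                                     dt[im[has_m]], prior)
            d_new <- .step_log_prior(lon[im[has_m]], lat[im[has_m]],
                                     plon[has_m], plat[has_m],
                                     dt[im[has_m]], prior)
            delta[has_m] <- delta[has_m] + d_new - d_old
          }
          if (any(has_p)) {
            d_old <- .step_log_prior(lon[idx[has_p]], lat[idx[has_p]],
                                     lon[ip[has_p]], lat[ip[has_p]],
                                     dt[idx[has_p]], prior)
            d_new <- .step_log_prior(plon[has_p], plat[has_p],
                                     lon[ip[has_p]], lat[ip[has_p]],
                                     dt[idx[has_p]], prior)
            delta[has_p] <- delta[has_p] + d_new - d_old
          }
          acc <- log(stats::runif(length(idx))) < delta
          acc[!is.finite(delta)] <- FALSE
          w <- idx[acc]
          lon[w] <- plon[acc]; lat[w] <- plat[acc]; ll[w] <- new_ll[acc]
          acc_n[idx] <- acc_n[idx] + acc; acc_d[idx] <- acc_d[idx] + 1
        }
        # block translation: shift a contiguous free segment by one
        # common offset; relaxes the long-wavelength (ridge) modes that
        # single-site moves only reach diffusively
        for (bm in seq_len(max(1L, n %/% 50))) {
          a <- sample.int(n, 1L)
          len <- 1L + stats::rgeom(1, 1 / 25)
          seg <- a:min(n, a + len)
          if (any(fixed[seg])) {
            stopb <- which(fixed[seg])[1]
            if (stopb == 1L) next
            seg <- seg[seq_len(stopb - 1L)]
          }
          a <- seg[1]; b <- seg[length(seg)]
          dla <- stats::rnorm(1, 0, bsc) / 111.32
          dlo <- stats::rnorm(1, 0, bsc) /
            (111.32 * pmax(0.1, cos(.deg2rad(mean(lat[seg])))))
          plon <- wrap_lon(lon[seg] + dlo)
          plat <- pmin(89.5, pmax(-89.5, lat[seg] + dla))
          new_ll <- ll_obs(plon, plat, seg)
          e0 <- max(1L, a - 1L); e1 <- min(n - 1L, b)
          lon2 <- lon; lat2 <- lat
          lon2[seg] <- plon; lat2[seg] <- plat
          d_old <- .step_log_prior(lon[e0:e1], lat[e0:e1],
                                   lon[e0:e1 + 1L], lat[e0:e1 + 1L],
                                   dt[e0:e1], prior)
          d_new <- .step_log_prior(lon2[e0:e1], lat2[e0:e1],
                                   lon2[e0:e1 + 1L], lat2[e0:e1 + 1L],
                                   dt[e0:e1], prior)
          delta <- sum(new_ll - ll[seg]) + sum(d_new - d_old)
          bacc_d <- bacc_d + 1
          if (is.finite(delta) && log(stats::runif(1)) < delta) {
            lon[seg] <- plon; lat[seg] <- plat; ll[seg] <- new_ll
            bacc_n <- bacc_n + 1
          }
        }
        if (it <= n_burn && it %% 50 == 0) {
          rate <- ifelse(acc_d > 0, acc_n / acc_d, 0.3)
          sc <- pmin(500, pmax(0.5, sc * exp(0.8 * (rate - 0.3))))
          acc_n[] <- 0; acc_d[] <- 0
          brate <- if (bacc_d > 0) bacc_n / bacc_d else 0.25
          bsc <- min(500, max(0.5, bsc * exp(0.8 * (brate - 0.25))))
          bacc_n <- 0; bacc_d <- 0
        }
        if (krow < length(keep_at) && it == keep_at[krow + 1L]) {
          krow <- krow + 1L
          keep_lon[krow, ] <- lon; keep_lat[krow, ] <- lat
        }
      }
      list(lon = keep_lon, lat = keep_lat,
           acceptance = mean(acc_n / pmax(1, acc_d)))
    })
    acc_all[ch] <- chains[[ch]]$acceptance
  }
  structure(list(chains = chains, times = twilights$time, fixed = fixed,
                 prep = prep, prior = prior, err = err,
                 zenith_deg = zenith_deg,
                 acceptance = acc_all,
                 n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = seed),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf(
    "Track posterior: %d chains x %d retained samples over %d locations (%d fixed)\n",
    length(x$chains), nrow(x$chains[[1]]$lon), length(x$times),
    sum(x$fixed)))
  cat(sprintf("post-burn-in acceptance: %s\n",
              paste(sprintf("%.2f", x$acceptance), collapse = " ")))
  invisible(x)
}

#' Posterior mean path
#'
#' @param chains A `posterior_chains` object.
#' @return data.frame(`time`, `lon`, `lat`).
#' @export
posterior_mean_path <- function(chains) {
  lon <- Reduce(`+`, lapply(chains$chains, function(c) colMeans(c$lon))) /
    length(chains$chains)
  lat <- Reduce(`+`, lapply(chains$chains, function(c) colMeans(c$lat))) /
    length(chains$chains)
  data.frame(time = chains$times, lon = lon, lat = lat)
}

#' Posterior distribution of implied step speeds
#'
#' Great-circle step speeds for every retained sample path.
#'
#' @param chains A `posterior_chains` object.
#' @return list: `mean` (posterior-mean speed, km/h over all steps and
#'   samples), `by_step` (posterior-mean speed per step).
#' @export
posterior_speeds <- function(chains) {
  tt <- as.numeric(chains$times)
  dt <- pmax(diff(tt) / 3600, 1e-6)
  n <- length(tt)
  acc <- NULL
  for (c in chains$chains) {
    sp <- haversine_km(c$lon[, -n, drop = FALSE], c$lat[, -n, drop = FALSE],
                       c$lon[, -1, drop = FALSE], c$lat[, -1, drop = FALSE]) /
      rep(dt, each = nrow(c$lon))
    sp <- matrix(sp, nrow = nrow(c$lon))
    acc <- if (is.null(acc)) sp else rbind(acc, sp)
  }
  list(mean = mean(acc), by_step = colMeans(acc))
}

#' Identify and pin polar-day gaps
#'
#' Finds maximal runs of civil days with no usable twilight (24-h
#' daylight at the animal's latitude, when light-based positioning is
#' impossible). For downstream covariate extraction the location
#' during each run is pinned to the last estimated position before the
#' run (or the first after it, for a gap at the start of the record).
#'
#' @param twilights data.frame(`time`, ...) of usable twilights.
#' @param span POSIXct length-2 deployment span.
#' @param min_gap_days Runs shorter than this are ignored.
#' @return data.frame(`start`, `end`, `duration_days`) of gaps. `start`
#'   is the first day without twilights and `end` the day they resume
#'   (exclusive), so `duration_days = end - start` counts the days of
#'   24-h daylight.
#' @export
handle_polar_day <- function(twilights, span, min_gap_days = 2) {
  d0 <- as.Date(as.POSIXct(span[1], tz = "UTC"))
  d1 <- as.Date(as.POSIXct(span[2], tz = "UTC"))
  all_days <- seq(d0, d1, by = "1 day")
  has_tw <- all_days %in% as.Date(trunc(twilights$time, "days"))
  r <- rle(!has_tw)
  ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
  gaps <- which(r$values)
  out <- data.frame(
    start = all_days[starts[gaps]],
    end = c(all_days, d1 + 1)[ends[gaps] + 1L])
  out$duration_days <- as.numeric(out$end - out$start)
  out[out$duration_days >= min_gap_days, , drop = FALSE]
}

#' Pin a path through polar-day gaps
#'
#' @param path data.frame(`time`, `lon`, `lat`).
#' @param gaps data.frame from [handle_polar_day()].
#' @return `path` with locations inside each gap replaced by the last
#'   position before the gap (or the first after, at the record start).
#' @export
pin_path <- function(path, gaps) {
  if (!nrow(gaps)) return(path)
  tt <- as.Date(trunc(path$time, "days"))
  for (g in seq_len(nrow(gaps))) {
    inside <- tt >= gaps$start[g] & tt < gaps$end[g]
    before <- which(tt < gaps$start[g])
    anchor <- if (length(before)) max(before) else min(which(!inside))
    path$lon[inside] <- path$lon[anchor]
    path$lat[inside] <- path$lat[anchor]
  }
  path
}

#' Densify sampled paths to intermediate locations
#'
#' Great-circle interpolated points between successive primary
#' locations of one sampled path: `k` points per segment at fractions
#' 1/(k+1), ..., k/(k+1), each weighted by `dt/k` hours so the weights
#' of a segment sum to its duration.
#'
#' @param lon,lat One sampled path (numeric vectors).
#' @param times POSIXct primary times.
#' @param k Points per segment (k = 1 gives midpoints).
#' @return data.frame(`lon`, `lat`, `weight_h`).
#' @export
intermediate_locations <- function(lon, lat, times, k = 10) {
  n <- length(lon)
  tt <- as.numeric(times)
  f <- seq_len(k) / (k + 1)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    p <- gc_interpolate(lon[i], lat[i], lon[i + 1], lat[i + 1], f)
    p$weight_h <- ((tt[i + 1] - tt[i]) / 3600) / k
    out[[i]] <- p
  }
  do.call(rbind, out)
}

#' Time-spent density grid from the track posterior
#'
#' Repeatedly draws sampled paths from the chains, densifies each to
#' intermediate locations weighted by elapsed time, and accumulates
#' the weights on a lon/lat grid. The mean grid is normalized to total
#' mass 1; per-cell quantiles across simulations summarize the spread.
#'
#' @param chains A `posterior_chains` object.
#' @param grid_spec list(`lon_range`, `lat_range`, `resolution`).
#' @param n_simulations Number of sampled paths (default 1000).
#' @param k Intermediate points per segment.
#' @param quantiles Per-cell quantile levels.
#' @param max_quantile_sims Simulated grids retained for the quantile
#'   computation.
#' @return Object of class `time_spent_grid`: `density` (\[lat, lon\]
#'   matrix summing to 1), `lon`, `lat`, `quantiles` (array), counts of
#'   clipped points.
#' @export
time_spent_grid <- function(chains, grid_spec, n_simulations = 1000,
                            k = 10, quantiles = c(0.025, 0.5, 0.975),
                            max_quantile_sims = 200) {
  lon_g <- seq(grid_spec$lon_range[1], grid_spec$lon_range[2],
               by = grid_spec$resolution)
  lat_g <- seq(grid_spec$lat_range[1], grid_spec$lat_range[2],
               by = grid_spec$resolution)
  nlon <- length(lon_g) - 1L; nlat <- length(lat_g) - 1L
  total <- matrix(0, nlat, nlon)
  keep <- min(n_simulations, max_quantile_sims)
  stash <- array(NA_real_, c(keep, nlat, nlon))
  n_ch <- length(chains$chains); n_s <- nrow(chains$chains[[1]]$lon)
  clipped <- 0L
  for (s in seq_len(n_simulations)) {
    ch <- ((s - 1L) %% n_ch) + 1L
    row <- ((s - 1L) %/% n_ch) %% n_s + 1L
    cc <- chains$chains[[ch]]
    dp <- intermediate_locations(cc$lon[row, ], cc$lat[row, ],
                                 chains$times, k)
    i <- findInterval(dp$lat, lat_g, rightmost.closed = TRUE)
    j <- findInterval(dp$lon, lon_g, rightmost.closed = TRUE)
    ok <- i >= 1 & i <= nlat & j >= 1 & j <= nlon
    clipped <- clipped + sum(!ok)
    g <- matrix(0, nlat, nlon)
    if (any(ok)) {
      tb <- tapply(dp$weight_h[ok], list(i[ok], j[ok]), sum)
      g[cbind(as.integer(rownames(tb))[row(tb)[!is.na(tb)]],
              as.integer(colnames(tb))[col(tb)[!is.na(tb)]])] <- tb[!is.na(tb)]
    }
    total <- total + g
    if (s <= keep) stash[s, , ] <- g / max(1e-12, sum(g))
  }
  if (clipped > 0)
    message(sprintf("time_spent_grid: %d intermediate points fell outside the grid",
                    clipped))
  q <- apply(stash, c(2, 3), stats::quantile, probs = quantiles, na.rm = TRUE)
  structure(list(density = total / sum(total),
                 lon = lon_g, lat = lat_g,
                 quantiles = q, quantile_levels = quantiles,
                 n_simulations = n_simulations, clipped = clipped),
            class = "time_spent_grid")
}
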