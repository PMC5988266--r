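# Use-availability habitat association: correlated-random-walk null
# tracks that preserve the observed step-length distribution, covariate
# extraction with posterior-uncertainty propagation (chain means), and
# the candidate-model ladder fitted with the penalized additive engine.

#' Habitat-analysis configuration
#'
#' @param n_use_chains MCMC chains averaged per time interval when
#'   extracting covariates at used locations (default 100).
#' @param n_null_runs Independent null-model tracks (default 10).
#' @param covariates Covariates to extract.
#' @return list of class `habitat_config`.
#' @export
habitat_config <- function(n_use_chains = 100, n_null_runs = 10,
                           covariates = c("depth", "sst", "ice")) {
  stopifnot(n_use_chains >= 1, n_null_runs >= 1)
  structure(list(n_use_chains = n_use_chains, n_null_runs = n_null_runs,
                 covariates = covariates), class = "habitat_config")
}

#' Correlated-random-walk null tracks
#'
#' Availability model for the use-availability design: each null track
#' starts at the source track's start, reuses its time stamps, and
#' takes the same number of steps with lengths resampled with
#' replacement from the source's step lengths. Headings are uniform
#' except for a weak drift toward the source's mean displacement
#' bearing, honouring the source's mean trajectory.
#'
#' @param track data.frame(`time`, `lon`, `lat`) — typically the
#'   posterior mean path.
#' @param n_runs Number of null tracks (default 10).
#' @param drift_weight Probability a step heads along the mean
#'   displacement bearing (with 30-degree noise) instead of uniformly.
#' @param seed RNG seed.
#' @return list of `n_runs` data.frames shaped like `track`.
#' @export
simulate_crw <- function(track, n_runs = 10, drift_weight = 0.2, seed = 1L) {
  n <- nrow(track)
  if (n < 11) stop("source track must have at least 10 steps")
  steps <- haversine_km(track$lon[-n], track$lat[-n],
                        track$lon[-1], track$lat[-1])
  if (all(steps < 1e-9)) stop("source track is degenerate (zero steps)")
  mean_bearing <- bearing_deg(track$lon[1], track$lat[1],
                              track$lon[n], track$lat[n])
  with_seed(seed, {
    lapply(seq_len(n_runs), function(run) {
      len <- sample(steps, n - 1, replace = TRUE)
      drift <- stats::runif(n - 1) < drift_weight
      head <- ifelse(drift,
                     mean_bearing + stats::rnorm(n - 1, 0, 30),
                     stats::runif(n - 1, 0, 360))
      lon <- numeric(n); lat <- numeric(n)
      lon[1] <- track$lon[1]; lat[1] <- track$lat[1]
      for (i in seq_len(n - 1)) {
        p <- destination_point(lon[i], lat[i], head[i], len[i])
        lon[i + 1] <- p$lon; lat[i + 1] <- p$lat
      }
      data.frame(time = track$time, lon = lon, lat = lat)
    })
  })
}

#' Build the use-availability table
#'
#' Use rows: for each time interval, each covariate is the mean of its
#' values at `n_use_chains` posterior location samples, propagating
#' location uncertainty. Null rows: covariates at the null-track
#' locations. SST comes from the weekly slice with monthly fallback;
#' intervals when the animal was hauled out on land are discarded; rows
#' with any non-finite covariate are dropped with a message.
#'
#' @param chains A `posterior_chains` object.
#' @param null_tracks List from [simulate_crw()].
#' @param env An `env_grids` object.
#' @param haulout_states Optional data.frame(`hour_start`, `state`)
#'   from [hourly_states()]; intervals overlapping a haul-out hour on
#'   land are dropped from the use rows.
#' @param config A [habitat_config()].
#' @return data.frame of class `use_avail_table`: `time`, `response`
#'   (1 use / 0 null), `depth`, `sst`, `ice`, `source_run`.
#' @export
extract_covariates <- function(chains, null_tracks, env,
                               haulout_states = NULL,
                               config = habitat_config()) {
  times <- chains$times
  n <- length(times)
  wk <- as.integer(strftime(times, "%V"))
  mo <- as.integer(strftime(times, "%m"))
  n_ch <- length(chains$chains)
  n_s <- nrow(chains$chains[[1]]$lon)
  take <- min(config$n_use_chains, n_ch * n_s)
  lon_s <- matrix(NA_real_, take, n); lat_s <- matrix(NA_real_, take, n)
  for (s in seq_len(take)) {
    ch <- ((s - 1L) %% n_ch) + 1L
    row <- ((s - 1L) %/% n_ch) %% n_s + 1L
    lon_s[s, ] <- chains$chains[[ch]]$lon[row, ]
    lat_s[s, ] <- chains$chains[[ch]]$lat[row, ]
  }
  cov_at <- function(lon, lat, wk, mo) {
    data.frame(
      depth = env_extract(env, "depth", lon, lat),
      sst = env_extract(env, "sst", lon, lat, week = wk, month = mo),
      ice = env_extract(env, "ice", lon, lat, month = mo))
  }
  use <- data.frame(time = times, response = 1L,
                    depth = NA_real_, sst = NA_real_, ice = NA_real_,
                    source_run = 0L)
  for (i in seq_len(n)) {
    cv <- cov_at(lon_s[, i], lat_s[, i], wk[i], mo[i])
    use$depth[i] <- mean(cv$depth, na.rm = TRUE)
    use$sst[i] <- mean(cv$sst, na.rm = TRUE)
    use$ice[i] <- mean(cv$ice, na.rm = TRUE)
  }
  if (!is.null(haulout_states) && nrow(haulout_states)) {
    ho <- haulout_states$hour_start[haulout_states$state == 1]
    if (length(ho)) {
      hr <- as.POSIXct(trunc(times, "hours"), tz = "UTC")
      use <- use[!(hr %in% ho), , drop = FALSE]
    }
  }
  nulls <- lapply(seq_along(null_tracks), function(r) {
    nt <- null_tracks[[r]]
    wkr <- as.integer(strftime(nt$time, "%V"))
    mor <- as.integer(strftime(nt$time, "%m"))
    cv <- cov_at(nt$lon, nt$lat, wkr, mor)
    data.frame(time = nt$time, response = 0L, depth = cv$depth,
               sst = cv$sst, ice = cv$ice, source_run = r)
  })
  out <- rbind(use, do.call(rbind, nulls))
  bad <- !stats::complete.cases(out[, c("depth", "sst", "ice")])
  if (any(bad))
    message(sprintf("extract_covariates: dropping %d rows with missing covariates",
                    sum(bad)))
  out <- out[!bad, , drop = FALSE]
  if (!nrow(out)) stop("no usable rows after covariate extraction")
  rownames(out) <- NULL
  class(out) <- c("use_avail_table", "data.frame")
  out
}

#' Fit the use-availability candidate ladder
#'
#' The nine-candidate family for three covariates: each covariate
#' alone as a linear term, each alone as a penalized smooth (cubic
#' regression spline with shrinkage), and the three pairwise linear
#' sums. Binomial response, logit link; candidates are ranked by
#' log-likelihood (forward selection over this family reduces to
#' taking the top-ranked model).
#'
#' @param table A `use_avail_table`.
#' @param basis_dim Basis dimension for the smooth candidates.
#' @return list: `ranking` (data.frame, best first), `fits` (named
#'   list of [pam_fit()] objects), `selected` (name of the best model).
#' @export
fit_ladder <- function(table, basis_dim = 10) {
  covs <- c("depth", "ice", "sst")
  present <- covs[covs %in% names(table)]
  if (length(present) < 2) stop("need at least two covariates")
  fits <- list()
  try_fit <- function(nm, expr) {
    f <- tryCatch(expr, error = function(e) {
      message(sprintf("fit_ladder: dropping candidate '%s' (%s)",
                      nm, conditionMessage(e)))
      NULL
    })
    if (!is.null(f)) fits[[nm]] <<- f
  }
  for (v in present)
    try_fit(v, pam_fit(table, "response", linear = v, link = "logit"))
  for (v in present) {
    # a raster-quantized covariate may carry fewer distinct values than
    # the default basis; shrink the basis to what the data can support
    bd <- min(basis_dim, length(unique(table[[v]])))
    if (bd < 4) next
    try_fit(paste0("s(", v, ")"),
            pam_fit(table, "response",
                    smooths = list(smooth_spec(v, basis_dim = bd,
                                               shrinkage = TRUE)),
                    link = "logit"))
  }
  if (length(present) >= 2) {
    prs <- utils::combn(present, 2)
    for (k in seq_len(ncol(prs)))
      try_fit(paste(prs[, k], collapse = " + "),
              pam_fit(table, "response", linear = prs[, k],
                      link = "logit"))
  }
  if (!length(fits)) stop("no ladder candidate could be fitted")
  ranking <- pam_compare(fits, criterion = "loglik")
  list(ranking = ranking, fits = fits, selected = ranking$model[1])
}
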