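# Shared fixtures, built in code at test time.

BIRD_ISLAND <- c(-38.05, -54.01)

# stationary track at a fixed site over a date range
stationary_track <- function(from, to, lonlat = BIRD_ISLAND) {
  data.frame(time = as.POSIXct(c(from, to), tz = "UTC"),
             lon = lonlat[1], lat = lonlat[2])
}

# winter residency deployment with rendered twilights and end fixes
residency_fixture <- function(n_steps = 80, seed = 4,
                              err = twilight_error_model()) {
  p <- track_params(n_steps = n_steps, seed = seed)
  sim <- simulate_track(p)
  tw <- render_twilights(sim$track, 96, err, seed = seed + 1L)
  n <- nrow(sim$track)
  fixes <- data.frame(time = sim$track$time[c(1, n)],
                      lon = sim$track$lon[c(1, n)],
                      lat = sim$track$lat[c(1, n)])
  list(sim = sim, twilights = tw, fixes = fixes, err = err)
}

# truth interpolated onto arbitrary times
truth_at <- function(track, times) {
  tt <- as.numeric(track$time)
  data.frame(
    lon = stats::approx(tt, track$lon, as.numeric(times), rule = 2)$y,
    lat = stats::approx(tt, track$lat, as.numeric(times), rule = 2)$y)
}

# immersion record assembled from explicit dry intervals (wet elsewhere)
immersion_from_bouts <- function(from, to, dry_intervals) {
  tt <- seq(as.POSIXct(from, tz = "UTC"), as.POSIXct(to, tz = "UTC"),
            by = 600)
  wet <- rep(200L, length(tt))
  for (iv in dry_intervals) {
    sel <- tt >= as.POSIXct(iv[1], tz = "UTC") &
      tt < as.POSIXct(iv[2], tz = "UTC")
    wet[sel] <- 0L
  }
  data.frame(time = tt, wet_count = wet)
}

# brute-force run-length oracle for dry-bout detection, written
# independently of the package's implementation
brute_bouts <- function(times, values, min_h = 1) {
  out <- list()
  i <- 1; n <- length(values)
  while (i <= n) {
    if (values[i] == -200) {
      j <- i
      while (j < n && values[j + 1] == -200) j <- j + 1
      start <- times[i]
      end <- if (j < n) times[j + 1] else times[j] + 600
      if ((as.numeric(end) - as.numeric(start)) / 3600 >= min_h)
        out[[length(out) + 1]] <- c(as.numeric(start), as.numeric(end))
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(out)) return(matrix(numeric(), 0, 2))
  do.call(rbind, out)
}

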