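# File formats and the pipeline driver: TSV/CSV logger records with
# ISO-8601 UTC timestamps, ESRI-ASCII raster export, YAML run
# configuration, JSON provenance, and run_pipeline() binding the
# stages end to end on a synthetic deployment.

# parse ISO-8601 timestamps, normalizing numeric UTC offsets
.parse_time <- function(x) {
  x <- trimws(as.character(x))
  x <- sub("T", " ", x)
  has_off <- grepl("[+-][0-9]{2}:?[0-9]{2}$", x)
  x[has_off] <- sub("([+-][0-9]{2}):?([0-9]{2})$", "\\1\\2", x[has_off])
  x <- sub("Z$", " +0000", x)
  x[!has_off & !grepl("[+-][0-9]{4}( |$)", x)] <-
    paste(x[!has_off & !grepl("[+-][0-9]{4}( |$)", x)], "+0000")
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S %z")
  short <- is.na(out)
  if (any(short))
    out[short] <- as.POSIXct(x[short], tz = "UTC", format = "%Y-%m-%d %z")
  out
}

.read_log <- function(path, value_col, validate) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                    stringsAsFactors = FALSE),
                  error = function(e) stop("unreadable log file: ", path))
  if (!nrow(raw)) stop("empty log file: ", path)
  if (ncol(raw) < 2) stop("expected a timestamp and a value column")
  names(raw)[1:2] <- c("time", value_col)
  tm <- .parse_time(raw$time)
  val <- suppressWarnings(as.numeric(raw[[value_col]]))
  bad <- is.na(tm) | is.na(val) | !validate(val)
  if (mean(bad) > 0.10)
    stop(sprintf("more than 10%% unusable rows in %s (%d of %d)",
                 path, sum(bad), nrow(raw)))
  if (any(bad))
    warning(sprintf("skipped %d unusable rows in %s", sum(bad), path))
  out <- data.frame(time = tm[!bad], value = val[!bad])
  out <- out[order(out$time), , drop = FALSE]
  if (anyDuplicated(as.numeric(out$time))) {
    warning("collapsing duplicate timestamps to their maximum value")
    mx <- tapply(out$value, as.numeric(out$time), max)
    out <- data.frame(
      time = as.POSIXct(as.numeric(names(mx)), tz = "UTC",
                        origin = "1970-01-01"),
      value = as.numeric(mx))
  }
  names(out)[2] <- value_col
  rownames(out) <- NULL
  out
}

#' Read a GLS light log
#'
#' TSV or CSV with an ISO-8601 UTC timestamp column and a light column
#' (maximum light per 10-min window). Unparseable rows are skipped
#' with a warning (error if more than 10%); duplicate timestamps are
#' collapsed to their maximum.
#'
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv`
#'   comma-separated).
#' @return data.frame(`time`, `light`), time-sorted.
#' @export
read_light_log <- function(path) {
  .read_log(path, "light", function(v) is.finite(v) & v >= 0)
}

#' Read a salt-water immersion log
#'
#' As [read_light_log()], with the wet-count range check 0--200 (the
#' number of positive 3-s salt-water tests in a 10-min window).
#'
#' @param path File path.
#' @return data.frame(`time`, `wet_count`).
#' @export
read_immersion_log <- function(path) {
  .read_log(path, "wet_count",
            function(v) is.finite(v) & v >= 0 & v <= 200)
}

#' Write a logger record table
#'
#' @param records data.frame whose first column is POSIXct.
#' @param path Destination (`.csv` or `.tsv`).
#' @export
write_log <- function(records, path) {
  out <- records
  out[[1]] <- strftime(out[[1]], "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a grid as an ESRI-ASCII raster
#'
#' @param density Matrix (rows = latitude ascending).
#' @param lon,lat Cell-edge or cell-centre coordinate vectors.
#' @param path Destination `.asc` path.
#' @param cellsize Cell size in degrees (inferred when `NULL`).
#' @export
write_esri_ascii <- function(density, lon, lat, path, cellsize = NULL) {
  if (is.null(cellsize)) cellsize <- diff(lon[1:2])
  hdr <- c(
    sprintf("ncols %d", ncol(density)),
    sprintf("nrows %d", nrow(density)),
    sprintf("xllcorner %.8f", min(lon)),
    sprintf("yllcorner %.8f", min(lat)),
    sprintf("cellsize %.8f", cellsize),
    "NODATA_value -9999")
  m <- density[rev(seq_len(nrow(density))), , drop = FALSE]  # north first
  m[!is.finite(m)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All stage parameters materialized with their defaults; any element
#' can be overridden via `...` or by loading a YAML file with
#' [read_run_config()]. Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    n_steps = 200L,
    start_time = "2012-08-02 00:00:00",
    zenith_deg = 96,
    light_threshold = 10,
    light_noise_sd = 0,
    twilight_scale_min = 8,
    n_chains = 4L,
    n_iter = 2000L,
    burn_in = 0.5,
    n_null_runs = 10L,
    n_use_chains = 100L,
    time_spent_simulations = 1000L,
    grid_resolution = 0.5,
    stages = c("simulate", "calibrate", "twilight", "locate",
               "haulout", "habitat", "activity"))
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "run_config")
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file of overrides for [run_config()].
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full synthetic-deployment pipeline
#'
#' Executes the requested stages in order — simulate a deployment,
#' calibrate at the deployment site, detect twilights, sample the
#' track posterior, segment haul-out bouts, habitat use-availability,
#' and activity modelling — writing each stage's CSV/raster outputs
#' plus a JSON provenance record into `out_dir`. Later stages depend
#' on earlier ones; requesting a stage without its dependency is a
#' structured error naming both.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("hydrurga_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(stage, dep, have) {
    if (!have) stop(sprintf("stage '%s' requires stage '%s' output",
                            stage, dep), call. = FALSE)
  }
  res <- list()
  st <- config$stages
  if ("simulate" %in% st) {
    p <- track_params(n_steps = config$n_steps,
                      start_time = as.POSIXct(config$start_time, tz = "UTC"),
                      seed = config$seed)
    sim <- simulate_track(p)
    res$track <- sim$track
    res$truth <- sim$truth
    lt <- render_light(sim$track, config$zenith_deg,
                       config$light_threshold,
                       noise_sd = config$light_noise_sd,
                       seed = config$seed)
    imm <- render_immersion(sim$track, haulout_schedule(),
                            seed = config$seed)
    res$lights <- lt; res$immersion <- imm$immersion
    res$true_bouts <- imm$bouts
    write_log(sim$track, file.path(out_dir, "true_track.csv"))
    write_log(lt, file.path(out_dir, "light_log.tsv"))
    write_log(imm$immersion, file.path(out_dir, "immersion_log.tsv"))
  }
  if ("calibrate" %in% st) {
    need("calibrate", "simulate", !is.null(res$lights))
    site <- c(res$track$lon[1], res$track$lat[1])
    # calibration period: the first stretch of the record at the site
    cal_len <- min(nrow(res$lights), 30 * 144)
    res$calibration <- calibrate(res$lights[seq_len(cal_len), ], site)
  }
  if ("twilight" %in% st) {
    need("twilight", "simulate", !is.null(res$lights))
    thr <- if (!is.null(res$calibration)) res$calibration$light_threshold
      else config$light_threshold
    tw <- detect_twilights(res$lights, thr)
    res$twilights <- tw[tw$quality == "ok", , drop = FALSE]
    write_log(tw, file.path(out_dir, "twilights.csv"))
  }
  if ("locate" %in% st) {
    need("locate", "twilight", !is.null(res$twilights))
    zen <- if (!is.null(res$calibration)) res$calibration$zenith_deg
      else config$zenith_deg
    n <- nrow(res$track)
    fixes <- data.frame(time = res$track$time[c(1, n)],
                        lon = res$track$lon[c(1, n)],
                        lat = res$track$lat[c(1, n)])
    res$chains <- sample_posterior(
      res$twilights, fixes, movement_prior(),
      twilight_error_model(scale = config$twilight_scale_min),
      zen, n_chains = config$n_chains, n_iter = config$n_iter,
      burn_in = config$burn_in, seed = config$seed)
    res$mean_path <- posterior_mean_path(res$chains)
    write_log(res$mean_path, file.path(out_dir, "mean_path.csv"))
    rng <- list(lon_range = range(res$mean_path$lon) + c(-3, 3),
                lat_range = range(res$mean_path$lat) + c(-3, 3),
                resolution = config$grid_resolution)
    tsg <- time_spent_grid(res$chains, rng,
                           n_simulations = config$time_spent_simulations)
    res$time_spent <- tsg
    write_esri_ascii(tsg$density, tsg$lon, tsg$lat,
                     file.path(out_dir, "time_spent.asc"))
  }
  if ("haulout" %in% st) {
    need("haulout", "simulate", !is.null(res$immersion))
    tri <- transform_immersion(res$immersion)
    bouts <- detect_bouts(tri)
    span <- range(res$immersion$time)
    states <- hourly_states(bouts, span)
    res$bouts <- bouts; res$states <- states
    res$haulout_summary <- haulout_summary(bouts, states, span)
    write_log(bouts, file.path(out_dir, "haulout_bouts.csv"))
    write_log(states, file.path(out_dir, "hourly_states.csv"))
    utils::write.csv(res$haulout_summary,
                     file.path(out_dir, "haulout_summary.csv"),
                     row.names = FALSE)
  }
  if ("habitat" %in% st) {
    need("habitat", "locate", !is.null(res$mean_path))
    need("habitat", "haulout", !is.null(res$states))
    env <- simulate_environment(env_field_spec())
    nulls <- simulate_crw(res$mean_path, config$n_null_runs,
                          seed = config$seed)
    tab <- extract_covariates(res$chains, nulls, env, res$states,
                              habitat_config(config$n_use_chains,
                                             config$n_null_runs))
    res$use_avail <- tab
    res$ladder <- fit_ladder(tab)
    utils::write.csv(tab, file.path(out_dir, "use_avail.csv"),
                     row.names = FALSE)
    utils::write.csv(res$ladder$ranking,
                     file.path(out_dir, "habitat_ladder.csv"),
                     row.names = FALSE)
  }
  if ("activity" %in% st) {
    need("activity", "locate", !is.null(res$mean_path))
    need("activity", "haulout", !is.null(res$states))
    env_spec <- env_field_spec()
    design <- build_design(res$states, res$mean_path,
                           env_spec$land_polygons,
                           env_spec$ice_edge_latitude_by_month)
    res$design <- design
    res$activity_fit <- fit_activity(design)
    res$diel_seasonal <- diel_seasonal_summary(design[,
      c("hour_start", "state")])
    utils::write.csv(design, file.path(out_dir, "activity_design.csv"),
                     row.names = FALSE)
    utils::write.csv(res$activity_fit$term_table,
                     file.path(out_dir, "activity_fit.csv"),
                     row.names = FALSE)
  }
  prov <- list(package = "hydrurga",
               version = as.character(utils::packageVersion("hydrurga")),
               r_version = R.version.string,
               run_at = strftime(Sys.time(), "%Y-%m-%dT%H:%M:%S",
                                 tz = "UTC"),
               config = unclass(config))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(res, "out_dir") <- out_dir
  invisible(res)
}
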