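# Haul-out segmentation of 10-min salt-water immersion logs: the
# dive-style transform (counts minus 200), dry-bout detection, hourly
# state assignment and deployment summaries.

#' Transform immersion counts to dive-style values
#'
#' Subtracts 200 from each wet-test count so that haul-out periods
#' appear as "dives" to run-length analysis: a completely dry window
#' becomes -200, a completely wet one 0. Out-of-range rows are dropped
#' with a warning.
#'
#' @param records data.frame(`time`, `wet_count`) with counts in
#'   \[0, 200\].
#' @return data.frame(`time`, `value`) with `value` in \[-200, 0\].
#' @export
transform_immersion <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("time", "wet_count") %in% names(records)))
  bad <- !is.finite(records$wet_count) |
    records$wet_count < 0 | records$wet_count > 200
  if (any(bad)) {
    warning(sprintf("dropping %d immersion rows outside [0, 200]", sum(bad)))
    records <- records[!bad, , drop = FALSE]
  }
  data.frame(time = records$time, value = records$wet_count - 200)
}

#' Detect haul-out bouts as completely-dry runs
#'
#' A bout starts at the first window reading -200 (completely dry) and
#' ends at the first subsequent window reading above -200. Runs shorter
#' than `min_dry_duration` hours are discarded. Runs interrupted or
#' terminated by recording gaps longer than `max_gap_min` are flagged
#' `truncated` (their duration is a lower bound) and excluded from
#' duration statistics by [haulout_summary()].
#'
#' @param transformed data.frame(`time`, `value`) from
#'   [transform_immersion()], time-sorted.
#' @param min_dry_duration Minimum bout duration, hours (default 1).
#' @param max_gap_min Recording gap that breaks a run, minutes.
#' @return data.frame(`start`, `end`, `duration_h`, `truncated`).
#' @export
detect_bouts <- function(transformed, min_dry_duration = 1,
                         max_gap_min = 30) {
  stopifnot(min_dry_duration > 0)
  tt <- as.numeric(transformed$time)
  if (is.unsorted(tt)) stop("immersion records must be sorted by time")
  v <- transformed$value
  n <- length(v)
  if (!n) return(data.frame(start = as.POSIXct(character(), tz = "UTC"),
                            end = as.POSIXct(character(), tz = "UTC"),
                            duration_h = numeric(), truncated = logical()))
  # segment the record at large gaps, then run-length scan each segment
  gap_after <- c(diff(tt) > max_gap_min * 60, TRUE)
  seg_id <- cumsum(c(0L, utils::head(gap_after, -1L)))
  out <- list()
  for (s in unique(seg_id)) {
    idx <- which(seg_id == s)
    dry <- v[idx] == -200
    r <- rle(dry)
    ends <- cumsum(r$lengths); starts <- c(1L, utils::head(ends, -1L) + 1L)
    for (k in which(r$values)) {
      i0 <- idx[starts[k]]
      truncated <- FALSE
      if (ends[k] < length(idx)) {
        t_end <- tt[idx[ends[k] + 1L]]  # first subsequent wet window
      } else {
        t_end <- tt[idx[ends[k]]] + 600  # run cut by gap / record end
        truncated <- TRUE
      }
      out[[length(out) + 1L]] <- data.frame(
        start = transformed$time[i0],
        end = as.POSIXct(t_end, tz = "UTC", origin = "1970-01-01"),
        duration_h = (t_end - tt[i0]) / 3600,
        truncated = truncated)
    }
  }
  if (!length(out)) return(data.frame(
    start = as.POSIXct(character(), tz = "UTC"),
    end = as.POSIXct(character(), tz = "UTC"),
    duration_h = numeric(), truncated = logical()))
  res <- do.call(rbind, out)
  res <- res[res$duration_h >= min_dry_duration, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assign each deployment hour as hauled out or at sea
#'
#' Clock-aligned UTC hour bins \[h:00, h+1:00); an hour is hauled out
#' (state 1) iff it overlaps any bout.
#'
#' @param bouts data.frame(`start`, `end`) from [detect_bouts()].
#' @param span POSIXct length-2 deployment span c(first, last).
#' @return data.frame(`hour_start` POSIXct, `state` integer 0/1).
#' @export
hourly_states <- function(bouts, span) {
  h0 <- as.numeric(trunc(as.POSIXct(span[1], tz = "UTC"), "hours"))
  h1 <- as.numeric(trunc(as.POSIXct(span[2], tz = "UTC") - 1e-6, "hours"))
  hrs <- seq(h0, h1, by = 3600)
  state <- integer(length(hrs))
  if (nrow(bouts)) {
    bs <- as.numeric(bouts$start); be <- as.numeric(bouts$end)
    for (b in seq_along(bs)) {
      ov <- hrs < be[b] & (hrs + 3600) > bs[b]
      state[ov] <- 1L
    }
  }
  data.frame(hour_start = as.POSIXct(hrs, tz = "UTC", origin = "1970-01-01"),
             state = state)
}

#' Summarise haul-out behaviour over a deployment
#'
#' The per-trip aggregates reported for archival wet/dry deployments:
#' total days hauled out, proportion of the deployment hauled out, the
#' maximum and median bout durations (hours; truncated bouts excluded),
#' the median/min/max interval between successive bouts (minutes), and
#' the longest continuous period in the water (days).
#'
#' @param bouts data.frame from [detect_bouts()].
#' @param states data.frame from [hourly_states()] (used for the
#'   recorded-time variant of the proportion).
#' @param span POSIXct length-2 deployment span.
#' @return One-row data.frame.
#' @export
haulout_summary <- function(bouts, states, span) {
  span_h <- as.numeric(difftime(span[2], span[1], units = "hours"))
  dur_ok <- bouts$duration_h[!bouts$truncated]
  total_h <- sum(bouts$duration_h)
  gaps_min <- if (nrow(bouts) > 1) {
    as.numeric(bouts$start[-1]) / 60 -
      as.numeric(bouts$end[-nrow(bouts)]) / 60
  } else numeric()
  data.frame(
    total_days = total_h / 24,
    proportion = total_h / span_h,
    proportion_recorded = mean(states$state),
    max_hours = if (length(dur_ok)) max(dur_ok) else NA_real_,
    median_hours = if (length(dur_ok)) stats::median(dur_ok) else NA_real_,
    median_interval_min = if (length(gaps_min)) stats::median(gaps_min) else NA_real_,
    min_interval_min = if (length(gaps_min)) min(gaps_min) else NA_real_,
    max_interval_min = if (length(gaps_min)) max(gaps_min) else NA_real_,
    longest_wet_days = if (length(gaps_min)) max(gaps_min) / 1440
      else span_h / 24)
}
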