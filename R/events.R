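# Event processing: collapse raw triggers into independent events, classify
# day/night, compute stratified effort, and estimate encounter rates with a
# camera-level bootstrap.

#' Collapse consecutive triggers into independent events
#'
#' A stationary animal re-triggering a camera produces runs of closely spaced
#' photographs that are one biological contact. Triggers at the same camera
#' separated by less than `gap_min` minutes are merged into a single event
#' stamped with the first trigger's time. Merging is chained: each trigger is
#' compared with the previous trigger, not the run's first, so run length
#' does not depend on where the run started. A merged event's `count` is the
#' largest group count seen in the run.
#'
#' The field protocol behind this rule identified contacts by an animal
#' entering and exiting the field of view; the numeric gap is the analyst's
#' operational surrogate and should be reported with results.
#'
#' @param events an `event_records` data frame sorted by
#'   (camera_id, timestamp), as returned by [read_events()].
#' @param gap_min independence gap in minutes (> 0); default 15.
#' @return collapsed `event_records` data frame.
#' @export
collapse_events <- function(events, gap_min = 15) {
  if (gap_min <= 0) stop("gap_min must be > 0")
  df <- as.data.frame(events)
  if (nrow(df) == 0) return(events)
  ord <- order(df$camera_id, df$timestamp)
  if (!identical(ord, seq_len(nrow(df))))
    stop("events must be sorted by (camera_id, timestamp); use read_events()/as_event_records()")
  same_cam <- c(FALSE, df$camera_id[-1] == df$camera_id[-nrow(df)])
  dt_min <- c(Inf, as.numeric(diff(df$timestamp), units = "mins"))
  new_run <- !(same_cam & dt_min < gap_min)
  run <- cumsum(new_run)
  first <- !duplicated(run)
  out <- df[first, , drop = FALSE]
  out$count <- as.integer(tapply(df$count, run, max))
  rownames(out) <- NULL
  class(out) <- c("event_records", "data.frame")
  out
}

#' Classify timestamps as night-time
#'
#' Night is the half-open daily window `[18:00, 06:00)` wrapping midnight, so
#' 18:00 itself is night, 06:00 is day, and no instant is double-counted.
#'
#' @param timestamps POSIXct vector.
#' @param window length-2 numeric, start and end clock hour of night.
#' @return logical vector, `TRUE` for night.
#' @export
is_night <- function(timestamps, window = c(18, 6)) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  h <- lt$hour + lt$min / 60 + lt$sec / 3600
  s <- window[1]; e <- window[2]
  if (s > e) h >= s | h < e else h >= s & h < e
}

#' Camera effort in a season-habitat-window stratum
#'
#' Sums active hours over the cameras of one stratum. The night window
#' contributes 12 of every 24 deployed hours (half the effort), the
#' convention needed for night-only encounter rates to be per night-hour.
#' Cameras falling outside every habitat polygon are excluded with a warning.
#'
#' @param deployments a `deployments` data frame.
#' @param window `"all"` or `"night"`.
#' @param habitat optional habitat label to restrict to.
#' @param map optional `habitat_map` used to assign cameras to habitats by
#'   point-in-polygon (required when `habitat` is given and the deployment
#'   table's own `habitat` column should not be trusted).
#' @return total effort in hours.
#' @export
stratum_effort <- function(deployments, window = c("all", "night"),
                           habitat = NULL, map = NULL) {
  window <- match.arg(window)
  dep <- .filter_habitat(deployments, habitat, map)
  eff <- sum(dep$effort_hours)
  if (window == "night") eff / 2 else eff
}

.filter_habitat <- function(deployments, habitat, map) {
  if (is.null(habitat)) return(deployments)
  if (!is.null(map)) {
    lab <- assign_habitat(map, deployments$x, deployments$y)
    if (anyNA(lab)) {
      warning(sprintf("camera(s) outside all habitat polygons excluded: %s",
                      paste(deployments$camera_id[is.na(lab)], collapse = ", ")),
              call. = FALSE)
    }
    deployments[!is.na(lab) & lab == habitat, , drop = FALSE]
  } else {
    deployments[deployments$habitat == habitat, , drop = FALSE]
  }
}

#' Per-camera tallies of independent events and effort
#'
#' Builds the (y, t) pairs that feed the encounter rate: one row per camera
#' with its independent-event count inside the chosen time window and its
#' effort hours in that window. By default an event contributes 1 to y
#' regardless of the number of individuals pictured (groups are non-cohesive
#' contacts); `per_individual = TRUE` adds the event's `count` instead.
#'
#' @param events collapsed `event_records` (see [collapse_events()]).
#' @param deployments a `deployments` data frame.
#' @param window `"all"` or `"night"`.
#' @param habitat,map optional stratification, as in [stratum_effort()].
#' @param per_individual count individuals rather than events.
#' @return data frame of class `"camera_tallies"` with columns `camera_id`,
#'   `y`, `t`.
#' @export
camera_tallies <- function(events, deployments, window = c("all", "night"),
                           habitat = NULL, map = NULL,
                           per_individual = FALSE) {
  window <- match.arg(window)
  dep <- .filter_habitat(deployments, habitat, map)
  ev <- as.data.frame(events)
  ev <- ev[ev$camera_id %in% dep$camera_id, , drop = FALSE]
  if (window == "night") ev <- ev[is_night(ev$timestamp), , drop = FALSE]
  contrib <- if (per_individual) ev$count else rep(1L, nrow(ev))
  y <- vapply(dep$camera_id,
              function(cid) sum(contrib[ev$camera_id == cid]), numeric(1))
  t <- dep$effort_hours
  if (window == "night") t <- t / 2
  out <- data.frame(camera_id = dep$camera_id, y = as.numeric(y), t = t,
                    stringsAsFactors = FALSE)
  zero_t <- out$t <= 0
  if (any(zero_t & out$y > 0))
    stop("camera with events but zero effort; check deployment intervals")
  if (any(zero_t)) {
    warning(sprintf("camera(s) with zero effort excluded: %s",
                    paste(out$camera_id[zero_t], collapse = ", ")),
            call. = FALSE)
    out <- out[!zero_t, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("camera_tallies", "data.frame")
  out
}

#' Encounter rate as a ratio of totals
#'
#' The rate is total independent events over total effort, `sum(y)/sum(t)` —
#' not the mean of per-camera rates — so cameras with more effort weigh more
#' and splitting one camera's record into sub-deployments changes nothing.
#'
#' @param tallies a `camera_tallies` data frame.
#' @return object of class `"encounter_rate"`: list with `rate` (events/h),
#'   `y_total`, `t_total`, and (after [bootstrap_rate()]) `var_boot`,
#'   `n_boot`, `seed`.
#' @export
encounter_rate <- function(tallies) {
  if (nrow(tallies) == 0 || sum(tallies$t) <= 0)
    stop("encounter rate undefined: no effort")
  structure(list(rate = sum(tallies$y) / sum(tallies$t),
                 y_total = sum(tallies$y), t_total = sum(tallies$t),
                 var_boot = NULL, n_boot = NULL, seed = NULL),
            class = "encounter_rate")
}

#' Bootstrap variance of the encounter rate
#'
#' Camera locations are resampled with replacement `n_boot` times; each
#' replicate recomputes the ratio-of-totals rate over the resampled cameras,
#' and `var_boot` is the variance across replicates. The camera is the
#' resampling unit because spatial heterogeneity among cameras, not Poisson
#' noise within a camera, dominates the rate's uncertainty.
#'
#' @param tallies a `camera_tallies` data frame with at least 2 cameras.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed integer seed, recorded in the result.
#' @return an `encounter_rate` object with `var_boot` filled in.
#' @export
bootstrap_rate <- function(tallies, n_boot = 10000, seed = NULL) {
  n <- nrow(tallies)
  if (n < 2) stop("bootstrap variance undefined with a single camera")
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  ysum <- colSums(matrix(tallies$y[idx], nrow = n))
  tsum <- colSums(matrix(tallies$t[idx], nrow = n))
  rates <- ysum / tsum
  out <- encounter_rate(tallies)
  out$var_boot <- stats::var(rates)
  out$n_boot <- as.integer(n_boot)
  out$seed <- seed
  out
}

#' @export
print.encounter_rate <- function(x, ...) {
  cat(sprintf("Encounter rate: %.6g events/h (y = %g, t = %g h)\n",
              x$rate, x$y_total, x$t_total))
  if (!is.null(x$var_boot))
    cat(sprintf("  bootstrap var = %.4g (n_boot = %d, seed = %s)\n",
                x$var_boot, x$n_boot,
                if (is.null(x$seed)) "none" else format(x$seed)))
  invisible(x)
}
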