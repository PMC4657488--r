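# Field-parameter estimation: detection-zone dimensions from approach trials
# and movement speed from continuous-follow logs.

# circular mean of bearings in degrees, in [0, 360)
circ_mean_deg <- function(deg) {
  a <- deg * pi / 180
  m <- atan2(mean(sin(a)), mean(cos(a))) * 180 / pi
  m %% 360
}

# SE of a circular mean: angular deviations from the mean are wrapped into
# (-180, 180] and treated linearly (adequate for the tightly clustered
# bearings a sensor-trigger protocol produces)
circ_se_deg <- function(deg) {
  m <- circ_mean_deg(deg)
  dev <- (deg - m + 180) %% 360 - 180
  stats::sd(dev) / sqrt(length(deg))
}

#' Detection-zone dimensions from field trials
#'
#' The radius comes from repeated frontal approaches: the mean distance from
#' the camera at first trigger, with the standard error of that mean. The
#' angle comes from paired approaches perpendicular to the sensor beam, one
#' from each side: it is the circular difference between the circular mean of
#' the left-side first-trigger bearings and that of the right-side bearings.
#' Circular means (unit-vector averaging) are essential because compass
#' bearings can straddle north; naive arithmetic means fail there. The
#' angle's SE combines the two mean-bearing SEs in quadrature.
#'
#' @param distances_m first-trigger distances from frontal approaches, metres.
#' @param bearings_left,bearings_right compass bearings (degrees) at first
#'   trigger for the left- and right-hand approach of each pair.
#' @return a [rem_params()] fragment: list with `r`, `se_r` (km), `theta`,
#'   `se_theta` (radians).
#' @export
estimate_detection_zone <- function(distances_m, bearings_left,
                                    bearings_right) {
  if (length(distances_m) < 2) stop("need >= 2 approach distances")
  if (any(distances_m <= 0)) stop("distances must be > 0")
  if (length(bearings_left) < 2 || length(bearings_right) < 2)
    stop("need >= 2 bearing pairs")
  # bearings are circular: wrap into [0, 360) so adding 360 changes nothing
  bearings_left <- bearings_left %% 360
  bearings_right <- bearings_right %% 360
  r_m <- mean(distances_m)
  se_r_m <- stats::sd(distances_m) / sqrt(length(distances_m))
  ml <- circ_mean_deg(bearings_left)
  mr <- circ_mean_deg(bearings_right)
  theta_deg <- abs((mr - ml + 180) %% 360 - 180)  # circular difference
  if (theta_deg > 180 - 1e-9 || theta_deg <= 0)
    stop("bearing pairs imply a detection angle outside (0, 180] degrees")
  se_theta_deg <- sqrt(circ_se_deg(bearings_left)^2 +
                         circ_se_deg(bearings_right)^2)
  list(r = r_m / 1000, se_r = se_r_m / 1000,
       theta = theta_deg * pi / 180, se_theta = se_theta_deg * pi / 180)
}

# night hours (clock in [18, 6)) contained in [start, end), computed exactly
# by integrating over whole days plus the fractional edges
.night_hours <- function(start, end) {
  h0 <- as.numeric(difftime(start, trunc(start, "days"), units = "hours"))
  len <- as.numeric(difftime(end, start, units = "hours"))
  if (len <= 0) return(0)
  # night mass of clock interval [0, h) within one day, h in [0, 24]
  night_to <- function(h) pmin(h, 6) + pmax(h - 18, 0)
  full_days <- floor((h0 + len) / 24)
  frac <- (h0 + len) %% 24
  (night_to(frac) - night_to(h0)) + 12 * full_days
}

#' Movement speed from continuous-follow logs
#'
#' A follow log records odometer distance over consecutive time segments for
#' one pride. Speed is distance along the path per unit time (odometer
#' semantics, not net displacement). Each pride's rate in the requested
#' window is the summed distance allocated to the window divided by the
#' window hours; segments straddling the 18:00/06:00 boundary are split
#' pro-rata by time, distance allocated proportionally. The group estimate
#' for each (habitat, season) is the unweighted mean across prides, with the
#' SE of that mean across prides — the pride, not the hour, is the sampling
#' unit, because hours within a follow are autocorrelated.
#'
#' @param follows data frame with columns `pride_id`, `habitat`, `season`,
#'   `start`, `end` (POSIXct or ISO-8601 strings), `km`.
#' @param window `"all"`, `"night"` or `"day"`.
#' @return data frame with one row per (habitat, season): `V` (km/h), `se_V`
#'   (NA with a single pride), `n_prides`, `window`.
#' @export
estimate_speed <- function(follows, window = c("all", "night", "day")) {
  window <- match.arg(window)
  .need_cols(follows, c("pride_id", "habitat", "season", "start", "end", "km"),
             "follows")
  f <- as.data.frame(follows, stringsAsFactors = FALSE)
  if (!inherits(f$start, "POSIXct")) f$start <- .parse_ts(f$start)
  if (!inherits(f$end, "POSIXct")) f$end <- .parse_ts(f$end)
  if (any(is.na(f$start) | is.na(f$end)))
    stop("unparseable follow segment datetime")
  if (any(f$km < 0)) stop("odometer distances must be >= 0")
  len <- as.numeric(difftime(f$end, f$start, units = "hours"))
  if (any(len <= 0)) stop("follow segments must have end > start")
  nh <- vapply(seq_len(nrow(f)),
               function(i) .night_hours(f$start[i], f$end[i]), numeric(1))
  f$win_hours <- switch(window, all = len, night = nh, day = len - nh)
  f$win_km <- f$km * f$win_hours / len
  per_pride <- do.call(rbind, lapply(
    split(f, f[c("pride_id", "habitat", "season")], drop = TRUE),
    function(g) {
      hrs <- sum(g$win_hours)
      data.frame(pride_id = g$pride_id[1], habitat = g$habitat[1],
                 season = g$season[1], hours = hrs,
                 V = if (hrs > 0) sum(g$win_km) / hrs else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  dropped <- is.na(per_pride$V)
  if (any(dropped)) {
    warning(sprintf("follow(s) with zero %s-window hours excluded: %s",
                    window, paste(per_pride$pride_id[dropped], collapse = ", ")),
            call. = FALSE)
    per_pride <- per_pride[!dropped, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(
    split(per_pride, per_pride[c("habitat", "season")], drop = TRUE),
    function(g) data.frame(
      habitat = g$habitat[1], season = g$season[1],
      V = mean(g$V),
      se_V = if (nrow(g) > 1) stats::sd(g$V) / sqrt(nrow(g)) else NA_real_,
      n_prides = nrow(g), window = window, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
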