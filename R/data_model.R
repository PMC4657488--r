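# Domain types, validation and readers/writers for the tabular and geometric
# inputs of the camera-trap density workflow.
#
# Conventions: all coordinates are projected planar km; timestamps are naive
# camera-stamped local times (stored with tz = "UTC" purely to avoid DST
# arithmetic, never converted); CSV is comma-separated UTF-8 with ISO-8601
# datetimes. Validation is fail-fast with row-addressed messages; permissive
# mode warns and drops offending rows instead.

.parse_ts <- function(x) {
  x <- trimws(as.character(x))
  fmts <- c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M",
            "%Y-%m-%dT%H:%M:%S", "%Y-%m-%dT%H:%M", "%Y-%m-%d")
  # strptime (unlike as.POSIXct's tryFormats) yields per-element NA for
  # invalid dates instead of failing wholesale
  out <- as.POSIXct(strptime(x, fmts[1], tz = "UTC"), tz = "UTC")
  for (f in fmts[-1]) {
    na <- is.na(out) & !is.na(x)
    if (!any(na)) break
    out[na] <- as.POSIXct(strptime(x[na], f, tz = "UTC"), tz = "UTC")
  }
  out
}

.fmt_ts <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = "UTC")

.need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
}

.row_problem <- function(rows, msg, permissive) {
  text <- sprintf("%s (row %s)", msg, paste(rows, collapse = ", "))
  if (permissive) {
    warning(text, call. = FALSE)
    rows
  } else {
    stop(text, call. = FALSE)
  }
}

#' Validate a camera deployment table
#'
#' A deployment is one camera placement: planar location (km), active
#' interval, and habitat label. Effort in hours is `end - start`.
#'
#' @param df data frame with columns `camera_id`, `x`, `y`, `start`, `end`,
#'   `habitat` (timestamps as POSIXct or ISO-8601 strings).
#' @param permissive warn and drop invalid rows instead of failing.
#' @return validated data frame of class `"deployments"` with an
#'   `effort_hours` column.
#' @export
as_deployments <- function(df, permissive = FALSE) {
  .need_cols(df, c("camera_id", "x", "y", "start", "end", "habitat"),
             "deployments")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$camera_id <- as.character(df$camera_id)
  if (!inherits(df$start, "POSIXct")) df$start <- .parse_ts(df$start)
  if (!inherits(df$end, "POSIXct")) df$end <- .parse_ts(df$end)
  drop <- integer(0)
  bad <- which(is.na(df$start) | is.na(df$end))
  if (length(bad))
    drop <- union(drop, .row_problem(bad, "unparseable deployment datetime",
                                     permissive))
  ok <- setdiff(seq_len(nrow(df)), bad)
  rev_rows <- ok[df$end[ok] <= df$start[ok]]
  if (length(rev_rows))
    drop <- union(drop, .row_problem(rev_rows,
                                     "deployment end is not after start",
                                     permissive))
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  dup <- which(duplicated(df$camera_id))
  if (length(dup))
    stop(sprintf("duplicate camera_id in deployment table (row %s)",
                 paste(dup, collapse = ", ")), call. = FALSE)
  df$effort_hours <- as.numeric(difftime(df$end, df$start, units = "hours"))
  rownames(df) <- NULL
  class(df) <- c("deployments", "data.frame")
  df
}

#' Read a camera deployment table from CSV
#'
#' @param path CSV file with header.
#' @param col_map optional named character vector mapping required names to
#'   the file's column names, e.g. `c(camera_id = "site")`.
#' @inheritParams as_deployments
#' @return a `deployments` data frame; see [as_deployments()].
#' @export
read_deployments <- function(path, col_map = NULL, permissive = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(df))
        stop(sprintf("column mapping: '%s' not found in %s",
                     col_map[[std]], path), call. = FALSE)
      names(df)[names(df) == col_map[[std]]] <- std
    }
  }
  as_deployments(df, permissive = permissive)
}

#' Write a deployment table to CSV
#' @param deployments a `deployments` data frame.
#' @param path output path.
#' @export
write_deployments <- function(deployments, path) {
  out <- as.data.frame(deployments)
  out$start <- .fmt_ts(out$start)
  out$end <- .fmt_ts(out$end)
  out$effort_hours <- NULL
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a photographic event table
#'
#' One row per camera trigger (or independent event after collapsing):
#' camera, timestamp, species and sex labels, and the number of individuals
#' in the contact. Records are returned sorted by (camera_id, timestamp).
#'
#' @param df data frame with columns `camera_id`, `timestamp`, `species`,
#'   `sex`, `count`.
#' @param deployments optional `deployments` table; if given, every event's
#'   camera must exist and its timestamp must fall inside the camera's active
#'   interval.
#' @param permissive warn and drop invalid rows instead of failing.
#' @return data frame of class `"event_records"`, sorted.
#' @export
as_event_records <- function(df, deployments = NULL, permissive = FALSE) {
  .need_cols(df, c("camera_id", "timestamp", "species", "sex", "count"),
             "events")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$camera_id <- as.character(df$camera_id)
  if (!inherits(df$timestamp, "POSIXct")) df$timestamp <- .parse_ts(df$timestamp)
  df$count <- suppressWarnings(as.integer(df$count))
  drop <- integer(0)
  bad <- which(is.na(df$timestamp))
  if (length(bad))
    drop <- union(drop, .row_problem(bad, "unparseable event timestamp",
                                     permissive))
  badc <- which(is.na(df$count) | df$count < 1L)
  if (length(badc))
    drop <- union(drop, .row_problem(badc, "event count must be >= 1",
                                     permissive))
  if (!is.null(deployments)) {
    unknown <- which(!df$camera_id %in% deployments$camera_id)
    if (length(unknown))
      drop <- union(drop, .row_problem(unknown, "unknown camera_id in events",
                                       permissive))
    keep <- setdiff(seq_len(nrow(df)), drop)
    idx <- match(df$camera_id[keep], deployments$camera_id)
    outside <- keep[df$timestamp[keep] < deployments$start[idx] |
                      df$timestamp[keep] > deployments$end[idx]]
    if (length(outside))
      drop <- union(drop, .row_problem(
        outside, "event timestamp outside camera deployment interval",
        permissive))
  }
  if (length(drop)) df <- df[-drop, , drop = FALSE]
  df <- df[order(df$camera_id, df$timestamp), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_records", "data.frame")
  df
}

#' Read a photographic event table from CSV
#' @inheritParams as_event_records
#' @param path CSV file with header.
#' @return an `event_records` data frame, sorted by (camera_id, timestamp).
#' @export
read_events <- function(path, deployments = NULL, permissive = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  as_event_records(df, deployments = deployments, permissive = permissive)
}

#' Write an event table to CSV
#' @param events an `event_records` data frame.
#' @param path output path.
#' @export
write_events <- function(events, path) {
  out <- as.data.frame(events)
  out$timestamp <- .fmt_ts(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Detection-zone and movement parameters of the encounter model
#'
#' Bundles the three field parameters the density estimator needs: mean
#' movement speed `V` (km/h), detection radius `r` (km) and full detection
#' angle `theta` (radians), each with a standard error. Degrees and metres
#' are accepted at the interface and converted exactly once, here; downstream
#' code never guesses units.
#'
#' @param V mean speed of movement, km/h.
#' @param r detection-zone radius, in `r_unit`.
#' @param theta full detection-zone angle, in `angle_unit`.
#' @param se_V,se_r,se_theta standard errors (same units as the parameter).
#' @param r_unit `"km"` or `"m"`.
#' @param angle_unit `"radians"` or `"degrees"`.
#' @return object of class `"rem_params"`: list with V, r (km), theta (rad)
#'   and their SEs.
#' @export
rem_params <- function(V, r, theta, se_V = 0, se_r = 0, se_theta = 0,
                       r_unit = c("km", "m"),
                       angle_unit = c("radians", "degrees")) {
  r_unit <- match.arg(r_unit)
  angle_unit <- match.arg(angle_unit)
  if (r_unit == "m") {
    r <- r / 1000; se_r <- se_r / 1000
  } else if (r > 0.5) {
    # a detection radius over 500 m is not a camera sensor: almost certainly
    # metres passed as km
    stop(sprintf(
      "r = %g km is implausibly large for a detection radius; if the value is in metres use r_unit = \"m\"",
      r), call. = FALSE)
  }
  if (angle_unit == "degrees") {
    theta <- theta * pi / 180; se_theta <- se_theta * pi / 180
  }
  if (!is.finite(V) || V <= 0) stop("V must be > 0")
  if (!is.finite(r) || r <= 0) stop("r must be > 0")
  if (!is.finite(theta) || theta <= 0 || theta >= 2 * pi)
    stop("theta must lie in (0, 2*pi) radians")
  if (se_V < 0 || se_r < 0 || se_theta < 0)
    stop("standard errors must be >= 0")
  structure(list(V = V, se_V = se_V, r = r, se_r = se_r,
                 theta = theta, se_theta = se_theta),
            class = "rem_params")
}

#' @export
print.rem_params <- function(x, ...) {
  cat(sprintf("REM parameters: V = %.4g km/h (se %.3g), r = %.4g km (se %.3g), theta = %.4g rad (se %.3g)\n",
              x$V, x$se_V, x$r, x$se_r, x$theta, x$se_theta))
  invisible(x)
}

#' Read pride census records
#'
#' A pride record carries the known number of adult females (cubs excluded)
#' and the direct-observation relocation points used to fit its utilization
#' distribution.
#'
#' @param prides_path CSV with columns `pride_id`, `n_females`, `season`.
#' @param obs_path CSV with columns `pride_id`, `x`, `y`, `timestamp`.
#' @param min_obs minimum relocations required per pride for home-range
#'   fitting (default 5).
#' @return list of pride records: each a list with `pride_id`, `n_females`,
#'   `season` and an `observations` data frame.
#' @export
read_prides <- function(prides_path, obs_path, min_obs = 5L) {
  pr <- utils::read.csv(prides_path, stringsAsFactors = FALSE)
  .need_cols(pr, c("pride_id", "n_females", "season"), "prides")
  obs <- utils::read.csv(obs_path, stringsAsFactors = FALSE)
  .need_cols(obs, c("pride_id", "x", "y", "timestamp"), "pride observations")
  obs$timestamp <- .parse_ts(obs$timestamp)
  bad <- which(pr$n_females < 0)
  if (length(bad))
    stop(sprintf("n_females must be >= 0 (row %s)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  lapply(seq_len(nrow(pr)), function(i) {
    o <- obs[obs$pride_id == pr$pride_id[i], c("x", "y", "timestamp")]
    if (nrow(o) < min_obs)
      stop(sprintf("pride '%s' has %d observation(s); >= %d required for home-range fitting",
                   pr$pride_id[i], nrow(o), min_obs), call. = FALSE)
    list(pride_id = pr$pride_id[i],
         n_females = as.integer(pr$n_females[i]),
         season = pr$season[i],
         observations = o)
  })
}

# ---- habitat maps (GeoJSON) -------------------------------------------------

.looks_geographic <- function(features) {
  all(vapply(features, function(f) {
    xy <- f$coords
    all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90)
  }, logical(1)))
}

#' Read a habitat map from GeoJSON
#'
#' Expects a FeatureCollection of simple polygons (no holes) with a
#' `habitat` property, in projected planar km. Because planar km coordinates
#' of a small study area can be numerically indistinguishable from lon/lat,
#' the file must declare its units with a top-level `"units": "km"` member
#' (emitted by [write_habitat_map()]) unless `assume_planar = TRUE`.
#'
#' @param path GeoJSON file.
#' @param assume_planar skip the declared-units check.
#' @return object of class `"habitat_map"`: list of features, each with
#'   `habitat` and a vertex matrix `coords`; plus unique `labels`.
#' @export
read_habitat_map <- function(path, assume_planar = FALSE) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("habitat map must be a GeoJSON FeatureCollection", call. = FALSE)
  features <- lapply(seq_along(gj$features), function(i) {
    f <- gj$features[[i]]
    g <- f$geometry
    if (is.null(g$type) || g$type != "Polygon")
      stop(sprintf("feature %d: only Polygon geometries are supported", i),
           call. = FALSE)
    if (length(g$coordinates) != 1)
      stop(sprintf("feature %d: polygons with holes are not supported", i),
           call. = FALSE)
    ring <- g$coordinates[[1]]
    xy <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # GeoJSON rings repeat the first vertex; drop the closing copy
    if (nrow(xy) > 1 && all(xy[1, ] == xy[nrow(xy), ]))
      xy <- xy[-nrow(xy), , drop = FALSE]
    hab <- f$properties$habitat
    if (is.null(hab))
      stop(sprintf("feature %d: missing 'habitat' property", i),
           call. = FALSE)
    if (!is_simple_polygon(xy))
      stop(sprintf("feature %d ('%s'): polygon is self-intersecting", i, hab),
           call. = FALSE)
    list(habitat = hab, coords = xy)
  })
  declared_km <- !is.null(gj$units) && identical(gj$units, "km")
  if (!assume_planar && !declared_km && .looks_geographic(features))
    stop(paste("coordinates fit inside lon/lat bounds and the file declares",
               "no planar units; add a top-level \"units\": \"km\" member or",
               "pass assume_planar = TRUE"), call. = FALSE)
  structure(list(features = features,
                 labels = unique(vapply(features, `[[`, "", "habitat"))),
            class = "habitat_map")
}

#' Write a habitat map to GeoJSON
#' @param map a `habitat_map` (or list of features with `habitat`, `coords`).
#' @param path output path.
#' @export
write_habitat_map <- function(map, path) {
  features <- if (inherits(map, "habitat_map")) map$features else map
  fs <- lapply(features, function(f) {
    xy <- rbind(f$coords, f$coords[1, ])
    list(type = "Feature",
         properties = list(habitat = f$habitat),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(xy)),
                                                   function(i) as.numeric(xy[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", units = "km",
                            features = fs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Total area of one habitat in a map
#' @param map a `habitat_map`.
#' @param habitat habitat label.
#' @return area in km^2 summed over the habitat's polygons.
#' @export
habitat_area <- function(map, habitat) {
  polys <- Filter(function(f) f$habitat == habitat, map$features)
  if (!length(polys)) stop(sprintf("no polygons labelled '%s'", habitat))
  sum(vapply(polys, function(f) polygon_area(f$coords), numeric(1)))
}

#' Assign points to habitats
#'
#' Boundary points go to the first containing polygon in file order.
#'
#' @param map a `habitat_map`.
#' @param x,y point coordinates (km).
#' @return character vector of habitat labels, `NA` where a point falls in no
#'   polygon.
#' @export
assign_habitat <- function(map, x, y) {
  out <- rep(NA_character_, length(x))
  for (f in map$features) {
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- point_in_polygon(x[todo], y[todo], f$coords)
    out[todo][hit] <- f$habitat
  }
  out
}
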