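# Shared fixture builders: everything is generated in code at test time.

ts <- function(x) as.POSIXct(x, tz = "UTC")

# minimal deployment table: n cameras on a line, each active [start, end)
make_deployments <- function(n = 3, start = "2010-08-01 00:00:00",
                             end = "2010-08-11 00:00:00",
                             habitat = "grassland") {
  as_deployments(data.frame(
    camera_id = sprintf("C%02d", seq_len(n)),
    x = seq_len(n), y = rep(1, n),
    start = start, end = end, habitat = habitat,
    stringsAsFactors = FALSE))
}

make_events <- function(camera_id, timestamp, count = 1L,
                        deployments = NULL) {
  as_event_records(data.frame(
    camera_id = camera_id, timestamp = timestamp,
    species = "lion", sex = "female", count = count,
    stringsAsFactors = FALSE), deployments = deployments)
}

# hand-built encounter rate with known variance, for variance-propagation
# tests that need rate uncertainty decoupled from any bootstrap
fixed_rate <- function(rate, cv) {
  structure(list(rate = rate, y_total = NA_real_, t_total = NA_real_,
                 var_boot = (cv * rate)^2, n_boot = 1L, seed = NULL),
            class = "encounter_rate")
}

# uniform utilization distribution over a w x h rectangle (cells of edge
# `cell`), bypassing the KDE: used for closed-form isopleth checks
uniform_ud <- function(w = 10, h = 10, cell = 0.25) {
  gx <- seq(cell / 2, w - cell / 2, by = cell)
  gy <- seq(cell / 2, h - cell / 2, by = cell)
  z <- matrix(1 / (length(gx) * length(gy)), length(gx), length(gy))
  structure(list(x = gx, y = gy, z = z, bandwidth = NA_real_, cell = cell),
            class = "utilization_distribution")
}

square <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
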