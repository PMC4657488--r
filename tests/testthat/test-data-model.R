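test_that("deployment reader validates rows and reports effort", {
  df <- data.frame(camera_id = c("A", "B", "C"),
                   x = 1:3, y = 1, start = "2010-08-01 00:00:00",
                   end = "2010-08-03 00:00:00", habitat = "grassland")
  dep <- read_deployments(tmp_csv(df))
  expect_s3_class(dep, "deployments")
  expect_equal(nrow(dep), 3)
  expect_equal(dep$effort_hours, rep(48, 3))

  bad <- df
  bad$end[2] <- "2010-07-01 00:00:00"
  expect_error(read_deployments(tmp_csv(bad)), "row 2")
  expect_warning(dep2 <- read_deployments(tmp_csv(bad), permissive = TRUE),
                 "row 2")
  expect_equal(nrow(dep2), 2)

  expect_error(read_deployments(tmp_csv(df[, -1])), "missing required column")
  # column mapping for foreign exports
  foreign <- df
  names(foreign)[1] <- "site"
  expect_equal(nrow(read_deployments(tmp_csv(foreign),
                                     col_map = c(camera_id = "site"))), 3)
})

test_that("event reader sorts, validates timestamps and camera ids", {
  dep <- make_deployments(2)
  df <- data.frame(camera_id = c("C02", "C01"),
                   timestamp = c("2010-08-02 10:00:00", "2010-08-03 11:00:00"),
                   species = "lion", sex = "female", count = 1)
  ev <- read_events(tmp_csv(df), deployments = dep)
  expect_equal(ev$camera_id, c("C01", "C02"))  # sorted

  bad <- df
  bad$timestamp[1] <- "2010-13-01 25:00"
  expect_error(read_events(tmp_csv(bad)), "row 1")

  unk <- df
  unk$camera_id[1] <- "C99"
  expect_error(read_events(tmp_csv(unk), deployments = dep), "unknown camera")

  outside <- df
  outside$timestamp[2] <- "2010-09-20 11:00:00"
  expect_error(read_events(tmp_csv(outside), deployments = dep),
               "outside camera deployment")
})

test_that("tables round-trip through CSV exactly", {
  dep <- make_deployments(4)
  p1 <- tempfile(fileext = ".csv")
  write_deployments(dep, p1)
  expect_equal(as.data.frame(read_deployments(p1)), as.data.frame(dep))

  ev <- make_events(c("C01", "C02"),
                    c("2010-08-02 10:00:00", "2010-08-02 11:30:05"),
                    count = c(2L, 1L), deployments = dep)
  p2 <- tempfile(fileext = ".csv")
  write_events(ev, p2)
  expect_equal(as.data.frame(read_events(p2, deployments = dep)),
               as.data.frame(ev))
})

test_that("habitat maps read, validate and measure polygons", {
  path <- tempfile(fileext = ".geojson")
  write_habitat_map(list(
    list(habitat = "grassland", coords = square(0, 0, 80, 20)),
    list(habitat = "woodland", coords = square(80, 0, 100, 20))), path)
  map <- read_habitat_map(path)
  expect_s3_class(map, "habitat_map")
  expect_equal(map$labels, c("grassland", "woodland"))
  # 100 x 20 strip split 80/20 -> 1600 and 400 km^2
  expect_equal(habitat_area(map, "grassland"), 1600)
  expect_equal(habitat_area(map, "woodland"), 400)

  expect_equal(assign_habitat(map, c(10, 90, 150), c(5, 5, 5)),
               c("grassland", "woodland", NA))
  # shared boundary goes to the first polygon in file order
  expect_equal(assign_habitat(map, 80, 10), "grassland")

  bow <- tempfile(fileext = ".geojson")
  write_habitat_map(list(
    list(habitat = "grassland", coords = cbind(c(0, 2, 0, 2), c(0, 2, 2, 0)))),
    bow)
  expect_error(read_habitat_map(bow), "self-intersecting")

  # small planar coordinates without declared units look geographic
  nounits <- tempfile(fileext = ".geojson")
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  gj$units <- NULL
  jsonlite::write_json(gj, nounits, auto_unbox = TRUE, digits = NA)
  expect_error(read_habitat_map(nounits), "units")
  expect_s3_class(read_habitat_map(nounits, assume_planar = TRUE),
                  "habitat_map")
})

test_that("rem_params normalises units once and rejects nonsense", {
  p <- rem_params(V = 0.173, r = 14.42, se_r = 0.778, theta = 50.12,
                  se_theta = 1.557, r_unit = "m", angle_unit = "degrees")
  expect_equal(p$r, 0.01442)
  expect_equal(p$theta, 50.12 * pi / 180)
  # metres passed as km must never be silently absorbed
  expect_error(rem_params(V = 0.173, r = 14.42, theta = 0.87), "metres")
  expect_error(rem_params(V = 0, r = 0.01, theta = 0.87), "V must be > 0")
  expect_error(rem_params(V = 0.2, r = 0.01, theta = 7), "theta")
})

test_that("pride reader enforces the minimum relocation count", {
  pr <- data.frame(pride_id = c("P1", "P2"), n_females = c(6L, 4L),
                   season = "dry")
  obs <- data.frame(pride_id = rep(c("P1", "P2"), c(6, 3)),
                    x = rnorm(9), y = rnorm(9),
                    timestamp = "2010-07-01 12:00:00")
  expect_error(read_prides(tmp_csv(pr), tmp_csv(obs)), "P2")
  obs_ok <- rbind(obs, data.frame(pride_id = "P2", x = 0:1, y = 0:1,
                                  timestamp = "2010-07-02 12:00:00"))
  prides <- read_prides(tmp_csv(pr), tmp_csv(obs_ok))
  expect_length(prides, 2)
  expect_equal(prides[[1]]$n_females, 6L)
  expect_equal(nrow(prides[[2]]$observations), 5)
})
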