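test_that("trigger runs collapse into independent events with chaining", {
  dep <- make_deployments(1)
  base <- ts("2010-08-02 12:00:00")
  # 0 s, 30 s, 20 min with a 10-min gap -> 2 events
  ev <- make_events(rep("C01", 3), base + c(0, 30, 1200), deployments = dep)
  out <- collapse_events(ev, gap_min = 10)
  expect_equal(nrow(out), 2)
  expect_equal(out$timestamp, base + c(0, 1200))  # stamped with first trigger

  # chained merging: 0, 9, 18 min all merge although 0 -> 18 exceeds the gap
  ev2 <- make_events(rep("C01", 3), base + c(0, 9, 18) * 60, deployments = dep)
  expect_equal(nrow(collapse_events(ev2, gap_min = 10)), 1)

  # single trigger passes through; merged count keeps the largest group
  expect_equal(nrow(collapse_events(ev2[1, ], gap_min = 10)), 1)
  ev3 <- make_events(rep("C01", 2), base + c(0, 60), count = c(1L, 3L),
                     deployments = dep)
  expect_equal(collapse_events(ev3, gap_min = 10)$count, 3L)

  expect_error(collapse_events(ev[c(3, 1, 2), ], gap_min = 10), "sorted")
  expect_error(collapse_events(ev, gap_min = 0), "gap_min")
})

test_that("collapsing is idempotent and respects camera boundaries", {
  dep <- make_deployments(2)
  base <- ts("2010-08-02 12:00:00")
  set.seed(11)
  raw <- make_events(sample(c("C01", "C02"), 40, TRUE),
                     base + sort(sample.int(7200, 40)), deployments = dep)
  once <- collapse_events(raw, gap_min = 15)
  twice <- collapse_events(once, gap_min = 15)
  expect_identical(as.data.frame(once), as.data.frame(twice))
  # same-instant triggers at different cameras stay distinct events
  sim <- make_events(c("C01", "C02"), rep(base, 2), deployments = dep)
  expect_equal(nrow(collapse_events(sim, gap_min = 15)), 2)
})

test_that("night classification is the half-open window [18:00, 06:00)", {
  stamps <- ts(c("2010-08-02 17:59:59", "2010-08-02 18:00:00",
                 "2010-08-03 00:30:00", "2010-08-03 06:00:00",
                 "2010-08-03 05:59:59", "2010-08-03 12:00:00"))
  expect_equal(is_night(stamps), c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE))
  # a non-wrapping window also works
  expect_equal(is_night(stamps, window = c(6, 18)),
               c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
})

test_that("night and day events partition the independent events", {
  dep <- make_deployments(3)
  set.seed(7)
  stamps <- ts("2010-08-01 00:00:00") + runif(200, 0, 9 * 86400)
  ev <- make_events(sample(dep$camera_id, 200, TRUE), stamps,
                    deployments = dep)
  ind <- collapse_events(ev, gap_min = 15)
  n_night <- sum(is_night(ind$timestamp))
  n_day <- sum(!is_night(ind$timestamp))
  expect_equal(n_night + n_day, nrow(ind))
})

test_that("stratum effort counts hours, halves for night, filters habitat", {
  dep <- make_deployments(1)  # 10 full days
  expect_equal(stratum_effort(dep), 240)
  expect_equal(stratum_effort(dep, window = "night"), 120)

  two <- as_deployments(data.frame(
    camera_id = c("G1", "W1"), x = c(5, 95), y = 5,
    start = "2010-08-01 00:00:00", end = "2010-08-11 00:00:00",
    habitat = c("grassland", "woodland")))
  expect_equal(stratum_effort(two, habitat = "grassland"), 240)

  path <- tempfile(fileext = ".geojson")
  write_habitat_map(list(
    list(habitat = "grassland", coords = square(0, 0, 80, 20)),
    list(habitat = "woodland", coords = square(80, 0, 100, 20))), path)
  map <- read_habitat_map(path)
  expect_equal(stratum_effort(two, habitat = "woodland", map = map), 240)
  # camera outside every polygon is excluded with a warning
  three <- as_deployments(data.frame(
    camera_id = c("G1", "W1", "X1"), x = c(5, 95, 300), y = 5,
    start = "2010-08-01 00:00:00", end = "2010-08-11 00:00:00",
    habitat = "grassland"))
  expect_warning(e <- stratum_effort(three, habitat = "grassland", map = map),
                 "outside")
  expect_equal(e, 240)
})

test_that("encounter rate is the ratio of totals", {
  t1 <- data.frame(camera_id = "A", y = 5, t = 1200)
  expect_equal(encounter_rate(t1)$rate, 5 / 1200)
  t2 <- data.frame(camera_id = c("A", "B"), y = c(0, 0), t = c(10, 10))
  expect_equal(encounter_rate(t2)$rate, 0)
  t3 <- data.frame(camera_id = c("A", "B"), y = c(0, 10), t = c(240, 240))
  expect_equal(encounter_rate(t3)$rate, 10 / 480)
  expect_error(encounter_rate(data.frame(camera_id = "A", y = 0, t = 0)),
               "no effort")
  # invariant to splitting one camera's record into sub-deployments
  split3 <- data.frame(camera_id = c("A", "B1", "B2"), y = c(0, 4, 6),
                       t = c(240, 100, 140))
  expect_equal(encounter_rate(split3)$rate, encounter_rate(t3)$rate)
})

test_that("bootstrap variance matches exhaustive resampling enumeration", {
  # two cameras: 2^2 equally likely resamples give rates {0, .5, .5, 1},
  # population variance 0.125
  t2 <- data.frame(camera_id = c("A", "B"), y = c(0, 10), t = c(10, 10))
  br <- bootstrap_rate(t2, n_boot = 1e5, seed = 42)
  expect_equal(br$rate, 0.5)
  expect_equal(br$var_boot, 0.125, tolerance = 0.02)
  expect_equal(br$seed, 42)

  # three cameras: full 3^3 enumeration oracle
  t3 <- data.frame(camera_id = c("A", "B", "C"), y = c(0, 5, 10),
                   t = c(10, 10, 10))
  idx <- expand.grid(1:3, 1:3, 1:3)
  rates <- apply(idx, 1, function(k) sum(t3$y[k]) / sum(t3$t[k]))
  exact <- mean((rates - mean(rates))^2)
  br3 <- bootstrap_rate(t3, n_boot = 1e5, seed = 42)
  expect_equal(br3$var_boot, exact, tolerance = 0.03)

  # no heterogeneity -> zero variance
  same <- data.frame(camera_id = c("A", "B", "C"), y = c(2, 2, 2),
                     t = c(10, 10, 10))
  expect_equal(bootstrap_rate(same, n_boot = 100, seed = 1)$var_boot, 0)

  expect_error(bootstrap_rate(t2[1, ], n_boot = 10, seed = 1),
               "single camera")
})

test_that("camera tallies assemble y and t per stratum window", {
  dep <- make_deployments(2)
  base <- ts("2010-08-02 12:00:00")
  ev <- make_events(c("C01", "C01", "C02"),
                    c(base, base + 10 * 3600, base + 11 * 3600),
                    count = c(2L, 1L, 1L), deployments = dep)
  tal <- camera_tallies(ev, dep)
  expect_equal(tal$y, c(2, 1))
  expect_equal(tal$t, c(240, 240))
  tal_n <- camera_tallies(ev, dep, window = "night")
  expect_equal(tal_n$y, c(1, 1))  # 22:00 and 23:00 events
  expect_equal(tal_n$t, c(120, 120))
  tal_i <- camera_tallies(ev, dep, per_individual = TRUE)
  expect_equal(tal_i$y, c(3, 1))
})
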