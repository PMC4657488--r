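test_that("segment-sector crossing geometry is exact", {
  # camera at origin facing +x, r = 1, theta = 90 degrees
  th <- pi / 2
  # straight pass through the zone: enters and exits
  iv <- remcam:::cpp_seg_sector(2, 0.2, -2, 0.2, 0, 0, 0, 1, th)
  expect_length(iv, 2)
  expect_true(iv[1] > 0 && iv[2] < 1)
  # segment that misses the sector (stays behind the wedge)
  expect_length(remcam:::cpp_seg_sector(-2, 0.5, -0.2, 0.5, 0, 0, 0, 1, th), 0)
  # endpoint inside
  iv2 <- remcam:::cpp_seg_sector(2, 0, 0.5, 0, 0, 0, 0, 1, th)
  expect_equal(iv2[2], 1)
  # wedge boundary: approach at 46 degrees off-axis misses a 90-degree sector
  p <- c(cos(46 * pi / 180), sin(46 * pi / 180)) * 0.5
  expect_length(remcam:::cpp_seg_sector(p[1], p[2], p[1], p[2], 0, 0, 0, 1, th), 0)
  # reflex sector (theta > pi) covers that same point
  expect_length(remcam:::cpp_seg_sector(p[1], p[2], p[1], p[2], 0, 0, 0, 1,
                                        1.9 * pi), 2)
})

test_that("the simulator is reproducible and degenerates sensibly", {
  cfg <- sim_config(arena = c(5, 5), density = 2, duration_h = 100,
                    n_cameras = 4, seed = 123)
  a <- simulate_encounters(cfg)
  b <- simulate_encounters(cfg)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  expect_identical(a$truth, b$truth)

  # zero animals -> zero events
  none <- simulate_encounters(sim_config(arena = c(5, 5), density = 0,
                                         duration_h = 50, n_cameras = 4,
                                         seed = 1))
  expect_equal(none$n_events, 0)

  # a bias scenario with q = 0 is exactly the unbiased model
  c0 <- sim_config(arena = c(5, 5), density = 2, duration_h = 100,
                   n_cameras = 4, bias_q = 0, seed = 123)
  expect_identical(as.data.frame(simulate_encounters(c0)$events),
                   as.data.frame(a$events))

  expect_error(sim_config(arena = c(1, 1), r = 0.6), "larger than the arena")
})

test_that("a near-full-circle zone spanning the arena saturates detections", {
  cfg <- sim_config(arena = c(6, 6), density = 2, speed = 0.2, r = 2.9,
                    theta = 2 * pi - 0.01, n_cameras = 1, duration_h = 50,
                    seed = 4)
  b <- simulate_encounters(cfg)
  expect_gt(b$n_events, b$truth$n_animals)  # every animal contacts repeatedly
})

test_that("event counts are invariant to halving the time step", {
  # straight-line movers with exact entry detection: dt only discretises the
  # path into collinear segments, so the events are identical
  c1 <- sim_config(arena = c(5, 5), density = 5, duration_h = 200,
                   n_cameras = 9, dt_min = 1, seed = 9)
  c2 <- sim_config(arena = c(5, 5), density = 5, duration_h = 200,
                   n_cameras = 9, dt_min = 0.5, seed = 9)
  n1 <- simulate_encounters(c1)$n_events
  n2 <- simulate_encounters(c2)$n_events
  expect_lt(abs(n2 - n1) / n1, 0.02)
})

test_that("unbiased encounter rates match the ideal-gas closed form", {
  th <- 50 * pi / 180
  rates <- vapply(1:30, function(s) {
    b <- simulate_encounters(sim_config(arena = c(5, 5), density = 5,
                                        duration_h = 500, n_cameras = 9,
                                        seed = s))
    b$n_events / (9 * 500)
  }, numeric(1))
  expected <- gas_rate(5, 0.2, 0.01, th)
  expect_equal(mean(rates), expected,
               tolerance = 3 * sd(rates) / sqrt(30) / expected)
})

test_that("daytime camera attraction inflates day events only", {
  cfg <- sim_config(arena = c(8, 8), density = 5, duration_h = 240,
                    n_cameras = 16, bias_q = 0.1, bias_rest_h = 2, seed = 31)
  b <- simulate_encounters(cfg)
  night <- is_night(b$events$timestamp)
  expect_gt(sum(!night), sum(night))  # day >> night under bias
  # all-events estimate grossly exceeds truth; night-only stays near it
  p <- rem_params(V = cfg$speed, r = cfg$r, theta = cfg$theta)
  D_all <- rem_density(encounter_rate(camera_tallies(b$events, b$deployments)), p)
  D_night <- rem_density(
    encounter_rate(camera_tallies(b$events, b$deployments, window = "night")), p)
  expect_gt(D_all, 2 * b$truth$density)
  expect_lt(abs(D_night - b$truth$density), D_all - b$truth$density)
})

test_that("fixture generators hit their stated geometry and truths", {
  grid <- sim_camera_grid(20, 42, cell_km2 = 5)
  expect_lt(abs(nrow(grid) - 168), 10)
  sp <- sort(unique(grid$x))
  expect_equal(sp[2] - sp[1], sqrt(5), tolerance = 0.05)

  # noiseless trials recover the true zone exactly
  tr <- sim_detection_trials(r_m = 14.4, theta_deg = 50, sd_m = 0, sd_deg = 0,
                             centre_deg = 0, seed = 2)
  z <- estimate_detection_zone(tr$distances_m, tr$bearings_left,
                               tr$bearings_right)
  expect_equal(z$r * 1000, 14.4)
  expect_equal(z$theta, 50 * pi / 180)
  expect_equal(z$se_theta, 0)

  # pride cloud fully inside a habitat gives p = 1 downstream
  pr <- sim_prides(data.frame(pride_id = "P1", n_females = 6L, season = "dry",
                              cx = 50, cy = 50, sd_km = 1), n_obs = 40,
                   seed = 3)
  ud <- fit_ud(pr$observations$x, pr$observations$y)
  hr <- isopleth(ud, 0.75)
  expect_equal(overlap_proportion(hr, square(0, 0, 100, 100)), 1)
})

test_that("same-seed runs write byte-identical fixture files", {
  b <- simulate_encounters(sim_config(arena = c(5, 5), density = 2,
                                      duration_h = 100, n_cameras = 4,
                                      seed = 77))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_events(b$events, f1)
  write_events(simulate_encounters(sim_config(arena = c(5, 5), density = 2,
                                              duration_h = 100, n_cameras = 4,
                                              seed = 77))$events, f2)
  expect_identical(readLines(f1), readLines(f2))
})
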