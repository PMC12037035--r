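drift_track <- function(n = 40, v = 0.5, dt = 0.1, theta = 0.3) {
  data.frame(frame = seq_len(n),
             x_um = v * dt * (seq_len(n) - 1) * cos(theta),
             y_um = v * dt * (seq_len(n) - 1) * sin(theta))
}

test_that("linking reconstructs simple and crossing geometries", {
  one <- data.frame(frame = 1:25, x_um = 0.01 * (1:25), y_um = 0)
  tk <- link_detections(one, max_link_um = 0.5)
  expect_equal(length(unique(tk$track_id)), 1)
  expect_equal(nrow(tk), 25)

  two <- rbind(data.frame(frame = 1:20, x_um = 0, y_um = 0),
               data.frame(frame = 1:20, x_um = 10, y_um = 0))
  tk2 <- link_detections(two, max_link_um = 1)
  expect_equal(length(unique(tk2$track_id)), 2)
  expect_true(all(tapply(tk2$x_um, tk2$track_id, function(x) length(unique(x))) == 1))

  # two tracks crossing in y while > max_link apart at the crossing frame
  a <- data.frame(frame = 1:21, x_um = seq(0, 2, length.out = 21), y_um = 0)
  b <- data.frame(frame = 1:21, x_um = seq(2, 0, length.out = 21), y_um = 0.8)
  tk3 <- link_detections(rbind(a, b), max_link_um = 0.3)
  expect_equal(length(unique(tk3$track_id)), 2)
  for (id in unique(tk3$track_id)) {
    expect_equal(length(unique(tk3$y_um[tk3$track_id == id])), 1)
  }

  expect_error(link_detections(rbind(one, one[1, ]), max_link_um = 1),
               "duplicate")
})

test_that("linking is invariant to detection row order and bridges gaps", {
  sim <- simulate_trajectories(5, 30, seed = 3)
  det <- as.data.frame(sim$tracks)[, c("frame", "x_um", "y_um")]
  shuf <- det[sample.int(nrow(det)), ]
  t1 <- link_detections(det, max_link_um = 0.5)
  t2 <- link_detections(shuf, max_link_um = 0.5)
  expect_equal(as.data.frame(t1), as.data.frame(t2))

  gap <- data.frame(frame = c(1:10, 13:20), x_um = 0.01 * c(1:10, 13:20),
                    y_um = 0)
  expect_equal(length(unique(link_detections(gap, 0.5, max_gap = 2)$track_id)), 1)
  expect_equal(length(unique(link_detections(gap, 0.5, max_gap = 1)$track_id)), 2)
})

test_that("MSD matches closed forms and the double-loop oracle", {
  still <- data.frame(frame = 1:30, x_um = 2, y_um = -1)
  expect_true(all(msd_curve(still, 5, dt_s = 0.1)$msd_um2 == 0))

  dr <- drift_track(n = 40, v = 0.5, dt = 0.1)
  m <- msd_curve(dr, 6, dt_s = 0.1)
  expect_equal(m$msd_um2, (0.5 * m$lag_s)^2, tolerance = 1e-12)

  sim <- simulate_trajectories(3, 60, seed = 9)
  for (tr in split_tracks(sim$tracks)) {
    m <- msd_curve(tr, 8)
    for (lag in c(1, 4, 8)) {
      expect_equal(m$msd_um2[lag], oracle_msd(tr$x_um, tr$y_um, lag),
                   tolerance = 1e-12)
    }
  }
})

test_that("diffusion is recovered from Brownian MSD slopes", {
  br <- simulate_trajectories(200, 100, switch_prob = 0,
                              start_state = "confined",
                              confinement_radius_um = Inf,
                              D_confined_um2s = 0.05, loc_error_um = 0,
                              seed = 17)
  D_hat <- mean(vapply(split_tracks(br$tracks),
                       function(tr) estimate_diffusion(msd_curve(tr, 4)),
                       numeric(1)))
  expect_equal(D_hat, 0.05, tolerance = 0.15)
})

test_that("motion classification separates drift, confinement, diffusion", {
  expect_setequal(unique(classify_motion(drift_track(), window = 16)), "active")

  conf <- simulate_trajectories(1, 200, switch_prob = 0,
                                start_state = "confined",
                                D_confined_um2s = 5e-3,
                                confinement_radius_um = 0.04,
                                loc_error_um = 0.005, seed = 5)
  lab <- classify_motion(split_tracks(conf$tracks)[[1]], window = 24)
  expect_gt(mean(lab == "confined"), 0.8)

  # track shorter than the window gets one whole-track label
  short <- drift_track(n = 10)
  expect_equal(length(unique(classify_motion(short, window = 16))), 1)
  expect_error(classify_motion(drift_track(), window = 4), "window")
})

test_that("two-state tracks are labeled with >= 90% frame accuracy", {
  st <- simulate_trajectories(40, 200, dt_s = 0.1,
                              D_confined_um2s = 5e-3, D_active_um2s = 2e-3,
                              drift_speed_um_s = 0.5, switch_prob = 0.005,
                              confinement_radius_um = 0.04,
                              loc_error_um = 0.005, seed = 21)
  acc <- mapply(function(tr, states) {
    mean(classify_motion(tr, window = 24) == states)
  }, split_tracks(st$tracks), st$ground_truth$states)
  expect_gte(mean(acc), 0.9)
})

test_that("speeds follow closed forms and geometric invariances", {
  expect_equal(mean_speed(data.frame(frame = 1:10, x_um = 1, y_um = 2),
                          dt_s = 0.1), 0)
  expect_equal(mean_speed(drift_track(v = 0.37, dt = 0.1), dt_s = 0.1), 0.37)

  # Brownian 2D step length is Rayleigh: E[speed] = sqrt(pi * D / dt)
  br <- simulate_trajectories(300, 50, switch_prob = 0,
                              start_state = "confined",
                              confinement_radius_um = Inf,
                              D_confined_um2s = 0.02, loc_error_um = 0,
                              dt_s = 0.1, seed = 23)
  v_hat <- mean(vapply(split_tracks(br$tracks), mean_speed, numeric(1)))
  expect_equal(v_hat, sqrt(pi * 0.02 / 0.1), tolerance = 0.05)

  # translation and rotation leave speed and MSD unchanged
  tr <- split_tracks(simulate_trajectories(1, 50, seed = 2)$tracks)[[1]]
  phi <- 0.7
  rot <- tr
  rot$x_um <- cos(phi) * tr$x_um - sin(phi) * tr$y_um + 5
  rot$y_um <- sin(phi) * tr$x_um + cos(phi) * tr$y_um - 3
  expect_equal(mean_speed(rot, dt_s = 0.1), mean_speed(tr, dt_s = 0.1),
               tolerance = 1e-12)
  expect_equal(msd_curve(rot, 5, dt_s = 0.1)$msd_um2,
               msd_curve(tr, 5, dt_s = 0.1)$msd_um2, tolerance = 1e-12)
})

test_that("track summaries carry per-state fractions", {
  st <- simulate_trajectories(5, 60, seed = 12)
  s <- summarize_tracks(st$tracks)
  expect_equal(nrow(s), 5)
  expect_equal(s$frac_confined + s$frac_free + s$frac_active, rep(1, 5))
  expect_true(all(s$analyzed))
})

test_that("particles are detected from a movie and track end to end", {
  # three bright stationary spots over 12 frames
  nfr <- 12L
  arr <- array(0, c(48, 48, nfr))
  pts <- rbind(c(12, 12), c(12, 36), c(36, 24))
  for (f in seq_len(nfr)) {
    img <- matrix(0, 48, 48)
    for (k in 1:3) {
      d2 <- outer((seq_len(48) - pts[k, 1])^2, (seq_len(48) - pts[k, 2])^2, `+`)
      img <- img + 200 * exp(-d2 / (2 * 1.5^2))
    }
    arr[, , f] <- img
  }
  sc <- image_scene(list(CD20 = arr), pixel_size_um = 0.1,
                    frame_interval_s = 0.1)
  det <- detect_particles(sc)
  expect_equal(nrow(det), 3L * nfr)
  tracks <- link_detections(det, max_link_um = 0.3, dt_s = 0.1)
  expect_equal(length(unique(tracks$track_id)), 3L)
  expect_error(detect_particles(image_scene(list(a = matrix(1, 4, 4)), 1)),
               "not a movie")
})
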