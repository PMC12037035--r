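test_that("generators are bit-reproducible for a fixed seed", {
  a <- simulate_cluster_image(5, seed = 42, cell_mask_radius_um = 2,
                              image_size_px = 96)
  b <- simulate_cluster_image(5, seed = 42, cell_mask_radius_um = 2,
                              image_size_px = 96)
  expect_identical(a$scene$channels, b$scene$channels)
  expect_identical(a$ground_truth$centers_px, b$ground_truth$centers_px)

  expect_identical(simulate_coloc_pair(0.5, seed = 7)$scene$channels,
                   simulate_coloc_pair(0.5, seed = 7)$scene$channels)
  expect_identical(simulate_frap_series(0.5, 10, noise_sd = 0.02,
                                        seed = 3)$series,
                   simulate_frap_series(0.5, 10, noise_sd = 0.02,
                                        seed = 3)$series)
  expect_identical(as.data.frame(simulate_trajectories(3, 20, seed = 5)$tracks),
                   as.data.frame(simulate_trajectories(3, 20, seed = 5)$tracks))
  expect_identical(simulate_synapse_scene(2, seed = 8,
                                          noise_sd = 3)$scene$channels,
                   simulate_synapse_scene(2, seed = 8,
                                          noise_sd = 3)$scene$channels)
})

test_that("cluster scenes honor count, packing, and ground truth", {
  blank <- simulate_cluster_image(0, seed = 1, cell_mask_radius_um = 2,
                                  image_size_px = 96, noise_sd = 1)
  expect_equal(blank$ground_truth$n_clusters, 0)
  expect_lt(max(blank$scene$channels$CD20), 10)

  sim <- simulate_cluster_image(20, mean_radius_um = 0.25, noise_sd = 0,
                                min_separation_um = 1.25, seed = 11,
                                cell_mask_radius_um = 6, image_size_px = 280)
  # oracle: components above half-max in the noiseless raster
  mask <- sim$ground_truth$noiseless > sim$ground_truth$intensity / 2
  expect_equal(oracle_count_components(mask), 20)
  # impossible packing is a clean error
  expect_error(simulate_cluster_image(80, mean_radius_um = 0.5,
                                      min_separation_um = 4,
                                      cell_mask_radius_um = 3,
                                      image_size_px = 160, seed = 1),
               "impossible packing")
})

test_that("coloc pairs record the true pixel overlap", {
  full <- simulate_coloc_pair(1, n_spots = 10, noise_sd = 0, seed = 2)
  expect_identical(full$ground_truth$mask_a, full$ground_truth$mask_b)
  expect_equal(full$ground_truth$true_overlap, 1)

  none <- simulate_coloc_pair(0, n_spots = 10, noise_sd = 0, seed = 2)
  expect_false(any(none$ground_truth$mask_a & none$ground_truth$mask_b))
  expect_equal(none$ground_truth$true_overlap, 0)

  half <- simulate_coloc_pair(0.5, n_spots = 10, noise_sd = 0, seed = 2)
  gt <- half$ground_truth
  expect_equal(gt$true_overlap, sum(gt$mask_a & gt$mask_b) / sum(gt$mask_a))
  expect_gt(gt$true_overlap, 0.3)
  expect_lt(gt$true_overlap, 0.7)
})

test_that("FRAP traces follow the closed-form recovery model", {
  # Fm = 1, no acquisition bleach: asymptote returns to pre-bleach level
  s1 <- simulate_frap_series(1, tau_s = 5, acquisition_bleach_rate = 0,
                             noise_sd = 0, n_post = 200, dt_s = 0.5, seed = 1)
  roi <- s1$series$roi - s1$series$bg
  pre <- mean(roi[seq_len(s1$series$bleach_index - 1)])
  expect_equal(tail(roi, 1) / pre, 1, tolerance = 1e-6)

  # Fm = 0: post-bleach flat at (1 - depth) * pre
  s0 <- simulate_frap_series(0, tau_s = 5, bleach_depth = 0.8,
                             noise_sd = 0, seed = 1)
  roi0 <- s0$series$roi - s0$series$bg
  post <- roi0[seq.int(s0$series$bleach_index, length(roi0))]
  expect_equal(post, rep(0.2 * roi0[1], length(post)), tolerance = 1e-10)

  # half-recovery of the ideal curve at tau * ln 2
  s <- simulate_frap_series(0.6, tau_s = 20, bleach_depth = 1, noise_sd = 0,
                            n_post = 400, dt_s = 0.0866, seed = 1)
  roi <- s$series$roi - s$series$bg
  bi <- s$series$bleach_index
  t_post <- s$series$t_s - s$series$t_s[bi]
  target <- roi[1] * 0.6 / 2  # half of the full recovery (depth 1)
  t_half_obs <- t_post[bi - 1 + which.min(abs(roi[bi:length(roi)] - target))]
  expect_equal(t_half_obs, 20 * log(2), tolerance = 0.01)
  expect_equal(s$ground_truth$t_half_s, 20 * log(2))
})

test_that("trajectory generator matches its stated physics", {
  still <- simulate_trajectories(3, 30, D_confined_um2s = 0,
                                 drift_speed_um_s = 0, switch_prob = 0,
                                 start_state = "confined",
                                 loc_error_um = 0, seed = 1)
  per <- split_tracks(still$tracks)
  expect_true(all(vapply(per, function(tr) mean_speed(tr) == 0, logical(1))))
  expect_true(all(unlist(still$ground_truth$states) == "confined"))

  # pure 2D Brownian motion: MSD slope ~ 4D over 200 tracks
  br <- simulate_trajectories(200, 100, switch_prob = 0,
                              start_state = "confined",
                              confinement_radius_um = Inf,
                              D_confined_um2s = 0.05, loc_error_um = 0,
                              seed = 31)
  D_hat <- mean(vapply(split_tracks(br$tracks), function(tr) {
    estimate_diffusion(msd_curve(tr, 4))
  }, numeric(1)))
  expect_equal(D_hat, 0.05, tolerance = 0.1)
})

test_that("PLA scenes conserve spots and stay countable", {
  zero <- simulate_pla_image(0, cell_count = 3, seed = 1)
  expect_identical(zero$ground_truth$spots_per_cell, rep(0L, 3))

  pl <- simulate_pla_image(12, cell_count = 3, seed = 5, noise_sd = 0)
  expect_equal(sum(pl$ground_truth$spots_per_cell), 12)
  # well-separated spots are countable from the noiseless raster
  mask <- pl$ground_truth$noiseless_pla > max(pl$ground_truth$noiseless_pla) / 2
  expect_equal(oracle_count_components(mask), 12)
})

test_that("synapse scenes encode the stated enrichment exactly", {
  eq <- simulate_synapse_scene(3, enrichment_ratio = 1, noise_sd = 0, seed = 2)
  cd70 <- eq$ground_truth$noiseless_cd70
  for (cm in eq$ground_truth$contact_masks) {
    inm <- oracle_mask_mean(cd70, cm)
    out <- setdiff(which(cd70 > 0), cm)
    expect_equal(inm, oracle_mask_mean(cd70, out), tolerance = 1e-12)
  }

  mix <- simulate_synapse_scene(0, n_free_b_cells = 5, seed = 3)
  expect_equal(mix$ground_truth$n_synapses, 0)
  expect_equal(mix$ground_truth$n_b_cells, 5)

  two <- simulate_synapse_scene(2, enrichment_ratio = 2, noise_sd = 0, seed = 4)
  cd70 <- two$ground_truth$noiseless_cd70
  for (cm in two$ground_truth$contact_masks) {
    inm <- oracle_mask_mean(cd70, cm)
    out_px <- setdiff(which(cd70 > 0), unlist(two$ground_truth$contact_masks))
    expect_equal(inm / oracle_mask_mean(cd70, out_px), 2, tolerance = 1e-12)
  }
})

test_that("stamp scenes have 5-um discs and exact mask-mean ratios", {
  st <- simulate_stamp_scene(on_stamp_enrichment = 3, noise_sd = 0, seed = 2,
                             pixel_size_um = 0.1)
  gt <- st$ground_truth
  # a 5-um disc at 0.1 um/px spans ~50 px
  one <- label_components(gt$stamp_mask)$labels == 1
  rows <- range(which(apply(one, 1, any)))
  expect_equal(diff(rows) + 1, 50, tolerance = 0.05)
  rep_ch <- gt$noiseless_reporter
  on <- which(gt$stamp_mask & gt$cell_mask)
  off <- which(!gt$stamp_mask & gt$cell_mask)
  expect_equal(oracle_mask_mean(rep_ch, on) / oracle_mask_mean(rep_ch, off), 3)

  flat <- simulate_stamp_scene(on_stamp_enrichment = 1, noise_sd = 0, seed = 2)
  g2 <- flat$ground_truth
  expect_equal(oracle_mask_mean(g2$noiseless_reporter,
                                which(g2$stamp_mask & g2$cell_mask)),
               oracle_mask_mean(g2$noiseless_reporter,
                                which(!g2$stamp_mask & g2$cell_mask)))
})

test_that("bead tables are proportional without noise", {
  b <- simulate_calibration_beads(noise_cv = 0, gain = 0.004, seed = 1,
                                  sample_abc = c(0, 95000))
  beads <- b[b$role == "bead", ]
  expect_equal(beads$mfi, 0.004 * beads$abc)
  expect_equal(b$mfi[b$role == "sample"], c(0, 0.004 * 95000))
})
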