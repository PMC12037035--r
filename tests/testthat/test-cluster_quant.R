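make_scene <- function(img, ps = 0.05) {
  image_scene(list(CD20 = img), pixel_size_um = ps)
}

test_that("cluster detection recovers well-separated spots exactly", {
  for (n in c(0, 5, 20)) {
    sim <- simulate_cluster_image(n, mean_radius_um = 0.5, noise_sd = 0,
                                  min_separation_um = 2.5, seed = 100 + n,
                                  cell_mask_radius_um = 10,
                                  image_size_px = 450)
    res <- detect_clusters(sim$scene, "CD20", threshold_mode = "auto")
    expect_equal(nrow(res$clusters), n)
    expect_equal(n_regions(res$mask), n)
    if (n > 0) {
      expect_equal(sum(res$clusters$area_um2),
                   sum(sim$ground_truth$true_areas_um2), tolerance = 0.1)
    }
  }
})

test_that("degenerate cluster inputs behave per contract", {
  blank <- make_scene(matrix(0, 64, 64))
  res <- detect_clusters(blank, "CD20")
  expect_equal(nrow(res$clusters), 0)

  bad <- make_scene(matrix(1, 8, 8))
  bad$channels$CD20[3, 3] <- Inf
  expect_error(detect_clusters(bad, "CD20"), "non-finite")
  expect_error(detect_clusters(make_scene(matrix(1, 8, 8)), "CD20",
                               otsu_offset_percent = 150), "-100, 100")
})

test_that("a two-maxima blob is split by the watershed", {
  img <- matrix(0, 60, 60)
  for (ctr in list(c(30, 25), c(30, 37))) {
    d2 <- outer((seq_len(60) - ctr[1])^2, (seq_len(60) - ctr[2])^2, `+`)
    img <- img + 100 * exp(-d2 / (2 * 4^2))
  }
  # one connected blob above threshold, two intensity maxima
  expect_equal(oracle_count_components(img > otsu_threshold(img)), 1)
  res <- detect_clusters(make_scene(img), "CD20", maxima_min_distance_px = 5,
                         threshold_mode = "auto", smooth_sigma_px = 1)
  expect_equal(nrow(res$clusters), 2)
})

test_that("count and area are invariant under constant intensity offset", {
  sim <- simulate_cluster_image(10, noise_sd = 2, seed = 9,
                                cell_mask_radius_um = 4, image_size_px = 200)
  base <- detect_clusters(sim$scene, "CD20", threshold_mode = "otsu_offset",
                          otsu_offset_percent = 20)
  shifted_scene <- make_scene(sim$scene$channels$CD20 + 37.5)
  shifted <- detect_clusters(shifted_scene, "CD20",
                             threshold_mode = "otsu_offset",
                             otsu_offset_percent = 20)
  expect_equal(nrow(shifted$clusters), nrow(base$clusters))
  expect_equal(shifted$clusters$area_um2, base$clusters$area_um2)
  expect_identical(shifted$mask$labels, base$mask$labels)
})

test_that("detection is deterministic", {
  sim <- simulate_cluster_image(8, noise_sd = 3, seed = 13,
                                cell_mask_radius_um = 3, image_size_px = 150)
  a <- detect_clusters(sim$scene, "CD20")
  b <- detect_clusters(sim$scene, "CD20")
  expect_identical(a$mask$labels, b$mask$labels)
  expect_identical(a$clusters, b$clusters)
})

test_that("PLA spot counting conserves totals and filters by size", {
  pl <- simulate_pla_image(12, cell_count = 3, seed = 4, noise_sd = 1)
  res <- count_pla_spots(pl$scene)
  expect_equal(sum(res$counts$dots_per_cell), 12)
  expect_equal(sort(res$counts$dots_per_cell[res$counts$cell_id > 0]),
               sort(pl$ground_truth$spots_per_cell))

  # a min area above every spot's size excludes them all
  res2 <- count_pla_spots(pl$scene, min_spot_area_px = 500L)
  expect_equal(sum(res2$counts$dots_per_cell), 0)

  # no cells: empty result plus a warning
  dark <- image_scene(list(DAPI = matrix(0, 40, 40),
                           PLA = matrix(0, 40, 40)), pixel_size_um = 0.1)
  expect_warning(res3 <- count_pla_spots(dark), "no cells")
  expect_equal(nrow(res3$counts), 0)
})

test_that("watershed separates touching PLA spots", {
  # two Gaussian dots ~2 sigma apart merge above threshold
  img <- matrix(0, 40, 40)
  for (cx in c(18, 23)) {
    d2 <- outer((seq_len(40) - 20)^2, (seq_len(40) - cx)^2, `+`)
    img <- img + 200 * exp(-d2 / (2 * 2^2))
  }
  dapi <- matrix(0, 40, 40)
  d2 <- outer((seq_len(40) - 20)^2, (seq_len(40) - 20)^2, `+`)
  dapi[d2 <= 15^2] <- 40
  dapi[d2 <= 8^2] <- 150
  sc <- image_scene(list(DAPI = dapi, PLA = img), pixel_size_um = 0.1)
  expect_equal(oracle_count_components(img > otsu_threshold(img)), 1)
  res <- count_pla_spots(sc)
  expect_equal(sum(res$counts$dots_per_cell), 2)
})

test_that("bead calibration inverts the generator", {
  b <- simulate_calibration_beads(noise_cv = 0, gain = 0.005, seed = 1)
  beads <- b[b$role == "bead", ]
  curve <- fit_calibration_curve(beads)
  expect_equal(curve$slope, 1, tolerance = 1e-9)
  expect_equal(curve$r_squared, 1, tolerance = 1e-9)

  # a sample with a bead's MFI recovers that bead's ABC
  out <- calibrate_molecules(beads, beads$mfi[2])
  expect_equal(out$molecules, beads$abc[2], tolerance = 1e-9)
  expect_false(out$extrapolated)
  out2 <- calibrate_molecules(beads, max(beads$mfi) * 10)
  expect_true(out2$extrapolated)

  expect_error(fit_calibration_curve(beads[1:2, ]), "at least 3")
  neg <- beads; neg$mfi[1] <- -1
  expect_error(fit_calibration_curve(neg), "non-positive")
  expect_error(calibrate_molecules(beads, c(1, -2)), "positive")
})

test_that("noisy replicated beads recover ABC within 10%", {
  true_abc <- 95000
  rec <- vapply(1:10, function(s) {
    b <- simulate_calibration_beads(noise_cv = 0.05, gain = 0.005, seed = s,
                                    sample_abc = true_abc)
    calibrate_molecules(b[b$role == "bead", ],
                        b$mfi[b$role == "sample"])$molecules
  }, numeric(1))
  expect_lt(abs(mean(rec) - true_abc) / true_abc, 0.1)
})

test_that("molecule apportionment conserves the cell total", {
  cl <- data.frame(cluster_id = 1:3, integrated_intensity = c(10, 30, 60))
  out <- molecules_per_cluster(cl, 1e5)
  expect_equal(sum(out$molecules), 1e5, tolerance = 1e-9)
  expect_equal(out$molecules, c(1e4, 3e4, 6e4))

  one <- molecules_per_cluster(cl[1, ], 500)
  expect_equal(one$molecules, 500)
  two <- molecules_per_cluster(
    data.frame(cluster_id = 1:2, integrated_intensity = c(5, 5)), 100)
  expect_equal(two$molecules, c(50, 50))
})
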