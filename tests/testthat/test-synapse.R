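test_that("synapse detection finds every conjugate contact", {
  sy <- simulate_synapse_scene(3, enrichment_ratio = 2, seed = 5)
  det <- detect_synapses(sy$scene)
  expect_equal(n_regions(det), 3)
  for (k in det$region_ids) {
    dm <- which(det$labels == k)
    iou <- max(vapply(sy$ground_truth$contact_masks, function(cm) {
      length(intersect(dm, cm)) / length(union(dm, cm))
    }, numeric(1)))
    expect_gt(iou, 0.3)
  }
})

test_that("scenes without B cells yield zero synapses with a warning", {
  # a free T cell: CD3 disc, empty MHC II channel
  cd3 <- matrix(0, 80, 80)
  d2 <- outer((seq_len(80) - 40)^2, (seq_len(80) - 40)^2, `+`)
  cd3[d2 <= 20^2] <- 100
  sc <- image_scene(list(CD3 = cd3, MHCII = matrix(0, 80, 80),
                         CD70 = matrix(0, 80, 80)), pixel_size_um = 0.1)
  expect_warning(det <- detect_synapses(sc), "no MHC II")
  expect_equal(n_regions(det), 0)
})

test_that("cd3_top_percent = 100 degenerates to the whole foreground", {
  sy <- simulate_synapse_scene(2, seed = 6)
  det <- detect_synapses(sy$scene, cd3_top_percent = 100, min_region_px = 10)
  cd3 <- scene_channel(sy$scene, "CD3")
  fg <- cd3 > otsu_threshold(cd3)
  expect_equal(sum(det$labels > 0), sum(fg))
})

test_that("recruitment scoring reproduces the generator ratio", {
  sy <- simulate_synapse_scene(3, enrichment_ratio = 2, noise_sd = 0, seed = 7)
  det <- detect_synapses(sy$scene)
  recs <- score_synapses(sy$scene, det, seed = 1)
  expect_true(all(recs$scored))
  expect_equal(recs$enrichment_pct, rep(200, 3), tolerance = 0.005)
  expect_true(all(recs$recruited))

  flat <- simulate_synapse_scene(3, enrichment_ratio = 1, noise_sd = 0,
                                 seed = 8)
  det1 <- detect_synapses(flat$scene)
  recs1 <- score_synapses(flat$scene, det1, seed = 1)
  expect_false(any(recs1$recruited))
})

test_that("the recruitment threshold is inclusive at exactly 150%", {
  sy <- simulate_synapse_scene(2, enrichment_ratio = 1.5, noise_sd = 0,
                               seed = 9)
  det <- detect_synapses(sy$scene)
  recs <- score_synapses(sy$scene, det, seed = 1)
  expect_equal(recs$enrichment_pct, rep(150, 2), tolerance = 1e-9)
  expect_true(all(recs$recruited))          # "150% or higher"
  # and just below the threshold it flips
  low <- simulate_synapse_scene(2, enrichment_ratio = 1.49, noise_sd = 0,
                                seed = 9)
  det2 <- detect_synapses(low$scene)
  recs2 <- score_synapses(low$scene, det2, seed = 1)
  expect_false(any(recs2$recruited))
})

test_that("control placement is seeded and reproducible", {
  sy <- simulate_synapse_scene(2, enrichment_ratio = 2, noise_sd = 4, seed = 3)
  # with noise the top percentile must roughly match the contact area
  # fraction of the CD3 foreground (~3%) for the contact to be found
  det <- detect_synapses(sy$scene, cd3_top_percent = 3, min_region_px = 15)
  expect_gt(n_regions(det), 0)
  r1 <- score_synapses(sy$scene, det, seed = 11)
  r2 <- score_synapses(sy$scene, det, seed = 11)
  expect_identical(r1, r2)
  r3 <- score_synapses(sy$scene, det, seed = 12)
  expect_false(identical(r1$out_mean, r3$out_mean))
})

test_that("synapses per cell follow the generator counts", {
  sy <- simulate_synapse_scene(4, n_free_b_cells = 4, seed = 10)
  det <- detect_synapses(sy$scene)
  tab <- synapses_per_cell(sy$scene, det)
  expect_equal(tab$n_synapses, 4)
  expect_equal(tab$n_b_cells, 8)
  expect_equal(tab$n_t_cells, 4)
  expect_equal(tab$synapses_per_b_cell, 0.5)

  none <- simulate_synapse_scene(0, n_free_b_cells = 5, seed = 11)
  det0 <- suppressWarnings(detect_synapses(none$scene))
  tab0 <- suppressWarnings(synapses_per_cell(none$scene, det0))
  expect_equal(tab0$n_synapses, 0)
  expect_equal(tab0$synapses_per_b_cell, 0)

  # zero B cells: missing value, not an error
  cd3 <- matrix(0, 60, 60); cd3[20:40, 20:40] <- 100
  sc <- image_scene(list(CD3 = cd3, MHCII = matrix(0, 60, 60)),
                    pixel_size_um = 0.1)
  empty_det <- label_mask(matrix(0L, 60, 60))
  tab2 <- synapses_per_cell(sc, empty_det)
  expect_true(is.na(tab2$synapses_per_b_cell))
})

test_that("stamp enrichment matches the generator and rejects empty stamps", {
  st <- simulate_stamp_scene(on_stamp_enrichment = 3, noise_sd = 0, seed = 2)
  out <- stamp_enrichment(st$scene)
  expect_equal(out$ratio, 3, tolerance = 1e-9)

  flat <- simulate_stamp_scene(on_stamp_enrichment = 1, noise_sd = 1, seed = 3)
  expect_equal(stamp_enrichment(flat$scene)$ratio, 1, tolerance = 0.02)

  dark <- image_scene(list(stamp = matrix(0, 50, 50),
                           reporter = matrix(1, 50, 50)), pixel_size_um = 0.1)
  expect_error(stamp_enrichment(dark), "empty stamp")
})

test_that("group comparison aggregates per image and tests ranks", {
  mk <- function(images, frac, seed) {
    set.seed(seed)
    do.call(rbind, lapply(seq_len(images), function(i) {
      rec <- runif(10) < frac
      data.frame(image = i, recruited = rec,
                 enrichment_pct = ifelse(rec, 200, 100) + rnorm(10, 0, 5))
    }))
  }
  res <- compare_groups(mk(10, 0.6, 1), mk(10, 0.25, 2))
  expect_equal(nrow(res$per_image), 20)
  expect_lt(res$tests$p_recruited_fraction, 0.05)

  # identical groups: no signal
  same <- mk(10, 0.5, 3)
  res2 <- compare_groups(same, mk(10, 0.5, 4))
  expect_gt(res2$tests$p_recruited_fraction, 0.05)

  # one image per group: p missing
  res3 <- compare_groups(mk(1, 0.5, 5), mk(1, 0.5, 6))
  expect_true(is.na(res3$tests$p_recruited_fraction))
})
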