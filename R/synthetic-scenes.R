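# Synthetic fluorescence scenes with exact ground truth.
#
# Every generator returns the scene together with a `ground_truth` list
# recording the generating parameters and the noiseless intermediate
# rasters/masks, so that independent brute-force oracles (pixel counting,
# mask means, connected components) can verify the recorded quantities.
# Cells are discs, membranes are ~3-px annuli, the PSF is an isotropic
# Gaussian (sigma 0.1 um, the Airyscan regime), and noise is additive
# Gaussian clipped at zero.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

.add_noise <- function(m, sd) {
  if (sd <= 0) return(m)
  m <- m + rnorm(length(m), 0, sd)   # recycling keeps dim
  m[m < 0] <- 0
  m
}

# add `value` to pixels whose centre lies within radius r of (cy, cx);
# bounding-box restricted. Coordinates in pixels (1-based row/col).
.paint_disc <- function(img, cy, cx, r, value, set = FALSE) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(img)
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
  sel <- d2 <= r^2
  block <- img[rows, cols, drop = FALSE]
  block[sel] <- if (set) value else block[sel] + value
  img[rows, cols] <- block
  img
}

.disc_mask <- function(nr, nc, cy, cx, r) {
  m <- matrix(FALSE, nr, nc)
  .paint_disc(m * 0, cy, cx, r, 1) > 0
}

# rejection-sample `n` centres inside a disc with pairwise min separation
.place_centers <- function(n, cy, cx, max_r, min_sep, max_attempts = 1e4) {
  if (n == 0) return(cbind(row = numeric(0), col = numeric(0)))
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (a in seq_len(max_attempts)) {
    ang <- runif(1, 0, 2 * pi)
    rad <- max_r * sqrt(runif(1))
    p <- c(cy + rad * sin(ang), cx + rad * cos(ang))
    ok <- placed == 0L ||
      all((pts[seq_len(placed), 1] - p[1])^2 +
          (pts[seq_len(placed), 2] - p[2])^2 >= min_sep^2)
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- p
      if (placed == n) break
    }
  }
  if (placed < n) {
    stop("impossible packing: placed ", placed, " of ", n,
         " centers in 10^4 attempts (min separation ", min_sep, " px)")
  }
  colnames(pts) <- c("row", "col")
  pts
}

#' Simulate a clustered membrane-protein image
#'
#' Gaussian-PSF spots (uniform discs of the stated radius convolved with
#' the PSF) on a dark background inside a circular cell mask, with
#' additive Gaussian noise clipped at zero. Emulates Airyscan images of
#' surface clusters on the bottom plasma membrane.
#'
#' @param n_clusters number of clusters (`>= 0`).
#' @param mean_radius_um cluster disc radius (all clusters share it, so
#'   ground-truth areas are exactly `pi * r^2`).
#' @param intensity peak intensity of a cluster disc.
#' @param cell_mask_radius_um radius of the circular cell footprint.
#' @param psf_sigma_um PSF standard deviation (default 0.1 um).
#' @param noise_sd additive Gaussian noise SD in intensity units.
#' @param min_separation_um minimum centre-to-centre distance; default
#'   `5 * mean_radius_um` (well-separated clusters). Placement failure
#'   after 1e4 attempts is an error.
#' @param seed integer seed; identical seeds give identical scenes.
#' @param pixel_size_um micrometers per pixel.
#' @param channel channel name for the raster.
#' @param image_size_px image side length; default fits the cell.
#' @return `list(scene, ground_truth)`; the ground truth records centers
#'   (pixels and um), true areas, and the noiseless raster.
#' @export
simulate_cluster_image <- function(n_clusters, mean_radius_um = 0.25,
                                   intensity = 100,
                                   cell_mask_radius_um = 8,
                                   psf_sigma_um = 0.1, noise_sd = 2,
                                   min_separation_um = 5 * mean_radius_um,
                                   seed = 1, pixel_size_um = 0.05,
                                   channel = "CD20",
                                   image_size_px = NULL) {
  stopifnot(n_clusters >= 0, mean_radius_um > 0, cell_mask_radius_um > 0)
  ps <- pixel_size_um
  if (is.null(image_size_px)) {
    image_size_px <- as.integer(ceiling(2 * (cell_mask_radius_um + 1) / ps))
  }
  n <- image_size_px
  .with_seed(seed, {
    ctr <- (n + 1) / 2
    r_px <- mean_radius_um / ps
    centers <- .place_centers(n_clusters, ctr, ctr,
                              max_r = (cell_mask_radius_um - mean_radius_um) / ps,
                              min_sep = min_separation_um / ps)
    img <- matrix(0, n, n)
    for (i in seq_len(n_clusters)) {
      img <- .paint_disc(img, centers[i, 1], centers[i, 2], r_px, intensity)
    }
    img <- gaussian_smooth(img, psf_sigma_um / ps)
    noiseless <- img
    img <- .add_noise(img, noise_sd)
    scene <- image_scene(stats::setNames(list(img), channel), pixel_size_um = ps)
    gt <- list(
      n_clusters = n_clusters,
      centers_px = centers,
      centers_um = (centers - 1) * ps,
      radius_um = mean_radius_um,
      true_areas_um2 = rep(pi * mean_radius_um^2, n_clusters),
      cell_mask_radius_um = cell_mask_radius_um,
      intensity = intensity,
      noiseless = noiseless
    )
    list(scene = scene, ground_truth = gt)
  })
}

#' Simulate a paired-channel colocalization scene
#'
#' Channel B spots are a copy of a fraction `overlap_fraction` of channel
#' A spots plus independently placed spots; the true pixel-overlap
#' fraction is recorded from the noiseless half-maximum binary masks.
#'
#' @param overlap_fraction fraction of A spots copied into B, in `[0, 1]`.
#' @param n_spots spots per channel.
#' @param seed integer seed.
#' @param noise_sd additive noise SD.
#' @param spot_radius_um,intensity,psf_sigma_um,pixel_size_um,image_size_px
#'   rendering parameters as in [simulate_cluster_image()].
#' @param channels two channel names (A, B).
#' @return `list(scene, ground_truth)` with noiseless masks `mask_a`,
#'   `mask_b` and `true_overlap` = |A & B| / |A|.
#' @export
simulate_coloc_pair <- function(overlap_fraction, n_spots = 30, seed = 1,
                                noise_sd = 2, spot_radius_um = 0.15,
                                intensity = 100, psf_sigma_um = 0.1,
                                pixel_size_um = 0.05, image_size_px = 256,
                                channels = c("CD20", "CD70")) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1, n_spots >= 0,
            length(channels) == 2L)
  ps <- pixel_size_um
  n <- image_size_px
  .with_seed(seed, {
    r_px <- spot_radius_um / ps
    sep <- 4 * r_px
    ctr <- (n + 1) / 2
    n_shared <- round(overlap_fraction * n_spots)
    n_b_only <- n_spots - n_shared
    # place all centres in one pass so every pair of spots (within and
    # across channels) keeps the minimum separation; disjointness of the
    # unshared spots is then guaranteed.
    all_centers <- .place_centers(n_spots + n_b_only, ctr, ctr,
                                  max_r = (n / 2 - 2) - r_px, min_sep = sep)
    a_centers <- all_centers[seq_len(n_spots), , drop = FALSE]
    b_centers <- rbind(a_centers[seq_len(n_shared), , drop = FALSE],
                       all_centers[n_spots + seq_len(n_b_only), , drop = FALSE])
    render <- function(centers) {
      img <- matrix(0, n, n)
      for (i in seq_len(nrow(centers))) {
        img <- .paint_disc(img, centers[i, 1], centers[i, 2], r_px, intensity)
      }
      gaussian_smooth(img, psf_sigma_um / ps)
    }
    ca <- render(a_centers); cb <- render(b_centers)
    mask_a <- ca >= intensity / 2
    mask_b <- cb >= intensity / 2
    true_overlap <- if (any(mask_a)) sum(mask_a & mask_b) / sum(mask_a) else NA_real_
    scene <- image_scene(stats::setNames(list(.add_noise(ca, noise_sd),
                                              .add_noise(cb, noise_sd)),
                                         channels), pixel_size_um = ps)
    gt <- list(overlap_fraction = overlap_fraction, n_spots = n_spots,
               mask_a = mask_a, mask_b = mask_b, true_overlap = true_overlap,
               noiseless_a = ca, noiseless_b = cb)
    list(scene = scene, ground_truth = gt)
  })
}

#' Simulate a FRAP intensity trace series
#'
#' Bleach-ROI trace
#' `I(t) = I_pre * exp(-lambda t) * [(1 - depth) + depth * Fm * (1 - exp(-t'/tau))]`
#' for post-bleach times `t'`, a whole-cell trace decaying with the same
#' acquisition-bleach rate `lambda`, and a constant background, all with
#' optional Gaussian noise. Noise is specified relative to the pre-bleach
#' ROI signal (`noise_sd = 0.01` is "1% noise").
#'
#' @param mobile_fraction true mobile fraction `Fm` in `[0, 1]`.
#' @param tau_s recovery time constant (s); the ideal half-time is
#'   `tau_s * log(2)`.
#' @param bleach_depth fraction of ROI signal removed by the bleach, in
#'   `(0, 1]`.
#' @param acquisition_bleach_rate imaging photobleaching rate `lambda`
#'   (1/s), applied from the first frame.
#' @param n_pre,n_post pre- and post-bleach frame counts.
#' @param dt_s frame interval (s).
#' @param noise_sd relative noise SD (fraction of pre-bleach ROI signal).
#' @param seed integer seed.
#' @param roi_prebleach,cell_prebleach,background intensity levels.
#' @return `list(series, ground_truth)`; `series` is a [frap_series()].
#' @export
simulate_frap_series <- function(mobile_fraction, tau_s, bleach_depth = 0.9,
                                 acquisition_bleach_rate = 0, n_pre = 10,
                                 n_post = 100, dt_s = 0.5, noise_sd = 0,
                                 seed = 1, roi_prebleach = 100,
                                 cell_prebleach = 200, background = 10) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, tau_s > 0,
            bleach_depth > 0, bleach_depth <= 1, n_pre >= 1, n_post >= 5)
  .with_seed(seed, {
    n <- n_pre + n_post
    t_s <- (seq_len(n) - 1) * dt_s
    lam <- acquisition_bleach_rate
    decay <- exp(-lam * t_s)
    bleach_index <- n_pre + 1L
    tp <- t_s - t_s[bleach_index]
    f <- rep(1, n)
    post <- seq.int(bleach_index, n)
    f[post] <- (1 - bleach_depth) +
      bleach_depth * mobile_fraction * (1 - exp(-tp[post] / tau_s))
    roi <- roi_prebleach * decay * f
    cell <- cell_prebleach * decay
    bg <- rep(background, n)
    sdv <- noise_sd * roi_prebleach
    if (sdv > 0) {
      roi <- roi + rnorm(n, 0, sdv)
      cell <- cell + rnorm(n, 0, sdv)
      bg <- bg + rnorm(n, 0, sdv / 4)
    }
    series <- frap_series(t_s, roi + bg, cell + bg, bg, bleach_index)
    gt <- list(mobile_fraction = mobile_fraction, tau_s = tau_s,
               t_half_s = tau_s * log(2), bleach_depth = bleach_depth,
               acquisition_bleach_rate = lam)
    list(series = series, ground_truth = gt)
  })
}

#' Simulate switching-diffusion single-particle trajectories
#'
#' Two-state per-frame Markov switching between confined motion
#' (diffusion reflected in a disc of `confinement_radius_um` around the
#' confinement anchor) and active motion (diffusion plus directed drift
#' whose direction persists per bout). Localization error is added to the
#' observed positions. The default frame interval is 0.1 s (10 Hz TIRF).
#'
#' @param n_tracks,n_frames track count and length.
#' @param dt_s frame interval (s).
#' @param D_confined_um2s,D_active_um2s diffusion coefficients (um^2/s).
#' @param drift_speed_um_s directed speed in the active state.
#' @param switch_prob per-frame probability of switching state.
#' @param confinement_radius_um confinement disc radius; `Inf` gives free
#'   diffusion in the confined state (pure Brownian motion when
#'   `switch_prob = 0`).
#' @param loc_error_um localization error SD per axis.
#' @param seed integer seed.
#' @param start_state `"random"`, `"confined"`, or `"active"`.
#' @param field_um tracks start uniformly in a square field of this side.
#' @return `list(tracks, ground_truth)`; `tracks` is a [trajectory_set()]
#'   and the ground truth stores per-frame state sequences.
#' @export
simulate_trajectories <- function(n_tracks = 50, n_frames = 100, dt_s = 0.1,
                                  D_confined_um2s = 2e-4,
                                  D_active_um2s = 1e-3,
                                  drift_speed_um_s = 0.1,
                                  switch_prob = 0.02,
                                  confinement_radius_um = 0.1,
                                  loc_error_um = 0.01, seed = 1,
                                  start_state = c("random", "confined", "active"),
                                  field_um = 20) {
  start_state <- match.arg(start_state)
  stopifnot(n_tracks >= 1, n_frames >= 2, dt_s > 0, switch_prob >= 0,
            switch_prob <= 1)
  .with_seed(seed, {
    rows <- vector("list", n_tracks)
    states <- vector("list", n_tracks)
    for (k in seq_len(n_tracks)) {
      pos <- matrix(NA_real_, n_frames, 2)
      st <- integer(n_frames)            # 1 = confined, 2 = active
      pos[1, ] <- runif(2, 0, field_um)
      st[1] <- switch(start_state, random = sample(1:2, 1), confined = 1L,
                      active = 2L)
      anchor <- pos[1, ]
      theta <- runif(1, 0, 2 * pi)
      for (f in 2:n_frames) {
        st[f] <- st[f - 1]
        if (switch_prob > 0 && runif(1) < switch_prob) {
          st[f] <- 3L - st[f]
          if (st[f] == 1L) anchor <- pos[f - 1, ] else theta <- runif(1, 0, 2 * pi)
        }
        if (st[f] == 1L) {
          step <- rnorm(2, 0, sqrt(2 * D_confined_um2s * dt_s))
          prop <- pos[f - 1, ] + step
          if (is.finite(confinement_radius_um)) {
            d <- sqrt(sum((prop - anchor)^2))
            R <- confinement_radius_um
            if (d > R) {
              prop <- anchor + (prop - anchor) / d * max(2 * R - d, 0.05 * R)
            }
          }
          pos[f, ] <- prop
        } else {
          pos[f, ] <- pos[f - 1, ] +
            drift_speed_um_s * dt_s * c(cos(theta), sin(theta)) +
            rnorm(2, 0, sqrt(2 * D_active_um2s * dt_s))
        }
      }
      obs <- pos + matrix(rnorm(2 * n_frames, 0, loc_error_um), n_frames, 2)
      rows[[k]] <- data.frame(track_id = k, frame = seq_len(n_frames),
                              x_um = obs[, 1], y_um = obs[, 2])
      states[[k]] <- c("confined", "active")[st]
    }
    tracks <- trajectory_set(do.call(rbind, rows), dt_s = dt_s)
    gt <- list(states = states, D_confined_um2s = D_confined_um2s,
               D_active_um2s = D_active_um2s,
               drift_speed_um_s = drift_speed_um_s,
               confinement_radius_um = confinement_radius_um,
               switch_prob = switch_prob)
    list(tracks = tracks, ground_truth = gt)
  })
}

#' Simulate a proximity-ligation-assay scene
#'
#' Cells are disjoint discs; the DAPI channel shows the cell body dimly
#' with a brighter nucleus, so cell footprints segment from DAPI alone.
#' PLA dots are Gaussian spots assigned to cells; the ground truth holds
#' the per-cell counts.
#'
#' @param n_spots total PLA dots.
#' @param spot_sigma_um Gaussian dot SD.
#' @param cell_count number of cells.
#' @param seed integer seed.
#' @param noise_sd additive noise SD.
#' @param pixel_size_um,cell_radius_um,nucleus_radius_um geometry.
#' @param spot_amplitude peak dot intensity.
#' @param min_separation_um minimum dot separation; default `4 *
#'   spot_sigma_um` keeps dots individually countable.
#' @return `list(scene, ground_truth)` with per-cell spot counts and the
#'   noiseless PLA raster.
#' @export
simulate_pla_image <- function(n_spots = 12, spot_sigma_um = 0.1,
                               cell_count = 3, seed = 1, noise_sd = 2,
                               pixel_size_um = 0.1, cell_radius_um = 4,
                               nucleus_radius_um = 2, spot_amplitude = 200,
                               min_separation_um = 4 * spot_sigma_um) {
  stopifnot(n_spots >= 0, cell_count >= 1)
  ps <- pixel_size_um
  .with_seed(seed, {
    r_cell <- cell_radius_um / ps
    tile <- ceiling(2 * r_cell + 12)
    n_col <- ceiling(sqrt(cell_count))
    n_row <- ceiling(cell_count / n_col)
    nr <- n_row * tile + 8L; nc <- n_col * tile + 8L
    dapi <- matrix(0, nr, nc)
    pla <- matrix(0, nr, nc)
    centers <- matrix(NA_real_, cell_count, 2)
    for (i in seq_len(cell_count)) {
      ri <- (i - 1) %/% n_col; ci <- (i - 1) %% n_col
      cy <- ri * tile + tile / 2 + 4 + runif(1, -2, 2)
      cx <- ci * tile + tile / 2 + 4 + runif(1, -2, 2)
      centers[i, ] <- c(cy, cx)
      dapi <- .paint_disc(dapi, cy, cx, r_cell, 40)
      dapi <- .paint_disc(dapi, cy, cx, nucleus_radius_um / ps, 110)
    }
    cell_of_spot <- if (n_spots > 0) sample.int(cell_count, n_spots, replace = TRUE)
                    else integer(0)
    sig_px <- spot_sigma_um / ps
    sep_px <- min_separation_um / ps
    spot_pos <- matrix(NA_real_, n_spots, 2)
    placed <- 0L
    attempts <- 0L
    for (s in seq_len(n_spots)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > 1e4) stop("impossible packing of PLA dots")
        ang <- runif(1, 0, 2 * pi); rad <- (r_cell - 3 * sig_px - 2) * sqrt(runif(1))
        p <- centers[cell_of_spot[s], ] + rad * c(sin(ang), cos(ang))
        if (placed == 0L ||
            all((spot_pos[seq_len(placed), 1] - p[1])^2 +
                (spot_pos[seq_len(placed), 2] - p[2])^2 >= sep_px^2)) {
          placed <- placed + 1L
          spot_pos[s, ] <- p
          break
        }
      }
    }
    for (s in seq_len(n_spots)) {
      cy <- spot_pos[s, 1]; cx <- spot_pos[s, 2]
      r0 <- max(1L, floor(cy - 4 * sig_px)); r1 <- min(nr, ceiling(cy + 4 * sig_px))
      c0 <- max(1L, floor(cx - 4 * sig_px)); c1 <- min(nc, ceiling(cx + 4 * sig_px))
      rows <- r0:r1; cols <- c0:c1
      d2 <- outer((rows - cy)^2, (cols - cx)^2, `+`)
      pla[rows, cols] <- pla[rows, cols] + spot_amplitude * exp(-d2 / (2 * sig_px^2))
    }
    noiseless_pla <- pla
    scene <- image_scene(list(DAPI = .add_noise(dapi, noise_sd),
                              PLA = .add_noise(pla, noise_sd)),
                         pixel_size_um = ps)
    counts <- tabulate(cell_of_spot, nbins = cell_count)
    gt <- list(n_spots = n_spots, cell_count = cell_count,
               spots_per_cell = counts, cell_centers_px = centers,
               spot_positions_px = spot_pos, noiseless_pla = noiseless_pla)
    list(scene = scene, ground_truth = gt)
  })
}

#' Simulate a B-T conjugate scene with immunological synapses
#'
#' Each conjugate is a CD3+ disc (T cell) slightly overlapping an MHCII+
#' disc (B cell). The contact zone is the B-cell membrane arc facing the
#' T cell; CD3 there is set to `cd3_contact_boost` times its base (TCR
#' accumulation), and CD70 on the B membrane is `enrichment_ratio` times
#' its out-of-contact level inside the contact.
#'
#' @param n_pairs number of conjugates.
#' @param enrichment_ratio true in/out CD70 ratio; scalar or one per pair.
#' @param contact_arc_deg angular width of the contact arc (degrees).
#' @param cd3_contact_boost CD3 multiplier inside the contact.
#' @param n_free_b_cells additional B cells without a T-cell partner.
#' @param seed integer seed.
#' @param noise_sd additive noise SD (intensity units; bases are ~100).
#' @param pixel_size_um,b_radius_um,t_radius_um geometry.
#' @param cd70_base,cd3_base,mhc2_base channel base intensities.
#' @return `list(scene, ground_truth)`; ground truth records contact
#'   masks (linear pixel indices), per-pair ratios, cell counts, and the
#'   noiseless CD70 raster.
#' @export
simulate_synapse_scene <- function(n_pairs, enrichment_ratio = 2,
                                   contact_arc_deg = 90,
                                   cd3_contact_boost = 4,
                                   n_free_b_cells = 0, seed = 1,
                                   noise_sd = 0, pixel_size_um = 0.1,
                                   b_radius_um = 3, t_radius_um = 2.5,
                                   cd70_base = 100, cd3_base = 100,
                                   mhc2_base = 120) {
  stopifnot(n_pairs >= 0, n_free_b_cells >= 0, all(enrichment_ratio >= 0))
  if (n_pairs + n_free_b_cells == 0) stop("empty scene: no cells requested")
  ratios <- rep_len(enrichment_ratio, max(n_pairs, 1L))[seq_len(n_pairs)]
  ps <- pixel_size_um
  rB <- b_radius_um / ps; rT <- t_radius_um / ps
  overlap_px <- 4
  pad <- ceiling(0.3 * rB) + 6   # inter-tile clearance scales with cell size
  tile_w <- ceiling(2 * rB + 2 * rT - overlap_px + pad)
  tile_h <- ceiling(2 * rB + pad)
  n_units <- n_pairs + n_free_b_cells
  n_col <- ceiling(sqrt(n_units))
  n_row <- ceiling(n_units / n_col)
  nr <- n_row * tile_h + 8L; nc <- n_col * tile_w + 8L
  .with_seed(seed, {
    cd3 <- matrix(0, nr, nc); mhc2 <- matrix(0, nr, nc); cd70 <- matrix(0, nr, nc)
    contact_masks <- vector("list", n_pairs)
    for (u in seq_len(n_units)) {
      ri <- (u - 1) %/% n_col; ci <- (u - 1) %% n_col
      cy <- ri * tile_h + tile_h / 2 + 4 + runif(1, -2, 2)
      is_pair <- u <= n_pairs
      cxc <- ci * tile_w + tile_w / 2 + 4 + runif(1, -2, 2)
      cxb <- if (is_pair) cxc - (rB + rT - overlap_px) / 2 else cxc
      mhc2 <- .paint_disc(mhc2, cy, cxb, rB, mhc2_base)
      # 3-px membrane annulus just inside the B-cell rim
      r0 <- max(1L, floor(cy - rB - 1)); r1 <- min(nr, ceiling(cy + rB + 1))
      c0 <- max(1L, floor(cxb - rB - 1)); c1 <- min(nc, ceiling(cxb + rB + 1))
      rows <- r0:r1; cols <- c0:c1
      dB <- sqrt(outer((rows - cy)^2, (cols - cxb)^2, `+`))
      memb <- dB >= rB - 3 & dB <= rB
      blk <- cd70[rows, cols]; blk[memb] <- cd70_base; cd70[rows, cols] <- blk
      if (is_pair) {
        cxt <- cxb + rB + rT - overlap_px
        cd3 <- .paint_disc(cd3, cy, cxt, rT, cd3_base)
        dT <- sqrt(outer((rows - cy)^2, (cols - cxt)^2, `+`))
        ang <- abs(atan2(outer(rows - cy, cols * 0, `+`),
                         outer(rows * 0, cols - cxb, `+`)))
        contact <- memb & dT <= rT + 3 & ang <= (contact_arc_deg / 2) * pi / 180
        blk <- cd70[rows, cols]; blk[contact] <- cd70_base * ratios[u]
        cd70[rows, cols] <- blk
        blk <- cd3[rows, cols]; blk[contact] <- cd3_base * cd3_contact_boost
        cd3[rows, cols] <- blk
        ci <- which(contact)                     # block-local -> scene-linear
        br <- (ci - 1L) %% length(rows) + 1L
        bc <- (ci - 1L) %/% length(rows) + 1L
        contact_masks[[u]] <- (cols[bc] - 1L) * nr + rows[br]
      }
    }
    noiseless_cd70 <- cd70
    scene <- .image_scene_fast(list(CD3 = .add_noise(cd3, noise_sd),
                                    MHCII = .add_noise(mhc2, noise_sd),
                                    CD70 = .add_noise(cd70, noise_sd)),
                               pixel_size_um = ps)
    gt <- list(n_synapses = n_pairs, n_b_cells = n_units,
               n_t_cells = n_pairs, ratios = ratios,
               contact_masks = contact_masks,
               noiseless_cd70 = noiseless_cd70,
               contact_area_fraction_of_cd3 = if (n_pairs > 0) {
                 sum(lengths(contact_masks)) / sum(noiseless_cd70 * 0 + (cd3 > 0))
               } else NA_real_)
    list(scene = scene, ground_truth = gt)
  })
}

#' Simulate a micropatterned-stamp scene
#'
#' A regular grid of circular ligand stamps (default 5 um diameter) under
#' a large cell footprint; the reporter channel mean on-stamp is
#' `on_stamp_enrichment` times the off-stamp mean inside the cell.
#'
#' @param spot_diameter_um stamp disc diameter (default 5 um).
#' @param pitch_um stamp grid pitch.
#' @param on_stamp_enrichment true on/off reporter ratio.
#' @param seed integer seed.
#' @param noise_sd additive noise SD.
#' @param pixel_size_um,image_size_px,cell_radius_um geometry.
#' @param reporter_base,stamp_intensity intensities.
#' @return `list(scene, ground_truth)` with the stamp and cell masks.
#' @export
simulate_stamp_scene <- function(spot_diameter_um = 5, pitch_um = 10,
                                 on_stamp_enrichment = 2, seed = 1,
                                 noise_sd = 0, pixel_size_um = 0.1,
                                 image_size_px = 300, cell_radius_um = 12,
                                 reporter_base = 50, stamp_intensity = 100) {
  stopifnot(spot_diameter_um > 0, pitch_um > spot_diameter_um / 2,
            on_stamp_enrichment >= 0)
  ps <- pixel_size_um
  n <- image_size_px
  .with_seed(seed, {
    r_spot <- spot_diameter_um / 2 / ps
    pitch <- pitch_um / ps
    stamp <- matrix(FALSE, n, n)
    cyx <- seq(pitch / 2, n, by = pitch)
    for (cy in cyx) for (cx in cyx) {
      stamp <- .paint_disc(stamp * 0, cy, cx, r_spot, 1) > 0 | stamp
    }
    ctr <- (n + 1) / 2 + runif(2, -3, 3)
    cell <- .disc_mask(n, n, ctr[1], ctr[2], cell_radius_um / ps)
    reporter <- matrix(0, n, n)
    reporter[cell] <- reporter_base
    reporter[cell & stamp] <- reporter_base * on_stamp_enrichment
    noiseless_reporter <- reporter
    scene <- image_scene(list(stamp = .add_noise(stamp * stamp_intensity, noise_sd),
                              reporter = .add_noise(reporter, noise_sd)),
                         pixel_size_um = ps)
    gt <- list(stamp_mask = stamp, cell_mask = cell,
               on_stamp_enrichment = on_stamp_enrichment,
               noiseless_reporter = noiseless_reporter)
    list(scene = scene, ground_truth = gt)
  })
}

#' Simulate a bead calibration table
#'
#' Bead mean fluorescence `MFI = gain * ABC * (1 + e)`, `e ~ N(0,
#' noise_cv)`, emulating a bead-based antibody-binding-capacity
#' calibration kit, plus optional samples of known ABC measured with the
#' same gain and noise.
#'
#' @param abc_values antibody-binding capacities of the bead populations.
#' @param gain fluorescence per antibody-binding site.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param sample_abc true ABC of samples to measure alongside the beads.
#' @return data.frame with columns `role` ("bead"/"sample"), `abc`
#'   (true value), `mfi`.
#' @export
simulate_calibration_beads <- function(abc_values = c(2500, 10000, 40000,
                                                      160000, 640000),
                                       gain = 0.005, noise_cv = 0, seed = 1,
                                       sample_abc = numeric(0)) {
  stopifnot(all(abc_values >= 0), gain > 0, noise_cv >= 0)
  .with_seed(seed, {
    noise <- function(k) 1 + rnorm(k, 0, noise_cv)
    beads <- data.frame(role = "bead", abc = abc_values,
                        mfi = gain * abc_values * noise(length(abc_values)))
    samp <- data.frame(role = character(0), abc = numeric(0), mfi = numeric(0))
    if (length(sample_abc)) {
      samp <- data.frame(role = "sample", abc = sample_abc,
                         mfi = gain * sample_abc * noise(length(sample_abc)))
    }
    rbind(beads, samp)
  })
}
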