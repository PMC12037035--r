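# dilate a sparse mask touching only a small region: restrict to the
# bounding box (padded by the radius) for speed on large scenes
.bbox_dilate <- function(mask, radius) {
  idx <- which(mask)
  if (!length(idx)) return(mask)
  nr <- nrow(mask)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  pad <- ceiling(radius)
  r0 <- max(1L, min(rr) - pad); r1 <- min(nr, max(rr) + pad)
  c0 <- max(1L, min(cc) - pad); c1 <- min(ncol(mask), max(cc) + pad)
  out <- mask
  out[r0:r1, c0:c1] <- cpp_dilate_disc(mask[r0:r1, c0:c1, drop = FALSE],
                                       as.numeric(radius))
  out
}

#' Detect candidate immunological synapses
#'
#' (1) The CD3 cell foreground is defined by an Otsu threshold; (2) the
#' contact threshold is the `100 - cd3_top_percent` intensity percentile
#' of CD3 over that foreground ("top 1 percent of CD3 signal" at the
#' default); (3) connected components of at least `min_region_px` pixels
#' at or above the threshold are candidates; (4) only components whose
#' dilation by `mhc2_adjacency_px` touches the MHC II-positive mask are
#' kept, automating the manual selection of T-B contacts by MHC II
#' signal.
#'
#' @param scene an [image_scene()].
#' @param cd3_channel,mhc2_channel channel names.
#' @param cd3_top_percent percentile width in `(0, 100]` (default 1).
#' @param min_region_px minimum contact size (default 20 px).
#' @param mhc2_adjacency_px adjacency radius to the B-cell mask
#'   (default 3 px).
#' @return a [label_mask()] with one label per candidate synapse.
#' @export
detect_synapses <- function(scene, cd3_channel = "CD3", mhc2_channel = "MHCII",
                            cd3_top_percent = 1.0, min_region_px = 20L,
                            mhc2_adjacency_px = 3) {
  stopifnot(cd3_top_percent > 0, cd3_top_percent <= 100)
  cd3 <- scene_channel(scene, cd3_channel)
  mhc2 <- scene_channel(scene, mhc2_channel)
  zero <- label_mask(matrix(0L, nrow(cd3), ncol(cd3)))
  t_mhc <- otsu_threshold(mhc2)
  if (is.na(t_mhc) || !any(mhc2 > t_mhc)) {
    warning("no MHC II signal: zero synapses")
    return(zero)
  }
  mhc_mask <- mhc2 > t_mhc
  # three-class threshold: the CD3 channel has background, T-cell body,
  # and contact levels, and plain Otsu can land between body and contact
  t_fg <- .foreground_threshold(cd3)$lo
  if (is.na(t_fg) || !any(cd3 > t_fg)) return(zero)
  fg <- cd3 > t_fg
  thr <- quantile(cd3[fg], probs = 1 - cd3_top_percent / 100, names = FALSE)
  cand <- fg & cd3 >= thr
  # hysteresis: top-percentile pixels seed the contact, which grows to
  # the connected region above the level midway between the cell
  # foreground and the percentile threshold. Under noise this recovers
  # the full contact instead of a scatter of fragments; on noiseless
  # scenes it reduces to the percentile components themselves.
  t_low <- (thr + t_fg) / 2
  grow <- fg & cd3 >= min(t_low, thr)
  cc <- label_components(grow, 8L)
  lab <- cc$labels
  nzi <- which(lab > 0L)
  seed_count <- tabulate(lab[cand], nbins = max(lab, 1L))
  by_comp <- split(nzi, lab[nzi])
  nr <- nrow(lab)
  keep <- integer(0)
  for (k in cc$region_ids) {
    if (seed_count[k] < min_region_px) next
    # adjacency test on the component's padded bounding box only
    ci <- by_comp[[as.character(k)]]
    rr <- (ci - 1L) %% nr + 1L; cl <- (ci - 1L) %/% nr + 1L
    pad <- ceiling(mhc2_adjacency_px)
    r0 <- max(1L, min(rr) - pad); r1 <- min(nr, max(rr) + pad)
    c0 <- max(1L, min(cl) - pad); c1 <- min(ncol(lab), max(cl) + pad)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rr - r0 + 1L, cl - c0 + 1L)] <- TRUE
    dil <- cpp_dilate_disc(sub, as.numeric(mhc2_adjacency_px))
    if (any(dil & mhc_mask[r0:r1, c0:c1])) keep <- c(keep, k)
  }
  label_mask(.relabel(lab, keep))
}

#' Score reporter recruitment at one synapse
#'
#' In-synapse mean = mean reporter intensity over the contact mask.
#' Out-of-synapse mean = mean over `n_control_rois` control regions
#' congruent to the contact, obtained by seeded random rotation of the
#' contact shape about the partner-cell membrane centroid, placed on the
#' membrane while avoiding the contact and its 2-px dilation (the
#' automated analogue of manually moving the ROI to five non-synapse
#' areas). Enrichment is `100 * in_mean / out_mean`; the recruitment
#' flag is inclusive at the threshold ("150% or higher").
#'
#' @param scene an [image_scene()].
#' @param reporter_channel channel to score (e.g. "CD70" or "MHCII").
#' @param contact_mask logical matrix, linear pixel indices, or a
#'   [label_mask()] with a single region.
#' @param n_control_rois number of control regions (default 5).
#' @param recruitment_threshold_pct recruitment cutoff (default 150,
#'   inclusive).
#' @param seed integer seed for control placement.
#' @param min_on_membrane_frac control placements must land at least
#'   this fraction of their pixels on the membrane (default 0.8); the
#'   mean uses the on-membrane pixels.
#' @param context precomputed reporter foreground (internal; lets
#'   [score_synapses()] threshold and label the scene once).
#' @return an object of class `SynapseRecord`: `in_mean`, `out_mean`,
#'   `enrichment_pct`, `recruited`, `n_controls_used`, `scored`.
#' @export
score_recruitment <- function(scene, reporter_channel, contact_mask,
                              n_control_rois = 5L,
                              recruitment_threshold_pct = 150,
                              seed = 1, min_on_membrane_frac = 0.8,
                              context = NULL) {
  img <- scene_channel(scene, reporter_channel)
  nr <- nrow(img); nc <- ncol(img)
  idx <- if (inherits(contact_mask, "LabelMask")) which(contact_mask$labels > 0L)
         else if (is.matrix(contact_mask)) which(contact_mask)
         else as.integer(contact_mask)
  if (!length(idx)) stop("empty contact mask")
  if (is.null(context)) context <- .recruitment_context(img)
  cc <- context$components
  crow <- (idx - 1L) %% nr + 1L
  ccol <- (idx - 1L) %/% nr + 1L
  # partner membrane = the foreground component(s) touching the contact
  # (a low-intensity contact may fall below the membrane threshold; then
  # look in its immediate 4-neighborhood)
  touched <- cc[idx]
  partner_ids <- setdiff(unique(touched), 0L)
  if (!length(partner_ids)) {
    nb_r <- pmin(pmax(rep(crow, 4L) + rep(c(-2L, 2L, 0L, 0L), each = length(idx)), 1L), nr)
    nb_c <- pmin(pmax(rep(ccol, 4L) + rep(c(0L, 0L, -2L, 2L), each = length(idx)), 1L), nc)
    partner_ids <- setdiff(unique(cc[(nb_c - 1L) * nr + nb_r]), 0L)
  }
  if (!length(partner_ids)) partner_ids <- -1L
  excl0 <- matrix(FALSE, nr, nc); excl0[idx] <- TRUE
  excluded <- .bbox_dilate(excl0, 2)
  if (partner_ids[1] > 0L) {
    w <- tabulate(factor(touched, levels = partner_ids),
                  nbins = length(partner_ids))
    main <- if (any(w > 0)) partner_ids[which.max(w)] else partner_ids[1]
    cy <- context$centroid_row[main]
    cx <- context$centroid_col[main]
  } else {
    cy <- mean(crow); cx <- mean(ccol)
  }
  in_mean <- mean(img[idx])
  placements <- list()
  .with_seed(seed, {
    attempts <- 0L
    while (length(placements) < n_control_rois && attempts < 1000L) {
      attempts <- attempts + 1L
      phi <- runif(1, 0, 2 * pi)
      rr <- round(cy + cos(phi) * (crow - cy) - sin(phi) * (ccol - cx))
      cc2 <- round(cx + sin(phi) * (crow - cy) + cos(phi) * (ccol - cx))
      ok <- rr >= 1 & rr <= nr & cc2 >= 1 & cc2 <= nc
      if (!all(ok)) next
      lin <- (cc2 - 1L) * nr + rr
      if (any(excluded[lin])) next
      on_mem <- if (length(partner_ids) == 1L) cc[lin] == partner_ids
                else cc[lin] %in% partner_ids
      if (sum(on_mem) < min_on_membrane_frac * length(on_mem)) next
      placements[[length(placements) + 1L]] <- lin[on_mem]
    }
  })
  if (length(placements) < n_control_rois) {
    warning("control ROI placement found only ", length(placements), " of ",
            n_control_rois, " positions")
  }
  if (!length(placements)) {
    return(structure(list(in_mean = in_mean, out_mean = NA_real_,
                          enrichment_pct = NA_real_, recruited = NA,
                          n_controls_used = 0L, scored = FALSE),
                     class = "SynapseRecord"))
  }
  out_mean <- mean(img[unlist(placements)])
  if (out_mean <= 0) {
    return(structure(list(in_mean = in_mean, out_mean = out_mean,
                          enrichment_pct = NA_real_, recruited = NA,
                          n_controls_used = length(placements),
                          scored = FALSE), class = "SynapseRecord"))
  }
  enr <- 100 * in_mean / out_mean
  structure(list(in_mean = in_mean, out_mean = out_mean,
                 enrichment_pct = enr,
                 recruited = enr >= recruitment_threshold_pct,
                 n_controls_used = length(placements), scored = TRUE),
            class = "SynapseRecord")
}

# reporter foreground (membrane) and its connected components, shared by
# all synapses of one scene
.recruitment_context <- function(img) {
  memb <- img > .foreground_threshold(img)$lo
  comp <- cpp_label_components(memb, 8L)
  nmax <- max(comp)
  idx <- which(comp > 0L)
  lab <- comp[idx]
  nr <- nrow(img)
  cnt <- tabulate(lab, nbins = nmax)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  sums <- rowsum(cbind(rr, cc), lab)
  sum_r <- numeric(nmax); sum_c <- numeric(nmax)
  at <- as.integer(rownames(sums))
  sum_r[at] <- sums[, 1]; sum_c[at] <- sums[, 2]
  list(membrane = memb, components = comp,
       centroid_row = sum_r / cnt, centroid_col = sum_c / cnt)
}

#' @export
print.SynapseRecord <- function(x, ...) {
  cat(sprintf("SynapseRecord: in %.1f | out %.1f | enrichment %.1f%% | %s\n",
              x$in_mean, x$out_mean, x$enrichment_pct,
              if (isTRUE(x$recruited)) "recruited" else "not recruited"))
  invisible(x)
}

#' Score every detected synapse of a scene
#'
#' @param scene an [image_scene()].
#' @param detected [label_mask()] from [detect_synapses()].
#' @param reporter_channel channel to score.
#' @param seed base seed; synapse `k` uses `seed + k`.
#' @param ... passed to [score_recruitment()].
#' @return data.frame with one row per synapse.
#' @export
score_synapses <- function(scene, detected, reporter_channel = "CD70",
                           seed = 1, ...) {
  ctx <- .recruitment_context(scene_channel(scene, reporter_channel))
  lab <- detected$labels
  nzi <- which(lab > 0L)
  by_comp <- split(nzi, lab[nzi])
  recs <- lapply(detected$region_ids, function(k) {
    score_recruitment(scene, reporter_channel, by_comp[[as.character(k)]],
                      seed = seed + k, context = ctx, ...)
  })
  g <- function(f, mode) vapply(recs, function(r) r[[f]], mode)
  data.frame(synapse_id = as.integer(detected$region_ids),
             in_mean = g("in_mean", numeric(1)),
             out_mean = g("out_mean", numeric(1)),
             enrichment_pct = g("enrichment_pct", numeric(1)),
             recruited = g("recruited", logical(1)),
             scored = g("scored", logical(1)))
}

#' Count synapses per B cell and per T cell
#'
#' B cells are MHC II-positive regions, T cells CD3-positive regions
#' (Otsu threshold, hole fill, connected components); a detected contact
#' counts as a synapse when its 1-px dilation touches at least one of
#' each. The total synapse count divided by the B-cell count gives
#' synapses per B cell; division by zero cells yields `NA`.
#'
#' @param scene an [image_scene()].
#' @param detected [label_mask()] of contacts.
#' @param cd3_channel,mhc2_channel channel names.
#' @param min_cell_px minimum cell region size (default 50 px).
#' @return one-row data.frame: `n_synapses`, `n_b_cells`, `n_t_cells`,
#'   `synapses_per_b_cell`, `synapses_per_t_cell`.
#' @export
synapses_per_cell <- function(scene, detected, cd3_channel = "CD3",
                              mhc2_channel = "MHCII", min_cell_px = 50L) {
  seg <- function(ch) {
    img <- scene_channel(scene, ch)
    thr <- .foreground_threshold(img)$lo
    if (is.na(thr)) return(label_mask(matrix(0L, nrow(img), ncol(img))))
    cc <- label_components(binary_fill_holes(img > thr), 8L)
    sizes <- tabulate(cc$labels[cc$labels > 0L], nbins = max(cc$labels, 1L))
    keep <- cc$region_ids[sizes[cc$region_ids] >= min_cell_px]
    label_mask(.relabel(cc$labels, keep))
  }
  b_cells <- seg(mhc2_channel)
  t_cells <- seg(cd3_channel)
  n_b <- length(b_cells$region_ids)
  n_t <- length(t_cells$region_ids)
  n_syn <- 0L
  for (k in detected$region_ids) {
    touch <- dilate_mask(detected$labels == k, 1)
    if (any(b_cells$labels[touch] > 0L) && any(t_cells$labels[touch] > 0L)) {
      n_syn <- n_syn + 1L
    }
  }
  data.frame(n_synapses = n_syn, n_b_cells = n_b, n_t_cells = n_t,
             synapses_per_b_cell = if (n_b > 0) n_syn / n_b else NA_real_,
             synapses_per_t_cell = if (n_t > 0) n_syn / n_t else NA_real_)
}

#' Reporter enrichment on micropatterned stamps
#'
#' Stamp mask from the Otsu-thresholded stamp channel; ratio = mean
#' reporter on-stamp / off-stamp within the cell footprint (the
#' Otsu-thresholded reporter foreground).
#'
#' @param scene an [image_scene()].
#' @param stamp_channel,reporter_channel channel names.
#' @return one-row data.frame: `on_mean`, `off_mean`, `ratio`.
#' @export
stamp_enrichment <- function(scene, stamp_channel = "stamp",
                             reporter_channel = "reporter") {
  stamp <- scene_channel(scene, stamp_channel)
  rep_ch <- scene_channel(scene, reporter_channel)
  t_s <- otsu_threshold(stamp)
  if (is.na(t_s) || !any(stamp > t_s)) stop("empty stamp channel")
  stamp_mask <- stamp > t_s
  # the reporter has up to three levels (background, cell, cell-on-stamp);
  # the cell footprint is cut at the background/cell-body boundary
  t_r <- .foreground_threshold(rep_ch)$lo
  cell <- if (is.na(t_r)) matrix(TRUE, nrow(rep_ch), ncol(rep_ch))
          else rep_ch > t_r
  on <- cell & stamp_mask
  off <- cell & !stamp_mask
  if (!any(on) || !any(off)) stop("cell footprint does not straddle the stamp pattern")
  on_mean <- mean(rep_ch[on]); off_mean <- mean(rep_ch[off])
  data.frame(on_mean = on_mean, off_mean = off_mean,
             ratio = on_mean / off_mean)
}

#' Compare recruitment between two groups of images
#'
#' Aggregates synapse records per image (the experimental unit): the
#' recruited-synapse fraction and the mean enrichment. Groups are
#' compared with a two-sided Mann-Whitney/Wilcoxon rank-sum test on the
#' per-image values; with fewer than two images in a group the p-values
#' are reported as missing.
#'
#' @param records_a,records_b data.frames of synapse records with an
#'   `image` column plus `recruited` and `enrichment_pct` (e.g. rbind of
#'   [score_synapses()] outputs with an added image id).
#' @return list with `per_image` (group, image, recruited_fraction,
#'   mean_enrichment) and `tests` (one-row data.frame with
#'   `p_recruited_fraction`, `p_enrichment`).
#' @export
compare_groups <- function(records_a, records_b) {
  agg <- function(df, grp) {
    stopifnot(all(c("image", "recruited", "enrichment_pct") %in% names(df)))
    out <- do.call(rbind, lapply(split(df, df$image), function(d) {
      data.frame(group = grp, image = d$image[1],
                 recruited_fraction = mean(d$recruited, na.rm = TRUE),
                 mean_enrichment = mean(d$enrichment_pct, na.rm = TRUE),
                 n_synapses = nrow(d))
    }))
    rownames(out) <- NULL
    out
  }
  pa <- agg(records_a, "A"); pb <- agg(records_b, "B")
  test_p <- function(va, vb) {
    if (length(va) < 2L || length(vb) < 2L) return(NA_real_)
    suppressWarnings(wilcox.test(va, vb, exact = FALSE)$p.value)
  }
  list(per_image = rbind(pa, pb),
       tests = data.frame(
         p_recruited_fraction = test_p(pa$recruited_fraction,
                                       pb$recruited_fraction),
         p_enrichment = test_p(pa$mean_enrichment, pb$mean_enrichment)))
}
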