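# Measurement of labeled regions against an intensity raster.
.measure_labels <- function(labels, intensity, pixel_size_um, min_size_px = 1L) {
  ids <- sort(unique(labels[labels > 0L]))
  if (!length(ids)) {
    return(data.frame(cluster_id = integer(0), pixel_count = integer(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0),
                      integrated_intensity = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0)))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  cnt <- tabulate(lab, nbins = max(ids))
  inten <- intensity[idx]
  sum_i <- vapply(ids, function(k) sum(inten[lab == k]), numeric(1))
  rr <- (idx - 1L) %% nrow(labels)        # 0-based row
  cc <- (idx - 1L) %/% nrow(labels)       # 0-based col
  cy <- vapply(ids, function(k) mean(rr[lab == k]), numeric(1))
  cx <- vapply(ids, function(k) mean(cc[lab == k]), numeric(1))
  out <- data.frame(cluster_id = ids, pixel_count = cnt[ids],
                    area_um2 = cnt[ids] * pixel_size_um^2,
                    mean_intensity = sum_i / cnt[ids],
                    integrated_intensity = sum_i,
                    centroid_x_um = cx * pixel_size_um,
                    centroid_y_um = cy * pixel_size_um)
  out <- out[out$pixel_count >= min_size_px, , drop = FALSE]
  out$cluster_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# relabel a mask keeping only the given original ids, renumbered 1..k
.relabel <- function(labels, keep_ids) {
  map <- integer(max(labels, 1L))
  map[keep_ids] <- seq_along(keep_ids)
  out <- labels
  out[out > 0L] <- map[out[out > 0L]]
  out
}

#' Detect membrane protein clusters
#'
#' Fixed pipeline: (1) Gaussian smoothing; (2) local maxima detection;
#' (3) maxima-seeded watershed segmentation of the smoothed image; (4)
#' global Otsu threshold shifted by `otsu_offset_percent` (a negative
#' offset of 20 lowers the threshold to 0.8 Totsu, the "Otsu, 20%"
#' convention; `threshold_mode = "auto"` uses the unshifted Otsu value);
#' (5) logical AND of segmentation and threshold mask; (6) binary hole
#' filling; (7) connected-component labeling (8-connected) respecting
#' watershed splits, size filtering, and per-label measurement.
#'
#' @param scene an [image_scene()].
#' @param channel channel to segment.
#' @param maxima_min_distance_px minimum peak separation (default 5).
#' @param threshold_mode `"otsu_offset"` or `"auto"`.
#' @param otsu_offset_percent percent by which the Otsu threshold is
#'   lowered, in `[-100, 100]` (20 means threshold = 0.8 Totsu; the paper
#'   default for CD20 is 20, for CD70 30).
#' @param smooth_sigma_px smoothing SD in pixels (default 1).
#' @param min_size_px minimum cluster size (default 4 px).
#' @return list with `mask` (a [label_mask()]) and `clusters`
#'   (data.frame of per-cluster records: `cluster_id`, `pixel_count`,
#'   `area_um2`, `mean_intensity`, `integrated_intensity`, centroid in
#'   um, 0-based pixel convention).
#' @export
detect_clusters <- function(scene, channel,
                            maxima_min_distance_px = 5,
                            threshold_mode = c("otsu_offset", "auto"),
                            otsu_offset_percent = 20,
                            smooth_sigma_px = 1, min_size_px = 4L) {
  threshold_mode <- match.arg(threshold_mode)
  if (abs(otsu_offset_percent) > 100) {
    stop("otsu_offset_percent must be in [-100, 100]")
  }
  img <- scene_channel(scene, channel)
  if (!all(is.finite(img))) stop("non-finite pixels in channel ", channel)
  ps <- scene$pixel_size_um
  empty <- list(mask = label_mask(matrix(0L, nrow(img), ncol(img))),
                clusters = .measure_labels(matrix(0L, 1, 1), matrix(0, 1, 1), ps))
  if (all(img == 0) || diff(range(img)) == 0) return(empty)
  sm <- gaussian_smooth(img, smooth_sigma_px)
  t_otsu <- otsu_threshold(sm)
  # the percent offset is applied to the span above the image minimum so
  # that the effective threshold shifts 1:1 with a constant intensity
  # offset (for a zero-background image this is simply 0.8 * T_otsu at
  # the default 20)
  mn <- min(sm)
  thr <- if (threshold_mode == "auto") t_otsu
         else mn + (t_otsu - mn) * (1 - otsu_offset_percent / 100)
  peaks <- find_local_maxima(sm, min_distance_px = maxima_min_distance_px,
                             threshold = thr)
  if (nrow(peaks) == 0L) return(empty)
  ws <- watershed_segment(sm, peaks)
  thr_mask <- sm > thr
  combined <- thr_mask & ws$labels > 0L
  filled <- binary_fill_holes(combined)
  cc <- cpp_label_components(filled, 8L)
  # respect watershed splits: a connected blob spanning two basins yields
  # two clusters (pair id = connected component x watershed basin)
  pair <- cc
  nz <- filled & ws$labels > 0L
  pair[!nz] <- 0L
  key <- (as.numeric(cc) - 1) * (max(ws$labels) + 1) + as.numeric(ws$labels)
  key[pair == 0L] <- 0
  uk <- sort(unique(key[key > 0]))
  lab <- matrix(match(key, uk, nomatch = 0L), nrow(img))
  # hole-filled pixels fall outside every basin; attach them to the
  # enclosing component's dominant label
  orphan <- filled & lab == 0L
  if (any(orphan)) {
    for (k in sort(unique(cc[orphan]))) {
      sel <- cc == k
      labs_here <- lab[sel]
      if (any(labs_here > 0L)) {
        dom <- as.integer(names(which.max(table(labs_here[labs_here > 0L]))))
        lab[sel & lab == 0L] <- dom
      }
    }
  }
  clusters <- .measure_labels(lab, img, ps, min_size_px = min_size_px)
  keep <- sort(unique(lab[lab > 0L]))
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- keep[sizes[keep] >= min_size_px]
  lab <- .relabel(lab, keep)
  list(mask = label_mask(lab), clusters = clusters)
}

#' Segment cells from a nuclear/cell stain
#'
#' Otsu threshold and hole filling give the cell footprint; a second
#' Otsu level within the footprint isolates the bright nuclei, whose
#' connected components seed a watershed that separates touching cells.
#' With a single intensity level (no distinct nuclei) the footprint
#' components are returned directly.
#'
#' @param img numeric matrix (e.g. the DAPI channel).
#' @param smooth_sigma_px smoothing before thresholding.
#' @return a [label_mask()] of cell regions.
#' @export
segment_cells <- function(img, smooth_sigma_px = 2) {
  sm <- gaussian_smooth(img, smooth_sigma_px)
  thr <- .foreground_threshold(sm)
  if (is.na(thr$lo)) return(label_mask(matrix(0L, nrow(img), ncol(img))))
  mask <- binary_fill_holes(sm > thr$lo)
  if (is.na(thr$hi)) return(label_components(mask, 8L))
  seeds <- cpp_label_components(mask & sm > thr$hi, 8L)
  if (max(seeds) == 0L) return(label_components(mask, 8L))
  ws <- watershed_segment(sm, seeds, mask = mask)
  # watershed lines between basins stay 0; keep them out of the regions
  label_mask(ws$labels)
}

#' Count PLA dots per cell
#'
#' Cells are segmented from the DAPI channel (threshold + watershed); the
#' PLA channel is thresholded to separate dots from background, watershed
#' splits touching dots, dots are size-filtered and each dot is assigned
#' to the cell region containing its centroid, else to the nearest cell
#' centroid within `assign_max_dist_px`, else to `cell_id` 0.
#'
#' @param scene an [image_scene()].
#' @param pla_channel,dapi_channel channel names.
#' @param min_spot_area_px,max_spot_area_px dot size window (pixels).
#' @param spot_maxima_min_distance_px dot peak separation for watershed.
#' @param assign_max_dist_px fallback assignment radius (default 10).
#' @return list with `counts` (data.frame `cell_id`, `dots_per_cell`; a
#'   `cell_id` 0 row collects orphan dots), `spots` (per-dot records) and
#'   `cells` (the cell [label_mask()]).
#' @export
count_pla_spots <- function(scene, pla_channel = "PLA", dapi_channel = "DAPI",
                            min_spot_area_px = 2L, max_spot_area_px = 200L,
                            spot_maxima_min_distance_px = 2,
                            assign_max_dist_px = 10) {
  pla <- scene_channel(scene, pla_channel)
  dapi <- scene_channel(scene, dapi_channel)
  cells <- segment_cells(dapi)
  if (length(cells$region_ids) == 0L) {
    warning("no cells found in DAPI channel")
    return(list(counts = data.frame(cell_id = integer(0),
                                    dots_per_cell = integer(0)),
                spots = NULL, cells = cells))
  }
  thr <- otsu_threshold(pla)
  spots <- if (is.na(thr)) NULL else {
    peaks <- find_local_maxima(pla, spot_maxima_min_distance_px, threshold = thr)
    if (nrow(peaks)) {
      ws <- watershed_segment(gaussian_smooth(pla, 0.5), peaks, mask = pla > thr)
      .measure_labels(ws$labels, pla, scene$pixel_size_um,
                      min_size_px = min_spot_area_px)
    } else NULL
  }
  if (!is.null(spots)) {
    spots <- spots[spots$pixel_count <= max_spot_area_px, , drop = FALSE]
  }
  ids <- cells$region_ids
  counts <- data.frame(cell_id = ids, dots_per_cell = 0L)
  orphans <- 0L
  if (!is.null(spots) && nrow(spots)) {
    ps <- scene$pixel_size_um
    cy_px <- spots$centroid_y_um / ps + 1
    cx_px <- spots$centroid_x_um / ps + 1
    cidx <- which(cells$labels > 0L)
    clab <- cells$labels[cidx]
    cent_y <- vapply(ids, function(k) mean((cidx[clab == k] - 1L) %% nrow(dapi)), numeric(1)) + 1
    cent_x <- vapply(ids, function(k) mean((cidx[clab == k] - 1L) %/% nrow(dapi)), numeric(1)) + 1
    spots$cell_id <- vapply(seq_len(nrow(spots)), function(s) {
      r <- round(cy_px[s]); c <- round(cx_px[s])
      r <- min(max(r, 1), nrow(dapi)); c <- min(max(c, 1), ncol(dapi))
      inside <- cells$labels[r, c]
      if (inside > 0L) return(as.integer(inside))
      d <- sqrt((cent_y - cy_px[s])^2 + (cent_x - cx_px[s])^2)
      if (min(d) <= assign_max_dist_px) ids[which.min(d)] else 0L
    }, integer(1))
    tab <- table(spots$cell_id)
    for (nm in names(tab)) {
      k <- as.integer(nm)
      if (k == 0L) orphans <- as.integer(tab[nm])
      else counts$dots_per_cell[counts$cell_id == k] <- as.integer(tab[nm])
    }
  }
  if (orphans > 0L) {
    counts <- rbind(data.frame(cell_id = 0L, dots_per_cell = orphans), counts)
  }
  rownames(counts) <- NULL
  list(counts = counts, spots = spots, cells = cells)
}

#' Fit a bead calibration curve
#'
#' Least-squares line in log10(MFI) - log10(ABC) space over the bead
#' populations of a calibration kit.
#'
#' @param beads data.frame with columns `abc`, `mfi` (bead rows only);
#'   needs at least 3 distinct positive ABC values and positive MFI.
#' @return an object of class `CalibrationCurve`: `slope`, `intercept`,
#'   `r_squared`, `mfi_range`.
#' @export
fit_calibration_curve <- function(beads) {
  stopifnot(is.data.frame(beads), all(c("abc", "mfi") %in% names(beads)))
  b <- beads[beads$abc > 0 & beads$mfi > 0, , drop = FALSE]
  if (length(unique(b$abc)) < 3L) {
    stop("need at least 3 bead populations with distinct positive ABC")
  }
  if (nrow(b) < nrow(beads)) stop("non-positive bead ABC or MFI values")
  fit <- lm(log10(mfi) ~ log10(abc), data = b)
  # suppressed: summary.lm warns on the (legitimate) exact fit of
  # noiseless calibration data
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 mfi_range = range(b$mfi)),
            class = "CalibrationCurve")
}

#' Convert sample MFI to molecule counts
#'
#' `molecules = 10^((log10 MFI - intercept) / slope)` on the bead
#' calibration line; samples outside the bead MFI range are flagged as
#' extrapolated.
#'
#' @param beads bead data.frame (`abc`, `mfi`) or a fitted
#'   [fit_calibration_curve()] object.
#' @param sample_mfi numeric vector of sample MFI values (`> 0`).
#' @return data.frame with `sample`, `mfi`, `molecules`, `extrapolated`.
#' @export
calibrate_molecules <- function(beads, sample_mfi) {
  curve <- if (inherits(beads, "CalibrationCurve")) beads
           else fit_calibration_curve(beads)
  if (any(sample_mfi <= 0)) stop("sample MFI values must be positive")
  mol <- 10^((log10(sample_mfi) - curve$intercept) / curve$slope)
  data.frame(sample = seq_along(sample_mfi), mfi = sample_mfi,
             molecules = mol,
             extrapolated = sample_mfi < curve$mfi_range[1] |
                            sample_mfi > curve$mfi_range[2])
}

#' Apportion a per-cell molecule total across clusters
#'
#' Distributes `cell_total_molecules` over the clusters of one cell
#' proportionally to integrated intensity; the per-cluster estimates sum
#' to the cell total exactly.
#'
#' @param clusters cluster data.frame from [detect_clusters()].
#' @param cell_total_molecules total surface molecules of the cell.
#' @param curve optional [fit_calibration_curve()] (kept for provenance;
#'   apportionment itself is intensity-proportional).
#' @return `clusters` with an added `molecules` column.
#' @export
molecules_per_cluster <- function(clusters, cell_total_molecules, curve = NULL) {
  stopifnot(is.data.frame(clusters), cell_total_molecules >= 0)
  total_int <- sum(clusters$integrated_intensity)
  clusters$molecules <- if (nrow(clusters) == 0L) numeric(0)
    else if (total_int <= 0) rep(cell_total_molecules / nrow(clusters),
                                 nrow(clusters))
    else cell_total_molecules * clusters$integrated_intensity / total_int
  clusters
}
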