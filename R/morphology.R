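#' Otsu threshold
#'
#' Histogram-based threshold maximizing between-class variance, the default
#' automatic threshold of the segmentation pipelines. Returns the midpoint
#' of the optimal histogram bin edge so that `x > threshold` separates the
#' classes.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins number of histogram bins (default 256).
#' @return threshold value; `NA` if `x` is constant.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(NA_real_)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_t <- mu_cum[n_bins]
  w1 <- 1 - w0
  ok <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[ok] <- (mu_t * w0[ok] - mu_cum[ok])^2 / (w0[ok] * w1[ok])
  k <- which.max(sigma_b)
  # threshold on the upper edge of the winning bin
  edges[k + 1L]
}

#' Three-class Otsu thresholds
#'
#' Exhaustive two-threshold Otsu: maximizes the between-class variance of
#' the three classes `x <= t1`, `t1 < x <= t2`, `x > t2`.
#'
#' @param x numeric vector or matrix.
#' @param n_bins histogram bins (default 128).
#' @return `c(t1, t2)` with `t1 < t2`, or `NA` for a constant input.
#' @export
otsu_multi <- function(x, n_bins = 128L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (diff(rng) == 0) return(c(NA_real_, NA_real_))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, edges, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  P <- cumsum(p); M <- cumsum(p * mids)
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(n_bins - 2L)) {
    j <- (i + 1L):(n_bins - 1L)
    w0 <- P[i]; w1 <- P[j] - P[i]; w2 <- 1 - P[j]
    m0 <- M[i]; m1 <- M[j] - M[i]; m2 <- M[n_bins] - M[j]
    ok <- w0 > 0 & w1 > 0 & w2 > 0
    s <- rep(-Inf, length(j))
    s[ok] <- (m0^2 / w0 + m1[ok]^2 / w1[ok] + m2[ok]^2 / w2[ok])
    k <- which.max(s)
    if (s[k] > best) { best <- s[k]; bi <- i; bj <- j[k] }
  }
  c(edges[bi + 1L], edges[bj + 1L])
}

# Foreground threshold for images with up to three intensity levels
# (background / cell body / bright structure). The middle class counts as
# foreground when it sits well above background relative to the bright
# class; otherwise it is background (the image is effectively bimodal).
.foreground_threshold <- function(x) {
  tt <- otsu_multi(x, n_bins = 64L)   # coarse bins suffice for level splits
  if (any(is.na(tt))) return(list(lo = otsu_threshold(x), hi = NA_real_))
  v <- as.numeric(x)
  m0 <- mean(v[v <= tt[1]])
  m1 <- mean(v[v > tt[1] & v <= tt[2]])
  m2 <- mean(v[v > tt[2]])
  if (!is.finite(m1) || (m1 - m0) < 0.15 * (m2 - m0)) {
    list(lo = tt[2], hi = NA_real_)        # bimodal: middle is background
  } else {
    list(lo = tt[1], hi = tt[2])           # trimodal: middle is cell body
  }
}

#' Gaussian smoothing
#'
#' Separable Gaussian convolution with replicate-edge padding; kernel
#' truncated at three standard deviations.
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels; `0` returns `m` unchanged.
#' @return smoothed matrix.
#' @export
gaussian_smooth <- function(m, sigma = 1) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  # pad by replication, convolve rows then columns via shifted sums
  conv1 <- function(mat, along_rows) {
    n <- if (along_rows) nrow(mat) else ncol(mat)
    idx <- seq_len(n)
    out <- 0
    for (j in -r:r) {
      sh <- pmin(pmax(idx + j, 1L), n)
      out <- out + k[j + r + 1L] * (if (along_rows) mat[sh, , drop = FALSE]
                                    else mat[, sh, drop = FALSE])
    }
    out
  }
  conv1(conv1(m, TRUE), FALSE)
}

#' Connected-component labeling
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8, the Analyze Particles convention).
#' @return a [label_mask()].
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  storage.mode(mask) <- "logical"
  label_mask(cpp_label_components(mask, as.integer(connectivity)))
}

#' Fill holes in a binary mask
#'
#' Background regions not 8-connected to the image border become foreground.
#'
#' @param mask logical matrix.
#' @return logical matrix.
#' @export
binary_fill_holes <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  cpp_fill_holes(mask)
}

#' Dilate a binary mask by a disc
#'
#' @param mask logical matrix.
#' @param radius_px disc radius in pixels.
#' @return logical matrix.
#' @export
dilate_mask <- function(mask, radius_px) {
  stopifnot(is.matrix(mask), radius_px >= 0)
  storage.mode(mask) <- "logical"
  if (radius_px == 0) return(mask)
  cpp_dilate_disc(mask, as.numeric(radius_px))
}

#' Local intensity maxima
#'
#' Finds strict local maxima (8-neighborhood, one per plateau) above a
#' threshold, then greedily enforces a minimum center-to-center distance in
#' decreasing intensity order. Deterministic for identical input.
#'
#' @param m numeric matrix.
#' @param min_distance_px minimum peak separation in pixels.
#' @param threshold intensity floor; peaks must exceed it (default: above
#'   the image minimum).
#' @return integer matrix with columns `row`, `col` (1-based).
#' @export
find_local_maxima <- function(m, min_distance_px = 3, threshold = NULL) {
  stopifnot(is.matrix(m))
  if (is.null(threshold)) threshold <- min(m)
  out <- cpp_local_maxima(m, as.numeric(min_distance_px), as.numeric(threshold))
  colnames(out) <- c("row", "col")
  out
}

#' Seeded watershed segmentation
#'
#' Meyer flooding descending from seed maxima on the intensity landscape;
#' basins meeting produce one-pixel watershed lines (label 0). This is the
#' "segmentation of maxima" step of the cluster pipeline (Find Maxima /
#' segmented-particles semantics).
#'
#' @param intensity numeric matrix (flooded from bright to dark).
#' @param seeds either an integer label matrix (`>0` seeds a basin) or an
#'   `n x 2` matrix of 1-based `(row, col)` peak coordinates, which are
#'   labeled `1..n` in row order.
#' @param mask optional logical matrix restricting the flood.
#' @param connectivity 4 or 8.
#' @return a [label_mask()]; watershed lines and unreached pixels are 0.
#' @export
watershed_segment <- function(intensity, seeds, mask = NULL, connectivity = 8L) {
  stopifnot(is.matrix(intensity))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  storage.mode(mask) <- "logical"
  if (is.matrix(seeds) && ncol(seeds) == 2L && nrow(seeds) > 0 &&
      !identical(dim(seeds), dim(intensity))) {
    sm <- matrix(0L, nrow(intensity), ncol(intensity))
    sm[cbind(seeds[, 1], seeds[, 2])] <- seq_len(nrow(seeds))
    seeds <- sm
  } else if (!identical(dim(seeds), dim(intensity))) {
    seeds <- matrix(0L, nrow(intensity), ncol(intensity))
  }
  storage.mode(seeds) <- "integer"
  label_mask(cpp_watershed(intensity, seeds, mask, as.integer(connectivity)))
}
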