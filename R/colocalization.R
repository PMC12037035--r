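#' Pearson correlation between two channels
#'
#' Sample Pearson correlation over the analysis mask (whole image when no
#' mask is given; zero-zero pixels inside the mask are retained).
#'
#' @param scene an [image_scene()].
#' @param ch_a,ch_b channel names.
#' @param mask optional logical matrix or [label_mask()] restricting the
#'   analysis (any nonzero label is included).
#' @return Pearson r, or `NA` with a warning for a constant channel.
#' @export
pearson_coefficient <- function(scene, ch_a, ch_b, mask = NULL) {
  a <- scene_channel(scene, ch_a)
  b <- scene_channel(scene, ch_b)
  sel <- .coerce_mask(mask, dim(a))
  va <- a[sel]; vb <- b[sel]
  if (length(va) < 2L) stop("need at least 2 pixels in the mask")
  if (sd(va) == 0 || sd(vb) == 0) {
    warning("constant channel: Pearson correlation undefined")
    return(NA_real_)
  }
  cor(va, vb)
}

.coerce_mask <- function(mask, dims) {
  if (is.null(mask)) return(matrix(TRUE, dims[1], dims[2]))
  m <- if (inherits(mask, "LabelMask")) mask$labels > 0L else mask
  stopifnot(identical(dim(m), dims))
  storage.mode(m) <- "logical"
  m
}

# reduced major-axis (standardized) regression b ~ a. Chosen over the
# plain major axis because it is equivariant under rescaling of either
# channel, which makes the Costes thresholds (and hence M1/M2) invariant
# under multiplication of a channel by a positive scalar.
.orth_regression <- function(a, b) {
  sxx <- stats::var(a); syy <- stats::var(b); sxy <- stats::cov(a, b)
  if (!is.finite(sxy) || sxy == 0 || sxx == 0 || syy == 0) return(NULL)
  slope <- sign(sxy) * sqrt(syy / sxx)
  list(slope = slope, intercept = mean(b) - slope * mean(a))
}

#' Manders overlap coefficients with Costes auto-thresholding
#'
#' `M1 = sum(A over pixels where B > T_b) / sum(A)` and symmetrically
#' `M2`. With `threshold_mode = "bisection_costes"` the threshold pair
#' lies on the orthogonal regression line `T_b = slope * T_a +
#' intercept`, and `T_a` is lowered by bisection until the Pearson
#' correlation of the pixels below both thresholds is in `(-0.01, 0]`
#' (or the search interval collapses below one intensity unit; at most
#' 64 halvings). A degenerate regression (constant channel) falls back
#' to fixed thresholds with a warning.
#'
#' @param scene an [image_scene()].
#' @param ch_a,ch_b channel names.
#' @param mask optional analysis mask.
#' @param threshold_mode `"bisection_costes"` or `"fixed"`.
#' @param thresholds fixed `(T_a, T_b)` for `threshold_mode = "fixed"`;
#'   defaults to the per-channel Otsu values.
#' @return an object of class `ColocResult`: `pearson_r`, `manders_m1`,
#'   `manders_m2`, `threshold_ch1`, `threshold_ch2`,
#'   `n_pixels_analyzed`, `threshold_mode`, `bisection_iterations`.
#' @export
manders_coefficients <- function(scene, ch_a, ch_b, mask = NULL,
                                 threshold_mode = c("bisection_costes", "fixed"),
                                 thresholds = NULL) {
  threshold_mode <- match.arg(threshold_mode)
  a <- scene_channel(scene, ch_a)
  b <- scene_channel(scene, ch_b)
  sel <- .coerce_mask(mask, dim(a))
  va <- a[sel]; vb <- b[sel]
  if (length(va) < 2L) stop("need at least 2 pixels in the mask")
  pear <- if (sd(va) == 0 || sd(vb) == 0) NA_real_ else cor(va, vb)
  iters <- 0L
  if (threshold_mode == "bisection_costes") {
    reg <- .orth_regression(va, vb)
    if (is.null(reg)) {
      warning("degenerate regression (constant channel); using fixed Otsu thresholds")
      threshold_mode <- "fixed"
    } else {
      lo <- min(va); hi <- max(va)
      # convergence when the interval is negligible on the channel's own
      # scale (so results are invariant under intensity rescaling); 64
      # halvings bound the search unconditionally
      eps <- (hi - lo) / 2^12
      t_a <- hi
      r_below <- function(t_a) {
        t_b <- reg$slope * t_a + reg$intercept
        below <- va < t_a & vb < t_b
        if (sum(below) < 2L) return(NA_real_)
        x <- va[below]; y <- vb[below]
        if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
        cor(x, y)
      }
      repeat {
        iters <- iters + 1L
        mid <- (lo + hi) / 2
        r <- r_below(mid)
        done <- (!is.na(r) && r <= 0 && r > -0.01) ||
                (hi - lo) < eps || iters >= 64L
        if (is.na(r) || r > 0) hi <- mid else lo <- mid
        t_a <- mid
        if (done) break
      }
      # thresholds never leave the observed intensity ranges
      t_a <- min(max(t_a, min(va)), max(va))
      t_b <- min(max(reg$slope * t_a + reg$intercept, min(vb)), max(vb))
    }
  }
  if (threshold_mode == "fixed") {
    if (is.null(thresholds)) {
      thresholds <- c(otsu_threshold(va), otsu_threshold(vb))
    }
    t_a <- thresholds[1]; t_b <- thresholds[2]
  }
  sum_a <- sum(va); sum_b <- sum(vb)
  m1 <- if (sum_a > 0) sum(va[vb > t_b]) / sum_a else NA_real_
  m2 <- if (sum_b > 0) sum(vb[va > t_a]) / sum_b else NA_real_
  structure(list(pearson_r = pear, manders_m1 = m1, manders_m2 = m2,
                 threshold_ch1 = t_a, threshold_ch2 = t_b,
                 n_pixels_analyzed = length(va),
                 threshold_mode = threshold_mode,
                 bisection_iterations = iters),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("ColocResult: r = %.3f | M1 = %.3f | M2 = %.3f | T = (%.3g, %.3g) | n = %d\n",
              x$pearson_r, x$manders_m1, x$manders_m2, x$threshold_ch1,
              x$threshold_ch2, x$n_pixels_analyzed))
  invisible(x)
}
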