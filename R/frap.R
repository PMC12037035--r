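#' FRAP trace series
#'
#' Raw fluorescence-recovery traces: bleach-zone, whole-cell, and
#' background mean intensities on a common time axis, with the index of
#' the first post-bleach frame. Requires at least 1 pre-bleach and 5
#' post-bleach frames and positive pre-bleach background-corrected ROI
#' signal.
#'
#' @param t_s strictly increasing time points (s).
#' @param roi bleach-zone mean intensity trace.
#' @param cell whole-cell mean intensity trace.
#' @param bg background mean intensity trace.
#' @param bleach_index index of the first post-bleach frame (`>= 2`).
#' @return an object of class `FRAPSeries`.
#' @export
frap_series <- function(t_s, roi, cell, bg, bleach_index) {
  n <- length(t_s)
  if (length(roi) != n || length(cell) != n || length(bg) != n) {
    stop("t_s, roi, cell, bg must have equal length")
  }
  if (any(diff(t_s) <= 0)) stop("t_s must be strictly increasing")
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2L) stop("need at least 1 pre-bleach frame")
  if (n - bleach_index + 1L < 5L) stop("need at least 5 post-bleach frames")
  pre <- seq_len(bleach_index - 1L)
  if (mean(roi[pre] - bg[pre]) <= 0) {
    stop("mean pre-bleach (roi - bg) must be positive")
  }
  structure(list(t_s = as.numeric(t_s), roi = as.numeric(roi),
                 cell = as.numeric(cell), bg = as.numeric(bg),
                 bleach_index = bleach_index),
            class = "FRAPSeries")
}

#' Double-normalize a FRAP series
#'
#' Corrects the bleach-zone trace for background and acquisition
#' photobleaching:
#' `I_norm(t) = [(roi - bg) / (cell - bg)] * [mean_pre(cell - bg) / mean_pre(roi - bg)]`.
#' The pre-bleach mean of the normalized curve is 1 by construction.
#'
#' @param series a [frap_series()].
#' @return data.frame with columns `t_s`, `i_norm` and attribute
#'   `bleach_index`.
#' @export
normalize_series <- function(series) {
  stopifnot(inherits(series, "FRAPSeries"))
  cb <- series$cell - series$bg
  if (any(cb <= 0)) {
    stop("cell - bg <= 0 at frame(s) ", paste(which(cb <= 0), collapse = ", "))
  }
  pre <- seq_len(series$bleach_index - 1L)
  rb <- series$roi - series$bg
  i_norm <- (rb / cb) * (mean(cb[pre]) / mean(rb[pre]))
  out <- data.frame(t_s = series$t_s, i_norm = i_norm)
  attr(out, "bleach_index") <- series$bleach_index
  out
}

# residual sum of squares of the recovery model at fixed tau, with the
# linear parameters (I0, A) profiled out by least squares
.frap_profile <- function(tp, y, tau) {
  x <- 1 - exp(-tp / tau)
  X <- cbind(1, x)
  fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
  if (is.null(fit)) return(list(rss = Inf, i0 = NA_real_, a = NA_real_))
  list(rss = sum(fit$residuals^2), i0 = fit$coefficients[1],
       a = fit$coefficients[2])
}

#' Fit single-exponential FRAP recovery
#'
#' Fits `I(t') = I0 + A * (1 - exp(-t'/tau))` to the post-bleach part of
#' a normalized curve (`t'` measured from the bleach frame). `tau` is
#' found by one-dimensional optimization with the linear parameters
#' profiled out, which converges unattended for any finite input. The
#' mobile fraction is `A / (1 - I0)` (fitted plateau convention); the
#' half-time is `tau * log(2)` exactly, a model identity.
#'
#' @param norm_curve data.frame `(t_s, i_norm)` from [normalize_series()],
#'   or any data.frame with those columns.
#' @param bleach_index first post-bleach frame; defaults to the attribute
#'   left by [normalize_series()].
#' @param plateau_method `"fit"` uses the fitted plateau `I0 + A`;
#'   `"last_frames"` replaces it by the mean of the last `k` points when
#'   estimating the mobile fraction.
#' @param k number of trailing frames for `plateau_method = "last_frames"`.
#' @return an object of class `FRAPFit`: a list with `mobile_fraction`
#'   (reported value capped at 1.05, with `capped` flag), `t_half_s`,
#'   `tau_s`, `plateau`, `i0`, `rss`, `n_points`, `converged`.
#' @export
fit_recovery <- function(norm_curve, bleach_index = attr(norm_curve, "bleach_index"),
                         plateau_method = c("fit", "last_frames"), k = 5L) {
  plateau_method <- match.arg(plateau_method)
  if (is.null(bleach_index)) stop("bleach_index not given and not an attribute")
  t_s <- norm_curve$t_s
  y_all <- norm_curve$i_norm
  post <- seq.int(bleach_index, length(t_s))
  if (length(post) < 5L) stop("need at least 5 post-bleach points")
  tp <- t_s[post] - t_s[bleach_index]
  y <- y_all[post]
  dt <- stats::median(diff(tp))
  span <- max(tp[length(tp)], dt)
  lo <- log(dt / 20); hi <- log(span * 50)
  opt <- stats::optimize(function(lt) .frap_profile(tp, y, exp(lt))$rss,
                         interval = c(lo, hi), tol = 1e-10)
  tau <- exp(opt$minimum)
  pf <- .frap_profile(tp, y, tau)
  i0 <- unname(pf$i0); a <- unname(pf$a)
  plateau <- i0 + a
  converged <- is.finite(pf$rss) && is.finite(i0) && is.finite(a)
  mf_plateau <- if (plateau_method == "fit") plateau
                else mean(y[seq.int(max(1L, length(y) - k + 1L), length(y))])
  mobile <- (mf_plateau - i0) / (1 - i0)
  capped <- FALSE
  if (is.finite(mobile) && mobile > 1.05) { mobile <- 1.05; capped <- TRUE }
  structure(list(mobile_fraction = mobile, t_half_s = tau * log(2),
                 tau_s = tau, plateau = plateau, i0 = i0, a = a,
                 rss = pf$rss, n_points = length(post),
                 converged = converged, capped = capped,
                 plateau_method = plateau_method),
            class = "FRAPFit")
}

#' @export
print.FRAPFit <- function(x, ...) {
  cat(sprintf("FRAPFit: mobile fraction %.3f | t1/2 %.2f s | tau %.2f s | %s\n",
              x$mobile_fraction, x$t_half_s, x$tau_s,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Batch FRAP analysis with a mean recovery curve
#'
#' Normalizes and fits every series, and assembles the across-trace mean
#' recovery curve with per-timepoint SEM on a common post-bleach time
#' grid (the first trace's post-bleach times truncated to the shortest
#' trace; other traces are linearly interpolated onto it).
#'
#' @param traces list of [frap_series()] objects.
#' @return list with `fits` (one data.frame row per trace) and
#'   `mean_curve` (data.frame `t_s`, `mean`, `sem`, `n`).
#' @export
batch_frap <- function(traces) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  norms <- lapply(traces, normalize_series)
  fits <- lapply(norms, fit_recovery)
  fit_df <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(trace = i, mobile_fraction = f$mobile_fraction,
               t_half_s = f$t_half_s, tau_s = f$tau_s, plateau = f$plateau,
               rss = f$rss, n_points = f$n_points, converged = f$converged)
  }))
  post_t <- lapply(seq_along(norms), function(i) {
    bi <- attr(norms[[i]], "bleach_index")
    norms[[i]]$t_s[seq.int(bi, nrow(norms[[i]]))] - norms[[i]]$t_s[bi]
  })
  t_max <- min(vapply(post_t, max, numeric(1)))
  grid <- post_t[[1]][post_t[[1]] <= t_max + 1e-12]
  vals <- vapply(seq_along(norms), function(i) {
    bi <- attr(norms[[i]], "bleach_index")
    idx <- seq.int(bi, nrow(norms[[i]]))
    stats::approx(post_t[[i]], norms[[i]]$i_norm[idx], xout = grid,
                  rule = 2)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  n <- ncol(vals)
  mean_v <- rowMeans(vals)
  sem <- if (n > 1) apply(vals, 1, stats::sd) / sqrt(n) else rep(0, length(grid))
  list(fits = fit_df,
       mean_curve = data.frame(t_s = grid, mean = mean_v, sem = sem, n = n))
}
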