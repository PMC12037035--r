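#' Trajectory set
#'
#' Linked particle tracks. Within a track, frames are strictly
#' increasing; positions are in micrometers.
#'
#' @param tracks data.frame with columns `track_id`, `frame`, `x_um`,
#'   `y_um`.
#' @param dt_s frame interval (s).
#' @return an object of class `TrajectorySet` (a data.frame with
#'   attribute `dt_s`).
#' @export
trajectory_set <- function(tracks, dt_s) {
  stopifnot(is.data.frame(tracks),
            all(c("track_id", "frame", "x_um", "y_um") %in% names(tracks)),
            dt_s > 0)
  tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  rownames(tracks) <- NULL
  for (id in unique(tracks$track_id)) {
    fr <- tracks$frame[tracks$track_id == id]
    if (any(diff(fr) <= 0)) stop("frames must be strictly increasing in track ", id)
  }
  structure(tracks, dt_s = dt_s, class = c("TrajectorySet", "data.frame"))
}

#' Split a trajectory set into per-track data frames
#' @param tracks a [trajectory_set()].
#' @return named list of data.frames, each carrying the `dt_s` attribute.
#' @export
split_tracks <- function(tracks) {
  dt <- attr(tracks, "dt_s")
  out <- split(as.data.frame(tracks), tracks$track_id)
  lapply(out, function(tr) { attr(tr, "dt_s") <- dt; tr })
}

#' Link particle detections into trajectories
#'
#' Greedy mutual-nearest-neighbor frame-to-frame linking: for each new
#' frame, a detection joins the active track whose head is its nearest
#' neighbor within `max_link_um` and for which it is in turn the nearest
#' detection. Tracks may bridge up to `max_gap` missing frames; unmatched
#' detections start new tracks. Deterministic and invariant to detection
#' row order within a frame.
#'
#' @param detections data.frame with columns `frame`, `x_um`, `y_um`.
#'   Duplicate `(frame, x_um, y_um)` rows are an error.
#' @param max_link_um maximum link distance per frame step.
#' @param max_gap maximum number of bridged missing frames (default 2).
#' @param dt_s frame interval for the resulting [trajectory_set()].
#' @return a [trajectory_set()].
#' @export
link_detections <- function(detections, max_link_um, max_gap = 2L, dt_s = 0.1) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x_um", "y_um") %in% names(detections)),
            max_link_um > 0, max_gap >= 0)
  if (anyDuplicated(detections[, c("frame", "x_um", "y_um")])) {
    stop("duplicate (frame, x_um, y_um) detection rows")
  }
  det <- detections[order(detections$frame, detections$x_um, detections$y_um), ]
  frames <- sort(unique(det$frame))
  track_of <- integer(nrow(det))
  # active track state: id, last x, y, last frame
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- integer(0)
  next_id <- 0L
  idx_by_frame <- split(seq_len(nrow(det)), det$frame)
  for (f in frames) {
    rows <- idx_by_frame[[as.character(f)]]
    live <- which(act_f >= f - 1L - max_gap & act_f < f)
    nx <- det$x_um[rows]; ny <- det$y_um[rows]
    assigned <- rep(FALSE, length(rows))
    if (length(live)) {
      dmat <- sqrt(outer(act_x[live], nx, `-`)^2 +
                   outer(act_y[live], ny, `-`)^2)
      dmat[dmat > max_link_um] <- Inf
      repeat {
        if (all(!is.finite(dmat))) break
        # mutual nearest pair: take the globally closest remaining pair,
        # which is necessarily mutually nearest
        k <- which.min(dmat)
        ti <- (k - 1L) %% length(live) + 1L
        di <- (k - 1L) %/% length(live) + 1L
        tr <- live[ti]
        track_of[rows[di]] <- act_id[tr]
        act_x[tr] <- nx[di]; act_y[tr] <- ny[di]; act_f[tr] <- f
        assigned[di] <- TRUE
        dmat[ti, ] <- Inf
        dmat[, di] <- Inf
      }
    }
    for (di in which(!assigned)) {
      next_id <- next_id + 1L
      act_id <- c(act_id, next_id)
      act_x <- c(act_x, nx[di]); act_y <- c(act_y, ny[di])
      act_f <- c(act_f, f)
      track_of[rows[di]] <- next_id
    }
  }
  out <- data.frame(track_id = track_of, frame = det$frame,
                    x_um = det$x_um, y_um = det$y_um)
  trajectory_set(out, dt_s = dt_s)
}

#' Time-averaged mean squared displacement
#'
#' `MSD(lag) = mean over t of |r(t + lag) - r(t)|^2`, using all frame
#' pairs with the given frame difference.
#'
#' @param track data.frame with `frame`, `x_um`, `y_um` and a `dt_s`
#'   attribute (e.g. from [split_tracks()]), or a single-track
#'   [trajectory_set()].
#' @param max_lag_frames largest lag (frames).
#' @param dt_s frame interval; defaults to the track attribute.
#' @return data.frame with `lag_frames`, `lag_s`, `msd_um2`, `n_pairs`.
#' @export
msd_curve <- function(track, max_lag_frames = 10L, dt_s = attr(track, "dt_s")) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(track)))
  if (is.null(dt_s)) stop("dt_s not given and not an attribute")
  tr <- track[order(track$frame), ]
  fr <- tr$frame; x <- tr$x_um; y <- tr$y_um
  lags <- seq_len(max_lag_frames)
  msd <- rep(NA_real_, length(lags)); np <- integer(length(lags))
  pos <- match(fr + rep(lags, each = length(fr)), fr)
  pos <- matrix(pos, nrow = length(fr))
  for (li in lags) {
    j <- pos[, li]
    ok <- !is.na(j)
    np[li] <- sum(ok)
    if (np[li] > 0) {
      msd[li] <- mean((x[j[ok]] - x[ok])^2 + (y[j[ok]] - y[ok])^2)
    }
  }
  data.frame(lag_frames = lags, lag_s = lags * dt_s, msd_um2 = msd,
             n_pairs = np)
}

#' Diffusion coefficient from an MSD curve
#'
#' Ordinary least squares on `MSD = 4 D lag + b` over the first
#' `n_lags` lags (2D Brownian motion); the intercept absorbs
#' localization error.
#'
#' @param msd data.frame from [msd_curve()].
#' @param n_lags number of initial lags used (default 4).
#' @return `D` in um^2/s.
#' @export
estimate_diffusion <- function(msd, n_lags = 4L) {
  use <- msd[seq_len(min(n_lags, nrow(msd))), ]
  use <- use[is.finite(use$msd_um2), ]
  if (nrow(use) < 2L) return(NA_real_)
  unname(coef(lm(msd_um2 ~ lag_s, data = use))[2] / 4)
}

# log-log MSD scaling exponent over lags 1..n_fit (n_fit >= 2)
.alpha_of <- function(tr_x, tr_y, n_fit, lag_min = 1L) {
  lags <- seq.int(lag_min, max(n_fit, lag_min + 1L))
  msd <- vapply(lags, function(d) {
    n <- length(tr_x) - d
    if (n < 1) return(NA_real_)
    mean((tr_x[(1 + d):(n + d)] - tr_x[1:n])^2 +
         (tr_y[(1 + d):(n + d)] - tr_y[1:n])^2)
  }, numeric(1))
  ok <- is.finite(msd) & msd > 0
  if (sum(ok) < 2L) return(NA_real_)
  unname(coef(lm(log(msd[ok]) ~ log(lags[ok])))[2])
}

#' Classify confined / free / active motion along a track
#'
#' Within each sliding window of `window` frames the MSD scaling exponent
#' `alpha` is fitted on `log MSD(lag) = log C + alpha log lag` over lags
#' `1..window/4` (starting at lag 2 when the window allows at least three
#' fit points, to suppress the localization-error intercept). The
#' centered window labels its middle frame: `confined` if `alpha <
#' alpha_confined`, `active` if `alpha > alpha_active`, else `free`.
#' Edge frames inherit the nearest full window; tracks shorter than the
#' window get a single whole-track label.
#'
#' @param track single-track data.frame (`frame`, `x_um`, `y_um`).
#' @param window window length in frames (`>= 8`).
#' @param alpha_confined,alpha_active thresholds (defaults 0.6 / 1.4).
#' @return character vector of per-frame labels, one per track row.
#' @export
classify_motion <- function(track, window = 32L, alpha_confined = 0.6,
                            alpha_active = 1.4) {
  stopifnot(window >= 8L)
  tr <- track[order(track$frame), ]
  n <- nrow(tr)
  lab_of <- function(alpha) {
    if (!is.finite(alpha)) "free"
    else if (alpha < alpha_confined) "confined"
    else if (alpha > alpha_active) "active"
    else "free"
  }
  n_fit <- max(2L, window %/% 4L)
  lag_min <- if (n_fit >= 4L) 2L else 1L
  if (n < window) {
    a <- .alpha_of(tr$x_um, tr$y_um, max(2L, n %/% 4L), lag_min = 1L)
    return(rep(lab_of(a), n))
  }
  starts <- seq_len(n - window + 1L)
  alphas <- vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    .alpha_of(tr$x_um[idx], tr$y_um[idx], n_fit, lag_min)
  }, numeric(1))
  labels <- character(n)
  half <- window %/% 2L
  centers <- starts + half - 1L
  win_lab <- vapply(alphas, lab_of, character(1))
  for (i in seq_len(n)) {
    j <- which.min(abs(centers - i))
    labels[i] <- win_lab[j]
  }
  labels
}

#' Mean frame-to-frame speed of a track
#'
#' Mean of `|r(t+1) - r(t)| / dt` over consecutive-frame steps.
#'
#' @param track single-track data.frame.
#' @param dt_s frame interval; defaults to the track attribute.
#' @return speed in um/s (0 for a single-point track).
#' @export
mean_speed <- function(track, dt_s = attr(track, "dt_s")) {
  if (is.null(dt_s)) stop("dt_s not given and not an attribute")
  tr <- track[order(track$frame), ]
  if (nrow(tr) < 2L) return(0)
  step1 <- diff(tr$frame) == 1L
  if (!any(step1)) return(NA_real_)
  d <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)[step1]
  mean(d) / dt_s
}

#' Per-track summary of a trajectory set
#'
#' @param tracks a [trajectory_set()].
#' @param window,alpha_confined,alpha_active passed to [classify_motion()].
#' @param min_track_len tracks shorter than this are summarized but
#'   flagged `analyzed = FALSE` (default 20 frames).
#' @return data.frame with one row per track: length, mean speed,
#'   diffusion estimate, and the fraction of frames in each motion state.
#' @export
summarize_tracks <- function(tracks, window = 32L, alpha_confined = 0.6,
                             alpha_active = 1.4, min_track_len = 20L) {
  dt <- attr(tracks, "dt_s")
  per <- split_tracks(tracks)
  do.call(rbind, lapply(per, function(tr) {
    n <- nrow(tr)
    lab <- if (n >= 8L) {
      classify_motion(tr, window = min(window, max(8L, n)),
                      alpha_confined = alpha_confined,
                      alpha_active = alpha_active)
    } else rep(NA_character_, n)
    msd <- if (n >= 5L) msd_curve(tr, max_lag_frames = min(10L, n - 1L),
                                  dt_s = dt) else NULL
    data.frame(track_id = tr$track_id[1], n_frames = n,
               mean_speed_um_s = mean_speed(tr, dt_s = dt),
               D_um2_s = if (is.null(msd)) NA_real_ else estimate_diffusion(msd),
               frac_confined = mean(lab == "confined"),
               frac_free = mean(lab == "free"),
               frac_active = mean(lab == "active"),
               analyzed = n >= min_track_len)
  }))
}

#' Detect particles in a movie for tracking
#'
#' Frame-by-frame spot detection reusing the cluster maxima detector:
#' Gaussian smoothing, Otsu floor, and local maxima separated by the
#' particle-size prior (a 0.35 um^2 spot is ~0.33 um across).
#'
#' @param scene an [image_scene()] whose channel is a 2D+time array.
#' @param channel channel name (default first).
#' @param particle_area_um2 expected particle footprint (default 0.35).
#' @param smooth_sigma_px smoothing before peak detection.
#' @return data.frame with `frame`, `x_um`, `y_um` ready for
#'   [link_detections()].
#' @export
detect_particles <- function(scene, channel = scene$channel_names[1],
                             particle_area_um2 = 0.35,
                             smooth_sigma_px = 1) {
  stopifnot(inherits(scene, "ImageScene"))
  ch <- scene$channels[[channel]]
  if (length(dim(ch)) != 3L) stop("channel '", channel, "' is not a movie")
  ps <- scene$pixel_size_um
  min_dist <- 2 * sqrt(particle_area_um2 / pi) / ps
  rows <- lapply(seq_len(dim(ch)[3]), function(f) {
    img <- gaussian_smooth(ch[, , f], smooth_sigma_px)
    thr <- otsu_threshold(img)
    if (is.na(thr)) return(NULL)
    pk <- find_local_maxima(img, min_distance_px = min_dist, threshold = thr)
    if (!nrow(pk)) return(NULL)
    data.frame(frame = f, x_um = (pk[, "col"] - 1) * ps,
               y_um = (pk[, "row"] - 1) * ps)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(frame = integer(0), x_um = numeric(0),
                                      y_um = numeric(0))
  out
}
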