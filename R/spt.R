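# Single-particle tracking analytics: spot linking, two MSD conventions,
# diffusion-coefficient estimation, confinement-plateau detection, motility
# classification and within-track state segmentation.
#
# Two MSD variants are provided. `msd_paper` is the cumulative sum of squared
# increments of the distance from the first position,
#   MSD(n) = sum_{i=1..n} (d_i - d_{i-1})^2,   d_i = |p_i - p_0|,
# which is non-decreasing by construction and grows linearly (not
# quadratically) even for straight-line motion; it is kept as the exact
# published convention. `msd_standard` is the conventional time-averaged MSD,
#   MSD(k) = mean_t |p_{t+k} - p_t|^2,
# which obeys diffusion theory (ensemble mean 4*D*k*dt + 4*sigma_loc^2 for
# 2D Brownian motion) and backs all quantitative checks.

#' Link per-frame spots into trajectories
#'
#' Greedy frame-to-frame nearest-neighbour assignment under a maximum
#' displacement. Unmatched spots start new tracks; a missing detection
#' terminates a track (no gap closing); tracks shorter than `min_length`
#' frames are discarded. Exact distance ties are broken by spot order.
#'
#' @param spots data.frame with columns `frame, x, y` (micrometres) and
#'   optionally `intensity`
#' @param frame_interval frame interval in seconds
#' @param max_displacement_um linking gate (um per frame)
#' @param min_length minimum retained track length in frames (default 5,
#'   i.e. at least 5 consecutive frames)
#' @return list of [trajectory()] objects
#' @export
link_tracks <- function(spots, frame_interval, max_displacement_um = 1,
                        min_length = 5L) {
  stopifnot(max_displacement_um > 0, min_length >= 2)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(spots))) stop("spots needs columns frame, x, y")
  if (nrow(spots) == 0L) return(list())
  frames <- sort(unique(spots$frame))
  active <- list()   # each: list(x=…, y=…, frame0, last_frame)
  done <- list()
  for (fr in frames) {
    cur <- spots[spots$frame == fr, , drop = FALSE]
    if (anyDuplicated(cur[, c("x", "y")])) {
      warning("duplicate spot coordinates in frame ", fr,
              "; ties broken by spot order")
    }
    # terminate tracks that skipped a frame
    if (length(active)) {
      ended <- vapply(active, function(a) a$last_frame != fr - 1L, logical(1))
      done <- c(done, active[ended])
      active <- active[!ended]
    }
    n_a <- length(active); n_c <- nrow(cur)
    matched_a <- logical(n_a); matched_c <- logical(n_c)
    if (n_a > 0 && n_c > 0) {
      ax <- vapply(active, function(a) tail(a$x, 1), numeric(1))
      ay <- vapply(active, function(a) tail(a$y, 1), numeric(1))
      dmat <- sqrt(outer(ax, cur$x, `-`)^2 + outer(ay, cur$y, `-`)^2)
      repeat {
        dmin <- min(dmat[!matched_a, !matched_c, drop = FALSE], Inf)
        if (!is.finite(dmin) || dmin > max_displacement_um) break
        hit <- which(dmat == dmin, arr.ind = TRUE)
        hit <- hit[!matched_a[hit[, 1]] & !matched_c[hit[, 2]], , drop = FALSE]
        if (nrow(hit) == 0L) break
        i <- hit[1, 1]; j <- hit[1, 2]
        active[[i]]$x <- c(active[[i]]$x, cur$x[j])
        active[[i]]$y <- c(active[[i]]$y, cur$y[j])
        active[[i]]$last_frame <- fr
        matched_a[i] <- TRUE; matched_c[j] <- TRUE
        dmat[i, ] <- Inf; dmat[, j] <- Inf
        if (all(matched_a) || all(matched_c)) break
      }
    }
    # unmatched active tracks terminate; unmatched spots start new tracks
    if (n_a > 0) {
      done <- c(done, active[!matched_a])
      active <- active[matched_a]
    }
    for (j in which(!matched_c)) {
      active[[length(active) + 1L]] <- list(x = cur$x[j], y = cur$y[j],
                                            frame0 = fr, last_frame = fr)
    }
  }
  done <- c(done, active)
  done <- Filter(function(a) length(a$x) >= min_length, done)
  lapply(seq_along(done), function(i) {
    a <- done[[i]]
    trajectory(paste0("track", i), a$x, a$y, frame_interval,
               frame0 = a$frame0)
  })
}

new_msd_curve <- function(variant, lag_s, value, frame_interval) {
  structure(list(variant = variant, lag_s = lag_s, value = value,
                 frame_interval = frame_interval), class = "MSDCurve")
}

#' @export
print.MSDCurve <- function(x, ...) {
  cat(sprintf("MSDCurve (%s): %d lags up to %.2f s, max %.4g um^2\n",
              x$variant, length(x$lag_s), max(x$lag_s), max(x$value)))
  invisible(x)
}

#' @export
#' @importFrom graphics plot
plot.MSDCurve <- function(x, ...) {
  plot(x$lag_s, x$value, type = "b", xlab = "lag (s)",
       ylab = expression(MSD ~ (mu * m^2)),
       main = paste0("MSD (", x$variant, ")"), ...)
}

#' Cumulative radial-increment MSD (published convention)
#'
#' `MSD(n) = sum_{i=1..n} (d_i - d_{i-1})^2` with `d_i` the distance of
#' position `i` from the first position. The sum index starts at `i = 1`
#' (the `i = 0` term would reference an undefined position). The curve is
#' non-decreasing in the lag and invariant under rigid rotations about the
#' first point.
#'
#' @param traj a [trajectory()] with at least 2 positions
#' @return an `MSDCurve` with `variant = "paper"`
#' @export
msd_paper <- function(traj) {
  n <- length(traj$x)
  if (n < 2L) stop("trajectory needs at least 2 positions")
  d <- sqrt((traj$x - traj$x[1])^2 + (traj$y - traj$y[1])^2)
  new_msd_curve("paper", seq_len(n - 1L) * traj$frame_interval,
                cumsum(diff(d)^2), traj$frame_interval)
}

#' Conventional time-averaged MSD
#'
#' `MSD(k) = mean_t |p_{t+k} - p_t|^2` for lags `k = 1 ..
#' floor(max_lag_frac * (N - 1))` (at least 4 lags when the track allows).
#'
#' @param traj a [trajectory()]
#' @param max_lag_frac fraction of the track length used as the maximum lag
#'   (default 0.25)
#' @return an `MSDCurve` with `variant = "standard"`
#' @export
msd_standard <- function(traj, max_lag_frac = 0.25) {
  n <- length(traj$x)
  if (n < 2L) stop("trajectory needs at least 2 positions")
  k_max <- max(min(4L, n - 1L), floor(max_lag_frac * (n - 1L)))
  k_max <- min(k_max, n - 1L)
  val <- vapply(seq_len(k_max), function(k) {
    dx <- traj$x[(1 + k):n] - traj$x[1:(n - k)]
    dy <- traj$y[(1 + k):n] - traj$y[1:(n - k)]
    mean(dx^2 + dy^2)
  }, numeric(1))
  new_msd_curve("standard", seq_len(k_max) * traj$frame_interval, val,
                traj$frame_interval)
}

#' Diffusion coefficient from the initial MSD slope
#'
#' Least-squares line with free intercept through the first `n_fit_lags`
#' `(lag, MSD)` points. In `"standard"` mode `D = slope / 4` (2D diffusion;
#' the intercept absorbs localization noise). In `"paper"` mode `D` is the
#' raw slope, matching the published convention which applies no `1/4`
#' factor. Negative slopes are clipped to `D = 0`.
#'
#' @param curve an `MSDCurve`
#' @param n_fit_lags number of initial lags in the fit (default 4)
#' @return list `D` (um^2/s), `slope`, `intercept`, `r_squared`, `n_fit_lags`,
#'   `variant`
#' @export
estimate_D <- function(curve, n_fit_lags = 4L) {
  if (length(curve$lag_s) < n_fit_lags) {
    stop("curve has fewer points than n_fit_lags")
  }
  t <- curve$lag_s[seq_len(n_fit_lags)]
  v <- curve$value[seq_len(n_fit_lags)]
  fit <- lm(v ~ t)
  slope <- unname(coef(fit)[2])
  ss_tot <- sum((v - mean(v))^2)
  r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  D <- if (curve$variant == "paper") slope else slope / 4
  list(D = max(D, 0), slope = slope, intercept = unname(coef(fit)[1]),
       r_squared = r2, n_fit_lags = n_fit_lags, variant = curve$variant)
}

#' Detect an MSD confinement plateau
#'
#' The curve is anchored at the origin (`MSD(0) = 0` by definition) and the
#' initial slope is the first-lag secant `MSD(lag_1) / lag_1`, i.e. the
#' short-time slope before any confinement saturation. A plateau is declared
#' when the tail of the curve (the later half of the lags) has flattened:
#' its mean secant slope from the origin falls below `plateau_level_frac` of
#' the initial slope. Averaging the tail makes the declaration robust to the
#' lag-to-lag noise of single-track MSD estimates, where a strict
#' window-by-window slope test either misses real plateaus or fires on noise
#' dips. The plateau time is then localized as the first lag whose local
#' slope (forward 3-point window) falls below `plateau_slope_frac` of the
#' initial slope (falling back to the first tail lag).
#'
#' A flat (all-zero) curve plateaus at the first lag; a perfect line through
#' the origin has no plateau (its tail secant equals the initial slope).
#'
#' @param curve an `MSDCurve` with at least 6 lag points
#' @param plateau_slope_frac local-slope fraction used to localize the
#'   plateau time (default 0.15)
#' @param plateau_level_frac tail-secant fraction below which a plateau is
#'   declared (default 0.5: the tail sits below half the initial-slope
#'   extrapolation)
#' @return plateau lag time in seconds, or `NULL` if no plateau
#' @export
detect_plateau <- function(curve, plateau_slope_frac = 0.15,
                           plateau_level_frac = 0.5) {
  k <- length(curve$lag_s)
  if (k < 6L) stop("plateau detection needs at least 6 lag points")
  lag <- c(0, curve$lag_s)
  val <- c(0, curve$value)
  init <- val[2] / lag[2]
  eps <- 1e-12 * max(abs(val), 1e-30)
  if (abs(init) <= eps) return(curve$lag_s[1])
  i0 <- max(2L, ceiling(k / 2))  # tail = later half of the lags
  tail_secant <- mean(curve$value[i0:k]) / mean(curve$lag_s[i0:k])
  if (tail_secant >= plateau_level_frac * init) return(NULL)
  slopes <- vapply(seq_len(k - 1L), function(j) {
    (val[j + 2L] - val[j]) / (lag[j + 2L] - lag[j])
  }, numeric(1))
  # slopes[j] covers lags (j-1, j, j+1); skip the origin window (j = 1)
  j <- which(slopes[-1] < plateau_slope_frac * init)[1] + 1L
  if (is.na(j)) j <- i0 + 1L
  lag[j]
}

#' Classify particle motility
#'
#' Stationary iff `D <= d_stationary` (default 0.01 um^2/s); otherwise
#' confined iff a plateau was detected; otherwise diffusive. The published
#' class averages (diffusive 0.057, confined 0.021, stationary 0.005
#' um^2/s) fall on the expected sides of these defaults.
#'
#' @param D diffusion coefficient, um^2/s (>= 0)
#' @param plateau_time plateau lag in seconds, or `NULL`
#' @param d_stationary stationary threshold (default 0.01)
#' @return `"stationary"`, `"confined"` or `"diffusive"`
#' @export
classify_motility <- function(D, plateau_time = NULL, d_stationary = 0.01) {
  if (is.na(D) || D < 0) stop("D must be non-negative")
  if (D <= d_stationary) return("stationary")
  if (!is.null(plateau_time)) return("confined")
  "diffusive"
}

#' Analyze one trajectory end to end
#'
#' Computes both MSD variants, the diffusion coefficient in each, the
#' plateau, and the motility class. The plateau is detected on a
#' longer-lag standard MSD curve (`plateau_lag_frac` of the track) because
#' confinement only shows once the curve has had time to saturate. The
#' stationary gate of the classification uses the short-time secant estimate
#' `D_1 = MSD(lag_1) / (4 lag_1)` rather than the reported multi-lag fit:
#' the multi-lag fit of a strongly confined track is depressed by the
#' saturating curve and would leak confined tracks into the stationary
#' class, whereas the first lag is unaffected by confinement.
#'
#' @param traj a [trajectory()] with at least `min_length` frames
#' @param config a [run_config()]; uses the `spt` block
#' @return one-row data.frame: `track_id, n_frames, D_paper, D_standard,
#'   plateau_s, class`
#' @export
analyze_trajectory <- function(traj, config = run_config()) {
  p <- config$spt
  if (length(traj$x) < p$min_length) {
    stop("trajectory shorter than min_length (", p$min_length, " frames)")
  }
  mp <- msd_paper(traj)
  ms <- msd_standard(traj, p$max_lag_frac)
  n_fit <- min(p$n_fit_lags, length(ms$lag_s))
  d_paper <- estimate_D(mp, min(p$n_fit_lags, length(mp$lag_s)))$D
  d_std <- estimate_D(ms, n_fit)$D
  ms_plateau <- msd_standard(traj, max(p$plateau_lag_frac, p$max_lag_frac))
  plateau <- if (length(ms_plateau$lag_s) >= 6L) {
    detect_plateau(ms_plateau, p$plateau_slope_frac, p$plateau_level_frac)
  } else NULL
  d_short <- ms$value[1] / (4 * ms$lag_s[1])
  cls <- classify_motility(d_short, plateau, p$d_stationary)
  data.frame(track_id = as.character(traj$track_id),
             n_frames = length(traj$x),
             D_paper = d_paper, D_standard = d_std,
             plateau_s = if (is.null(plateau)) NA_real_ else plateau,
             class = cls, stringsAsFactors = FALSE)
}

#' Analyze a list of trajectories
#'
#' @param trajectories list of [trajectory()] objects
#' @param config a [run_config()]
#' @return data.frame, one row per track (see [analyze_trajectory()]),
#'   with an `n_segments` column from [segment_states()] where the track is
#'   long enough (otherwise `NA`)
#' @export
analyze_tracks <- function(trajectories, config = run_config()) {
  rows <- lapply(trajectories, function(tr) {
    row <- analyze_trajectory(tr, config)
    row$n_segments <- if (length(tr$x) >= 2 * config$spt$window) {
      nrow(segment_states(tr, config)$segments)
    } else NA_integer_
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Segment a trajectory into motility states
#'
#' A rolling window of `window` frames (stride `step`) is analyzed with the
#' standard MSD; each window's diffusion coefficient is classified with the
#' [classify_motility()] thresholds (plateau detection requires more lags
#' than a short window offers, so window classes are stationary/diffusive).
#' The window class is assigned to the window's centre frame, adjacent
#' same-class windows are merged, and segments shorter than `window` frames
#' are absorbed into the preceding segment. Change points sit at the class
#' switches.
#'
#' @param traj a [trajectory()] with at least `2 * window` frames
#' @param config a [run_config()]; uses `spt$window`, `spt$step`,
#'   `spt$d_stationary`, `spt$plateau_slope_frac`
#' @return list with `segments` (data.frame `class, start_s, end_s,
#'   mean_D`) and `change_points_s` (numeric, possibly empty)
#' @export
segment_states <- function(traj, config = run_config()) {
  p <- config$spt
  n <- length(traj$x)
  w <- p$window
  if (n < 2L * w) stop("trajectory too short for state segmentation (needs ",
                       2L * w, " frames)")
  dt <- traj$frame_interval
  starts <- seq(1L, n - w + 1L, by = p$step)
  centers <- starts + (w - 1) / 2
  d_hat <- numeric(length(starts))
  cls <- character(length(starts))
  for (i in seq_along(starts)) {
    sub <- trajectory(traj$track_id, traj$x[starts[i]:(starts[i] + w - 1L)],
                      traj$y[starts[i]:(starts[i] + w - 1L)], dt)
    ms <- msd_standard(sub, max_lag_frac = 0.5)
    est <- estimate_D(ms, min(p$n_fit_lags, length(ms$lag_s)))
    d_hat[i] <- est$D
    plateau <- if (length(ms$lag_s) >= 6L) {
      detect_plateau(ms, p$plateau_slope_frac, p$plateau_level_frac)
    } else NULL
    cls[i] <- classify_motility(est$D, plateau, p$d_stationary)
  }
  # merge adjacent same-class windows
  runs <- rle(cls)
  seg_end_idx <- cumsum(runs$lengths)
  seg_start_idx <- c(1L, head(seg_end_idx, -1L) + 1L)
  segments <- data.frame(class = runs$values,
                         start_i = seg_start_idx, end_i = seg_end_idx,
                         stringsAsFactors = FALSE)
  # absorb segments shorter than the window into the previous segment
  min_windows <- max(1L, ceiling(w / p$step))
  i <- 2L
  while (i <= nrow(segments)) {
    if (segments$end_i[i] - segments$start_i[i] + 1L < min_windows) {
      segments$end_i[i - 1L] <- segments$end_i[i]
      segments <- segments[-i, , drop = FALSE]
      # re-merge if neighbours now share a class
      if (i <= nrow(segments) &&
          segments$class[i - 1L] == segments$class[i]) {
        segments$end_i[i - 1L] <- segments$end_i[i]
        segments <- segments[-i, , drop = FALSE]
      }
    } else i <- i + 1L
  }
  seg_df <- data.frame(
    class = segments$class,
    start_s = (centers[segments$start_i] - 1) * dt,
    end_s = (centers[segments$end_i] - 1) * dt,
    mean_D = vapply(seq_len(nrow(segments)), function(j) {
      mean(d_hat[segments$start_i[j]:segments$end_i[j]])
    }, numeric(1)),
    stringsAsFactors = FALSE)
  seg_df$start_s[1] <- 0
  seg_df$end_s[nrow(seg_df)] <- (n - 1) * dt
  cps <- if (nrow(seg_df) > 1) seg_df$start_s[-1] else numeric(0)
  list(segments = seg_df, change_points_s = cps)
}
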