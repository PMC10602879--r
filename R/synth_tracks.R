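# Synthetic single-particle trajectories. Defaults follow live imaging of
# single RNA particles streamed on 2D frames at 200-600 ms intervals for up
# to 30 s, with diffusive motion around D ~ 0.05 um^2/s.

#' Particle motion model
#'
#' @param kind one of `"brownian"`, `"confined"`, `"stationary"`,
#'   `"switching"`
#' @param D diffusion coefficient, um^2/s (brownian/confined)
#' @param R confinement radius, um (confined: reflecting circular boundary
#'   about the segment start point, giving a standard-MSD plateau near `R^2`)
#' @param sigma_loc localization-noise standard deviation, um, added
#'   independently to every reported position
#' @param segments for `"switching"` only: list of sub-models with durations,
#'   e.g. `list(list(kind = "brownian", D = 0.05, duration = 15),
#'   list(kind = "stationary", duration = 15))`; durations (s) must sum to
#'   the trajectory duration
#' @return a list of class `MotionModel`
#' @export
motion_model <- function(kind = c("brownian", "confined", "stationary",
                                  "switching"),
                         D = 0.05, R = 0.5, sigma_loc = 0.02,
                         segments = NULL) {
  kind <- match.arg(kind)
  stopifnot(D >= 0, R > 0, sigma_loc >= 0)
  if (kind == "switching") {
    if (is.null(segments) || !length(segments)) {
      stop("switching model requires segments")
    }
    for (s in segments) {
      stopifnot(s$kind %in% c("brownian", "confined", "stationary"),
                s$duration > 0)
    }
  }
  structure(list(kind = kind, D = D, R = R, sigma_loc = sigma_loc,
                 segments = segments), class = "MotionModel")
}

#' Simulate one 2D trajectory
#'
#' Brownian steps have independent per-axis increments of variance
#' `2 * D * dt`; confined motion reflects each proposed position radially at
#' a circle of radius `R` about the segment start; stationary particles stay
#' put. Localization noise is added to every position afterwards. Switching
#' models concatenate their segments continuously.
#'
#' @param model a [motion_model()]
#' @param frame_interval frame interval in seconds (typically 0.2-0.6 s)
#' @param n_frames number of frames (>= 2)
#' @param seed optional RNG seed
#' @param track_id id for the resulting [trajectory()]
#' @return a [trajectory()]
#' @export
simulate_trajectory <- function(model, frame_interval = 0.2, n_frames = 150L,
                                seed = NULL, track_id = "sim") {
  stopifnot(inherits(model, "MotionModel"), n_frames >= 2,
            frame_interval > 0)
  dt <- frame_interval
  duration <- (n_frames - 1) * dt
  segs <- if (model$kind == "switching") model$segments else
    list(list(kind = model$kind, D = model$D, R = model$R,
              duration = duration))
  tot <- sum(vapply(segs, `[[`, numeric(1), "duration"))
  if (model$kind == "switching" && abs(tot - duration) > dt / 2) {
    stop("switching segment durations (", tot, " s) must sum to the ",
         "trajectory duration (", duration, " s)")
  }
  with_seed(seed, {
    x <- numeric(n_frames); y <- numeric(n_frames)
    seg_end <- cumsum(vapply(segs, `[[`, numeric(1), "duration"))
    cur_seg <- 1L
    anchor <- c(0, 0)
    for (i in seq_len(n_frames - 1L)) {
      t_next <- i * dt
      while (cur_seg < length(segs) && t_next > seg_end[cur_seg] + 1e-9) {
        cur_seg <- cur_seg + 1L
        anchor <- c(x[i], y[i])  # confinement re-anchors at the switch
      }
      s <- segs[[cur_seg]]
      D <- s$D %||% model$D
      R <- s$R %||% model$R
      if (s$kind == "stationary") {
        x[i + 1] <- x[i]; y[i + 1] <- y[i]
      } else {
        step <- rnorm(2, sd = sqrt(2 * D * dt))
        p <- c(x[i] + step[1], y[i] + step[2])
        if (s$kind == "confined") {
          # radial reflection at the circle; repeat for rare very large steps
          for (rep in 1:100) {
            v <- p - anchor
            d <- sqrt(sum(v^2))
            if (d <= R) break
            p <- anchor + v * (2 * R - d) / d
          }
        }
        x[i + 1] <- p[1]; y[i + 1] <- p[2]
      }
    }
    if (model$sigma_loc > 0) {
      x <- x + rnorm(n_frames, sd = model$sigma_loc)
      y <- y + rnorm(n_frames, sd = model$sigma_loc)
    }
    trajectory(track_id, x, y, dt)
  })
}

#' Simulate an ensemble of trajectories
#'
#' @param n number of tracks
#' @param model a [motion_model()] (applied to every track)
#' @param frame_interval frame interval in seconds
#' @param n_frames frames per track
#' @param seed RNG seed for the ensemble
#' @return list of [trajectory()] objects with ids `"sim1"`, `"sim2"`, ...
#' @export
simulate_tracks <- function(n, model, frame_interval = 0.2, n_frames = 150L,
                            seed = 1L) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      simulate_trajectory(model, frame_interval, n_frames, seed = NULL,
                          track_id = paste0("sim", i))
    })
  })
}
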