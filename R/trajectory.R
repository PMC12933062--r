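#' Simulate an open-field foraging trajectory
#'
#' Generates a smoothed random walk with Ornstein-Uhlenbeck velocity dynamics
#' and specular reflection at the arena walls. With the defaults (15 Hz
#' sampling, velocity correlation time 2 s, mean running speed 8 cm/s) a
#' 35-minute session covers essentially all 2.5 cm spatial bins of an 80 cm
#' arena, emulating free foraging.
#'
#' @param arena An [arena_spec()].
#' @param duration Session duration in seconds. Must be positive.
#' @param mean_speed Target mean running speed in cm/s. Must be positive.
#' @param dt Sampling interval in seconds (default 1/15, i.e. 15 Hz frames).
#' @param tau Velocity correlation time constant in seconds.
#' @param seed Optional integer seed for reproducibility.
#' @return A `data.frame` of class `trajectory` with columns `t`, `x`, `y`,
#'   `speed` and attributes `arena` and `dt`.
#' @export
simulate_trajectory <- function(arena = arena_spec(), duration, mean_speed = 8,
                                dt = 1 / 15, tau = 2, seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) stop("'duration' must be positive")
  if (!is.numeric(mean_speed) || mean_speed <= 0) stop("'mean_speed' must be positive")
  side <- arena$side_length
  n <- max(1L, as.integer(ceiling(duration / dt)))
  with_seed_if(seed, {
    # per-axis stationary sd of an OU velocity giving E|v| = mean_speed
    s <- mean_speed / sqrt(pi / 2)
    a <- exp(-dt / tau)
    b <- s * sqrt(1 - a^2)
    ex <- stats::rnorm(n); ey <- stats::rnorm(n)
    vx <- numeric(n); vy <- numeric(n); x <- numeric(n); y <- numeric(n)
    vx[1] <- s * ex[1]; vy[1] <- s * ey[1]
    x[1] <- side / 2; y[1] <- side / 2
    if (n > 1L) {
      for (i in 2:n) {
        vx[i] <- a * vx[i - 1] + b * ex[i]
        vy[i] <- a * vy[i - 1] + b * ey[i]
        x[i] <- x[i - 1] + vx[i] * dt
        y[i] <- y[i - 1] + vy[i] * dt
        if (x[i] < 0) { x[i] <- -x[i]; vx[i] <- -vx[i] }
        if (x[i] > side) { x[i] <- 2 * side - x[i]; vx[i] <- -vx[i] }
        if (y[i] < 0) { y[i] <- -y[i]; vy[i] <- -vy[i] }
        if (y[i] > side) { y[i] <- 2 * side - y[i]; vy[i] <- -vy[i] }
      }
    }
    out <- data.frame(t = (seq_len(n) - 1) * dt, x = x, y = y,
                      speed = sqrt(vx^2 + vy^2))
    attr(out, "arena") <- arena
    attr(out, "dt") <- dt
    class(out) <- c("trajectory", "data.frame")
    out
  })
}

#' Speed-filter a trajectory (and optionally an event train)
#'
#' Removes samples whose running speed, computed from smoothed positions, is
#' below `v_min`. Events are filtered by mapping each event time to its frame
#' and dropping events whose frame was removed. Both occupancy and event
#' accumulation downstream therefore exclude immobility.
#'
#' @param traj A [simulate_trajectory()] trajectory (columns `t,x,y`).
#' @param events Optional `data.frame` with columns `t` and `amplitude`.
#' @param v_min Speed threshold in cm/s; samples with speed < `v_min` are
#'   dropped. `v_min = 0` is the identity.
#' @param smooth_window Width in seconds of the boxcar used to smooth
#'   positions before differentiating to speed.
#' @return A list with elements `traj` (filtered trajectory, with attribute
#'   `keep`, the logical frame mask) and `events` (filtered events or `NULL`).
#' @export
speed_filter <- function(traj, events = NULL, v_min = 2, smooth_window = 1 / 3) {
  dt <- attr(traj, "dt")
  if (is.null(dt)) dt <- stats::median(diff(traj$t))
  spd <- smoothed_speed(traj, dt, smooth_window)
  keep <- spd >= v_min
  if (!any(keep)) stop("speed filter removed every sample; v_min too high")
  ft <- traj[keep, , drop = FALSE]
  attr(ft, "arena") <- attr(traj, "arena")
  attr(ft, "dt") <- dt
  attr(ft, "keep") <- keep
  class(ft) <- class(traj)
  fe <- NULL
  if (!is.null(events)) {
    idx <- event_frames(events$t, traj$t)
    fe <- events[keep[idx], , drop = FALSE]
  }
  list(traj = ft, events = fe)
}

# speed from boxcar-smoothed positions; endpoints handled by shrinking window
smoothed_speed <- function(traj, dt, smooth_window) {
  w <- max(1L, as.integer(round(smooth_window / dt)))
  if (w %% 2L == 0L) w <- w + 1L
  xs <- boxcar(traj$x, w); ys <- boxcar(traj$y, w)
  n <- length(xs)
  if (n == 1L) return(traj$speed %||% 0)
  dx <- c(diff(xs), 0); dy <- c(diff(ys), 0)
  dx[n] <- dx[n - 1]; dy[n] <- dy[n - 1]
  sqrt(dx^2 + dy^2) / dt
}

boxcar <- function(x, w) {
  if (w <= 1L || length(x) < w) return(x)
  k <- rep(1 / w, w)
  sm <- stats::filter(x, k, sides = 2)
  sm[is.na(sm)] <- x[is.na(sm)]
  as.numeric(sm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# frame index (into traj times) for each event time
event_frames <- function(ev_t, traj_t) {
  idx <- findInterval(ev_t, traj_t)
  pmin(pmax(idx, 1L), length(traj_t))
}
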