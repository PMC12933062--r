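#' Calcium-kernel configuration for surrogate dF/F traces
#'
#' Single-exponential kernel on a GCaMP6s-like timescale. Event amplitudes are
#' scaled by `gain` and convolved with `exp(-t / tau)`; white noise of
#' standard deviation `noise_sd` is added.
#'
#' @param tau Decay time constant in seconds.
#' @param gain dF/F amplitude per unit deconvolved event amplitude.
#' @param noise_sd Standard deviation of the additive white noise.
#' @return A list of class `calcium_kernel`.
#' @export
calcium_kernel <- function(tau = 1.5, gain = 0.6, noise_sd = 0.13) {
  structure(list(tau = tau, gain = gain, noise_sd = noise_sd),
            class = "calcium_kernel")
}

# position-dependent event intensity (events/s) for one cell at trajectory
# samples; includes place fields, optional object bump, and uniform noise
cell_intensity <- function(pop, i, x, y, noise_rate, object_xy = NULL,
                           object_sigma = 5) {
  lam <- rep(noise_rate, length(x))
  if (pop$active[i]) {
    f <- pop$fields[[i]]
    s2 <- 2 * pop$sigma[i]^2
    for (k in seq_len(nrow(f))) {
      lam <- lam + pop$peak_rate[i] *
        exp(-((x - f[k, 1])^2 + (y - f[k, 2])^2) / s2)
    }
  }
  if (!is.null(object_xy) && !is.null(pop$object_vector) &&
      !is.na(pop$object_vector[i, 1])) {
    v <- pop$object_vector[i, ]
    cx <- object_xy[1] + v[1] * cos(v[2] * pi / 180)
    cy <- object_xy[2] + v[1] * sin(v[2] * pi / 180)
    # object response is a clear, dominant field for vector-tuned cells
    lam <- lam + 1.5 * max(pop$peak_rate[i], 0.8) *
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * object_sigma^2))
  }
  lam
}

#' Generate deconvolved events and a surrogate dF/F trace for one cell
#'
#' Events are drawn from an inhomogeneous Poisson process whose intensity is
#' the cell's Gaussian place-field bump(s) evaluated along the trajectory,
#' plus a uniform noise rate (plus the object bump for object sessions).
#' Event amplitudes are gamma-distributed with mean 1. The dF/F trace is the
#' amplitude-weighted impulse train convolved with the exponential calcium
#' kernel plus white noise.
#'
#' @param pop A [place_field_population()].
#' @param i Cell index within `pop`.
#' @param traj Trajectory the events are driven by.
#' @param noise_rate Position-independent event rate, events/s.
#' @param kernel A [calcium_kernel()].
#' @param object_xy Optional object position (cm) for object sessions.
#' @param seed Optional integer seed.
#' @return A list of class `cell_recording` with elements `cell_id`, `events`
#'   (`data.frame` with `t`, `amplitude`), `dff` (numeric, one value per
#'   frame), `centroid` (anatomical, um).
#' @export
generate_events <- function(pop, i, traj, noise_rate = 0.01,
                            kernel = calcium_kernel(), object_xy = NULL,
                            seed = NULL) {
  if (nrow(traj) == 0L) stop("trajectory is empty")
  dt <- attr(traj, "dt") %||% stats::median(diff(traj$t))
  with_seed_if(seed, {
    lam <- cell_intensity(pop, i, traj$x, traj$y, noise_rate, object_xy)
    counts <- stats::rpois(length(lam), lam * dt)
    idx <- rep.int(seq_along(counts), counts)
    n_ev <- length(idx)
    ev <- data.frame(
      t = traj$t[idx] + stats::runif(n_ev, 0, dt),
      amplitude = stats::rgamma(n_ev, shape = 2, scale = 0.5)
    )
    ev <- ev[order(ev$t), , drop = FALSE]
    rownames(ev) <- NULL
    dff <- dff_from_events(ev, traj$t, dt, kernel)
    structure(list(cell_id = pop$cell_id[i], events = ev, dff = dff,
                   centroid = pop$centroids[i, ]),
              class = "cell_recording")
  })
}

# exponential-kernel convolution of the amplitude impulse train + white noise
dff_from_events <- function(events, t_frames, dt, kernel) {
  n <- length(t_frames)
  imp <- numeric(n)
  if (nrow(events) > 0L) {
    fr <- event_frames(events$t, t_frames)
    imp_sum <- rowsum(events$amplitude * kernel$gain, fr)
    imp[as.integer(rownames(imp_sum))] <- imp_sum
  }
  clean <- as.numeric(stats::filter(imp, exp(-dt / kernel$tau),
                                    method = "recursive"))
  clean + stats::rnorm(n, 0, kernel$noise_sd)
}

#' Generate a full synthetic session
#'
#' Simulates (or reuses) a trajectory and generates events and dF/F for every
#' cell of the population. Per-cell seeds are derived from `seed` so the
#' session is reproducible end-to-end.
#'
#' @param pop A [place_field_population()] (optionally tagged with an object
#'   position by [generate_object_session()]).
#' @param duration Session duration in seconds (ignored when `traj` given).
#' @param traj Optional pre-simulated trajectory.
#' @param noise_rate,kernel Passed to [generate_events()].
#' @param label Environment label, e.g. `"A"`, `"B"`, `"A2"`, `"object"`.
#' @param seed Optional integer master seed for the session.
#' @return A list of class `session`: `traj`, `cells` (list of
#'   `cell_recording`), `label`, `object_xy` (or `NULL`), plus the population
#'   geometry as attributes.
#' @export
generate_session <- function(pop, duration = 2100, traj = NULL,
                             noise_rate = 0.01, kernel = calcium_kernel(),
                             label = "A", seed = NULL) {
  arena <- attr(pop, "arena")
  object_xy <- attr(pop, "object_xy")
  with_seed_if(seed, {
    if (is.null(traj))
      traj <- simulate_trajectory(arena, duration)
    cells <- lapply(seq_along(pop$cell_id), function(i)
      generate_events(pop, i, traj, noise_rate, kernel, object_xy))
    structure(list(traj = traj, cells = cells, label = label,
                   object_xy = object_xy),
              arena = arena, fov = attr(pop, "fov"),
              class = "session")
  })
}

#' @export
print.session <- function(x, ...) {
  cat(sprintf("<session %s> %d cells, %.0f s%s\n", x$label,
              length(x$cells), max(x$traj$t),
              if (!is.null(x$object_xy))
                sprintf(", object at (%g, %g) cm", x$object_xy[1],
                        x$object_xy[2]) else ""))
  invisible(x)
}

#' Noiseless expected tuning map of a synthetic cell
#'
#' Evaluates the generative Gaussian field model at spatial-bin centres,
#' giving the tuning map a cell would converge to with unlimited data. Used
#' for large calibration suites where simulating event trains for every cell
#' is unnecessary.
#'
#' @param pop A population; `i` the cell index.
#' @param arena Arena spec (defaults to the population's).
#' @param bin_size Spatial bin side, cm.
#' @param noise_rate Uniform event rate added everywhere.
#' @return A matrix (x-bins x y-bins) of expected event rate.
#' @export
expected_rate_map <- function(pop, i, arena = NULL, bin_size = 2.5,
                              noise_rate = 0.01) {
  arena <- arena %||% attr(pop, "arena")
  ctr <- bin_centers(arena$side_length, bin_size)
  g <- expand.grid(x = ctr, y = ctr)
  matrix(cell_intensity(pop, i, g$x, g$y, noise_rate), length(ctr), length(ctr))
}

bin_centers <- function(side, bin_size) {
  nb <- as.integer(ceiling(side / bin_size))
  (seq_len(nb) - 0.5) * bin_size
}
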