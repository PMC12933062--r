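#' Circularly shift event times (shuffle for spatial-information calibration)
#'
#' Each shuffle shifts all event times by one uniform random offset in
#' `[min_shift, duration - min_shift]`, wrapping around the session end, so
#' inter-event structure is preserved while the position-event relation is
#' destroyed.
#'
#' @param events `data.frame` with column `t` (and any others, preserved).
#' @param duration Session duration in seconds.
#' @param n_shuffles Number of shuffles.
#' @param min_shift Minimum shift in seconds; `duration` must exceed
#'   `2 * min_shift`.
#' @param seed Optional integer seed.
#' @return A list of `n_shuffles` numeric vectors of shifted event times.
#' @export
shuffle_events <- function(events, duration, n_shuffles = 1000,
                           min_shift = 30, seed = NULL) {
  if (duration <= 2 * min_shift)
    stop("session too short for circular shuffling (duration <= 2 * min_shift)")
  with_seed_if(seed, {
    shifts <- stats::runif(n_shuffles, min_shift, duration - min_shift)
    lapply(shifts, function(s) (events$t + s) %% duration)
  })
}

# shared binning machinery for one session: speed filter, occupancy, visited
# mask, smoothing operator, and per-original-frame bin index (NA if filtered)
map_machinery <- function(traj, arena = NULL, bin_size = 2.5, sigma = 2.5,
                          v_min = 2) {
  arena <- arena %||% attr(traj, "arena")
  dt <- attr(traj, "dt") %||% stats::median(diff(traj$t))
  sf <- speed_filter(traj, v_min = v_min)
  keep <- attr(sf$traj, "keep")
  nb <- as.integer(ceiling(arena$side_length / bin_size))
  bi_all <- grid_bin_index(traj$x, traj$y, bin_size, nb)
  bi_kept <- ifelse(keep, bi_all, NA_integer_)
  occ <- matrix(tabulate(bi_all[keep], nb * nb) * dt, nb, nb)
  list(arena = arena, dt = dt, nb = nb, keep = keep, bi = bi_kept,
       occ = occ, visited = occ > 0, S = smoothing_operator(nb, sigma),
       n_frames = nrow(traj), t_frames = traj$t, bin_size = bin_size,
       duration = nrow(traj) * dt)
}

# smoothed rate map (matrix, NA unvisited) from event bin indices + amplitudes
rate_map_from_bins <- function(mm, ev_bins, ev_amp, smooth = TRUE) {
  amp <- numeric(mm$nb^2)
  ok <- !is.na(ev_bins)
  if (any(ok)) {
    s <- rowsum(ev_amp[ok], ev_bins[ok])
    amp[as.integer(rownames(s))] <- s
  }
  raw <- matrix(NA_real_, mm$nb, mm$nb)
  raw[mm$visited] <- amp[as.vector(mm$visited)] / mm$occ[mm$visited]
  if (!smooth) return(raw)
  v <- mm$visited * 1
  rv <- raw; rv[!mm$visited] <- 0
  num <- mm$S %*% rv %*% t(mm$S)
  den <- mm$S %*% v %*% t(mm$S)
  out <- matrix(NA_real_, mm$nb, mm$nb)
  okb <- mm$visited & den > 0
  out[okb] <- num[okb] / den[okb]
  out
}

si_from_rate <- function(rate, occ, visited) {
  v <- visited & !is.na(rate)
  p <- occ[v]; p <- p / sum(p)
  lam <- rate[v]
  lbar <- sum(p * lam)
  if (lbar <= 0) return(NA_real_)
  pos <- lam > 0
  sum(p[pos] * (lam[pos] / lbar) * log2(lam[pos] / lbar))
}

#' Split-half stability of a cell's spatial tuning
#'
#' Tuning maps are computed on interleaved 1-minute blocks (odd vs even) and
#' correlated over jointly visited bins. Returns `NA` when either half lacks
#' coverage or variance.
#'
#' @param traj Trajectory (unfiltered; speed filtering applied internally).
#' @param events Event `data.frame` (`t`, `amplitude`).
#' @param block_s Block length in seconds.
#' @param v_min Speed threshold, cm/s.
#' @param ... Passed to [compute_tuning_map()].
#' @return Pearson r between half-session maps, or `NA`.
#' @export
split_half_stability <- function(traj, events, block_s = 60, v_min = 2, ...) {
  blk <- floor(traj$t / block_s) %% 2
  ev_fr <- event_frames(events$t, traj$t)
  r <- tryCatch({
    halves <- lapply(0:1, function(h) {
      tr_h <- traj[blk == h, , drop = FALSE]
      attr(tr_h, "arena") <- attr(traj, "arena")
      attr(tr_h, "dt") <- attr(traj, "dt")
      class(tr_h) <- class(traj)
      ev_h <- events[blk[ev_fr] == h, , drop = FALSE]
      sf <- speed_filter(tr_h, ev_h, v_min = v_min)
      compute_tuning_map(sf$traj, sf$events, ...)
    })
    map_correlation(halves[[1]], halves[[2]])
  }, error = function(e) NA_real_)
  r
}

#' Classify place cells in a session
#'
#' A cell is a place cell iff it passes the inclusion filters (SNR strictly
#' above `snr_min`, at least `min_events` events), its spatial information
#' exceeds the `si_percentile` quantile of `n_shuffles` circular event-time
#' shuffles, its split-half stability exceeds `r_min`, and at least one place
#' field is detected in its smoothed tuning map.
#'
#' @param session A session (see [generate_session()]).
#' @param n_shuffles Number of circular shuffles for the SI criterion.
#' @param si_percentile Shuffle quantile the observed SI must exceed.
#' @param r_min Split-half stability threshold.
#' @param snr_min,min_events Inclusion filters (see
#'   [apply_inclusion_filters()]).
#' @param v_min Speed threshold, cm/s.
#' @param bin_size,sigma Map parameters (sigma in bins).
#' @param min_shift Minimum circular shift, seconds.
#' @param seed Optional integer seed (governs the shuffles).
#' @param ... Passed to [detect_fields()].
#' @return A `data.frame` with one row per cell: `cell_id`, `snr`,
#'   `n_events`, `included`, `si`, `si_thresh`, `stability`, `n_fields`,
#'   `main_x`, `main_y` (main-field centroid, cm), `is_place_cell`.
#' @export
classify_place_cells <- function(session, n_shuffles = 1000,
                                 si_percentile = 0.95, r_min = 0.3,
                                 snr_min = 3, min_events = 40, v_min = 2,
                                 bin_size = 2.5, sigma = 2.5, min_shift = 30,
                                 seed = NULL, ...) {
  traj <- session$traj
  mm <- map_machinery(traj, bin_size = bin_size, sigma = sigma, v_min = v_min)
  qc <- session_qc(session, snr_min = snr_min, min_events = min_events)
  with_seed_if(seed, {
    rows <- lapply(seq_along(session$cells), function(ci) {
      cr <- session$cells[[ci]]
      out <- data.frame(cell_id = cr$cell_id, snr = qc$snr[ci],
                        n_events = qc$n_events[ci], included = qc$included[ci],
                        si = NA_real_, si_thresh = NA_real_,
                        stability = NA_real_, n_fields = 0L,
                        main_x = NA_real_, main_y = NA_real_,
                        is_place_cell = FALSE)
      if (!out$included) return(out)
      ev <- cr$events
      fr <- event_frames(ev$t, mm$t_frames)
      rate <- rate_map_from_bins(mm, mm$bi[fr], ev$amplitude)
      out$si <- si_from_rate(rate, mm$occ, mm$visited)
      # circular shuffles in frame units (uniform dt)
      min_fr <- as.integer(round(min_shift / mm$dt))
      shifts <- sample(seq(min_fr, mm$n_frames - min_fr), n_shuffles,
                       replace = TRUE)
      si_null <- vapply(shifts, function(s) {
        fr_s <- ((fr - 1L + s) %% mm$n_frames) + 1L
        si_from_rate(rate_map_from_bins(mm, mm$bi[fr_s], ev$amplitude),
                     mm$occ, mm$visited)
      }, numeric(1))
      out$si_thresh <- stats::quantile(si_null, si_percentile, names = FALSE,
                                       na.rm = TRUE)
      out$stability <- split_half_stability(traj, ev, v_min = v_min,
                                            bin_size = bin_size, sigma = sigma)
      tm <- structure(list(rate = rate, occupancy = mm$occ,
                           visited = mm$visited, bin_size = bin_size,
                           bin_centers = bin_centers(mm$arena$side_length,
                                                     bin_size),
                           arena = mm$arena),
                      class = "tuning_map")
      flds <- detect_fields(tm, ...)
      out$n_fields <- length(flds)
      if (out$n_fields > 0) {
        out$main_x <- flds[[1]]$centroid[1]
        out$main_y <- flds[[1]]$centroid[2]
      }
      out$is_place_cell <- isTRUE(out$si > out$si_thresh) &&
        isTRUE(out$stability > r_min) && out$n_fields >= 1L
      out
    })
    do.call(rbind, rows)
  })
}

#' Cross-environment activity status
#'
#' A cell is "stable in both" environments iff it is a classified place cell
#' in both classification tables (matched by `cell_id`).
#'
#' @param class_a,class_b Tables from [classify_place_cells()].
#' @return Logical vector along `class_a$cell_id`.
#' @export
stable_in_both <- function(class_a, class_b) {
  idx <- match(class_a$cell_id, class_b$cell_id)
  class_a$is_place_cell & !is.na(idx) & class_b$is_place_cell[idx]
}
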