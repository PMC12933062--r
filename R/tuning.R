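#' Compute a spatial tuning map
#'
#' Sums deconvolved event amplitudes within 2.5 cm spatial bins, divides by
#' the time spent in each bin, and smooths with a 2D Gaussian kernel under
#' the visited-bin mask (normalized convolution with reflecting boundaries,
#' so unvisited bins neither receive rate nor dilute their neighbours).
#' Inputs are expected to be speed-filtered (see [speed_filter()]).
#'
#' @param traj Trajectory (speed-filtered).
#' @param events `data.frame` with `t`, `amplitude` (speed-filtered).
#' @param arena Arena spec (defaults to the trajectory's).
#' @param bin_size Spatial bin side in cm.
#' @param sigma Gaussian smoothing width. Interpreted in bin units by
#'   default (`sigma_units = "bins"`, i.e. 2.5 bins = 6.25 cm); set
#'   `sigma_units = "cm"` to interpret it in centimetres.
#' @param sigma_units `"bins"` or `"cm"`.
#' @param smooth Apply smoothing (`TRUE`) or leave the raw rate map.
#' @return Object of class `tuning_map`: matrices `rate` (smoothed),
#'   `rate_raw`, `occupancy` (s), logical `visited`, plus `bin_size`,
#'   `bin_centers`, `sigma_bins`, `arena`. Rate is `NA` on unvisited bins.
#' @export
compute_tuning_map <- function(traj, events, arena = NULL, bin_size = 2.5,
                               sigma = 2.5, sigma_units = c("bins", "cm"),
                               smooth = TRUE) {
  arena <- arena %||% attr(traj, "arena")
  if (is.null(arena)) stop("arena spec required")
  sigma_units <- match.arg(sigma_units)
  sigma_bins <- if (sigma_units == "cm") sigma / bin_size else sigma
  dt <- attr(traj, "dt") %||% stats::median(diff(traj$t))
  nb <- as.integer(ceiling(arena$side_length / bin_size))
  bi <- grid_bin_index(traj$x, traj$y, bin_size, nb)
  occ <- numeric(nb * nb)
  tb <- tabulate(bi, nb * nb)
  occ <- tb * dt
  if (sum(occ) == 0) stop("zero total occupancy")
  amp <- numeric(nb * nb)
  if (nrow(events) > 0L) {
    fr <- event_frames(events$t, traj$t)
    s <- rowsum(events$amplitude, bi[fr])
    amp[as.integer(rownames(s))] <- s
  }
  occ_m <- matrix(occ, nb, nb)
  visited <- occ_m > 0
  raw <- matrix(NA_real_, nb, nb)
  raw[visited] <- amp[as.vector(visited)] / occ_m[visited]
  rate <- if (smooth) smooth_masked(raw, visited, sigma_bins) else raw
  structure(list(rate = rate, rate_raw = raw, occupancy = occ_m,
                 visited = visited, bin_size = bin_size,
                 bin_centers = bin_centers(arena$side_length, bin_size),
                 sigma_bins = sigma_bins, arena = arena),
            class = "tuning_map")
}

#' @export
print.tuning_map <- function(x, ...) {
  cat(sprintf("<tuning_map> %d x %d bins of %g cm, peak %.3g events/s, %d unvisited\n",
              nrow(x$rate), ncol(x$rate), x$bin_size,
              max(x$rate, na.rm = TRUE), sum(!x$visited)))
  invisible(x)
}

# linear bin index (x-bin fastest) on an nb x nb grid
grid_bin_index <- function(x, y, bin_size, nb) {
  ix <- pmin(pmax(floor(x / bin_size), 0), nb - 1)
  iy <- pmin(pmax(floor(y / bin_size), 0), nb - 1)
  as.integer(ix + nb * iy + 1)
}

# 1D Gaussian smoothing operator with reflecting boundaries; symmetric and
# doubly stochastic, so constants and total mass are preserved exactly
smoothing_operator <- function(n, sigma_bins, circular = FALSE) {
  r <- max(1L, as.integer(ceiling(3 * sigma_bins)))
  w <- stats::dnorm(-r:r, sd = sigma_bins)
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- i + (-r:r)
    if (circular) {
      src <- ((src - 1) %% n) + 1
    } else {
      src <- ifelse(src < 1, 1 - src, src)            # reflect low edge
      src <- ifelse(src > n, 2 * n + 1 - src, src)    # reflect high edge
      src <- pmin(pmax(src, 1L), n)
    }
    for (k in seq_along(src)) S[i, src[k]] <- S[i, src[k]] + w[k]
  }
  S
}

# normalized (mask-aware) separable Gaussian smoothing of a 2D map
smooth_masked <- function(rate, visited, sigma_bins, circular_cols = FALSE) {
  if (sigma_bins <= 0) return(rate)
  Sr <- smoothing_operator(nrow(rate), sigma_bins)
  Sc <- smoothing_operator(ncol(rate), sigma_bins, circular = circular_cols)
  v <- visited * 1
  rv <- rate
  rv[!visited] <- 0
  num <- Sr %*% rv %*% t(Sc)
  den <- Sr %*% v %*% t(Sc)
  out <- matrix(NA_real_, nrow(rate), ncol(rate))
  ok <- visited & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Pearson correlation between two tuning maps
#'
#' Computed over bins visited in both maps only. Returns `NA` when either map
#' has zero variance over the common mask; errors when the visited masks are
#' disjoint.
#'
#' @param map_a,map_b `tuning_map` objects (or plain matrices, with
#'   `NA` = unvisited).
#' @return Pearson r (scalar), or `NA` when undefined.
#' @export
map_correlation <- function(map_a, map_b) {
  a <- if (inherits(map_a, "tuning_map")) map_a$rate else map_a
  b <- if (inherits(map_b, "tuning_map")) map_b$rate else map_b
  if (!all(dim(a) == dim(b))) stop("maps must share grid geometry")
  m <- !is.na(a) & !is.na(b)
  if (!any(m)) stop("visited masks are disjoint")
  av <- a[m]; bv <- b[m]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

#' Rate-weighted centre of mass of a tuning map
#'
#' @param map A `tuning_map`.
#' @return `c(x, y)` in cm.
#' @export
map_com <- function(map) {
  r <- map$rate
  r[is.na(r)] <- 0
  tot <- sum(r)
  if (tot == 0) return(c(NA_real_, NA_real_))
  ctr <- map$bin_centers
  c(sum(rowSums(r) * ctr), sum(colSums(r) * ctr)) / tot
}

#' Detect place fields in a smoothed tuning map
#'
#' Fields are 4-connected components of visited bins whose smoothed rate is
#' at least `threshold_fraction` of the map peak, with area at least
#' `min_area` bins and at most `max_area_fraction` of the arena. The field
#' centroid is the rate-weighted mean position of its bins. Fields are
#' returned main field first: highest peak, ties broken by larger area, then
#' by lowest (row, col) index of the peak bin.
#'
#' @param map A `tuning_map`.
#' @param threshold_fraction Rate threshold as a fraction of the map peak.
#' @param min_area Minimum component size in bins.
#' @param max_area_fraction Maximum component size as a fraction of all bins.
#' @return A list of `place_field` objects (possibly empty), each with
#'   `bins` (k x 2 row/col indices), `centroid` (cm), `peak_rate`,
#'   `area_cm2`.
#' @export
detect_fields <- function(map, threshold_fraction = 0.3, min_area = 4,
                          max_area_fraction = 0.5) {
  r <- map$rate
  pk <- suppressWarnings(max(r, na.rm = TRUE))
  if (!is.finite(pk) || pk <= 0) return(list())
  mask <- !is.na(r) & r >= threshold_fraction * pk
  lab <- label_components(mask)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  max_area <- max_area_fraction * length(r)
  fields <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area || nrow(idx) > max_area) next
    w <- r[lab == l]
    cx <- sum(map$bin_centers[idx[, 1]] * w) / sum(w)
    cy <- sum(map$bin_centers[idx[, 2]] * w) / sum(w)
    pk_i <- which.max(w)
    fields[[length(fields) + 1L]] <- structure(
      list(bins = idx, centroid = c(cx, cy), peak_rate = max(w),
           peak_bin = idx[pk_i, ], area_cm2 = nrow(idx) * map$bin_size^2),
      class = "place_field")
  }
  if (length(fields) == 0L) return(fields)
  o <- order(-vapply(fields, `[[`, numeric(1), "peak_rate"),
             -vapply(fields, `[[`, numeric(1), "area_cm2"),
             vapply(fields, function(f) f$peak_bin[1], numeric(1)),
             vapply(fields, function(f) f$peak_bin[2], numeric(1)))
  fields[o]
}

#' @rdname detect_fields
#' @param field A `place_field`.
#' @export
field_centroid <- function(field) field$centroid

# 4-connected component labelling of a logical matrix (flood fill)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      i <- ((p - 1L) %% nr) + 1L
      j <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (i > 1L) p - 1L, if (i < nr) p + 1L,
                  if (j > 1L) p - nr, if (j < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Spatial information of a tuning map (bits per event)
#'
#' The standard information-per-event measure:
#' `SI = sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` with
#' `p_i` the occupancy share of bin `i` and `lambda_bar` the
#' occupancy-weighted mean rate. Bins with zero rate contribute zero.
#'
#' @param map A `tuning_map` (smoothed rate used).
#' @return Spatial information in bits/event.
#' @export
spatial_information <- function(map) {
  v <- map$visited & !is.na(map$rate)
  p <- map$occupancy[v]
  p <- p / sum(p)
  lam <- map$rate[v]
  lbar <- sum(p * lam)
  if (lbar <= 0) stop("mean rate is zero; spatial information undefined")
  pos <- lam > 0
  sum(p[pos] * (lam[pos] / lbar) * log2(lam[pos] / lbar))
}

#' Compute an allocentric object-tuning map
#'
#' Describes activity as a function of the animal's distance from (2 cm bins)
#' and allocentric angle to (6 degree bins) a discrete object: event
#' amplitudes summed per (distance, angle) bin, divided by the time spent
#' there, then smoothed like a spatial map with circular wrapping along the
#' angle axis. Angle origin is arena east, counter-clockwise positive.
#'
#' @param traj Speed-filtered trajectory.
#' @param events Speed-filtered events (`t`, `amplitude`).
#' @param object_xy Object position `(x, y)` in cm.
#' @param dist_bin Distance bin width, cm.
#' @param angle_bin Angle bin width, degrees; must divide 360.
#' @param max_dist Maximum distance covered by the map, cm. Defaults to the
#'   largest in-arena distance from the object, rounded up to a bin edge.
#' @param sigma Smoothing width in bins.
#' @param smooth Apply smoothing.
#' @param min_occupancy Minimum kernel-pooled occupancy (seconds) for a bin
#'   to carry a rate estimate.
#'
#' @details Unlike spatial maps, (distance, angle) bins subtend wildly
#'   unequal arena areas — bins near the object are visited for fractions of
#'   a second and their raw rates are high-variance. Smoothing is the same
#'   mask-normalized convolution used for spatial maps, but bins whose
#'   kernel-pooled occupancy stays below `min_occupancy` (or that were never
#'   visited) carry no estimate, so near-empty regions cannot contribute
#'   spurious peaks.
#' @return Object of class `object_tuning_map`: `rate`
#'   (distance bins x angle bins), `rate_raw`, `occupancy`, `visited`,
#'   `dist_centers`, `angle_centers`, `object_xy`.
#' @export
compute_object_map <- function(traj, events, object_xy, dist_bin = 2,
                               angle_bin = 6, max_dist = NULL, sigma = 2.5,
                               smooth = TRUE, min_occupancy = 1) {
  if (360 %% angle_bin != 0) stop("'angle_bin' must divide 360")
  dt <- attr(traj, "dt") %||% stats::median(diff(traj$t))
  dx <- traj$x - object_xy[1]
  dy <- traj$y - object_xy[2]
  d <- sqrt(dx^2 + dy^2)
  a <- (atan2(dy, dx) * 180 / pi) %% 360
  if (is.null(max_dist)) max_dist <- ceiling(max(d) / dist_bin) * dist_bin
  nd <- as.integer(ceiling(max_dist / dist_bin))
  na_ <- as.integer(360 / angle_bin)
  id <- pmin(pmax(floor(d / dist_bin), 0), nd - 1)
  ia <- pmin(floor(a / angle_bin), na_ - 1)
  bi <- as.integer(id + nd * ia + 1)
  occ <- tabulate(bi, nd * na_) * dt
  if (sum(occ) == 0) stop("zero total occupancy")
  amp <- numeric(nd * na_)
  if (nrow(events) > 0L) {
    fr <- event_frames(events$t, traj$t)
    s <- rowsum(events$amplitude, bi[fr])
    amp[as.integer(rownames(s))] <- s
  }
  occ_m <- matrix(occ, nd, na_)
  amp_m <- matrix(amp, nd, na_)
  raw <- matrix(NA_real_, nd, na_)
  raw[occ_m > 0] <- amp_m[occ_m > 0] / occ_m[occ_m > 0]
  if (smooth) {
    Sr <- smoothing_operator(nd, sigma)
    Sc <- smoothing_operator(na_, sigma, circular = TRUE)
    pooled_occ <- Sr %*% occ_m %*% t(Sc)
    visited <- occ_m > 0 & pooled_occ >= min_occupancy
    rate <- smooth_masked(raw, occ_m > 0, sigma, circular_cols = TRUE)
    rate[!visited] <- NA_real_
  } else {
    visited <- occ_m > 0
    rate <- raw
  }
  structure(list(rate = rate, rate_raw = raw, occupancy = occ_m,
                 visited = visited,
                 dist_centers = (seq_len(nd) - 0.5) * dist_bin,
                 angle_centers = (seq_len(na_) - 0.5) * angle_bin,
                 object_xy = object_xy),
            class = "object_tuning_map")
}

#' Tuning maps for all cells of a session
#'
#' Speed-filters the session once and computes one tuning map per cell,
#' sharing the occupancy computation. The visited mask is common to all cells
#' (it depends only on the trajectory).
#'
#' @param session A session.
#' @param v_min Speed threshold, cm/s.
#' @param ... Passed to [compute_tuning_map()].
#' @return A list of `tuning_map` objects, one per cell.
#' @export
session_tuning_maps <- function(session, v_min = 2, ...) {
  sf <- speed_filter(session$traj, v_min = v_min)
  keep <- attr(sf$traj, "keep")
  lapply(session$cells, function(cr) {
    idx <- event_frames(cr$events$t, session$traj$t)
    ev <- cr$events[keep[idx], , drop = FALSE]
    compute_tuning_map(sf$traj, ev, ...)
  })
}
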