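#' Preferred object vector of a cell
#'
#' The preferred (distance, angle) is the location of the peak of the
#' smoothed allocentric object-tuning map, refined to the rate-weighted
#' centroid (in object-centred Cartesian coordinates) of the bins at or
#' above `refine_fraction` of the peak that lie within `refine_radius` cm of
#' the peak — a lower-variance estimate of the field centre than the raw
#' argmax bin, especially close to the object where single bins subtend tiny
#' areas. Angle is allocentric, 0 degrees = arena east, counter-clockwise
#' positive, in `[0, 360)`.
#'
#' @param object_map An [compute_object_map()] map.
#' @param refine_fraction,refine_radius Refinement parameters (see above);
#'   `refine_fraction = 1` reduces to the raw argmax bin.
#' @return A list of class `object_tuning`: `distance` (cm), `angle`
#'   (deg), `peak_rate`.
#' @export
object_vector_tuning <- function(object_map, refine_fraction = 0.6,
                                 refine_radius = 10) {
  r <- object_map$rate
  if (all(is.na(r))) stop("empty object map")
  pk_val <- max(r, na.rm = TRUE)
  pk <- which(r == pk_val, arr.ind = TRUE)[1, ]
  th <- object_map$angle_centers * pi / 180
  X <- outer(object_map$dist_centers, cos(th))
  Y <- outer(object_map$dist_centers, sin(th))
  px <- X[pk[1], pk[2]]
  py <- Y[pk[1], pk[2]]
  sel <- !is.na(r) & r >= refine_fraction * pk_val &
    (X - px)^2 + (Y - py)^2 <= refine_radius^2
  w <- r[sel]
  cx <- sum(X[sel] * w) / sum(w)
  cy <- sum(Y[sel] * w) / sum(w)
  structure(list(distance = sqrt(cx^2 + cy^2),
                 angle = (atan2(cy, cx) * 180 / pi) %% 360,
                 peak_rate = pk_val),
            class = "object_tuning")
}

#' Circular difference between two angles
#'
#' @param a,b Angles in degrees.
#' @return The wrapped absolute difference in `[0, 180]`.
#' @export
circular_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Classify a cell as object-tuned across the object protocol
#'
#' A cell is object-tuned iff (i) it expresses a prominent field at an
#' object-referenced location in both object sessions, (ii) the preferred
#' vectors of the two sessions agree (distance difference within `d_tol`,
#' circular angle difference within `a_tol`; cells firing at the object
#' itself, preferred distance near zero, are exempt from the angle test
#' since direction is undefined there), and (iii) the field is new: the
#' baseline (no-object) spatial map at the corresponding arena locations is
#' below `new_frac` of the object-session rate there.
#'
#' Preferred vectors are extracted from the baseline-subtracted spatial maps
#' (object-session rate minus baseline rate, floored at zero) and then
#' expressed relative to the object. The subtraction cancels pre-existing
#' place fields — the map-level form of the "new field" requirement — and
#' the arena-space extraction avoids the polar distortions of the
#' (distance, angle) grid, whose bins subtend tiny areas near the object and
#' are angularly over-smoothed far from it. When baseline-referenced object
#' maps are supplied instead (`object_maps$base1`, `base2`), or no spatial
#' maps are given, vectors fall back to the (subtracted) object-map peak.
#'
#' @param spatial_maps List with `baseline`, `obj1`, `obj2` spatial
#'   `tuning_map`s of the cell.
#' @param object_maps List with `obj1`, `obj2` object-tuning maps.
#' @param object_xy List with `obj1`, `obj2` object positions (cm).
#' @param d_tol Distance-consistency tolerance, cm. Also used as the
#'   endpoint tolerance: two vectors whose object-centred Cartesian
#'   endpoints lie within `d_tol` of each other are consistent regardless of
#'   their nominal angle difference — near the object a small positional
#'   discrepancy can subtend a large angle, which is the general form of the
#'   "firing at the object" exemption.
#' @param a_tol Angle-consistency tolerance, degrees.
#' @param new_frac "New field" criterion: baseline rate at the field
#'   location must be below this fraction of the object-session rate there.
#' @param prominence Object-map peak must exceed `prominence` times the
#'   object-map mean in both object sessions (guards against flat noise
#'   maps); with baseline subtraction the peak of the difference map must
#'   instead exceed `min_diff_peak`.
#' @param min_diff_peak Minimum baseline-subtracted peak rate (events/s)
#'   for a real object response.
#' @param at_object_dist Preferred distances below this (cm) count as "at
#'   the object" and skip the angle test.
#' @return A list: `is_object_tuned`, `tuning` (an `object_tuning` from the
#'   first object session, with added `consistency` = endpoint distance in
#'   cm between the two session vectors), `delta_distance`, `delta_angle`,
#'   `is_new_field`.
#' @export
classify_object_tuned <- function(spatial_maps, object_maps = NULL,
                                  object_xy, d_tol = 10, a_tol = 45,
                                  new_frac = 0.5, prominence = 3,
                                  min_diff_peak = 0.12,
                                  at_object_dist = 4) {
  spatial_route <- !is.null(spatial_maps$baseline) &&
    !is.null(spatial_maps$obj1) && !is.null(spatial_maps$obj2)
  if (spatial_route) {
    d1 <- subtract_rate_maps(spatial_maps$obj1, spatial_maps$baseline)
    d2 <- subtract_rate_maps(spatial_maps$obj2, spatial_maps$baseline)
    v1 <- object_vector_from_spatial(d1, object_xy$obj1)
    v2 <- object_vector_from_spatial(d2, object_xy$obj2)
    subtracted <- TRUE
    om1 <- NULL; om2 <- NULL
  } else {
    subtracted <- !is.null(object_maps$base1) && !is.null(object_maps$base2)
    om1 <- if (subtracted)
      subtract_object_map(object_maps$obj1, object_maps$base1)
    else object_maps$obj1
    om2 <- if (subtracted)
      subtract_object_map(object_maps$obj2, object_maps$base2)
    else object_maps$obj2
    v1 <- object_vector_tuning(om1)
    v2 <- object_vector_tuning(om2)
  }
  dd <- abs(v1$distance - v2$distance)
  da <- circular_diff(v1$angle, v2$angle)
  at_object <- v1$distance <= at_object_dist && v2$distance <= at_object_dist
  endpoint <- sqrt(v1$distance^2 + v2$distance^2 -
                   2 * v1$distance * v2$distance * cos((v1$angle - v2$angle) *
                                                       pi / 180))
  consistent <- endpoint <= d_tol ||
    (dd <= d_tol && (at_object || da <= a_tol))
  prom_ok <- if (spatial_route || subtracted) {
    c(v1$peak_rate >= min_diff_peak, v2$peak_rate >= min_diff_peak)
  } else {
    vapply(list(om1, om2), function(m) {
      mu <- mean(m$rate, na.rm = TRUE)
      mu > 0 && max(m$rate, na.rm = TRUE) >= prominence * mu
    }, logical(1))
  }
  # arena locations implied by each session's vector
  loc <- function(xy, v)
    c(xy[1] + v$distance * cos(v$angle * pi / 180),
      xy[2] + v$distance * sin(v$angle * pi / 180))
  l1 <- loc(object_xy$obj1, v1)
  l2 <- loc(object_xy$obj2, v2)
  base1 <- map_value_at(spatial_maps$baseline, l1)
  base2 <- map_value_at(spatial_maps$baseline, l2)
  obj1_rate <- map_value_at(spatial_maps$obj1, l1)
  obj2_rate <- map_value_at(spatial_maps$obj2, l2)
  new1 <- !is.na(obj1_rate) && obj1_rate > 0 &&
    (is.na(base1) || base1 < new_frac * obj1_rate)
  new2 <- !is.na(obj2_rate) && obj2_rate > 0 &&
    (is.na(base2) || base2 < new_frac * obj2_rate)
  is_new <- new1 && new2
  tuning <- v1
  tuning$consistency <- sqrt(v1$distance^2 + v2$distance^2 -
    2 * v1$distance * v2$distance * cos((v1$angle - v2$angle) * pi / 180))
  list(is_object_tuned = all(prom_ok) && consistent && is_new,
       tuning = tuning, delta_distance = dd, delta_angle = da,
       is_new_field = is_new)
}

# spatial-map difference (floored at zero) over the common visited mask
subtract_rate_maps <- function(obj_map, base_map) {
  out <- obj_map
  common <- !is.na(obj_map$rate) & !is.na(base_map$rate)
  r <- matrix(NA_real_, nrow(out$rate), ncol(out$rate))
  r[common] <- pmax(obj_map$rate[common] - base_map$rate[common], 0)
  out$rate <- r
  out
}

# preferred object vector from a (subtracted) spatial rate map: peak bin,
# refined to the rate-weighted centroid of bins >= 60% of peak within 10 cm
object_vector_from_spatial <- function(map, object_xy, refine_fraction = 0.6,
                                       refine_radius = 10) {
  r <- map$rate
  if (all(is.na(r))) stop("empty map")
  pk_val <- max(r, na.rm = TRUE)
  pk <- which(r == pk_val, arr.ind = TRUE)[1, ]
  ctr <- map$bin_centers
  X <- matrix(ctr, nrow(r), ncol(r))
  Y <- matrix(ctr, nrow(r), ncol(r), byrow = TRUE)
  px <- ctr[pk[1]]; py <- ctr[pk[2]]
  sel <- !is.na(r) & r >= refine_fraction * pk_val &
    (X - px)^2 + (Y - py)^2 <= refine_radius^2
  w <- r[sel]
  cx <- sum(X[sel] * w) / sum(w)
  cy <- sum(Y[sel] * w) / sum(w)
  dx <- cx - object_xy[1]
  dy <- cy - object_xy[2]
  structure(list(distance = sqrt(dx^2 + dy^2),
                 angle = (atan2(dy, dx) * 180 / pi) %% 360,
                 peak_rate = pk_val),
            class = "object_tuning")
}

# object-session map minus the baseline session mapped to the same object
# coordinates; negative differences (lost fields) are floored at zero
subtract_object_map <- function(obj_map, base_map) {
  out <- obj_map
  common <- !is.na(obj_map$rate) & !is.na(base_map$rate)
  r <- matrix(NA_real_, nrow(out$rate), ncol(out$rate))
  r[common] <- pmax(obj_map$rate[common] - base_map$rate[common], 0)
  out$rate <- r
  out
}

# smoothed map value at an arena location (nearest bin); NA outside/unvisited
map_value_at <- function(map, xy) {
  nb <- nrow(map$rate)
  i <- floor(xy[1] / map$bin_size) + 1
  j <- floor(xy[2] / map$bin_size) + 1
  if (i < 1 || i > nb || j < 1 || j > nb) return(NA_real_)
  map$rate[i, j]
}

#' Classify object-tuned cells across a whole protocol
#'
#' Convenience wrapper running [classify_object_tuned()] for every cell of a
#' four-session object protocol (baseline, object, object moved, post).
#'
#' @param sessions List with `baseline`, `obj1`, `obj2` sessions (the post
#'   session is not needed for classification).
#' @param object_xy List with `obj1`, `obj2` positions (cm).
#' @param v_min Speed threshold for the maps.
#' @param min_events Cells with fewer events in either object session are
#'   not classified.
#' @param ... Passed to [classify_object_tuned()].
#' @return A `data.frame`: `cell_id`, `is_object_tuned`,
#'   `preferred_distance`, `preferred_angle`, `consistency`,
#'   `delta_distance`, `delta_angle`.
#' @export
classify_object_cells <- function(sessions, object_xy, v_min = 2,
                                  min_events = 40, ...) {
  n <- length(sessions$baseline$cells)
  maps_base <- session_tuning_maps(sessions$baseline, v_min = v_min)
  maps_o1 <- session_tuning_maps(sessions$obj1, v_min = v_min)
  maps_o2 <- session_tuning_maps(sessions$obj2, v_min = v_min)
  rows <- lapply(seq_len(n), function(i) {
    out <- data.frame(cell_id = sessions$baseline$cells[[i]]$cell_id,
                      is_object_tuned = FALSE, preferred_distance = NA_real_,
                      preferred_angle = NA_real_, consistency = NA_real_,
                      delta_distance = NA_real_, delta_angle = NA_real_)
    if (nrow(sessions$obj1$cells[[i]]$events) < min_events ||
        nrow(sessions$obj2$cells[[i]]$events) < min_events) return(out)
    cl <- classify_object_tuned(
      spatial_maps = list(baseline = maps_base[[i]], obj1 = maps_o1[[i]],
                          obj2 = maps_o2[[i]]),
      object_xy = object_xy, ...)
    out$is_object_tuned <- cl$is_object_tuned
    out$preferred_distance <- cl$tuning$distance
    out$preferred_angle <- cl$tuning$angle
    out$consistency <- cl$tuning$consistency
    out$delta_distance <- cl$delta_distance
    out$delta_angle <- cl$delta_angle
    out
  })
  do.call(rbind, rows)
}

#' Rayleigh test of circular uniformity
#'
#' `Z = n * Rbar^2` with `Rbar` the mean resultant length; the p-value uses
#' the standard series approximation.
#'
#' @param angles Angles in degrees, `n >= 5`.
#' @return A list: `Z`, `p`, `n`, `rbar`.
#' @export
rayleigh_uniformity <- function(angles) {
  n <- length(angles)
  if (n < 5L) stop("need at least 5 angles")
  th <- angles * pi / 180
  rbar <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                  (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  list(Z = Z, p = p, n = n, rbar = rbar)
}

#' Anatomical organization of object-tuned cells
#'
#' Pairwise circular differences in preferred angle versus anatomical
#' distance: KSG mutual information, an expanding-circle profile of the
#' angular difference, and Cliff's delta between the smallest and largest
#' radius groups.
#'
#' @param centroids n x 2 anatomical centroids (um) of object-tuned cells.
#' @param angles Preferred angles, degrees.
#' @param distances Optional preferred distances (cm); when given, the MI of
#'   anatomical distance versus pairwise difference in field-to-object
#'   distance is reported too.
#' @param radii Anatomical radii, um.
#' @param n_boot,n_ctrl,level Profile parameters.
#' @param seed Optional integer seed.
#' @return A list: `pairs` (`data.frame` with `anat_dist`, `delta_angle`),
#'   `mi_angle`, `mi_distance` (or NULL), `profile`, `cliffs_delta`
#'   (smallest vs largest radius groups).
#' @export
object_topography <- function(centroids, angles, distances = NULL,
                              radii = seq(15, 60, by = 5), n_boot = 10000,
                              n_ctrl = 200, level = 0.99, seed = NULL) {
  n <- nrow(centroids)
  if (n < 2L) stop("need at least 2 object-tuned cells")
  anat <- as.matrix(stats::dist(centroids))
  dth <- outer(angles, angles, circular_diff)
  ut <- upper.tri(anat)
  mi_a <- mutual_information_knn(anat[ut], dth[ut], seed = seed)
  mi_d <- NULL
  if (!is.null(distances)) {
    ddist <- abs(outer(distances, distances, `-`))
    mi_d <- mutual_information_knn(anat[ut], ddist[ut], seed = seed)
  }
  prof <- expanding_circle_profile(anat, dth, radii, n_boot = n_boot,
                                   n_ctrl = n_ctrl, level = level,
                                   seed = seed)
  g_small <- dth[ut][anat[ut] <= radii[1]]
  g_large <- dth[ut][anat[ut] <= radii[length(radii)]]
  cd <- if (length(g_small) && length(g_large))
    cliffs_delta(g_small, g_large) else NA_real_
  list(pairs = data.frame(anat_dist = anat[ut], delta_angle = dth[ut]),
       mi_angle = mi_a, mi_distance = mi_d, profile = prof,
       cliffs_delta = cd)
}
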