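#' Anatomical-topography coupling configuration
#'
#' Controls the alternative hypothesis the clustering battery is designed to
#' detect: local clusters of similarly tuned place cells. With
#' `coupling_lambda = 0` anatomy and tuning are fully distributed
#' (statistically independent). With `coupling_lambda > 0`, circular
#' anatomical patches of diameter `cluster_scale` (covering a `coverage`
#' fraction of the FOV) each carry a shared field anchor in the arena; a
#' member cell's field centroid is the convex mixture
#' `lambda * (anchor + jitter) + (1 - lambda) * uniform`, while cells outside
#' every patch keep independent uniform fields. Expected field distance
#' therefore increases with anatomical distance up to about `cluster_scale`,
#' and within-patch similarity is spatially patchy — the signature the binned
#' Moran analysis is designed to pick up.
#'
#' @param coupling_lambda Mixing weight in `[0, 1]`. 0 = fully distributed.
#' @param cluster_scale Patch diameter, micrometres.
#' @param coverage Fraction of the FOV covered by patches (in expectation).
#' @param field_jitter SD (cm) of the within-patch scatter of field centroids
#'   around the patch anchor.
#' @return An object of class `clustering_config`.
#' @export
clustering_config <- function(coupling_lambda = 0, cluster_scale = 150,
                              coverage = 0.8, field_jitter = 4) {
  if (coupling_lambda < 0 || coupling_lambda > 1)
    stop("'coupling_lambda' must be in [0, 1]")
  if (cluster_scale <= 0) stop("'cluster_scale' must be positive")
  if (coverage <= 0 || coverage > 1) stop("'coverage' must be in (0, 1]")
  structure(list(coupling_lambda = coupling_lambda,
                 cluster_scale = cluster_scale, coverage = coverage,
                 field_jitter = field_jitter),
            class = "clustering_config")
}

#' Generate a synthetic place-cell population
#'
#' Places `n_cells` somata uniformly in the FOV with a minimum spacing
#' (dart-throwing), assigns each cell one or two Gaussian place fields in the
#' arena, a field width, a peak event rate and an active/silent flag. The
#' anatomical-field coupling of [clustering_config()] is applied to the main
#' field centroid; with `coupling_lambda = 0` field positions are independent
#' of anatomy.
#'
#' @param n_cells Number of cells.
#' @param arena,fov Geometry specs.
#' @param active_fraction Fraction of cells active (spatially tuned) in the
#'   environment; the rest only emit noise events. Must be in (0, 1].
#' @param clustering A [clustering_config()].
#' @param min_spacing Minimum anatomical distance between somata, um.
#' @param two_field_prob Probability a cell carries a second place field.
#' @param sigma_range Range (cm) from which per-cell field widths are drawn.
#' @param rate_range Range (events/s) for per-cell peak event rates.
#' @param seed Optional integer seed.
#' @return An object of class `cell_population`: a list with matrix
#'   `centroids` (n x 2, um), list `fields` (per cell k x 2 matrix, cm;
#'   row 1 = main field), vectors `sigma`, `peak_rate`, `active`, and the
#'   specs as attributes.
#' @export
place_field_population <- function(n_cells, arena = arena_spec(),
                                   fov = fov_spec(), active_fraction = 0.35,
                                   clustering = clustering_config(),
                                   min_spacing = 10, two_field_prob = 0.2,
                                   sigma_range = c(4.5, 7.5),
                                   rate_range = c(0.5, 1.5), seed = NULL) {
  if (active_fraction <= 0 || active_fraction > 1)
    stop("'active_fraction' must be in (0, 1]")
  # random-sequential-adsorption jamming limit for discs of radius
  # min_spacing/2 covers ~54.7% of the plane
  capacity <- floor(0.54 * fov$width * fov$height /
                      (pi * (min_spacing / 2)^2))
  if (n_cells > capacity)
    stop(sprintf("n_cells = %d exceeds packing capacity (~%d) at %g um spacing",
                 n_cells, capacity, min_spacing))
  side <- arena$side_length
  with_seed_if(seed, {
    cent <- dart_throw(n_cells, fov$width, fov$height, min_spacing)
    u <- matrix(stats::runif(2 * n_cells, 0, side), n_cells, 2)
    if (clustering$coupling_lambda > 0) {
      main <- patch_coupled_fields(cent, u, clustering, fov, side)
    } else {
      main <- u
    }
    sigma <- stats::runif(n_cells, sigma_range[1], sigma_range[2])
    peak <- stats::runif(n_cells, rate_range[1], rate_range[2])
    second <- stats::runif(n_cells) < two_field_prob
    fields <- lapply(seq_len(n_cells), function(i) {
      f <- main[i, , drop = FALSE]
      if (second[i]) f <- rbind(f, stats::runif(2, 0, side))
      dimnames(f) <- NULL
      f
    })
    active <- stats::runif(n_cells) < active_fraction
    structure(list(centroids = cent, fields = fields, sigma = sigma,
                   peak_rate = peak, active = active,
                   cell_id = seq_len(n_cells)),
              arena = arena, fov = fov, clustering = clustering,
              active_fraction = active_fraction,
              class = "cell_population")
  })
}

#' @export
print.cell_population <- function(x, ...) {
  cat(sprintf("<cell_population> %d cells (%d active), FOV %g x %g um\n",
              length(x$cell_id), sum(x$active),
              attr(x, "fov")$width, attr(x, "fov")$height))
  invisible(x)
}

# uniform anatomical centroids with hard minimum spacing
dart_throw <- function(n, width, height, min_spacing) {
  cent <- matrix(NA_real_, n, 2)
  placed <- 0L
  max_tries <- 500L * n
  tries <- 0L
  while (placed < n) {
    if (tries >= max_tries)
      stop("could not place all somata at the requested minimum spacing")
    tries <- tries + 1L
    p <- c(stats::runif(1, 0, width), stats::runif(1, 0, height))
    ok <- placed == 0L ||
      min((cent[1:placed, 1] - p[1])^2 + (cent[1:placed, 2] - p[2])^2) >=
        min_spacing^2
    if (ok) {
      placed <- placed + 1L
      cent[placed, ] <- p
    }
  }
  cent
}

# cluster-patch coupling: shared field anchors within sparse circular
# anatomical patches, mixed per cell with an independent uniform draw
patch_coupled_fields <- function(cent, u, clustering, fov, side) {
  n <- nrow(cent)
  lam <- clustering$coupling_lambda
  R <- clustering$cluster_scale / 2
  K <- max(1L, round(clustering$coverage * fov$width * fov$height /
                       (pi * R^2)))
  centers <- cbind(stats::runif(K, 0, fov$width),
                   stats::runif(K, 0, fov$height))
  anchors <- matrix(stats::runif(2 * K, 0, side), K, 2)
  d2 <- outer(cent[, 1], centers[, 1], `-`)^2 +
    outer(cent[, 2], centers[, 2], `-`)^2
  near <- max.col(-d2, ties.method = "first")
  member <- d2[cbind(seq_len(n), near)] <= R^2
  f <- u
  idx <- which(member)
  if (length(idx)) {
    jit <- matrix(stats::rnorm(2 * length(idx), 0, clustering$field_jitter),
                  ncol = 2)
    f[idx, ] <- lam * (anchors[near[idx], , drop = FALSE] + jit) +
      (1 - lam) * u[idx, , drop = FALSE]
  }
  pmin(pmax(f, 0), side)
}

#' Generate a remapped companion population
#'
#' Models exposure to a second environment. `mode = "orthogonal"` redraws all
#' field centroids independently and redraws the active subset (global
#' remapping, as between two different arenas); `mode = "preserved"` returns
#' the identical field layout and active set (as for re-exposure to the same
#' arena, where only event noise differs between sessions).
#'
#' @param base_population A [place_field_population()].
#' @param mode `"orthogonal"` or `"preserved"`.
#' @param seed Optional integer seed.
#' @return A list with elements `A` (the base population) and `B`.
#' @export
generate_remapping_pair <- function(base_population,
                                    mode = c("orthogonal", "preserved"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  A <- base_population
  if (mode == "preserved") return(list(A = A, B = A))
  arena <- attr(A, "arena")
  side <- arena$side_length
  n <- length(A$cell_id)
  with_seed_if(seed, {
    B <- A
    B$fields <- lapply(A$fields, function(f) {
      matrix(stats::runif(2 * nrow(f), 0, side), nrow(f), 2)
    })
    B$active <- stats::runif(n) < attr(A, "active_fraction")
    list(A = A, B = B)
  })
}

#' Add object-vector tuning to a population
#'
#' A random fraction of cells is given an object vector (preferred distance
#' and allocentric angle). When events are generated for a session containing
#' an object, these cells gain an additive Gaussian intensity bump at
#' `object_xy + vector`; the same vector is reused when the object moves.
#' Preferred angles are uniform on the circle; preferred distances are
#' log-normal with median `dist_median` cm.
#'
#' @param base_population A [place_field_population()].
#' @param object_fraction Fraction of cells to make object-tuned.
#' @param dist_median,dist_sdlog Log-normal parameters of preferred distance.
#' @param max_dist Preferred distances are truncated to this value (cm).
#' @param seed Optional integer seed.
#' @return The population with added `object_vector` (n x 2 matrix:
#'   distance cm, angle deg; NA rows for untuned cells) and logical
#'   `object_tuned`.
#' @export
assign_object_vectors <- function(base_population, object_fraction = 0.1,
                                  dist_median = 15, dist_sdlog = 0.5,
                                  max_dist = 35, seed = NULL) {
  n <- length(base_population$cell_id)
  with_seed_if(seed, {
    tuned <- stats::runif(n) < object_fraction
    vec <- matrix(NA_real_, n, 2)
    k <- sum(tuned)
    if (k > 0) {
      d <- pmin(stats::rlnorm(k, log(dist_median), dist_sdlog), max_dist)
      a <- stats::runif(k, 0, 360)
      vec[tuned, ] <- cbind(d, a)
    }
    pop <- base_population
    pop$object_vector <- vec
    pop$object_tuned <- tuned
    pop
  })
}

#' Build the session spec for an object-protocol session
#'
#' Validates the object position and returns the population tagged with the
#' object location, ready for [generate_session()]. With
#' `object_fraction = 0` (no cell given a vector) sessions are identical in
#' distribution to the base population's.
#'
#' @param base_population A population, typically after
#'   [assign_object_vectors()].
#' @param object_xy Object position `(x, y)` in cm; must lie inside the arena.
#' @return The population with attribute `object_xy` set.
#' @export
generate_object_session <- function(base_population, object_xy) {
  arena <- attr(base_population, "arena")
  if (any(object_xy < 0) || any(object_xy > arena$side_length))
    stop("object position must lie inside the arena")
  pop <- base_population
  attr(pop, "object_xy") <- as.numeric(object_xy)
  pop
}
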