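#' Pairwise map correlations for a set of cells
#'
#' All maps of one session share the visited mask (it depends only on the
#' trajectory), so pairwise Pearson correlations reduce to the correlation of
#' the map matrix rows over the common visited bins.
#'
#' @param maps A list of `tuning_map` objects, or a cells-by-bins matrix.
#' @return A symmetric n x n correlation matrix (diagonal 1; `NA` where a
#'   map has zero variance).
#' @export
pairwise_map_correlations <- function(maps) {
  M <- if (is.matrix(maps)) maps else map_matrix(maps)
  if (!anyNA(M)) {
    sds <- apply(M, 1, stats::sd)
    Z <- (M - rowMeans(M)) / sds
    C <- tcrossprod(Z) / (ncol(M) - 1)
    C[sds == 0, ] <- NA_real_
    C[, sds == 0] <- NA_real_
    diag(C)[sds > 0] <- 1
    return(C)
  }
  suppressWarnings(stats::cor(t(M), use = "pairwise.complete.obs"))
}

#' Flatten a list of tuning maps to a cells-by-bins matrix
#'
#' Only bins visited in every map are kept.
#'
#' @param maps List of `tuning_map` objects (or plain matrices).
#' @return A numeric matrix, one row per cell.
#' @export
map_matrix <- function(maps) {
  mats <- lapply(maps, function(m) if (inherits(m, "tuning_map")) m$rate else m)
  common <- Reduce(`&`, lapply(mats, function(m) !is.na(m)))
  do.call(rbind, lapply(mats, function(m) m[common]))
}

#' Build the place-cell pair table
#'
#' One row per unordered pair of place cells: anatomical distance (um),
#' main-field distance (cm) and tuning-map correlation. Pooling across
#' environments is done by concatenating tables. Pairs closer than 15 um
#' anatomically are flagged (`close_pair`) for downstream exclusion but are
#' not removed here.
#'
#' @param centroids n x 2 matrix of anatomical centroids (um).
#' @param field_centroids n x 2 matrix of main place-field centroids (cm).
#' @param maps Optional maps (list or matrix) for the correlation column.
#' @param cell_id Optional identifiers (default `1:n`).
#' @param close_um Flagging distance for overlapping somata, um.
#' @return A `data.frame`: `cell_i`, `cell_j`, `anat_dist`, `field_dist`,
#'   `map_corr` (NA when no maps given), `close_pair`.
#' @export
build_pair_table <- function(centroids, field_centroids, maps = NULL,
                             cell_id = NULL, close_um = 15) {
  n <- nrow(centroids)
  if (n < 2L) {
    return(data.frame(cell_i = integer(), cell_j = integer(),
                      anat_dist = numeric(), field_dist = numeric(),
                      map_corr = numeric(), close_pair = logical()))
  }
  cell_id <- cell_id %||% seq_len(n)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  da <- as.matrix(stats::dist(centroids))
  df <- as.matrix(stats::dist(field_centroids))
  mc <- if (is.null(maps)) NA_real_ else pairwise_map_correlations(maps)[ij]
  data.frame(cell_i = cell_id[ij[, 1]], cell_j = cell_id[ij[, 2]],
             anat_dist = da[ij], field_dist = df[ij], map_corr = mc,
             close_pair = da[ij] < close_um)
}

#' Kraskov k-nearest-neighbour mutual information for continuous pairs
#'
#' MI estimate in nats (KSG algorithm 1, Chebyshev metric). A small uniform
#' jitter breaks ties. Negative estimates (possible for independent data) are
#' clamped to zero; the raw estimate is kept in the `raw` attribute. Constant
#' input returns 0 with attribute `degenerate = TRUE`.
#'
#' @param x,y Paired numeric samples, `n >= 100` recommended.
#' @param k Number of neighbours.
#' @param jitter_sd Scale of the tie-breaking jitter relative to the sample SD.
#' @param seed Optional integer seed (for the jitter only).
#' @return MI in nats (scalar, >= 0).
#' @export
mutual_information_knn <- function(x, y, k = 3, jitter_sd = 1e-10,
                                   seed = NULL) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  with_seed_if(seed, {
    xj <- x + stats::rnorm(length(x), 0, jitter_sd * stats::sd(x))
    yj <- y + stats::rnorm(length(y), 0, jitter_sd * stats::sd(y))
    raw <- ksg_mi_cpp(xj, yj, as.integer(k))
    out <- max(raw, 0)
    attr(out, "raw") <- raw
    out
  })
}

#' Binned (equal-frequency) mutual information cross-check
#'
#' Plug-in MI on an equal-frequency discretization of both margins; a simple
#' independent cross-check of [mutual_information_knn()].
#'
#' @param x,y Paired samples.
#' @param n_bins Number of quantile bins per margin.
#' @return MI in nats.
#' @export
mutual_information_binned <- function(x, y, n_bins = 16) {
  qx <- cut(rank(x, ties.method = "first"), n_bins, labels = FALSE)
  qy <- cut(rank(y, ties.method = "first"), n_bins, labels = FALSE)
  p <- table(qx, qy) / length(x)
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
}

#' Assign cells to a square anatomical bin grid
#'
#' The FOV is tiled with `n_bins` x `n_bins` square bins anchored at the FOV
#' corner (with the default 8 per axis a 350 um FOV gives ~45 um bins).
#'
#' @param centroids n x 2 anatomical centroids (um).
#' @param fov A [fov_spec()].
#' @param n_bins Bins per axis.
#' @return A list of class `anatomical_bin_grid`: `bin` (bin index per
#'   cell), `bin_centers` (n_bins^2 x 2, um), `n_bins`, `bin_size`.
#' @export
anatomical_bin_grid <- function(centroids, fov = fov_spec(), n_bins = 8) {
  bs_x <- fov$width / n_bins
  bs_y <- fov$height / n_bins
  ix <- pmin(pmax(floor(centroids[, 1] / bs_x), 0), n_bins - 1)
  iy <- pmin(pmax(floor(centroids[, 2] / bs_y), 0), n_bins - 1)
  bin <- as.integer(ix + n_bins * iy + 1)
  g <- expand.grid(x = (seq_len(n_bins) - 0.5) * bs_x,
                   y = (seq_len(n_bins) - 0.5) * bs_y)
  structure(list(bin = bin, bin_centers = as.matrix(g), n_bins = n_bins,
                 bin_size = c(bs_x, bs_y)),
            class = "anatomical_bin_grid")
}

# mean pairwise statistic within one cell set, excluding anatomically
# overlapping pairs; NA when no valid pair remains
mean_pairwise_stat <- function(idx, stat, anat_dist, exclusion) {
  if (length(idx) < 2L) return(NA_real_)
  s <- stat[idx, idx]
  d <- anat_dist[idx, idx]
  ut <- upper.tri(s)
  ok <- ut & d >= exclusion & !is.na(s)
  if (!any(ok)) return(NA_real_)
  mean(s[ok])
}

#' Within-bin mean pairwise similarity
#'
#' For each anatomical bin holding at least `min_cells` place cells, the mean
#' pairwise statistic (tuning-map or dF/F correlation) over its cell pairs,
#' excluding pairs closer than `exclusion` um (overlapping somata). Bins left
#' without a valid pair are dropped.
#'
#' @param grid An [anatomical_bin_grid()].
#' @param stat_matrix n x n pairwise statistic matrix.
#' @param anat_dist n x n anatomical distance matrix (um).
#' @param min_cells Minimum place cells per analysed bin.
#' @param exclusion Pair-exclusion distance, um.
#' @return A `data.frame`: `bin`, `bin_x`, `bin_y`, `n_cells`, `mean_stat`.
#' @export
within_bin_similarity <- function(grid, stat_matrix, anat_dist, min_cells = 3,
                                  exclusion = 15) {
  tab <- table(grid$bin)
  bins <- as.integer(names(tab))[tab >= min_cells]
  rows <- lapply(bins, function(b) {
    idx <- which(grid$bin == b)
    ms <- mean_pairwise_stat(idx, stat_matrix, anat_dist, exclusion)
    data.frame(bin = b, bin_x = grid$bin_centers[b, 1],
               bin_y = grid$bin_centers[b, 2], n_cells = length(idx),
               mean_stat = ms)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bin = integer(), bin_x = numeric(), bin_y = numeric(),
               n_cells = integer(), mean_stat = numeric())
  out <- out[!is.na(out$mean_stat), , drop = FALSE]
  if (nrow(out) == 0L) warning("no qualifying anatomical bins")
  rownames(out) <- NULL
  out
}

#' Size-matched random control for within-bin similarity
#'
#' For each analysed bin, draws `n_iter` random cell sets of the same size
#' (without replacement within a draw) from the session's full roster and
#' recomputes the same mean pairwise statistic with the same exclusion rule.
#' Each iteration's bins are aggregated to a median, giving the null
#' distribution of the within-bin median.
#'
#' @param stat_matrix,anat_dist As in [within_bin_similarity()].
#' @param bin_sizes Integer sizes of the observed bins.
#' @param n_iter Number of control iterations.
#' @param exclusion Pair-exclusion distance, um.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n_iter` control medians.
#' @export
size_matched_control <- function(stat_matrix, anat_dist, bin_sizes,
                                 n_iter = 200, exclusion = 15, seed = NULL) {
  n <- nrow(stat_matrix)
  if (any(bin_sizes > n)) stop("a bin exceeds the session roster size")
  with_seed_if(seed, {
    vapply(seq_len(n_iter), function(it) {
      ms <- vapply(bin_sizes, function(sz) {
        idx <- sample.int(n, sz)
        mean_pairwise_stat(idx, stat_matrix, anat_dist, exclusion)
      }, numeric(1))
      stats::median(ms, na.rm = TRUE)
    }, numeric(1))
  })
}

#' Percentile bootstrap confidence interval for the median
#'
#' @param values Numeric sample, `n >= 2`.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level (e.g. 0.99).
#' @param seed Optional integer seed.
#' @return A list: `median`, `lo`, `hi`, `level`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000, level = 0.99,
                                seed = NULL) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  with_seed_if(seed, {
    meds <- boot_medians_cpp(values, as.integer(n_boot))
    a <- (1 - level) / 2
    q <- stats::quantile(meds, c(a, 1 - a), names = FALSE)
    list(median = stats::median(values), lo = q[1], hi = q[2], level = level)
  })
}

#' Row-standardized inverse-distance spatial weights
#'
#' `w_ij = 1/d_ij` for `0 < d_ij <= cutoff`, zero otherwise; rows are scaled
#' to sum to one (rows without neighbours stay zero).
#'
#' @param coords n x 2 positions.
#' @param cutoff Neighbourhood cutoff in the coordinate units.
#' @return An n x n weight matrix.
#' @export
weights_inverse_distance <- function(coords, cutoff) {
  d <- as.matrix(stats::dist(coords))
  W <- ifelse(d > 0 & d <= cutoff, 1 / d, 0)
  diag(W) <- 0
  row_standardize(W)
}

#' Contiguity weights on a regular grid
#'
#' Rook (edge-sharing) or queen (edge- or corner-sharing) contiguity between
#' the cells of an `nr` x `nc` grid, row-standardized.
#'
#' @param nr,nc Grid dimensions.
#' @param type `"rook"` or `"queen"`.
#' @return An (nr*nc) x (nr*nc) weight matrix; unit order is column-major.
#' @export
weights_contiguity <- function(nr, nc, type = c("rook", "queen")) {
  type <- match.arg(type)
  n <- nr * nc
  idx <- cbind(rep(seq_len(nr), nc), rep(seq_len(nc), each = nr))
  offs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (type == "queen")
    offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  W <- matrix(0, n, n)
  for (u in seq_len(n)) {
    nb <- sweep(offs, 2, idx[u, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= nr & nb[, 2] >= 1 & nb[, 2] <= nc
    W[u, nb[ok, 1] + (nb[ok, 2] - 1) * nr] <- 1
  }
  row_standardize(W)
}

row_standardize <- function(W) {
  rs <- rowSums(W)
  pos <- rs > 0
  W[pos, ] <- W[pos, , drop = FALSE] / rs[pos]
  W
}

#' Global Moran's I with a permutation null
#'
#' `I = (n / S0) * (z' W z) / (z' z)` with `z` the centred values and `S0`
#' the total weight. The null distribution is obtained by randomly
#' reassigning the values across units and recomputing I; clustering is
#' declared when the observed I exceeds the 95th percentile of the null.
#'
#' @param values Numeric vector, one value per spatial unit (>= 8 units).
#' @param W Spatial weight matrix (see [weights_inverse_distance()]).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return Object of class `moran_result`: `I`, `expected` (= -1/(n-1)),
#'   `null` (permutation values), `p95`, `significant`, `p_value`.
#' @export
# bare Moran's I statistic (no null)
moran_stat <- function(values, W) {
  z <- values - mean(values)
  (length(values) / sum(W)) * as.numeric(crossprod(z, W %*% z)) / sum(z^2)
}

morans_i <- function(values, W, n_perm = 1000, seed = NULL) {
  n <- length(values)
  if (n < 8L) stop("need at least 8 spatial units")
  if (stats::sd(values) == 0) stop("zero variance in values")
  z <- values - mean(values)
  s0 <- sum(W)
  denom <- sum(z^2)
  I <- (n / s0) * as.numeric(crossprod(z, W %*% z)) / denom
  with_seed_if(seed, {
    Z <- vapply(seq_len(n_perm), function(p) sample(z), numeric(n))
    null <- (n / s0) * colSums(Z * (W %*% Z)) / denom
    p95 <- stats::quantile(null, 0.95, names = FALSE)
    structure(list(I = I, expected = -1 / (n - 1), null = null, p95 = p95,
                   significant = I > p95,
                   p_value = (1 + sum(null >= I)) / (n_perm + 1)),
              class = "moran_result")
  })
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("<moran_result> I = %.4f (E[I] = %.4f), null p95 = %.4f, %s (p = %.4f)\n",
              x$I, x$expected, x$p95,
              if (x$significant) "CLUSTERED" else "not clustered", x$p_value))
  invisible(x)
}

#' Local Moran's I with conditional permutation p-values
#'
#' `I_i = z_i * (W z)_i / (sum(z^2) / n)`. Each unit's null holds its own
#' value fixed and permutes the remaining values among the other units;
#' p-values are upper-tail (local clustering) and Bonferroni-corrected
#' across units by default.
#'
#' @inheritParams morans_i
#' @param alpha Per-test significance level (applied to adjusted p-values).
#' @param adjust Multiple-testing correction (see [stats::p.adjust()]).
#' @return A `data.frame`: `unit`, `local_i`, `p`, `p_adj`, `significant`.
#' @export
local_morans_i <- function(values, W, n_perm = 1000, alpha = 0.05,
                           adjust = "bonferroni", seed = NULL) {
  n <- length(values)
  if (n < 8L) stop("need at least 8 spatial units")
  if (stats::sd(values) == 0) stop("zero variance in values")
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  li <- z * as.numeric(W %*% z) / m2
  with_seed_if(seed, {
    p <- vapply(seq_len(n), function(i) {
      wi <- W[i, -i]
      zi_rest <- z[-i]
      lag_null <- vapply(seq_len(n_perm), function(p_)
        sum(wi * sample(zi_rest)), numeric(1))
      null_i <- z[i] * lag_null / m2
      (1 + sum(null_i >= li[i])) / (n_perm + 1)
    }, numeric(1))
    p_adj <- stats::p.adjust(p, adjust)
    data.frame(unit = seq_len(n), local_i = li, p = p, p_adj = p_adj,
               significant = p_adj < alpha)
  })
}

#' Cliff's delta effect size
#'
#' `d = (#(x_i > y_j) - #(x_i < y_j)) / (n_x * n_y)`, in `[-1, 1]`.
#'
#' @param x,y Non-empty numeric samples.
#' @return Scalar effect size.
#' @export
cliffs_delta <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  ys <- sort(y)
  n_le <- findInterval(x, ys)                    # y_j <= x_i
  n_lt <- findInterval(x, ys, left.open = TRUE)  # y_j <  x_i
  greater <- sum(n_lt)
  less <- sum(length(y) - n_le)
  (greater - less) / (length(x) * length(y))
}

#' Expanding-circle neighbourhood profile
#'
#' At each radius, pools the pairwise statistic over all unordered cell pairs
#' within that anatomical distance (closed boundary: a neighbour exactly on
#' the circle is included), reports the median with a percentile-bootstrap
#' CI, and compares it to the median of `n_ctrl` size-matched random draws
#' from pairs at all distances.
#'
#' @param dist_matrix n x n distance matrix defining the circles (um for
#'   anatomical profiles, cm for field-space profiles).
#' @param stat_matrix n x n pairwise statistic (map correlation, field
#'   distance, anatomical distance, ...).
#' @param radii Strictly increasing radii (default 15 to 60 um in 5 um
#'   steps).
#' @param n_boot Bootstrap resamples for the CI.
#' @param n_ctrl Size-matched random-control iterations.
#' @param level CI level.
#' @param seed Optional integer seed.
#' @return A `data.frame` of class `neighborhood_profile`: `radius`,
#'   `n_pairs`, `median`, `lo`, `hi`, `control_median`,
#'   `control_inside_ci`. Radii with fewer than 2 pairs are reported with
#'   `NA` statistics.
#' @export
expanding_circle_profile <- function(dist_matrix, stat_matrix,
                                     radii = seq(15, 60, by = 5),
                                     n_boot = 10000, n_ctrl = 200,
                                     level = 0.99, seed = NULL) {
  if (any(diff(radii) <= 0)) stop("'radii' must be strictly increasing")
  ut <- upper.tri(dist_matrix)
  d <- dist_matrix[ut]
  s <- stat_matrix[ut]
  ok <- !is.na(s)
  d <- d[ok]; s <- s[ok]
  with_seed_if(seed, {
    rows <- lapply(radii, function(r) {
      v <- s[d <= r]
      if (length(v) < 2L) {
        return(data.frame(radius = r, n_pairs = length(v), median = NA_real_,
                          lo = NA_real_, hi = NA_real_,
                          control_median = NA_real_,
                          control_inside_ci = NA))
      }
      ci <- bootstrap_median_ci(v, n_boot = n_boot, level = level)
      ctrl <- stats::median(subset_medians_cpp(s, length(v),
                                               as.integer(n_ctrl)))
      data.frame(radius = r, n_pairs = length(v), median = ci$median,
                 lo = ci$lo, hi = ci$hi, control_median = ctrl,
                 control_inside_ci = ctrl >= ci$lo & ctrl <= ci$hi)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("neighborhood_profile", "data.frame")
    out
  })
}

#' Field-space neighbourhood profile
#'
#' Mirror of [expanding_circle_profile()] with the roles of anatomical and
#' field space swapped: circles expand over place-field distance (cm) and the
#' pooled statistic is the anatomical distance (um) between the pairs.
#'
#' @param field_dist_matrix n x n place-field distance matrix (cm).
#' @param anat_dist_matrix n x n anatomical distance matrix (um).
#' @param radii Field-distance radii in cm.
#' @inheritParams expanding_circle_profile
#' @return See [expanding_circle_profile()].
#' @export
fieldspace_profile <- function(field_dist_matrix, anat_dist_matrix,
                               radii = seq(5, 50, by = 5), n_boot = 10000,
                               n_ctrl = 200, level = 0.99, seed = NULL) {
  expanding_circle_profile(field_dist_matrix, anat_dist_matrix, radii,
                           n_boot = n_boot, n_ctrl = n_ctrl, level = level,
                           seed = seed)
}

#' Nearest-neighbour tuning comparison
#'
#' For each place cell, the pairwise statistic with its anatomically nearest
#' place-cell neighbour (ties broken by lowest cell index) is compared to the
#' statistic with a random partner from the same session (excluding self).
#' Global Moran's I is computed on the per-cell nearest-neighbour statistic
#' at the cell positions.
#'
#' The Moran permutation null reassigns cell identities (rows/columns of the
#' statistic matrix) over the anatomical positions and recomputes the
#' nearest-neighbour statistic, rather than permuting the derived values:
#' mutual nearest neighbours share an identical derived value, so a plain
#' value permutation is badly anti-conservative for this statistic.
#'
#' @param centroids n x 2 anatomical centroids (um).
#' @param stat_matrix n x n pairwise statistic.
#' @param weight_cutoff Cutoff (um) for the inverse-distance Moran weights.
#' @param n_perm Moran permutations.
#' @param seed Optional integer seed.
#' @return A list: `table` (`cell`, `neighbor`, `nn_dist`, `observed`,
#'   `random_partner`, `random`) and `moran` (a `moran_result`).
#' @export
nearest_neighbor_analysis <- function(centroids, stat_matrix,
                                      weight_cutoff = 90, n_perm = 1000,
                                      seed = NULL) {
  n <- nrow(centroids)
  if (n < 2L) stop("need at least 2 cells")
  d <- as.matrix(stats::dist(centroids))
  diag(d) <- Inf
  nn <- apply(d, 1, which.min)   # which.min takes the lowest index on ties
  with_seed_if(seed, {
    rnd <- vapply(seq_len(n), function(i) {
      j <- sample.int(n - 1L, 1L)
      if (j >= i) j + 1L else j
    }, integer(1))
    obs <- stat_matrix[cbind(seq_len(n), nn)]
    ran <- stat_matrix[cbind(seq_len(n), rnd)]
    tab <- data.frame(cell = seq_len(n), neighbor = nn,
                      nn_dist = d[cbind(seq_len(n), nn)], observed = obs,
                      random_partner = rnd, random = ran)
    W <- weights_inverse_distance(centroids, weight_cutoff)
    mor <- if (n >= 8L && stats::sd(obs[!is.na(obs)]) > 0) {
      fill <- function(v) { v[is.na(v)] <- mean(v, na.rm = TRUE); v }
      I <- moran_stat(fill(obs), W)
      null <- vapply(seq_len(n_perm), function(p) {
        perm <- sample.int(n)
        moran_stat(fill(stat_matrix[perm, perm][cbind(seq_len(n), nn)]), W)
      }, numeric(1))
      p95 <- stats::quantile(null, 0.95, names = FALSE)
      structure(list(I = I, expected = -1 / (n - 1), null = null, p95 = p95,
                     significant = I > p95,
                     p_value = (1 + sum(null >= I)) / (n_perm + 1)),
                class = "moran_result")
    } else NULL
    list(table = tab, moran = mor)
  })
}
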