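test_that("pair tables enumerate unordered pairs with exact geometry", {
  cent <- rbind(c(0, 0), c(350, 350), c(0, 350))
  fld <- rbind(c(10, 10), c(70, 70), c(10, 70))
  pt <- build_pair_table(cent, fld)
  expect_equal(nrow(pt), 3)                       # n(n-1)/2
  expect_equal(max(pt$anat_dist), sqrt(2) * 350, tolerance = 1e-12)
  expect_true(all(pt$cell_i < pt$cell_j))         # no self pairs
  expect_equal(nrow(build_pair_table(cent[1, , drop = FALSE],
                                     fld[1, , drop = FALSE])), 0)
  # close-pair flagging at 15 um
  cent2 <- rbind(c(0, 0), c(10, 0), c(100, 0))
  pt2 <- build_pair_table(cent2, fld)
  expect_equal(pt2$close_pair, c(TRUE, FALSE, FALSE))
})

test_that("KSG mutual information matches closed forms", {
  set.seed(1)
  x <- runif(1000)
  expect_gt(mutual_information_knn(x, x, seed = 2), 2)   # deterministic link

  x2 <- runif(10000); y2 <- runif(10000)
  expect_lt(mutual_information_knn(x2, y2, seed = 3), 0.01)

  # bivariate Gaussian rho = 0.6: MI = -log(1 - rho^2) / 2 = 0.2231 nats
  z1 <- rnorm(10000); z2 <- 0.6 * z1 + sqrt(1 - 0.36) * rnorm(10000)
  mi <- mutual_information_knn(z1, z2, seed = 4)
  expect_lt(abs(as.numeric(mi) - (-log(1 - 0.36) / 2)), 0.02)
  # binned estimator agrees as an independent cross-check
  expect_equal(mutual_information_binned(z1, z2), -log(1 - 0.36) / 2,
               tolerance = 0.05)

  m0 <- mutual_information_knn(rep(1, 200), rnorm(200))
  expect_equal(as.numeric(m0), 0)
  expect_true(attr(m0, "degenerate"))
})

test_that("within-bin similarity applies the membership and exclusion rules", {
  # 5 cells: three in one bin (one pair overlapping), two in another
  cent <- rbind(c(5, 5), c(10, 5), c(40, 5), c(100, 100), c(110, 100))
  stat <- matrix(0, 5, 5)
  stat[1, 2] <- stat[2, 1] <- 0.9    # excluded: 5 um apart
  stat[1, 3] <- stat[3, 1] <- 0.4
  stat[2, 3] <- stat[3, 2] <- 0.2
  stat[4, 5] <- stat[5, 4] <- 0.8
  grid <- anatomical_bin_grid(cent, fov_spec(), n_bins = 8)
  anat <- as.matrix(dist(cent))
  wb <- within_bin_similarity(grid, stat, anat)
  expect_equal(nrow(wb), 1)                  # 2-cell bin skipped
  expect_equal(wb$mean_stat, mean(c(0.4, 0.2)))  # overlap pair excluded
  wb2 <- within_bin_similarity(grid, stat, anat, exclusion = 0)
  expect_equal(wb2$mean_stat, mean(c(0.9, 0.4, 0.2)))
})

test_that("size-matched controls reproduce constant statistics exactly", {
  set.seed(2)
  cent <- matrix(runif(40, 0, 350), 20, 2)
  anat <- as.matrix(dist(cent))
  const <- matrix(0.5, 20, 20)
  ctrl <- size_matched_control(const, anat, bin_sizes = c(3, 4, 5),
                               n_iter = 25, seed = 3)
  expect_true(all(ctrl == 0.5))
  expect_error(size_matched_control(const, anat, bin_sizes = 30), "roster")
})

test_that("bootstrap median CIs match a brute-force oracle and nest", {
  b <- bootstrap_median_ci(rep(3, 10), n_boot = 500, seed = 1)
  expect_equal(c(b$median, b$lo, b$hi), c(3, 3, 3))

  x <- 1:5
  b2 <- bootstrap_median_ci(x, n_boot = 1e5, level = 0.99, seed = 2)
  expect_lte(b2$lo, 3); expect_gte(b2$hi, 3)
  # brute-force oracle: plain R resampling loop
  set.seed(3)
  meds <- replicate(2e4, median(sample(x, 5, replace = TRUE)))
  q <- quantile(meds, c(0.005, 0.995), names = FALSE)
  expect_equal(b2$lo, q[1], tolerance = 0.51)
  expect_equal(b2$hi, q[2], tolerance = 0.51)

  # CI width shrinks roughly like 1/sqrt(n)
  set.seed(4)
  w <- vapply(c(50, 200, 800), function(n) {
    ci <- bootstrap_median_ci(rnorm(n), n_boot = 3000)
    ci$hi - ci$lo
  }, numeric(1))
  expect_gt(w[1] / w[2], 1.4)
  expect_gt(w[2] / w[3], 1.4)

  # 99% CI contains the 95% CI on the same draw sequence
  y <- rexp(40)
  c99 <- bootstrap_median_ci(y, n_boot = 5000, level = 0.99, seed = 5)
  c95 <- bootstrap_median_ci(y, n_boot = 5000, level = 0.95, seed = 5)
  expect_lte(c99$lo, c95$lo)
  expect_gte(c99$hi, c95$hi)
  expect_error(bootstrap_median_ci(1), "at least 2")
})

test_that("global Moran's I matches direct formula, ape, and known cases", {
  # checkerboard with rook weights: perfect dispersion, I = -1
  v <- outer(1:4, 1:4, function(i, j) (-1)^(i + j))
  W <- weights_contiguity(4, 4, "rook")
  m <- morans_i(as.vector(v), W, n_perm = 200, seed = 1)
  expect_equal(m$I, -1, tolerance = 1e-12)
  expect_false(m$significant)

  # random instances: direct double-loop oracle to 1e-10, and ape cross-check
  skip_if_not_installed("ape")
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(8:50, 1)
    xy <- matrix(runif(2 * n, 0, 100), n, 2)
    vals <- rnorm(n)
    W <- weights_inverse_distance(xy, cutoff = 40)
    if (sum(W) == 0) next
    m <- morans_i(vals, W, n_perm = 10)
    z <- vals - mean(vals)
    acc <- 0
    for (i in 1:n) for (j in 1:n) acc <- acc + W[i, j] * z[i] * z[j]
    I_direct <- (n / sum(W)) * acc / sum(z^2)
    expect_equal(m$I, I_direct, tolerance = 1e-10)
    expect_equal(m$I, ape::Moran.I(vals, W)$observed, tolerance = 1e-10)
  }

  # a smooth gradient over positions is detected as clustered
  xy <- expand.grid(x = 1:8, y = 1:8)
  grad <- xy$x + xy$y + rnorm(64, 0, 0.3)
  Wg <- weights_inverse_distance(as.matrix(xy), cutoff = 2)
  mg <- morans_i(grad, Wg, n_perm = 500, seed = 3)
  expect_true(mg$significant)

  expect_error(morans_i(rep(1, 20), Wg[1:20, 1:20]), "variance")
  expect_error(morans_i(rnorm(5), matrix(1, 5, 5)), "at least 8")
})

test_that("local Moran's I decomposes the global statistic", {
  set.seed(5)
  xy <- matrix(runif(60, 0, 100), 30, 2)
  vals <- rnorm(30)
  W <- weights_inverse_distance(xy, cutoff = 50)
  g <- morans_i(vals, W, n_perm = 10)
  l <- local_morans_i(vals, W, n_perm = 100, seed = 6)
  # sum of local I equals S0 * global I (row-standardized: S0 = n)
  expect_equal(sum(l$local_i), sum(W) * g$I, tolerance = 1e-10)

  # isolated hot unit among cold neighbours has negative local I
  vals2 <- rep(-1, 30); vals2[7] <- 5
  l2 <- local_morans_i(vals2, W, n_perm = 50, seed = 7)
  expect_lt(l2$local_i[7], 0)
})

test_that("Cliff's delta matches exhaustive counting and is antisymmetric", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 2, 4)), -1 / 3)
  expect_equal(cliffs_delta(1:5, 1:5), 0)
  expect_equal(cliffs_delta(6:10, 1:5), 1)
  expect_error(cliffs_delta(numeric(), 1:3), "empty")
  set.seed(8)
  for (rep in 1:25) {
    x <- sample(0:20, sample(3:30, 1), replace = TRUE)
    y <- sample(0:20, sample(3:30, 1), replace = TRUE)
    d_oracle <- (sum(outer(x, y, ">")) - sum(outer(x, y, "<"))) /
      (length(x) * length(y))
    expect_equal(cliffs_delta(x, y), d_oracle, tolerance = 1e-12)
    expect_equal(cliffs_delta(x, y), -cliffs_delta(y, x), tolerance = 1e-12)
    expect_lte(abs(cliffs_delta(x, y)), 1)
  }
})

test_that("expanding-circle profiles use closed boundaries and honest nulls", {
  # neighbour exactly on the circle boundary is included
  cent <- rbind(c(0, 0), c(15, 0), c(200, 0), c(0, 200), c(200, 200),
                c(100, 100), c(300, 300), c(320, 300))
  stat <- matrix(rnorm(64), 8, 8); stat <- (stat + t(stat)) / 2
  anat <- as.matrix(dist(cent))
  pr <- expanding_circle_profile(anat, stat, radii = c(15, 20),
                                 n_boot = 200, n_ctrl = 20, seed = 1)
  # d(1,2) = 15 exactly -> included at radius 15; d(7,8) = 20 joins at 20
  expect_equal(pr$n_pairs[1], 1)
  expect_equal(pr$n_pairs[2], 2)
  expect_error(expanding_circle_profile(anat, stat, radii = c(20, 15)),
               "increasing")

  # uncoupled population: control median inside the 99% CI nearly everywhere
  pop <- place_field_population(300, active_fraction = 1, seed = 31)
  M <- expected_map_matrix(pop)
  corr <- pairwise_map_correlations(M)
  anat <- as.matrix(dist(pop$centroids))
  prof <- expanding_circle_profile(anat, corr, n_boot = 2000, n_ctrl = 100,
                                   seed = 32)
  expect_gte(sum(prof$control_inside_ci, na.rm = TRUE), 9)

  # strong coupling: smallest-radius median escapes the control
  popc <- place_field_population(300, active_fraction = 1,
                                 clustering = clustering_config(0.9, 100),
                                 seed = 33)
  Mc <- expected_map_matrix(popc)
  corrc <- pairwise_map_correlations(Mc)
  anatc <- as.matrix(dist(popc$centroids))
  profc <- expanding_circle_profile(anatc, corrc, n_boot = 2000,
                                    n_ctrl = 100, seed = 34)
  expect_false(profc$control_inside_ci[1])
  expect_gt(profc$median[1], profc$control_median[1])

  # field-space mirror: anatomical distance flat over field radii when
  # uncoupled, depressed at small field distances when coupled
  fld <- truth_fields(pop)
  pf <- fieldspace_profile(as.matrix(dist(fld)), anat, n_boot = 2000,
                           n_ctrl = 100, seed = 35)
  expect_gte(sum(pf$control_inside_ci, na.rm = TRUE), 8)  # single session
  fldc <- truth_fields(popc)
  pfc <- fieldspace_profile(as.matrix(dist(fldc)), anatc, n_boot = 2000,
                            n_ctrl = 100, seed = 36)
  expect_false(pfc$control_inside_ci[1])
  expect_lt(pfc$median[1], pfc$control_median[1])
})

test_that("nearest-neighbour analysis pairs every cell and ties by index", {
  cent <- rbind(c(0, 0), c(10, 0))
  stat <- matrix(c(NA, 0.4, 0.4, NA), 2, 2)
  nn <- nearest_neighbor_analysis(cent, stat, seed = 1)
  expect_equal(nn$table$neighbor, c(2L, 1L))      # each other's neighbour

  # tie broken by lowest cell index
  cent3 <- rbind(c(0, 0), c(10, 0), c(-10, 0))
  stat3 <- matrix(0, 3, 3)
  nn3 <- nearest_neighbor_analysis(cent3, stat3, seed = 2)
  expect_equal(nn3$table$neighbor[1], 2L)

  # uncoupled population: observed and random-partner medians agree
  pop <- place_field_population(300, active_fraction = 1, seed = 41)
  corr <- pairwise_map_correlations(expected_map_matrix(pop))
  res <- nearest_neighbor_analysis(pop$centroids, corr, n_perm = 300,
                                   seed = 42)
  expect_false(res$moran$significant)
  expect_lt(abs(median(res$table$observed) - median(res$table$random)), 0.08)
})
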