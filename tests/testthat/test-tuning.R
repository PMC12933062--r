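test_that("tuning map geometry and occupancy normalization are exact", {
  # 80 cm arena at 2.5 cm bins -> 32 x 32 grid
  tr <- simulate_trajectory(duration = 60, seed = 1)
  m <- compute_tuning_map(tr, data.frame(t = numeric(), amplitude = numeric()))
  expect_equal(dim(m$rate), c(32, 32))
  # no events -> zero rate on every visited bin
  expect_true(all(m$rate[m$visited] == 0))

  # toy 2-bin world: 3 amplitude-1 events in 6 s in bin 1, none in bin 2
  dt <- 1
  tr2 <- make_trajectory(x = c(rep(1, 6), rep(4, 6)), y = rep(1, 12), dt = dt,
                         arena = arena_spec(5))
  ev <- data.frame(t = c(0.5, 2.5, 4.5), amplitude = 1)
  m2 <- compute_tuning_map(tr2, ev, bin_size = 2.5, smooth = FALSE)
  expect_equal(m2$rate_raw[1, 1], 0.5)
  expect_equal(m2$rate_raw[2, 1], 0)

  # conservation: sum(rate_raw * occupancy) equals the total event amplitude
  tr3 <- simulate_trajectory(duration = 300, seed = 2)
  ev3 <- data.frame(t = runif(200, 0, 300), amplitude = rexp(200))
  m3 <- compute_tuning_map(tr3, ev3, smooth = FALSE)
  expect_equal(sum(m3$rate_raw * m3$occupancy, na.rm = TRUE),
               sum(ev3$amplitude), tolerance = 1e-10)

  expect_error(compute_tuning_map(tr3[0, ], ev3), "occupancy")
})

test_that("mask-normalized smoothing preserves mass and constants", {
  set.seed(3)
  r <- matrix(rexp(1024), 32, 32)
  m <- make_map(r)
  sm <- placetopo:::smooth_masked(r, matrix(TRUE, 32, 32), 2.5)
  expect_equal(sum(sm), sum(r), tolerance = 1e-6)       # mass conserved
  cm <- placetopo:::smooth_masked(matrix(5, 32, 32), matrix(TRUE, 32, 32), 2.5)
  expect_equal(max(abs(cm - 5)), 0, tolerance = 1e-12)  # constants fixed

  # unvisited bins do not dilute their neighbours
  vis <- matrix(TRUE, 32, 32); vis[1:16, ] <- FALSE
  cm2 <- placetopo:::smooth_masked(matrix(5, 32, 32), vis, 2.5)
  expect_equal(max(abs(cm2[vis] - 5)), 0, tolerance = 1e-12)
  expect_true(all(is.na(cm2[!vis])))
})

test_that("speed filtering removes immobility from occupancy and events", {
  tr <- simulate_trajectory(duration = 120, seed = 4)
  ev <- data.frame(t = runif(50, 0, 120), amplitude = 1)
  # v_min = 0 is the identity
  sf0 <- speed_filter(tr, ev, v_min = 0)
  expect_equal(nrow(sf0$traj), nrow(tr))
  expect_equal(nrow(sf0$events), nrow(ev))

  # a stationary epoch contributes no occupancy at v_min = 2
  still <- make_trajectory(x = rep(70, 150), y = rep(70, 150))
  still$t <- still$t + max(tr$t) + 1 / 15
  both <- rbind(as.data.frame(tr), as.data.frame(still))
  attr(both, "arena") <- arena_spec(); attr(both, "dt") <- 1 / 15
  class(both) <- c("trajectory", "data.frame")
  m_aug <- compute_tuning_map(speed_filter(both, v_min = 2)$traj,
                              data.frame(t = numeric(), amplitude = numeric()))
  m_raw <- compute_tuning_map(speed_filter(both, v_min = 0)$traj,
                              data.frame(t = numeric(), amplitude = numeric()))
  # the 10 s stationary epoch is gone (only splice-jump frames may remain)
  expect_gt(m_raw$occupancy[29, 29], 9)
  expect_lt(m_aug$occupancy[29, 29], 0.3)

  expect_error(speed_filter(tr, v_min = 1e5), "every sample")
})

test_that("map correlation behaves over the common visited mask", {
  a <- make_map(gauss_map(20, 20))
  expect_equal(map_correlation(a, a), 1)

  # spatially shuffled self decorrelates on average
  set.seed(5)
  r <- vapply(1:200, function(i) {
    b <- a
    b$rate <- matrix(sample(a$rate), 32, 32)
    map_correlation(a, b)
  }, numeric(1))
  expect_lt(abs(mean(r)), 0.02)

  # two disjoint single fields are negatively correlated
  b <- make_map(gauss_map(60, 60))
  expect_lt(map_correlation(a, b), 0)

  # zero variance -> NA; disjoint masks -> error
  flat <- make_map(matrix(1, 32, 32))
  expect_true(is.na(map_correlation(a, flat)))
  half1 <- make_map(rbind(matrix(1, 16, 32), matrix(NA, 16, 32)))
  half2 <- make_map(rbind(matrix(NA, 16, 32), matrix(1, 16, 32)))
  expect_error(map_correlation(half1, half2), "disjoint")
})

test_that("rotating the world rotates the tuning map", {
  tr <- simulate_trajectory(duration = 600, seed = 6)
  ev <- data.frame(t = runif(400, 0, 600), amplitude = 1)
  m <- compute_tuning_map(tr, ev)
  tr_rot <- tr
  tr_rot$x <- 80 - tr$y
  tr_rot$y <- tr$x
  m_rot <- compute_tuning_map(tr_rot, ev)
  rot90 <- function(mm) t(mm)[nrow(mm):1, ]
  expect_equal(m_rot$rate, rot90(m$rate), tolerance = 1e-10)
})

test_that("field detection finds bumps with the stated tie rules", {
  m <- make_map(gauss_map(40, 40))
  f <- detect_fields(m)
  expect_length(f, 1)
  expect_lt(sqrt(sum((field_centroid(f[[1]]) - c(40, 40))^2)), 2.5)

  # two equal bumps -> two fields; main is the lowest (row, col) peak
  m2 <- make_map(gauss_map(20, 20) + gauss_map(60, 60))
  f2 <- detect_fields(m2)
  expect_length(f2, 2)
  expect_true(all(f2[[1]]$peak_bin <= f2[[2]]$peak_bin))

  # uniform map: single whole-arena component fails the max-area rule
  expect_length(detect_fields(make_map(matrix(1, 32, 32)),
                              threshold_fraction = 0.2), 0)
  # all-zero map -> no fields
  expect_length(detect_fields(make_map(matrix(0, 32, 32))), 0)
})

test_that("component labelling matches a brute-force oracle", {
  set.seed(7)
  for (i in 1:20) {
    mask <- matrix(runif(100) < 0.4, 10, 10)
    lab <- placetopo:::label_components(mask)
    # oracle: repeated neighbour dilation from each unlabeled seed
    oracle <- matrix(0L, 10, 10)
    cur <- 0L
    for (s in which(mask)) {
      if (oracle[s] != 0L) next
      cur <- cur + 1L
      comp <- s
      repeat {
        grow <- unique(unlist(lapply(comp, function(p) {
          i0 <- (p - 1) %% 10 + 1; j0 <- (p - 1) %/% 10 + 1
          c(if (i0 > 1) p - 1, if (i0 < 10) p + 1,
            if (j0 > 1) p - 10, if (j0 < 10) p + 10)
        })))
        grow <- grow[mask[grow] & !(grow %in% comp)]
        if (!length(grow)) break
        comp <- c(comp, grow)
      }
      oracle[comp] <- cur
    }
    # same partition (labels may differ in order)
    expect_equal(lab > 0, oracle > 0)
    expect_equal(length(unique(lab[lab > 0])), length(unique(oracle[oracle > 0])))
    for (l in unique(lab[lab > 0]))
      expect_length(unique(oracle[lab == l]), 1)
  }
})

test_that("spatial information has its closed-form values", {
  # uniform map -> 0 bits
  expect_equal(spatial_information(make_map(matrix(2, 8, 8))), 0)
  # one-hot over N equally occupied bins -> log2(N), exactly
  for (N in c(4, 16, 64)) {
    n <- sqrt(N)
    r <- matrix(0, n, n); r[1, 1] <- 2
    expect_equal(spatial_information(make_map(r)), log2(N))
  }
  expect_error(spatial_information(make_map(matrix(0, 4, 4))), "undefined")
})

test_that("object maps bin distance and angle allocentrically", {
  # animal due east of the object at 10 cm whenever events occur
  dt <- 1 / 15
  ang <- seq(0, 2 * pi, length.out = 400)
  tr <- make_trajectory(x = 40 + 15 * cos(ang), y = 40 + 15 * sin(ang), dt = dt)
  tr <- rbind(as.data.frame(tr), data.frame(t = max(tr$t) + (1:100) * dt,
                                            x = 50, y = 40, speed = 10))
  attr(tr, "arena") <- arena_spec(); attr(tr, "dt") <- dt
  class(tr) <- c("trajectory", "data.frame")
  ev <- data.frame(t = max(tr$t) - (1:50) * dt, amplitude = 1)
  om <- compute_object_map(tr, ev, object_xy = c(40, 40), smooth = FALSE, min_occupancy = 0)
  hot <- which(om$rate_raw > 0, arr.ind = TRUE)
  expect_equal(unique(om$dist_centers[hot[, 1]]), 11)   # bin [10, 12) cm
  expect_equal(unique(om$angle_centers[hot[, 2]]), 3)   # bin [0, 6) deg

  # object at the corner: distances beyond the arena are never visited
  om2 <- compute_object_map(tr, ev, object_xy = c(0, 0), max_dist = 120)
  far <- om2$dist_centers > 115
  expect_false(any(om2$visited[far, ]))

  # circular angle smoothing wraps: uniform ring stays uniform across 0/360
  omr <- compute_object_map(tr[1:400, ], data.frame(t = tr$t[1:400],
                                                    amplitude = 1),
                            object_xy = c(40, 40), min_occupancy = 0)
  ring <- omr$rate[which.min(abs(omr$dist_centers - 15)), ]
  expect_lt(stats::sd(ring) / mean(ring), 0.1)
})
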