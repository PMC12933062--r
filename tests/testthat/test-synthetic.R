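test_that("trajectories stay in the arena, are deterministic, and cover it", {
  arena <- arena_spec()
  # very short session still yields at least one in-bounds sample
  tr <- simulate_trajectory(arena, duration = 0.1, seed = 1)
  expect_gte(nrow(tr), 1)
  expect_true(all(tr$x >= 0 & tr$x <= 80 & tr$y >= 0 & tr$y <= 80))

  expect_identical(simulate_trajectory(arena, 60, seed = 7),
                   simulate_trajectory(arena, 60, seed = 7))
  expect_error(simulate_trajectory(arena, duration = 0), "positive")
  expect_error(simulate_trajectory(arena, 10, mean_speed = -1), "positive")

  # a 35-minute session visits at least 95% of the 2.5 cm bins
  tr <- simulate_trajectory(arena, duration = 2100, seed = 11)
  bi <- unique(paste(pmin(floor(tr$x / 2.5), 31), pmin(floor(tr$y / 2.5), 31)))
  expect_gte(length(bi) / 1024, 0.95)
})

test_that("uncoupled populations have anatomy-independent fields", {
  r_all <- vapply(1:20, function(s) {
    pop <- place_field_population(500, seed = s)
    da <- as.vector(dist(pop$centroids))
    df <- as.vector(dist(truth_fields(pop)))
    cor(da, df)
  }, numeric(1))
  expect_lt(abs(mean(r_all)), 0.02)
  expect_lt(max(abs(r_all)), 0.08)
})

test_that("strong coupling makes field distance track anatomical distance", {
  stats_ <- vapply(1:20, function(s) {
    pop <- place_field_population(
      500, clustering = clustering_config(1, 150), seed = 100 + s)
    da <- as.vector(dist(pop$centroids))
    df <- as.vector(dist(truth_fields(pop)))
    w <- da <= 150
    # binned conditional means of field distance over anatomical distance
    b <- cut(da[w], seq(0, 150, by = 30))
    mono <- unname(tapply(df[w], b, mean))
    c(r = cor(da[w], df[w]), first = mono[1], last = mono[length(mono)],
      nn_ratio = {
        dm <- as.matrix(dist(pop$centroids)); diag(dm) <- Inf
        nn <- apply(dm, 1, which.min)
        fld <- truth_fields(pop)
        median(sqrt(rowSums((fld - fld[nn, ])^2))) / median(dist(fld))
      })
  }, numeric(4))
  # positive relation within the patch scale, monotone conditional mean
  expect_gt(mean(stats_["r", ]), 0.15)
  expect_true(all(stats_["r", ] > 0))
  expect_true(all(stats_["last", ] > stats_["first", ]))
  # nearest neighbours end up with much closer fields than random pairs
  expect_lt(mean(stats_["nn_ratio", ]), 0.5)
})

test_that("population geometry and activity respect their contracts", {
  pop <- place_field_population(400, active_fraction = 0.35, seed = 3)
  d <- dist(pop$centroids)
  expect_gte(min(d), 10)                       # minimum somatic spacing
  expect_true(all(pop$centroids >= 0 & pop$centroids <= 350))
  for (f in pop$fields) expect_true(all(f >= 0 & f <= 80))
  # ~35% active per environment
  expect_gt(mean(pop$active), 0.28)
  expect_lt(mean(pop$active), 0.42)
  expect_error(place_field_population(10, active_fraction = 0), "active_fraction")
  expect_error(place_field_population(10000), "packing capacity")
})

test_that("event generation follows the intensity model", {
  pop <- place_field_population(1, active_fraction = 1, two_field_prob = 0,
                                seed = 5)
  pop$fields[[1]] <- matrix(c(40, 40), 1, 2)
  pop$sigma <- 6
  tr <- simulate_trajectory(duration = 2100, seed = 6)

  # zero intensity -> empty event train
  pop0 <- pop
  pop0$peak_rate <- 0
  rec0 <- generate_events(pop0, 1, tr, noise_rate = 0, seed = 7)
  expect_equal(nrow(rec0$events), 0)

  # field recovered by direct histogramming (raw rate argmax near truth)
  pop$peak_rate <- 1
  rec <- generate_events(pop, 1, tr, seed = 7)
  expect_true(all(rec$events$t >= 0 & rec$events$t <= max(tr$t) + 1 / 15))
  sf <- speed_filter(tr, rec$events)
  m <- compute_tuning_map(sf$traj, sf$events)
  pk <- which(m$rate == max(m$rate, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_lt(sqrt(sum(((pk - 0.5) * 2.5 - c(40, 40))^2)), 5)
  # cross-check: amplitude-weighted mean event position
  ev_mean <- c(weighted.mean(tr$x[findInterval(rec$events$t, tr$t)],
                             rec$events$amplitude),
               weighted.mean(tr$y[findInterval(rec$events$t, tr$t)],
                             rec$events$amplitude))
  expect_lt(sqrt(sum((ev_mean - c(40, 40))^2)), 5)

  # doubling the peak rate doubles the expected event count
  tr_s <- simulate_trajectory(duration = 300, seed = 8)
  n1 <- vapply(1:50, function(s)
    nrow(generate_events(pop, 1, tr_s, noise_rate = 0, seed = s)$events),
    numeric(1))
  pop2 <- pop
  pop2$peak_rate <- 2
  n2 <- vapply(1:50, function(s)
    nrow(generate_events(pop2, 1, tr_s, noise_rate = 0, seed = 1000 + s)$events),
    numeric(1))
  expect_gt(mean(n2) / mean(n1), 1.8)
  expect_lt(mean(n2) / mean(n1), 2.2)
})

test_that("sessions are reproducible end-to-end under a fixed seed", {
  pop <- place_field_population(5, seed = 1)
  s1 <- generate_session(pop, duration = 120, seed = 10)
  s2 <- generate_session(pop, duration = 120, seed = 10)
  expect_identical(s1, s2)
})

test_that("remapping pairs preserve or redraw field layouts as requested", {
  pop <- place_field_population(200, active_fraction = 0.35, seed = 21)
  pres <- generate_remapping_pair(pop, "preserved")
  expect_identical(pres$A$fields, pres$B$fields)

  orth <- generate_remapping_pair(pop, "orthogonal", seed = 22)
  expect_false(identical(orth$A$fields, orth$B$fields))
  expect_error(generate_remapping_pair(pop, "sideways"))

  # orthogonal active subsets are redrawn independently: joint fraction is
  # approximately the product of the marginals
  joint <- mean(orth$A$active & orth$B$active)
  expect_gt(joint, 0.05)
  expect_lt(joint, 0.21)

  # orthogonal-mode tuning-map correlations look like random pairings, not 1
  sub <- which(orth$A$active & orth$B$active)
  ma <- t(vapply(sub, function(i) as.vector(expected_rate_map(orth$A, i)),
                 numeric(1024)))
  mb <- t(vapply(sub, function(i) as.vector(expected_rate_map(orth$B, i)),
                 numeric(1024)))
  same_cell <- vapply(seq_along(sub), function(k) cor(ma[k, ], mb[k, ]),
                      numeric(1))
  rand_pair <- cor(t(ma), t(mb))[upper.tri(diag(length(sub)))]
  expect_lt(abs(median(same_cell) - median(rand_pair)), 0.1)
  expect_lt(median(same_cell), 0.5)
})

test_that("preserved maps with fresh event noise stay highly correlated", {
  fx <- small_session(n_cells = 25, duration = 1200, seed = 31)
  s2 <- generate_session(fx$pop, duration = 1200, seed = 32)
  maps1 <- session_tuning_maps(fx$session)
  maps2 <- session_tuning_maps(s2)
  r <- vapply(seq_len(25), function(i)
    map_correlation(maps1[[i]], maps2[[i]]), numeric(1))
  expect_gt(median(r, na.rm = TRUE), 0.6)
})

test_that("object sessions implement the vector model", {
  pop <- place_field_population(300, active_fraction = 0.35, seed = 41)
  expect_error(generate_object_session(pop, c(90, 40)), "inside the arena")

  pop <- assign_object_vectors(pop, object_fraction = 0.5, seed = 42)
  tuned <- which(pop$object_tuned)
  expect_gt(length(tuned), 100)
  expect_true(all(pop$object_vector[tuned, 1] >= 0))

  # preferred angles are drawn uniformly: Rayleigh test non-significant
  rt <- rayleigh_uniformity(pop$object_vector[tuned, 2])
  expect_gt(rt$p, 0.01)

  # the same vector is reused when the object moves: expected firing location
  # shifts exactly with the object (construction)
  i <- tuned[1]
  pop$active[i] <- FALSE   # isolate the object response from any place field
  tr <- simulate_trajectory(duration = 2100, seed = 43)
  sf <- speed_filter(tr)
  loc_of_peak <- function(object_xy) {
    rec <- generate_events(pop, i, tr, object_xy = object_xy, seed = 44)
    keep <- attr(sf$traj, "keep")
    idx <- keep[findInterval(rec$events$t, tr$t)]
    m <- compute_tuning_map(sf$traj, rec$events[idx, ], smooth = TRUE)
    f <- detect_fields(m)
    f[[1]]$centroid
  }
  v <- pop$object_vector[i, ]
  expected1 <- c(30, 40) + v[1] * c(cos(v[2] * pi / 180), sin(v[2] * pi / 180))
  p1 <- loc_of_peak(c(30, 40))
  p2 <- loc_of_peak(c(50, 40))
  expect_lt(sqrt(sum((p1 - expected1)^2)), 7)
  expect_lt(sqrt(sum((p2 - p1) - c(20, 0))^2), 7)
})
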