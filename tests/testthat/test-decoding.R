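test_that("the decoder splits time into interleaved train/test bins", {
  fx <- small_session(n_cells = 15, duration = 2100, seed = 1)
  model <- fit_decoder(fx$session)
  tb <- model$tbin
  # 2100 s at 0.5 s -> 2100 train and 2100 test bins, disjoint, alternating
  expect_equal(length(unique(tb[model$is_train])), 2100)
  expect_equal(length(unique(tb[!model$is_train])), 2100)
  expect_length(intersect(unique(tb[model$is_train]),
                          unique(tb[!model$is_train])), 0)
  expect_true(all(diff(sort(unique(tb[model$is_train]))) == 2))
  # refitting is deterministic
  expect_identical(model$log_rate, fit_decoder(fx$session)$log_rate)
  expect_error(fit_decoder(fx$session, bin_width = 60), "100 training")
})

test_that("log-domain posterior matches a direct-product oracle", {
  fx <- small_session(n_cells = 5, duration = 600, seed = 2)
  model <- fit_decoder(fx$session, bin_size = 20)   # <= 16 spatial bins
  res <- decode_position(model, fx$session, return_posterior = TRUE)
  # posterior rows are normalized
  expect_true(all(abs(rowSums(res$posterior) - 1) < 1e-9))

  # direct-product oracle on raw probabilities
  traj <- fx$session$traj
  lam <- exp(model$log_rate) * model$bin_width
  prior <- exp(model$log_prior)
  spd_keep <- attr(speed_filter(traj, v_min = model$v_min)$traj, "keep")
  use <- !model$is_train & spd_keep
  test_bins <- sort(unique(model$tbin[use]))
  for (b in sample(seq_along(test_bins), 25)) {
    k <- vapply(seq_along(model$cell_idx), function(ci) {
      ev <- fx$session$cells[[model$cell_idx[ci]]]$events
      fr <- placetopo:::event_frames(ev$t, traj$t)
      sum(ev$amplitude[use[fr] & model$tbin[fr] == test_bins[b]])
    }, numeric(1))
    post_direct <- prior * apply(lam^k * exp(-lam), 2, prod)
    expect_equal(which.max(res$posterior[b, ]), which.max(post_direct))
    expect_equal(res$posterior[b, ], post_direct / sum(post_direct),
                 tolerance = 1e-8)
  }
})

test_that("uninformative cells do not move the decoded position", {
  fx <- small_session(n_cells = 8, duration = 600, seed = 3)
  model <- fit_decoder(fx$session, bin_size = 10)
  res1 <- decode_position(model, fx$session)
  # append a uniform-rate cell: constant likelihood across space
  model2 <- model
  model2$log_rate <- rbind(model$log_rate, log(rep(0.5, ncol(model$log_rate))))
  model2$cell_idx <- c(model$cell_idx, length(fx$session$cells) + 1L)
  sess2 <- fx$session
  sess2$cells[[length(sess2$cells) + 1L]] <- structure(
    list(cell_id = 999L,
         events = data.frame(t = seq(1, 599, by = 2), amplitude = 1),
         dff = NULL, centroid = c(0, 0)), class = "cell_recording")
  res2 <- decode_position(model2, sess2)
  expect_equal(res2$table$decoded_x, res1$table$decoded_x)
  expect_equal(res2$table$decoded_y, res1$table$decoded_y)
})

test_that("synthetic place-cell populations decode far above chance", {
  fx <- small_session(n_cells = 80, duration = 1200, seed = 4)
  cl_idx <- seq_len(80)
  model <- fit_decoder(fx$session)
  res <- decode_position(model, fx$session)
  set.seed(5)
  chance <- median(sqrt(rowSums((matrix(runif(4000, 0, 80), 2000, 2) -
                                 matrix(runif(4000, 0, 80), 2000, 2))^2)))
  expect_lt(res$median_error, chance / 2)
  # more cells decode better
  res_small <- decode_position(model, fx$session, cell_subset = 1:10)
  expect_lt(res$median_error, res_small$median_error)
})

test_that("local and similar-tuned subset machinery respects its contracts", {
  fx <- small_session(n_cells = 40, duration = 900, seed = 6)
  model <- fit_decoder(fx$session)
  tab <- local_vs_random_decoding(model, fx$session, fx$pop$centroids,
                                  radii = c(60, 120), n_ref = 3,
                                  n_random = 3, seed = 7)
  expect_true(all(tab$n_cells >= 2))
  expect_true(all(tab$error_local > 0 & tab$error_random_mean > 0))

  fld <- truth_fields(fx$pop)
  expect_setequal(similar_tuning_subset(fld, 40, seed = 8), 1:40)
  sub <- similar_tuning_subset(fld, 10, anchor = c(40, 40))
  d <- sqrt(rowSums((fld - 40)^2))
  expect_setequal(sub, order(d)[1:10])
  expect_error(similar_tuning_subset(fld, 99), "roster")
})
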