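#' Fit a Bayesian position decoder on alternating temporal bins
#'
#' Time is divided into bins of `bin_width` seconds which alternate between
#' training and test. Per-cell expected event rates per spatial bin are fit
#' as tuning maps on the training frames only (speed-filtered), and the
#' spatial prior is the training occupancy. Rates are floored to avoid
#' log(0).
#'
#' @param session A session whose cells will be used for decoding (typically
#'   the classified place cells).
#' @param cell_idx Indices of the cells to include (default all).
#' @param bin_width Temporal bin width, seconds.
#' @param bin_size,sigma Spatial map parameters.
#' @param v_min Speed threshold, cm/s (applied to training and test).
#' @param rate_floor Minimum expected rate per spatial bin, events/s.
#' @param flat_prior Use a flat prior over visited bins instead of the
#'   training occupancy.
#' @return An object of class `decoder_model`: `log_rate` (cells x visited
#'   spatial bins), `rate_sum`, `log_prior`, `bin_xy` (visited-bin centres),
#'   `bin_width`, per-frame metadata for test-bin extraction.
#' @export
fit_decoder <- function(session, cell_idx = NULL, bin_width = 0.5,
                        bin_size = 2.5, sigma = 2.5, v_min = 2,
                        rate_floor = 1e-3, flat_prior = FALSE) {
  traj <- session$traj
  dt <- attr(traj, "dt") %||% stats::median(diff(traj$t))
  cell_idx <- cell_idx %||% seq_along(session$cells)
  tbin <- floor(traj$t / bin_width)
  is_train <- tbin %% 2 == 0
  n_train_bins <- length(unique(tbin[is_train]))
  if (n_train_bins < 100L)
    stop("session too short: fewer than 100 training bins")
  # training machinery: speed filter restricted to training frames
  tr_train <- traj[is_train, , drop = FALSE]
  attr(tr_train, "arena") <- attr(traj, "arena")
  attr(tr_train, "dt") <- dt
  class(tr_train) <- class(traj)
  mm <- map_machinery(tr_train, bin_size = bin_size, sigma = sigma,
                      v_min = v_min)
  vis <- as.vector(mm$visited)
  rates <- vapply(cell_idx, function(ci) {
    ev <- session$cells[[ci]]$events
    fr_all <- event_frames(ev$t, traj$t)
    keep_ev <- is_train[fr_all]
    fr_tr <- event_frames(ev$t[keep_ev], tr_train$t)
    r <- rate_map_from_bins(mm, mm$bi[fr_tr], ev$amplitude[keep_ev])
    pmax(as.vector(r)[vis], rate_floor)
  }, numeric(sum(vis)))
  rates <- t(rates)   # cells x visited bins
  prior <- if (flat_prior) rep(1 / sum(vis), sum(vis)) else {
    p <- as.vector(mm$occ)[vis]
    p / sum(p)
  }
  ctr <- bin_centers(mm$arena$side_length, bin_size)
  nb <- mm$nb
  xy <- cbind(rep(ctr, nb)[vis], rep(ctr, each = nb)[vis])
  # grid row/col of each visited bin, for the argmax tie-break convention
  rc <- cbind(((which(vis) - 1L) %% nb) + 1L, ((which(vis) - 1L) %/% nb) + 1L)
  structure(list(log_rate = log(rates), rate_sum = colSums(rates),
                 log_prior = log(prior), bin_xy = xy, bin_rc = rc,
                 cell_idx = cell_idx, bin_width = bin_width,
                 bin_size = bin_size, v_min = v_min, dt = dt,
                 is_train = is_train, tbin = tbin),
            class = "decoder_model")
}

#' Decode position on the held-out test bins
#'
#' Per test bin, the log posterior over visited spatial bins is
#' `log prior + sum_c [ k_c log(rate_c dt) - rate_c dt ]` with `k_c` the
#' (amplitude-summed) event count of cell `c` in the bin; the decoded
#' position is the argmax bin centre (ties broken by lowest (row, col)).
#' Immobility frames are excluded from both event counts and the true
#' position; test bins with no speed-passing frame are skipped.
#'
#' @param model A [fit_decoder()] model.
#' @param session The session decoded (provides events and true positions).
#' @param cell_subset Optional subset (indices into `model$cell_idx`) to
#'   decode from, e.g. an anatomically local group.
#' @param return_posterior Return the full posterior matrix (test bins x
#'   spatial bins), normalized to sum to one per bin.
#' @return An object of class `decoding_result`: `table` (`data.frame` with
#'   `tbin`, `decoded_x/y`, `true_x/y`, `error`), `median_error` (cm),
#'   `n_cells`, and optionally `posterior`.
#' @export
decode_position <- function(model, session, cell_subset = NULL,
                            return_posterior = FALSE) {
  traj <- session$traj
  sub <- cell_subset %||% seq_along(model$cell_idx)
  cells <- model$cell_idx[sub]
  spd_keep <- attr(speed_filter(traj, v_min = model$v_min)$traj, "keep")
  use_frame <- !model$is_train & spd_keep
  if (!any(use_frame)) stop("no usable test frames")
  tb <- model$tbin
  test_bins <- sort(unique(tb[use_frame]))
  bin_of <- match(tb, test_bins)          # NA for train bins
  bin_of[!use_frame] <- NA
  ntb <- length(test_bins)
  # per-cell amplitude-summed counts per test bin
  K <- matrix(0, length(cells), ntb)
  for (r in seq_along(cells)) {
    ev <- session$cells[[cells[r]]]$events
    fr <- event_frames(ev$t, traj$t)
    b <- bin_of[fr]
    ok <- !is.na(b)
    if (any(ok)) {
      s <- rowsum(ev$amplitude[ok], b[ok])
      K[r, as.integer(rownames(s))] <- s
    }
  }
  lam_dt <- model$bin_width
  LR <- model$log_rate[sub, , drop = FALSE] + log(lam_dt)
  const <- -lam_dt * colSums(exp(model$log_rate[sub, , drop = FALSE]))
  LL <- crossprod(K, LR)                                   # test bins x space
  LL <- sweep(LL, 2, const + model$log_prior, `+`)
  # argmax with lowest-(row, col) tie-break
  dec <- apply(LL, 1, function(v) {
    cand <- which(v == max(v))
    if (length(cand) > 1L) {
      o <- order(model$bin_rc[cand, 1], model$bin_rc[cand, 2])
      cand <- cand[o]
    }
    cand[1]
  })
  # true position: mean of speed-passing frames per test bin
  tx <- rowsum(traj$x[use_frame], bin_of[use_frame]) /
    tabulate(bin_of[use_frame], ntb)
  ty <- rowsum(traj$y[use_frame], bin_of[use_frame]) /
    tabulate(bin_of[use_frame], ntb)
  err <- sqrt((model$bin_xy[dec, 1] - tx)^2 + (model$bin_xy[dec, 2] - ty)^2)
  out <- list(table = data.frame(tbin = test_bins,
                                 decoded_x = model$bin_xy[dec, 1],
                                 decoded_y = model$bin_xy[dec, 2],
                                 true_x = as.numeric(tx),
                                 true_y = as.numeric(ty),
                                 error = as.numeric(err)),
              median_error = stats::median(err), n_cells = length(cells))
  if (return_posterior) {
    P <- exp(LL - apply(LL, 1, max))
    out$posterior <- P / rowSums(P)
  }
  structure(out, class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d cells, %d test bins, median error %.2f cm\n",
              x$n_cells, nrow(x$table), x$median_error))
  invisible(x)
}

#' Local versus random-subset decoding comparison
#'
#' For each of `n_ref` reference place cells and each anatomical radius,
#' decodes position from the cells within the radius of the reference cell
#' and compares the median error to `n_random` size-matched random subsets
#' from the same session. Cell-radius entries with fewer than 2 cells are
#' skipped.
#'
#' @param model A fitted [fit_decoder()] model (over the place cells).
#' @param session The session.
#' @param centroids Anatomical centroids (um) of the model's cells, in model
#'   cell order.
#' @param radii Anatomical radii, um.
#' @param n_ref Number of reference cells (sampled without replacement).
#' @param n_random Size-matched random subsets per test.
#' @param seed Optional integer seed.
#' @return A `data.frame`: `reference`, `radius`, `n_cells`,
#'   `error_local`, `error_random_mean` (mean of the `n_random` subset
#'   median errors).
#' @export
local_vs_random_decoding <- function(model, session, centroids,
                                     radii = c(20, 40, 60, 80, 100),
                                     n_ref = 20, n_random = 25, seed = NULL) {
  n <- length(model$cell_idx)
  stopifnot(nrow(centroids) == n)
  d <- as.matrix(stats::dist(centroids))
  with_seed_if(seed, {
    refs <- sample.int(n, min(n_ref, n))
    rows <- list()
    for (ref in refs) {
      for (r in radii) {
        loc <- which(d[ref, ] <= r)
        if (length(loc) < 2L) next
        e_loc <- decode_position(model, session, loc)$median_error
        e_rnd <- vapply(seq_len(n_random), function(it) {
          decode_position(model, session,
                          sample.int(n, length(loc)))$median_error
        }, numeric(1))
        rows[[length(rows) + 1L]] <-
          data.frame(reference = ref, radius = r, n_cells = length(loc),
                     error_local = e_loc, error_random_mean = mean(e_rnd))
      }
    }
    if (!length(rows)) stop("no cell-radius entry had >= 2 cells")
    do.call(rbind, rows)
  })
}

#' Functionally similar-tuned cell subset
#'
#' Selects the `k` cells whose main-field centroids are closest to a random
#' anchor location in the arena — a functional (not anatomical) similarity
#' control: decoding from such a subset is expected to be worse than from a
#' size-matched random subset.
#'
#' @param field_centroids n x 2 main-field centroids (cm).
#' @param k Subset size (`k <= n`).
#' @param anchor Optional anchor `(x, y)` in cm; random within the field
#'   bounding box when omitted.
#' @param seed Optional integer seed.
#' @return Integer vector of `k` cell indices.
#' @export
similar_tuning_subset <- function(field_centroids, k, anchor = NULL,
                                  seed = NULL) {
  n <- nrow(field_centroids)
  if (k > n) stop("k exceeds the cell roster")
  with_seed_if(seed, {
    if (is.null(anchor))
      anchor <- c(stats::runif(1, min(field_centroids[, 1]),
                               max(field_centroids[, 1])),
                  stats::runif(1, min(field_centroids[, 2]),
                               max(field_centroids[, 2])))
    d <- sqrt((field_centroids[, 1] - anchor[1])^2 +
              (field_centroids[, 2] - anchor[2])^2)
    order(d)[seq_len(k)]
  })
}
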