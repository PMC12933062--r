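# Small programmatic fixtures shared across test files.

# hand-built trajectory visiting given (x, y) waypoints, one frame per dwell
make_trajectory <- function(x, y, dt = 1 / 15, arena = arena_spec()) {
  tr <- data.frame(t = (seq_along(x) - 1) * dt, x = x, y = y,
                   speed = rep(10, length(x)))
  attr(tr, "arena") <- arena
  attr(tr, "dt") <- dt
  class(tr) <- c("trajectory", "data.frame")
  tr
}

# tuning_map object built directly from a rate matrix (occupancy uniform)
make_map <- function(rate, bin_size = 2.5, occupancy = NULL,
                     arena = arena_spec(nrow(rate) * bin_size)) {
  visited <- !is.na(rate)
  occ <- occupancy %||% (visited * 1)
  structure(list(rate = rate, rate_raw = rate, occupancy = occ,
                 visited = visited, bin_size = bin_size,
                 bin_centers = (seq_len(nrow(rate)) - 0.5) * bin_size,
                 sigma_bins = 0, arena = arena),
            class = "tuning_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian-bump rate matrix on an nb x nb grid (centres in cm)
gauss_map <- function(cx, cy, sigma = 6, nb = 32, bin_size = 2.5, peak = 1) {
  ctr <- (seq_len(nb) - 0.5) * bin_size
  outer(ctr, ctr, function(x, y)
    peak * exp(-((x - cx)^2 + (y - cy)^2) / (2 * sigma^2)))
}

# small event-driven synthetic session reused by several files
small_session <- function(n_cells = 40, duration = 900, seed = 42,
                          active_fraction = 1, lambda = 0, scale = 50, ...) {
  pop <- place_field_population(
    n_cells, active_fraction = active_fraction,
    clustering = clustering_config(lambda, scale), seed = seed, ...)
  sess <- generate_session(pop, duration = duration, seed = seed + 1)
  list(pop = pop, session = sess)
}

# expected-rate map matrix (cells x bins) for calibration-style tests
expected_map_matrix <- function(pop) {
  t(vapply(seq_along(pop$cell_id), function(i)
    as.vector(expected_rate_map(pop, i)), numeric(1024)))
}

# main-field truth centroids of a population
truth_fields <- function(pop) {
  t(vapply(pop$fields, function(f) f[1, ], numeric(2)))
}
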