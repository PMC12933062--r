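#' Detect significant calcium transients in a dF/F trace
#'
#' Marks contiguous epochs where dF/F exceeds `k` robust standard deviations
#' (MAD-based) above the trace median for at least `min_duration` seconds;
#' epochs separated by less than `merge_gap` seconds are merged. The
#' complement of the mask defines the noise epochs used by [compute_snr()].
#'
#' @param dff Numeric dF/F trace (one value per frame), length >= 100.
#' @param dt Frame interval in seconds.
#' @param k Threshold in robust SDs.
#' @param min_duration Minimum transient duration, seconds.
#' @param merge_gap Gaps shorter than this (seconds) are bridged.
#' @return Logical vector, `TRUE` during significant transients.
#' @export
detect_transients <- function(dff, dt = 1 / 15, k = 3, min_duration = 0.5,
                              merge_gap = 0.2) {
  if (length(dff) < 100L) stop("trace too short (< 100 frames)")
  s <- stats::mad(dff)
  if (s == 0) stop("degenerate input: constant dF/F trace")
  above <- dff > stats::median(dff) + k * s
  r <- rle(above)
  # bridge sub-threshold gaps shorter than merge_gap between transients
  gap_frames <- max(1L, as.integer(round(merge_gap / dt)))
  if (length(r$lengths) > 2L) {
    interior <- which(!r$values & r$lengths < gap_frames)
    interior <- interior[interior > 1L & interior < length(r$values)]
    r$values[interior] <- TRUE
    r <- rle(inverse.rle(r))
  }
  # enforce minimum duration
  min_frames <- max(1L, as.integer(round(min_duration / dt)))
  r$values[r$values & r$lengths < min_frames] <- FALSE
  inverse.rle(rle(inverse.rle(r)))
}

#' Per-cell signal-to-noise ratio of a dF/F trace
#'
#' Signal is the mean over transients of each transient's 90th-percentile
#' dF/F; noise is the mean absolute frame-to-frame difference of dF/F outside
#' transients. SNR is their ratio. A cell without any detected transient gets
#' `snr = 0` with `no_transients = TRUE` (it will fail the SNR filter).
#'
#' @param dff Numeric dF/F trace.
#' @param transient_mask Logical mask from [detect_transients()].
#' @return A list of class `snr_result`: `snr`, `signal_level`,
#'   `noise_level`, `transient_mask`, `no_transients`.
#' @export
compute_snr <- function(dff, transient_mask) {
  stopifnot(length(dff) == length(transient_mask))
  r <- rle(transient_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tr_runs <- which(r$values)
  # noise: |diff| between consecutive frames that are both outside transients
  out <- !transient_mask
  both_out <- out[-length(out)] & out[-1L]
  noise <- if (any(both_out)) mean(abs(diff(dff))[both_out]) else NA_real_
  if (length(tr_runs) == 0L) {
    return(structure(list(snr = 0, signal_level = 0, noise_level = noise,
                          transient_mask = transient_mask,
                          no_transients = TRUE),
                     class = "snr_result"))
  }
  if (is.na(noise) || noise <= 0)
    stop("no usable noise epochs outside transients")
  signal <- mean(vapply(tr_runs, function(j)
    stats::quantile(dff[starts[j]:ends[j]], 0.9, names = FALSE), numeric(1)))
  structure(list(snr = signal / noise, signal_level = signal,
                 noise_level = noise, transient_mask = transient_mask,
                 no_transients = FALSE),
            class = "snr_result")
}

#' @export
print.snr_result <- function(x, ...) {
  cat(sprintf("<snr_result> SNR = %.2f (signal %.3f / noise %.3f)\n",
              x$snr, x$signal_level, x$noise_level))
  invisible(x)
}

#' Apply the per-cell inclusion filters
#'
#' A cell enters further analyses only if its SNR strictly exceeds `snr_min`
#' and it emitted at least `min_events` deconvolved events within the
#' environment.
#'
#' @param qc A `data.frame` with columns `cell_id`, `snr`, `n_events`.
#' @param snr_min SNR threshold (strict inequality).
#' @param min_events Minimum event count (inclusive).
#' @return The `qc` table with an added logical column `included`.
#' @export
apply_inclusion_filters <- function(qc, snr_min = 3, min_events = 40) {
  stopifnot(all(c("cell_id", "snr", "n_events") %in% names(qc)))
  qc$included <- qc$snr > snr_min & qc$n_events >= min_events
  qc
}

#' QC table for a session
#'
#' Computes SNR and event counts for every cell of a session and applies the
#' inclusion filters.
#'
#' @param session A [generate_session()] session (or equivalent structure).
#' @param ... Passed to [detect_transients()] / [apply_inclusion_filters()].
#' @return A `data.frame`: `cell_id`, `snr`, `n_events`, `included`.
#' @export
session_qc <- function(session, ...) {
  dt <- attr(session$traj, "dt") %||% stats::median(diff(session$traj$t))
  rows <- lapply(session$cells, function(cr) {
    snr <- tryCatch({
      m <- detect_transients(cr$dff, dt = dt)
      compute_snr(cr$dff, m)$snr
    }, error = function(e) 0)
    data.frame(cell_id = cr$cell_id, snr = snr, n_events = nrow(cr$events))
  })
  apply_inclusion_filters(do.call(rbind, rows), ...)
}
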