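#' Write / read a session container
#'
#' Sessions are stored as a single-file hierarchical container (RDS): the
#' trajectory arrays, per-cell dF/F traces, event tables and anatomical
#' centroids, the environment label, arena/FOV specs and provenance
#' metadata. The round trip is lossless.
#'
#' @param session A session.
#' @param path File path.
#' @param metadata Optional named list stored alongside the data (seeds,
#'   config hash, ...).
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the session with metadata in the `metadata` attribute.
#' @export
write_session <- function(session, path, metadata = list()) {
  payload <- list(
    format = "placetopo-session", version = 1L,
    traj = as.data.frame(session$traj),
    dt = attr(session$traj, "dt"),
    arena = attr(session, "arena"), fov = attr(session, "fov"),
    label = session$label, object_xy = session$object_xy,
    cells = lapply(session$cells, function(cr)
      list(cell_id = cr$cell_id, events = cr$events, dff = cr$dff,
           centroid = cr$centroid)),
    metadata = metadata
  )
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  p <- readRDS(path)
  if (!identical(p$format, "placetopo-session"))
    stop("not a placetopo session container: ", path)
  for (f in c("traj", "arena", "label", "cells"))
    if (is.null(p[[f]])) stop("session container is missing field '", f, "'")
  for (i in seq_along(p$cells))
    if (is.null(p$cells[[i]]$events))
      stop("cell ", i, " is missing its 'events' table")
  traj <- p$traj
  attr(traj, "arena") <- p$arena
  attr(traj, "dt") <- p$dt
  class(traj) <- c("trajectory", "data.frame")
  cells <- lapply(p$cells, function(cr)
    structure(cr, class = "cell_recording"))
  out <- structure(list(traj = traj, cells = cells, label = p$label,
                        object_xy = p$object_xy),
                   arena = p$arena, fov = p$fov, class = "session")
  attr(out, "metadata") <- p$metadata
  out
}

#' Export / import a session as CSV fixtures
#'
#' Writes `trajectory.csv` (`t, x, y`), `events.csv`
#' (`cell_id, t, amplitude`) and `centroids.csv` (`cell_id, x, y`) into a
#' directory for cross-language use. dF/F traces are not part of the CSV
#' fixture format.
#'
#' @param session A session.
#' @param dir Directory (created if needed).
#' @param arena,fov,dt Geometry needed to rebuild the session on import.
#' @return `export_session_csv()` returns `dir` invisibly;
#'   `import_session_csv()` returns a session (without dF/F).
#' @export
export_session_csv <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(session$traj[, c("t", "x", "y")],
                   file.path(dir, "trajectory.csv"), row.names = FALSE)
  ev <- do.call(rbind, lapply(session$cells, function(cr)
    if (nrow(cr$events)) cbind(cell_id = cr$cell_id, cr$events)))
  if (is.null(ev)) ev <- data.frame(cell_id = integer(), t = numeric(),
                                    amplitude = numeric())
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  cent <- data.frame(
    cell_id = vapply(session$cells, `[[`, numeric(1), "cell_id"),
    x = vapply(session$cells, function(cr) cr$centroid[1], numeric(1)),
    y = vapply(session$cells, function(cr) cr$centroid[2], numeric(1)))
  utils::write.csv(cent, file.path(dir, "centroids.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname export_session_csv
#' @param label Environment label for the imported session.
#' @export
import_session_csv <- function(dir, arena = arena_spec(), fov = fov_spec(),
                               dt = 1 / 15, label = "A") {
  traj <- utils::read.csv(file.path(dir, "trajectory.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  cent <- utils::read.csv(file.path(dir, "centroids.csv"))
  traj$speed <- c(sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt, 0)
  if (nrow(traj) > 1) traj$speed[nrow(traj)] <- traj$speed[nrow(traj) - 1]
  attr(traj, "arena") <- arena
  attr(traj, "dt") <- dt
  class(traj) <- c("trajectory", "data.frame")
  cells <- lapply(seq_len(nrow(cent)), function(i) {
    e <- ev[ev$cell_id == cent$cell_id[i], c("t", "amplitude"), drop = FALSE]
    rownames(e) <- NULL
    structure(list(cell_id = cent$cell_id[i], events = e, dff = NULL,
                   centroid = c(cent$x[i], cent$y[i])),
              class = "cell_recording")
  })
  structure(list(traj = traj, cells = cells, label = label, object_xy = NULL),
            arena = arena, fov = fov, class = "session")
}

#' Cohort-count percentages
#'
#' Report arithmetic for cohort tables: `100 * numerator / denominator`,
#' rounded to the requested precision.
#'
#' @param numerator,denominator Non-negative counts (vectorized);
#'   denominators must be positive.
#' @param digits Decimal places of the reported percentage.
#' @return Numeric vector of percentages.
#' @export
report_cohort_fractions <- function(numerator, denominator, digits = 2) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0)) stop("counts must be non-negative")
  round(100 * numerator / denominator, digits)
}
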