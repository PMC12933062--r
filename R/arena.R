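#' Arena geometry specification
#'
#' Describes the square open-field arena the animal forages in. The default
#' matches the standard 80 cm x 80 cm box with 50 cm high walls; wall height is
#' carried as metadata only.
#'
#' @param side_length Side of the square arena in cm. Must be positive.
#' @param wall_height Wall height in cm (metadata, not used by any analysis).
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(side_length = 80, wall_height = 50) {
  if (!is.numeric(side_length) || length(side_length) != 1L || side_length <= 0)
    stop("'side_length' must be a single positive number")
  structure(list(side_length = side_length, wall_height = wall_height),
            class = "arena_spec")
}

#' Imaging field-of-view specification
#'
#' Anatomical coordinates of cells are expressed in micrometres within this
#' field of view. The default 350 um x 350 um matches a miniaturized
#' two-photon microscope imaging a CA1 cell layer.
#'
#' @param width,height FOV extents in micrometres. Must be positive.
#' @return An object of class `fov_spec`.
#' @export
fov_spec <- function(width = 350, height = 350) {
  if (width <= 0 || height <= 0) stop("FOV extents must be positive")
  structure(list(width = width, height = height), class = "fov_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g cm x %g cm, walls %g cm\n",
              x$side_length, x$side_length, x$wall_height))
  invisible(x)
}

#' @export
print.fov_spec <- function(x, ...) {
  cat(sprintf("<fov_spec> %g um x %g um\n", x$width, x$height))
  invisible(x)
}

# Run expr with a fixed RNG seed when seed is non-NULL, without disturbing
# the caller's RNG stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
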