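#' Single-cell contour on a uniform angular grid
#'
#' The package represents every cell outline as a star-shaped parametric
#' curve R(theta) = R0 + h(theta) sampled on the uniform grid
#' theta_j = 2*pi*j/N, j = 0..N-1, about the cell centroid. Radii are stored
#' in meters; the pixel size used for the conversion is kept alongside.
#'
#' @param radii Numeric vector of radii R(theta_j) in meters, all positive.
#' @param pixel_size Pixel size in m/px used when the contour was extracted
#'   (for purely synthetic contours, the nominal scale).
#' @param centroid Length-2 numeric, centroid in pixel coordinates (0-based).
#' @param cell_id Optional label.
#' @return Object of class `rbc_contour` with fields `angles`, `radii`,
#'   `centroid`, `pixel_size`, `cell_id`.
#' @export
contour_polar <- function(radii, pixel_size, centroid = c(0, 0),
                          cell_id = NA_character_) {
  radii <- as.numeric(radii)
  n <- length(radii)
  if (n < 8L) stop("a contour needs at least 8 angular samples")
  if (!all(is.finite(radii)) || any(radii <= 0))
    stop("invalid contour: all radii must be finite and positive")
  stopifnot(pixel_size > 0)
  structure(list(angles = angle_grid(n), radii = radii,
                 centroid = as.numeric(centroid),
                 pixel_size = pixel_size, cell_id = cell_id),
            class = "rbc_contour")
}

#' @export
print.rbc_contour <- function(x, ...) {
  r0 <- mean(x$radii)
  cat(sprintf(
    "Cell contour: N = %d angles, R0 = %.3f um, fluctuation rms = %.1f nm\n",
    length(x$radii), r0 * 1e6, stats::sd(x$radii) * 1e9))
  invisible(x)
}

#' Mean radius and angular fluctuation of a contour
#'
#' `contour_R0` is the angular mean radius; `contour_h` the zero-mean
#' perturbation h(theta) = R(theta) - R0.
#' @param contour An `rbc_contour`.
#' @return Scalar (m) or numeric vector (m).
#' @export
contour_R0 <- function(contour) mean(contour$radii)

#' @rdname contour_R0
#' @export
contour_h <- function(contour) contour$radii - mean(contour$radii)

#' Cartesian polygon of a contour (meters, centered on the centroid)
#' @param contour An `rbc_contour`.
#' @return Two-column matrix (x, y) in meters.
#' @export
contour_xy <- function(contour) {
  cbind(x = contour$radii * cos(contour$angles),
        y = contour$radii * sin(contour$angles))
}

#' @export
plot.rbc_contour <- function(x, ...) {
  xy <- contour_xy(x) * 1e6
  graphics::plot(rbind(xy, xy[1, ]), type = "l", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}
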