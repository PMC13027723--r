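# Polygon primitives used by the shape descriptors. Contours are
# star-shaped by construction (positive radii about the centroid), which
# rules out self-intersection.

polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

polygon_perimeter <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  sum(sqrt(diff(c(x, x[1L]))^2 + diff(c(y, y[1L]))^2))
}

# Second central area moments of the filled polygon (per unit area), via the
# standard Green's-theorem formulas; returns the covariance-like matrix of
# the area distribution.
polygon_second_moments <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  cross <- x * y2 - x2 * y
  A <- sum(cross) / 2
  cx <- sum((x + x2) * cross) / (6 * A)
  cy <- sum((y + y2) * cross) / (6 * A)
  Ixx <- sum((y^2 + y * y2 + y2^2) * cross) / 12      # integral of y^2 dA
  Iyy <- sum((x^2 + x * x2 + x2^2) * cross) / 12      # integral of x^2 dA
  Ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cross) / 24
  mxx <- Iyy / A - cx^2   # var of x over the area
  myy <- Ixx / A - cy^2   # var of y
  mxy <- Ixy / A - cx * cy
  matrix(c(mxx, mxy, mxy, myy), 2L, 2L)
}

#' Morphomechanical descriptors of an accepted cell contour
#'
#' Computes the shape descriptors used for morphometric phenotyping: area A
#' (shoelace formula on the resampled polygon), perimeter P (closed
#' polyline length), equivalent radius R_eq = sqrt(A/pi), angular mean
#' radius R0, standard circularity C = 4 pi A / P^2, linear circularity
#' C_lin = 2 pi R_eq / P (so C_lin^2 = C algebraically), form factor
#' F = P^2/A, and elongation E = a/b from the inertia-equivalent ellipse:
#' the semi-axes a = 2 sqrt(lambda1), b = 2 sqrt(lambda2) come from the
#' eigenvalues of the second central area moments of the filled polygon.
#' The contour fluctuation amplitude Delta is included from
#' [fluctuation_amplitude()].
#'
#' @param contour An [contour_polar()].
#' @param cell_id,condition Labels copied into the record.
#' @return One-row data.frame (SI units): A_m2, P_m, Req_m, R0_m, C, C_lin,
#'   F, E, a_m, b_m, delta_m, cell_id, condition.
#' @export
measure_contour <- function(contour, cell_id = contour$cell_id,
                            condition = NA_character_) {
  stopifnot(inherits(contour, "rbc_contour"))
  xy <- contour_xy(contour)
  A <- polygon_area(xy)
  if (A <= 0) stop("invalid contour: non-positive area")
  P <- polygon_perimeter(xy)
  Req <- sqrt(A / pi)
  R0 <- contour_R0(contour)
  M <- polygon_second_moments(xy)
  ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (ev[2L] <= 0) stop("invalid contour: degenerate second moments")
  a <- 2 * sqrt(ev[1L]); b <- 2 * sqrt(ev[2L])
  data.frame(A_m2 = A, P_m = P, Req_m = Req, R0_m = R0,
             C = 4 * pi * A / P^2, C_lin = 2 * pi * Req / P,
             F = P^2 / A, E = a / b, a_m = a, b_m = b,
             delta_m = fluctuation_amplitude(contour),
             cell_id = cell_id, condition = condition,
             stringsAsFactors = FALSE)
}

#' Contour fluctuation amplitude
#'
#' The instantaneous angular roughness of one contour: the root mean square
#' of h(theta) = R(theta) - R0 over the angular grid (population divisor N).
#'
#' @param contour An [contour_polar()].
#' @return Delta in meters.
#' @export
fluctuation_amplitude <- function(contour) {
  stopifnot(inherits(contour, "rbc_contour"))
  h <- contour_h(contour)
  sqrt(mean(h^2))
}

#' Normocyte fraction of a field
#'
#' The ratio of cells meeting the acceptance (normality) criteria to the
#' total number of detected cells.
#'
#' @param accepted_count,total_count Non-negative counts,
#'   `total_count >= accepted_count`, `total_count > 0`.
#' @return Fraction in [0, 1].
#' @export
normocyte_fraction <- function(accepted_count, total_count) {
  stopifnot(accepted_count >= 0, total_count >= accepted_count)
  if (total_count == 0) stop("total_count must be positive")
  accepted_count / total_count
}
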