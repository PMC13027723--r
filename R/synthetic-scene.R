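#' Planted cell description for synthetic bright-field scenes
#'
#' A cell is rendered as a dark annular rim (radial Gaussian trough) on a
#' bright background, the appearance of a suspended discocyte's equatorial
#' rim in bright field. A `defect` plants a controlled violation of one
#' acceptance criterion; `expected_accept` is FALSE whenever defect != none.
#'
#' @param center Pixel coordinates (x, y), 0-based.
#' @param radius Rim radius in micrometers.
#' @param mode_amplitudes Named numeric vector, mode index -> amplitude in
#'   micrometers, added as cos(n theta) perturbations of the rim radius.
#' @param rim_width Radial Gaussian width of the rim trough, micrometers.
#' @param rim_depth Fractional intensity depth of the trough in (0, 1].
#' @param defect One of "none", "border", "aggregate", "blurred", "small",
#'   "large", "elongated".
#' @return A list of class `rbc_planted_cell`.
#' @export
planted_cell <- function(center, radius = 7.4,
                         mode_amplitudes = c(`3` = 0.06),
                         rim_width = 0.45, rim_depth = 0.6,
                         defect = c("none", "border", "aggregate", "blurred",
                                    "small", "large", "elongated")) {
  defect <- match.arg(defect)
  stopifnot(length(center) == 2L, radius > 0, rim_width > 0,
            rim_depth > 0, rim_depth <= 1)
  structure(list(center = as.numeric(center), radius = radius,
                 mode_amplitudes = mode_amplitudes,
                 rim_width = rim_width, rim_depth = rim_depth,
                 defect = defect,
                 expected_accept = identical(defect, "none")),
            class = "rbc_planted_cell")
}

#' Specification of a synthetic bright-field cell-field scene
#'
#' @param image_size Side of the square image in pixels.
#' @param pixel_size Pixel size in micrometers per pixel.
#' @param cells List of [planted_cell()]s.
#' @param noise_sd Additive Gaussian noise sd as a fraction of full scale.
#' @param background Background intensity on the [0, 1] scale.
#' @param seed Integer seed.
#' @return A list of class `rbc_scene_spec`.
#' @export
scene_spec <- function(image_size = 640L, pixel_size = 0.206, cells = list(),
                       noise_sd = 0.01, background = 0.85, seed = 1L) {
  stopifnot(image_size > 0, pixel_size > 0, noise_sd >= 0,
            background > 0, background <= 1)
  stopifnot(all(vapply(cells, inherits, TRUE, "rbc_planted_cell")))
  structure(list(image_size = as.integer(image_size),
                 pixel_size = pixel_size, cells = cells,
                 noise_sd = noise_sd, background = background, seed = seed),
            class = "rbc_scene_spec")
}

# Defect -> rejection reason code expected from detect_and_filter().
defect_reason <- function(defect) {
  switch(defect,
         none = NA_character_, border = "border", blurred = "focus",
         aggregate = "aggregate", elongated = "circularity",
         small = "size", large = "size",
         stop("unknown defect: ", defect))
}

# Rim radius (px) as a function of angle for one planted cell; handles the
# shape-altering defects. `ratio` for the elongated defect is area-matched.
planted_radius_px <- function(cell, theta, pixel_size) {
  r_px <- cell$radius / pixel_size
  if (cell$defect == "elongated") {
    ratio <- 2
    a <- r_px * sqrt(ratio); b <- r_px / sqrt(ratio)
    r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  } else {
    r <- rep(r_px, length(theta))
  }
  ma <- cell$mode_amplitudes
  if (length(ma)) {
    for (j in seq_along(ma)) {
      n <- as.integer(names(ma)[j])
      r <- r + (ma[[j]] / pixel_size) * cos(n * theta)
    }
  }
  r
}

# Multiply a dark Gaussian rim trough into `img` (dim1 = x, 0-based coords).
render_rim <- function(img, center, radius_fun, width_px, depth) {
  nx <- nrow(img); ny <- ncol(img)
  rmax <- max(radius_fun(angle_grid(256L))) + 4 * width_px
  x <- max(0L, floor(center[1L] - rmax)):min(nx - 1L, ceiling(center[1L] + rmax))
  y <- max(0L, floor(center[2L] - rmax)):min(ny - 1L, ceiling(center[2L] + rmax))
  if (!length(x) || !length(y)) return(img)
  dx <- outer(x - center[1L], rep(1, length(y)))
  dy <- outer(rep(1, length(x)), y - center[2L])
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) %% (2 * pi)
  rim <- matrix(radius_fun(as.vector(th)), nrow(r), ncol(r))
  trough <- depth * exp(-(r - rim)^2 / (2 * width_px^2))
  img[x + 1L, y + 1L] <- img[x + 1L, y + 1L] * (1 - trough)
  img
}

#' Render a synthetic bright-field cell field with a ground-truth manifest
#'
#' Cells are dark annular rims on a bright background; additive Gaussian
#' noise of sd `noise_sd` is applied last. Identical seeds give bit-identical
#' images. Defect-free cells must not overlap each other or the border.
#'
#' The defects render as: `border` a rim crossing the image edge;
#' `aggregate` a fused pair of overlapping rims; `blurred` a wide shallow
#' rim (defocused cell) that fails the rim-contrast focus test; `small` /
#' `large` rims outside the equivalent-radius window; `elongated` an
#' area-matched 2:1 ellipse failing the circularity criterion.
#'
#' @param spec An [scene_spec()].
#' @return List with `image` (matrix, dim1 = x, values in [0, 1] up to
#'   noise) and `manifest` (data.frame: cell_id, x, y, radius_um, defect,
#'   expected_accept, expected_reason).
#' @export
generate_field_scene <- function(spec) {
  stopifnot(inherits(spec, "rbc_scene_spec"))
  cells <- spec$cells
  # overlap / border pre-check for defect-free cells
  good <- Filter(function(c) c$defect == "none", cells)
  if (length(good)) {
    rpx <- vapply(good, function(c)
      (c$radius + 3 * c$rim_width) / spec$pixel_size, 0)
    cen <- t(vapply(good, function(c) c$center, c(0, 0)))
    for (i in seq_along(good)) {
      if (any(cen[i, ] - rpx[i] < 0) ||
          any(cen[i, ] + rpx[i] > spec$image_size - 1L))
        stop("rejected scene spec: defect-free cell ", i, " touches the border")
      if (i > 1L) {
        d <- sqrt(rowSums((cen[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cen[i, ], i - 1L, 2L, byrow = TRUE))^2))
        if (any(d < rpx[seq_len(i - 1L)] + rpx[i]))
          stop("rejected scene spec: defect-free cells overlap")
      }
    }
  }
  img <- matrix(spec$background, spec$image_size, spec$image_size)
  rows <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    w_px <- cell$rim_width / spec$pixel_size
    if (cell$defect == "aggregate") {
      # fused L-shaped triad; the offset ~1.7x the filled radius keeps the
      # rims connected while the hull spans the empty corner, so the
      # component fails the solidity test rather than merely circularity
      off <- 1.7 * (cell$radius + 0.75) / spec$pixel_size
      for (dxy in list(c(0, 0), c(off, 0), c(0, off))) {
        ctr <- cell$center + dxy
        img <- render_rim(img, ctr,
                          function(th) planted_radius_px(cell, th, spec$pixel_size),
                          w_px, cell$rim_depth)
      }
    } else {
      img <- render_rim(img, cell$center,
                        function(th) planted_radius_px(cell, th, spec$pixel_size),
                        w_px, cell$rim_depth)
    }
    rows[[i]] <- data.frame(cell_id = sprintf("plant%02d", i),
                            x = cell$center[1L], y = cell$center[2L],
                            radius_um = cell$radius, defect = cell$defect,
                            expected_accept = cell$expected_accept,
                            expected_reason = defect_reason(cell$defect),
                            stringsAsFactors = FALSE)
  }
  if (spec$noise_sd > 0) {
    img <- with_gen_seed(spec$seed,
      img + matrix(stats::rnorm(length(img), sd = spec$noise_sd),
                   nrow(img), ncol(img)))
  }
  manifest <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(cell_id = character(), x = numeric(), y = numeric(),
               radius_um = numeric(), defect = character(),
               expected_accept = logical(), expected_reason = character(),
               stringsAsFactors = FALSE)
  }
  list(image = img, manifest = manifest)
}

#' Nine-cell demonstration scene with planted acceptance defects
#'
#' Five defect-free cells plus one each of the border, aggregate, blurred
#' (defocused) and elongated defects, on a 640 px field at 0.206 um/px.
#' Used throughout the tests as the ground-truth fixture for the
#' segmentation acceptance filters.
#'
#' @param seed Integer seed for the noise field.
#' @return An [scene_spec()].
#' @export
demo_scene_spec <- function(seed = 1L) {
  px <- 0.206
  good <- function(x, y, r = 7.4, amp = 0.06)
    planted_cell(c(x, y), radius = r, mode_amplitudes = c(`3` = amp))
  cells <- list(
    good(110, 110), good(320, 90, r = 7.6), good(540, 120, r = 7.2),
    good(100, 330), good(300, 300, r = 7.4, amp = 0.1),
    planted_cell(c(630, 320), defect = "border"),
    planted_cell(c(480, 420), defect = "aggregate"),
    planted_cell(c(130, 540), rim_width = 1.6, rim_depth = 0.30,
                 defect = "blurred"),
    planted_cell(c(360, 560), defect = "elongated"))
  scene_spec(image_size = 640L, pixel_size = px, cells = cells,
             noise_sd = 0.01, seed = seed)
}

#' Render a fluctuating-contour video stack
#'
#' Turns a fluctuation field h(theta, t) into a synthetic high-speed video:
#' frame k draws the contour R(theta, t_k) = R0 + h(theta, t_k) as a dark
#' rim, optionally translated by a rigid per-frame drift to exercise the
#' tracker's re-centering.
#'
#' @param field An `rbc_fluctuation_field` (meters).
#' @param radius0 Mean contour radius in meters.
#' @param image_size Frame side in pixels.
#' @param pixel_size Pixel size in meters per pixel (video optics; 50 nm/px
#'   in the reference acquisition).
#' @param rim_width Rim trough width in meters.
#' @param rim_depth Fractional trough depth.
#' @param drift Length-2 rigid drift in px/frame.
#' @param noise_sd Additive Gaussian noise sd (fraction of full scale).
#' @param background Background intensity.
#' @param seed Seed for the noise.
#' @return 3-D array `image_size x image_size x T`.
#' @export
render_contour_video <- function(field, radius0, image_size = 96L,
                                 pixel_size = 50e-9, rim_width = 1e-7,
                                 rim_depth = 0.6, drift = c(0, 0),
                                 noise_sd = 0, background = 0.85,
                                 seed = 1L) {
  stopifnot(inherits(field, "rbc_fluctuation_field"))
  h <- field$h
  n_ang <- nrow(h); T_ <- ncol(h)
  theta <- angle_grid(n_ang)
  w_px <- rim_width / pixel_size
  center0 <- c(image_size - 1, image_size - 1) / 2
  frames <- array(background, c(image_size, image_size, T_))
  for (k in seq_len(T_)) {
    r_px <- (radius0 + h[, k]) / pixel_size
    ctr <- center0 + drift * (k - 1)
    if (any(ctr - max(r_px) - 3 * w_px < 0) ||
        any(ctr + max(r_px) + 3 * w_px > image_size - 1))
      stop("contour exits the frame at frame ", k)
    rad_fun <- function(th)
      stats::approx(c(theta, 2 * pi), c(r_px, r_px[1L]), xout = th,
                    rule = 2)$y
    frames[, , k] <- render_rim(matrix(background, image_size, image_size),
                                ctr, rad_fun, w_px, rim_depth)
  }
  if (noise_sd > 0) {
    frames <- with_gen_seed(seed,
      frames + array(stats::rnorm(length(frames), sd = noise_sd),
                     dim(frames)))
  }
  frames
}
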