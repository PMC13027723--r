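#' Preprocess a bright-field frame
#'
#' Gaussian noise reduction (sigma = 2 px) followed by a global affine
#' rescale of intensities to [0, 1], the standard conditioning step before
#' thresholding.
#'
#' @param frame Numeric matrix (dim1 = x).
#' @param sigma Gaussian blur sigma in pixels.
#' @return Matrix of the same size with values in [0, 1].
#' @export
preprocess_frame <- function(frame, sigma = 2) {
  stopifnot(is.matrix(frame), length(frame) > 0)
  rng0 <- range(frame)
  if (!all(is.finite(rng0)) || rng0[2L] <= rng0[1L])
    stop_degenerate("degenerate input: constant frame cannot be normalized")
  # kernel must fit inside the frame (EBImage brush is 2*ceil(3 sigma)+1)
  radius <- min(2L * ceiling(3 * sigma) + 1L,
                (min(dim(frame)) - 1L) %/% 2L * 2L - 1L)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(frame),
                                          sigma = sigma, radius = radius))
  rng <- range(sm)
  if (rng[2L] <= rng[1L])
    stop_degenerate("degenerate input: constant frame cannot be normalized")
  (sm - rng[1L]) / (rng[2L] - rng[1L])
}

#' Otsu's threshold by exhaustive between-class variance maximization
#'
#' Builds a `levels`-bin histogram over the frame's intensity range and
#' scans every bin boundary, returning the one maximizing the between-class
#' variance w0 w1 (mu0 - mu1)^2. Ties are broken toward the lowest
#' threshold. Pixels strictly below the returned value form the dark class.
#'
#' @param frame Numeric matrix with at least two distinct values.
#' @param levels Number of histogram bins (default 256).
#' @return Threshold intensity, with attribute `bin` giving the split index
#'   (dark class = bins 1..bin).
#' @export
otsu_threshold <- function(frame, levels = 256L) {
  v <- as.vector(frame)
  rng <- range(v)
  if (!all(is.finite(rng)) || rng[2L] <= rng[1L])
    stop_degenerate("degenerate input: Otsu needs at least two distinct values")
  edges <- seq(rng[1L], rng[2L], length.out = levels + 1L)
  counts <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE),
                               1L), levels), nbins = levels)
  p <- counts / sum(counts)
  mids <- (edges[-1L] + edges[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[levels]
  t_cand <- seq_len(levels - 1L)
  w0t <- w0[t_cand]; w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  bcv <- rep(-Inf, levels - 1L)
  mu0 <- mu_cum[t_cand] / w0t
  mu1 <- (mu_tot - mu_cum[t_cand]) / w1t
  bcv[valid] <- (w0t * w1t * (mu0 - mu1)^2)[valid]
  t_best <- which.max(bcv)  # which.max takes the first (lowest) maximum
  structure(edges[t_best + 1L], bin = t_best)
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# diagonally are merged with union-find and relabeled in raster order.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  nlab <- max(lab)
  if (nlab > 1L) {
    nx <- nrow(lab); ny <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nx, -ny]), as.vector(lab[-1L, -1L])),
      cbind(as.vector(lab[-nx, -1L]), as.vector(lab[-1L, -ny])))
    pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                     pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (r in seq_len(nrow(pairs))) {
      a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(nlab), find, 0L)
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  # consecutive ids in raster order of first pixel
  ids <- unique(as.vector(lab[lab > 0]))
  ids <- ids[order(match(ids, as.vector(lab)))]
  out <- array(0L, dim(lab))
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

#' Acceptance criteria for candidate erythrocytes
#'
#' Filters applied to labeled components before morphometric analysis:
#' border clearance, rim-contrast focus test, convex-hull solidity
#' (aggregate detection), circularity, and an equivalent-radius window
#' restricting the analysis to normocytic cells.
#'
#' @param circularity_min Minimum 4*pi*A/P^2 (default 0.9).
#' @param radius_window Equivalent-radius window in micrometers
#'   (default c(7, 8)).
#' @param border_margin Border clearance in pixels.
#' @param focus_metric_min Minimum rim contrast (background - rim minimum) /
#'   background, evaluated on the globally normalized frame; out-of-focus
#'   cells fall below it. After global normalization the deepest in-focus
#'   rims span most of the unit intensity range, so the default rejection
#'   point sits at mid-contrast (0.45).
#' @param solidity_min Minimum convex-hull solidity; fused aggregates fall
#'   below it.
#' @param min_area_px Components smaller than this many pixels are treated
#'   as noise specks and dropped without logging.
#' @return A list of class `rbc_criteria`.
#' @export
acceptance_criteria <- function(circularity_min = 0.9,
                                radius_window = c(7, 8),
                                border_margin = 1L,
                                focus_metric_min = 0.45,
                                solidity_min = 0.9,
                                min_area_px = 30L) {
  stopifnot(circularity_min > 0, circularity_min <= 1,
            length(radius_window) == 2L, radius_window[1L] < radius_window[2L],
            border_margin >= 0, focus_metric_min >= 0, solidity_min > 0)
  structure(list(circularity_min = circularity_min,
                 radius_window = radius_window,
                 border_margin = as.integer(border_margin),
                 focus_metric_min = focus_metric_min,
                 solidity_min = solidity_min,
                 min_area_px = as.integer(min_area_px)),
            class = "rbc_criteria")
}

#' Detect candidate cells and apply the acceptance filters
#'
#' Binarizes the preprocessed frame at the Otsu threshold (cells = dark
#' class), fills holes (the bright cell interior inside the dark rim),
#' labels 8-connected components, and tests each against the acceptance
#' criteria in a fixed order: border clearance, focus (rim contrast),
#' solidity (aggregate), circularity, equivalent-radius window. Every
#' rejection is logged with the first failing reason code; accepted
#' components are reported in raster order of their centroids.
#'
#' @param frame Preprocessed frame from [preprocess_frame()].
#' @param criteria An [acceptance_criteria()].
#' @param pixel_size Pixel size in micrometers per pixel.
#' @return List: `accepted` / `rejected` data.frames (id, cx, cy,
#'   equivalent_radius_um, circularity, solidity, focus, reason),
#'   `labels` (integer matrix), `threshold`, `n_detected`.
#' @export
detect_and_filter <- function(frame, criteria = acceptance_criteria(),
                              pixel_size) {
  stopifnot(is.matrix(frame), inherits(criteria, "rbc_criteria"),
            pixel_size > 0)
  thr <- otsu_threshold(frame)
  mask <- frame < as.numeric(thr)
  # cell rims cover a few percent of a field; when the dark class swallows a
  # large fraction of the frame the threshold is splitting noise, not cells
  if (mean(mask) > 0.3) {
    empty <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                        equivalent_radius_um = numeric(),
                        circularity = numeric(), solidity = numeric(),
                        focus = numeric(), reason = character(),
                        stringsAsFactors = FALSE)
    return(list(accepted = empty, rejected = empty,
                labels = array(0L, dim(frame)),
                threshold = as.numeric(thr), n_detected = 0L))
  }
  filled <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  labels <- label_components(filled)
  nlab <- max(labels)
  bg <- stats::median(frame[!filled])
  nx <- nrow(frame); ny <- ncol(frame)
  rows <- list()
  for (id in seq_len(nlab)) {
    idx <- which(labels == id, arr.ind = TRUE)
    if (nrow(idx) < criteria$min_area_px) next
    xs <- idx[, 1L] - 1L; ys <- idx[, 2L] - 1L
    cx <- mean(xs); cy <- mean(ys)
    reason <- NA_character_
    circ <- sol <- req_um <- NA_real_
    focus <- (bg - min(frame[idx])) / bg
    if (any(xs < criteria$border_margin) || any(ys < criteria$border_margin) ||
        any(xs >= nx - criteria$border_margin) ||
        any(ys >= ny - criteria$border_margin)) {
      reason <- "border"
    } else if (focus < criteria$focus_metric_min) {
      reason <- "focus"
    } else {
      sol <- component_solidity(labels, id)
      if (!is.finite(sol) || sol < criteria$solidity_min) {
        reason <- "aggregate"
      } else {
        geo <- tryCatch(
          component_geometry(frame, labels, id, pixel_size),
          rbc_star_convex_error = function(e) NULL)
        if (is.null(geo)) {
          reason <- "aggregate"  # non-star-convex shapes are fused/debris
        } else {
          circ <- geo$circularity
          req_um <- geo$equivalent_radius_um
          cx <- geo$cx; cy <- geo$cy
          if (circ < criteria$circularity_min) reason <- "circularity"
          else if (req_um < criteria$radius_window[1L] ||
                   req_um > criteria$radius_window[2L]) reason <- "size"
        }
      }
    }
    rows[[id]] <- data.frame(id = id, cx = cx, cy = cy,
                             equivalent_radius_um = req_um,
                             circularity = circ, solidity = sol,
                             focus = focus, reason = reason,
                             stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), cx = numeric(), cy = numeric(),
               equivalent_radius_um = numeric(), circularity = numeric(),
               solidity = numeric(), focus = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  res <- res[order(round(res$cy), res$cx), , drop = FALSE]
  rownames(res) <- NULL
  list(accepted = res[is.na(res$reason), , drop = FALSE],
       rejected = res[!is.na(res$reason), , drop = FALSE],
       labels = labels, threshold = as.numeric(thr), n_detected = nrow(res))
}

# Geometry of one component. Solidity comes from the raw boundary pixel
# chain (waist concavities of fused aggregates must not be smoothed away);
# area, perimeter and circularity come from the harmonically smoothed
# outline, which is pixelation-robust for the near-circular shapes that
# survive the solidity test.
component_solidity <- function(labels, id) {
  mask <- labels == id
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1L]]
  A_raw <- abs(polygon_area(oc))
  hull <- grDevices::chull(oc)
  A_hull <- abs(polygon_area(oc[hull, , drop = FALSE]))
  if (A_hull <= 0) return(NA_real_)
  A_raw / A_hull
}

component_geometry <- function(frame, labels, id, pixel_size,
                               n_angles = 360L, spline_degree = 12L) {
  ct <- extract_contour(frame, labels, id, n_angles = n_angles,
                        spline_degree = spline_degree,
                        pixel_size = pixel_size * 1e-6)
  xy <- contour_xy(ct)
  A <- polygon_area(xy)
  P <- polygon_perimeter(xy)
  list(circularity = 4 * pi * A / P^2,
       equivalent_radius_um = sqrt(A / pi) * 1e6,
       cx = ct$centroid[1L], cy = ct$centroid[2L])
}

#' Extract a smooth polar contour from a labeled component
#'
#' Boundary pixels of the (hole-filled) component are expressed in polar
#' form (theta, r) about the darkness-weighted centroid and smoothed by
#' periodic trigonometric least squares of the configured harmonic degree;
#' the degree is raised (up to a cap) until the fit residual RMS is at most
#' `rms_tol_px`, so the smoothing contract is residual-bounded rather than
#' knot-based. To mitigate pixelation, the contour is then refined to
#' sub-pixel accuracy: along a dense fan of rays the intensity trough of
#' the rim is localized by parabolic interpolation of the radial profile
#' minimum, and the refined samples are smoothed by the same
#' residual-bounded harmonic fit before resampling on the uniform N-angle
#' grid. The refined contour therefore follows the rim's optical center,
#' not the binarization boundary. Radii are converted to meters via
#' `pixel_size`.
#'
#' @param frame Intensity frame used for the darkness-weighted centroid and
#'   the sub-pixel rim refinement (pass NULL for a binary centroid and no
#'   refinement).
#' @param labels Integer label matrix from [detect_and_filter()].
#' @param id Component id.
#' @param n_angles Angular samples of the output contour (720 for fields,
#'   1024 for high-speed videos).
#' @param spline_degree Initial number of harmonics (12 for fields, 18 for
#'   videos).
#' @param pixel_size Pixel size in meters per pixel.
#' @param rms_tol_px Residual bound in pixels for the smoothing fits.
#' @param refine Localize the rim trough to sub-pixel accuracy (default
#'   TRUE whenever an intensity frame is supplied).
#' @return An [contour_polar()] object (radii in meters; centroid in pixel
#'   coordinates).
#' @export
extract_contour <- function(frame, labels, id, n_angles = 720L,
                            spline_degree = 12L, pixel_size,
                            rms_tol_px = 0.25, refine = !is.null(frame)) {
  stopifnot(pixel_size > 0, n_angles >= 8, spline_degree >= 1)
  mask <- labels == id
  if (!any(mask)) stop("no component with id ", id)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1L]]  # 0-based (x, y)
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(frame)) {
    w <- rep(1, nrow(idx))
  } else {
    w <- pmax(max(frame[idx]) - frame[idx] + 1e-9, 0)
  }
  cx <- sum((idx[, 1L] - 1) * w) / sum(w)
  cy <- sum((idx[, 2L] - 1) * w) / sum(w)
  th <- atan2(oc[, 2L] - cy, oc[, 1L] - cx) %% (2 * pi)
  # +0.5: boundary pixel centers sit half a pixel inside the region edge
  r <- sqrt((oc[, 1L] - cx)^2 + (oc[, 2L] - cy)^2) + 0.5
  check_star_convex(th, r)
  fit <- fit_periodic_radius(th, r, spline_degree, rms_tol_px)
  if (refine && !is.null(frame)) {
    th_fan <- angle_grid(max(256L, 2L * n_angles))
    r0 <- eval_periodic_radius(fit, th_fan)
    r_ref <- refine_rim_radius(frame, cx, cy, th_fan, r0)
    fit <- fit_periodic_radius(th_fan, r_ref, spline_degree, rms_tol_px)
  }
  radii_px <- eval_periodic_radius(fit, angle_grid(n_angles))
  if (any(radii_px <= 0))
    stop("contour fit produced non-positive radii for component ", id)
  contour_polar(radii_px * pixel_size, pixel_size = pixel_size,
                centroid = c(cx, cy), cell_id = as.character(id))
}

# Sub-pixel rim localization: for each ray, sample the bilinear intensity
# profile around the initial radius and place the rim at the parabolic
# interpolation of the profile minimum. The window reaches further inward
# than outward because the initial radius comes from the binarization
# boundary, which lies on the outer flank of the rim trough. Rays where
# the minimum sits at the search-window edge keep their initial radius.
refine_rim_radius <- function(frame, cx, cy, theta, r0,
                              window_px = c(-8, 3), step_px = 0.25) {
  offs <- seq(window_px[1L], window_px[2L], by = step_px)
  n_off <- length(offs)
  rr <- outer(r0, rep(1, n_off)) + outer(rep(1, length(r0)), offs)
  px <- cx + rr * cos(theta)
  py <- cy + rr * sin(theta)
  prof <- matrix(bilinear_at(frame, as.vector(px), as.vector(py)),
                 length(r0), n_off)
  m <- max.col(-prof, ties.method = "first")
  # local quadratic least squares around the grid minimum: a 3-point
  # parabola sits below the bilinear interpolation artifacts, so the vertex
  # is estimated from a +/- 1 px neighborhood instead
  hw <- as.integer(round(1 / step_px))
  interior <- m > hw & m <= n_off - hw
  out <- r0
  idx_in <- which(interior)
  if (length(idx_in)) {
    rel <- (-hw:hw) * step_px
    X <- cbind(1, rel, rel^2)
    pinv <- solve(crossprod(X), t(X))  # 3 x (2 hw + 1)
    sub <- t(vapply(idx_in, function(i) prof[i, (m[i] - hw):(m[i] + hw)],
                    numeric(2L * hw + 1L)))
    beta <- sub %*% t(pinv)
    delta <- ifelse(beta[, 3L] > 1e-12, -beta[, 2L] / (2 * beta[, 3L]), 0)
    delta <- pmin(pmax(delta, -1), 1)
    out[idx_in] <- r0[idx_in] + offs[m[idx_in]] + delta
  }
  out
}

# Bilinear interpolation of a matrix (dim1 = x, 0-based coordinates).
bilinear_at <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  x <- pmin(pmax(x, 0), nx - 1 - 1e-9)
  y <- pmin(pmax(y, 0), ny - 1 - 1e-9)
  ix <- floor(x); iy <- floor(y)
  fx <- x - ix; fy <- y - iy
  i1 <- cbind(ix + 1, iy + 1)
  (1 - fx) * (1 - fy) * img[i1] +
    fx * (1 - fy) * img[cbind(ix + 2, iy + 1)] +
    (1 - fx) * fy * img[cbind(ix + 1, iy + 2)] +
    fx * fy * img[cbind(ix + 2, iy + 2)]
}

# A boundary is usable only if it is single-valued in polar form about the
# centroid (star-convex within tolerance): bins of theta must not contain
# widely separated radii.
check_star_convex <- function(th, r, n_bins = 60L, tol = 0.35) {
  b <- pmin(floor(th / (2 * pi) * n_bins) + 1L, n_bins)
  rmed <- stats::median(r)
  spread <- vapply(split(r, b), function(v) diff(range(v)), 0)
  if (any(spread > tol * rmed)) {
    stop(structure(class = c("rbc_star_convex_error", "error", "condition"),
                   list(message = paste0(
                     "component boundary is not star-convex about its ",
                     "centroid (max radial spread ",
                     signif(max(spread) / rmed, 3), " of median radius)"),
                     call = sys.call(-1))))
  }
  invisible(TRUE)
}

# Periodic trigonometric least-squares smoothing of (theta, r): intercept
# plus `degree` harmonics, degree raised until residual RMS <= rms_tol_px
# (capped by the data). Boundary samples are first averaged in angular bins
# to suppress the ~0.3 px pixelation jitter the fit must not chase.
fit_periodic_radius <- function(th, r, degree, rms_tol_px = 0.25) {
  n_bins <- max(8L * degree, 96L)
  b <- pmin(floor(th / (2 * pi) * n_bins) + 1L, n_bins)
  rb <- vapply(split(r, b), mean, 0)
  wb <- vapply(split(r, b), length, 0L)
  # mean angle within each occupied bin (no wrap: bin 1 starts at theta = 0)
  tb <- vapply(split(th, b), mean, 0)
  cap <- max(degree, min(40L, floor((length(rb) - 1) / 4)))
  d <- min(degree, cap)
  repeat {
    X <- harmonic_design(tb, d)
    fit <- stats::lm.wfit(X, rb, w = as.numeric(wb))
    rms <- sqrt(stats::weighted.mean(fit$residuals^2, wb))
    if (rms <= rms_tol_px || d >= cap) break
    d <- min(d + 2L, cap)
  }
  list(coef = fit$coefficients, degree = d, rms_px = rms)
}

harmonic_design <- function(th, degree) {
  X <- matrix(1, length(th), 1L + 2L * degree)
  for (k in seq_len(degree)) {
    X[, 2L * k] <- cos(k * th)
    X[, 2L * k + 1L] <- sin(k * th)
  }
  X
}

eval_periodic_radius <- function(fit, th) {
  drop(harmonic_design(th, fit$degree) %*% fit$coef)
}
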