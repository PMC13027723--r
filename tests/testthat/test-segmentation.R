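test_that("preprocessing normalizes intensities and smooths impulses", {
  fr <- matrix(15, 32L, 32L)
  fr[4:28, 4:28] <- seq(10, 20, length.out = 625)
  out <- preprocess_frame(fr)
  expect_equal(range(out), c(0, 1))
  imp <- matrix(0.5, 32L, 32L); imp[16L, 16L] <- 1
  out_imp <- preprocess_frame(imp)
  norm_in <- (imp - min(imp)) / diff(range(imp))
  roughness <- function(m) mean(diff(m)^2) + mean(t(diff(t(m)))^2)
  expect_lt(roughness(out_imp), roughness(norm_in))
  expect_error(preprocess_frame(matrix(1, 8L, 8L)), "constant")
})

test_that("Otsu separates a two-valued image and rejects constants", {
  v <- c(rep(0.2, 40L), rep(0.8, 60L))
  fr <- matrix(v, 10L, 10L)
  thr <- otsu_threshold(fr)
  expect_gt(as.numeric(thr), 0.2)
  expect_lte(as.numeric(thr), 0.8)
  expect_error(otsu_threshold(matrix(0.5, 4L, 4L)), "degenerate")
})

test_that("Otsu equals the exhaustive between-class-variance scan", {
  for (s in 1:25) {
    set.seed(s)
    w <- stats::runif(1, 0.2, 0.8)
    v <- c(stats::rnorm(round(2000 * w), 0.3, 0.05),
           stats::rnorm(round(2000 * (1 - w)), 0.7, 0.08))
    thr <- otsu_threshold(matrix(v, ncol = 50L))
    expect_identical(attr(thr, "bin"), otsu_bruteforce_bin(v))
  }
})

test_that("planted defects are rejected for the planted reasons", {
  fx <- scene_fixture(1L)
  man <- fx$scene$manifest
  expect_equal(nrow(fx$det$accepted), sum(man$expected_accept))
  expect_setequal(fx$det$rejected$reason,
                  man$expected_reason[!man$expected_accept])
  # accepted centroids match the planted defect-free cells one-to-one
  good <- man[man$expected_accept, ]
  d <- outer(fx$det$accepted$cx, good$x, "-")^2 +
       outer(fx$det$accepted$cy, good$y, "-")^2
  expect_true(all(apply(sqrt(d), 1L, min) < 3))
})

test_that("acceptance is invariant under scene rotation", {
  fx <- scene_fixture(1L)
  fr_rot <- fx$frame[nrow(fx$frame):1, ncol(fx$frame):1]  # 180 degrees
  det_rot <- detect_and_filter(fr_rot, acceptance_criteria(),
                               pixel_size = fx$spec$pixel_size)
  expect_equal(nrow(det_rot$accepted), nrow(fx$det$accepted))
  expect_equal(sort(det_rot$rejected$reason), sort(fx$det$rejected$reason))
})

test_that("an elongated cell fails circularity, a mis-sized one the radius window", {
  mk_scene <- function(cell) {
    sp <- scene_spec(image_size = 320L, pixel_size = 0.206,
                     cells = list(cell), noise_sd = 0.005, seed = 2L)
    detect_and_filter(preprocess_frame(generate_field_scene(sp)$image),
                      acceptance_criteria(), pixel_size = 0.206)
  }
  det_e <- mk_scene(planted_cell(c(160, 160), defect = "elongated"))
  expect_equal(det_e$rejected$reason, "circularity")
  # numeric perimeter oracle: area-matched 2:1 ellipse has C < 0.9
  th <- seq(0, 2 * pi, length.out = 2001L)
  a <- sqrt(2); b <- 1 / sqrt(2)
  P <- sum(sqrt(diff(a * cos(th))^2 + diff(b * sin(th))^2))
  expect_lt(4 * pi * (pi * a * b) / P^2, 0.9)
  det_s <- mk_scene(planted_cell(c(160, 160), radius = 4.5, defect = "small"))
  expect_equal(det_s$rejected$reason, "size")
  det_l <- mk_scene(planted_cell(c(160, 160), radius = 8.8, defect = "large"))
  expect_equal(det_l$rejected$reason, "size")
  det_ok <- mk_scene(planted_cell(c(160, 160), radius = 7.5,
                                  mode_amplitudes = numeric(0),
                                  defect = "none"))
  expect_equal(nrow(det_ok$accepted), 1L)
  expect_lt(abs(det_ok$accepted$equivalent_radius_um - 7.5), 0.25)
})

test_that("extracted contours reproduce a digitized disk to sub-pixel accuracy", {
  n <- 128L
  img <- matrix(0.9, n, n)
  idx <- expand.grid(x = 0:(n - 1L), y = 0:(n - 1L))
  r <- sqrt((idx$x - 63.5)^2 + (idx$y - 63.5)^2)
  img[r <= 40] <- 0.1
  labels <- matrix(as.integer(r <= 40), n, n)
  ct <- extract_contour(NULL, labels, 1L, n_angles = 720L,
                        spline_degree = 12L, pixel_size = 1e-6,
                        refine = FALSE)
  expect_true(all(abs(ct$radii / 1e-6 - 40) < 0.5))
})

test_that("a planted mode-3 perturbation survives the contour round trip", {
  amp_um <- 0.4
  sp <- scene_spec(image_size = 320L, pixel_size = 0.206,
                   cells = list(planted_cell(c(160, 160), radius = 6.6,
                                             mode_amplitudes = c(`3` = amp_um))),
                   noise_sd = 0.005, seed = 2L)
  fr <- preprocess_frame(generate_field_scene(sp)$image)
  det <- detect_and_filter(fr, acceptance_criteria(radius_window = c(5, 10)),
                           pixel_size = 0.206)
  ct <- extract_contour(fr, det$labels, det$accepted$id[1L],
                        n_angles = 720L, pixel_size = 0.206e-6)
  h3 <- 2 * sqrt(mode_spectrum(ct)$power[3L])  # amplitude of cos(3 theta)
  expect_rel_error(h3 * 1e6, amp_um, 0.10)
})

test_that("non-star-convex boundaries raise a dedicated error", {
  n <- 128L
  idx <- expand.grid(x = 0:(n - 1L), y = 0:(n - 1L))
  r <- sqrt((idx$x - 63.5)^2 + (idx$y - 63.5)^2)
  crescent <- r <= 40 & !(sqrt((idx$x - 83.5)^2 + (idx$y - 63.5)^2) <= 35)
  labels <- matrix(as.integer(crescent), n, n)
  expect_error(extract_contour(NULL, labels, 1L, pixel_size = 1e-6),
               class = "rbc_star_convex_error")
})

test_that("contour extraction is rotation-equivariant", {
  sp <- scene_spec(image_size = 320L, pixel_size = 0.206,
                   cells = list(planted_cell(c(160, 160), radius = 6.6,
                                             mode_amplitudes = c(`3` = 0.3))),
                   noise_sd = 0, seed = 2L)
  fr <- preprocess_frame(generate_field_scene(sp)$image)
  det <- detect_and_filter(fr, acceptance_criteria(radius_window = c(5, 10)),
                           pixel_size = 0.206)
  ct <- extract_contour(fr, det$labels, det$accepted$id[1L],
                        n_angles = 720L, pixel_size = 0.206e-6)
  # rotate image by 90 degrees: (x, y) -> (y, nx - 1 - x)
  fr_rot <- t(fr)[, nrow(fr):1]
  det_rot <- detect_and_filter(fr_rot, acceptance_criteria(radius_window = c(5, 10)),
                               pixel_size = 0.206)
  ct_rot <- extract_contour(fr_rot, det_rot$labels, det_rot$accepted$id[1L],
                            n_angles = 720L, pixel_size = 0.206e-6)
  # (x, y) -> (y, nx-1-x) maps angle phi to phi - pi/2, so h_rot[j] = h[j+180]
  h <- contour_h(ct); h_rot <- contour_h(ct_rot)
  shift <- 720L / 4L
  h_shifted <- c(h_rot[(720L - shift + 1L):720L], h_rot[seq_len(720L - shift)])
  expect_lt(sqrt(mean((h - h_shifted)^2)) / sqrt(mean(h^2)), 0.05)
})

test_that("tracking removes rigid drift and re-centering is idempotent", {
  fld0 <- fluctuation_field(matrix(0, 64L, 30L), fps = 2000)
  vid <- render_contour_video(fld0, radius0 = 1.5e-6, image_size = 128L,
                              pixel_size = 50e-9, drift = c(0.5, -0.3))
  fld <- track_video(vid, fps = 2000, pixel_size = 50e-9, n_angles = 256L)
  expect_lt(max(abs(fld$h)) / 50e-9, 0.2)
  fld2 <- fluctuation_field(fld$h, fps = fld$fps)
  expect_equal(fld2$h, fld$h, tolerance = 1e-12)
})

test_that("tracking recovers the planted per-angle variance of a rendered field", {
  sp <- ou_spec(n_angles = 64L, n_frames = 200L, fps = 2000,
                stiffness_true = 2e-6, friction_true = 1e-7, seed = 5L)
  dyn <- generate_mode_dynamics(sp, mode_band = 2:8)
  vid <- render_contour_video(dyn$field, radius0 = 2.5e-6, image_size = 128L,
                              pixel_size = 50e-9)
  fld <- track_video(vid, fps = 2000, pixel_size = 50e-9, n_angles = 64L)
  v_p <- mean(apply(dyn$field$h, 1L, stats::var))
  v_r <- mean(apply(fld$h, 1L, stats::var))
  expect_rel_error(v_r, v_p, 0.15)
})

test_that("a blank frame aborts tracking with the frame index", {
  fld0 <- fluctuation_field(matrix(0, 32L, 6L), fps = 1000)
  vid <- render_contour_video(fld0, radius0 = 1.5e-6, image_size = 96L)
  vid[, , 4L] <- 0.85
  expect_error(track_video(vid, fps = 1000, pixel_size = 50e-9,
                           n_angles = 64L),
               "frame 4")
})
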