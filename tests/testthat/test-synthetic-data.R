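test_that("empty scene renders a uniform background with an empty manifest", {
  sp <- scene_spec(image_size = 64L, pixel_size = 0.2, cells = list(),
                   noise_sd = 0, seed = 1)
  sc <- generate_field_scene(sp)
  expect_true(all(sc$image == sp$background))
  expect_equal(nrow(sc$manifest), 0L)
})

test_that("rendered rim trough sits at the planted radius", {
  r_um <- 3.7; px <- 0.103
  sp <- scene_spec(image_size = 128L, pixel_size = px,
                   cells = list(planted_cell(c(63.5, 63.5), radius = r_um,
                                             mode_amplitudes = numeric(0))),
                   noise_sd = 0, seed = 1)
  sc <- generate_field_scene(sp)
  prof <- radial_profile(sc$image, 63.5, 63.5)
  r_min <- prof$r_px[which.min(prof$intensity)]
  expect_lt(abs(r_min * px - r_um), 1.5 * px)
})

test_that("generators are deterministic given the seed", {
  sp <- demo_scene_spec(11)
  expect_identical(generate_field_scene(sp)$image,
                   generate_field_scene(sp)$image)
  ou <- ou_spec(n_angles = 4L, n_frames = 200L, seed = 42L)
  expect_identical(generate_angle_dynamics(ou)$field$h,
                   generate_angle_dynamics(ou)$field$h)
  es <- ensemble_spec(n_cells = 5L, n_angles = 64L, seed = 7L)
  expect_identical(generate_static_ensemble(es)$contours[[3L]]$radii,
                   generate_static_ensemble(es)$contours[[3L]]$radii)
  expect_identical(generate_absorbance(0.3, blank_sd = 0.01, seed = 9L),
                   generate_absorbance(0.3, blank_sd = 0.01, seed = 9L))
})

test_that("overlapping defect-free cells are rejected at spec time", {
  cells <- list(planted_cell(c(100, 100)), planted_cell(c(120, 100)))
  sp <- scene_spec(image_size = 256L, pixel_size = 0.206, cells = cells)
  expect_error(generate_field_scene(sp), "overlap")
  expect_error(generate_field_scene(
    scene_spec(image_size = 256L, pixel_size = 0.206,
               cells = list(planted_cell(c(20, 128))))), "border")
})

test_that("OU series follow the exact discrete autocorrelation", {
  ou <- ou_spec(n_angles = 1L, n_frames = 6000L, fps = 2000,
                stiffness_true = 2e-6, friction_true = 1e-7, seed = 3L)
  h <- generate_angle_dynamics(ou)$field$h[1L, ]
  rho_hat <- stats::cor(h[-length(h)], h[-1L])
  rho_true <- exp(-(ou$stiffness_true / ou$friction_true) / ou$fps)
  se <- sqrt((1 - rho_true^2) / length(h))
  expect_lt(abs(rho_hat - rho_true), 3 * se)
})

test_that("stiff OU limit collapses the fluctuation variance", {
  ou <- ou_spec(n_angles = 2L, n_frames = 500L, fps = 2000,
                stiffness_true = 1, friction_true = 100, seed = 1L)
  h <- generate_angle_dynamics(ou)$field$h
  expect_lt(stats::sd(h), 1e-10)  # kBT/k0 ~ 4e-21 m^2 -> sd ~ 7e-11 m
})

test_that("different angular stations are independent", {
  ou <- ou_spec(n_angles = 2L, n_frames = 6000L, fps = 2000,
                stiffness_true = 2e-6, friction_true = 2e-8, seed = 5L)
  h <- generate_angle_dynamics(ou)$field$h
  expect_lt(abs(stats::cor(h[1L, ], h[2L, ])), 0.1)
})

test_that("OU output is stationary across record halves", {
  devs <- vapply(1:5, function(s) {
    ou <- ou_spec(n_angles = 8L, n_frames = 4000L, fps = 2000,
                  stiffness_true = 2e-6, friction_true = 2e-8, seed = s)
    h <- generate_angle_dynamics(ou)$field$h
    v1 <- mean(apply(h[, 1:2000], 1L, stats::var))
    v2 <- mean(apply(h[, 2001:4000], 1L, stats::var))
    # variance-of-variance SE for ~independent samples at this omega/fps
    n_eff <- 8 * 2000 / (2 * ou$fps / (ou$stiffness_true / ou$friction_true))
    (v1 - v2) / (sqrt(2 / n_eff) * (v1 + v2) / 2)
  }, 0)
  expect_lt(abs(mean(devs)), 3)
})

test_that("static ensembles carry the planted Helfrich-like mode power", {
  es <- ensemble_spec(n_cells = 1000L, n_angles = 128L, tension_true = 5e-7,
                      mode_band = 3L, seed = 2L)
  ens <- generate_static_ensemble(es)
  p3 <- vapply(ens$contours,
               function(ct) mode_spectrum(ct)$power[3L], 0)
  expected <- kB * es$temperature / (6 * pi * es$tension_true)
  expect_rel_error(mean(p3), expected, 0.10)
})

test_that("ensemble contours are real, mean-free and circular at infinite tension", {
  es <- ensemble_spec(n_cells = 3L, n_angles = 720L, tension_true = 1e15,
                      seed = 4L)
  for (ct in generate_static_ensemble(es)$contours) {
    expect_lt(max(abs(contour_h(ct))), 1e-12 * contour_R0(ct))
  }
  es2 <- ensemble_spec(n_cells = 5L, n_angles = 720L, tension_true = 5e-7,
                       seed = 4L)
  for (ct in generate_static_ensemble(es2)$contours) {
    expect_true(is.numeric(ct$radii))  # real-valued by construction
    expect_lt(abs(mean(contour_h(ct))), 1e-12 * contour_R0(ct))
  }
})

test_that("a zero fluctuation field renders identical frames", {
  fld <- fluctuation_field(matrix(0, 32L, 4L), fps = 1000)
  vid <- render_contour_video(fld, radius0 = 1.5e-6, image_size = 96L)
  for (k in 2:4) expect_identical(vid[, , k], vid[, , 1L])
})

test_that("planted rigid drift appears in the binarized rim centroid", {
  fld <- fluctuation_field(matrix(0, 32L, 10L), fps = 1000)
  vid <- render_contour_video(fld, radius0 = 1.5e-6, image_size = 110L,
                              pixel_size = 50e-9, drift = c(0.5, -0.3))
  cent <- t(vapply(1:10, function(k) {
    m <- vid[, , k] < 0.6
    idx <- which(m, arr.ind = TRUE)
    c(mean(idx[, 1L]), mean(idx[, 2L]))
  }, c(0, 0)))
  step <- apply(diff(cent), 2L, mean)
  expect_lt(abs(step[1L] - 0.5), 0.1)
  expect_lt(abs(step[2L] + 0.3), 0.1)
})

test_that("a planted mode-3 oscillation modulates the rim radius as rendered", {
  T_ <- 16L; amp_px <- 4
  ph <- seq(0, 2 * pi, length.out = T_ + 1L)[-(T_ + 1L)]
  h <- outer(cos(3 * rbcflicker:::angle_grid(64L)), amp_px * 50e-9 * cos(ph))
  fld <- fluctuation_field(h, fps = 1000)
  # re-add the time mean the constructor removes: planted oscillation is
  # mean-free over the full cycle, so h is unchanged
  vid <- render_contour_video(fld, radius0 = 2e-6, image_size = 128L,
                              pixel_size = 50e-9)
  r_theta0 <- vapply(seq_len(T_), function(k) {
    prof <- vid[64:128, 64L, k]        # ray along +x from the center
    (which.min(prof) - 1L) + 0.5       # px, crude rim position
  }, 0)
  osc <- (max(r_theta0) - min(r_theta0)) / 2
  expect_lt(abs(osc - amp_px), 0.1 * amp_px + 0.5)
})

test_that("absorbance generator encodes the planted hemolysis level", {
  rec0 <- generate_absorbance(hb_level = 0, blank_sd = 0, seed = 1L)
  blank <- rec0[rec0$role == "blank", c("A415", "A380", "A450")][1L, ]
  sample0 <- rec0[rec0$role == "sample", c("A415", "A380", "A450")][1L, ]
  expect_equal(unlist(sample0), unlist(blank), tolerance = 1e-12)
  rec1 <- generate_absorbance(hb_level = 1, blank_sd = 0, seed = 1L)
  s1 <- rec1[rec1$role == "sample", c("A415", "A380", "A450")][1L, ]
  ref <- rec1[rec1$role == "lysis_reference", c("A415", "A380", "A450")][1L, ]
  expect_equal(unlist(s1), unlist(ref), tolerance = 1e-12)
})

test_that("blank read noise matches the requested sd", {
  rec <- generate_absorbance(hb_level = 0.1, blank_sd = 0.01, seed = 6L)
  blanks <- rec[rec$role == "blank", ]
  expect_equal(nrow(blanks), 15L)
  s <- stats::sd(blanks$A415)
  expect_gt(s, 0.005); expect_lt(s, 0.015)
})
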