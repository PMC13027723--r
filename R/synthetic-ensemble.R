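#' Specification of a synthetic static contour ensemble
#'
#' Ground truth for the ensemble ("ergodic") tension analysis: a population
#' of contours whose low-order Fourier modes fluctuate with the
#' tension-dominated Helfrich-like spectrum E|h_n|^2 = kBT / (2 pi n sigma0)
#' for n in `mode_band`, zero elsewhere.
#'
#' @param n_cells Number of contours in the ensemble.
#' @param n_angles Angular samples per contour.
#' @param tension_true Effective lateral tension sigma0 in N/m.
#' @param mode_band Integer mode indices carrying power (all >= 2; the
#'   translation mode n = 1 is never populated).
#' @param radius0 Mean contour radius R0 in meters.
#' @param temperature Temperature in K.
#' @param seed Integer seed.
#' @return A list of class `rbc_ensemble_spec`.
#' @export
ensemble_spec <- function(n_cells = 300L, n_angles = 720L,
                          tension_true = 5e-7, mode_band = c(2L, 3L, 4L),
                          radius0 = 7.5e-6, temperature = 310.15, seed = 1L) {
  mode_band <- as.integer(mode_band)
  stopifnot(n_cells >= 1, n_angles >= 8, tension_true > 0,
            all(mode_band >= 2), radius0 > 0, temperature > 0)
  structure(list(n_cells = as.integer(n_cells),
                 n_angles = as.integer(n_angles),
                 tension_true = tension_true, mode_band = mode_band,
                 radius0 = radius0, temperature = temperature, seed = seed),
            class = "rbc_ensemble_spec")
}

#' Generate a static contour ensemble with known effective tension
#'
#' Each contour is R(theta) = R0 + h(theta) with independent real mode
#' amplitudes: h(theta) = sum_n a_n cos(n theta) + b_n sin(n theta),
#' a_n, b_n ~ N(0, 2 kBT / (2 pi n sigma0)) so that the complex Fourier
#' coefficient h_n = (a_n - i b_n)/2 (forward transform normalised by 1/N)
#' satisfies E|h_n|^2 = kBT / (2 pi n sigma0). h is real by construction and
#' carries no n = 0 component, so the angular mean of h is exactly zero.
#'
#' @param spec An [ensemble_spec()].
#' @return List with `contours` (list of `rbc_contour`) and `truth`
#'   (sigma0, expected per-mode power, temperature).
#' @export
generate_static_ensemble <- function(spec) {
  stopifnot(inherits(spec, "rbc_ensemble_spec"))
  kBT <- kB * spec$temperature
  theta <- angle_grid(spec$n_angles)
  v <- 2 * kBT / (2 * pi * spec$mode_band * spec$tension_true)  # Var(a_n)
  with_gen_seed(spec$seed, {
    contours <- lapply(seq_len(spec$n_cells), function(i) {
      h <- numeric(spec$n_angles)
      for (j in seq_along(spec$mode_band)) {
        n <- spec$mode_band[j]
        ab <- stats::rnorm(2L, sd = sqrt(v[j]))
        h <- h + ab[1L] * cos(n * theta) + ab[2L] * sin(n * theta)
      }
      contour_polar(spec$radius0 + h, pixel_size = 0.103e-6,
                    cell_id = sprintf("ens%04d", i))
    })
    truth <- list(sigma0 = spec$tension_true,
                  power_expected = stats::setNames(
                    kBT / (2 * pi * spec$mode_band * spec$tension_true),
                    spec$mode_band),
                  temperature = spec$temperature)
    list(contours = contours, truth = truth)
  })
}
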