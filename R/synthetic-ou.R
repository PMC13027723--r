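#' Simulate stationary Ornstein-Uhlenbeck series by the exact discrete update
#'
#' Each series follows the overdamped Langevin dynamics of a local contour
#' coordinate h(t) in a harmonic well of stiffness `k0` with friction `gamma0`
#' at temperature `T`: relaxation rate omega = k0/gamma0, stationary variance
#' kBT/k0, short-time diffusivity kBT/gamma0. The update is the exact
#' transition density of the OU process,
#' \deqn{h_{k+1} = h_k e^{-\omega \Delta t} + \xi
#'       \sqrt{(k_BT/k_0)(1 - e^{-2\omega\Delta t})},}
#' not an Euler step, so recovery tests are free of discretisation bias.
#' The initial value of every series is a stationary draw.
#'
#' @param n_series Number of independent series (rows).
#' @param n_frames Number of time samples per series (columns).
#' @param dt Time step in seconds.
#' @param var_stat Stationary variance kBT/k0, in m^2.
#' @param omega Relaxation rate k0/gamma0, in 1/s.
#' @param seed Optional integer seed (deterministic output).
#' @return Matrix `n_series x n_frames` in meters.
#' @export
simulate_ou <- function(n_series, n_frames, dt, var_stat, omega, seed = NULL) {
  stopifnot(n_series >= 1, n_frames >= 2, dt > 0, var_stat > 0, omega > 0)
  with_gen_seed(seed, {
    phi <- exp(-omega * dt)
    sd_innov <- sqrt(var_stat * (1 - phi^2))
    h <- matrix(0, n_series, n_frames)
    h[, 1L] <- stats::rnorm(n_series, sd = sqrt(var_stat))
    for (k in seq_len(n_frames - 1L)) {
      h[, k + 1L] <- h[, k] * phi + stats::rnorm(n_series, sd = sd_innov)
    }
    h
  })
}

#' Specification of a simulated per-angle fluctuation dynamics record
#'
#' Ground-truth parameters for [generate_angle_dynamics()]: each angular
#' station of the contour relaxes in an independent harmonic well.
#'
#' @param n_angles Number of angular stations (independent series).
#' @param n_frames Number of frames.
#' @param fps Frame rate in frames per second.
#' @param stiffness_true Per-coordinate stiffness k0 in N/m.
#' @param friction_true Friction coefficient gamma0 in kg/s.
#' @param temperature Temperature in K.
#' @param seed Integer seed.
#' @return A list of class `rbc_ou_spec`.
#' @export
ou_spec <- function(n_angles = 64L, n_frames = 6000L, fps = 2000,
                    stiffness_true = 2e-6, friction_true = 1e-7,
                    temperature = 310.15, seed = 1L) {
  stopifnot(n_angles >= 1, n_frames >= 2, fps > 0,
            stiffness_true > 0, friction_true > 0, temperature > 0)
  structure(list(n_angles = as.integer(n_angles),
                 n_frames = as.integer(n_frames), fps = fps,
                 stiffness_true = stiffness_true,
                 friction_true = friction_true,
                 temperature = temperature, seed = seed),
            class = "rbc_ou_spec")
}

#' Generate a synthetic per-angle fluctuation field with known dynamics
#'
#' Simulates `n_angles` independent stationary OU series (the per-angle
#' contour fluctuation time series of one cell) and returns them as a
#' fluctuation field together with the ground truth record. The integration
#' step must resolve the relaxation: (k0/gamma0)/fps < 0.1 or the spec is
#' rejected.
#'
#' @param spec An [ou_spec()].
#' @return List with `field` (an `rbc_fluctuation_field`: matrix `h` of size
#'   n_angles x n_frames in meters, `fps`, `cell_id`) and `truth` (list with
#'   k0, gamma0, D0 = kBT/gamma0, omega0 = k0/gamma0, var0 = kBT/k0).
#' @export
generate_angle_dynamics <- function(spec) {
  stopifnot(inherits(spec, "rbc_ou_spec"))
  omega0 <- spec$stiffness_true / spec$friction_true
  if (omega0 / spec$fps >= 0.1) {
    stop("time step 1/fps does not resolve the relaxation rate: ",
         "(k0/gamma0)/fps = ", signif(omega0 / spec$fps, 3), " >= 0.1")
  }
  kBT <- kB * spec$temperature
  var0 <- kBT / spec$stiffness_true
  h <- simulate_ou(spec$n_angles, spec$n_frames, 1 / spec$fps,
                   var0, omega0, seed = spec$seed)
  field <- fluctuation_field(h, fps = spec$fps, cell_id = "synthetic")
  truth <- list(k0 = spec$stiffness_true, gamma0 = spec$friction_true,
                D0 = kBT / spec$friction_true, omega0 = omega0, var0 = var0,
                temperature = spec$temperature)
  list(field = field, truth = truth)
}

#' Generate a band-limited fluctuation field with known OU dynamics
#'
#' Variant of [generate_angle_dynamics()] whose angular profile is smooth:
#' the field is a superposition of Fourier modes in `mode_band`, each mode
#' coordinate following an independent stationary OU process with a common
#' relaxation rate omega0 = k0/gamma0. Every per-angle series is then
#' exactly an OU process with stationary variance kBT/k0 and short-time
#' diffusivity kBT/gamma0 (the per-mode variances sum to kBT/k0 at every
#' angle), but unlike the angularly independent generator the field is
#' band-limited, so it survives rendering and optical contour tracking:
#' an angularly white field has piecewise-linear corners no smooth-contour
#' tracker can represent.
#'
#' @param spec An [ou_spec()]; `stiffness_true`/`friction_true` are the
#'   per-angle (not per-mode) parameters.
#' @param mode_band Integer mode indices carrying the power (default 2:8).
#' @return As [generate_angle_dynamics()]; `truth` additionally carries
#'   `mode_band`.
#' @export
generate_mode_dynamics <- function(spec, mode_band = 2:8) {
  stopifnot(inherits(spec, "rbc_ou_spec"), all(mode_band >= 1))
  omega0 <- spec$stiffness_true / spec$friction_true
  if (omega0 / spec$fps >= 0.1) {
    stop("time step 1/fps does not resolve the relaxation rate: ",
         "(k0/gamma0)/fps = ", signif(omega0 / spec$fps, 3), " >= 0.1")
  }
  kBT <- kB * spec$temperature
  var0 <- kBT / spec$stiffness_true
  v_mode <- var0 / length(mode_band)
  coefs <- simulate_ou(2L * length(mode_band), spec$n_frames, 1 / spec$fps,
                       v_mode, omega0, seed = spec$seed)
  theta <- angle_grid(spec$n_angles)
  h <- matrix(0, spec$n_angles, spec$n_frames)
  for (j in seq_along(mode_band)) {
    n <- mode_band[j]
    h <- h + cos(n * theta) %o% coefs[2L * j - 1L, ] +
             sin(n * theta) %o% coefs[2L * j, ]
  }
  field <- fluctuation_field(h, fps = spec$fps, cell_id = "synthetic")
  truth <- list(k0 = spec$stiffness_true, gamma0 = spec$friction_true,
                D0 = kBT / spec$friction_true, omega0 = omega0, var0 = var0,
                mode_band = mode_band, temperature = spec$temperature)
  list(field = field, truth = truth)
}
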