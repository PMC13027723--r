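# Fourier convention stamped into every spectrum so tensions are never
# separated from the normalization that produced them: forward transform
# h_n = (1/N) sum_j h(theta_j) exp(-i n theta_j), two-sided coefficients,
# tension inverted from the one-sided modulus.
FOURIER_CONVENTION <- "fft/N two-sided, one-sided modes 1..N/2, v1"

#' Contour Fourier-mode power of a fluctuation profile
#'
#' Transforms h(theta_j) on the uniform N-angle grid with the FFT and
#' returns the per-mode squared modulus |h_n|^2 for n = 1..N/2 under the
#' 1/N forward normalization (so a profile c*cos(3 theta) carries
#' |h_3|^2 = c^2/4). The n = 0 (mean) component is excluded by
#' construction; n = 1 is the translation mode and is reported but never
#' used for tension.
#'
#' @param h Numeric vector of length N >= 8: fluctuation profile in meters
#'   on the uniform angular grid, or an `rbc_contour` (its h(theta) is
#'   used).
#' @return Object of class `rbc_mode_spectrum`: data.frame-like list with
#'   `modes`, `power` (m^2), `n_samples = 1`, `convention_id`.
#' @export
mode_spectrum <- function(h) {
  if (inherits(h, "rbc_contour")) h <- contour_h(h)
  h <- as.numeric(h)
  n <- length(h)
  if (n < 8L) stop("need at least 8 angular samples")
  if (!all(is.finite(h))) stop("non-finite fluctuation profile")
  coef <- stats::fft(h) / n
  modes <- seq_len(n %/% 2L)
  structure(list(modes = modes, power = Mod(coef[modes + 1L])^2,
                 n_samples = 1L, convention_id = FOURIER_CONVENTION),
            class = "rbc_mode_spectrum")
}

#' @export
print.rbc_mode_spectrum <- function(x, ...) {
  cat(sprintf("Mode spectrum: %d modes, %d sample(s), convention '%s'\n",
              length(x$modes), x$n_samples, x$convention_id))
  invisible(x)
}

#' @export
plot.rbc_mode_spectrum <- function(x, ...) {
  graphics::plot(x$modes, x$power, log = "xy", xlab = "mode n",
                 ylab = expression("<|h"[n] * "|"^2 * "> (m"^2 * ")"), ...)
  invisible(x)
}

#' Ensemble-averaged mode spectrum
#'
#' Arithmetic per-mode mean over a population of single-contour spectra
#' (the ergodic proxy: ensemble averaging over cells at one instant in
#' place of time averaging for one cell). All inputs must share the mode
#' grid and Fourier convention.
#'
#' @param spectra List of `rbc_mode_spectrum`.
#' @return An `rbc_mode_spectrum` with `n_samples` = number of inputs.
#' @export
ensemble_spectrum <- function(spectra) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "rbc_mode_spectrum")))
  conv <- unique(vapply(spectra, function(s) s$convention_id, ""))
  if (length(conv) != 1L)
    stop("mixed Fourier conventions in ensemble: ", paste(conv, collapse = " / "))
  nm <- vapply(spectra, function(s) length(s$modes), 0L)
  if (length(unique(nm)) != 1L)
    stop("spectra have differing mode counts")
  pw <- rowMeans(vapply(spectra, function(s) s$power, numeric(nm[1L])))
  structure(list(modes = spectra[[1L]]$modes, power = pw,
                 n_samples = length(spectra), convention_id = conv),
            class = "rbc_mode_spectrum")
}

#' Effective lateral tension from low-mode fluctuation power
#'
#' In the tension-dominated regime (wave vectors well below the
#' tension/bending crossover) the equatorial fluctuation spectrum of a
#' Helfrich-like membrane falls off inversely with the mode index, and an
#' operational effective tension follows from
#' sigma_eff = kBT / (2 pi n <|h_n|^2>), evaluated at a low mode (default
#' n = 3) or averaged over a low-mode band. The absolute scale is tied to
#' the Fourier convention stamped in the spectrum; sigma_eff is a
#' comparative descriptor under a fixed acquisition and analysis pipeline,
#' not an absolute material constant.
#'
#' @param spectrum An `rbc_mode_spectrum` (typically ensemble-averaged).
#' @param thermal An [thermal_context()].
#' @param mode_used Integer mode index >= 2, or a band of indices (the
#'   per-mode tensions are then averaged).
#' @return Object of class `rbc_tension`: list with `sigma_eff` (N/m),
#'   `mode_used`, `n_cells`, `temperature`, `convention_id`.
#' @export
effective_tension <- function(spectrum, thermal = thermal_context(),
                              mode_used = 3L) {
  stopifnot(inherits(spectrum, "rbc_mode_spectrum"))
  thermal <- as_thermal(thermal)
  mode_used <- as.integer(mode_used)
  if (any(mode_used < 2L))
    stop("mode_used must be >= 2 (n = 1 is the translation mode)")
  pos <- match(mode_used, spectrum$modes)
  if (anyNA(pos)) stop("requested mode(s) absent from the spectrum")
  pw <- spectrum$power[pos]
  if (any(pw <= 0))
    stop("zero power at requested mode(s): tension is undefined")
  sigma <- mean(thermal$kBT / (2 * pi * mode_used * pw))
  structure(list(sigma_eff = sigma, mode_used = mode_used,
                 n_cells = spectrum$n_samples,
                 temperature = thermal$temperature,
                 convention_id = spectrum$convention_id),
            class = "rbc_tension")
}

#' @export
print.rbc_tension <- function(x, ...) {
  cat(sprintf(
    "Effective lateral tension: %.3g N/m (mode %s, %d cells, T = %.2f K)\n",
    x$sigma_eff, paste(x$mode_used, collapse = ","), x$n_cells,
    x$temperature))
  invisible(x)
}
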