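#' Boltzmann constant (J/K)
#'
#' Exact SI value, used by every fluctuation-inference formula in the package.
#' @export
kB <- 1.380649e-23

#' Thermal context for fluctuation inference
#'
#' Bundles the absolute temperature with the thermal energy `kBT` so that
#' every estimator (effective tension, effective rigidity, friction) draws on
#' one consistent value. The default 310.15 K corresponds to the 37 degree C
#' acquisition temperature of the imaging protocol.
#'
#' @param temperature Absolute temperature in kelvin. Must be positive.
#' @return An object of class `rbc_thermal` with fields `temperature` (K) and
#'   `kBT` (J).
#' @examples
#' th <- thermal_context()
#' th$kBT  # ~4.28e-21 J at 37 C
#' @export
thermal_context <- function(temperature = 310.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0)
  structure(list(temperature = temperature, kBT = kB * temperature),
            class = "rbc_thermal")
}

#' @export
print.rbc_thermal <- function(x, ...) {
  cat(sprintf("Thermal context: T = %.2f K, kBT = %.6g J\n",
              x$temperature, x$kBT))
  invisible(x)
}

as_thermal <- function(x) {
  if (inherits(x, "rbc_thermal")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(thermal_context(x))
  stop("expected a thermal_context() or a temperature in kelvin")
}
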