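#' Mean squared displacement of a fluctuation time series
#'
#' MSD(tau_m) = <(h(t + tau_m) - h(t))^2> over all T - m overlapping pairs,
#' for lags m = 0..max_lag (in units of 1/fps).
#'
#' @param series Numeric time series (meters).
#' @param max_lag Largest lag in frames; must satisfy max_lag < T - 1.
#' @param fps Frame rate, used to express lags in seconds.
#' @return Object of class `rbc_msd`: list with `lag_s`, `msd` (m^2),
#'   `n_pairs`.
#' @export
msd_curve <- function(series, max_lag = 10L, fps = 1) {
  series <- as.numeric(series)
  T_ <- length(series)
  max_lag <- as.integer(max_lag)
  if (max_lag >= T_ - 1L) stop("max_lag must be below the series length - 1")
  stopifnot(max_lag >= 1, fps > 0)
  lags <- 0:max_lag
  msd <- vapply(lags, function(m) {
    if (m == 0L) return(0)
    mean((series[(m + 1L):T_] - series[seq_len(T_ - m)])^2)
  }, 0)
  structure(list(lag_s = lags / fps, msd = msd, n_pairs = T_ - lags),
            class = "rbc_msd")
}

#' @export
plot.rbc_msd <- function(x, ...) {
  graphics::plot(x$lag_s, x$msd, xlab = "lag (s)",
                 ylab = expression("MSD (m"^2 * ")"), ...)
  invisible(x)
}

#' Einstein diffusivity from the initial MSD slope
#'
#' Least-squares fit of MSD = 2 D tau through the origin over the first
#' `fit_lags` positive lags (default 10, i.e. 5 ms at 2000 fps, well inside
#' the linear short-time regime for typical relaxation times). The fit's
#' relative residual is attached as a quality flag.
#'
#' @param msd An [msd_curve()].
#' @param fit_lags Number of positive lags in the fit window (>= 2).
#' @return D in m^2/s with attribute `rel_residual`.
#' @export
fit_diffusivity <- function(msd, fit_lags = 10L) {
  stopifnot(inherits(msd, "rbc_msd"), fit_lags >= 2)
  keep <- which(msd$lag_s > 0)[seq_len(fit_lags)]
  if (anyNA(keep)) stop("fit window exceeds the available lags")
  tau <- msd$lag_s[keep]; y <- msd$msd[keep]
  if (all(y == 0))
    stop_degenerate("degenerate series: MSD is identically zero over the fit window")
  D <- sum(y * tau) / (2 * sum(tau^2))
  resid <- y - 2 * D * tau
  structure(D, rel_residual = sqrt(mean(resid^2)) / sqrt(mean(y^2)))
}

#' Effective local rigidity by equipartition
#'
#' Under thermal equilibrium a harmonically confined contour coordinate
#' satisfies <h^2> = kBT / k_eff, so k_eff = kBT / <h^2>_t with the
#' time-averaged mean square of the zero-mean series (population divisor
#' T). Equivalent to the large-lag MSD plateau: MSD(tau -> inf) = 2 <h^2>.
#'
#' @param series Numeric time series (meters).
#' @param thermal An [thermal_context()].
#' @return k_eff in N/m.
#' @export
effective_rigidity <- function(series, thermal = thermal_context()) {
  thermal <- as_thermal(thermal)
  series <- as.numeric(series)
  ms <- mean((series - mean(series))^2)
  if (ms <= 0) stop_degenerate("degenerate series: zero variance")
  thermal$kBT / ms
}

#' Friction and relaxation frequency from rigidity and diffusivity
#'
#' The Einstein relation gives the effective friction gamma = kBT / D for
#' the overdamped contour coordinate; the characteristic relaxation
#' frequency is omega_c = k_eff / gamma = k_eff D / kBT and tau_c = 1 /
#' omega_c. By construction gamma * D = kBT exactly.
#'
#' @param k_eff Effective rigidity in N/m (> 0).
#' @param D Diffusivity in m^2/s (> 0).
#' @param thermal An [thermal_context()].
#' @return List: gamma (kg/s), omega_c (1/s), tau_c (s).
#' @export
derived_rates <- function(k_eff, D, thermal = thermal_context()) {
  thermal <- as_thermal(thermal)
  if (!is.finite(k_eff) || k_eff <= 0) stop("k_eff must be positive")
  if (!is.finite(D) || D <= 0) stop("D must be positive")
  gamma <- thermal$kBT / D
  omega_c <- k_eff * D / thermal$kBT
  list(gamma = gamma, omega_c = omega_c, tau_c = 1 / omega_c)
}

#' Signal volatility (non-stationarity marker)
#'
#' Moving standard deviation of the signal over `window_s` windows placed
#' every `stride_s` (half-overlapping by default); the volatility is the
#' standard deviation across the window-sd sequence, i.e. the variability
#' of the fluctuation amplitude within the record. A stationary-amplitude
#' signal has volatility near zero regardless of its overall amplitude.
#' Partial trailing windows are discarded.
#'
#' @param series Numeric time series.
#' @param fps Frame rate in frames per second.
#' @param window_s Window length in seconds (default 0.5).
#' @param stride_s Window step in seconds (default 0.25).
#' @return Volatility in the units of `series`.
#' @export
signal_volatility <- function(series, fps, window_s = 0.5, stride_s = 0.25) {
  series <- as.numeric(series)
  stopifnot(fps > 0, window_s > 0, stride_s > 0)
  n_win <- max(2L, round(window_s * fps))
  stride <- max(1L, round(stride_s * fps))
  T_ <- length(series)
  if (T_ < n_win) stop("series shorter than one volatility window")
  starts <- seq.int(1L, T_ - n_win + 1L, by = stride)
  if (length(starts) < 2L) stop("fewer than 2 volatility windows")
  sds <- vapply(starts, function(s) stats::sd(series[s:(s + n_win - 1L)]), 0)
  stats::sd(sds)
}

#' Per-cell viscoelastic summary of a fluctuation field
#'
#' Computes k_eff, D and volatility for every angular station of the field,
#' aggregates to the cell level by the median across angles (robust to dead
#' angles), and derives gamma, omega_c and tau_c from the aggregated
#' values. Angles whose series are degenerate (zero variance, or an MSD fit
#' failure) are dropped and counted; a cell with more than half its angles
#' degenerate is flagged unusable.
#'
#' @param field An [fluctuation_field()].
#' @param thermal An [thermal_context()].
#' @param fit_lags MSD fit window (positive lags), see [fit_diffusivity()].
#' @param max_lag Largest MSD lag computed.
#' @param window_s,stride_s Volatility windows, see [signal_volatility()].
#' @param condition Label copied into the record.
#' @return Object of class `rbc_dynamics`: one-row data.frame with columns
#'   cell_id, condition, k_eff, D, gamma, omega_c, tau_c, volatility,
#'   n_angles_used, usable.
#' @export
cell_summary <- function(field, thermal = thermal_context(),
                         fit_lags = 10L, max_lag = max(10L, fit_lags),
                         window_s = 0.5, stride_s = 0.25,
                         condition = NA_character_) {
  stopifnot(inherits(field, "rbc_fluctuation_field"))
  thermal <- as_thermal(thermal)
  n_ang <- nrow(field$h)
  k_a <- D_a <- v_a <- rep(NA_real_, n_ang)
  for (j in seq_len(n_ang)) {
    s <- field$h[j, ]
    ok <- tryCatch({
      k_a[j] <- effective_rigidity(s, thermal)
      D_a[j] <- as.numeric(fit_diffusivity(
        msd_curve(s, max_lag = max_lag, fps = field$fps), fit_lags))
      v_a[j] <- signal_volatility(s, field$fps, window_s, stride_s)
      TRUE
    }, rbc_degenerate_input = function(e) FALSE)
    if (!ok) { k_a[j] <- D_a[j] <- v_a[j] <- NA_real_ }
  }
  used <- which(is.finite(k_a) & is.finite(D_a) & D_a > 0)
  usable <- length(used) >= n_ang / 2
  if (!usable) {
    rec <- data.frame(cell_id = field$cell_id, condition = condition,
                      k_eff = NA_real_, D = NA_real_, gamma = NA_real_,
                      omega_c = NA_real_, tau_c = NA_real_,
                      volatility = NA_real_, n_angles_used = length(used),
                      usable = FALSE, stringsAsFactors = FALSE)
    return(structure(rec, class = c("rbc_dynamics", "data.frame")))
  }
  k_eff <- stats::median(k_a[used])
  D <- stats::median(D_a[used])
  rates <- derived_rates(k_eff, D, thermal)
  rec <- data.frame(cell_id = field$cell_id, condition = condition,
                    k_eff = k_eff, D = D, gamma = rates$gamma,
                    omega_c = rates$omega_c, tau_c = rates$tau_c,
                    volatility = stats::median(v_a[used]),
                    n_angles_used = length(used), usable = TRUE,
                    stringsAsFactors = FALSE)
  structure(rec, class = c("rbc_dynamics", "data.frame"))
}

#' @export
print.rbc_dynamics <- function(x, ...) {
  cat("Per-cell flickering descriptors:\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
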