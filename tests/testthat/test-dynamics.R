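test_that("MSD handles degenerate and analytic series exactly", {
  cst <- msd_curve(rep(2e-8, 50L), max_lag = 10L, fps = 100)
  expect_true(all(cst$msd == 0))
  expect_equal(cst$msd[1L], 0)
  c0 <- 3e-8
  alt <- msd_curve(rep(c(c0, -c0), 30L), max_lag = 6L, fps = 100)
  expect_equal(alt$msd[c(2L, 4L, 6L) + 1L], rep(0, 3L))
  expect_equal(alt$msd[c(1L, 3L, 5L) + 1L], rep(4 * c0^2, 3L))
  expect_error(msd_curve(rnorm(10L), max_lag = 9L), "max_lag")
})

test_that("MSD equals the brute-force double loop", {
  set.seed(21)
  for (len in c(20L, 97L, 200L)) {
    s <- stats::rnorm(len, sd = 1e-8)
    mc <- msd_curve(s, max_lag = 15L, fps = 2000)
    expect_equal(mc$msd, msd_bruteforce(s, 15L), tolerance = 1e-15)
  }
})

test_that("OU mean squared displacement follows the closed form", {
  th0 <- thermal_context()
  k0 <- 2e-6; g0 <- 1e-7
  omega <- k0 / g0; var0 <- th0$kBT / k0
  h <- simulate_ou(20L, 6000L, 1 / 2000, var0, omega, seed = 4L)
  max_lag <- 50L  # tau up to 25 ms = 0.5/omega
  msd_avg <- Reduce(`+`, lapply(seq_len(20L), function(j)
    msd_curve(h[j, ], max_lag = max_lag, fps = 2000)$msd)) / 20
  tau <- (0:max_lag) / 2000
  closed <- 2 * var0 * (1 - exp(-omega * tau))
  rel <- abs(msd_avg[-1L] / closed[-1L] - 1)
  expect_lt(stats::median(rel), 0.10)
})

test_that("diffusivity is recovered from the initial MSD slope", {
  D0 <- 3e-15
  lin <- structure(list(lag_s = (0:12) / 2000,
                        msd = 2 * D0 * (0:12) / 2000,
                        n_pairs = rep(100L, 13L)), class = "rbc_msd")
  expect_equal(as.numeric(fit_diffusivity(lin, 10L)), D0, tolerance = 1e-12)
  th0 <- thermal_context()
  k0 <- 2e-6; g0 <- 1e-7
  h <- simulate_ou(8L, 6000L, 1 / 2000, th0$kBT / k0, k0 / g0, seed = 6L)
  D_hat <- stats::median(vapply(seq_len(8L), function(j)
    as.numeric(fit_diffusivity(msd_curve(h[j, ], 10L, fps = 2000), 10L)), 0))
  expect_rel_error(D_hat, th0$kBT / g0, 0.15)
  cst <- msd_curve(rep(1e-8, 100L), max_lag = 12L, fps = 2000)
  expect_error(fit_diffusivity(cst, 10L), class = "rbc_degenerate_input")
})

test_that("effective rigidity is the equipartition inverse of the variance", {
  th0 <- thermal_context()
  k0 <- 2e-6
  s <- c(-1, 1) * sqrt(th0$kBT / k0)  # mean square exactly kBT/k0
  expect_equal(effective_rigidity(s, th0), k0, tolerance = 1e-12)
  expect_error(effective_rigidity(rep(1e-8, 10L), th0),
               class = "rbc_degenerate_input")
  k_hat <- vapply(1:20, function(seed) {
    h <- simulate_ou(1L, 6000L, 1 / 2000, th0$kBT / k0, 100, seed = seed)
    effective_rigidity(h[1L, ], th0)
  }, 0)
  expect_rel_error(stats::median(k_hat), k0, 0.10)
})

test_that("friction and relaxation frequency derive exactly from k_eff and D", {
  th0 <- thermal_context()
  r <- derived_rates(k_eff = 1, D = th0$kBT, th0)
  expect_equal(r$gamma, 1, tolerance = 1e-15)
  g <- 1e-7
  r2 <- derived_rates(k_eff = 2e-6, D = th0$kBT / g, th0)
  expect_equal(r2$omega_c, 20, tolerance = 1e-12)
  expect_equal(r2$omega_c * r2$tau_c, 1, tolerance = 1e-12)
  expect_error(derived_rates(-1, 1e-15, th0), "positive")
  expect_error(derived_rates(1e-6, 0, th0), "positive")
})

test_that("omega_c recovery composes the rigidity and diffusivity recoveries", {
  th0 <- thermal_context()
  k0 <- 2e-6; g0 <- 1e-7
  omega_hat <- vapply(1:10, function(seed) {
    h <- simulate_ou(1L, 6000L, 1 / 2000, th0$kBT / k0, k0 / g0, seed = 100 + seed)
    k_hat <- effective_rigidity(h[1L, ], th0)
    D_hat <- as.numeric(fit_diffusivity(msd_curve(h[1L, ], 10L, fps = 2000), 10L))
    derived_rates(k_hat, D_hat, th0)$omega_c
  }, 0)
  expect_rel_error(stats::median(omega_hat), k0 / g0, 0.20)
})

test_that("volatility flags amplitude modulation and nothing else", {
  expect_error(signal_volatility(rep(1, 10L), fps = 2000), "window")
  s_const <- rep(2e-8, 4000L)
  expect_equal(signal_volatility(s_const, fps = 2000), 0)
  # sinusoid with an integer number of periods per window
  t <- seq_len(4000L)
  sinu <- 3e-8 * sin(2 * pi * t / 250)  # 4 periods per 0.5 s window
  expect_lt(signal_volatility(sinu, fps = 2000), 1e-12 * 3e-8)
  # offset invariance and linear amplitude scaling
  set.seed(5)
  s <- stats::rnorm(4000L, sd = 1e-8)
  v0 <- signal_volatility(s, fps = 2000)
  expect_equal(signal_volatility(s + 5e-7, fps = 2000), v0, tolerance = 1e-9)
  expect_equal(signal_volatility(3 * s, fps = 2000), 3 * v0, tolerance = 1e-9)
  # modulated beats stationary in most seed pairs (full census in acceptance)
  wins <- vapply(1:20, function(seed) {
    set.seed(seed)
    stat <- stats::rnorm(4000L, sd = 1e-8)
    mod <- stats::rnorm(4000L, sd = 1e-8) *
      rep(c(1, 2), each = 2000L)
    signal_volatility(mod, 2000) > signal_volatility(stat, 2000)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("cell summaries aggregate angles robustly and keep gamma D = kBT", {
  th0 <- thermal_context()
  k0 <- 2e-6; g0 <- 1e-7
  dyn <- generate_angle_dynamics(ou_spec(n_angles = 64L, n_frames = 4000L,
                                         fps = 2000, stiffness_true = k0,
                                         friction_true = g0, seed = 2L))
  rec <- cell_summary(dyn$field, th0)
  expect_true(rec$usable)
  expect_rel_error(rec$k_eff, k0, 0.10)
  expect_equal(rec$gamma * rec$D, th0$kBT, tolerance = 1e-9 * th0$kBT)
  expect_equal(rec$omega_c * rec$tau_c, 1, tolerance = 1e-12)
  # dead angles are dropped and counted, the summary stands
  h2 <- dyn$field$h
  h2[1:10, ] <- 0
  fld2 <- fluctuation_field(h2, fps = 2000)
  rec2 <- cell_summary(fld2, th0)
  expect_equal(rec2$n_angles_used, 54L)
  expect_rel_error(rec2$k_eff, rec$k_eff, 0.05)
  # > 50% degenerate angles flags the cell unusable
  h3 <- dyn$field$h
  h3[1:40, ] <- 0
  rec3 <- cell_summary(fluctuation_field(h3, fps = 2000), th0)
  expect_false(rec3$usable)
})

test_that("omega_c increases with k_eff at fixed D", {
  th0 <- thermal_context()
  D <- 1e-13
  k <- c(1e-6, 2e-6, 5e-6)
  w <- vapply(k, function(kk) derived_rates(kk, D, th0)$omega_c, 0)
  expect_true(all(diff(w) > 0))
})
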