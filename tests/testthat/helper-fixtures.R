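# Shared fixtures and independent oracles. Expensive fixtures are memoized
# for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Demo scene rendered, preprocessed and segmented (per seed).
scene_fixture <- function(seed = 1L) {
  memo(paste0("scene", seed), {
    spec <- demo_scene_spec(seed)
    scene <- generate_field_scene(spec)
    fr <- preprocess_frame(scene$image)
    det <- detect_and_filter(fr, acceptance_criteria(),
                             pixel_size = spec$pixel_size)
    list(spec = spec, scene = scene, frame = fr, det = det)
  })
}

# Analytic circle / ellipse contours on the uniform grid (radii in meters).
circle_contour <- function(radius_m = 3.5e-6, n = 720L, pixel = 0.103e-6) {
  contour_polar(rep(radius_m, n), pixel_size = pixel)
}

ellipse_contour <- function(a_m, b_m, n = 720L, pixel = 0.103e-6) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  r <- a_m * b_m / sqrt((b_m * cos(th))^2 + (a_m * sin(th))^2)
  contour_polar(r, pixel_size = pixel)
}

# --- independent oracles -------------------------------------------------

# Exhaustive Otsu: scan all bin splits of a 256-bin histogram, maximizing
# between-class variance computed from first principles.
otsu_bruteforce_bin <- function(v, levels = 256L) {
  rng <- range(v)
  edges <- seq(rng[1L], rng[2L], length.out = levels + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              levels)
  counts <- tabulate(bin, nbins = levels)
  mids <- (edges[-1L] + edges[-(levels + 1L)]) / 2
  best <- -Inf; best_t <- NA_integer_
  n_tot <- sum(counts)
  for (t in seq_len(levels - 1L)) {
    n0 <- sum(counts[1:t]); n1 <- n_tot - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / n0
    mu1 <- sum(counts[(t + 1):levels] * mids[(t + 1):levels]) / n1
    bcv <- (n0 / n_tot) * (n1 / n_tot) * (mu0 - mu1)^2
    if (bcv > best + 1e-18) { best <- bcv; best_t <- t }
  }
  best_t
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(na+nb, na) group assignments of the pooled ranks.
mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2L, function(idx)
    sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force MSD by the double loop over all ordered pairs.
msd_bruteforce <- function(series, max_lag) {
  T_ <- length(series)
  vapply(0:max_lag, function(m) {
    if (m == 0L) return(0)
    acc <- 0
    for (t in seq_len(T_ - m)) acc <- acc + (series[t + m] - series[t])^2
    acc / (T_ - m)
  }, 0)
}

# Radial intensity profile of an image about a center (for rim-position
# oracles): mean intensity in 1 px annuli.
radial_profile <- function(img, cx, cy) {
  idx <- which(is.finite(img), arr.ind = TRUE)
  r <- sqrt((idx[, 1L] - 1 - cx)^2 + (idx[, 2L] - 1 - cy)^2)
  b <- floor(r) + 1L
  prof <- tapply(img[idx], b, mean)
  data.frame(r_px = as.numeric(names(prof)) - 0.5, intensity = as.numeric(prof))
}

expect_rel_error <- function(value, truth, tol) {
  expect_lt(abs(value / truth - 1), tol)
}
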