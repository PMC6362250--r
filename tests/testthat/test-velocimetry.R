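test_that("covariance of a static phasor is rank one with conserved trace", {
  spec <- phantom_spec(n_positions = 4, depth_px = 16, noise_sigma = 0,
                       static_amplitude = 1.5, seed = 2)
  ens <- make_flow_phantom(spec)$ensemble
  cov <- ensemble_covariance(ens, 2, c(1, 16))
  es <- eigen_split(cov, 1)
  n <- spec$n_repeats
  expect_equal(es$values[1], 1.5^2 * n, tolerance = 1e-10)
  expect_lt(max(es$values[-1]), 1e-10)
  # trace = mean per-depth signal energy, conserved by the eigenvalues
  energy <- mean(apply(Mod(ens$signal[, , 2])^2, 1, sum))
  expect_equal(sum(es$values), energy, tolerance = 1e-10)
  expect_equal(sum(es$values), Re(sum(diag(cov$matrix))),
               tolerance = 1e-10)
})

test_that("orthogonal static and flow components split into two eigenvalues", {
  # construct exactly orthogonal temporal vectors: DC and a phasor at a
  # bin frequency (f = rate * m / N); the per-depth relative phases step
  # through a full cycle so the static/flow cross terms cancel exactly
  n <- 50; rate <- 20000
  f <- rate * 4 / n
  t_k <- (0:(n - 1)) / rate
  a_static <- 2; a_flow <- 1.2
  z <- 32
  X <- matrix(0i, z, n)
  for (i in seq_len(z))
    X[i, ] <- a_static +
      a_flow * exp(1i * (2 * pi * i / z + 2 * pi * f * t_k))
  sig <- array(X, dim = c(z, n, 1))
  ens <- ascan_ensemble(sig, rate, c(7, 7))
  es <- eigen_split(ensemble_covariance(ens, 1), 1)
  expect_equal(sort(es$values[1:2], decreasing = TRUE),
               c(a_static^2 * n, a_flow^2 * n), tolerance = 1e-6)
  expect_lt(max(es$values[-(1:2)]), 1e-6)
  # the flow eigenvector correlates with the programmed phasor
  phasor <- exp(1i * 2 * pi * f * t_k) / sqrt(n)
  expect_gt(Mod(sum(Conj(es$vectors[, 2]) * phasor)), 0.99)
})

test_that("eigen_split validates clutter count and PSD input", {
  spec <- phantom_spec(n_positions = 2, depth_px = 16, seed = 3)
  cov <- ensemble_covariance(make_flow_phantom(spec)$ensemble, 1)
  expect_error(eigen_split(cov, 50), "n_clutter")
  bad <- cov
  bad$matrix <- bad$matrix - diag(10, nrow(bad$matrix))
  expect_error(eigen_split(bad, 1), "positive semi-definite")
  expect_error(ensemble_covariance(make_flow_phantom(spec)$ensemble, 1,
                                   c(1, 99)), "window")
})

test_that("lag-one frequency is exact for pure phasors and wraps aliases", {
  rate <- 20000
  mk <- function(f, n = 50) exp(1i * 2 * pi * f * (0:(n - 1)) / rate)
  lf <- lag_one_frequency(mk(1007.5), rate)
  expect_equal(lf$frequency_hz, 1007.5, tolerance = 1e-9)
  expect_true(lf$defined)
  # constant vector: 0 Hz, full coherence
  expect_equal(lag_one_frequency(rep(1 + 0i, 50), rate)$frequency_hz, 0)
  # beyond-Nyquist input aliases by wrap-around
  expect_equal(lag_one_frequency(mk(12000), rate)$frequency_hz, -8000,
               tolerance = 1e-9)
  # broadband noise vector is flagged undefined
  set.seed(4)
  noise <- complex(real = rnorm(50), imaginary = rnorm(50))
  expect_false(lag_one_frequency(noise, rate)$defined)
})

test_that("frequency-to-velocity mapping is the exact Doppler inverse", {
  cal <- velocity_calibration(center_wavelength_nm = 1340,
                              refractive_index = 1.35)
  expect_equal(frequency_to_velocity(1007.46, cal), 0.5, tolerance = 1e-5)
  expect_equal(frequency_to_velocity(0, cal), 0)
  cal2 <- velocity_calibration(slope_mm_s_per_hz =
                                 2 * cal$slope_mm_s_per_hz)
  expect_equal(frequency_to_velocity(100, cal2),
               2 * frequency_to_velocity(100, cal))
  expect_error(frequency_to_velocity(1, NULL), "calibration")
  expect_error(velocity_calibration(), "missing calibration")
})

test_that("velocity map recovers programmed vessel velocities", {
  for (v in c(0.3, 1.5)) {
    ph <- make_flow_phantom(vessel_phantom(v, snr = 10,
                                           seed = round(100 * v)))
    vf <- velocity_map(ph$ensemble)
    vin <- abs(vf$velocity[ph$truth$vessel_mask_true & vf$flow_mask])
    expect_gt(length(vin), 20)
    expect_lt(abs(stats::median(vin) - v) / v, 0.05)
  }
})

test_that("static phantoms produce no flow voxels", {
  spec <- phantom_spec(n_positions = 16, depth_px = 32,
                       noise_sigma = sqrt(0.1), seed = 31)
  vf <- velocity_map(make_flow_phantom(spec)$ensemble)
  expect_equal(sum(vf$flow_mask), 0)
})

test_that("recovered velocity is monotone in programmed velocity", {
  vs <- c(0.2, 0.5, 1, 1.8, 2.6)
  med <- vapply(seq_along(vs), function(i) {
    ph <- make_flow_phantom(vessel_phantom(vs[i], seed = 300 + i,
                                           n_positions = 12,
                                           depth_px = 32))
    vf <- velocity_map(ph$ensemble)
    stats::median(abs(vf$velocity[ph$truth$vessel_mask_true &
                                  vf$flow_mask]))
  }, numeric(1))
  expect_equal(stats::cor(med, vs, method = "spearman"), 1)
})

test_that("diameter gating selects the right vessels for statistics", {
  # two vessels: ~30 um (in gate) at 0.7 mm/s, ~60 um at 2 mm/s
  spec <- phantom_spec(
    preset = "omag-v", n_positions = 24, depth_px = 64,
    noise_sigma = 0.05, static_amplitude = 1, seed = 17,
    flow_segments = list(
      list(positions = c(3, 10), depths = c(10, 13),
           velocity_mm_s = 0.7, amplitude = 1),     # 4 px * 7 um = 28 um
      list(positions = c(14, 22), depths = c(40, 48),
           velocity_mm_s = 2, amplitude = 1)))      # 9 px * 7 um = 63 um
  ph <- make_flow_phantom(spec)
  fv <- omag_flow(ph$ensemble)
  # noise-floor threshold: slow vessels sit well below the Otsu level
  # set by the bright fast vessel
  mask <- binarize(fv$flow, "fixed",
                   threshold = 3 * stats::median(fv$flow))
  diam <- estimate_vessel_diameters(mask, pixel_um = 7)
  labels <- attr(diam, "labels")
  vf <- velocity_map(ph$ensemble)
  gated <- gated_velocity_stats(vf, labels, diam, gate = c(20, 40))
  expect_false(gated$empty)
  expect_lt(abs(gated$mean_mm_s - 0.7) / 0.7, 0.1)
  # gate [0, Inf) covers all vessels
  all_v <- gated_velocity_stats(vf, labels, diam, gate = c(0, Inf))
  expect_gte(all_v$n_vessels, 2)
  expect_error(gated_velocity_stats(vf, labels, diam, gate = c(40, 20)),
               "inverted")
  none <- gated_velocity_stats(vf, labels, diam, gate = c(500, 600))
  expect_true(none$empty)
})

test_that("perfusion rate follows the unit arithmetic oracle", {
  # one vessel d = 40 um, v = 1 mm/s -> 0.0754 uL/min
  pr <- perfusion_rate(40, 1, fov_mm2 = 2.25, tissue_depth_mm = 0.89)
  expect_equal(pr$q_fov_ul_min, pi * 0.02^2 * 60, tolerance = 1e-12)
  expect_equal(pr$q_fov_ul_min, 0.0754, tolerance = 1e-3)
  # additivity and empty case
  pr2 <- perfusion_rate(c(40, 40), c(1, 1), tissue_depth_mm = 0.89)
  expect_equal(pr2$q_fov_ul_min, 2 * pr$q_fov_ul_min)
  expect_equal(perfusion_rate(numeric(0), numeric(0),
                              tissue_depth_mm = 0.89)$q_fov_ul_min, 0)
  expect_error(perfusion_rate(40, 1), "tissue depth")
  # volumetric normalization: uL/min over mm^3 == mL/min per mL
  expect_equal(pr$q_volumetric_ml_min_ml,
               pr$q_fov_ul_min / (2.25 * 0.89))
})

test_that("healthy-region normalization reproduces the printed ratio", {
  expect_equal(normalize_to_healthy(24.5, 117.9), 0.208, tolerance = 1e-3)
  expect_equal(normalize_to_healthy(5, 5), 1)
  expect_equal(normalize_to_healthy(0, 10), 0)
  expect_error(normalize_to_healthy(1, 0), "positive")
})
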