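test_that("static clutter cancels exactly and structure is preserved", {
  spec <- phantom_spec(n_positions = 8, depth_px = 16, noise_sigma = 0,
                       static_amplitude = 2.5, seed = 1)
  fv <- omag_flow(make_flow_phantom(spec)$ensemble)
  expect_equal(max(fv$flow), 0)
  expect_equal(fv$structure, matrix(2.5, 16, 8))
})

test_that("flow contrast matches the closed-form phasor difference", {
  # pure rotation at frequency f: |S(k+1) - S(k)| = 2 A |sin(pi f dt)|
  for (v in c(0.3, 1, 2.5)) {
    spec <- phantom_spec(n_positions = 4, depth_px = 8, noise_sigma = 0,
                         static_amplitude = 0, seed = 5,
                         flow_segments = list(list(
                           positions = c(1, 4), depths = c(1, 8),
                           velocity_mm_s = v, amplitude = 1.7)))
    fv <- omag_flow(make_flow_phantom(spec)$ensemble)
    f <- doppler_frequency(v, 1340, 1.35)
    expected <- 2 * 1.7 * abs(sin(pi * f / 20000))
    expect_equal(max(abs(fv$flow - expected)), 0, tolerance = 1e-10)
  }
})

test_that("flow is invariant to global phase and linear in amplitude", {
  spec <- vessel_phantom(0.8, seed = 21, n_positions = 10, depth_px = 32)
  ens <- make_flow_phantom(spec)$ensemble
  base <- omag_flow(ens)
  rot <- ens
  rot$signal <- ens$signal * exp(1i * 1.234)
  expect_equal(omag_flow(rot)$flow, base$flow, tolerance = 1e-12)
  scl <- ens
  scl$signal <- ens$signal * 3
  expect_equal(omag_flow(scl)$flow, 3 * base$flow, tolerance = 1e-12)
})

test_that("flow contrast separates vessel from background voxels", {
  spec <- vessel_phantom(1, snr = 10, seed = 9, n_positions = 24,
                         depth_px = 48)
  ph <- make_flow_phantom(spec)
  fv <- omag_flow(ph$ensemble)
  expect_gt(rank_auc(fv$flow, ph$truth$vessel_mask_true), 0.95)
})

test_that("maximum intensity projection collapses the requested axis", {
  vol <- array(0, dim = c(3, 4, 5))
  vol[2, , ] <- 7
  expect_equal(mip(vol, 1), matrix(7, 4, 5))
  expect_equal(mip(array(0, c(2, 3, 4)), 1), matrix(0, 3, 4))
  # single-slice volume: identity
  one <- array(runif(12), dim = c(1, 3, 4))
  expect_equal(mip(one, 1), one[1, , ])
})

test_that("binarization honors fixed thresholds, Otsu and inversion", {
  img <- matrix(c(rep(0, 40), rep(1, 60)), 10)
  expect_equal(binarize(img, "fixed", threshold = 0.5), img > 0.5)
  expect_equal(binarize(img, "fixed", threshold = 0.5, invert = TRUE),
               img < 0.5)
  # bimodal image: Otsu level between the modes, mask = exhaustive oracle
  set.seed(8)
  bi <- matrix(c(rnorm(60, 0.2, 0.02), rnorm(40, 0.8, 0.02)), 10)
  mask <- binarize(bi, "otsu")
  # oracle: exhaustive sweep minimizing intra-class variance
  cand <- sort(unique(as.vector(bi)))
  icv <- vapply(cand[-length(cand)], function(t) {
    a <- bi[bi <= t]; b <- bi[bi > t]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  best <- cand[which.min(icv)]
  expect_equal(mask, bi > best)
  expect_warning(binarize(matrix(1, 5, 5), "otsu"), "flat")
})

test_that("vessel area density is exact on constructed masks", {
  m <- matrix(FALSE, 10, 10)
  m[1:5, 1:5] <- TRUE
  expect_equal(vessel_area_density(m), 25)
  expect_equal(vessel_area_density(matrix(TRUE, 4, 4)), 100)
  roi <- matrix(FALSE, 10, 10); roi[1:5, ] <- TRUE
  expect_equal(vessel_area_density(m, roi), 50)
  expect_error(vessel_area_density(m, matrix(FALSE, 10, 10)), "empty")
})

test_that("density is monotone under mask dilation", {
  set.seed(2)
  m <- matrix(runif(400) > 0.9, 20, 20)
  dil <- m
  dil[-1, ] <- dil[-1, ] | m[-20, ]
  dil[, -1] <- dil[, -1] | m[, -20]
  expect_gte(vessel_area_density(dil), vessel_area_density(m))
})

test_that("cylinder phantom MIP density matches analytic footprint", {
  # y-axis cylinder, footprint band of width = diameter
  vol <- make_vessel_volume(
    list(list(axis = "y", center_um = c(29, 29), diameter_um = 30)),
    volume_shape = c(30, 12, 30), pixel_um = 2)
  dens <- vessel_area_density(mip(vol$mask * 1, 1) > 0)
  p <- 30 / (30 * 2)          # analytic footprint fraction
  one_row_pct <- 100 / 30     # one pixel column of the footprint
  expect_lte(abs(dens - 100 * p), one_row_pct + 1e-9)
})

test_that("component labeling respects the connectivity setting", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE   # touch diagonally
  expect_equal(max(label_components(m, 8)), 1)
  expect_equal(max(label_components(m, 4)), 2)
  v <- array(FALSE, dim = c(3, 3, 3))
  v[1, 1, 1] <- TRUE; v[2, 2, 2] <- TRUE
  expect_equal(max(label_components(v, 26)), 1)
  expect_equal(max(label_components(v, 6)), 2)
})

test_that("diameter estimates recover rendered bar widths", {
  bar <- matrix(FALSE, 40, 40)
  bar[10:24, 5:35] <- TRUE           # 15 px wide at 2 um/px = 30 um
  d <- estimate_vessel_diameters(bar, 2)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$diameter_um - 30), 2 + 1e-9)
  # single pixel -> one pixel width
  px1 <- matrix(FALSE, 5, 5); px1[3, 3] <- TRUE
  expect_equal(estimate_vessel_diameters(px1, 2)$diameter_um, 2)
  # two disjoint bars -> two rows
  two <- matrix(FALSE, 40, 40)
  two[5:9, 2:38] <- TRUE; two[25:31, 2:38] <- TRUE
  expect_equal(nrow(estimate_vessel_diameters(two, 2)), 2)
  # empty mask -> empty table
  expect_equal(nrow(estimate_vessel_diameters(matrix(FALSE, 4, 4), 2)), 0)
})

test_that("diameters are within one pixel of truth for >= 5 px vessels", {
  for (w in c(5, 8, 12, 20)) {
    m <- matrix(FALSE, 50, 50)
    m[10:(10 + w - 1), 5:45] <- TRUE
    d <- estimate_vessel_diameters(m, 1)
    expect_lte(abs(d$diameter_um - w), 1 + 1e-9)
  }
})
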