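test_that("particle analysis excludes sub-threshold particles exactly", {
  field <- standard_lumen_field()
  # truth: 10 of 50 um^2 survive the 20 um^2 exclusion, 5 of 10 um^2 do not
  ps <- particle_analysis(field$image$pixels > 0, pixel_um = 1,
                          min_area_um2 = 20)
  expect_equal(nrow(ps$particles), 10)
  expect_true(all(abs(ps$particles$area_um2 - 50) <= 1))
  # min_area = 0 retains all 15
  ps0 <- particle_analysis(field$image$pixels > 0, 1, min_area_um2 = 0)
  expect_equal(nrow(ps0$particles), 15)
  # empty mask -> empty set
  expect_equal(nrow(particle_analysis(matrix(FALSE, 5, 5), 1)$particles), 0)
})

test_that("particle count is monotone non-increasing in the area filter", {
  field <- standard_lumen_field()
  counts <- vapply(c(0, 5, 20, 45, 60), function(a)
    nrow(particle_analysis(field$image$pixels > 0, 1, a)$particles),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("distance bins assign particles by the half-open convention", {
  lumens <- data.frame(x_um = c(100, 400, 700), y_um = c(50, 50, 50),
                       area_um2 = 50)
  out <- make_lumen_image(lumens, 1, c(100, 1000), wall_x_um = 0)
  ps <- particle_analysis(out$image$pixels > 0, 1)
  stats <- distance_binned_stats(ps, wall_x_um = 0)
  expect_equal(stats$count[1:3], c(1, 1, 1))
  expect_equal(stats$count[4], 0)
  # edge case: centroid exactly at 300 um falls in the second bin
  # (rectangle over columns 298:303, pixel centers 297.5..302.5)
  m <- matrix(FALSE, 60, 700)
  m[20:24, 298:303] <- TRUE
  pe <- particle_analysis(m, 1)
  expect_equal(pe$particles$centroid_x_um, 300)
  se <- distance_binned_stats(pe, wall_x_um = 0)
  expect_equal(se$count[1:2], c(0, 1))
  expect_error(distance_binned_stats(ps), "wall reference")
})

test_that("bin densities weighted by bin area sum to the overall density", {
  set.seed(12)
  lumens <- data.frame(x_um = c(80, 250, 420, 580, 820),
                       y_um = seq(30, 170, length.out = 5),
                       area_um2 = 50)
  out <- make_lumen_image(lumens, 2, c(100, 500), wall_x_um = 0)
  ps <- particle_analysis(out$image$pixels > 0, 2)
  st <- distance_binned_stats(ps, wall_x_um = 0,
                              bins = c(0, 300, 600, 900, 1200))
  st <- st[st$bin_area_mm2 > 0, ]
  total_area <- sum(st$bin_area_mm2)
  overall <- sum(st$count) / total_area
  expect_equal(sum(st$density_per_mm2 * st$bin_area_mm2) / total_area,
               overall, tolerance = 1e-12)
})

test_that("area fraction normalizes, clips and stays within [0, 100]", {
  ref <- matrix(FALSE, 10, 10); ref[, 1:5] <- TRUE   # 50 px reference
  sig <- matrix(FALSE, 10, 10); sig[1:5, 1:5] <- TRUE
  expect_equal(area_fraction(sig, 1, reference_mask = ref), 50)
  expect_equal(area_fraction(matrix(FALSE, 10, 10), 1,
                             reference_area_um2 = 100), 0)
  # signal outside the reference is clipped before division
  sig2 <- matrix(TRUE, 10, 10)
  expect_equal(area_fraction(sig2, 1, reference_mask = ref), 100)
  expect_error(area_fraction(sig, 1), "positive")
  # additive over disjoint signal regions
  s1 <- matrix(FALSE, 10, 10); s1[1:2, 1:5] <- TRUE
  s2 <- matrix(FALSE, 10, 10); s2[7:8, 1:5] <- TRUE
  expect_equal(area_fraction(s1 | s2, 1, reference_mask = ref),
               area_fraction(s1, 1, reference_mask = ref) +
               area_fraction(s2, 1, reference_mask = ref))
})

test_that("colocalization fraction counts overlapping objects", {
  # 100 nuclei grid, marker covers exactly 2 of them
  nuc <- matrix(FALSE, 100, 100)
  for (i in 0:9) for (j in 0:9)
    nuc[(i * 10 + 2):(i * 10 + 4), (j * 10 + 2):(j * 10 + 4)] <- TRUE
  ps <- particle_analysis(nuc, 1, min_area_um2 = 0)
  expect_equal(nrow(ps$particles), 100)
  marker <- matrix(FALSE, 100, 100)
  marker[2:4, 2:4] <- TRUE; marker[12:14, 2:4] <- TRUE
  expect_equal(colocalization_fraction(marker, ps)$percent, 2)
  expect_equal(colocalization_fraction(matrix(FALSE, 100, 100),
                                       ps)$percent, 0)
  expect_equal(colocalization_fraction(nuc, ps)$percent, 100)
  empty <- particle_analysis(matrix(FALSE, 5, 5), 1)
  expect_true(colocalization_fraction(marker, empty)$empty)
})

test_that("perfused area recovers a known coverage fraction", {
  img <- matrix(0, 100, 100)
  img[1:30, ] <- 1                       # 30% of the field
  pa <- perfused_area(img, pixel_um = 2, threshold = 0.5)
  expect_equal(pa$percent_of_field, 30)
  expect_equal(pa$area_um2, 3000 * 4)
  expect_equal(perfused_area(matrix(0, 10, 10), 1,
                             threshold = 0.5)$percent_of_field, 0)
  roi <- matrix(FALSE, 100, 100); roi[1:50, ] <- TRUE
  expect_equal(perfused_area(img, 2, 0.5, roi)$percent_of_field, 60)
})

test_that("bead tracking reproduces programmed velocities", {
  # 27 um per 0.27 s frame -> 100 um/s, exact
  mov <- make_bead_movie(data.frame(x0_um = 20, y0_um = 30,
                                    vx_um_s = 100, vy_um_s = 0),
                         0.27, 4, c(64, 160), 1)
  tr <- track_beads(mov$frames, 0.27, 1)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$velocity_um_s, 100, tolerance = 1e-9)
  # static bead -> zero velocity
  still <- make_bead_movie(data.frame(x0_um = 20, y0_um = 30,
                                      vx_um_s = 0, vy_um_s = 0),
                           0.27, 3, c(64, 64), 1)
  expect_equal(track_beads(still$frames, 0.27, 1)$velocity_um_s, 0)
})

test_that("tracker is exact on multi-bead non-crossing movies", {
  speeds <- c(40, 60, 75, 90)
  tracks <- data.frame(x0_um = 15, y0_um = c(20, 60, 100, 140),
                       vx_um_s = speeds, vy_um_s = 0)
  mov <- make_bead_movie(tracks, 0.27, 5, c(160, 200), 1)
  tr <- track_beads(mov$frames, 0.27, 1, max_displacement_um = 40)
  tr <- tr[tr$n_steps == 4, ]
  expect_equal(nrow(tr), 4)
  expect_true(all(abs(sort(tr$velocity_um_s) - sort(speeds)) /
                  sort(speeds) < 0.05))
})

test_that("crossing beads terminate rather than swap identities silently", {
  tracks <- data.frame(x0_um = c(20, 80), y0_um = c(50, 50),
                       vx_um_s = c(60, -60), vy_um_s = 0)
  mov <- make_bead_movie(tracks, 0.25, 5, c(100, 120), 1)
  tr <- track_beads(mov$frames, 0.25, 1, max_displacement_um = 30)
  # when beads merge, detections drop to one blob; tracks must not
  # report velocities wildly off the programmed 60 um/s
  expect_true(all(tr$velocity_um_s[tr$n_steps > 0] < 120))
})
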