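#' Scan-protocol presets
#'
#' Two repeated A-line protocols are built in:
#'
#' * `"omag"` — angiography protocol: 16 repeats at each of 250 lateral
#'   positions, repeats spaced by the 280 frames/s inter-frame interval.
#' * `"omag-v"` — velocimetry protocol: 50 repeats at each of 200 lateral
#'   positions at a 20,000 A-lines/s sampling rate.
#'
#' Both cover a 1.5 x 1.5 mm^2 field of view at a 1340 nm center
#' wavelength.
#'
#' @param preset preset name.
#' @return a list of protocol parameters.
#' @export
scan_preset <- function(preset = c("omag-v", "omag")) {
  preset <- match.arg(preset)
  switch(preset,
    "omag-v" = list(preset_name = "omag-v", n_repeats = 50L,
                    n_positions = 200L, a_line_rate_hz = 20000),
    "omag"   = list(preset_name = "omag", n_repeats = 16L,
                    n_positions = 250L, a_line_rate_hz = 280)
  )
}

#' Specification of a flow phantom
#'
#' Describes a complex-valued repeated A-line ensemble: static tissue
#' clutter everywhere, plus rectangular "vessel" segments of scatterers
#' moving at programmed axial velocities, plus circular complex Gaussian
#' noise. The Doppler relation `f = 2 n v / lambda0` links each programmed
#' velocity to the phasor rotation frequency encoded in the repeat series.
#'
#' @param preset scan preset name, see [scan_preset()]. Individual fields
#'   can be overridden by the named arguments.
#' @param n_positions,n_repeats,a_line_rate_hz scan geometry/timing.
#' @param depth_px samples per A-line.
#' @param field_of_view_mm lateral field of view, `c(x, y)` in mm.
#' @param pixel_um `c(axial, lateral)` pixel spacing in um. The lateral
#'   spacing defaults to `field_of_view_mm[1] * 1000 / n_positions`.
#' @param center_wavelength_nm source center wavelength (nm).
#' @param refractive_index refractive index of the flowing medium.
#' @param noise_sigma standard deviation of the additive circular complex
#'   noise (per complex sample).
#' @param static_amplitude amplitude of the static clutter phasor.
#' @param flow_segments list of segments, each a list with elements
#'   `positions = c(lo, hi)`, `depths = c(lo, hi)` (1-based inclusive pixel
#'   ranges), `velocity_mm_s` (signed axial velocity) and `amplitude`.
#' @param seed RNG seed; a fixed seed makes the phantom bit-identical.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(preset = "omag-v",
                         n_positions = NULL, n_repeats = NULL,
                         a_line_rate_hz = NULL, depth_px = 64L,
                         field_of_view_mm = c(1.5, 1.5),
                         pixel_um = NULL,
                         center_wavelength_nm = 1340,
                         refractive_index = 1.35,
                         noise_sigma = 0.1, static_amplitude = 1,
                         flow_segments = list(), seed = 1L) {
  p <- scan_preset(preset)
  if (!is.null(n_positions)) p$n_positions <- as.integer(n_positions)
  if (!is.null(n_repeats)) p$n_repeats <- as.integer(n_repeats)
  if (!is.null(a_line_rate_hz)) p$a_line_rate_hz <- a_line_rate_hz
  if (is.null(pixel_um))
    pixel_um <- c(7, field_of_view_mm[1] * 1000 / p$n_positions)
  spec <- structure(list(
    preset_name = p$preset_name, n_positions = p$n_positions,
    n_repeats = p$n_repeats, a_line_rate_hz = p$a_line_rate_hz,
    depth_px = as.integer(depth_px), field_of_view_mm = field_of_view_mm,
    pixel_um = pixel_um, center_wavelength_nm = center_wavelength_nm,
    refractive_index = refractive_index, noise_sigma = noise_sigma,
    static_amplitude = static_amplitude, flow_segments = flow_segments,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$n_repeats >= 2, spec$a_line_rate_hz > 0,
            spec$depth_px >= 1, spec$noise_sigma >= 0,
            spec$static_amplitude >= 0)
  vmax <- aliasing_limit_mm_s(spec$a_line_rate_hz,
                              spec$center_wavelength_nm,
                              spec$refractive_index)
  for (seg in spec$flow_segments) {
    stopifnot(length(seg$positions) == 2, length(seg$depths) == 2,
              seg$positions[1] >= 1, seg$positions[2] <= spec$n_positions,
              seg$depths[1] >= 1, seg$depths[2] <= spec$depth_px,
              seg$amplitude >= 0)
    if (abs(seg$velocity_mm_s) >= vmax)
      stop("programmed velocity ", seg$velocity_mm_s,
           " mm/s is at or above the aliasing limit of ",
           signif(vmax, 4), " mm/s", call. = FALSE)
  }
  invisible(spec)
}

#' Generate a complex repeated A-line flow phantom
#'
#' Builds the ensemble `S(z, k, x)` (depth x repeats x lateral positions):
#' each voxel's repeat series is a static clutter phasor of constant
#' (voxel-random) phase, plus for each flow segment covering the voxel a
#' phasor `amplitude * exp(i (phi0 + 2 pi f t_k))` rotating at the Doppler
#' frequency of the programmed velocity, plus i.i.d. circular complex
#' Gaussian noise. `t_k = k / a_line_rate_hz`.
#'
#' @param spec a [phantom_spec()].
#' @return a list with `ensemble` (an `ascan_ensemble`) and `truth`
#'   carrying `velocity_map_true` (mm/s, depth x positions),
#'   `vessel_mask_true` and the spec itself.
#' @export
make_flow_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    d <- spec$depth_px; n <- spec$n_repeats; p <- spec$n_positions
    t_k <- (seq_len(n) - 1) / spec$a_line_rate_hz
    # static clutter: per-voxel constant phase across repeats
    phi_static <- matrix(runif(d * p, 0, 2 * pi), d, p)
    sig <- array(0i, dim = c(d, n, p))
    for (k in seq_len(n))
      sig[, k, ] <- spec$static_amplitude * exp(1i * phi_static)
    vmap <- matrix(0, d, p)
    for (seg in spec$flow_segments) {
      zr <- seg$depths[1]:seg$depths[2]
      xr <- seg$positions[1]:seg$positions[2]
      f <- doppler_frequency(seg$velocity_mm_s, spec$center_wavelength_nm,
                             spec$refractive_index)
      phi0 <- matrix(runif(length(zr) * length(xr), 0, 2 * pi),
                     length(zr), length(xr))
      for (k in seq_len(n))
        sig[zr, k, xr] <- sig[zr, k, xr] +
          seg$amplitude * exp(1i * (phi0 + 2 * pi * f * t_k[k]))
      vmap[zr, xr] <- vmap[zr, xr] + seg$velocity_mm_s
    }
    if (spec$noise_sigma > 0) {
      s <- spec$noise_sigma / sqrt(2)
      sig <- sig + array(complex(real = rnorm(d * n * p, sd = s),
                                 imaginary = rnorm(d * n * p, sd = s)),
                         dim = c(d, n, p))
    }
    ensemble <- ascan_ensemble(sig, a_line_rate_hz = spec$a_line_rate_hz,
                               pixel_um = spec$pixel_um,
                               center_wavelength_nm = spec$center_wavelength_nm,
                               refractive_index = spec$refractive_index,
                               preset_name = spec$preset_name)
    list(ensemble = ensemble,
         truth = list(velocity_map_true = vmap,
                      vessel_mask_true = vmap != 0,
                      spec = spec))
  })
}

#' Repeated A-line ensemble container
#'
#' @param signal complex array, depth x repeats x lateral positions.
#' @param a_line_rate_hz repeat sampling rate (Hz).
#' @param pixel_um `c(axial, lateral)` spacing in um.
#' @param center_wavelength_nm,refractive_index optics metadata used for
#'   the default Doppler velocity calibration.
#' @param preset_name optional protocol label.
#' @return object of class `ascan_ensemble`.
#' @export
ascan_ensemble <- function(signal, a_line_rate_hz, pixel_um,
                           center_wavelength_nm = 1340,
                           refractive_index = 1.35,
                           preset_name = NULL) {
  stopifnot(is.complex(signal), length(dim(signal)) == 3,
            dim(signal)[2] >= 2, all(is.finite(Mod(signal))),
            a_line_rate_hz > 0)
  structure(list(signal = signal, a_line_rate_hz = a_line_rate_hz,
                 pixel_um = pixel_um,
                 center_wavelength_nm = center_wavelength_nm,
                 refractive_index = refractive_index,
                 preset_name = preset_name),
            class = "ascan_ensemble")
}

#' @export
print.ascan_ensemble <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<ascan_ensemble> %d depth x %d repeats x %d positions, %g A-lines/s%s\n",
              d[1], d[2], d[3], x$a_line_rate_hz,
              if (is.null(x$preset_name)) "" else paste0(" (", x$preset_name, ")")))
  invisible(x)
}

#' Rasterize a 3-D volume of cylindrical vessels
#'
#' Renders axis-aligned cylinders into a binary volume indexed `[z, y, x]`.
#'
#' @param layout list of cylinders, each a list with `axis` (`"x"`, `"y"`
#'   or `"z"`: the cylinder's long axis), `center_um` (coordinates of the
#'   axis in the two perpendicular directions, in volume order),
#'   `diameter_um`, and optionally `velocity_mm_s`.
#' @param volume_shape integer `c(nz, ny, nx)`.
#' @param pixel_um voxel spacing in um (isotropic scalar or length-3
#'   `c(z, y, x)`).
#' @return list with `mask` (logical array) and `truth` (per-vessel
#'   diameter/velocity table and a velocity volume).
#' @export
make_vessel_volume <- function(layout, volume_shape, pixel_um) {
  if (length(pixel_um) == 1) pixel_um <- rep(pixel_um, 3)
  stopifnot(length(volume_shape) == 3, all(pixel_um > 0))
  mask <- array(FALSE, dim = volume_shape)
  vvol <- array(0, dim = volume_shape)
  # voxel-center coordinates along each axis (um)
  ax <- lapply(1:3, function(i) (seq_len(volume_shape[i]) - 0.5) * pixel_um[i])
  rows <- list()
  for (i in seq_along(layout)) {
    cyl <- layout[[i]]
    long <- match(cyl$axis, c("z", "y", "x"))
    if (is.na(long)) stop("cylinder axis must be one of 'z', 'y', 'x'")
    perp <- setdiff(1:3, long)
    r <- cyl$diameter_um / 2
    c1 <- cyl$center_um[1]; c2 <- cyl$center_um[2]
    if (max(c1 + r, c2 + r) > max(ax[[perp[1]]][volume_shape[perp[1]]] + pixel_um[perp[1]] / 2,
                                  ax[[perp[2]]][volume_shape[perp[2]]] + pixel_um[perp[2]] / 2) ||
        min(c1 - r, c2 - r) < 0)
      stop("cylinder ", i, " extends outside the volume")
    d1 <- ax[[perp[1]]] - c1
    d2 <- ax[[perp[2]]] - c2
    inside2d <- outer(d1^2, d2^2, "+") <= r^2      # perp[1] x perp[2]
    idx <- which(inside2d, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      for (j in seq_len(volume_shape[long])) {
        coords <- matrix(0L, nrow(idx), 3)
        coords[, perp[1]] <- idx[, 1]
        coords[, perp[2]] <- idx[, 2]
        coords[, long] <- j
        mask[coords] <- TRUE
        vvol[coords] <- vvol[coords] +
          if (is.null(cyl$velocity_mm_s)) 0 else cyl$velocity_mm_s
      }
    }
    rows[[i]] <- data.frame(vessel = i, axis = cyl$axis,
                            diameter_um = cyl$diameter_um,
                            velocity_mm_s = if (is.null(cyl$velocity_mm_s))
                              NA_real_ else cyl$velocity_mm_s)
  }
  list(mask = mask,
       truth = list(vessels = if (length(rows)) do.call(rbind, rows)
                    else data.frame(vessel = integer(), axis = character(),
                                    diameter_um = numeric(),
                                    velocity_mm_s = numeric()),
                    velocity_volume = vvol, pixel_um = pixel_um))
}

#' Render a calibrated lumen image with known particle truth
#'
#' Each lumen is drawn as a filled quasi-disk whose pixel count equals the
#' requested area to the nearest whole pixel: pixels are taken in order of
#' distance from the centroid, so rendered areas are within half a pixel
#' area of the request.
#'
#' @param lumens data.frame with columns `x_um`, `y_um` (centroid) and
#'   `area_um2`; lumens must not overlap.
#' @param pixel_um isotropic pixel size (um/pixel).
#' @param image_shape `c(rows, cols)`; x runs along columns, y along rows.
#' @param wall_x_um optional x-position (um) of a vertical vessel wall;
#'   when given, per-lumen distances `x_um - wall_x_um` are recorded in
#'   the truth table.
#' @return list with `image` (a [quant_image()]) and `truth` (per-lumen
#'   table: requested and rendered areas, centroid, distance to wall).
#' @export
make_lumen_image <- function(lumens, pixel_um, image_shape,
                             wall_x_um = NULL) {
  px_area <- pixel_um^2
  img <- matrix(0, image_shape[1], image_shape[2])
  xs <- (seq_len(image_shape[2]) - 0.5) * pixel_um
  ys <- (seq_len(image_shape[1]) - 0.5) * pixel_um
  rendered <- numeric(nrow(lumens))
  for (i in seq_len(nrow(lumens))) {
    n_px <- round(lumens$area_um2[i] / px_area)
    if (n_px < 1) {
      warning("lumen ", i, " smaller than one pixel; rendering one pixel")
      n_px <- 1
    }
    d2 <- outer((ys - lumens$y_um[i])^2, (xs - lumens$x_um[i])^2, "+")
    ord <- order(d2)[seq_len(n_px)]
    if (any(img[ord] > 0)) stop("lumen ", i, " overlaps a previous lumen")
    img[ord] <- 1
    rendered[i] <- n_px * px_area
  }
  truth <- cbind(lumens,
                 area_rendered_um2 = rendered,
                 distance_um = if (is.null(wall_x_um)) NA_real_
                               else lumens$x_um - wall_x_um)
  list(image = quant_image(img, pixel_um, channel = "synthetic-lumen"),
       truth = truth)
}

#' Simulate a fluorescent bead time-lapse with known displacements
#'
#' @param tracks data.frame with columns `x0_um`, `y0_um` and velocity
#'   components `vx_um_s`, `vy_um_s`.
#' @param frame_interval_s seconds between frames.
#' @param n_frames number of frames (>= 2).
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_um um per pixel.
#' @param bead_radius_um rendered bead radius.
#' @return list with `frames` (rows x cols x n_frames array in `[0, 1]`)
#'   and `truth` (per-bead per-frame positions and the per-frame
#'   displacement implied by each velocity).
#' @export
make_bead_movie <- function(tracks, frame_interval_s, n_frames,
                            image_shape = c(128, 128), pixel_um = 1,
                            bead_radius_um = 2) {
  stopifnot(n_frames >= 2, frame_interval_s > 0)
  frames <- array(0, dim = c(image_shape, n_frames))
  xs <- (seq_len(image_shape[2]) - 0.5) * pixel_um
  ys <- (seq_len(image_shape[1]) - 0.5) * pixel_um
  pos <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    dt <- (t - 1) * frame_interval_s
    px <- tracks$x0_um + tracks$vx_um_s * dt
    py <- tracks$y0_um + tracks$vy_um_s * dt
    lim_x <- image_shape[2] * pixel_um; lim_y <- image_shape[1] * pixel_um
    if (any(px < bead_radius_um | px > lim_x - bead_radius_um |
            py < bead_radius_um | py > lim_y - bead_radius_um))
      stop("bead leaves the frame at frame ", t)
    for (b in seq_len(nrow(tracks))) {
      d2 <- outer((ys - py[b])^2, (xs - px[b])^2, "+")
      frames[, , t][d2 <= bead_radius_um^2] <- 1
    }
    pos[[t]] <- data.frame(bead = seq_len(nrow(tracks)), frame = t,
                           x_um = px, y_um = py)
  }
  speed <- sqrt(tracks$vx_um_s^2 + tracks$vy_um_s^2)
  list(frames = frames,
       truth = list(positions = do.call(rbind, pos),
                    speed_um_s = speed,
                    displacement_per_frame_um = speed * frame_interval_s,
                    frame_interval_s = frame_interval_s,
                    pixel_um = pixel_um))
}

#' Simulate an integer count matrix with planted differential genes
#'
#' Negative-binomial counts for two or more groups with a subset of genes
#' shifted by a programmed log2 fold change in the last group relative to
#' the first. Baseline per-gene means are log-normal; a configurable
#' fraction of genes is near-silent so the counts-per-million keep-filter
#' has something to remove.
#'
#' @param n_genes number of genes.
#' @param groups character/factor of group labels, one per sample.
#' @param libsize target library size scaling (mean total counts are
#'   proportional to it; must be > 0).
#' @param n_de number of planted differential genes; planted only among
#'   genes whose baseline mean is at least `min_de_mu` (a differential
#'   call is only meaningful for expressed genes).
#' @param log2fc planted log2 fold change (last group vs first).
#' @param dispersion negative-binomial dispersion (1/size). The default
#'   0.02 (biological CV ~14%) reflects replicate engineered constructs
#'   from a single cell batch, where biological variability is far below
#'   that of independent tissue donors.
#' @param frac_silent fraction of genes with near-zero expression.
#' @param min_de_mu minimum baseline mean for DE-eligible genes.
#' @param seed RNG seed.
#' @return list with `counts` (genes x samples integer matrix with
#'   dimnames), `groups`, and `truth` (`de_genes`, `silent_genes`,
#'   per-gene expected means).
#' @export
make_count_matrix <- function(n_genes = 2000, groups = rep(c("A", "B"), each = 3),
                              libsize = 1, n_de = 100, log2fc = 2,
                              dispersion = 0.02, frac_silent = 0.1,
                              min_de_mu = 50, seed = 1L) {
  stopifnot(libsize > 0, n_de <= n_genes)
  with_seed(seed, {
    n_s <- length(groups)
    base_mu <- rlnorm(n_genes, meanlog = log(100), sdlog = 1) * libsize
    silent <- sample.int(n_genes, round(frac_silent * n_genes))
    base_mu[silent] <- runif(length(silent), 0, 0.02) * libsize
    eligible <- setdiff(which(base_mu >= min_de_mu), silent)
    if (length(eligible) < n_de)
      stop("not enough expressed genes to plant ", n_de, " DE genes")
    de <- sample(eligible, n_de)
    glev <- unique(groups)
    mu <- matrix(base_mu, n_genes, n_s)
    mu[de, groups == glev[length(glev)]] <-
      mu[de, groups == glev[length(glev)]] * 2^log2fc
    counts <- matrix(rnbinom(n_genes * n_s, mu = mu, size = 1 / dispersion),
                     n_genes, n_s)
    dimnames(counts) <- list(sprintf("gene%05d", seq_len(n_genes)),
                             sprintf("%s_%d", groups, ave(seq_len(n_s),
                                     groups, FUN = seq_along)))
    list(counts = counts, groups = groups,
         truth = list(de_genes = rownames(counts)[de],
                      silent_genes = rownames(counts)[silent],
                      base_mu = base_mu, log2fc = log2fc))
  })
}
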