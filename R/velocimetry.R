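#' Covariance of a repeated A-line ensemble
#'
#' Stacks the repeat series of the depth samples in a window into the
#' Hermitian sample covariance
#' `C = (1/Z) * sum_z x_z x_z^H`,
#' where `x_z` is the length-`N` complex repeat series at depth `z`.
#'
#' @param ensemble an [ascan_ensemble()].
#' @param position lateral position index.
#' @param depth_window `c(lo, hi)` depth pixel range (1-based inclusive);
#'   windows of at least the ensemble repeat count are recommended.
#' @return `ensemble_covariance`: list with the `N x N` complex `matrix`,
#'   `n_samples`, `position`, `a_line_rate_hz`.
#' @export
ensemble_covariance <- function(ensemble, position,
                                depth_window = c(1, dim(ensemble$signal)[1])) {
  stopifnot(inherits(ensemble, "ascan_ensemble"))
  d <- dim(ensemble$signal)
  if (position < 1 || position > d[3]) stop("position outside ensemble")
  if (depth_window[1] < 1 || depth_window[2] > d[1] ||
      depth_window[1] > depth_window[2])
    stop("depth window outside volume")
  X <- ensemble$signal[depth_window[1]:depth_window[2], , position,
                       drop = FALSE]
  z <- dim(X)[1]
  dim(X) <- c(z, d[2])
  C <- (t(X) %*% Conj(X)) / z
  structure(list(matrix = C, n_samples = z, position = position,
                 a_line_rate_hz = ensemble$a_line_rate_hz),
            class = "ensemble_covariance")
}

#' Eigendecomposition of an ensemble covariance into clutter and flow
#'
#' Diagonal factorization of the Hermitian covariance; eigenpairs are
#' sorted by descending eigenvalue and the first `n_clutter` components
#' are labeled as static-tissue clutter, the remainder as candidate flow
#' components. Eigenvalue sum equals the covariance trace.
#'
#' @param cov an [ensemble_covariance()].
#' @param n_clutter number of clutter components (0 to N-1). The fixed
#'   default of 1 reflects a single dominant static component;
#'   `n_clutter = "adaptive"` instead counts components whose eigenvalue
#'   exceeds `adaptive_mult` times the median eigenvalue.
#' @param tol relative tolerance for the positive-semidefinite check.
#' @param adaptive_mult noise-floor multiple for the adaptive rule.
#' @return `eigen_split`: list with `values` (descending, clipped at 0),
#'   complex `vectors` (columns), `n_clutter`, `a_line_rate_hz`.
#' @export
eigen_split <- function(cov, n_clutter = 1, tol = 1e-8,
                        adaptive_mult = 10) {
  stopifnot(inherits(cov, "ensemble_covariance"))
  e <- eigen(cov$matrix, symmetric = TRUE)
  n <- length(e$values)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("covariance is not positive semi-definite: corrupt input")
  vals <- pmax(e$values, 0)
  if (identical(n_clutter, "adaptive"))
    n_clutter <- sum(vals > adaptive_mult * stats::median(vals))
  stopifnot(n_clutter >= 0, n_clutter <= n - 1)
  structure(list(values = vals, vectors = e$vectors,
                 n_clutter = as.integer(n_clutter),
                 a_line_rate_hz = cov$a_line_rate_hz),
            class = "eigen_split")
}

#' Lag-one autocorrelation frequency of a temporal eigenvector
#'
#' `r = sum_k e(k+1) * conj(e(k))`; the mean Doppler frequency is
#' `arg(r) * rate / (2 pi)`, confined to `(-rate/2, rate/2]`. The
#' normalized magnitude of `r` ("coherence", 1 for a pure phasor) gates
#' broadband noise components: below `min_coherence` the frequency is
#' flagged undefined.
#'
#' @param eigvec complex vector (length >= 2).
#' @param a_line_rate_hz repeat sampling rate (Hz).
#' @param min_coherence threshold below which the estimate is flagged.
#' @return list with `frequency_hz`, `coherence`, `defined`.
#' @export
lag_one_frequency <- function(eigvec, a_line_rate_hz, min_coherence = 0.7) {
  n <- length(eigvec)
  stopifnot(n >= 2)
  r <- sum(eigvec[-1] * Conj(eigvec[-n]))
  energy <- sum(Mod(eigvec)^2)
  coherence <- Mod(r) * n / ((n - 1) * energy)
  freq <- Arg(r) * a_line_rate_hz / (2 * pi)
  list(frequency_hz = freq, coherence = coherence,
       defined = coherence >= min_coherence)
}

#' Linear frequency-to-velocity calibration
#'
#' Either an explicit slope (mm/s per Hz, e.g. from a phantom-calibrated
#' linear fit of velocity against measured frequency) or the Doppler slope
#' `lambda0 / (2 n)` derived from the optics.
#'
#' @param slope_mm_s_per_hz explicit linear slope.
#' @param center_wavelength_nm,refractive_index optics for the Doppler
#'   default slope.
#' @return object of class `velocity_calibration`.
#' @export
velocity_calibration <- function(slope_mm_s_per_hz = NULL,
                                 center_wavelength_nm = NULL,
                                 refractive_index = NULL) {
  if (is.null(slope_mm_s_per_hz)) {
    if (is.null(center_wavelength_nm) || is.null(refractive_index))
      stop("missing calibration: give a slope or (wavelength, index)")
    slope_mm_s_per_hz <- center_wavelength_nm * 1e-6 /
      (2 * refractive_index)
  }
  structure(list(slope_mm_s_per_hz = slope_mm_s_per_hz),
            class = "velocity_calibration")
}

#' Convert measured frequency to velocity
#'
#' Exactly linear: `v = slope * f`.
#'
#' @param frequency_hz frequency (Hz), vectorized.
#' @param calibration a [velocity_calibration()].
#' @return velocity in mm/s.
#' @export
frequency_to_velocity <- function(frequency_hz, calibration) {
  if (!inherits(calibration, "velocity_calibration"))
    stop("missing calibration")
  calibration$slope_mm_s_per_hz * frequency_hz
}

#' Velocimetry map from a repeated A-line ensemble
#'
#' Full chain per lateral position and axial window: ensemble covariance
#' -> eigendecomposition -> clutter removal (`n_clutter` leading
#' components) -> lag-one autocorrelation frequency of the leading flow
#' eigenvector (or an eigenvalue-weighted combination of all flow
#' components) -> linear velocity. The window is declared flow-carrying
#' only if the leading flow eigenvalue exceeds `noise_k` times the noise
#' floor (mean of the trailing eigenvalues) and the eigenvector passes the
#' coherence gate; velocity is assigned to the voxels whose projection
#' energy onto the flow eigenvector exceeds `noise_k` times the noise
#' floor. Frequencies within 5% of Nyquist are flagged as potentially
#' aliased.
#'
#' @param ensemble an [ascan_ensemble()].
#' @param n_clutter clutter components, see [eigen_split()].
#' @param calibration a [velocity_calibration()]; defaults to the Doppler
#'   slope from the ensemble optics metadata.
#' @param depth_window_px axial pooling window (pixels).
#' @param noise_k noise-floor multiple for flow detection.
#' @param min_coherence lag-one coherence gate.
#' @param weighted if `TRUE`, combine the lag-one autocorrelations of all
#'   flow eigenvectors weighted by their eigenvalues instead of using only
#'   the leading one.
#' @return `velocity_field`: list with `velocity` (mm/s; `NA` outside flow
#'   voxels), `frequency` (Hz), `flow_mask`, `aliased` (logical),
#'   `pixel_um`, `calibration`.
#' @export
velocity_map <- function(ensemble, n_clutter = 1, calibration = NULL,
                         depth_window_px = 16, noise_k = 3,
                         min_coherence = 0.7, weighted = FALSE) {
  stopifnot(inherits(ensemble, "ascan_ensemble"))
  if (is.null(calibration))
    calibration <- velocity_calibration(
      center_wavelength_nm = ensemble$center_wavelength_nm,
      refractive_index = ensemble$refractive_index)
  d <- dim(ensemble$signal)
  n_rep <- d[2]
  starts <- seq(1, d[1], by = depth_window_px)
  vel <- matrix(NA_real_, d[1], d[3])
  freq <- matrix(NA_real_, d[1], d[3])
  aliased <- matrix(FALSE, d[1], d[3])
  rate <- ensemble$a_line_rate_hz
  for (x in seq_len(d[3])) {
    for (s0 in starts) {
      s1 <- min(s0 + depth_window_px - 1, d[1])
      cov <- ensemble_covariance(ensemble, x, c(s0, s1))
      es <- eigen_split(cov, n_clutter)
      i_flow <- es$n_clutter + 1
      if (i_flow > n_rep) next
      rest <- if (i_flow + 1 <= n_rep)
        mean(es$values[(i_flow + 1):n_rep]) else 0
      floor_lvl <- max(rest, .Machine$double.eps)
      if (es$values[i_flow] <= noise_k * floor_lvl) next
      # The static tissue of a fixed specimen has a known slow-time
      # signature: the constant (DC) vector. Finite-window sample
      # covariances mix the clutter and flow eigenvectors when their
      # powers are comparable, which biases the lag-one phase toward
      # DC; deflating the flow eigenvector of its DC content removes
      # that leakage deterministically.
      u_dc <- rep(1 / sqrt(n_rep), n_rep)
      deflate <- function(v) {
        v <- v - sum(Conj(u_dc) * v) * u_dc
        nrm <- sqrt(sum(Mod(v)^2))
        if (nrm < 1e-6) NULL else v / nrm
      }
      e_flow <- deflate(es$vectors[, i_flow])
      if (is.null(e_flow)) next
      if (weighted) {
        # eigenvalue-weighted circular combination of flow components
        r_tot <- 0i; e_tot <- 0
        for (j in i_flow:n_rep) {
          v <- deflate(es$vectors[, j])
          if (is.null(v)) next
          r_tot <- r_tot + es$values[j] *
            sum(v[-1] * Conj(v[-n_rep]))
          e_tot <- e_tot + es$values[j]
        }
        coherence <- Mod(r_tot) * n_rep / ((n_rep - 1) * e_tot)
        lf <- list(frequency_hz = Arg(r_tot) * rate / (2 * pi),
                   coherence = coherence,
                   defined = coherence >= min_coherence)
      } else {
        lf <- lag_one_frequency(e_flow, rate, min_coherence)
      }
      if (!lf$defined) next
      # per-voxel projection energy onto the (deflated) flow signature
      X <- ensemble$signal[s0:s1, , x, drop = FALSE]
      dim(X) <- c(s1 - s0 + 1, n_rep)
      proj <- Mod(X %*% Conj(e_flow))^2
      hit <- proj > noise_k * floor_lvl
      if (!any(hit)) next
      zz <- (s0:s1)[hit]
      freq[zz, x] <- lf$frequency_hz
      vel[zz, x] <- frequency_to_velocity(lf$frequency_hz, calibration)
      aliased[zz, x] <- abs(lf$frequency_hz) >= 0.95 * rate / 2
    }
  }
  structure(list(velocity = vel, frequency = freq,
                 flow_mask = !is.na(vel), aliased = aliased,
                 pixel_um = ensemble$pixel_um, calibration = calibration),
            class = "velocity_field")
}

#' Diameter-gated velocity statistics
#'
#' Mean and SD of in-vessel voxel velocities restricted to vessels whose
#' estimated diameter falls inside the gate (the small-arteriole gate of
#' 20-40 um by default).
#'
#' @param field a `velocity_field` from [velocity_map()].
#' @param labels integer component-label matrix aligned with the field
#'   (e.g. `attr(estimate_vessel_diameters(...), "labels")`).
#' @param diameters data.frame from [estimate_vessel_diameters()].
#' @param gate `c(lo, hi)` diameter gate in um (inclusive).
#' @return list with `mean_mm_s`, `sd_mm_s`, `n_voxels`, `n_vessels`,
#'   `empty` flag.
#' @export
gated_velocity_stats <- function(field, labels, diameters,
                                 gate = c(20, 40)) {
  if (gate[1] > gate[2]) stop("inverted gate bounds")
  keep <- diameters$label[diameters$diameter_um >= gate[1] &
                          diameters$diameter_um <= gate[2]]
  if (length(keep) == 0)
    return(list(mean_mm_s = NA_real_, sd_mm_s = NA_real_, n_voxels = 0L,
                n_vessels = 0L, empty = TRUE))
  sel <- labels %in% keep & field$flow_mask
  v <- field$velocity[sel]
  v <- v[!is.na(v)]
  list(mean_mm_s = mean(v), sd_mm_s = stats::sd(v),
       n_voxels = length(v), n_vessels = length(keep),
       empty = length(v) == 0)
}

#' Perfusion rate of a vessel population
#'
#' Volume flow is velocity times lumen cross-section summed over vessels,
#' `Q_fov = sum_i v_i * pi * (d_i / 2)^2`, reported in uL/min for the
#' imaged field of view, and normalized to a volumetric rate
#' (mL/min per mL tissue) by the field-of-view area times a configured
#' tissue depth.
#'
#' @param diameter_um per-vessel diameters (um).
#' @param velocity_mm_s per-vessel mean velocities (mm/s); absolute values
#'   are used (flow direction does not change delivered volume).
#' @param fov_mm2 imaged field-of-view area (mm^2); 1.5 x 1.5 mm default.
#' @param tissue_depth_mm effective tissue depth for the volumetric
#'   normalization; no default — it must be configured explicitly.
#' @return list with `q_fov_ul_min` and `q_volumetric_ml_min_ml`.
#' @export
perfusion_rate <- function(diameter_um, velocity_mm_s, fov_mm2 = 2.25,
                           tissue_depth_mm = NULL) {
  if (is.null(tissue_depth_mm)) stop("missing tissue depth configuration")
  stopifnot(length(diameter_um) == length(velocity_mm_s))
  r_mm <- diameter_um / 2000
  q_mm3_s <- sum(abs(velocity_mm_s) * pi * r_mm^2)   # mm^3/s == uL/s
  q_fov <- q_mm3_s * 60
  # uL/min per mm^3 equals mL/min per mL
  list(q_fov_ul_min = q_fov,
       q_volumetric_ml_min_ml = q_fov / (fov_mm2 * tissue_depth_mm))
}

#' Per-vessel velocity table from a velocity field
#'
#' Joins component labels/diameters with the mean in-vessel voxel
#' velocity, as input to [perfusion_rate()].
#'
#' @inheritParams gated_velocity_stats
#' @return data.frame with `label`, `diameter_um`, `velocity_mm_s`,
#'   `n_voxels`.
#' @export
vessel_velocity_table <- function(field, labels, diameters) {
  out <- diameters[, c("label", "diameter_um")]
  out$velocity_mm_s <- NA_real_
  out$n_voxels <- 0L
  for (i in seq_len(nrow(out))) {
    sel <- labels == out$label[i] & field$flow_mask
    v <- field$velocity[sel]
    v <- v[!is.na(v)]
    out$n_voxels[i] <- length(v)
    if (length(v)) out$velocity_mm_s[i] <- mean(v)
  }
  out
}

#' Normalize a graft perfusion rate to its healthy reference region
#'
#' @param q_graft graft perfusion rate.
#' @param q_healthy perfusion rate of the corresponding healthy region;
#'   must be positive.
#' @return dimensionless ratio.
#' @examples
#' normalize_to_healthy(24.5, 117.9) # ~0.208
#' @export
normalize_to_healthy <- function(q_graft, q_healthy) {
  if (q_healthy <= 0) stop("healthy reference rate must be positive")
  q_graft / q_healthy
}
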