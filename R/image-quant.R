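#' Calibrated 2-D image container
#'
#' @param pixels numeric matrix of intensities; x runs along columns,
#'   y along rows, with pixel centers at `(i - 0.5) * pixel_um`.
#' @param pixel_um isotropic pixel size (um/pixel).
#' @param channel optional channel label.
#' @return object of class `quant_image`.
#' @export
quant_image <- function(pixels, pixel_um, channel = NULL) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)), pixel_um > 0)
  structure(list(pixels = pixels, pixel_um = pixel_um, channel = channel),
            class = "quant_image")
}

#' @export
print.quant_image <- function(x, ...) {
  cat(sprintf("<quant_image> %d x %d px, %g um/px%s\n", nrow(x$pixels),
              ncol(x$pixels), x$pixel_um,
              if (is.null(x$channel)) "" else paste0(" [", x$channel, "]")))
  invisible(x)
}

as_mask <- function(x) {
  if (inherits(x, "quant_image")) x <- x$pixels
  if (!is.logical(x)) x <- x > 0
  x
}

#' Particle analysis with small-object exclusion
#'
#' Labels connected components of a binary mask and removes particles
#' smaller than `min_area_um2` (background speckle); the 20 um^2 default
#' matches common fluorescence lumen quantification practice.
#'
#' @param mask logical matrix (or `quant_image` of a binary image).
#' @param pixel_um isotropic pixel size (um).
#' @param min_area_um2 particles with area strictly below this are
#'   excluded.
#' @param connectivity component connectivity (4 or 8).
#' @return `particle_set`: list with `particles` (data.frame: `label`,
#'   `area_um2`, `centroid_x_um`, `centroid_y_um`,
#'   `equivalent_diameter_um`), `labels` (post-filter label matrix) and
#'   `pixel_um`.
#' @export
particle_analysis <- function(mask, pixel_um, min_area_um2 = 20,
                              connectivity = 8) {
  mask <- as_mask(mask)
  labels <- label_components(mask, connectivity)
  n <- max(labels)
  px_area <- pixel_um^2
  keep_rows <- list()
  out_labels <- array(0L, dim = dim(labels))
  new_lab <- 0L
  for (l in seq_len(n)) {
    idx <- which(labels == l, arr.ind = TRUE)
    area <- nrow(idx) * px_area
    if (area < min_area_um2) next
    new_lab <- new_lab + 1L
    out_labels[labels == l] <- new_lab
    keep_rows[[new_lab]] <- data.frame(
      label = new_lab, area_um2 = area,
      centroid_x_um = mean(idx[, 2] - 0.5) * pixel_um,
      centroid_y_um = mean(idx[, 1] - 0.5) * pixel_um,
      equivalent_diameter_um = 2 * sqrt(area / pi))
  }
  particles <- if (length(keep_rows)) do.call(rbind, keep_rows)
    else data.frame(label = integer(), area_um2 = numeric(),
                    centroid_x_um = numeric(), centroid_y_um = numeric(),
                    equivalent_diameter_um = numeric())
  structure(list(particles = particles, labels = out_labels,
                 pixel_um = pixel_um), class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles at %g um/px\n",
              nrow(x$particles), x$pixel_um))
  invisible(x)
}

#' Distance-binned particle density and size
#'
#' Assigns each particle to a distance bin (half-open `[lo, hi)`) by its
#' centroid distance from a reference vessel wall and reports per-bin
#' particle density (particles/mm^2 of bin area) and mean particle area.
#' Particles beyond the last bin edge are counted in a separate overflow
#' row.
#'
#' @param particles a `particle_set`.
#' @param wall_mask logical matrix marking wall pixels, used both for
#'   centroid distances (Euclidean distance transform) and bin areas;
#'   alternatively give `wall_x_um` for a straight vertical wall.
#' @param wall_x_um x-position (um) of a vertical wall (distance is then
#'   `centroid_x - wall_x`).
#' @param bins increasing numeric vector of bin edges in um
#'   (default 0, 300, 600, 900).
#' @return data.frame with one row per bin plus an overflow row:
#'   `bin_lo_um`, `bin_hi_um`, `count`, `bin_area_mm2`,
#'   `density_per_mm2`, `mean_area_um2`.
#' @export
distance_binned_stats <- function(particles, wall_mask = NULL,
                                  wall_x_um = NULL,
                                  bins = c(0, 300, 600, 900)) {
  stopifnot(inherits(particles, "particle_set"))
  if (is.null(wall_mask) && is.null(wall_x_um))
    stop("a wall reference (wall_mask or wall_x_um) is required")
  p <- particles$particles
  px <- particles$pixel_um
  if (!is.null(wall_mask)) {
    dmap <- EBImage::distmap(matrix(as.numeric(!wall_mask),
                                    nrow(wall_mask))) * px
    ri <- pmax(1, pmin(nrow(wall_mask), round(p$centroid_y_um / px + 0.5)))
    ci <- pmax(1, pmin(ncol(wall_mask), round(p$centroid_x_um / px + 0.5)))
    dist <- dmap[cbind(ri, ci)]
    pix_dist <- as.vector(dmap)
  } else {
    dist <- p$centroid_x_um - wall_x_um
    nc <- ncol(particles$labels); nr <- nrow(particles$labels)
    pix_dist <- rep((seq_len(nc) - 0.5) * px - wall_x_um, each = nr)
  }
  n_bins <- length(bins) - 1
  rows <- vector("list", n_bins + 1)
  for (b in seq_len(n_bins)) {
    inb <- dist >= bins[b] & dist < bins[b + 1]
    area_mm2 <- sum(pix_dist >= bins[b] & pix_dist < bins[b + 1]) *
      px^2 / 1e6
    rows[[b]] <- data.frame(
      bin_lo_um = bins[b], bin_hi_um = bins[b + 1], count = sum(inb),
      bin_area_mm2 = area_mm2,
      density_per_mm2 = if (area_mm2 > 0) sum(inb) / area_mm2 else NA_real_,
      mean_area_um2 = if (any(inb)) mean(p$area_um2[inb]) else NA_real_)
  }
  over <- dist >= bins[length(bins)]
  over_area <- sum(pix_dist >= bins[length(bins)]) * px^2 / 1e6
  rows[[n_bins + 1]] <- data.frame(
    bin_lo_um = bins[length(bins)], bin_hi_um = Inf, count = sum(over),
    bin_area_mm2 = over_area,
    density_per_mm2 = if (over_area > 0) sum(over) / over_area else NA_real_,
    mean_area_um2 = if (any(over)) mean(p$area_um2[over]) else NA_real_)
  do.call(rbind, rows)
}

#' Signal area as a fraction of a reference area
#'
#' E.g. platelet (CD41a+) coverage normalized to vessel wall surface
#' area. When a reference mask is supplied the signal is clipped to it
#' first.
#'
#' @param signal_mask logical matrix of above-threshold signal.
#' @param pixel_um pixel size (um).
#' @param reference_area_um2 reference area; alternatively derived from
#'   `reference_mask`.
#' @param reference_mask optional logical matrix of the reference region.
#' @return percent in `[0, 100]`.
#' @export
area_fraction <- function(signal_mask, pixel_um,
                          reference_area_um2 = NULL,
                          reference_mask = NULL) {
  signal_mask <- as_mask(signal_mask)
  if (!is.null(reference_mask)) {
    reference_mask <- as_mask(reference_mask)
    signal_mask <- signal_mask & reference_mask
    reference_area_um2 <- sum(reference_mask) * pixel_um^2
  }
  if (is.null(reference_area_um2) || reference_area_um2 <= 0)
    stop("reference area must be positive")
  100 * sum(signal_mask) * pixel_um^2 / reference_area_um2
}

#' Fraction of objects colocalizing with a marker
#'
#' Percent of particles (e.g. nuclei) that overlap a co-registered marker
#' mask (e.g. TUNEL+) by at least `min_overlap_frac` of their area; the
#' default counts any overlap.
#'
#' @param marker_mask logical matrix.
#' @param object_set a `particle_set`.
#' @param min_overlap_frac minimum overlapped fraction of an object's
#'   area for it to count as positive (0 = any overlapping pixel).
#' @return list with `percent`, `n_positive`, `n_objects`; empty object
#'   sets give `percent = NA` with a flag.
#' @export
colocalization_fraction <- function(marker_mask, object_set,
                                    min_overlap_frac = 0) {
  stopifnot(inherits(object_set, "particle_set"))
  marker_mask <- as_mask(marker_mask)
  n <- nrow(object_set$particles)
  if (n == 0)
    return(list(percent = NA_real_, n_positive = 0L, n_objects = 0L,
                empty = TRUE))
  pos <- 0L
  for (l in object_set$particles$label) {
    sel <- object_set$labels == l
    frac <- sum(marker_mask & sel) / sum(sel)
    if (frac > min_overlap_frac || (min_overlap_frac == 0 && frac > 0))
      pos <- pos + 1L
  }
  list(percent = 100 * pos / n, n_positive = pos, n_objects = n,
       empty = FALSE)
}

#' Perfused area of a (stitched) bead image
#'
#' Thresholds the bead signal and reports the covered area, absolutely
#' and as a percentage of the analysis region (by convention twice the
#' original pattern boundary, supplied as the `roi`).
#'
#' @param image a [quant_image()] or numeric matrix.
#' @param pixel_um pixel size (um); taken from the `quant_image` if
#'   absent.
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param roi optional logical matrix; image and mask are cropped to it.
#' @return list with `area_um2` and `percent_of_field`.
#' @export
perfused_area <- function(image, pixel_um = NULL, threshold = "otsu",
                          roi = NULL) {
  if (inherits(image, "quant_image")) {
    if (is.null(pixel_um)) pixel_um <- image$pixel_um
    image <- image$pixels
  }
  stopifnot(!is.null(pixel_um))
  mask <- if (identical(threshold, "otsu")) binarize(image, "otsu")
          else binarize(image, "fixed", threshold = threshold)
  if (is.null(roi)) roi <- array(TRUE, dim = dim(mask))
  mask <- mask & roi
  list(area_um2 = sum(mask) * pixel_um^2,
       percent_of_field = 100 * sum(mask) / sum(roi))
}

#' Bead-tracking velocimetry
#'
#' Detects bead centroids per frame (threshold + connected components)
#' and links them frame-to-frame by mutual nearest neighbors within a
#' displacement gate. A link with two equally near candidates is
#' ambiguous: the track is terminated there. Velocity is the mean
#' inter-frame displacement over the frame interval.
#'
#' @param frames numeric array rows x cols x n_frames (>= 2 frames).
#' @param frame_interval_s seconds between frames.
#' @param pixel_um um per pixel.
#' @param threshold detection threshold on intensity.
#' @param max_displacement_um linking gate (um).
#' @return data.frame with one row per track: `track`, `n_steps`,
#'   `velocity_um_s`, `mean_step_um`.
#' @export
track_beads <- function(frames, frame_interval_s, pixel_um,
                        threshold = 0.5, max_displacement_um = Inf) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2,
            frame_interval_s > 0)
  n_f <- dim(frames)[3]
  detect <- function(t) {
    lab <- label_components(frames[, , t] > threshold, 8)
    n <- max(lab)
    if (n == 0) return(data.frame(x_um = numeric(), y_um = numeric()))
    cx <- cy <- numeric(n)
    for (l in seq_len(n)) {
      idx <- which(lab == l, arr.ind = TRUE)
      cx[l] <- mean(idx[, 2] - 0.5) * pixel_um
      cy[l] <- mean(idx[, 1] - 0.5) * pixel_um
    }
    data.frame(x_um = cx, y_um = cy)
  }
  dets <- lapply(seq_len(n_f), detect)
  # active tracks: list of (current position, accumulated steps)
  tracks <- lapply(seq_len(nrow(dets[[1]])), function(i)
    list(pos = unlist(dets[[1]][i, ]), steps = numeric(0), open = TRUE))
  for (t in 2:n_f) {
    nxt <- dets[[t]]
    taken <- rep(FALSE, nrow(nxt))
    for (k in seq_along(tracks)) {
      tr <- tracks[[k]]
      if (!tr$open) next
      if (nrow(nxt) == 0) { tracks[[k]]$open <- FALSE; next }
      dd <- sqrt((nxt$x_um - tr$pos[1])^2 + (nxt$y_um - tr$pos[2])^2)
      dd[taken] <- Inf
      j <- which.min(dd)
      if (!is.finite(dd[j]) || dd[j] > max_displacement_um) {
        tracks[[k]]$open <- FALSE
        next
      }
      if (sum(abs(dd - dd[j]) < 1e-9) > 1) {
        # equally distant candidates: ambiguous link
        tracks[[k]]$open <- FALSE
        next
      }
      taken[j] <- TRUE
      tracks[[k]]$steps <- c(tr$steps, dd[j])
      tracks[[k]]$pos <- c(nxt$x_um[j], nxt$y_um[j])
    }
    # unclaimed detections start new tracks
    for (j in which(!taken))
      tracks[[length(tracks) + 1]] <-
        list(pos = unlist(nxt[j, ]), steps = numeric(0), open = TRUE)
  }
  rows <- lapply(seq_along(tracks), function(k) {
    st <- tracks[[k]]$steps
    data.frame(track = k, n_steps = length(st),
               velocity_um_s = if (length(st))
                 mean(st) / frame_interval_s else NA_real_,
               mean_step_um = if (length(st)) mean(st) else NA_real_)
  })
  do.call(rbind, rows)
}
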