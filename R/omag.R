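#' Inter-repeat complex-differential OMAG flow reconstruction
#'
#' Flow contrast is the mean magnitude of the complex difference between
#' adjacent repeats,
#' `flow(z, x) = (1/(N-1)) * sum_k |S(z, k+1, x) - S(z, k, x)|`,
#' which cancels static clutter exactly (a constant phasor differences to
#' zero) while a phasor rotating at Doppler frequency `f` leaves
#' `2 A |sin(pi f dt)|` per pair. The structural image is the mean
#' magnitude `(1/N) * sum_k |S(z, k, x)|`.
#'
#' @param ensemble an [ascan_ensemble()].
#' @return a `flow_volume`: list with `flow` and `structure` matrices
#'   (depth x positions) and `pixel_um`.
#' @export
omag_flow <- function(ensemble) {
  stopifnot(inherits(ensemble, "ascan_ensemble"))
  s <- ensemble$signal
  n <- dim(s)[2]
  if (n < 2) stop("insufficient repeats: need at least 2")
  d <- dim(s)[1]; p <- dim(s)[3]
  flow <- matrix(0, d, p)
  for (k in seq_len(n - 1)) {
    dk <- Mod(s[, k + 1, , drop = FALSE] - s[, k, , drop = FALSE])
    dim(dk) <- c(d, p)
    flow <- flow + dk
  }
  flow <- flow / (n - 1)
  str_img <- matrix(apply(Mod(s), c(1, 3), mean), d, p)
  structure(list(flow = flow, structure = str_img,
                 pixel_um = ensemble$pixel_um),
            class = "flow_volume")
}

#' Maximum intensity projection
#'
#' @param volume numeric array (2-D or 3-D) or a `flow_volume` (its `flow`
#'   component is projected).
#' @param axis axis to collapse (1-based).
#' @param pixel_um optional um spacing of the surviving axes, attached to
#'   the result when it is 2-D.
#' @return matrix (or vector for 2-D input); 2-D results are returned as a
#'   [quant_image()] when `pixel_um` is supplied.
#' @export
mip <- function(volume, axis = 1, pixel_um = NULL) {
  if (inherits(volume, "flow_volume")) {
    if (is.null(pixel_um)) pixel_um <- volume$pixel_um[2]
    volume <- volume$flow
  }
  nd <- length(dim(volume))
  if (is.null(nd)) stop("volume must be an array")
  stopifnot(axis >= 1, axis <= nd)
  out <- apply(volume, setdiff(seq_len(nd), axis), max)
  if (length(dim(out)) == 2 && !is.null(pixel_um))
    out <- quant_image(out, pixel_um)
  out
}

#' Binarize an image
#'
#' @param image a [quant_image()] or numeric matrix.
#' @param method `"otsu"` (threshold chosen by Otsu's criterion on the
#'   intensity histogram) or `"fixed"`.
#' @param threshold numeric threshold, required for `method = "fixed"`.
#' @param invert if `TRUE`, select pixels below the threshold.
#' @return logical matrix. A flat image under Otsu yields an all-`FALSE`
#'   mask with a warning.
#' @export
binarize <- function(image, method = c("otsu", "fixed"), threshold = NULL,
                     invert = FALSE) {
  method <- match.arg(method)
  px <- if (inherits(image, "quant_image")) image$pixels else image
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    thr <- threshold
  } else {
    rng <- range(px)
    if (diff(rng) == 0) {
      warning("flat image: Otsu threshold undefined, returning empty mask")
      return(matrix(FALSE, nrow(px), ncol(px)))
    }
    norm <- (px - rng[1]) / diff(rng)
    thr <- rng[1] + EBImage::otsu(norm, range = c(0, 1)) * diff(rng)
  }
  if (invert) px < thr else px > thr
}

#' Vessel area density of a binary en-face mask
#'
#' Percentage of the region of interest occupied by vessel pixels.
#'
#' @param mask logical matrix (vessel = `TRUE`).
#' @param roi optional logical matrix of the same shape; default whole
#'   field.
#' @return percent in `[0, 100]`.
#' @export
vessel_area_density <- function(mask, roi = NULL) {
  stopifnot(is.logical(mask))
  if (is.null(roi)) roi <- array(TRUE, dim = dim(mask))
  stopifnot(identical(dim(roi), dim(mask)))
  n_roi <- sum(roi)
  if (n_roi == 0) stop("empty region of interest")
  100 * sum(mask & roi) / n_roi
}

#' Label connected components
#'
#' Union of foreground voxels under a configurable neighborhood:
#' 4- or 8-connectivity in 2-D, 6- or 26-connectivity in 3-D.
#'
#' @param mask logical array (2-D or 3-D).
#' @param connectivity 4/8 (2-D) or 6/26 (3-D); defaults to 8 and 26.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = NULL) {
  nd <- length(dim(mask))
  stopifnot(nd %in% c(2, 3))
  if (is.null(connectivity)) connectivity <- if (nd == 2) 8 else 26
  offsets <- neighbor_offsets(nd, connectivity)
  fg <- which(mask)
  labels <- array(0L, dim = dim(mask))
  if (length(fg) == 0) return(labels)
  id <- array(0L, dim = dim(mask))
  id[fg] <- seq_along(fg)
  dm <- dim(mask)
  coords <- arrayInd(fg, dm)
  edges <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb <- sweep(coords, 2, offsets[r, ], "+")
    ok <- rep(TRUE, nrow(nb))
    for (j in seq_len(nd)) ok <- ok & nb[, j] >= 1 & nb[, j] <= dm[j]
    if (!any(ok)) next
    nb_lin <- nb[ok, , drop = FALSE]
    nb_idx <- id[nb_lin]
    src <- id[fg][ok]
    keep <- nb_idx > 0
    if (any(keep))
      edges <- c(edges, rbind(src[keep], nb_idx[keep]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  # renumber components in first-appearance order for determinism
  relab <- match(comp, unique(comp))
  labels[fg] <- relab
  labels
}

neighbor_offsets <- function(nd, connectivity) {
  if (nd == 2) {
    all_off <- as.matrix(expand.grid(dz = -1:1, dx = -1:1))
    all_off <- all_off[rowSums(abs(all_off)) > 0, ]
    if (connectivity == 4) all_off <- all_off[rowSums(abs(all_off)) == 1, ]
    else if (connectivity != 8) stop("2-D connectivity must be 4 or 8")
  } else {
    all_off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    all_off <- all_off[rowSums(abs(all_off)) > 0, ]
    if (connectivity == 6) all_off <- all_off[rowSums(abs(all_off)) == 1, ]
    else if (connectivity != 26) stop("3-D connectivity must be 6 or 26")
  }
  # half the offsets suffice (each adjacency seen once)
  all_off[seq_len(nrow(all_off) / 2), , drop = FALSE]
}

#' Per-vessel diameters from a binary mask
#'
#' For each connected component the diameter is taken from the Euclidean
#' distance transform: twice its maximum (which is attained on the medial
#' axis) minus one pixel to correct for the half-pixel overshoot of
#' center-to-center distances, converted to um.
#'
#' @param mask logical 2-D matrix.
#' @param pixel_um isotropic pixel size in um.
#' @param connectivity passed to [label_components()].
#' @return data.frame with `label`, `area_px`, `area_um2`, `diameter_um`;
#'   empty for an empty mask.
#' @export
estimate_vessel_diameters <- function(mask, pixel_um, connectivity = 8) {
  stopifnot(is.logical(mask), length(dim(mask)) == 2, pixel_um > 0)
  labels <- label_components(mask, connectivity)
  n <- max(labels)
  if (n == 0)
    return(data.frame(label = integer(), area_px = integer(),
                      area_um2 = numeric(), diameter_um = numeric()))
  dmap <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  out <- data.frame(label = seq_len(n), area_px = NA_integer_,
                    area_um2 = NA_real_, diameter_um = NA_real_)
  for (l in seq_len(n)) {
    sel <- labels == l
    out$area_px[l] <- sum(sel)
    out$area_um2[l] <- sum(sel) * pixel_um^2
    out$diameter_um[l] <- (2 * max(dmap[sel]) - 1) * pixel_um
  }
  attr(out, "labels") <- labels
  out
}
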