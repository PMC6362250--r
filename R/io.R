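#' Write / read a repeated A-line ensemble
#'
#' The complex signal is stored as paired 32-bit float TIFF stacks
#' (real and imaginary parts, one frame per repeat) next to a JSON
#' metadata sidecar carrying the timing and optics fields.
#'
#' @param ensemble an [ascan_ensemble()].
#' @param path_prefix file prefix; writes `<prefix>_real.tif`,
#'   `<prefix>_imag.tif`, `<prefix>.json`.
#' @return (invisibly) the three paths.
#' @export
write_ensemble <- function(ensemble, path_prefix) {
  stopifnot(inherits(ensemble, "ascan_ensemble"))
  d <- dim(ensemble$signal)
  # TIFF stores [0, 1]; map each part affinely and record the transform
  rng_re <- range(Re(ensemble$signal))
  rng_im <- range(Im(ensemble$signal))
  to_frames <- function(part, rng) lapply(seq_len(d[2]), function(k) {
    m <- part[, k, , drop = FALSE]; dim(m) <- c(d[1], d[3])
    (m - rng[1]) / max(diff(rng), 1e-12)
  })
  p_re <- paste0(path_prefix, "_real.tif")
  p_im <- paste0(path_prefix, "_imag.tif")
  p_js <- paste0(path_prefix, ".json")
  tiff::writeTIFF(to_frames(Re(ensemble$signal), rng_re), p_re,
                  bits.per.sample = 32)
  tiff::writeTIFF(to_frames(Im(ensemble$signal), rng_im), p_im,
                  bits.per.sample = 32)
  meta <- ensemble[setdiff(names(ensemble), "signal")]
  meta$dim <- d
  meta$range_real <- rng_re
  meta$range_imag <- rng_im
  jsonlite::write_json(meta, p_js, auto_unbox = TRUE, digits = NA)
  invisible(c(p_re, p_im, p_js))
}

#' @rdname write_ensemble
#' @param path_prefix file prefix used by [write_ensemble()].
#' @export
read_ensemble <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  re <- tiff::readTIFF(paste0(path_prefix, "_real.tif"), all = TRUE)
  im <- tiff::readTIFF(paste0(path_prefix, "_imag.tif"), all = TRUE)
  d <- meta$dim
  sig <- array(0i, dim = d)
  s_re <- max(diff(meta$range_real), 1e-12)
  s_im <- max(diff(meta$range_imag), 1e-12)
  for (k in seq_len(d[2]))
    sig[, k, ] <- complex(
      real = re[[k]] * s_re + meta$range_real[1],
      imaginary = im[[k]] * s_im + meta$range_imag[1])
  ascan_ensemble(sig, a_line_rate_hz = meta$a_line_rate_hz,
                 pixel_um = meta$pixel_um,
                 center_wavelength_nm = meta$center_wavelength_nm,
                 refractive_index = meta$refractive_index,
                 preset_name = meta$preset_name)
}

#' Write a calibrated image to 16-bit TIFF
#'
#' Intensities are scaled to the stored `[0, 1]` range by the image
#' maximum; the scale and pixel size go to a JSON sidecar so the image
#' round-trips.
#'
#' @param image a [quant_image()].
#' @param path output `.tif` path (sidecar gets `.json` appended).
#' @return (invisibly) the path.
#' @export
write_quant_image <- function(image, path) {
  stopifnot(inherits(image, "quant_image"))
  mx <- max(image$pixels, 1e-12)
  tiff::writeTIFF(image$pixels / mx, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_um = image$pixel_um,
                            channel = image$channel, scale = mx),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_quant_image
#' @export
read_quant_image <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * meta$scale
  quant_image(px, meta$pixel_um, channel = meta$channel)
}

#' Write / read a vessel network as CSV edge + node lists
#'
#' @param network a [vessel_network()].
#' @param path_prefix writes `<prefix>_nodes.csv`, `<prefix>_edges.csv`
#'   and `<prefix>.json` (inlet/outlet metadata).
#' @return (invisibly) the paths.
#' @export
write_network <- function(network, path_prefix) {
  stopifnot(inherits(network, "vessel_network"))
  p_n <- paste0(path_prefix, "_nodes.csv")
  p_e <- paste0(path_prefix, "_edges.csv")
  p_j <- paste0(path_prefix, ".json")
  utils::write.csv(network$nodes, p_n, row.names = FALSE)
  utils::write.csv(network$edges, p_e, row.names = FALSE)
  jsonlite::write_json(list(inlet = network$inlet,
                            outlets = network$outlets), p_j,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(p_n, p_e, p_j))
}

#' @rdname write_network
#' @export
read_network <- function(path_prefix) {
  nodes <- utils::read.csv(paste0(path_prefix, "_nodes.csv"))
  edges <- utils::read.csv(paste0(path_prefix, "_edges.csv"))
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  vessel_network(nodes, edges, inlet = meta$inlet,
                 outlets = meta$outlets)
}

#' Export a vessel network to GraphML
#'
#' @param network a [vessel_network()].
#' @param path output `.graphml` path.
#' @export
write_network_graphml <- function(network, path) {
  g <- igraph::graph_from_data_frame(
    network$edges, directed = FALSE,
    vertices = network$nodes[, c("id", "x_um", "y_um", "z_um")])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Thin wrapper over `fgsea::gmtPathways()`.
#'
#' @param path GMT file path.
#' @return named list of gene-id character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the fgsea package")
  fgsea::gmtPathways(path)
}

#' Write / read a count matrix as TSV (genes x samples)
#'
#' @param counts integer matrix with gene row names and sample column
#'   names.
#' @param path TSV path.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(data.frame(gene = rownames(counts), counts,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
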