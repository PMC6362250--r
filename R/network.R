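#' Microvessel network container
#'
#' A graph of cylindrical vessel segments for Poiseuille hemodynamics.
#'
#' @param nodes data.frame with columns `id`, `x_um`, `y_um`, `z_um`.
#' @param edges data.frame with columns `from`, `to`, `radius_um`,
#'   `length_um`, `viscosity_mPas`; edge lengths must be at least the
#'   Euclidean node distance.
#' @param inlet,outlets node ids of the pressure inlet and outlet(s),
#'   used for equivalent-resistance queries.
#' @return object of class `vessel_network`.
#' @export
vessel_network <- function(nodes, edges, inlet = NULL, outlets = NULL) {
  stopifnot(all(c("id", "x_um", "y_um", "z_um") %in% names(nodes)),
            all(c("from", "to", "radius_um", "length_um",
                  "viscosity_mPas") %in% names(edges)),
            all(edges$radius_um > 0), all(edges$length_um > 0),
            all(edges$viscosity_mPas > 0),
            !anyDuplicated(nodes$id),
            all(edges$from %in% nodes$id), all(edges$to %in% nodes$id))
  co <- function(id) unlist(nodes[match(id, nodes$id),
                                  c("x_um", "y_um", "z_um")])
  eu <- sqrt((nodes$x_um[match(edges$from, nodes$id)] -
              nodes$x_um[match(edges$to, nodes$id)])^2 +
             (nodes$y_um[match(edges$from, nodes$id)] -
              nodes$y_um[match(edges$to, nodes$id)])^2 +
             (nodes$z_um[match(edges$from, nodes$id)] -
              nodes$z_um[match(edges$to, nodes$id)])^2)
  if (any(edges$length_um < eu - 1e-6))
    stop("edge length shorter than Euclidean node distance")
  net <- structure(list(nodes = nodes, edges = edges, inlet = inlet,
                        outlets = outlets), class = "vessel_network")
  if (!is.null(inlet) && !is.null(outlets)) {
    g <- network_graph(net)
    comp <- igraph::components(g)$membership
    if (any(comp[as.character(outlets)] != comp[as.character(inlet)]))
      stop("inlet and outlets are not connected")
  }
  net
}

network_graph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = network$nodes$id))
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Hagen-Poiseuille conductance of a cylindrical segment
#'
#' `g = pi r^4 / (8 mu L)` in SI units (m^3 s^-1 Pa^-1): the laminar
#' volume flow per unit pressure drop.
#'
#' @param radius_um lumen radius (um).
#' @param length_um segment length (um).
#' @param viscosity_mPas dynamic viscosity (mPa s).
#' @return conductance in m^3/(s Pa).
#' @export
edge_conductance <- function(radius_um, length_um, viscosity_mPas) {
  if (any(radius_um <= 0) || any(length_um <= 0) ||
      any(viscosity_mPas <= 0))
    stop("radius, length and viscosity must be positive")
  pi * (radius_um * 1e-6)^4 /
    (8 * viscosity_mPas * 1e-3 * length_um * 1e-6)
}

#' Wall shear stress of Poiseuille flow in a segment
#'
#' `tau = 4 mu Q / (pi r^3)`, reported in dyne/cm^2 (1 Pa = 10 dyne/cm^2).
#'
#' @param radius_um lumen radius (um).
#' @param viscosity_mPas dynamic viscosity (mPa s).
#' @param q_ul_min volume flow (uL/min; sign ignored).
#' @return shear stress in dyne/cm^2.
#' @export
wall_shear <- function(radius_um, viscosity_mPas, q_ul_min) {
  q_si <- abs(q_ul_min) / M3S_TO_UL_MIN
  tau_pa <- 4 * viscosity_mPas * 1e-3 * q_si / (pi * (radius_um * 1e-6)^3)
  tau_pa * PA_TO_DYNE_CM2
}

#' Solve nodal pressures and edge flows of a vessel network
#'
#' Kirchhoff current balance with Hagen-Poiseuille edge conductances:
#' every interior node satisfies `sum_e g_e (P_neighbor - P_node) = 0`
#' (or equals an imposed inflow), fixed-pressure nodes are eliminated as
#' Dirichlet conditions, and edge flows follow `Q_e = g_e dP_e`.
#'
#' @param network a [vessel_network()].
#' @param pressures named numeric vector of fixed nodal pressures (Pa);
#'   at least one is required.
#' @param inflows optional named numeric vector of imposed nodal inflows
#'   (uL/min, positive into the network).
#' @return `flow_solution`: list with `pressures_pa` (named vector),
#'   `edges` (the edge table with `conductance`, `flow_ul_min` signed
#'   from `from` to `to`, `shear_dyne_cm2`), `total_inlet_flow_ul_min`,
#'   `resistance_pa_min_ul` (`dP / Q` between inlet and the common outlet
#'   pressure, when defined) and the worst interior Kirchhoff residual.
#' @export
solve_pressures <- function(network, pressures, inflows = NULL) {
  stopifnot(inherits(network, "vessel_network"), length(pressures) >= 1)
  ids <- as.character(network$nodes$id)
  n <- length(ids)
  fixed <- names(pressures)
  if (!all(fixed %in% ids)) stop("unknown node in pressure BCs")
  g_e <- edge_conductance(network$edges$radius_um,
                          network$edges$length_um,
                          network$edges$viscosity_mPas)
  ia <- match(as.character(network$edges$from), ids)
  ib <- match(as.character(network$edges$to), ids)
  L <- matrix(0, n, n)
  for (e in seq_along(g_e)) {
    L[ia[e], ia[e]] <- L[ia[e], ia[e]] + g_e[e]
    L[ib[e], ib[e]] <- L[ib[e], ib[e]] + g_e[e]
    L[ia[e], ib[e]] <- L[ia[e], ib[e]] - g_e[e]
    L[ib[e], ia[e]] <- L[ib[e], ia[e]] - g_e[e]
  }
  b <- rep(0, n)
  if (!is.null(inflows)) {
    if (!all(names(inflows) %in% ids)) stop("unknown node in flow BCs")
    b[match(names(inflows), ids)] <- inflows / M3S_TO_UL_MIN
  }
  is_fixed <- ids %in% fixed
  p <- rep(NA_real_, n)
  p[is_fixed] <- pressures[match(ids[is_fixed], fixed)]
  free <- which(!is_fixed)
  if (length(free) > 0) {
    # a free component with no path to any fixed-pressure node is singular
    g <- network_graph(network)
    comp <- igraph::components(g)$membership
    fixed_comps <- unique(comp[fixed])
    orphan <- ids[!is_fixed & !(comp[ids] %in% fixed_comps)]
    if (length(orphan) > 0)
      stop("no pressure reference reaches component containing node(s): ",
           paste(utils::head(orphan, 5), collapse = ", "))
    rhs <- b[free] - L[free, is_fixed, drop = FALSE] %*% p[is_fixed]
    p[free] <- solve(L[free, free, drop = FALSE], rhs)
  }
  names(p) <- ids
  q_si <- g_e * (p[ia] - p[ib])
  edges <- network$edges
  edges$conductance <- g_e
  edges$flow_ul_min <- q_si * M3S_TO_UL_MIN
  edges$shear_dyne_cm2 <- wall_shear(edges$radius_um,
                                     edges$viscosity_mPas,
                                     edges$flow_ul_min)
  # Kirchhoff residual at interior (non-fixed, no-inflow) nodes
  div <- rep(0, n)
  for (e in seq_along(g_e)) {
    div[ia[e]] <- div[ia[e]] - q_si[e]
    div[ib[e]] <- div[ib[e]] + q_si[e]
  }
  interior <- !is_fixed & b == 0
  resid <- if (any(interior))
    max(abs(div[interior])) / max(abs(q_si), .Machine$double.eps) else 0
  total_in <- NA_real_
  resistance <- NA_real_
  if (!is.null(network$inlet) &&
      as.character(network$inlet) %in% names(p)) {
    inlet <- as.character(network$inlet)
    total_in <- -div[match(inlet, ids)] * M3S_TO_UL_MIN
    if (!is.null(network$outlets)) {
      p_out <- p[as.character(network$outlets)]
      if (diff(range(p_out)) < 1e-9 && abs(total_in) > 0)
        resistance <- (p[inlet] - p_out[1]) / total_in
    }
  }
  structure(list(pressures_pa = p, edges = edges,
                 total_inlet_flow_ul_min = total_in,
                 resistance_pa_min_ul = resistance,
                 kirchhoff_residual = resid),
            class = "flow_solution")
}

#' Equivalent hydraulic resistance between inlet and outlets
#'
#' Applies a unit pressure drop between the network inlet and its
#' outlet(s) and returns `dP / Q_total` (Pa per uL/min).
#'
#' @param network a [vessel_network()] with inlet and outlets set.
#' @param delta_p_pa pressure drop to apply (Pa).
#' @return resistance in Pa/(uL/min).
#' @export
equivalent_resistance <- function(network, delta_p_pa = 100) {
  stopifnot(!is.null(network$inlet), !is.null(network$outlets))
  bc <- c(delta_p_pa, rep(0, length(network$outlets)))
  names(bc) <- c(as.character(network$inlet),
                 as.character(network$outlets))
  sol <- solve_pressures(network, bc)
  delta_p_pa / sol$total_inlet_flow_ul_min
}

#' Rectangular grid vessel network
#'
#' A rows x cols lattice of identical cylindrical segments with the inlet
#' at one corner and the outlet at the opposite corner, mirroring
#' lithographically patterned microvessel grids (e.g. a 13 x 13 grid of
#' 125 um lumens). Edge count is `rows (cols - 1) + cols (rows - 1)`.
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @param lumen_diameter_um lumen diameter (um).
#' @param spacing_um center-to-center channel spacing (um).
#' @param viscosity_mPas fluid viscosity; 1 mPa s approximates culture
#'   medium, 3.5 mPa s whole blood.
#' @return a [vessel_network()].
#' @export
grid_network <- function(rows, cols, lumen_diameter_um = 125,
                         spacing_um = 500, viscosity_mPas = 1) {
  stopifnot(rows >= 2, cols >= 2)
  idx <- function(r, c) (r - 1) * cols + c
  nodes <- expand.grid(c = seq_len(cols), r = seq_len(rows))
  nodes <- data.frame(id = idx(nodes$r, nodes$c),
                      x_um = (nodes$c - 1) * spacing_um,
                      y_um = (nodes$r - 1) * spacing_um,
                      z_um = 0)
  nodes <- nodes[order(nodes$id), ]
  from <- integer(0); to <- integer(0)
  for (r in seq_len(rows)) for (c in seq_len(cols - 1)) {
    from <- c(from, idx(r, c)); to <- c(to, idx(r, c + 1))
  }
  for (c in seq_len(cols)) for (r in seq_len(rows - 1)) {
    from <- c(from, idx(r, c)); to <- c(to, idx(r + 1, c))
  }
  edges <- data.frame(from = from, to = to,
                      radius_um = lumen_diameter_um / 2,
                      length_um = spacing_um,
                      viscosity_mPas = viscosity_mPas)
  vessel_network(nodes, edges, inlet = idx(1, 1),
                 outlets = idx(rows, cols))
}

#' Add angiogenic sprouts to a vessel network
#'
#' Sprouts are thin segments (diameter below 50 um by default) added
#' either as bridges between existing non-adjacent nodes — which by
#' Rayleigh monotonicity can only lower the network's hydraulic
#' resistance — or as dead-end stubs to a new terminal node, which carry
#' no steady flow but are retained for geometry and shear reporting.
#'
#' @param network a [vessel_network()].
#' @param n_sprouts number of sprouts to add.
#' @param diameter_range_um sprout diameter range (um), sampled uniformly.
#' @param mode `"bridge"` or `"dead_end"`.
#' @param max_span_um bridges only connect node pairs at most this far
#'   apart (um).
#' @param seed RNG seed for reproducible sprouting.
#' @return the augmented [vessel_network()]; sprouts that cannot be
#'   attached (no eligible node pair) are skipped with a message.
#' @export
add_sprouts <- function(network, n_sprouts, diameter_range_um = c(20, 50),
                        mode = c("bridge", "dead_end"),
                        max_span_um = 1500, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "vessel_network"))
  with_seed(seed, {
    nodes <- network$nodes
    edges <- network$edges
    visc <- edges$viscosity_mPas[1]
    adj <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    next_id <- max(nodes$id) + 1
    added <- 0
    guard <- 0
    while (added < n_sprouts && guard < n_sprouts * 500) {
      guard <- guard + 1
      d_um <- runif(1, diameter_range_um[1], diameter_range_um[2])
      if (mode == "bridge") {
        pair <- sample(nodes$id, 2)
        key <- paste(min(pair), max(pair))
        i <- match(pair, nodes$id)
        span <- sqrt(sum((unlist(nodes[i[1], c("x_um", "y_um", "z_um")]) -
                          unlist(nodes[i[2], c("x_um", "y_um", "z_um")]))^2))
        if (key %in% adj || span > max_span_um || span == 0) next
        edges <- rbind(edges, data.frame(
          from = pair[1], to = pair[2], radius_um = d_um / 2,
          length_um = span, viscosity_mPas = visc))
        adj <- c(adj, key)
      } else {
        src <- sample(nodes$id, 1)
        i <- match(src, nodes$id)
        len <- runif(1, 50, 300)
        ang <- runif(1, 0, 2 * pi)
        nodes <- rbind(nodes, data.frame(
          id = next_id, x_um = nodes$x_um[i] + len * cos(ang),
          y_um = nodes$y_um[i] + len * sin(ang), z_um = nodes$z_um[i]))
        edges <- rbind(edges, data.frame(
          from = src, to = next_id, radius_um = d_um / 2,
          length_um = len, viscosity_mPas = visc))
        next_id <- next_id + 1
      }
      added <- added + 1
    }
    if (added < n_sprouts)
      message("attached ", added, " of ", n_sprouts, " sprouts")
    vessel_network(nodes, edges, inlet = network$inlet,
                   outlets = network$outlets)
  })
}
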