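#' Blood fluid properties
#'
#' Blood modeled as incompressible and Newtonian: density 1055 kg/m^3 and
#' dynamic viscosity 4 mPa.s by default.
#'
#' @param density Density in kg/m^3 (> 0).
#' @param viscosity Dynamic viscosity in Pa.s (> 0).
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1055, viscosity = 0.004) {
  if (density <= 0 || viscosity <= 0)
    stop("density and viscosity must be > 0", call. = FALSE)
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Boundary conditions for the steady flow solve
#'
#' A constant inflow velocity at the (degree-1) inlet and zero-pressure
#' conditions at all outlets. Case templates use 0.1 m/s (the simpler,
#' cropped anatomy) or 0.39 m/s (the complex anatomies); both derive from
#' phase-contrast MRI in the Circle of Willis, rescaled to the case's inflow
#' cross-section via [scale_inflow()].
#'
#' @param inlet_velocity Mean inflow velocity in m/s (> 0).
#' @param reference_velocity,reference_area Optional reference measurement
#'   (m/s, m^2); when both are given together with the case's inlet area the
#'   inflow is rescaled flow-preservingly.
#' @param outlet_pressure Fixed outlet pressure; must be 0 Pa.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_velocity = 0.1,
                                reference_velocity = NULL,
                                reference_area = NULL,
                                outlet_pressure = 0) {
  if (inlet_velocity <= 0) stop("inlet_velocity must be > 0", call. = FALSE)
  if (outlet_pressure != 0)
    stop("outlet pressure is fixed at 0 Pa by contract", call. = FALSE)
  structure(list(inlet_velocity = inlet_velocity,
                 reference_velocity = reference_velocity,
                 reference_area = reference_area,
                 outlet_pressure = 0),
            class = "boundary_conditions")
}

#' Hagen--Poiseuille resistance of a vessel segment
#'
#' `R = 8 * eta * L / (pi * r^4)` with `L` the centerline polyline length:
#' the laminar, fully developed resistance of a straight rigid tube, the
#' building block of the reduced-order network model.
#'
#' @param segment A [vessel_segment()], or a list with `radius` and
#'   `centerline`.
#' @param viscosity Dynamic viscosity in Pa.s.
#' @return Resistance in Pa.s/m^3.
#' @export
segment_resistance <- function(segment, viscosity = 0.004) {
  r <- segment$radius
  if (is.null(r) || !is.finite(r) || r <= 0)
    stop("radius must be > 0", call. = FALSE)
  L <- polyline_length(segment$centerline)
  8 * viscosity * L / (pi * r^4)
}

#' Rescale a reference inflow velocity to a case inflow area
#'
#' Flow-preserving convention: the reference volumetric flow
#' `Q = v_ref * A_ref` is pushed through the case's inflow cross-section, so
#' the case velocity is `v_ref * A_ref / A_case`.
#'
#' @param v_ref Reference velocity (m/s).
#' @param a_ref Reference cross-sectional area (m^2, > 0).
#' @param a_case Case inflow cross-sectional area (m^2, > 0).
#' @return Case inflow velocity in m/s.
#' @export
scale_inflow <- function(v_ref, a_ref, a_case) {
  if (a_ref <= 0 || a_case <= 0)
    stop("cross-sectional areas must be > 0", call. = FALSE)
  v_ref * a_ref / a_case
}

#' Solve steady laminar flow on the vessel graph
#'
#' Kirchhoff / Hagen--Poiseuille network solve: unknown pressures at all
#' non-outlet nodes, conductance `1/R` per open segment, fixed volumetric
#' inflow `Q_in = v_in * A_in` injected at each inlet (A_in = pi r^2 of the
#' inlet segment), outlets pinned to 0 Pa. The resulting sparse system is
#' symmetric positive definite and solved by Cholesky factorization. Blocked
#' feeders (via `state`) are absent from the system and carry zero flow.
#'
#' @param net A [vascular_network()].
#' @param state Optional [embolization_state()]; blocked feeders are removed
#'   before solving.
#' @param fluid A [fluid_properties()].
#' @param bc A [boundary_conditions()].
#' @return Object of class `flow_solution` with `node_pressure` (Pa; `NA`
#'   for nodes cut off from any outlet), `segment_flow` (m^3/s, signed
#'   proximal -> distal), `mean_velocity` (m/s), `segment_id`, `Q_in`, and
#'   the mass-balance `residual` relative to `Q_in`.
#' @export
solve_flow <- function(net, state = NULL,
                       fluid = fluid_properties(),
                       bc = boundary_conditions()) {
  if (!is.null(state)) net <- apply_embolization(net, state)$network
  segs <- net$segments
  node_ids <- rownames(net$nodes)

  v_in <- bc$inlet_velocity
  if (!is.null(bc$reference_velocity) && !is.null(bc$reference_area)) {
    a_in_tot <- sum(vapply(net$inlet_nodes, function(nd)
      pi * inlet_segment(net, nd)$radius^2, numeric(1)))
    v_in <- scale_inflow(bc$reference_velocity, bc$reference_area, a_in_tot)
  }

  # feasibility: each inlet must reach an outlet through open segments
  g <- network_graph(net)
  reach <- igraph::distances(g, v = net$inlet_nodes, to = net$outlet_nodes)
  if (!all(apply(is.finite(reach), 1L, any)))
    stop("no open outflow path from inlet to any outlet", call. = FALSE)

  # solve only on the component(s) connected to an outlet
  comp <- igraph::components(g)
  out_comps <- unique(comp$membership[net$outlet_nodes])
  solved_nodes <- node_ids[comp$membership[node_ids] %in% out_comps]
  unknown <- setdiff(solved_nodes, net$outlet_nodes)
  ui <- setNames(seq_along(unknown), unknown)

  cond <- vapply(segs, segment_resistance, numeric(1),
                 viscosity = fluid$viscosity)
  if (any(cond == 0))
    stop("zero-resistance (zero-length) segment in the flow graph; ",
         "merge its nodes before solving", call. = FALSE)
  cond <- 1 / cond

  n_u <- length(unknown)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs <- numeric(n_u)
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    if (!(s$proximal_node %in% solved_nodes)) next
    gi <- cond[k]
    a <- ui[s$proximal_node]; b <- ui[s$distal_node]
    if (!is.na(a)) { trip_i <- c(trip_i, a); trip_j <- c(trip_j, a); trip_x <- c(trip_x, gi) }
    if (!is.na(b)) { trip_i <- c(trip_i, b); trip_j <- c(trip_j, b); trip_x <- c(trip_x, gi) }
    if (!is.na(a) && !is.na(b)) {
      trip_i <- c(trip_i, a, b); trip_j <- c(trip_j, b, a)
      trip_x <- c(trip_x, -gi, -gi)
    }
  }
  inlet_area <- vapply(net$inlet_nodes, function(nd)
    pi * inlet_segment(net, nd)$radius^2, numeric(1))
  q_in <- v_in * inlet_area
  for (i in seq_along(net$inlet_nodes))
    rhs[ui[net$inlet_nodes[i]]] <- rhs[ui[net$inlet_nodes[i]]] + q_in[i]

  L <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n_u, n_u), symmetric = FALSE)
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)
  p_u <- tryCatch(as.numeric(Matrix::solve(L, rhs)),
                  error = function(e)
                    stop("pressure system is singular: ", conditionMessage(e),
                         call. = FALSE))

  p <- setNames(rep(NA_real_, length(node_ids)), node_ids)
  p[net$outlet_nodes] <- 0
  p[unknown] <- p_u

  Q <- vapply(seq_along(segs), function(k) {
    s <- segs[[k]]
    if (!(s$proximal_node %in% solved_nodes)) return(0)
    (p[s$proximal_node] - p[s$distal_node]) * cond[k]
  }, numeric(1))
  radii <- vapply(segs, function(s) s$radius, numeric(1))
  seg_ids <- vapply(segs, function(s) s$id, integer(1))

  # mass balance at interior (non-inlet, non-outlet) solved nodes
  net_flow <- setNames(numeric(length(node_ids)), node_ids)
  for (k in seq_along(segs)) {
    s <- segs[[k]]
    net_flow[s$proximal_node] <- net_flow[s$proximal_node] - Q[k]
    net_flow[s$distal_node] <- net_flow[s$distal_node] + Q[k]
  }
  interior <- setdiff(solved_nodes, c(net$inlet_nodes, net$outlet_nodes))
  residual <- if (length(interior) > 0L)
    max(abs(net_flow[interior])) / sum(q_in) else 0

  structure(list(node_pressure = p,
                 segment_id = seg_ids,
                 segment_flow = setNames(Q, seg_ids),
                 mean_velocity = setNames(Q / (pi * radii^2), seg_ids),
                 Q_in = sum(q_in),
                 inlet_velocity = v_in,
                 residual = residual),
            class = "flow_solution")
}

inlet_segment <- function(net, inlet_node) {
  for (s in net$segments)
    if (s$proximal_node == inlet_node || s$distal_node == inlet_node) return(s)
  stop("inlet node ", inlet_node, " has no incident segment", call. = FALSE)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> %d segments, Q_in = %.4g mL/s, residual %.2e\n",
              length(x$segment_flow), x$Q_in * 1e6, x$residual))
  invisible(x)
}

#' Per-feeder flow redistribution report
#'
#' Quantifies how occluding some feeders alters the flow in the others:
#' relative flow change `(Q_variant - Q_baseline) / Q_baseline` per feeder.
#' Feeders blocked in the variant report -100%; a feeder with zero baseline
#' flow reports `NA` (undefined) rather than dividing by zero.
#'
#' @param net The common [vascular_network()].
#' @param baseline,variant Two [solve_flow()] solutions on `net` (the
#'   variant typically under an embolization state).
#' @param fluid A [fluid_properties()] (for the delta-p column).
#' @return Data frame: feeder_id, Q_baseline, Q_variant, mean_velocity,
#'   delta_p (Pa), rel_change (fraction), pct_change.
#' @export
flow_change_report <- function(net, baseline, variant,
                               fluid = fluid_properties()) {
  fids <- feeder_ids(net)
  rows <- lapply(fids, function(id) {
    key <- as.character(id)
    qb <- baseline$segment_flow[key]
    qv <- variant$segment_flow[key]
    blocked <- !(key %in% names(variant$segment_flow))
    seg <- get_segment(net, id)
    if (blocked) {
      rel <- -1; qv <- 0; mv <- 0; dp <- NA_real_
    } else if (is.na(qb) || qb == 0) {
      rel <- NA_real_
      mv <- variant$mean_velocity[key]
      dp <- qv * segment_resistance(seg, fluid$viscosity)
    } else {
      rel <- (qv - qb) / qb
      mv <- variant$mean_velocity[key]
      dp <- qv * segment_resistance(seg, fluid$viscosity)
    }
    data.frame(feeder_id = id, Q_baseline = unname(qb), Q_variant = unname(qv),
               mean_velocity = unname(mv), delta_p = unname(dp),
               rel_change = rel, pct_change = 100 * rel)
  })
  do.call(rbind, rows)
}
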