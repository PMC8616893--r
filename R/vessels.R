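#' Vessel compartment labels
#'
#' The five anatomical compartments of an AVM vessel model: the parent
#' artery tree, the feeders supplying the nidus, the nidus itself, the
#' draining veins leaving the nidus, and the downstream veins.
#'
#' @return Character vector of the five valid compartment labels.
#' @export
compartments <- function() c("artery", "feeder", "nidus", "drainer", "vein")

#' Construct a vessel segment
#'
#' A segment is a tube of constant radius swept along a centerline polyline
#' between two network nodes, carrying one anatomical compartment label.
#'
#' @param id Integer segment id, unique within a network.
#' @param proximal_node,distal_node Node ids (character or integer-like).
#' @param radius Lumen radius in meters; must be > 0.
#' @param centerline Matrix (>= 2 rows x 3 columns) of 3D points in meters;
#'   the first and last row must coincide with the node positions.
#' @param compartment One of [compartments()].
#' @return An object of class `vessel_segment`.
#' @export
vessel_segment <- function(id, proximal_node, distal_node, radius, centerline,
                           compartment) {
  centerline <- as_points3(centerline)
  compartment <- match.arg(compartment, compartments())
  seg <- structure(
    list(id = as.integer(id),
         proximal_node = as.character(proximal_node),
         distal_node = as.character(distal_node),
         radius = as.numeric(radius),
         centerline = centerline,
         compartment = compartment),
    class = "vessel_segment")
  validate_vessel_segment(seg)
  seg
}

validate_vessel_segment <- function(seg) {
  if (!is.finite(seg$radius) || seg$radius <= 0)
    stop("segment ", seg$id, ": radius must be > 0", call. = FALSE)
  if (nrow(seg$centerline) < 2L)
    stop("segment ", seg$id, ": centerline needs at least 2 points", call. = FALSE)
  if (polyline_length(seg$centerline) <= 0)
    stop("segment ", seg$id, ": centerline has zero length", call. = FALSE)
  invisible(seg)
}

segment_length <- function(seg) polyline_length(seg$centerline)

#' Construct a labeled vascular network
#'
#' @param nodes Named list or named 3-column matrix of node positions in
#'   meters; names are node ids.
#' @param segments List of [vessel_segment()] objects.
#' @param inlet_nodes,outlet_nodes Character vectors of node ids; each must
#'   have graph degree 1.
#' @param validate Run the structural validity checks (default `TRUE`).
#' @return An object of class `vascular_network`.
#' @export
vascular_network <- function(nodes, segments, inlet_nodes, outlet_nodes,
                             validate = TRUE) {
  if (is.list(nodes)) {
    nm <- names(nodes)
    nodes <- do.call(rbind, lapply(nodes, as.numeric))
    rownames(nodes) <- nm
  }
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  net <- structure(
    list(nodes = nodes,
         segments = segments,
         inlet_nodes = as.character(inlet_nodes),
         outlet_nodes = as.character(outlet_nodes)),
    class = "vascular_network")
  if (validate) validate_network(net)
  net
}

#' Validate a vascular network
#'
#' Checks node-id uniqueness, connectivity, degree-1 inlets/outlets,
#' centerline/node coincidence, and that every feeder lies on some
#' inlet-to-outlet path.
#'
#' @param net A [vascular_network()].
#' @return The network, invisibly; errors describe the first violation.
#' @export
validate_network <- function(net) {
  ids <- rownames(net$nodes)
  if (anyDuplicated(ids)) stop("node ids are not unique", call. = FALSE)
  for (seg in net$segments) {
    validate_vessel_segment(seg)
    for (end in c("proximal_node", "distal_node"))
      if (!seg[[end]] %in% ids)
        stop("segment ", seg$id, ": unknown node ", seg[[end]], call. = FALSE)
    if (max(abs(seg$centerline[1L, ] - net$nodes[seg$proximal_node, ])) > 1e-12 ||
        max(abs(seg$centerline[nrow(seg$centerline), ] -
                net$nodes[seg$distal_node, ])) > 1e-12)
      stop("segment ", seg$id, ": centerline endpoints must coincide with nodes",
           call. = FALSE)
  }
  seg_ids <- vapply(net$segments, function(s) s$id, integer(1))
  if (anyDuplicated(seg_ids)) stop("segment ids are not unique", call. = FALSE)
  g <- network_graph(net)
  if (igraph::components(g)$no != 1L)
    stop("network graph is not connected", call. = FALSE)
  deg <- igraph::degree(g)
  for (v in c(net$inlet_nodes, net$outlet_nodes))
    if (deg[v] != 1L)
      stop("inlet/outlet node ", v, " must have degree 1", call. = FALSE)
  if (length(intersect(net$inlet_nodes, net$outlet_nodes)) > 0L)
    stop("inlet and outlet sets must be disjoint", call. = FALSE)
  # every feeder on some inlet -> outlet path: removing the feeder edge must
  # either disconnect inlet side from outlet side, or the feeder's endpoints
  # must each reach an inlet resp. outlet
  for (seg in net$segments) {
    if (seg$compartment != "feeder") next
    up <- igraph::distances(g, v = seg$proximal_node, to = net$inlet_nodes)
    dn <- igraph::distances(g, v = seg$distal_node, to = net$outlet_nodes)
    if (!any(is.finite(up)) || !any(is.finite(dn)))
      stop("feeder segment ", seg$id, " is not on any inlet-outlet path",
           call. = FALSE)
  }
  invisible(net)
}

# igraph view of the network; multi-edges allowed, edge attr "sid" = segment
# id, "len" = polyline length, "compartment".
network_graph <- function(net, segment_ids = NULL) {
  segs <- net$segments
  if (!is.null(segment_ids))
    segs <- Filter(function(s) s$id %in% segment_ids, segs)
  el <- do.call(rbind, lapply(segs, function(s) c(s$proximal_node, s$distal_node)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(rownames(net$nodes), igraph::V(g)$name)),
    name = setdiff(rownames(net$nodes), igraph::V(g)$name))
  igraph::E(g)$sid <- vapply(segs, function(s) s$id, integer(1))
  igraph::E(g)$len <- vapply(segs, segment_length, numeric(1))
  igraph::E(g)$compartment <- vapply(segs, function(s) s$compartment, character(1))
  g
}

feeder_segments <- function(net) {
  Filter(function(s) s$compartment == "feeder", net$segments)
}

#' Feeder ids of a network, in stable (ascending id) order
#' @param net A [vascular_network()].
#' @return Integer vector of feeder segment ids.
#' @export
feeder_ids <- function(net) {
  sort(vapply(feeder_segments(net), function(s) s$id, integer(1)))
}

get_segment <- function(net, id) {
  for (s in net$segments) if (s$id == id) return(s)
  stop("no segment with id ", id, call. = FALSE)
}

#' @export
print.vascular_network <- function(x, ...) {
  comp <- table(factor(vapply(x$segments, function(s) s$compartment,
                              character(1)), levels = compartments()))
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ",
      length(x$segments), " segments\n", sep = "")
  cat("  segments:", paste(names(comp), comp, sep = "=", collapse = " "), "\n")
  cat("  inlets:", paste(x$inlet_nodes, collapse = ", "),
      " outlets:", paste(x$outlet_nodes, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a vascular network to structured JSON text
#'
#' Writes nodes, segments (with centerlines), labels, inlet/outlet sets and
#' a `units` field ("m"). [read_network_json()] is the exact inverse.
#'
#' @param net A [vascular_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  obj <- list(
    format = "avmflow-network",
    units = "m",
    nodes = list(ids = rownames(net$nodes), positions = unname(net$nodes)),
    inlet_nodes = net$inlet_nodes,
    outlet_nodes = net$outlet_nodes,
    segments = lapply(net$segments, function(s)
      list(id = s$id, proximal_node = s$proximal_node,
           distal_node = s$distal_node, radius = s$radius,
           compartment = s$compartment, centerline = unname(s$centerline))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a vascular network from its JSON serialization
#' @param path File written by [write_network_json()].
#' @return A [vascular_network()].
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "avmflow-network"))
    stop("not an avmflow network file: ", path, call. = FALSE)
  nodes <- as.matrix(obj$nodes$positions)
  rownames(nodes) <- obj$nodes$ids
  segs <- lapply(seq_len(nrow(obj$segments)), function(i) {
    s <- obj$segments[i, ]
    vessel_segment(s$id, s$proximal_node, s$distal_node, s$radius,
                   as.matrix(s$centerline[[1L]]), s$compartment)
  })
  vascular_network(nodes, segs, obj$inlet_nodes, obj$outlet_nodes)
}

# Fixed display palette; shades chosen once, hex-documented.
.compartment_palette <- c(
  artery  = "#8B0000", # dark red
  feeder  = "#FF0000", # red
  nidus   = "#FF8080", # light red
  drainer = "#800080", # purple
  vein    = "#0000FF") # blue

#' Display color of a compartment
#'
#' Fixed lookup table mapping each of the five compartment labels to an RGBA
#' color: arteries dark red (`#8B0000`), feeders red (`#FF0000`), nidus light
#' red (`#FF8080`), draining veins purple (`#800080`), veins blue (`#0000FF`);
#' alpha always 1. The mapping is total and injective over the labels.
#'
#' @param compartment Character vector of compartment labels.
#' @return Numeric matrix with one row per input and columns r, g, b, a in
#'   \[0, 1\].
#' @export
compartment_color <- function(compartment) {
  bad <- setdiff(compartment, compartments())
  if (length(bad) > 0L)
    stop("unknown compartment label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  hex <- .compartment_palette[compartment]
  rgb <- t(vapply(hex, function(h)
    as.numeric(strtoi(c(substr(h, 2, 3), substr(h, 4, 5), substr(h, 6, 7)),
                      16L)) / 255, numeric(3)))
  out <- cbind(rgb, 1)
  dimnames(out) <- list(compartment, c("r", "g", "b", "a"))
  out
}
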