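#' Construct an embolization state
#'
#' One of the 2^N blocked/unblocked feeder combinations: an ordered logical
#' flag per feeder (TRUE = blocked), ordered by ascending feeder segment id.
#'
#' @param blocked Logical vector, one flag per feeder.
#' @param feeder_ids Integer feeder segment ids in the same (ascending) order.
#' @return Object of class `embolization_state`.
#' @export
embolization_state <- function(blocked, feeder_ids) {
  blocked <- as.logical(blocked)
  feeder_ids <- as.integer(feeder_ids)
  if (length(blocked) != length(feeder_ids))
    stop("one blocked flag per feeder id required", call. = FALSE)
  if (is.unsorted(feeder_ids, strictly = TRUE))
    stop("feeder ids must be strictly ascending", call. = FALSE)
  structure(list(blocked = blocked, feeder_ids = feeder_ids),
            class = "embolization_state")
}

#' Bitstring form of an embolization state ("0" = open, "1" = blocked)
#' @param state An [embolization_state()].
#' @return Character scalar, first character = lowest feeder id.
#' @export
state_bitstring <- function(state) {
  paste(as.integer(state$blocked), collapse = "")
}

#' @export
print.embolization_state <- function(x, ...) {
  cat("<embolization_state> ", state_bitstring(x),
      " (feeders ", paste(x$feeder_ids, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Enumerate all blocked/unblocked feeder combinations
#'
#' Returns all 2^n embolization states in lexicographic bitstring order, the
#' all-open state first. With three feeders this yields the eight variants
#' that drive eight flow computations.
#'
#' @param n_feeders Number of feeders (>= 0), or a [vascular_network()]
#'   whose feeder count and ids are used.
#' @return List of [embolization_state()] objects of length `2^n`.
#' @export
enumerate_variants <- function(n_feeders) {
  if (inherits(n_feeders, "vascular_network")) {
    fids <- feeder_ids(n_feeders)
    n <- length(fids)
  } else {
    n <- as.integer(n_feeders)
    if (is.na(n) || n < 0L) stop("n_feeders must be >= 0", call. = FALSE)
    fids <- seq_len(n)
  }
  if (n > 24L) stop("refusing to enumerate 2^", n, " variants", call. = FALSE)
  lapply(seq_len(2^n) - 1L, function(code) {
    bits <- if (n == 0L) logical(0) else
      as.logical(bitwAnd(bitwShiftR(code, (n - 1L):0L), 1L))
    embolization_state(bits, fids)
  })
}

#' Apply an embolization state to a network
#'
#' Blocking removes the feeder from the flow graph entirely (full occlusion,
#' infinite resistance); geometry is untouched. An occlusion marker is
#' emitted at each blocked feeder's distal, nidus-side end — the transition
#' of the feeder into the nidus, where the sclerosant is deposited. The
#' marker is a short cylinder: its axis is the local centerline tangent, its
#' radius the feeder radius, and its length 10% of the feeder length
#' (display only). The input network is never mutated.
#'
#' @param net A [vascular_network()].
#' @param state An [embolization_state()] matching the network's feeders.
#' @return List with `network` (flow graph: the input minus blocked feeder
#'   segments) and `markers` (data frame: feeder_id, x, y, z, axis_x..z,
#'   radius, length).
#' @export
apply_embolization <- function(net, state) {
  fids <- feeder_ids(net)
  if (!identical(fids, state$feeder_ids) ||
      length(state$blocked) != length(fids))
    stop("state does not match the network's feeders", call. = FALSE)
  blocked_ids <- fids[state$blocked]
  markers <- do.call(rbind, lapply(blocked_ids, function(id) {
    seg <- get_segment(net, id)
    cl <- seg$centerline
    npt <- nrow(cl)
    ax <- cl[npt, ] - cl[npt - 1L, ]
    ax <- ax / vnorm(ax)
    data.frame(feeder_id = id,
               x = cl[npt, 1L], y = cl[npt, 2L], z = cl[npt, 3L],
               axis_x = ax[1L], axis_y = ax[2L], axis_z = ax[3L],
               radius = seg$radius, length = 0.1 * segment_length(seg))
  }))
  if (is.null(markers))
    markers <- data.frame(feeder_id = integer(0), x = numeric(0),
                          y = numeric(0), z = numeric(0), axis_x = numeric(0),
                          axis_y = numeric(0), axis_z = numeric(0),
                          radius = numeric(0), length = numeric(0))
  open_segments <- Filter(function(s) !(s$id %in% blocked_ids), net$segments)
  flow_net <- vascular_network(net$nodes, open_segments, net$inlet_nodes,
                               net$outlet_nodes, validate = FALSE)
  list(network = flow_net, markers = markers)
}

#' Construct an embolization plan
#' @param order Integer feeder ids in embolization order.
#' @param keep_open Number of feeders that must remain unblocked (>= 1).
#' @return Object of class `embolization_plan`.
#' @export
embolization_plan <- function(order, keep_open) {
  structure(list(order = as.integer(order), keep_open = as.integer(keep_open)),
            class = "embolization_plan")
}

#' @export
print.embolization_plan <- function(x, ...) {
  cat("<embolization_plan> close", length(x$order), "feeders in order:",
      paste(x$order, collapse = " -> "),
      sprintf("(keep %d open)\n", x$keep_open))
  invisible(x)
}

#' Plan an embolization order with the clinical heuristic
#'
#' Orders feeders for step-wise occlusion the way interventionalists plan
#' it: small-diameter, proximally located feeders first, larger and more
#' distal feeders later, and enough feeders left open to preserve venous
#' outflow. Sort keys: diameter ascending, then centerline path distance
#' from the inlet ascending, then feeder id ascending (deterministic
#' tie-break). The plan closes `n_feeders - keep_open` feeders.
#'
#' @param net A [vascular_network()].
#' @param keep_open Feeders to leave open, `1 <= keep_open <= n_feeders`.
#' @return An [embolization_plan()].
#' @export
plan_embolization_order <- function(net, keep_open = 1L) {
  fsegs <- feeder_segments(net)
  n <- length(fsegs)
  keep_open <- as.integer(keep_open)
  if (keep_open < 1L) stop("keep_open must be >= 1", call. = FALSE)
  if (keep_open > n)
    stop("keep_open (", keep_open, ") exceeds the feeder count (", n, ")",
         call. = FALSE)
  g <- network_graph(net)
  dist_in <- igraph::distances(g, v = net$inlet_nodes,
                               weights = igraph::E(g)$len)
  info <- data.frame(
    id = vapply(fsegs, function(s) s$id, integer(1)),
    diameter = vapply(fsegs, function(s) 2 * s$radius, numeric(1)),
    dist = vapply(fsegs, function(s)
      min(dist_in[, s$proximal_node]), numeric(1)))
  info <- info[order(info$diameter, info$dist, info$id), ]
  embolization_plan(head(info$id, n - keep_open), keep_open)
}
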