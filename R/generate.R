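#' Configuration for the synthetic AVM generator
#'
#' Describes a synthetic arteriovenous malformation: a parent artery whose
#' branches feed a nidus (a random connected vessel tangle) that drains
#' through draining veins into the venous side. Stands in for a segmented
#' patient vessel model; all lengths are meters.
#'
#' @param n_feeders Number of feeder segments (>= 1).
#' @param n_nidus_nodes Number of nidus graph nodes (>= 2).
#' @param n_drainers Number of draining-vein segments (>= 1).
#' @param nidus_mean_degree Target mean degree of the nidus graph (> 0);
#'   realized degree is at least that of a spanning tree.
#' @param radius_ranges Named list of `(min, max)` radius ranges in meters,
#'   one per compartment. Defaults reflect cerebral vessel calibers: parent
#'   artery 1.2--1.5 mm, feeders 0.3--0.6 mm, nidus vessels 0.1--0.25 mm,
#'   draining veins 0.4--0.8 mm, veins 0.8--1.2 mm.
#' @param domain_extent Numeric length-3, bounding extent of the model in
#'   meters (default 20 x 12 x 12 mm).
#' @param seed Integer seed; the whole generation is deterministic in it.
#' @return An object of class `avm_config`.
#' @export
avm_config <- function(n_feeders = 3L,
                       n_nidus_nodes = 12L,
                       n_drainers = 2L,
                       nidus_mean_degree = 3,
                       radius_ranges = list(
                         artery  = c(1.2e-3, 1.5e-3),
                         feeder  = c(3e-4, 6e-4),
                         nidus   = c(1e-4, 2.5e-4),
                         drainer = c(4e-4, 8e-4),
                         vein    = c(8e-4, 1.2e-3)),
                       domain_extent = c(0.020, 0.012, 0.012),
                       seed = 1L) {
  cfg <- structure(
    list(n_feeders = as.integer(n_feeders),
         n_nidus_nodes = as.integer(n_nidus_nodes),
         n_drainers = as.integer(n_drainers),
         nidus_mean_degree = as.numeric(nidus_mean_degree),
         radius_ranges = radius_ranges,
         domain_extent = as.numeric(domain_extent),
         seed = as.integer(seed)),
    class = "avm_config")
  validate_avm_config(cfg)
  cfg
}

validate_avm_config <- function(cfg) {
  if (cfg$n_feeders < 1L) stop("n_feeders must be >= 1", call. = FALSE)
  if (cfg$n_drainers < 1L) stop("n_drainers must be >= 1", call. = FALSE)
  if (cfg$n_nidus_nodes < 2L) stop("n_nidus_nodes must be >= 2", call. = FALSE)
  if (cfg$nidus_mean_degree <= 0) stop("nidus_mean_degree must be > 0", call. = FALSE)
  for (comp in compartments()) {
    rr <- cfg$radius_ranges[[comp]]
    if (is.null(rr) || length(rr) != 2L || rr[1] <= 0 || rr[1] >= rr[2])
      stop("radius range for ", comp, " must satisfy 0 < min < max", call. = FALSE)
  }
  if (length(cfg$domain_extent) != 3L || any(cfg$domain_extent <= 0))
    stop("domain_extent must be 3 positive lengths", call. = FALSE)
  if (is.na(cfg$seed)) stop("seed is mandatory", call. = FALSE)
  invisible(cfg)
}

# Jittered polyline of npt points from a to b; endpoints exact.
jittered_polyline <- function(a, b, npt = 5L, jitter = 0) {
  t <- seq(0, 1, length.out = npt)
  pts <- outer(t, b - a) + rep(a, each = npt)
  if (jitter > 0 && npt > 2L) {
    e <- b - a
    u <- perp_unit(e)
    v <- pracma_cross(e / vnorm(e), u)
    mid <- seq(2L, npt - 1L)
    amp <- jitter * sin(pi * t[mid])  # taper to zero at the endpoints
    pts[mid, ] <- pts[mid, , drop = FALSE] +
      outer(amp * runif(length(mid), -1, 1), u) +
      outer(amp * runif(length(mid), -1, 1), v)
  }
  pts
}

#' Generate a seeded synthetic AVM vascular network
#'
#' Builds the compartment topology artery -> feeder -> nidus -> drainer ->
#' vein: a parent artery trunk from a single degree-1 inlet to a branching
#' hub, `n_feeders` short artery branches fanning out to feeder origins,
#' feeder segments into distinct nidus boundary nodes, a nidus synthesized as
#' a random connected graph (random spanning tree plus extra proximity-free
#' random edges up to the target mean degree) over points in a ball, and
#' `n_drainers` draining veins leaving the nidus, each continuing as a vein
#' to its own degree-1 outlet. Radii are drawn uniformly from the
#' per-compartment ranges. All randomness flows through one generator seeded
#' from `config$seed`, so equal configs give identical networks.
#'
#' @param config An [avm_config()].
#' @return A validated [vascular_network()].
#' @export
generate_synthetic_avm <- function(config) {
  validate_avm_config(config)
  withr::with_seed(config$seed, generate_avm_impl(config))
}

generate_avm_impl <- function(cfg) {
  ext <- cfg$domain_extent
  rr <- function(comp) runif(1, cfg$radius_ranges[[comp]][1],
                             cfg$radius_ranges[[comp]][2])
  nf <- cfg$n_feeders; nn <- cfg$n_nidus_nodes; nd <- cfg$n_drainers

  nodes <- list(); segs <- list(); sid <- 0L
  add_seg <- function(p, d, radius, cl, comp) {
    sid <<- sid + 1L
    segs[[sid]] <<- vessel_segment(sid, p, d, radius, cl, comp)
  }

  # parent artery: inlet -> hub
  inlet <- c(0, ext[2] / 2, ext[3] / 2)
  hub <- c(0.22 * ext[1], ext[2] / 2, ext[3] / 2)
  nodes[["inlet"]] <- inlet
  nodes[["hub"]] <- hub
  add_seg("inlet", "hub", rr("artery"),
          jittered_polyline(inlet, hub, 5L, 0.01 * ext[1]), "artery")

  # nidus node cloud in a ball around the domain center-right
  nidus_center <- c(0.55 * ext[1], ext[2] / 2, ext[3] / 2)
  nidus_radius <- 0.18 * min(ext)
  u <- matrix(rnorm(3L * nn), ncol = 3L)
  u <- u / sqrt(rowSums(u * u)) * (nidus_radius * runif(nn)^(1 / 3))
  nidus_pts <- sweep(u, 2L, nidus_center, "+")
  nidus_ids <- paste0("n", seq_len(nn))
  for (i in seq_len(nn)) nodes[[nidus_ids[i]]] <- nidus_pts[i, ]

  # feeder attachment: the nf nidus nodes closest to the arterial side
  ord_in <- order(nidus_pts[, 1L])
  attach_in <- nidus_ids[ord_in[seq_len(min(nf, nn))]]
  if (nf > nn) attach_in <- c(attach_in, sample(nidus_ids, nf - nn, replace = TRUE))

  # artery branches fan out from the hub toward each feeder origin
  for (i in seq_len(nf)) {
    tgt <- nodes[[attach_in[i]]]
    fo <- hub + 0.55 * (tgt - hub) +
      c(0, runif(1, -0.08, 0.08) * ext[2], runif(1, -0.08, 0.08) * ext[3])
    fo_id <- paste0("f", i)
    nodes[[fo_id]] <- fo
    add_seg("hub", fo_id, rr("artery"),
            jittered_polyline(hub, fo, 4L, 0.005 * ext[1]), "artery")
    add_seg(fo_id, attach_in[i], rr("feeder"),
            jittered_polyline(fo, tgt, 5L, 0.004 * ext[1]), "feeder")
  }

  # nidus graph: random spanning tree + extra random edges to mean degree
  tree_edges <- cbind(seq(2L, nn),
                      vapply(seq(2L, nn), function(i)
                        sample.int(i - 1L, 1L), integer(1)))
  m_target <- max(nn - 1L, round(cfg$nidus_mean_degree * nn / 2))
  all_pairs <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  free <- all_pairs[!(key(all_pairs) %in% key(tree_edges)), , drop = FALSE]
  n_extra <- min(m_target - (nn - 1L), nrow(free))
  edges <- tree_edges
  if (n_extra > 0L)
    edges <- rbind(edges, free[sample.int(nrow(free), n_extra), , drop = FALSE])
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1L]; b <- edges[k, 2L]
    add_seg(nidus_ids[a], nidus_ids[b], rr("nidus"),
            jittered_polyline(nidus_pts[a, ], nidus_pts[b, ], 4L,
                              0.002 * ext[1]), "nidus")
  }

  # drainers leave from the venous-side nidus nodes, veins reach outlets
  ord_out <- order(nidus_pts[, 1L], decreasing = TRUE)
  attach_out <- nidus_ids[ord_out[seq_len(min(nd, nn))]]
  if (nd > nn) attach_out <- c(attach_out, sample(nidus_ids, nd - nn, replace = TRUE))
  for (i in seq_len(nd)) {
    src <- nodes[[attach_out[i]]]
    frac <- if (nd == 1L) 0.5 else (i - 1) / (nd - 1)
    vn <- c(0.8 * ext[1], (0.25 + 0.5 * frac) * ext[2],
            ext[3] / 2 + runif(1, -0.05, 0.05) * ext[3])
    out <- c(ext[1], (0.25 + 0.5 * frac) * ext[2], vn[3])
    vn_id <- paste0("v", i); out_id <- paste0("out", i)
    nodes[[vn_id]] <- vn; nodes[[out_id]] <- out
    add_seg(attach_out[i], vn_id, rr("drainer"),
            jittered_polyline(src, vn, 5L, 0.006 * ext[1]), "drainer")
    add_seg(vn_id, out_id, rr("vein"),
            jittered_polyline(vn, out, 4L, 0.004 * ext[1]), "vein")
  }

  vascular_network(nodes, segs, "inlet", paste0("out", seq_len(nd)))
}
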