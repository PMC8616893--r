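#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif rnorm setNames
#' @importFrom utils write.csv head tail
NULL

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Euclidean length of the polyline given as an n x 3 matrix.
polyline_length <- function(pts) {
  pts <- as_points3(pts)
  if (nrow(pts) < 2L) return(0)
  d <- diff(pts)
  sum(sqrt(rowSums(d * d)))
}

# Coerce to an n x 3 numeric matrix of 3D points.
as_points3 <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) %% 3L == 0L)
    x <- matrix(as.numeric(x), ncol = 3L, byrow = TRUE)
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3L) stop("points must have 3 columns", call. = FALSE)
  dimnames(x) <- NULL
  x
}

# Normalize rows of an n x 3 matrix; zero rows stay zero.
unit_rows <- function(m) {
  n <- sqrt(rowSums(m * m))
  ok <- n > 0
  m[ok, ] <- m[ok, , drop = FALSE] / n[ok]
  m
}

vnorm <- function(v) sqrt(sum(v * v))

# A unit vector perpendicular to v (any stable choice).
perp_unit <- function(v) {
  v <- v / vnorm(v)
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- pracma_cross(v, a)
  w / vnorm(w)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Minimum distance from each query point to a polyline, together with the
# unit tangent of the nearest polyline piece (oriented along the polyline).
# points: n x 3; centerline: m x 3 (m >= 2). Returns list(dist, tangent).
dist_to_polyline <- function(points, centerline) {
  points <- as_points3(points)
  cl <- as_points3(centerline)
  n <- nrow(points)
  best_d2 <- rep(Inf, n)
  best_tan <- matrix(0, n, 3L)
  for (i in seq_len(nrow(cl) - 1L)) {
    p <- cl[i, ]
    q <- cl[i + 1L, ]
    e <- q - p
    len2 <- sum(e * e)
    if (len2 == 0) next
    rel <- sweep(points, 2L, p)
    t <- clamp((rel %*% e)[, 1L] / len2, 0, 1)
    foot <- outer(t, e) + rep(p, each = n)
    dv <- points - foot
    d2 <- rowSums(dv * dv)
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      tan_u <- e / sqrt(len2)
      best_tan[upd, ] <- rep(tan_u, each = sum(upd))
    }
  }
  list(dist = sqrt(best_d2), tangent = best_tan)
}
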