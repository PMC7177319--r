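# Internal geometry helpers. All coordinates are planar metric (metres);
# geographic inputs must be projected upstream.

polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

# cumulative curve length at each vertex
polyline_cumlen <- function(coords) {
  c(0, cumsum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)))
}

# point on a polyline at curve distance t (clamped to [0, length])
point_at_t <- function(coords, t) {
  cl <- polyline_cumlen(coords)
  L <- cl[length(cl)]
  t <- min(max(t, 0), L)
  i <- findInterval(t, cl, rightmost.closed = TRUE)
  i <- min(i, nrow(coords) - 1L)
  seg_len <- cl[i + 1L] - cl[i]
  f <- if (seg_len > 0) (t - cl[i]) / seg_len else 0
  c(coords[i, 1] + f * (coords[i + 1L, 1] - coords[i, 1]),
    coords[i, 2] + f * (coords[i + 1L, 2] - coords[i, 2]))
}

# sub-polyline between curve distances t0 < t1
sub_polyline <- function(coords, t0, t1) {
  cl <- polyline_cumlen(coords)
  L <- cl[length(cl)]
  t0 <- min(max(t0, 0), L); t1 <- min(max(t1, 0), L)
  if (t1 <= t0) return(matrix(numeric(0), ncol = 2))
  keep <- which(cl > t0 & cl < t1)
  pts <- rbind(point_at_t(coords, t0),
               coords[keep, , drop = FALSE],
               point_at_t(coords, t1))
  unname(pts)
}

# distance of point (px, py) to segment (ax, ay)-(bx, by); vectorised over
# points. Returns list(dist, t) where t is curve position along the segment.
point_segment_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) {
    d <- sqrt((px - ax)^2 + (py - ay)^2)
    return(list(dist = d, t = rep(0, length(px))))
  }
  u <- ((px - ax) * dx + (py - ay) * dy) / len2
  u <- pmin(pmax(u, 0), 1)
  qx <- ax + u * dx; qy <- ay + u * dy
  list(dist = sqrt((px - qx)^2 + (py - qy)^2), t = u * sqrt(len2))
}

# nearest point on a polyline: returns list(dist, t) for a single point
project_onto_polyline <- function(p, coords) {
  cl <- polyline_cumlen(coords)
  best <- list(dist = Inf, t = 0)
  for (i in seq_len(nrow(coords) - 1L)) {
    r <- point_segment_dist(p[1], p[2], coords[i, 1], coords[i, 2],
                            coords[i + 1L, 1], coords[i + 1L, 2])
    if (r$dist < best$dist) best <- list(dist = r$dist, t = cl[i] + r$t)
  }
  best
}

# minimum distance from many points to a polyline (vectorised over points)
points_polyline_dist <- function(px, py, coords) {
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(coords) - 1L)) {
    r <- point_segment_dist(px, py, coords[i, 1], coords[i, 2],
                            coords[i + 1L, 1], coords[i + 1L, 2])
    d <- pmin(d, r$dist)
  }
  d
}

# merge a two-column matrix of [start, end) intervals; returns merged matrix
merge_intervals <- function(iv, eps = 1e-9) {
  iv <- iv[iv[, 2] - iv[, 1] > eps, , drop = FALSE]
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    k <- nrow(out)
    if (iv[i, 1] <= out[k, 2] + eps) {
      out[k, 2] <- max(out[k, 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
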