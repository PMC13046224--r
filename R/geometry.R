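# Small planar-geometry helpers shared by the axial and trajectory layers.
# The visibility-graph hot path lives in src/vga_core.cpp; these R versions
# serve the low-volume call sites (axial adjacency, route distances,
# layout validation).

#' Do two segments intersect or touch?
#'
#' Segments are closed: shared endpoints and T-junctions count as
#' intersections. Used for axial-line adjacency, where lines meeting at a
#' junction are connected.
#'
#' @param a1,a2 numeric length-2 endpoints of the first segment.
#' @param b1,b2 numeric length-2 endpoints of the second segment.
#' @param tol numeric tolerance in the same units as the coordinates.
#' @return logical scalar.
#' @export
segments_intersect <- function(a1, a2, b1, b2, tol = 1e-6) {
  r <- a2 - a1
  s <- b2 - b1
  denom <- r[1] * s[2] - r[2] * s[1]
  w <- b1 - a1
  if (abs(denom) > tol * max(1, sum(abs(r)), sum(abs(s)))) {
    t <- (w[1] * s[2] - w[2] * s[1]) / denom
    u <- (w[1] * r[2] - w[2] * r[1]) / denom
    lo <- -tol; hi <- 1 + tol
    return(t >= lo && t <= hi && u >= lo && u <= hi)
  }
  # parallel: touching/overlap detected via endpoint-to-segment distances
  d <- min(
    point_segment_distance(b1[1], b1[2], a1[1], a1[2], a2[1], a2[2]),
    point_segment_distance(b2[1], b2[2], a1[1], a1[2], a2[1], a2[2]),
    point_segment_distance(a1[1], a1[2], b1[1], b1[2], b2[1], b2[2]),
    point_segment_distance(a2[1], a2[2], b1[1], b1[2], b2[1], b2[2])
  )
  d <= tol
}

#' Distance from points to a segment
#'
#' Vectorised over the points.
#'
#' @param px,py point coordinates.
#' @param ax,ay,bx,by segment endpoints.
#' @return numeric vector of Euclidean distances.
#' @export
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

#' Minimum distance from points to a polyline
#'
#' @param px,py point coordinates (vectorised).
#' @param line two-column matrix of polyline vertices.
#' @return numeric vector of distances.
#' @export
point_polyline_distance <- function(px, py, line) {
  stopifnot(is.matrix(line), ncol(line) == 2, nrow(line) >= 2)
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(line) - 1)) {
    d <- pmin(d, point_segment_distance(px, py,
                                        line[k, 1], line[k, 2],
                                        line[k + 1, 1], line[k + 1, 2]))
  }
  d
}

# strict-interior test against a layout's obstacle set (C++ backend)
points_in_obstacle <- function(x, y, obstacles) {
  if (length(obstacles) == 0) return(rep(FALSE, length(x)))
  .cpp_point_in_obstacle(as.numeric(x), as.numeric(y), obstacles)
}

# ring self-intersection check (non-adjacent edge pairs)
ring_is_simple <- function(ring, tol = 1e-9) {
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  edges <- lapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    list(a = ring[i, ], b = ring[j, ])
  })
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      # skip adjacent edges (share a vertex by construction)
      if (j == i + 1L || (i == 1L && j == n)) next
      if (segments_intersect(edges[[i]]$a, edges[[i]]$b,
                             edges[[j]]$a, edges[[j]]$b, tol = tol))
        return(FALSE)
    }
  }
  TRUE
}
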