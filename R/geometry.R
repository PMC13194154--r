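#' Polygon geometry primitives
#'
#' Polygons are numeric matrices with two columns (x, y), one vertex per row.
#' Rings may be given open or closed; [close_ring()] normalizes to closed.
#' A polygon *with holes* is a list of rings: the first ring is the outer
#' boundary, subsequent rings are holes. Point-in-polygon uses the even-odd
#' rule over all rings, so holes subtract by parity. Points exactly on a ring
#' boundary count as inside; this only matters on a set of measure zero but is
#' fixed here so the patch-counting rules are fully deterministic.
#'
#' @name geometry
#' @keywords internal
NULL

#' Close a polygon ring
#'
#' Appends the first vertex at the end unless the ring is already closed.
#'
#' @param ring numeric matrix with columns x, y.
#' @return closed ring matrix.
#' @keywords internal
close_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2 || nrow(ring) < 3) {
    stop("a polygon ring must be a numeric matrix with 2 columns and >= 3 vertices")
  }
  n <- nrow(ring)
  if (!isTRUE(all.equal(ring[1, ], ring[n, ], check.attributes = FALSE))) {
    ring <- rbind(ring, ring[1, ])
  }
  unname(ring)
}

#' Shoelace area of a simple ring
#'
#' @param ring numeric matrix with columns x, y (open or closed).
#' @return unsigned area in the square of the coordinate unit.
#' @export
polygon_area <- function(ring) {
  ring <- close_ring(ring)
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# Remove consecutive duplicate vertices and re-close; the only "repair" we
# attempt before declaring a ring invalid.
dedupe_ring <- function(ring) {
  ring <- close_ring(ring)
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  close_ring(ring[keep, , drop = FALSE])
}

# Proper self-intersection test (O(E^2), rings here are small). Shared
# endpoints of adjacent edges are not intersections.
ring_self_intersects <- function(ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  if (n < 4L) return(FALSE)
  seg <- cbind(ring[1:n, , drop = FALSE], ring[2:(n + 1L), , drop = FALSE])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges share a vertex
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Validate (and minimally repair) a polygon ring
#'
#' Drops consecutive duplicate vertices, closes the ring, and rejects rings
#' that remain self-intersecting. There is no geometric re-noding: a ring a
#' pathologist's tool exported as a bow-tie is an annotation error, not
#' something to guess a fix for.
#'
#' @param ring numeric matrix with columns x, y.
#' @return closed, validated ring.
#' @keywords internal
validate_ring <- function(ring) {
  ring <- dedupe_ring(ring)
  if (nrow(ring) < 4L) stop("polygon ring has fewer than 3 distinct vertices")
  if (ring_self_intersects(ring)) {
    stop("polygon ring is self-intersecting and could not be repaired")
  }
  ring
}

# pure even-odd crossing parity for one ring (no boundary handling);
# half-open crossing rule avoids double-counting shared vertices
points_parity_ring <- function(x, y, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  inside <- logical(length(x))
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]; x2 <- ring[k + 1L, 1]; y2 <- ring[k + 1L, 2]
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside
}

#' Points-in-ring test (even-odd crossing number, boundary inclusive)
#'
#' @param x,y numeric vectors of point coordinates.
#' @param ring closed ring matrix.
#' @return logical vector: crossing parity is odd, or point lies on an edge.
#' @keywords internal
points_in_ring <- function(x, y, ring) {
  points_parity_ring(x, y, ring) | points_on_ring(x, y, ring)
}

#' Points-in-polygon test over a list of polygons (with optional holes)
#'
#' @param x,y numeric vectors of point coordinates.
#' @param polygons list of polygons; each polygon is either a ring matrix or a
#'   list of rings (outer first, holes after).
#' @return logical vector: point falls inside at least one polygon, holes
#'   subtracted by even-odd parity; boundary points count as inside.
#' @export
points_in_polygons <- function(x, y, polygons) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) return(logical(0))
  if (length(polygons) == 0L) return(logical(length(x)))
  res <- logical(length(x))
  for (poly in polygons) {
    rings <- if (is.list(poly)) poly else list(poly)
    parity <- logical(length(x))
    on_any <- logical(length(x))
    for (ring in rings) {
      ring <- close_ring(ring)
      # pure parity so holes subtract correctly; boundary points (of any
      # ring, outer or hole) are forced inside afterwards
      parity <- xor(parity, points_parity_ring(x, y, ring))
      on_any <- on_any | points_on_ring(x, y, ring)
    }
    res <- res | parity | on_any
  }
  res
}

# boundary-only test, shared by points_in_polygons
points_on_ring <- function(x, y, ring) {
  ring <- close_ring(ring)
  n <- nrow(ring) - 1L
  on_edge <- logical(length(x))
  for (k in seq_len(n)) {
    x1 <- ring[k, 1]; y1 <- ring[k, 2]; x2 <- ring[k + 1L, 1]; y2 <- ring[k + 1L, 2]
    d <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    tol <- 1e-9 * max(1, abs(x1), abs(x2), abs(y1), abs(y2))
    on_edge <- on_edge | (abs(d) <= tol &
      x >= pmin(x1, x2) - tol & x <= pmax(x1, x2) + tol &
      y >= pmin(y1, y2) - tol & y <= pmax(y1, y2) + tol)
  }
  on_edge
}

#' Rounded-rectangle ring
#'
#' @param x0,y0 lower-left corner.
#' @param width,height side lengths (same unit as the corner).
#' @param radius corner radius; clamped to half the shorter side.
#' @param n_arc vertices per corner arc.
#' @return closed ring matrix.
#' @export
rounded_rect <- function(x0, y0, width, height, radius = min(width, height) / 8,
                         n_arc = 16L) {
  stopifnot(width > 0, height > 0, radius >= 0)
  radius <- min(radius, width / 2, height / 2)
  if (radius == 0) {
    return(close_ring(rbind(
      c(x0, y0), c(x0 + width, y0),
      c(x0 + width, y0 + height), c(x0, y0 + height)
    )))
  }
  corner <- function(cx, cy, from, to) {
    th <- seq(from, to, length.out = n_arc)
    cbind(cx + radius * cos(th), cy + radius * sin(th))
  }
  ring <- rbind(
    corner(x0 + width - radius, y0 + radius, -pi / 2, 0),
    corner(x0 + width - radius, y0 + height - radius, 0, pi / 2),
    corner(x0 + radius, y0 + height - radius, pi / 2, pi),
    corner(x0 + radius, y0 + radius, pi, 3 * pi / 2)
  )
  close_ring(ring)
}

#' Regular-polygon approximation of a circle
#'
#' @param cx,cy center.
#' @param r radius.
#' @param n number of vertices.
#' @return closed ring matrix.
#' @export
circle_ring <- function(cx, cy, r, n = 32L) {
  stopifnot(r > 0, n >= 3)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  close_ring(cbind(cx + r * cos(th), cy + r * sin(th)))
}

# bounding box over a list of polygons (rings or ring-lists); outer rings only
polygons_bbox <- function(polygons) {
  outers <- lapply(polygons, function(p) if (is.list(p)) p[[1]] else p)
  all_xy <- do.call(rbind, lapply(outers, close_ring))
  c(
    xmin = min(all_xy[, 1]), ymin = min(all_xy[, 2]),
    xmax = max(all_xy[, 1]), ymax = max(all_xy[, 2])
  )
}
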