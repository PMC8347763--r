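#' Construct a plot boundary polygon
#'
#' A `plot_polygon` is a named polygon in the rasters' planar coordinates,
#' stored as one or more rings (n x 2 matrices of x, y vertices, open —
#' the closing vertex is implicit). Membership follows the even-odd rule,
#' so interior rings act as holes (e.g. a road strip crossing a plot) and
#' several disjoint outer rings represent a plot split into sections.
#' Outer rings are stored counter-clockwise, holes clockwise; signed ring
#' areas then add up to the plot area.
#'
#' @param name plot identifier.
#' @param rings a single n x 2 matrix or a list of them; ring 1 is the
#'   outer boundary, additional rings are holes unless `orient = FALSE`.
#' @param orient if TRUE (default) rings are re-oriented (ring 1 CCW,
#'   others CW). Pass FALSE when ring orientations already encode
#'   outer/hole roles (used for multi-part plots).
#' @return object of class `plot_polygon`.
#' @export
plot_polygon <- function(name, rings, orient = TRUE) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- close_open_ring(as.matrix(r))
    if (nrow(r) < 3L) stop("a polygon ring needs at least 3 vertices", call. = FALSE)
    r
  })
  if (orient)
    rings <- lapply(seq_along(rings), function(i) orient_ring(rings[[i]], hole = i > 1L))
  for (r in rings)
    if (ring_self_intersects(r))
      stop(sprintf("invalid geometry in plot '%s': ring is self-intersecting", name),
           call. = FALSE)
  structure(list(name = as.character(name), rings = rings), class = "plot_polygon")
}

#' Axis-aligned rectangle as a plot polygon
#' @param name plot identifier.
#' @param xmin,xmax,ymin,ymax rectangle bounds, meters.
#' @return [plot_polygon].
#' @export
rect_polygon <- function(name, xmin, xmax, ymin, ymax) {
  plot_polygon(name, cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax)))
}

#' @export
print.plot_polygon <- function(x, ...) {
  cat(sprintf("<plot_polygon> '%s': %d ring(s), area %.1f m^2\n",
              x$name, length(x$rings), polygon_area(x)))
  invisible(x)
}

# drop an explicit closing vertex if present
close_open_ring <- function(ring) {
  if (nrow(ring) > 1L && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  ring
}

ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

orient_ring <- function(ring, hole = FALSE) {
  a <- ring_signed_area(ring)
  want_ccw <- !hole
  if ((a > 0) != want_ccw) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
  ring
}

# proper-crossing test between non-adjacent edges of one ring (bow-tie check)
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4L) return(FALSE)
  seg <- cbind(ring, rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE]))
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Polygon area (holes subtracted)
#' @param p a [plot_polygon].
#' @return area in m^2.
#' @export
polygon_area <- function(p) {
  sum(vapply(p$rings, ring_signed_area, numeric(1)))
}

#' Polygon bounding box
#' @param p a [plot_polygon].
#' @return named vector xmin, xmax, ymin, ymax.
#' @export
polygon_bbox <- function(p) {
  xy <- do.call(rbind, p$rings)
  c(xmin = min(xy[, 1]), xmax = max(xy[, 1]), ymin = min(xy[, 2]), ymax = max(xy[, 2]))
}

#' Even-odd point-in-polygon test
#' @param p a [plot_polygon].
#' @param x,y coordinate vectors of equal length.
#' @return logical vector.
#' @export
points_in_polygon <- function(p, x, y) {
  inside <- rep(FALSE, length(x))
  for (ring in p$rings) {
    rx <- ring[, 1]; ry <- ring[, 2]
    n <- nrow(ring)
    j <- n
    for (i in seq_len(n)) {
      yi <- ry[i]; yj <- ry[j]; xi <- rx[i]; xj <- rx[j]
      crosses <- ((yi > y) != (yj > y)) &
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
      j <- i
    }
  }
  inside
}

#' Translate a polygon
#' @param p a [plot_polygon].
#' @param dx,dy shift in meters.
#' @return shifted [plot_polygon].
#' @export
translate_polygon <- function(p, dx, dy = 0) {
  p$rings <- lapply(p$rings, function(r) cbind(r[, 1] + dx, r[, 2] + dy))
  p
}

# Sutherland-Hodgman clip of one ring by an axis-aligned rectangle.
# Orientation (and hence signed area) is preserved, so clipping every ring
# and summing signed areas gives the exact polygon/rectangle intersection
# area, holes included.
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  clip_edge <- function(pts, keep, isect) {
    n <- nrow(pts)
    if (n == 0L) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    prev <- pts[n, ]
    prev_in <- keep(prev)
    for (i in seq_len(n)) {
      cur <- pts[i, ]
      cur_in <- keep(cur)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, isect(prev, cur))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, isect(prev, cur))
      }
      prev <- cur; prev_in <- cur_in
    }
    out
  }
  ix <- function(a, b, x) { t <- (x - a[1]) / (b[1] - a[1]); c(x, a[2] + t * (b[2] - a[2])) }
  iy <- function(a, b, y) { t <- (y - a[2]) / (b[2] - a[2]); c(a[1] + t * (b[1] - a[1]), y) }
  r <- ring
  r <- clip_edge(r, function(p) p[1] >= xmin, function(a, b) ix(a, b, xmin))
  r <- clip_edge(r, function(p) p[1] <= xmax, function(a, b) ix(a, b, xmax))
  r <- clip_edge(r, function(p) p[2] >= ymin, function(a, b) iy(a, b, ymin))
  r <- clip_edge(r, function(p) p[2] <= ymax, function(a, b) iy(a, b, ymax))
  r
}

#' Exact intersection area of a polygon with an axis-aligned rectangle
#' @param p a [plot_polygon].
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return area in m^2 (>= 0).
#' @export
polygon_rect_intersection_area <- function(p, xmin, xmax, ymin, ymax) {
  a <- 0
  for (ring in p$rings) {
    cl <- clip_ring_rect(ring, xmin, xmax, ymin, ymax)
    if (nrow(cl) >= 3L) a <- a + ring_signed_area(cl)
  }
  max(a, 0)
}
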