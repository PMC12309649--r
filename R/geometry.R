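# Planar geometry primitives for the equal-area analysis frame.
#
# Polygons are rings: n x 2 coordinate matrices, vertices in order, not
# repeated at the close. A geometry is a list of rings whose interiors are
# treated as a union (no holes; site boundaries do not need them). All
# computations are planar and in km / km^2, which is exact for the
# equal-area frame the analysis runs in.

as_ring <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 2) stop("a ring needs two coordinate columns", call. = FALSE)
  n <- nrow(m)
  # drop an explicitly closed last vertex
  if (n > 1 && isTRUE(all(m[1, ] == m[n, ]))) m <- m[-n, , drop = FALSE]
  storage.mode(m) <- "double"
  unname(m)
}

#' Signed area of a ring (shoelace formula)
#'
#' Positive for counter-clockwise vertex order. For a self-intersecting ring
#' the shoelace value is the signed sum of its lobes, not the enclosed area.
#'
#' @param ring An n x 2 vertex matrix.
#' @export
ring_area <- function(ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  if (n < 3) return(0)
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a geometry (list of disjoint rings), km^2
#' @param rings A ring matrix or a list of ring matrices.
#' @export
polygon_area <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  sum(vapply(rings, function(r) abs(ring_area(r)), numeric(1)))
}

# Even-odd point-in-ring test, vectorised over points. The strict
# inequalities give consistent half-open boundary behaviour: a point on a
# shared edge of two abutting polygons is counted inside exactly one of
# them, which is what makes split-invariance of overlap areas exact.
points_in_ring <- function(px, py, ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  inside <- logical(length(px))
  if (n < 3) return(inside)
  xj <- ring[n, 1]; yj <- ring[n, 2]
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

#' Which points fall inside a geometry?
#'
#' Union semantics across rings: a point is inside if it is inside any ring.
#'
#' @param pts Two-column matrix of point coordinates.
#' @param rings A ring matrix or list of ring matrices.
#' @return Logical vector, one element per point.
#' @export
points_in_polygon <- function(pts, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(length(px))
  for (r in rings) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- points_in_ring(px[todo], py[todo], r)
  }
  inside
}

# Orientation of the triangle (a, b, c): > 0 counter-clockwise.
orient2 <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

# Proper-crossing test for two segments p1-p2 and q1-q2 (shared endpoints
# and collinear touching excluded); returns the intersection point or NULL.
segment_crossing <- function(p1, p2, q1, q2) {
  d1 <- orient2(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- orient2(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- orient2(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- orient2(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    t <- d1 / (d1 - d2)
    return(p1 + t * (p2 - p1))
  }
  NULL
}

# Does segment p1-p2 touch or cross q1-q2 anywhere (incl. collinear overlap)?
segments_touch <- function(p1, p2, q1, q2) {
  d1 <- orient2(q1[1], q1[2], q2[1], q2[2], p1[1], p1[2])
  d2 <- orient2(q1[1], q1[2], q2[1], q2[2], p2[1], p2[2])
  d3 <- orient2(p1[1], p1[2], p2[1], p2[2], q1[1], q1[2])
  d4 <- orient2(p1[1], p1[2], p2[1], p2[2], q2[1], q2[2])
  if (((d1 > 0) != (d2 > 0) || d1 == 0 || d2 == 0) &&
      ((d3 > 0) != (d4 > 0) || d3 == 0 || d4 == 0)) {
    on_seg <- function(d, a, b, c) {
      d == 0 &&
        min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
        min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
    }
    if (d1 == 0 || d2 == 0 || d3 == 0 || d4 == 0) {
      return(on_seg(d1, q1, q2, p1) || on_seg(d2, q1, q2, p2) ||
               on_seg(d3, p1, p2, q1) || on_seg(d4, p1, p2, q2))
    }
    return(TRUE)
  }
  FALSE
}

# All proper self-crossings of a ring between non-adjacent edges.
# Returns a list of list(i, j, pt).
ring_self_crossings <- function(ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  if (n < 4) return(list())
  nxt <- c(seq_len(n)[-1], 1L)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (j == i + 1L || (i == 1L && j == n)) next  # adjacent edges
      pt <- segment_crossing(ring[i, ], ring[nxt[i], ],
                             ring[j, ], ring[nxt[j], ])
      if (!is.null(pt)) out[[length(out) + 1L]] <- list(i = i, j = j, pt = pt)
    }
  }
  out
}

#' Is a ring a simple, usable polygon boundary?
#'
#' OGC-style validity for a single ring: at least three distinct finite
#' vertices, non-zero area, and no self-intersection (proper crossings and
#' non-adjacent touching both disqualify).
#'
#' @param ring An n x 2 vertex matrix.
#' @export
ring_is_valid <- function(ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  if (n < 3 || !all(is.finite(ring))) return(FALSE)
  if (anyDuplicated(ring)) return(FALSE)
  if (abs(ring_area(ring)) <= 0) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_touch(ring[i, ], ring[nxt[i], ],
                         ring[j, ], ring[nxt[j], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Exact area of the union of rings (dissolved area), km^2
#'
#' Vertical slab sweep: the x axis is cut at every vertex and every pairwise
#' edge crossing, so within a slab edges are non-crossing straight lines and
#' the union is a stack of trapezoids found by even-odd parity per ring.
#' Exact up to floating point; no rasterisation involved.
#'
#' @param rings A ring matrix or list of simple ring matrices.
#' @export
union_area <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, as_ring)
  rings <- rings[vapply(rings, nrow, 1L) >= 3]
  if (!length(rings)) return(0)

  # edge table: x1 y1 x2 y2 ring_id
  ed <- do.call(rbind, lapply(seq_along(rings), function(k) {
    r <- rings[[k]]
    n <- nrow(r)
    nxt <- c(seq_len(n)[-1], 1L)
    cbind(r[, 1], r[, 2], r[nxt, 1], r[nxt, 2], k)
  }))
  # breakpoints: vertices plus crossings between edges of different rings
  xs <- c(ed[, 1], ed[, 3])
  ne <- nrow(ed)
  for (i in seq_len(ne - 1L)) {
    for (j in seq.int(i + 1L, ne)) {
      if (ed[i, 5] == ed[j, 5]) next  # rings assumed simple
      pt <- segment_crossing(ed[i, 1:2], ed[i, 3:4], ed[j, 1:2], ed[j, 3:4])
      if (!is.null(pt)) xs <- c(xs, pt[1])
    }
  }
  xs <- sort(unique(xs))
  if (length(xs) < 2) return(0)

  exmin <- pmin(ed[, 1], ed[, 3])
  exmax <- pmax(ed[, 1], ed[, 3])
  total <- 0
  nring <- length(rings)
  for (s in seq_len(length(xs) - 1L)) {
    xlo <- xs[s]; xhi <- xs[s + 1L]
    w <- xhi - xlo
    if (w <= 0) next
    xm <- (xlo + xhi) / 2
    act <- which(exmin <= xlo & exmax >= xhi & exmin < exmax)
    if (length(act) < 2) next
    t <- (xm - ed[act, 1]) / (ed[act, 3] - ed[act, 1])
    ym <- ed[act, 2] + t * (ed[act, 4] - ed[act, 2])
    o <- order(ym)
    ym <- ym[o]
    rid <- ed[act[o], 5]
    parity <- logical(nring)
    for (k in seq_len(length(act) - 1L)) {
      parity[rid[k]] <- !parity[rid[k]]
      if (any(parity)) total <- total + w * (ym[k + 1L] - ym[k])
    }
  }
  total
}

#' Axis-aligned rectangle ring
#'
#' @param x1,y1,x2,y2 Opposite corners in km.
#' @return A 4 x 2 ring matrix (counter-clockwise).
#' @export
rect_ring <- function(x1, y1, x2, y2) {
  xs <- sort(c(x1, x2)); ys <- sort(c(y1, y2))
  cbind(c(xs[1], xs[2], xs[2], xs[1]), c(ys[1], ys[1], ys[2], ys[2]))
}

bbox_of <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  m <- do.call(rbind, rings)
  c(xmin = min(m[, 1]), ymin = min(m[, 2]),
    xmax = max(m[, 1]), ymax = max(m[, 2]))
}
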