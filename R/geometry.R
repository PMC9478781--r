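# Planar polygon engine.
#
# All pipeline geometries are simple polygons in Cartesian coordinates
# (abstract length units for synthetic data). A polygon is a list of rings;
# the first ring is the outer boundary, any further rings are holes. Rings
# are stored "open" (the closing vertex is implicit). A multipolygon is a
# collection of member polygons; the pipeline only ever builds multipolygons
# whose members are pairwise interior-disjoint (tessellation pieces), and the
# exact union area is cached at construction so later area queries are O(1).

#' Construct a polygon
#'
#' @param outer Two-column numeric matrix of outer-ring vertices, in order.
#'   A repeated closing vertex is tolerated and dropped.
#' @param holes Optional list of hole rings (same format).
#' @param id Optional identifier used in error messages.
#' @param validate Check ring validity (closure, >= 3 vertices,
#'   non-self-intersection, positive area). Default `TRUE`.
#' @return An object of class `trr_polygon`.
#' @export
trr_polygon <- function(outer, holes = list(), id = NULL, validate = TRUE) {
  rings <- lapply(c(list(outer), holes), normalize_ring)
  p <- structure(list(rings = rings, id = id), class = "trr_polygon")
  if (validate) validate_polygon(p)
  p
}

#' Construct a multipolygon from member polygons
#'
#' Members are expected to be pairwise interior-disjoint (the invariant all
#' pipeline products satisfy); the exact union area is computed and cached.
#' Overlapping members are accepted -- the cached area is still the exact
#' union area -- but such objects are flagged and refuse piecewise
#' intersection queries.
#'
#' @param polys List of `trr_polygon` objects.
#' @param id Optional identifier.
#' @return An object of class `trr_multipolygon`.
#' @export
trr_multipolygon <- function(polys, id = NULL) {
  stopifnot(length(polys) > 0)
  if (inherits(polys, "trr_polygon")) polys <- list(polys)
  lapply(polys, function(p) {
    if (!inherits(p, "trr_polygon")) stop("members must be trr_polygon objects")
  })
  sum_area <- sum(vapply(polys, geo_area, numeric(1)))
  if (length(polys) == 1L) {
    uarea <- sum_area
  } else {
    uarea <- union_area(polys)
  }
  overlapping <- (sum_area - uarea) > 1e-9 * max(sum_area, 1)
  structure(list(polys = polys, id = id, area = uarea,
                 overlapping = overlapping),
            class = "trr_multipolygon")
}

# Drop a repeated closing vertex and check shape.
normalize_ring <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || ncol(m) != 2) stop("ring must be a numeric n x 2 matrix")
  n <- nrow(m)
  if (n >= 2 && all(m[1, ] == m[n, ])) m <- m[-n, , drop = FALSE]
  m
}

#' @export
print.trr_polygon <- function(x, ...) {
  cat(sprintf("<polygon%s: %d ring(s), area %.6g>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$rings), geo_area(x)))
  invisible(x)
}

#' @export
print.trr_multipolygon <- function(x, ...) {
  cat(sprintf("<multipolygon%s: %d member(s), area %.6g>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              length(x$polys), x$area))
  invisible(x)
}

# Signed shoelace area of an open ring (positive when counter-clockwise).
ring_signed_area <- function(m) {
  x <- m[, 1]; y <- m[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Validity: >= 3 vertices, no repeated consecutive vertices, no
# self-intersection, strictly positive ring area.
validate_polygon <- function(p, id = NULL) {
  id <- id %||% p$id %||% "<unnamed>"
  for (m in p$rings) {
    if (!all(is.finite(m))) stop(sprintf("polygon %s: non-finite coordinates", id))
    if (nrow(m) < 3) stop(sprintf("polygon %s: ring with fewer than 3 vertices", id))
    if (ring_self_intersects(m))
      stop(sprintf("polygon %s: self-intersecting ring", id))
    if (abs(ring_signed_area(m)) <= 0)
      stop(sprintf("polygon %s: degenerate (zero-area) ring", id))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Proper-crossing test between non-adjacent edges (shared endpoints allowed).
ring_self_intersects <- function(m) {
  n <- nrow(m)
  if (n < 4) return(FALSE)
  a <- m; b <- m[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]   # edge n is adjacent to edge 1
    if (!length(js)) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                           b[js, , drop = FALSE]))) return(TRUE)
  }
  FALSE
}

# Vectorised proper-intersection test of segment (p,q) against segments
# (r[i,], s[i,]). Touching at endpoints does not count.
segments_cross <- function(p, q, r, s) {
  d1 <- (q[1] - p[1]) * (r[, 2] - p[2]) - (q[2] - p[2]) * (r[, 1] - p[1])
  d2 <- (q[1] - p[1]) * (s[, 2] - p[2]) - (q[2] - p[2]) * (s[, 1] - p[1])
  d3 <- (s[, 1] - r[, 1]) * (p[2] - r[, 2]) - (s[, 2] - r[, 2]) * (p[1] - r[, 1])
  d4 <- (s[, 1] - r[, 1]) * (q[2] - r[, 2]) - (s[, 2] - r[, 2]) * (q[1] - r[, 1])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Polygon or multipolygon area
#'
#' Planar (shoelace) area; holes are subtracted. For multipolygons the cached
#' exact union area is returned, so overlapping members are not double
#' counted.
#'
#' @param g A `trr_polygon` or `trr_multipolygon`.
#' @return Non-negative scalar area.
#' @export
geo_area <- function(g) {
  if (inherits(g, "trr_multipolygon")) return(g$area)
  if (!inherits(g, "trr_polygon")) stop("not a geometry object")
  a <- abs(ring_signed_area(g$rings[[1]]))
  if (length(g$rings) > 1) {
    for (h in g$rings[-1]) a <- a - abs(ring_signed_area(h))
  }
  max(a, 0)
}

# ---- convex decomposition -------------------------------------------------

is_convex_ring <- function(m) {
  n <- nrow(m)
  nx <- c(2:n, 1); nnx <- c(3:n, 1, 2)
  cr <- (m[nx, 1] - m[, 1]) * (m[nnx, 2] - m[nx, 2]) -
        (m[nx, 2] - m[, 2]) * (m[nnx, 1] - m[nx, 1])
  all(cr >= 0) || all(cr <= 0)
}

orient_ccw <- function(m) if (ring_signed_area(m) < 0) m[nrow(m):1, , drop = FALSE] else m

# Ear-clipping triangulation of a simple CCW ring. O(n^2); rings here are
# small. Returns a list of 3x2 matrices.
triangulate_ring <- function(m) {
  m <- orient_ccw(m)
  n <- nrow(m)
  if (n == 3) return(list(m))
  idx <- seq_len(n)
  tris <- vector("list", n - 2)
  k <- 0
  guard <- 0
  while (length(idx) > 3) {
    n_cur <- length(idx)
    found <- FALSE
    for (ii in seq_len(n_cur)) {
      i0 <- idx[if (ii == 1) n_cur else ii - 1]
      i1 <- idx[ii]
      i2 <- idx[if (ii == n_cur) 1 else ii + 1]
      a <- m[i0, ]; b <- m[i1, ]; c <- m[i2, ]
      cr <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
      if (cr <= 1e-14 * max(abs(m))^2) next       # reflex or degenerate corner
      others <- setdiff(idx, c(i0, i1, i2))
      if (length(others) && any(point_in_triangle(m[others, , drop = FALSE], a, b, c)))
        next
      k <- k + 1
      tris[[k]] <- rbind(a, b, c)
      idx <- idx[idx != i1]
      found <- TRUE
      break
    }
    guard <- guard + 1
    if (!found || guard > 10 * n)
      stop("triangulation failed; is the ring simple?")
  }
  k <- k + 1
  tris[[k]] <- m[idx, , drop = FALSE]
  tris[seq_len(k)]
}

point_in_triangle <- function(pts, a, b, c) {
  s1 <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
  s2 <- (c[1] - b[1]) * (pts[, 2] - b[2]) - (c[2] - b[2]) * (pts[, 1] - b[1])
  s3 <- (a[1] - c[1]) * (pts[, 2] - c[2]) - (a[2] - c[2]) * (pts[, 1] - c[1])
  (s1 > 0 & s2 > 0 & s3 > 0) | (s1 < 0 & s2 < 0 & s3 < 0)
}

# Decompose a polygon into signed convex pieces: the outer ring contributes
# +1 pieces, each hole -1 pieces. A convex ring is kept whole.
convex_pieces <- function(p) {
  if (inherits(p, "trr_multipolygon")) {
    if (isTRUE(p$overlapping))
      stop("piecewise operations require interior-disjoint multipolygon members")
    return(do.call(c, lapply(p$polys, convex_pieces)))
  }
  out <- list()
  for (i in seq_along(p$rings)) {
    ring <- p$rings[[i]]
    sgn <- if (i == 1) 1 else -1
    if (is_convex_ring(ring)) {
      out[[length(out) + 1L]] <- list(coords = orient_ccw(ring), sign = sgn)
    } else {
      for (tr in triangulate_ring(ring))
        out[[length(out) + 1L]] <- list(coords = tr, sign = sgn)
    }
  }
  out
}

# ---- convex clipping ------------------------------------------------------

# Sutherland-Hodgman: clip polygon `subject` (any simple CCW ring) against a
# convex CCW `clipper`. Returns a matrix (possibly with < 3 rows when the
# intersection is empty/degenerate).
convex_clip <- function(subject, clipper) {
  out <- subject
  nc <- nrow(clipper)
  for (i in seq_len(nc)) {
    if (nrow(out) < 3) return(out[0, , drop = FALSE])
    p <- clipper[i, ]
    q <- clipper[if (i == nc) 1 else i + 1, ]
    out <- clip_halfplane(out, p, q)
  }
  out
}

# Keep the part of ring `pts` on the left of directed line p->q.
clip_halfplane <- function(pts, p, q) {
  n <- nrow(pts)
  s <- (q[1] - p[1]) * (pts[, 2] - p[2]) - (q[2] - p[2]) * (pts[, 1] - p[1])
  eps <- 1e-12 * max(1, max(abs(pts)))^2
  inside <- s >= -eps
  if (all(inside)) return(pts)
  if (!any(inside)) return(pts[0, , drop = FALSE])
  nxt <- c(2:n, 1)
  res <- matrix(0, 2 * n, 2)
  k <- 0
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (inside[i]) { k <- k + 1; res[k, ] <- pts[i, ] }
    if (xor(inside[i], inside[j])) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1
      res[k, ] <- pts[i, ] + t * (pts[j, ] - pts[i, ])
    }
  }
  res[seq_len(k), , drop = FALSE]
}

piece_area <- function(m) if (nrow(m) < 3) 0 else abs(ring_signed_area(m))

bbox_of <- function(m) c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2]))

bboxes_disjoint <- function(a, b) {
  a[3] <= b[1] || b[3] <= a[1] || a[4] <= b[2] || b[4] <= a[2]
}

#' Area of intersection of two geometries
#'
#' Both arguments may be polygons or (interior-disjoint) multipolygons. The
#' geometries are decomposed into signed convex pieces and every piece pair
#' is clipped (Sutherland-Hodgman); signed piece-pair areas sum to the exact
#' intersection area, holes included.
#'
#' @param a,b Geometries.
#' @return Non-negative scalar area.
#' @export
geo_intersection_area <- function(a, b) {
  pa <- convex_pieces(a)
  pb <- convex_pieces(b)
  bxa <- lapply(pa, function(p) bbox_of(p$coords))
  bxb <- lapply(pb, function(p) bbox_of(p$coords))
  tot <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (bboxes_disjoint(bxa[[i]], bxb[[j]])) next
      clp <- convex_clip(pa[[i]]$coords, pb[[j]]$coords)
      tot <- tot + pa[[i]]$sign * pb[[j]]$sign * piece_area(clp)
    }
  }
  max(tot, 0)
}

#' Area of the symmetric difference of two geometries
#'
#' `area(a) + area(b) - 2 * intersection_area(a, b)`, with the intersection
#' computed geometrically. Identical inputs give 0.
#'
#' @param a,b Geometries.
#' @return Non-negative scalar area.
#' @export
geo_symmetric_difference_area <- function(a, b) {
  max(geo_area(a) + geo_area(b) - 2 * geo_intersection_area(a, b), 0)
}

#' Dissolve (union) a set of polygons
#'
#' Returns a multipolygon whose area is the exact union area of the inputs.
#' For interior-disjoint inputs -- the pipeline case, where referral regions
#' tessellate the study region -- the union area equals the sum of input
#' areas.
#'
#' @param polys Non-empty list of `trr_polygon` objects.
#' @param id Optional identifier for the result.
#' @return A `trr_multipolygon`.
#' @export
geo_dissolve <- function(polys, id = NULL) {
  if (inherits(polys, "trr_polygon")) polys <- list(polys)
  if (!length(polys)) stop("cannot dissolve an empty set of polygons")
  trr_multipolygon(polys, id = id)
}

# ---- exact union area via vertical slab decomposition ---------------------

# Exact area of the union of simple hole-free polygons. The x-axis is cut at
# every vertex x and every pairwise edge-crossing x; inside one slab no two
# edges cross and no edge begins or ends, so each polygon's cross-section is
# a y-interval with linear endpoints and the union length at the slab
# midpoint times the slab width integrates the union exactly.
union_area <- function(polys) {
  pieces <- list()
  for (p in polys) {
    if (inherits(p, "trr_multipolygon")) {
      for (q in p$polys) pieces <- c(pieces, list(q))
    } else pieces <- c(pieces, list(p))
  }
  rings <- lapply(pieces, function(p) {
    if (length(p$rings) > 1) stop("union_area supports hole-free polygons only")
    p$rings[[1]]
  })
  edges <- do.call(rbind, lapply(seq_along(rings), function(i) {
    m <- rings[[i]]; n <- nrow(m)
    cbind(m[, 1], m[, 2], m[c(2:n, 1), 1], m[c(2:n, 1), 2], i)
  }))
  xs <- c(edges[, 1], edges[, 3])
  xs <- c(xs, edge_crossing_xs(edges))
  xs <- sort(unique(xs))
  if (length(xs) < 2) return(0)
  total <- 0
  ring_bb <- lapply(rings, bbox_of)
  for (s in seq_len(length(xs) - 1)) {
    x0 <- xs[s]; x1 <- xs[s + 1]
    if (x1 - x0 <= 0) next
    xm <- (x0 + x1) / 2
    ivals <- NULL
    for (i in seq_along(rings)) {
      bb <- ring_bb[[i]]
      if (bb[1] >= x1 || bb[3] <= x0) next
      iv <- ring_y_interval(rings[[i]], xm)
      if (!is.null(iv)) ivals <- rbind(ivals, iv)
    }
    if (is.null(ivals)) next
    total <- total + (x1 - x0) * merged_length(ivals)
  }
  total
}

# x-coordinates of proper crossings between edges of different rings.
edge_crossing_xs <- function(edges) {
  ne <- nrow(edges)
  if (ne < 2) return(numeric(0))
  out <- numeric(0)
  for (i in seq_len(ne - 1)) {
    j <- (i + 1):ne
    e <- edges[i, ]
    f <- edges[j, , drop = FALSE]
    rx <- e[3] - e[1]; ry <- e[4] - e[2]
    sx <- f[, 3] - f[, 1]; sy <- f[, 4] - f[, 2]
    den <- rx * sy - ry * sx
    ok <- abs(den) > 1e-14
    if (!any(ok)) next
    qpx <- f[, 1] - e[1]; qpy <- f[, 2] - e[2]
    t <- (qpx * sy - qpy * sx) / den
    u <- (qpx * ry - qpy * rx) / den
    hit <- ok & t > 0 & t < 1 & u > 0 & u < 1
    if (any(hit)) out <- c(out, e[1] + t[hit] * rx)
  }
  out
}

# The y cross-section of a simple ring at x = xm. For the rings used here
# (convex or star-shaped slab pieces) the section is one interval; for a
# general simple ring the section may be several intervals -- return them all
# as a matrix, one row per interval.
ring_y_interval <- function(m, xm) {
  n <- nrow(m)
  x1 <- m[, 1]; y1 <- m[, 2]
  x2 <- m[c(2:n, 1), 1]; y2 <- m[c(2:n, 1), 2]
  lo <- pmin(x1, x2); hi <- pmax(x1, x2)
  sel <- lo < xm & hi > xm
  if (!any(sel)) return(NULL)
  t <- (xm - x1[sel]) / (x2[sel] - x1[sel])
  ys <- sort(y1[sel] + t * (y2[sel] - y1[sel]))
  k <- length(ys)
  if (k %% 2 != 0) return(matrix(c(min(ys), max(ys)), 1))  # numeric guard
  matrix(ys, ncol = 2, byrow = TRUE)
}

merged_length <- function(ivals) {
  o <- order(ivals[, 1])
  a <- ivals[o, 1]; b <- ivals[o, 2]
  tot <- 0; cur_a <- a[1]; cur_b <- b[1]
  for (i in seq_along(a)[-1]) {
    if (a[i] <= cur_b) {
      cur_b <- max(cur_b, b[i])
    } else {
      tot <- tot + (cur_b - cur_a)
      cur_a <- a[i]; cur_b <- b[i]
    }
  }
  tot + (cur_b - cur_a)
}

# ---- points ---------------------------------------------------------------

#' Distance between two points
#'
#' Euclidean distance in planar mode; great-circle (haversine) distance in
#' statute miles when `lonlat = TRUE` and coordinates are (longitude,
#' latitude) degrees.
#'
#' @param a,b Numeric length-2 vectors.
#' @param lonlat Interpret coordinates as lon/lat degrees.
#' @return Non-negative scalar distance.
#' @export
geo_distance <- function(a, b, lonlat = FALSE) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite point coordinates")
  if (lonlat) {
    geosphere::distHaversine(a, b) / 1609.344
  } else {
    sqrt(sum((a - b)^2))
  }
}

#' Polygon centroid
#'
#' Area-weighted centroid of the outer ring minus holes.
#'
#' @param p A `trr_polygon` or `trr_multipolygon`.
#' @return Numeric length-2 vector.
#' @export
geo_centroid <- function(p) {
  if (inherits(p, "trr_multipolygon")) {
    cs <- t(vapply(p$polys, geo_centroid, numeric(2)))
    w <- vapply(p$polys, geo_area, numeric(1))
    return(colSums(cs * w) / sum(w))
  }
  num <- c(0, 0); den <- 0
  for (i in seq_along(p$rings)) {
    m <- p$rings[[i]]
    sa <- ring_signed_area(m)
    n <- nrow(m)
    xn <- m[c(2:n, 1), 1]; yn <- m[c(2:n, 1), 2]
    cx <- sum((m[, 1] + xn) * (m[, 1] * yn - xn * m[, 2])) / 6
    cy <- sum((m[, 2] + yn) * (m[, 1] * yn - xn * m[, 2])) / 6
    sgn <- if (i == 1) 1 else -1
    # (cx, cy) integrates to signed-area * centroid; correct for ring
    # orientation, then subtract holes
    num <- num + sgn * sign(sa) * c(cx, cy)
    den <- den + sgn * abs(sa)
  }
  num / den
}

# Rectangle helper used across the package and its tests.
rect_poly <- function(x0, y0, x1, y1, id = NULL) {
  trr_polygon(rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1)),
              id = id, validate = FALSE)
}
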