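# Independent oracles used across the suite. These deliberately avoid the
# package's own geometry code paths.

# Even-odd ray-casting point-in-polygon over the rings of a polygon (holes
# flip parity) or the members of a multipolygon.
oracle_pip <- function(px, py, geom) {
  rings <- if (inherits(geom, "trr_multipolygon")) {
    unlist(lapply(geom$polys, function(p) p$rings), recursive = FALSE)
  } else geom$rings
  inside <- rep(FALSE, length(px))
  for (m in rings) {
    n <- nrow(m)
    x1 <- m[, 1]; y1 <- m[, 2]
    x2 <- m[c(2:n, 1), 1]; y2 <- m[c(2:n, 1), 2]
    cross <- rep(FALSE, length(px))
    for (e in seq_len(n)) {
      hit <- ((y1[e] > py) != (y2[e] > py)) &
        (px < x1[e] + (py - y1[e]) / (y2[e] - y1[e]) * (x2[e] - x1[e]))
      cross <- xor(cross, hit)
    }
    inside <- xor(inside, cross)
  }
  inside
}

# Monte-Carlo area estimate by uniform sampling over the bounding box.
oracle_mc_area <- function(geom, n = 1e6, seed = 42) {
  rings <- if (inherits(geom, "trr_multipolygon")) {
    unlist(lapply(geom$polys, function(p) p$rings), recursive = FALSE)
  } else geom$rings
  all_xy <- do.call(rbind, rings)
  x0 <- min(all_xy[, 1]); x1 <- max(all_xy[, 1])
  y0 <- min(all_xy[, 2]); y1 <- max(all_xy[, 2])
  set.seed(seed)
  px <- runif(n, x0, x1); py <- runif(n, y0, y1)
  mean(oracle_pip(px, py, geom)) * (x1 - x0) * (y1 - y0)
}

# Monte-Carlo area of a union of geometries (inside any member).
oracle_mc_union_area <- function(geoms, n = 1e6, seed = 42) {
  all_xy <- do.call(rbind, unlist(lapply(geoms, function(g) {
    if (inherits(g, "trr_multipolygon"))
      unlist(lapply(g$polys, function(p) p$rings), recursive = FALSE)
    else g$rings
  }), recursive = FALSE))
  x0 <- min(all_xy[, 1]); x1 <- max(all_xy[, 1])
  y0 <- min(all_xy[, 2]); y1 <- max(all_xy[, 2])
  set.seed(seed)
  px <- runif(n, x0, x1); py <- runif(n, y0, y1)
  inside <- rep(FALSE, n)
  for (g in geoms) inside <- inside | oracle_pip(px, py, g)
  mean(inside) * (x1 - x0) * (y1 - y0)
}

# Haversine great-circle distance in statute miles, written from the
# formula (R = 6378137 m, matching the default sphere radius used by the
# implementation's backend).
oracle_haversine_miles <- function(a, b, radius_m = 6378137) {
  to_rad <- pi / 180
  dlat <- (b[2] - a[2]) * to_rad
  dlon <- (b[1] - a[1]) * to_rad
  h <- sin(dlat / 2)^2 +
    cos(a[2] * to_rad) * cos(b[2] * to_rad) * sin(dlon / 2)^2
  2 * radius_m * asin(sqrt(h)) / 1609.344
}

# Brute-force signed-rank two-sided p by enumerating every sign vector.
oracle_wilcoxon <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- as.vector(signs %*% r)
  p <- 2 * min(mean(sums <= W + 1e-12), mean(sums >= W - 1e-12))
  list(W = W, p = min(p, 1))
}

# Random star-shaped simple polygon: random radii at sorted random angles.
random_simple_polygon <- function(nv = 8, seed = 1, cx = 0, cy = 0) {
  set.seed(seed)
  ang <- sort(runif(nv, 0, 2 * pi))
  rad <- runif(nv, 0.5, 2)
  trr_polygon(cbind(cx + rad * cos(ang), cy + rad * sin(ang)))
}

# Fully aligned synthetic configuration: zip cells equal tracts, HRR Voronoi
# seeds at the centers of a 2 x 2 macro-grid so HRR boundaries fall on tract
# lines.
aligned_geography <- function(seed = 1) {
  geography_config(side = 40, n = 4, k = 2, h = 4, m = 2, delta = 0,
                   n_centers = 4, cluster_p = 0, seed = seed,
                   hrr_seeds = rbind(c(10, 10), c(30, 10),
                                     c(10, 30), c(30, 30)))
}

unit_square <- function(id = NULL) trrlink:::rect_poly(0, 0, 1, 1, id = id)
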