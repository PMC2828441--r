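#' Polygon area by the shoelace formula
#'
#' @param poly numeric matrix with two columns (x, y); an open ring
#'   (the closing vertex must not be repeated).
#' @return area in squared input units (non-negative).
#' @export
polygon_area <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Envelope (bounding-box) centroid of a polygon
#'
#' Returns the centre of the polygon's axis-aligned bounding envelope,
#' the centroid convention used throughout the demand analysis. This is
#' deliberately *not* the area centroid: for non-symmetric polygons the
#' two differ.
#'
#' @param poly numeric matrix with columns (x, y), at least 3 vertices.
#' @return numeric vector `c(x, y)`.
#' @export
envelope_centroid <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2)
  if (nrow(poly) < 3) stop("polygon must have at least 3 vertices")
  rx <- range(poly[, 1]); ry <- range(poly[, 2])
  if (diff(rx) == 0 && diff(ry) == 0) {
    stop("degenerate polygon: zero spatial extent")
  }
  c(mean(rx), mean(ry))
}

# Clip a convex polygon by the half-plane a*x + b*y <= c
# (Sutherland-Hodgman, one edge). Returns a matrix, possibly with 0 rows.
clip_halfplane <- function(poly, a, b, c) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  v <- a * poly[, 1] + b * poly[, 2] - c
  inside <- v <= 1e-12 * max(1, abs(c))
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0L, , drop = FALSE])
  out <- matrix(0, nrow = 2L * n, ncol = 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) {
      m <- m + 1L; out[m, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- v[i] / (v[i] - v[j])
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

# Voronoi cells of seed points clipped to a rectangular box.
# Exact construction by successive half-plane clips against perpendicular
# bisectors; neighbours are visited in order of distance and clipping stops
# once half the distance to the next seed exceeds the cell's current
# circumradius (no further bisector can cut the cell).
voronoi_cells <- function(seeds, bbox) {
  stopifnot(is.matrix(seeds), ncol(seeds) == 2)
  k <- nrow(seeds)
  box <- rbind(
    c(bbox["xmin"], bbox["ymin"]), c(bbox["xmax"], bbox["ymin"]),
    c(bbox["xmax"], bbox["ymax"]), c(bbox["xmin"], bbox["ymax"])
  )
  dimnames(box) <- NULL
  if (k == 1L) return(list(box))
  cells <- vector("list", k)
  for (i in seq_len(k)) {
    p <- seeds[i, ]
    d2 <- (seeds[, 1] - p[1])^2 + (seeds[, 2] - p[2])^2
    ord <- order(d2)
    ord <- ord[ord != i]
    cell <- box
    for (j in ord) {
      dj <- sqrt(d2[j])
      rmax2 <- max((cell[, 1] - p[1])^2 + (cell[, 2] - p[2])^2)
      if ((dj / 2)^2 > rmax2) break
      q <- seeds[j, ]
      cell <- clip_halfplane(
        cell,
        2 * (q[1] - p[1]), 2 * (q[2] - p[2]),
        q[1]^2 + q[2]^2 - p[1]^2 - p[2]^2
      )
      if (nrow(cell) == 0L) break
    }
    cells[[i]] <- cell
  }
  cells
}

# Even-odd ray-casting point-in-polygon test, vectorised over points.
# Points within `eps` of a polygon edge count as inside, so boundary
# points can be resolved by a deterministic first-in-id-order tie rule
# by the caller.
point_in_polygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  inside <- logical(length(px))
  onedge <- logical(length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses & !is.na(crosses))
    # distance from point to segment (i, j)
    dx <- xj - xi; dy <- yj - yi
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - xi) * dx + (py - yi) * dy) / L2))
    d2 <- (xi + t * dx - px)^2 + (yi + t * dy - py)^2
    onedge <- onedge | d2 <= eps^2
  }
  inside | onedge
}

# Draw n uniform points inside a convex polygon by fan triangulation:
# pick a triangle with probability proportional to its area, then sample
# uniformly within it. Exact (no rejection), so the draw count is n always.
sample_points_in_polygon <- function(poly, n) {
  stopifnot(nrow(poly) >= 3)
  if (n == 0L) return(matrix(numeric(0), ncol = 2))
  v0 <- poly[1, ]
  m <- nrow(poly) - 2L
  areas <- numeric(m)
  for (t in seq_len(m)) {
    a <- poly[t + 1L, ] - v0; b <- poly[t + 2L, ] - v0
    areas[t] <- abs(a[1] * b[2] - a[2] * b[1]) / 2
  }
  tri <- sample.int(m, n, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    a <- poly[tri[i] + 1L, ]; b <- poly[tri[i] + 2L, ]
    out[i, ] <- (1 - r1[i]) * v0 + r1[i] * ((1 - r2[i]) * a + r2[i] * b)
  }
  out
}
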