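#' Windowed geometry primitives
#'
#' Exact annulus-window intersection areas (the DRP edge correction), polygon
#' containment tests, and clipped Voronoi tessellation. Coordinates are
#' continuous micrometres; all distances Euclidean.
#'
#' @name geometry
NULL

# area of {x^2 + y^2 <= r^2} intersected with [0, a] x [0, b], a, b >= 0
quadrant_disk_area <- function(a, b, r) {
  if (r <= 0 || a <= 0 || b <= 0) return(0)
  a <- min(a, r)
  b <- min(b, r)
  if (a * a + b * b <= r * r) return(a * b)
  # circle crosses y = b at x0 < a
  x0 <- sqrt(max(r * r - b * b, 0))
  antider <- function(x) {
    s <- max(r * r - x * x, 0)
    0.5 * (x * sqrt(s) + r * r * asin(min(max(x / r, -1), 1)))
  }
  b * x0 + antider(a) - antider(x0)
}

disk_window_area <- function(cx, cy, r, window) {
  w <- window$width_um
  h <- window$height_um
  quadrant_disk_area(cx, cy, r) +
    quadrant_disk_area(w - cx, cy, r) +
    quadrant_disk_area(cx, h - cy, r) +
    quadrant_disk_area(w - cx, h - cy, r)
}

#' Area of an annulus clipped to the window
#'
#' Exact area of `{p : r_inner <= |p - center| < r_outer}` intersected with
#' the window, computed analytically as the difference of two circle-rectangle
#' intersection areas. This is the per-reference-point edge correction used by
#' the density recovery profile.
#'
#' @param center Numeric length-2 `(x, y)` in um; must lie inside the window.
#' @param r_inner,r_outer Annulus radii, `0 <= r_inner < r_outer`.
#' @param window A [field_window()].
#' @return Area in um^2, in `(0, pi * (r_outer^2 - r_inner^2)]`.
#' @examples
#' win <- field_window(100)
#' annulus_window_area(c(50, 50), 0, 10, win)  # pi * 100, fully interior
#' @export
annulus_window_area <- function(center, r_inner, r_outer, window) {
  stopifnot(inherits(window, "field_window"))
  if (!(r_inner >= 0 && r_outer > r_inner)) {
    stop("need 0 <= r_inner < r_outer", call. = FALSE)
  }
  if (!in_window(center[1], center[2], window)) {
    stop("annulus center outside window", call. = FALSE)
  }
  disk_window_area(center[1], center[2], r_outer, window) -
    disk_window_area(center[1], center[2], r_inner, window)
}

validate_polygon <- function(vertices) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2 || nrow(v) < 3 || any(!is.finite(v))) {
    stop("polygon needs >= 3 finite (x, y) vertices", call. = FALSE)
  }
  # drop a duplicated closing vertex
  if (nrow(v) > 3 && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (!polygon_is_simple(v)) stop("polygon is self-intersecting", call. = FALSE)
  if (abs(signed_area(v)) <= 0) stop("polygon has zero area", call. = FALSE)
  unname(v)
}

signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Polygon area (shoelace)
#'
#' @param vertices An n x 2 matrix (or coercible) of polygon vertices in
#'   order, not self-intersecting.
#' @return Absolute area in um^2.
#' @export
polygon_area <- function(vertices) {
  abs(signed_area(validate_polygon(vertices)))
}

polygon_perimeter <- function(v) {
  xn <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])
  sum(sqrt(rowSums((xn - v)^2)))
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

cross2 <- function(a, b) a[1] * b[2] - a[2] * b[1]

polygon_is_simple <- function(v) {
  n <- nrow(v)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      # skip adjacent edges (share a vertex)
      if (abs(i - j) <= 1 || (i == 1 && j == n)) next
      if (segments_intersect(v[i, ], v[i %% n + 1, ],
                             v[j, ], v[j %% n + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Test points for polygon membership
#'
#' Even-odd (ray crossing) rule; points exactly on the boundary may fall on
#' either side and should not be relied upon.
#'
#' @param px,py Numeric vectors of query coordinates (um).
#' @param vertices Polygon vertex matrix.
#' @return Logical vector.
#' @export
points_in_polygon <- function(px, py, vertices) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# min distance from each (px, py) to the polygon boundary
dist_to_polygon_boundary <- function(px, py, v) {
  n <- nrow(v)
  d2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    a <- v[i, ]
    b <- v[i %% n + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
    dx <- px - (a[1] + t * ab[1])
    dy <- py - (a[2] + t * ab[2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Is a soma disk fully inside a polygon?
#'
#' TRUE iff the closed disk of radius `diameter/2` about the soma center lies
#' entirely within the polygon: the center is inside and its distance to the
#' polygon boundary is at least the radius. This is the full-containment rule
#' used when counting somata enclosed by a dendritic territory.
#'
#' @param x_um,y_um Soma center (vectors allowed).
#' @param diameter_um Soma diameter(s) in um.
#' @param vertices Polygon vertex matrix (validated).
#' @return Logical vector.
#' @export
disk_fully_inside <- function(x_um, y_um, diameter_um, vertices) {
  v <- validate_polygon(vertices)
  r <- rep_len(diameter_um / 2, length(x_um))
  inside <- points_in_polygon(x_um, y_um, v)
  out <- inside
  if (any(inside)) {
    d <- dist_to_polygon_boundary(x_um[inside], y_um[inside], v)
    out[inside] <- d >= r[inside]
  }
  out
}

# Sutherland-Hodgman clip of polygon `poly` by half-plane {p : (p - m).d <= 0}
clip_halfplane <- function(poly, m, d) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  val <- (poly[, 1] - m[1]) * d[1] + (poly[, 2] - m[2]) * d[2]
  if (all(val <= 0)) return(poly)
  keep_any <- any(val <= 0)
  if (!keep_any) return(poly[0, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    vi <- val[i]; vj <- val[j]
    if (vi <= 0) out <- rbind(out, poly[i, ])
    if ((vi < 0 && vj > 0) || (vi > 0 && vj < 0)) {
      t <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

#' Window-clipped Voronoi tessellation
#'
#' Computes each soma's Voronoi domain intersected with the window by
#' successive bisector half-plane clipping (neighbors visited in distance
#' order with a pruning bound, so typical cost is near-linear per domain).
#' Domains whose boundary touches the window edge are flagged, not dropped;
#' the regularity-index consumer decides exclusion.
#'
#' @param field A [soma_field()] with at least 4 non-collinear points.
#' @return A list with one element per soma: `list(id, vertices, area_um2,
#'   is_border)`. Clipped areas sum to the window area.
#' @export
voronoi_domains <- function(field) {
  stopifnot(inherits(field, "soma_field"))
  pts <- as.matrix(field$points[, c("x_um", "y_um")])
  n <- nrow(pts)
  if (n < 4) stop("need at least 4 points for a Voronoi tessellation",
                  call. = FALSE)
  # collinearity check
  cent <- colMeans(pts)
  sv <- svd(sweep(pts, 2, cent))$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("all points are collinear", call. = FALSE)
  }
  w <- field$window$width_um
  h <- field$window$height_um
  rect <- matrix(c(0, 0, w, 0, w, h, 0, h), ncol = 2, byrow = TRUE)
  eps <- 1e-9 * max(w, h)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- pts[i, ]
    dx <- pts[, 1] - p[1]
    dy <- pts[, 2] - p[2]
    d2 <- dx * dx + dy * dy
    ord <- order(d2)
    ord <- ord[ord != i]
    poly <- rect
    for (j in ord) {
      dj <- sqrt(d2[j])
      # bisector at distance dj/2 cannot cut if the cell already fits closer
      maxv <- sqrt(max((poly[, 1] - p[1])^2 + (poly[, 2] - p[2])^2))
      if (dj / 2 >= maxv) break
      m <- (p + pts[j, ]) / 2
      poly <- clip_halfplane(poly, m, c(dx[j], dy[j]))
      if (nrow(poly) < 3) break
    }
    is_border <- nrow(poly) >= 1 &&
      any(poly[, 1] < eps | poly[, 1] > w - eps |
            poly[, 2] < eps | poly[, 2] > h - eps)
    area <- if (nrow(poly) >= 3) abs(signed_area(poly)) else 0
    out[[i]] <- list(id = field$points$id[i], vertices = poly,
                     area_um2 = area, is_border = is_border)
  }
  out
}
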