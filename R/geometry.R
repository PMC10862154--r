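# Internal planar geometry: point-in-polygon with an explicit boundary
# convention, polygon validity checks, and point-to-polyline distances.
# Pixel centres sit at integer coordinates, origin top-left, x rightward,
# y downward; all physical quantities follow from pixel_spacing_um.

# Crossing-number (even-odd) parity, vectorised over points. The parity of
# points exactly on the boundary is arbitrary; callers resolve those with
# .on_boundary().
.crossing_parity <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ye[i] > py))
    if (any(crosses)) {
      xi <- xs[i] + (py[crosses] - ys[i]) * (xe[i] - xs[i]) / (ye[i] - ys[i])
      hit <- px[crosses] < xi
      inside[crosses] <- xor(inside[crosses], hit)
    }
  }
  inside
}

.strictly_inside <- function(px, py, poly) {
  .crossing_parity(px, py, poly) & !.on_boundary(px, py, poly)
}

.on_boundary <- function(px, py, poly, tol = 1e-7) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  on <- logical(length(px))
  for (i in seq_len(n)) {
    dx <- xe[i] - xs[i]; dy <- ye[i] - ys[i]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) next
    perp <- abs((px - xs[i]) * dy - (py - ys[i]) * dx) / sqrt(len2)
    t <- ((px - xs[i]) * dx + (py - ys[i]) * dy) / len2
    on <- on | (perp <= tol & t >= -tol & t <= 1 + tol)
  }
  on
}

# Half-open containment used for mask construction: boundary points count as
# inside the periosteal polygon and outside endosteal polygons, so abutting
# regions never double-count a pixel.
.point_in_polygon <- function(px, py, poly, boundary = c("inside", "outside")) {
  boundary <- match.arg(boundary)
  parity <- .crossing_parity(px, py, poly)
  on <- .on_boundary(px, py, poly)
  if (boundary == "inside") (parity & !on) | on else parity & !on
}

.segments_intersect <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry) {
    v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
    sign(v)
  }
  o1 <- o(ax, ay, bx, by, cx, cy)
  o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay)
  o4 <- o(cx, cy, dx, dy, bx, by)
  proper <- (o1 != o2) & (o3 != o4) & o1 != 0 & o2 != 0 & o3 != 0 & o4 != 0
  on_seg <- function(px, py, qx, qy, rx, ry) {
    o(px, py, qx, qy, rx, ry) == 0 &
      rx >= pmin(px, qx) & rx <= pmax(px, qx) &
      ry >= pmin(py, qy) & ry <= pmax(py, qy)
  }
  proper |
    on_seg(ax, ay, bx, by, cx, cy) | on_seg(ax, ay, bx, by, dx, dy) |
    on_seg(cx, cy, dx, dy, ax, ay) | on_seg(cx, cy, dx, dy, bx, by)
}

# A polygon is simple when no two non-adjacent edges intersect.
.is_simple_polygon <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  for (i in seq_len(n - 2)) {
    j <- (i + 2):n
    # edge n is adjacent to edge 1
    j <- j[!(i == 1 & j == n)]
    if (!length(j)) next
    hit <- .segments_intersect(xs[i], ys[i], xe[i], ye[i],
                               xs[j], ys[j], xe[j], ye[j])
    if (any(hit)) return(FALSE)
  }
  TRUE
}

.polygons_cross <- function(a, b) {
  na <- nrow(a); nb <- nrow(b)
  axs <- a[, 1]; ays <- a[, 2]
  axe <- axs[c(2:na, 1)]; aye <- ays[c(2:na, 1)]
  bxs <- b[, 1]; bys <- b[, 2]
  bxe <- bxs[c(2:nb, 1)]; bye <- bys[c(2:nb, 1)]
  for (i in seq_len(na)) {
    if (any(.segments_intersect(axs[i], ays[i], axe[i], aye[i],
                                bxs, bys, bxe, bye))) {
      return(TRUE)
    }
  }
  FALSE
}

# Minimum Euclidean distance from each point to a closed polyline, in the
# points' coordinate units.
.dist_to_polyline <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  best <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    dx <- xe[i] - xs[i]; dy <- ye[i] - ys[i]
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - xs[i]) * dx + (py - ys[i]) * dy) / len2))
    d2 <- (px - (xs[i] + t * dx))^2 + (py - (ys[i] + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's stream afterwards so generators never perturb user randomness.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
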