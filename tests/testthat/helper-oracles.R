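# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use naive per-element algorithms so they stay
# independent of the vectorised implementation paths they check.

# Brute-force triangle threshold: compute the perpendicular distance to the
# peak-to-tail line for every bin, one at a time.
triangle_oracle <- function(h) {
  nz <- which(h > 0)
  if (length(nz) < 2L) return(nz[1] - 1L)
  peak <- which.max(h)
  lo <- nz[1]; hi <- nz[length(nz)]
  end <- if ((hi - peak) >= (peak - lo)) hi else lo
  if (end == peak) return(peak - 1L)
  p1 <- c((peak - 1) / 255, 1)
  p2 <- c((end - 1) / 255, h[end] / max(h))
  len <- sqrt(sum((p2 - p1)^2))
  rng <- if (end > peak) peak:end else end:peak
  best_d <- -1; best_bin <- NA_integer_
  for (b in rng) {
    q <- c((b - 1) / 255, h[b] / max(h))
    d <- abs((p2[1] - p1[1]) * (p1[2] - q[2]) -
               (p1[1] - q[1]) * (p2[2] - p1[2])) / len
    better <- d > best_d + 1e-12
    tie <- abs(d - best_d) <= 1e-12 && abs(b - peak) < abs(best_bin - peak)
    if (better || tie) {
      best_d <- max(best_d, d)
      best_bin <- b
    }
  }
  best_bin - 1L
}

# A plausible random intensity histogram: one smooth peak plus noise, with a
# random support range (some empty bins at the ends).
random_histogram <- function() {
  mu <- runif(1, 30, 220)
  sig <- runif(1, 5, 60)
  x <- 0:255
  h <- round(2000 * exp(-(x - mu)^2 / (2 * sig^2)) + rpois(256, 2))
  cut_lo <- sample(0:40, 1); cut_hi <- sample(215:255, 1)
  h[x < cut_lo | x > cut_hi] <- 0
  if (sum(h > 0) < 2) h[c(100, 150)] <- c(10, 5)
  h
}

# Stack-based flood fill labelling, one pixel at a time.
flood_label <- function(grid, connectivity = 8L) {
  nr <- nrow(grid); nc <- ncol(grid)
  offs <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  }
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (grid[rr, cc] && lab[rr, cc] == 0L) {
      cur <- cur + 1L
      stack <- list(c(rr, cc))
      lab[rr, cc] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (o in offs) {
          q <- p + o
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              grid[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# Canonical component representation for set comparison: sorted list of
# sorted linear-index vectors.
canonical_components <- function(comps) {
  comps <- unname(lapply(comps, function(v) unname(sort(as.integer(v)))))
  comps[order(vapply(comps, min, integer(1)))]
}

components_from_labels <- function(lab) {
  canonical_components(split(which(lab > 0), lab[lab > 0]))
}

# Axis-aligned square contours with half-integer vertices so no pixel centre
# sits exactly on an edge: outer square holds `side^2` pixel centres.
square_contours <- function(side = 100, inner = c(40, 60)) {
  outer <- cbind(x = c(-0.5, side - 0.5, side - 0.5, -0.5),
                 y = c(-0.5, -0.5, side - 0.5, side - 0.5))
  endo <- cbind(x = c(inner[1] - 0.5, inner[2] - 0.5, inner[2] - 0.5,
                      inner[1] - 0.5),
                y = c(inner[1] - 0.5, inner[1] - 0.5, inner[2] - 0.5,
                      inner[2] - 0.5))
  contour_set(outer, list(endo))
}

# Stamp a disc of radius r (px) into a logical matrix, pixel-centre rule.
stamp_disc <- function(m, cx, cy, r, value = TRUE) {
  for (col in max(1, floor(cx - r)):min(ncol(m), ceiling(cx + r + 2))) {
    for (row in max(1, floor(cy - r)):min(nrow(m), ceiling(cy + r + 2))) {
      if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= r^2) m[row, col] <- value
    }
  }
  m
}

# A minimal measured-record table for filter tests.
fake_records <- function(area, circ) {
  n <- length(area)
  data.frame(
    id = seq_len(n), n_px = rep(10L, n), area_mm2 = area,
    perimeter_um = rep(100, n), circularity = circ,
    x_px = rep(0, n), y_px = rep(0, n),
    eq_diameter_um = 2 * sqrt(area / pi) * 1e3,
    feret_max_um = rep(50, n),
    canal_class = classify_canal(area),
    stringsAsFactors = FALSE
  )
}
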