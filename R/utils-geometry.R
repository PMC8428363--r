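# Geometry primitives for polygon annotations.
#
# Coordinate dialect used throughout: x to the right, y down, 0-based pixel
# coordinates. Polygons are N x 2 matrices (columns x, y), closed implicitly
# (the last vertex connects back to the first).

# Evaluate a function with a private RNG stream so generators are pure:
# the caller's .Random.seed is untouched.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

checkPolygon <- function(poly) {
  if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L) {
    stop("polygon must be a matrix with >= 3 rows and columns (x, y)")
  }
  if (any(!is.finite(poly))) stop("polygon vertices must be finite")
  if (isSelfIntersecting(poly)) {
    stop("polygon is self-intersecting; annotations must be simple polygons")
  }
  invisible(poly)
}

# Proper/improper intersection of two closed segments p1-p2 and p3-p4,
# excluding the shared-endpoint contacts that consecutive polygon edges have.
segmentsCross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(TRUE)
  }
  on <- function(a, b, c) {
    d(a, b, c) == 0 &&
      min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  on(p1, p2, p3) || on(p1, p2, p4) || on(p3, p4, p1) || on(p3, p4, p2)
}

isSelfIntersecting <- function(poly) {
  n <- nrow(poly)
  idx <- function(k) ((k - 1L) %% n) + 1L
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (b <= a) next
      # skip adjacent edges (they share a vertex by construction)
      if (b == a + 1L || (a == 1L && b == n)) next
      if (segmentsCross(poly[a, ], poly[idx(a + 1L), ],
                        poly[b, ], poly[idx(b + 1L), ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Boundary-inclusive point-in-polygon: a point on an edge or vertex counts as
# inside. Interior test is an even-odd ray cast with the standard half-open
# edge rule. Vectorized over points.
pointInPolygon <- function(px, py, poly, eps = 1e-9) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  m <- length(px)
  inside <- logical(m)
  onEdge <- logical(m)
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    # on-segment test: collinear and within the segment's bounding box
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    seglen2 <- (x2 - x1)^2 + (y2 - y1)^2
    tol <- eps * max(1, sqrt(seglen2))
    col <- abs(cross) <= tol
    inbox <- px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
      py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
    onEdge <- onEdge | (col & inbox)
    # ray cast to the right, half-open in y
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  inside | onEdge
}

# Is (px, py) inside (boundary-inclusive) any polygon of a list?
pointInAnyPolygon <- function(px, py, polygons) {
  hit <- rep(FALSE, length(px))
  for (poly in polygons) {
    todo <- !hit
    if (!any(todo)) break
    hit[todo] <- pointInPolygon(px[todo], py[todo], poly)
  }
  hit
}
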