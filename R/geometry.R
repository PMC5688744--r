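# Low-level 2D geometry: vectors, the circle-distribution primitive used for
# every loop (re)drawing, and segment-crossing tests for the overlap counter.
# Coordinates are Cartesian with y increasing upward; writers convert.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

# 90-degree counter-clockwise rotation
vperp <- function(v) c(-v[2L], v[1L])

vrot <- function(v, theta) {
  c(cos(theta) * v[1L] - sin(theta) * v[2L],
    sin(theta) * v[1L] + cos(theta) * v[2L])
}

#' Distribute points on a circle between two anchors
#'
#' Places `n` points on a circle passing through both anchors, on the given
#' side of the line a-b, so that the `n + 1` consecutive arc gaps
#' (a to p1, ..., pn to b) are equal. The circle radius is solved numerically
#' (bisection on the central angle) so that each gap's chord length is as
#' close as possible to `backbone_step`; when the anchors are too far apart
#' for that spacing on any circle, the minimal circle through the anchors
#' (a semicircular arc) is used instead.
#'
#' @param a,b Anchor points, numeric length-2, distinct.
#' @param n Number of points to place (`n = 0` returns an empty matrix).
#' @param side Direction (numeric length-2, need not be unit or
#'   perpendicular) indicating the half-plane of line a-b that receives the
#'   arc.
#' @param backbone_step Desired chord length per gap.
#' @return An `n` x 2 matrix of points, ordered from `a` to `b`.
#' @export
distribute_on_circle <- function(a, b, n, side, backbone_step = 8) {
  if (n == 0L) return(matrix(numeric(0), ncol = 2L))
  stopifnot(n >= 1L, length(a) == 2L, length(b) == 2L)
  d <- vnorm(b - a)
  if (d < 1e-12) stop("coincident anchors")
  u <- (b - a) / d
  sperp <- side - sum(side * u) * u        # component of `side` normal to a-b
  if (vnorm(sperp) < 1e-12) stop("side direction is parallel to the anchor line")
  sperp <- vunit(sperp)
  gaps <- n + 1L
  # chord per gap on a circle where the a..b arc subtends angle theta:
  chord_gap <- function(theta) d * sin(theta / (2 * gaps)) / sin(theta / 2)
  lo <- 1e-7; hi <- 2 * pi - 1e-6
  if (chord_gap(lo) >= backbone_step) {
    theta <- pi                            # anchors too far apart: semicircle
  } else if (chord_gap(hi) <= backbone_step) {
    theta <- hi
  } else {
    theta <- stats::uniroot(function(t) chord_gap(t) - backbone_step,
                            c(lo, hi), tol = 1e-12)$root
  }
  r <- d / (2 * sin(theta / 2))
  m <- (a + b) / 2
  centre <- m - sperp * (r * cos(theta / 2))
  phi_a <- atan2(a[2L] - centre[2L], a[1L] - centre[1L])
  # choose sweep sign so the arc midpoint lands on the requested side
  pick <- function(s) {
    mid <- centre + r * c(cos(phi_a + s * theta / 2), sin(phi_a + s * theta / 2))
    sum((mid - m) * sperp)
  }
  s <- if (pick(1) >= pick(-1)) 1 else -1
  k <- seq_len(n)
  phi <- phi_a + s * theta * k / gaps
  cbind(centre[1L] + r * cos(phi), centre[2L] + r * sin(phi))
}

# Solve the radius of a closed loop circle: chords ch must satisfy
# sum(2*asin(ch/(2r))) = 2*pi. Returns max(ch)/2 if even that cannot close
# (tiny loops), which degrades to an evenly spread placement.
loop_circle_radius <- function(chords) {
  r0 <- max(chords) / 2
  f <- function(r) sum(2 * asin(pmin(1, chords / (2 * r)))) - 2 * pi
  if (f(r0) <= 0) return(r0)
  hi <- sum(chords)            # generous upper bound: f(hi) < 0
  while (f(hi) > 0) hi <- hi * 2
  stats::uniroot(f, c(r0, hi), tol = 1e-12)$root
}

# ---- segment crossings ------------------------------------------------------

# Orientation of triple (vectorized): sign of cross product, with tolerance.
orient <- function(ax, ay, bx, by, cx, cy, eps = 1e-9) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  ifelse(abs(v) < eps, 0, sign(v))
}

# Do closed segments p1-p2 and q1-q2 intersect "properly"? Vectorized over
# rows. Proper = straddling crossing, a collinear overlap of positive length,
# or an endpoint of one in the interior of the other; a bare endpoint-to-
# endpoint touch does not count. Segments sharing a residue are excluded by
# the caller before this test.
segments_cross <- function(p1x, p1y, p2x, p2y, q1x, q1y, q2x, q2y, eps = 1e-9) {
  o1 <- orient(p1x, p1y, p2x, p2y, q1x, q1y, eps)
  o2 <- orient(p1x, p1y, p2x, p2y, q2x, q2y, eps)
  o3 <- orient(q1x, q1y, q2x, q2y, p1x, p1y, eps)
  o4 <- orient(q1x, q1y, q2x, q2y, p2x, p2y, eps)
  proper <- (o1 * o2 < 0) & (o3 * o4 < 0)
  on_seg <- function(ax, ay, bx, by, px, py) {
    # p collinear with a-b assumed; is p within the box, strictly inside?
    (pmin(ax, bx) - eps <= px) & (px <= pmax(ax, bx) + eps) &
      (pmin(ay, by) - eps <= py) & (py <= pmax(ay, by) + eps) &
      !((abs(px - ax) < eps & abs(py - ay) < eps) |
          (abs(px - bx) < eps & abs(py - by) < eps))
  }
  touch <- (o1 == 0 & on_seg(p1x, p1y, p2x, p2y, q1x, q1y)) |
    (o2 == 0 & on_seg(p1x, p1y, p2x, p2y, q2x, q2y)) |
    (o3 == 0 & on_seg(q1x, q1y, q2x, q2y, p1x, p1y)) |
    (o4 == 0 & on_seg(q1x, q1y, q2x, q2y, p2x, p2y))
  # fully collinear segments overlapping over a positive length (covers the
  # degenerate identical-segments case the interior test misses)
  ovl <- (o1 == 0 & o2 == 0 & o3 == 0 & o4 == 0) &
    (pmin(pmax(p1x, p2x), pmax(q1x, q2x)) - pmax(pmin(p1x, p2x), pmin(q1x, q2x)) > eps |
       pmin(pmax(p1y, p2y), pmax(q1y, q2y)) - pmax(pmin(p1y, p2y), pmin(q1y, q2y)) > eps)
  proper | touch | ovl
}
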