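# Convex-polygon utilities used for tile-footprint overlap computations.
# Tile footprints under affine transforms are convex quadrilaterals, so
# Sutherland-Hodgman clipping is exact here.

polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Clip subject polygon by convex clip polygon; both counter-clockwise or
# clockwise consistently. Returns matrix (possibly 0 rows).
clip_convex <- function(subject, clip) {
  clip <- orient_ccw(clip)
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0) return(matrix(numeric(0), 0, 2))
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(inp)
    side <- (b[1] - a[1]) * (inp[, 2] - a[2]) - (b[2] - a[2]) * (inp[, 1] - a[1])
    for (j in seq_len(n)) {
      k <- if (j == n) 1 else j + 1
      cur_in <- side[j] >= -1e-12
      nxt_in <- side[k] >= -1e-12
      if (cur_in) out <- rbind(out, inp[j, ])
      if (xor(cur_in, nxt_in)) {
        t <- side[j] / (side[j] - side[k])
        out <- rbind(out, inp[j, ] + t * (inp[k, ] - inp[j, ]))
      }
    }
  }
  out
}

orient_ccw <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  s <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (s < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

overlap_area <- function(poly_a, poly_b) {
  polygon_area(clip_convex(poly_a, poly_b))
}

points_in_convex <- function(pts, poly) {
  poly <- orient_ccw(poly)
  n <- nrow(poly)
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
    side <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & side >= -1e-12
  }
  inside
}

# Uniform samples inside a convex polygon by rejection from its bbox.
sample_in_convex <- function(poly, n) {
  lo <- apply(poly, 2, min); hi <- apply(poly, 2, max)
  out <- matrix(numeric(0), 0, 2)
  guard <- 0
  while (nrow(out) < n && guard < 1000) {
    m <- max(4 * (n - nrow(out)), 16)
    cand <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]))
    out <- rbind(out, cand[points_in_convex(cand, poly), , drop = FALSE])
    guard <- guard + 1
  }
  out[seq_len(min(n, nrow(out))), , drop = FALSE]
}
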