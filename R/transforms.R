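#' @importFrom stats median sd rnorm runif setNames dist hclust cutree
#' @importFrom utils head tail
NULL

# Transform kinds supported throughout the package. All transforms are 2D
# mappings from a tile's local pixel frame to a more global frame; a tile's
# transform list is applied first -> last (local -> global).
TRANSFORM_KINDS <- c("translation", "rigid", "similarity", "affine",
                     "polynomial2", "thin_plate_spline", "reference",
                     "interpolated")

new_transform <- function(kind, ...) {
  stopifnot(kind %in% TRANSFORM_KINDS)
  structure(list(kind = kind, ...), class = c(paste0("tf_", kind), "transform"))
}

#' Create a translation transform
#'
#' @param tx,ty Translation in pixels.
#' @return A `transform` object.
#' @export
tf_translation <- function(tx = 0, ty = 0) {
  new_transform("translation", tx = as.numeric(tx), ty = as.numeric(ty))
}

#' Create a rigid (rotation + translation) transform
#'
#' @param theta Rotation angle in radians (counter-clockwise in the
#'   x-right/y-down pixel convention the package uses throughout).
#' @param tx,ty Translation in pixels.
#' @return A `transform` object.
#' @export
tf_rigid <- function(theta = 0, tx = 0, ty = 0) {
  new_transform("rigid", theta = as.numeric(theta),
                tx = as.numeric(tx), ty = as.numeric(ty))
}

#' Create a similarity transform (uniform scale + rotation + translation)
#'
#' @param s Uniform scale factor, must be > 0.
#' @param theta Rotation angle in radians.
#' @param tx,ty Translation in pixels.
#' @return A `transform` object.
#' @export
tf_similarity <- function(s = 1, theta = 0, tx = 0, ty = 0) {
  if (s <= 0) stop("similarity scale must be positive")
  new_transform("similarity", s = as.numeric(s), theta = as.numeric(theta),
                tx = as.numeric(tx), ty = as.numeric(ty))
}

#' Create an affine transform
#'
#' Maps p to `M %*% p + t`.
#'
#' @param M 2x2 linear matrix.
#' @param t Length-2 translation vector (pixels).
#' @return A `transform` object.
#' @export
tf_affine <- function(M = diag(2), t = c(0, 0)) {
  M <- matrix(as.numeric(M), 2, 2)
  new_transform("affine", M = M, t = as.numeric(t))
}

#' Create a second-order polynomial transform
#'
#' Each output axis is a linear combination of the basis
#' (1, x, y, x^2, xy, y^2).
#'
#' @param coef 2x6 coefficient matrix; row 1 produces x', row 2 produces y'.
#' @return A `transform` object.
#' @export
tf_polynomial2 <- function(coef) {
  coef <- matrix(as.numeric(coef), 2, 6)
  new_transform("polynomial2", coef = coef)
}

#' Create a thin-plate-spline transform
#'
#' The mapping is `p -> a + B p + sum_k w_k U(|p - c_k|)` with the 2D
#' biharmonic kernel `U(r) = r^2 log(r)` and `U(0) = 0`.
#'
#' @param centers Kx2 matrix of control points (pixels).
#' @param a Length-2 affine offset.
#' @param B 2x2 affine linear part.
#' @param w Kx2 matrix of kernel weights (column 1 for x', column 2 for y').
#' @return A `transform` object.
#' @export
tf_tps <- function(centers, a = c(0, 0), B = diag(2), w = NULL) {
  centers <- as_pts(centers)
  if (is.null(w)) w <- matrix(0, nrow(centers), 2)
  w <- matrix(as.numeric(w), nrow(centers), 2)
  new_transform("thin_plate_spline", centers = centers, a = as.numeric(a),
                B = matrix(as.numeric(B), 2, 2), w = w)
}

#' Create a reference transform
#'
#' Points at a shared transform stored in a [tile_collection()]'s
#' `shared` registry (used for the lens-distortion correction every tile of
#' an acquisition group has in common).
#'
#' @param ref_id Identifier of the shared transform.
#' @return A `transform` object.
#' @export
tf_reference <- function(ref_id) {
  new_transform("reference", ref_id = as.character(ref_id))
}

#' Create an interpolated transform
#'
#' Blends two transforms: `p -> (1 - lambda) * Ta(p) + lambda * Tb(p)`.
#' Used during chunk fusion to hand over smoothly between independently
#' aligned chunks.
#'
#' @param a,b Component transforms.
#' @param lambda_blend Blend weight in `[0, 1]`; 0 gives `a`, 1 gives `b`.
#' @return A `transform` object.
#' @export
tf_interpolated <- function(a, b, lambda_blend) {
  stopifnot(inherits(a, "transform"), inherits(b, "transform"))
  new_transform("interpolated", a = a, b = b,
                lambda_blend = as.numeric(lambda_blend))
}

as_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2, byrow = FALSE)
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 2) stop("points must be an N x 2 matrix")
  pts
}

# TPS kernel U(r) = r^2 log r, U(0) = 0, evaluated on squared distances.
tps_U <- function(r2) {
  out <- numeric(length(r2))
  pos <- r2 > 0
  out[pos] <- 0.5 * r2[pos] * log(r2[pos])
  out
}

tps_kernel_matrix <- function(pts, centers) {
  # N x K matrix of U(|p_i - c_k|)
  d2 <- outer(pts[, 1], centers[, 1], "-")^2 +
        outer(pts[, 2], centers[, 2], "-")^2
  matrix(tps_U(d2), nrow(pts), nrow(centers))
}

#' Apply a transform to points
#'
#' @param t A `transform`.
#' @param pts N x 2 matrix of points (pixels).
#' @param refs Named list resolving reference transforms (usually a
#'   collection's `shared` registry).
#' @return N x 2 matrix of mapped points.
#' @export
tf_apply <- function(t, pts, refs = NULL) {
  pts <- as_pts(pts)
  if (nrow(pts) == 0) return(pts)
  if (any(!is.finite(pts))) stop("points must be finite")
  switch(t$kind,
    translation = cbind(pts[, 1] + t$tx, pts[, 2] + t$ty),
    rigid = ,
    similarity = ,
    affine = {
      af <- tf_as_affine(t)
      sweep(pts %*% t(af$M), 2, af$t, "+")
    },
    polynomial2 = {
      basis <- poly2_basis(pts)
      basis %*% t(t$coef)
    },
    thin_plate_spline = {
      U <- tps_kernel_matrix(pts, t$centers)
      sweep(pts %*% t(t$B), 2, t$a, "+") + U %*% t$w
    },
    reference = {
      if (is.null(refs) || is.null(refs[[t$ref_id]]))
        stop("unresolved reference transform: ", t$ref_id)
      tf_apply(refs[[t$ref_id]], pts, refs)
    },
    interpolated = {
      lb <- t$lambda_blend
      if (!is.finite(lb) || lb < 0 || lb > 1)
        stop("interpolated transform blend weight must be in [0, 1]")
      (1 - lb) * tf_apply(t$a, pts, refs) + lb * tf_apply(t$b, pts, refs)
    },
    stop("unknown transform kind: ", t$kind)
  )
}

poly2_basis <- function(pts) {
  cbind(1, pts[, 1], pts[, 2], pts[, 1]^2, pts[, 1] * pts[, 2], pts[, 2]^2)
}

#' Apply an ordered transform list to points
#'
#' Transforms compose first to last (local frame to global frame).
#'
#' @param tlist List of `transform` objects.
#' @inheritParams tf_apply
#' @return N x 2 matrix of mapped points.
#' @export
tf_apply_list <- function(tlist, pts, refs = NULL) {
  pts <- as_pts(pts)
  for (t in tlist) pts <- tf_apply(t, pts, refs)
  pts
}

#' Express a linear-family transform as an affine
#'
#' @param t A translation, rigid, similarity, or affine transform.
#' @return A list with elements `M` (2x2) and `t` (length 2).
#' @export
tf_as_affine <- function(t) {
  switch(t$kind,
    translation = list(M = diag(2), t = c(t$tx, t$ty)),
    rigid = list(M = rot2(t$theta), t = c(t$tx, t$ty)),
    similarity = list(M = t$s * rot2(t$theta), t = c(t$tx, t$ty)),
    affine = list(M = t$M, t = t$t),
    stop("transform kind '", t$kind, "' has no exact affine form")
  )
}

# Best-fit affine of an arbitrary transform over a frame, by least squares
# on a 4x4 sample grid; exact for affine-family inputs.
tf_affine_approx <- function(t, width = 1, height = 1, refs = NULL) {
  if (t$kind %in% c("translation", "rigid", "similarity", "affine"))
    return(tf_as_affine(t))
  gx <- seq(0, width, length.out = 4)
  gy <- seq(0, height, length.out = 4)
  g <- cbind(rep(gx, each = 4), rep(gy, times = 4))
  out <- tf_apply(t, g, refs)
  X <- cbind(g, 1)
  beta <- solve(crossprod(X), crossprod(X, out))
  list(M = t(beta[1:2, , drop = FALSE]), t = beta[3, ])
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Compose a list of affine-family transforms into one affine
#'
#' @param tlist List of translation/rigid/similarity/affine transforms,
#'   applied first to last.
#' @return A single affine `transform`.
#' @export
tf_compose_affine <- function(tlist) {
  M <- diag(2); tv <- c(0, 0)
  for (t in tlist) {
    af <- tf_as_affine(t)
    M <- af$M %*% M
    tv <- af$M %*% tv + af$t
  }
  tf_affine(M, as.numeric(tv))
}

#' Invert a transform
#'
#' Linear-family transforms invert analytically; thin plate splines invert
#' numerically with Newton iteration started from the inverse of the affine
#' part (tolerance 1e-6 px, at most 20 iterations).
#'
#' @param t A `transform`.
#' @param refs Reference registry for `reference` transforms.
#' @return For the linear family, an affine `transform`. For TPS (and any
#'   other kind), a function mapping N x 2 points back through the inverse.
#' @export
tf_invert <- function(t, refs = NULL) {
  if (t$kind %in% c("translation", "rigid", "similarity", "affine")) {
    af <- tf_as_affine(t)
    Mi <- solve(af$M)
    return(tf_affine(Mi, as.numeric(-Mi %*% af$t)))
  }
  if (t$kind == "reference") return(tf_invert(refs[[t$ref_id]], refs))
  function(pts) tf_invert_numeric(t, as_pts(pts), refs)
}

tf_invert_numeric <- function(t, pts, refs = NULL, tol = 1e-6, max_iter = 20) {
  # Newton iteration on p |-> T(p) - target, Jacobian by finite differences.
  guess <- if (t$kind == "thin_plate_spline") {
    Bi <- solve(t$B)
    sweep(pts, 2, t$a, "-") %*% t(Bi)
  } else pts
  h <- 1e-4
  for (it in seq_len(max_iter)) {
    f0 <- tf_apply(t, guess, refs) - pts
    if (max(abs(f0)) < tol) break
    fx <- (tf_apply(t, cbind(guess[, 1] + h, guess[, 2]), refs) -
           tf_apply(t, guess, refs)) / h
    fy <- (tf_apply(t, cbind(guess[, 1], guess[, 2] + h), refs) -
           tf_apply(t, guess, refs)) / h
    det <- fx[, 1] * fy[, 2] - fy[, 1] * fx[, 2]
    det[abs(det) < 1e-12] <- 1e-12
    dx <- (f0[, 1] * fy[, 2] - f0[, 2] * fy[, 1]) / det
    dy <- (fx[, 1] * f0[, 2] - fx[, 2] * f0[, 1]) / det
    guess <- cbind(guess[, 1] - dx, guess[, 2] - dy)
  }
  guess
}

#' Fit a transform to weighted point correspondences
#'
#' Direct weighted least-squares fits: translation by the weighted mean
#' displacement, rigid/similarity by closed-form orthogonal Procrustes with
#' `det(R) = +1` enforced, affine and polynomial by weighted normal
#' equations, thin plate spline by exact interpolation through `src` as
#' control points.
#'
#' @param kind One of `"translation"`, `"rigid"`, `"similarity"`,
#'   `"affine"`, `"polynomial2"`, `"thin_plate_spline"`.
#' @param src,dst N x 2 matrices of corresponding points.
#' @param weights Optional length-N positive weights (default all 1).
#' @return The fitted `transform`.
#' @export
fit_transform <- function(kind, src, dst, weights = NULL) {
  src <- as_pts(src); dst <- as_pts(dst)
  n <- nrow(src)
  if (nrow(dst) != n) stop("src and dst must have equal length")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop("weights length must match points")
  min_n <- c(translation = 1, rigid = 2, similarity = 2, affine = 3,
             polynomial2 = 6, thin_plate_spline = 3)[kind]
  if (is.na(min_n)) stop("cannot fit transform kind: ", kind)
  if (n < min_n) stop("need at least ", min_n, " points to fit ", kind)
  w <- weights / sum(weights)
  switch(kind,
    translation = {
      d <- dst - src
      tf_translation(sum(w * d[, 1]), sum(w * d[, 2]))
    },
    rigid = fit_procrustes(src, dst, w, scale = FALSE),
    similarity = fit_procrustes(src, dst, w, scale = TRUE),
    affine = {
      basis <- cbind(src, 1)
      beta <- weighted_lstsq(basis, dst, weights, kind)
      tf_affine(M = t(beta[1:2, , drop = FALSE]), t = beta[3, ])
    },
    polynomial2 = {
      basis <- poly2_basis(src)
      beta <- weighted_lstsq(basis, dst, weights, kind)
      tf_polynomial2(t(beta))
    },
    thin_plate_spline = fit_tps_interp(src, dst)
  )
}

weighted_lstsq <- function(X, Y, w, kind) {
  XtW <- t(X * w)
  G <- XtW %*% X
  if (rcond(G) < 1e-12)
    stop("degenerate point configuration (rank deficient) fitting ", kind)
  solve(G, XtW %*% Y)
}

fit_procrustes <- function(src, dst, w, scale = FALSE) {
  # Weighted Umeyama: rotation from SVD of the weighted cross-covariance,
  # det(R) = +1 enforced via sign correction of the smallest singular vector.
  mu_s <- colSums(src * w); mu_d <- colSums(dst * w)
  S <- sweep(src, 2, mu_s); D <- sweep(dst, 2, mu_d)
  C <- t(D * w) %*% S
  sv <- svd(C)
  sgn <- sign(det(sv$u %*% t(sv$v)))
  E <- diag(c(1, sgn))
  R <- sv$u %*% E %*% t(sv$v)
  theta <- atan2(R[2, 1], R[1, 1])
  if (scale) {
    var_s <- sum(w * rowSums(S^2))
    s <- sum(sv$d * diag(E)) / var_s
    tv <- mu_d - s * R %*% mu_s
    tf_similarity(s, theta, tv[1], tv[2])
  } else {
    tv <- mu_d - R %*% mu_s
    tf_rigid(theta, tv[1], tv[2])
  }
}

fit_tps_interp <- function(centers, targets, lambda = 0) {
  # Exact (lambda = 0) or lightly smoothed interpolating TPS through
  # centers -> targets: [[K + lambda I, P], [P', 0]] [w; a] = [targets; 0].
  K <- nrow(centers)
  S <- tps_system(centers, lambda)
  rhs <- rbind(targets, matrix(0, 3, 2))
  coef <- tryCatch(solve_equilibrated(S, rhs), error = function(e)
    stop("degenerate control-point configuration (rank deficient) fitting thin_plate_spline"))
  w <- coef[seq_len(K), , drop = FALSE]
  a <- coef[K + 1, ]
  B <- t(coef[(K + 2):(K + 3), , drop = FALSE])
  tf_tps(centers, a = a, B = B, w = w)
}

tps_system <- function(centers, lambda = 0) {
  K <- nrow(centers)
  Kmat <- tps_kernel_matrix(centers, centers) + diag(lambda, K)
  P <- cbind(1, centers)
  rbind(cbind(Kmat, P), cbind(t(P), matrix(0, 3, 3)))
}

# Symmetric diagonal equilibration: the TPS system mixes kernel entries of
# order width^2 log(width) with polynomial columns of order 1, which is
# numerically singular at raw pixel scales.
solve_equilibrated <- function(S, rhs) {
  d <- 1 / sqrt(pmax(apply(abs(S), 1, max), 1e-300))
  z <- solve(S * outer(d, d), rhs * d)
  z * d
}

# Linear evaluation operator of the interpolating TPS: row i gives weights
# over the K node target positions such that f(p_i) = E[i, ] %*% targets.
tps_eval_operator <- function(pts, centers) {
  K <- nrow(centers)
  S <- tps_system(centers)
  rhs <- rbind(diag(K), matrix(0, 3, K))
  Sinv_cols <- solve_equilibrated(S, rhs)
  cbind(tps_kernel_matrix(pts, centers), 1, pts) %*% Sinv_cols
}

#' Extract per-axis scale factors from an affine transform
#'
#' QR-style decomposition: `s_x` is the norm of the first column of the
#' linear part and `s_y = det(M) / s_x`, so shear does not inflate both
#' axes. Used for the tile-distortion MAD statistic.
#'
#' @param t An affine-family `transform`.
#' @return Named numeric vector `c(s_x, s_y)`.
#' @export
extract_scales <- function(t) {
  M <- tf_as_affine(t)$M
  dt <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  if (dt <= 0)
    stop("orientation-reversing affine (det <= 0); refusing to extract scales")
  s_x <- sqrt(M[1, 1]^2 + M[2, 1]^2)
  c(s_x = s_x, s_y = dt / s_x)
}
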