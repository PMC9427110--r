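# Tile-pair generation and robust point-correspondence computation:
# multiscale keypoint candidates -> locally optimized RANSAC consensus ->
# iterative 3-sigma residual trimming.

#' Generate candidate tile pairs
#'
#' Same-section pairs are tiles whose transformed footprints overlap by at
#' least `min_overlap_frac` of the tile area; cross-section pairs are
#' section pairs within `z_window`, skipping missing sections (so a gap of
#' several lost sections still yields pairs across it).
#'
#' @param coll A [tile_collection()] with current transforms.
#' @param z_window Maximum section distance for cross-section pairs (0
#'   disables them).
#' @param min_overlap_frac Minimum overlap area as a fraction of tile area.
#' @return Data frame: p_id, q_id, relation, overlap_frac (same-section
#'   rows) / dz (cross-section rows as `sec_<z>` pairs).
#' @export
generate_tile_pairs <- function(coll, z_window = 0, min_overlap_frac = 0.02) {
  ids <- names(coll$tiles)
  out <- list()
  if (length(ids) > 0) {
    feet <- lapply(ids, function(id) tile_footprint(coll, id))
    names(feet) <- ids
    bbox <- t(vapply(feet, function(f)
      c(min(f[, 1]), min(f[, 2]), max(f[, 1]), max(f[, 2])), numeric(4)))
    zs <- vapply(ids, function(id) coll$tiles[[id]]$z, integer(1))
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i || zs[i] != zs[j]) next
      if (bbox[i, 3] < bbox[j, 1] || bbox[j, 3] < bbox[i, 1] ||
          bbox[i, 4] < bbox[j, 2] || bbox[j, 4] < bbox[i, 2]) next
      area <- coll$tiles[[ids[i]]]$width * coll$tiles[[ids[i]]]$height
      frac <- overlap_area(feet[[ids[i]]], feet[[ids[j]]]) / area
      if (frac >= min_overlap_frac)
        out[[length(out) + 1]] <- data.frame(
          p_id = ids[i], q_id = ids[j], relation = "same_section",
          overlap_frac = frac, dz = 0L)
    }
  }
  if (z_window > 0) {
    secs <- coll$sections
    for (a in seq_along(secs)) for (b in seq_along(secs)) {
      if (b <= a) next
      dz <- secs[b] - secs[a]
      if (dz > z_window) next
      out[[length(out) + 1]] <- data.frame(
        p_id = sprintf("sec_%d", secs[a]), q_id = sprintf("sec_%d", secs[b]),
        relation = "cross_section", overlap_frac = NA_real_,
        dz = as.integer(dz))
    }
  }
  if (length(out) == 0)
    return(data.frame(p_id = character(0), q_id = character(0),
                      relation = character(0), overlap_frac = numeric(0),
                      dz = integer(0)))
  do.call(rbind, out)
}

# ---- keypoint detection and description ------------------------------------

# Difference-of-Gaussians keypoints over a small scale ladder with
# orientation-normalized, contrast-normalized patch descriptors. A
# lightweight stand-in for full SIFT with the same invariances (rotation
# via dominant gradient orientation, contrast via mean/sd normalization).
detect_keypoints <- function(img, n_scales = 4, sigma0 = 1.6,
                             contrast_thresh = 1.5, max_keypoints = 1500) {
  img <- as.matrix(img)
  sig <- sigma0 * 2^(seq_len(n_scales + 1) / 2 - 0.5)
  pyr <- lapply(sig, function(s) safe_gblur(img, s))
  kps <- list()
  for (k in seq_len(n_scales - 1) + 1) {
    d0 <- pyr[[k - 1]] - pyr[[k]]
    d1 <- pyr[[k]] - pyr[[k + 1]]
    m <- local_extrema(d1, contrast_thresh)
    if (nrow(m) == 0) next
    # 3D check against the neighboring DoG level at the same location
    keep <- abs(d1[m]) >= abs(d0[m])
    m <- m[keep, , drop = FALSE]
    if (nrow(m) == 0) next
    kps[[length(kps) + 1]] <- data.frame(
      x = m[, 2] - 1, y = m[, 1] - 1, sigma = sig[k],
      score = abs(d1[m]))
  }
  if (length(kps) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      score = numeric(0)))
  kp <- do.call(rbind, kps)
  kp <- kp[order(-kp$score), , drop = FALSE]
  head(kp, max_keypoints)
}

safe_gblur <- function(img, sigma) {
  # EBImage filters cannot exceed the image; fall back to identity when the
  # image is too small for the kernel.
  ks <- 2 * ceiling(3 * sigma) + 1
  if (ks > min(dim(img))) return(img)
  EBImage::gblur(img, sigma = sigma)
}

local_extrema <- function(d, thresh) {
  # strict 3x3 local maxima of |DoG| above the contrast threshold
  a <- abs(d)
  h <- nrow(a); w <- ncol(a)
  if (h < 3 || w < 3) return(cbind(integer(0), integer(0)))
  c0 <- a[2:(h - 1), 2:(w - 1)]
  is_max <- c0 > thresh
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & c0 >= a[2:(h - 1) + dy, 2:(w - 1) + dx]
  }
  idx <- which(is_max, arr.ind = TRUE)
  idx + 1  # offset back to full-image indices
}

keypoint_orientation <- function(img, kp) {
  # dominant gradient orientation in a window of ~3 sigma
  n <- nrow(kp)
  ori <- numeric(n)
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(n)) {
    r <- max(2, round(1.5 * kp$sigma[i]))
    x0 <- round(kp$x[i]); y0 <- round(kp$y[i])
    xs <- max(1, x0 - r + 1):min(w, x0 + r + 1)
    ys <- max(1, y0 - r + 1):min(h, y0 + r + 1)
    sub <- img[ys, xs, drop = FALSE]
    if (nrow(sub) < 3 || ncol(sub) < 3) { ori[i] <- 0; next }
    gx <- sub[2:(nrow(sub) - 1), 3:ncol(sub)] -
          sub[2:(nrow(sub) - 1), 1:(ncol(sub) - 2)]
    gy <- sub[3:nrow(sub), 2:(ncol(sub) - 1)] -
          sub[1:(nrow(sub) - 2), 2:(ncol(sub) - 1)]
    ori[i] <- atan2(sum(gy * abs(gy)), sum(gx * abs(gx)))
  }
  ori
}

describe_keypoints <- function(img, kp, patch = 8) {
  # patch x patch intensity samples on a rotated, scale-normalized grid,
  # mean/sd normalized for contrast invariance
  n <- nrow(kp)
  if (n == 0) return(matrix(numeric(0), 0, patch * patch))
  ori <- keypoint_orientation(img, kp)
  grid0 <- as.matrix(expand.grid(
    seq(-1, 1, length.out = patch), seq(-1, 1, length.out = patch)))
  desc <- matrix(NA_real_, n, patch * patch)
  for (i in seq_len(n)) {
    rad <- 4 * kp$sigma[i]
    R <- rot2(ori[i])
    g <- grid0 %*% t(R) * rad
    xs <- kp$x[i] + g[, 1]; ys <- kp$y[i] + g[, 2]
    v <- bilinear_sample(img, xs, ys)
    s <- sd(v)
    desc[i, ] <- if (s < 1e-9) 0 else (v - mean(v)) / s
  }
  desc
}

#' Detect correspondence candidates between two images
#'
#' Multiscale keypoints with rotation- and contrast-invariant descriptors
#' are matched by nearest neighbor with a ratio test; returns raw
#' candidates, unfiltered. Featureless images (fewer than 8 keypoints)
#' yield an empty set flagged `low_content`.
#'
#' @param img_p,img_q Grayscale image matrices.
#' @param ratio Nearest-neighbor ratio-test threshold.
#' @param max_keypoints Keypoint budget per image.
#' @return List: `P`, `Q` (N x 2 candidate coordinates, x/y pixel order),
#'   `low_content` flag.
#' @export
detect_candidates <- function(img_p, img_q, ratio = 0.92,
                              max_keypoints = 1500) {
  kp_p <- detect_keypoints(img_p, max_keypoints = max_keypoints)
  kp_q <- detect_keypoints(img_q, max_keypoints = max_keypoints)
  if (nrow(kp_p) < 8 || nrow(kp_q) < 8)
    return(list(P = matrix(numeric(0), 0, 2), Q = matrix(numeric(0), 0, 2),
                low_content = TRUE))
  dp <- describe_keypoints(img_p, kp_p)
  dq <- describe_keypoints(img_q, kp_q)
  # squared euclidean distances via the expansion trick
  d2 <- outer(rowSums(dp^2), rowSums(dq^2), "+") - 2 * dp %*% t(dq)
  sel <- integer(0); selq <- integer(0)
  for (i in seq_len(nrow(d2))) {
    o <- order(d2[i, ])[1:2]
    if (d2[i, o[1]] <= ratio^2 * d2[i, o[2]]) {
      sel <- c(sel, i); selq <- c(selq, o[1])
    }
  }
  # enforce one-to-one by keeping the best candidate per q keypoint
  if (length(sel) > 0) {
    qual <- d2[cbind(sel, selq)]
    ord <- order(qual)
    seen <- logical(nrow(kp_q)); keep <- logical(length(sel))
    for (k in ord) {
      if (!seen[selq[k]]) { seen[selq[k]] <- TRUE; keep[k] <- TRUE }
    }
    sel <- sel[keep]; selq <- selq[keep]
  }
  list(P = cbind(kp_p$x[sel], kp_p$y[sel]),
       Q = cbind(kp_q$x[selq], kp_q$y[selq]),
       low_content = FALSE)
}

model_min_n <- function(kind) {
  c(translation = 1, rigid = 2, similarity = 2, affine = 3,
    polynomial2 = 6)[kind]
}

#' Filter candidates with locally optimized RANSAC
#'
#' Classic RANSAC sampling of minimal candidate sets, but each hypothesis
#' is locally optimized: the transform is refit by least squares on all
#' current inliers and the inlier set updated, alternating until the set
#' is stable. The largest stable inlier set and its model win.
#'
#' @param P,Q N x 2 candidate coordinates.
#' @param model_kind Consensus model (default `"affine"`, the usual
#'   same-section choice; similarity tolerates section-scale rotations for
#'   cross-section pairs).
#' @param n_iter RANSAC hypothesis count.
#' @param inlier_tol Inlier residual tolerance in px.
#' @param min_inliers Minimum consensus size; below this the pair is
#'   flagged unmatchable.
#' @param seed Optional seed for reproducible sampling.
#' @return List: `inliers` (index vector into rows of P/Q), `model`
#'   (fitted transform or NULL), `unmatchable` flag.
#' @export
filter_matches_ransac <- function(P, Q, model_kind = "affine", n_iter = 200,
                                  inlier_tol = 3, min_inliers = 8,
                                  seed = NULL) {
  P <- as_pts(P); Q <- as_pts(Q)
  n <- nrow(P)
  mn <- model_min_n(model_kind)
  empty <- list(inliers = integer(0), model = NULL, unmatchable = TRUE)
  if (n < max(mn, min_inliers)) return(empty)
  run <- function() {
    best <- empty
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, mn)
      m <- tryCatch(fit_transform(model_kind, P[idx, , drop = FALSE],
                                  Q[idx, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(m)) next
      inl <- which(ransac_residuals(m, P, Q) <= inlier_tol)
      if (length(inl) < max(mn, min_inliers)) next
      # local optimization: alternate full-inlier refit and set update
      repeat {
        m2 <- tryCatch(fit_transform(model_kind, P[inl, , drop = FALSE],
                                     Q[inl, , drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(m2)) break
        inl2 <- which(ransac_residuals(m2, P, Q) <= inlier_tol)
        if (length(inl2) < mn) break
        if (identical(inl2, inl)) { m <- m2; break }
        inl <- inl2; m <- m2
      }
      if (length(inl) > length(best$inliers))
        best <- list(inliers = inl, model = m, unmatchable = FALSE)
    }
    if (length(best$inliers) < min_inliers) empty else best
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

ransac_residuals <- function(model, P, Q) {
  d <- tf_apply(model, P) - Q
  sqrt(rowSums(d^2))
}

#' Trim inliers by the 3-sigma residual rule
#'
#' Iteratively removes candidates whose residual magnitude exceeds the
#' mean plus 3 standard deviations of the residual distribution under the
#' current optimal transform, refitting after each pass, until no more
#' removals. Strict inequality and an n-1 sd denominator, so an
#' all-equal-residual set removes nothing; never trims below the model's
#' minimal sample size.
#'
#' @param P,Q N x 2 inlier coordinates.
#' @param model_kind Transform family to refit.
#' @param n_sigma Trim threshold in standard deviations.
#' @return List: `keep` (index vector into input rows), `model` (refitted
#'   transform or NULL for empty input), `flagged` (TRUE if trimming
#'   stopped to protect the minimal sample size).
#' @export
trim_matches <- function(P, Q, model_kind = "affine", n_sigma = 3) {
  P <- as_pts(P); Q <- as_pts(Q)
  keep <- seq_len(nrow(P))
  mn <- model_min_n(model_kind)
  if (length(keep) == 0)
    return(list(keep = integer(0), model = NULL, flagged = FALSE))
  if (length(keep) < mn)
    return(list(keep = keep, model = NULL, flagged = TRUE))
  model <- fit_transform(model_kind, P[keep, , drop = FALSE],
                         Q[keep, , drop = FALSE])
  repeat {
    r <- ransac_residuals(model, P[keep, , drop = FALSE],
                          Q[keep, , drop = FALSE])
    s <- if (length(r) > 1) sd(r) else 0
    thr <- mean(r) + n_sigma * s
    drop <- r > thr
    if (!any(drop)) break
    if (length(keep) - sum(drop) < mn)
      return(list(keep = keep, model = model, flagged = TRUE))
    keep <- keep[!drop]
    model <- fit_transform(model_kind, P[keep, , drop = FALSE],
                           Q[keep, , drop = FALSE])
  }
  list(keep = keep, model = model, flagged = FALSE)
}

#' Compute robust point matches for an image pair
#'
#' The full candidate -> consensus -> trim chain used by both same-section
#' and cross-section matching.
#'
#' @inheritParams detect_candidates
#' @inheritParams filter_matches_ransac
#' @return List: `P`, `Q` (trimmed matches), `model`, `low_content`,
#'   `unmatchable`.
#' @export
match_images <- function(img_p, img_q, model_kind = "affine", n_iter = 200,
                         inlier_tol = 3, min_inliers = 8, ratio = 0.92,
                         seed = NULL) {
  cand <- detect_candidates(img_p, img_q, ratio = ratio)
  if (cand$low_content || nrow(cand$P) < min_inliers)
    return(list(P = matrix(numeric(0), 0, 2), Q = matrix(numeric(0), 0, 2),
                model = NULL, low_content = cand$low_content,
                unmatchable = TRUE))
  f <- filter_matches_ransac(cand$P, cand$Q, model_kind, n_iter, inlier_tol,
                             min_inliers, seed = seed)
  if (f$unmatchable)
    return(list(P = matrix(numeric(0), 0, 2), Q = matrix(numeric(0), 0, 2),
                model = NULL, low_content = FALSE, unmatchable = TRUE))
  tr <- trim_matches(cand$P[f$inliers, , drop = FALSE],
                     cand$Q[f$inliers, , drop = FALSE], model_kind)
  idx <- f$inliers[tr$keep]
  list(P = cand$P[idx, , drop = FALSE], Q = cand$Q[idx, , drop = FALSE],
       model = tr$model, low_content = FALSE, unmatchable = FALSE)
}
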