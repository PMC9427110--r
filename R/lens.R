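# Shared thin-plate-spline lens-distortion correction, estimated from a
# high-overlap calibration montage by alternating montage solves and
# grid-averaged residual-disagreement fitting.

#' Estimate a shared lens-distortion correction
#'
#' Alternating estimation on a high-overlap calibration montage whose
#' matches are in raw (distorted) coordinates: (a) solve a per-tile affine
#' montage on the currently corrected coordinates; (b) regress every match
#' pair's disagreement vector onto the displacement field of a
#' `grid_n` x `grid_n` node grid over the tile frame (through the
#' interpolating-TPS evaluation operator, with a grid-Laplacian smoothness
#' penalty on the total field); (c) refit the interpolating TPS through
#' the updated nodes. Repeats until the largest grid-node update falls
#' below `tol` or `max_iter` is reached.
#'
#' The montage solves run stiff (`lambda_stiff` on the linear terms) for
#' most iterations so that field components a free affine montage would
#' silently absorb - notably quadratic terms - remain observable, then a
#' short soft phase (`lambda_soft`, `refine_iter` iterations) lets tiles
#' fit their own linear perturbations. The returned TPS is gauge-fixed to
#' zero mean displacement and unit mean scale over the grid, since any
#' affine component belongs to the montage transforms, not the lens.
#'
#' @param calib Calibration [tile_collection()] (overlap >= 0.3).
#' @param matches [point_match_set()] in raw tile coordinates.
#' @param grid_n Grid nodes per axis (minimum 5).
#' @param tol Convergence tolerance on grid-node updates (px).
#' @param max_iter Maximum alternations (including `refine_iter`).
#' @param lambda_stiff,lambda_soft Relative linear-term regularization of
#'   the inner montage solves in the two phases.
#' @param refine_iter Soft-phase iteration count.
#' @param smooth_beta Strength of the Laplacian smoothness penalty
#'   relative to the data term.
#' @return A thin-plate-spline `transform` mapping raw to corrected
#'   coordinates, with attribute `"iterations"`.
#' @export
estimate_lens_correction <- function(calib, matches, grid_n = 10, tol = 0.05,
                                     max_iter = 10, lambda_stiff = 10,
                                     lambda_soft = 0.01, refine_iter = 1,
                                     smooth_beta = 1) {
  if (grid_n < 5) stop("grid_n must be at least 5")
  ids <- names(calib$tiles)
  comp <- match_graph_components(matches$entries, ids)
  live <- comp[!is.na(comp)]
  if (length(unique(live)) > 1)
    stop("calibration montage pair graph is disconnected")
  w <- calib$tiles[[1]]$width; h <- calib$tiles[[1]]$height
  gx <- seq(0, w, length.out = grid_n)
  gy <- seq(0, h, length.out = grid_n)
  nodes <- cbind(rep(gx, each = grid_n), rep(gy, times = grid_n))
  smooth_Q <- grid_laplacian_form(grid_n)
  disp <- matrix(0, nrow(nodes), 2)  # current node displacement estimate
  z <- calib$sections[1]
  # Stiff phase: montage linear parts pinned near identity so that field
  # components a free affine montage could absorb (notably quadratic
  # terms) stay observable. Then a short soft phase lets tiles fit their
  # own linear perturbations and cleans up the remaining disagreement.
  iters <- 0
  for (phase in 1:2) {
    lam <- if (phase == 1) lambda_stiff else lambda_soft
    n_it <- if (phase == 1) max_iter - refine_iter else refine_iter
    opts <- solve_options(lambda_linear = lam)
    for (it in seq_len(n_it)) {
      lens_cur <- fit_tps_interp(nodes, nodes + disp)
      corrected <- correct_matches(matches, lens_cur)
      sol <- solve_montage(calib, corrected, opts, z = z)
      upd <- accumulate_disagreement(sol$coll, corrected, nodes, disp,
                                     smooth_Q, smooth_beta)
      disp <- gauge_fix_displacement(nodes, disp + upd)
      iters <- iters + 1
      if (max(sqrt(rowSums(upd^2))) < tol) break
    }
  }
  lens <- fit_tps_interp(nodes, nodes + disp)
  attr(lens, "iterations") <- iters
  lens
}

grid_laplacian_form <- function(grid_n) {
  # quadratic form of the 4-neighbor grid Laplacian; penalizes wiggly
  # (pitch-periodic, pair-unobservable) node patterns, not smooth fields
  idx <- function(ix, iy) (ix - 1) * grid_n + iy
  L <- matrix(0, grid_n^2, grid_n^2)
  k <- 0
  for (ix in seq_len(grid_n)) for (iy in seq_len(grid_n)) {
    k <- k + 1
    nb <- c(if (ix > 1) idx(ix - 1, iy), if (ix < grid_n) idx(ix + 1, iy),
            if (iy > 1) idx(ix, iy - 1), if (iy < grid_n) idx(ix, iy + 1))
    L[k, idx(ix, iy)] <- length(nb)
    L[k, nb] <- -1
  }
  crossprod(L)
}

correct_matches <- function(matches, lens) {
  entries <- lapply(matches$entries, function(e) {
    e$P <- tf_apply(lens, e$P)
    e$Q <- tf_apply(lens, e$Q)
    e
  })
  point_match_set(entries)
}

accumulate_disagreement <- function(coll, matches, nodes, disp, smooth_Q,
                                    smooth_beta) {
  # Linearized least-squares field update: moving node displacements by
  # delta changes each pair disagreement v_k = T_q(q) - T_p(p) by
  # approximately (E(q_k) - E(p_k)) delta (tile linear parts ~ identity),
  # so delta = argmin sum ||v_k + (E(q_k) - E(p_k)) delta||^2 + smoothness.
  # The Laplacian penalty suppresses tile-pitch-periodic node patterns
  # that pair disagreements cannot observe.
  Xs <- list(); vs <- list()
  for (e in matches$entries) {
    gp <- tile_map_points(coll, e$p_id, e$P)
    gq <- tile_map_points(coll, e$q_id, e$Q)
    Xs[[length(Xs) + 1]] <-
      tps_eval_operator(e$Q, nodes) - tps_eval_operator(e$P, nodes)
    vs[[length(vs) + 1]] <- gq - gp
  }
  X <- do.call(rbind, Xs)
  v <- do.call(rbind, vs)
  G <- crossprod(X)
  gm <- mean(diag(G))
  R <- smooth_beta * gm * smooth_Q / mean(diag(smooth_Q)) +
    diag(1e-4 * gm, ncol(G))
  # penalties act on the *total* field disp + delta, anchoring the
  # alternation against drift along pair-unobservable directions
  -solve(G + R, crossprod(X, v) + R %*% disp)
}

gauge_fix_displacement <- function(nodes, disp) {
  # remove the best-fit affine component of the displacement field: zero
  # mean displacement and unit mean scale, leaving only the nonlinear part
  X <- cbind(nodes, 1)
  beta <- solve(crossprod(X), crossprod(X, disp))
  disp - X %*% beta
}

#' Prepend the shared lens correction to every tile
#'
#' Installs the lens TPS in the collection's shared-transform registry and
#' prepends a reference transform to every tile in the matching lens
#' group. Idempotent: re-application replaces the reference rather than
#' stacking. Tiles of other groups are left untouched with a warning.
#'
#' @param coll A [tile_collection()].
#' @param lens The lens `transform` from [estimate_lens_correction()].
#' @param group_id Lens group to apply to (default: all tiles).
#' @param ref_id Registry key for the shared transform.
#' @return The updated collection, state `lens_corrected`.
#' @export
apply_lens_correction <- function(coll, lens, group_id = NULL,
                                  ref_id = "lens") {
  coll$shared[[ref_id]] <- lens
  skipped <- character(0)
  for (id in names(coll$tiles)) {
    tile <- coll$tiles[[id]]
    if (!is.null(group_id) && tile$group_id != group_id) {
      skipped <- c(skipped, id)
      next
    }
    tl <- tile$transforms
    if (length(tl) > 0 && tl[[1]]$kind == "reference") tl <- tl[-1]
    coll$tiles[[id]]$transforms <- c(list(tf_reference(ref_id)), tl)
  }
  if (length(skipped) > 0)
    warning(length(skipped), " tiles outside lens group '", group_id,
            "' left uncorrected")
  coll$state <- "lens_corrected"
  coll
}

#' Sample the lens displacement field on a grid
#'
#' Displacement `lens(p) - p` on a regular grid over the tile frame, for
#' quiver-style inspection of distortion magnitude and direction.
#'
#' @param lens A lens `transform`.
#' @param grid_n Grid nodes per axis.
#' @param width,height Tile frame extent (defaults to the TPS control-point
#'   bounding box).
#' @param png Optional path for a rendered quiver figure.
#' @return Data frame: x, y, dx, dy.
#' @export
distortion_quiver <- function(lens, grid_n = 10, width = NULL, height = NULL,
                              png = NULL) {
  if (is.null(width)) {
    if (lens$kind == "thin_plate_spline") {
      width <- max(lens$centers[, 1]); height <- max(lens$centers[, 2])
    } else stop("width/height required for non-TPS lens transforms")
  }
  gx <- seq(0, width, length.out = grid_n)
  gy <- seq(0, height, length.out = grid_n)
  g <- cbind(rep(gx, each = grid_n), rep(gy, times = grid_n))
  d <- tf_apply(lens, g) - g
  out <- data.frame(x = g[, 1], y = g[, 2], dx = d[, 1], dy = d[, 2])
  if (!is.null(png)) {
    grDevices::png(png, width = 700, height = 700)
    on.exit(grDevices::dev.off())
    sc <- max(1e-9, max(sqrt(d[, 1]^2 + d[, 2]^2)))
    len <- 0.04 * width / sc
    graphics::plot(NA, xlim = c(0, width), ylim = c(height, 0), asp = 1,
                   xlab = "x (px)", ylab = "y (px)",
                   main = "lens distortion field")
    ok <- sqrt(out$dx^2 + out$dy^2) > 1e-12
    graphics::arrows(out$x[ok], out$y[ok], out$x[ok] + out$dx[ok] * len,
                     out$y[ok] + out$dy[ok] * len, length = 0.05,
                     col = "firebrick")
  }
  out
}
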