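#' Solver options for montage and section alignment
#'
#' Regularization factors are specified relative to the mean diagonal of
#' `A' W A`, making them transferable across montage sizes; each parameter
#' class (translation / linear / polynomial) can be constrained separately.
#' Regularization always pulls toward the initialization `t0`, never toward
#' zero.
#'
#' @param model_kind `"translation"`, `"affine"`, `"polynomial2"`, or
#'   `"similarity"` (the joint rotational model used by the 3D stages).
#' @param lambda_translation,lambda_linear,lambda_polynomial Nonnegative
#'   relative regularization factors per parameter class.
#' @param init Initialization source: `"stage"` (nominal stage positions,
#'   identity linear part) or `"current"` (the tiles' present transforms).
#' @param tolerance Relative residual tolerance for the linear solve.
#' @param max_unknowns Guard against accidentally huge systems.
#' @return A `solve_options` object.
#' @export
solve_options <- function(model_kind = "affine", lambda_translation = 1e-5,
                          lambda_linear = 1e3, lambda_polynomial = 1e5,
                          init = "stage", tolerance = 1e-10,
                          max_unknowns = 2e5) {
  kinds <- c("translation", "affine", "polynomial2", "similarity")
  if (!model_kind %in% kinds)
    stop("unsupported model_kind: ", model_kind)
  lam <- c(lambda_translation, lambda_linear, lambda_polynomial)
  if (any(lam < 0)) stop("regularization factors must be nonnegative")
  if (all(lam == 0)) stop("at least one regularization factor must be positive")
  structure(list(model_kind = model_kind,
                 lambda_translation = lambda_translation,
                 lambda_linear = lambda_linear,
                 lambda_polynomial = lambda_polynomial,
                 init = init, tolerance = tolerance,
                 max_unknowns = max_unknowns),
            class = "solve_options")
}

model_nparam <- function(kind) {
  switch(kind, translation = 1, affine = 3, polynomial2 = 6,
         stop("no per-axis basis for model_kind ", kind))
}

model_basis <- function(kind, pts) {
  switch(kind,
    translation = matrix(1, nrow(pts), 1),
    affine = cbind(pts, 1),
    polynomial2 = poly2_basis(pts))
}

# lambda class per column: translation columns get lambda_translation, etc.
model_lambda_classes <- function(kind) {
  switch(kind,
    translation = "t",
    affine = c("l", "l", "t"),
    polynomial2 = c("t", "l", "l", "p", "p", "p"))
}

model_t0 <- function(kind, af) {
  # af: list(M, t) affine initialization; returns list(x =, y =) parameter
  # vectors reproducing it (quadratic terms zero).
  switch(kind,
    translation = list(x = af$t[1], y = af$t[2]),
    affine = list(x = c(af$M[1, 1], af$M[1, 2], af$t[1]),
                  y = c(af$M[2, 1], af$M[2, 2], af$t[2])),
    polynomial2 = list(x = c(af$t[1], af$M[1, 1], af$M[1, 2], 0, 0, 0),
                       y = c(af$t[2], af$M[2, 1], af$M[2, 2], 0, 0, 0)))
}

params_to_transform <- function(kind, px, py) {
  switch(kind,
    translation = tf_translation(px[1], py[1]),
    affine = tf_affine(M = rbind(c(px[1], px[2]), c(py[1], py[2])),
                       t = c(px[3], py[3])),
    polynomial2 = tf_polynomial2(rbind(px, py)))
}

tile_init_affine <- function(coll, tile, init) {
  if (init == "stage") {
    list(M = diag(2), t = tile$stage_position)
  } else {
    tlist <- tile$transforms
    if (length(tlist) > 0 && tlist[[1]]$kind == "reference")
      tlist <- tlist[-1]
    if (length(tlist) == 0) return(list(M = diag(2), t = tile$stage_position))
    chain_affine_approx(tlist, tile$width, tile$height, coll$shared)
  }
}

#' Assemble the regularized least-squares system for a montage
#'
#' One row per correspondence point: for a match between tiles i and j the
#' row encodes `T_i(p) - T_j(q) = 0` in the model's per-axis basis, with
#' positive basis entries in tile i's column block and negative in tile
#' j's. The x and y axes share the constraint matrix `A`; right-hand sides
#' are zero for in-section montages. Tiles with no correspondences are
#' excluded and reported as dropped.
#'
#' @param matches A [point_match_set()] in lens-corrected local frames.
#' @param coll The [tile_collection()] being solved.
#' @param opts A [solve_options()].
#' @return A `solve_system` with sparse `A`, weight vector `W`, per-axis
#'   right-hand sides and initializations, absolute `lambda_diag`, the
#'   tile-to-column index map, and the dropped-tile list.
#' @export
assemble_system <- function(matches, coll, opts = solve_options()) {
  kind <- opts$model_kind
  np <- model_nparam(kind)
  ids_all <- names(coll$tiles)
  counts <- setNames(numeric(length(ids_all)), ids_all)
  use <- vapply(matches$entries, function(e)
    e$p_id %in% ids_all && e$q_id %in% ids_all, logical(1))
  entries <- matches$entries[use]
  for (e in entries) {
    counts[e$p_id] <- counts[e$p_id] + nrow(e$P)
    counts[e$q_id] <- counts[e$q_id] + nrow(e$Q)
  }
  solved_ids <- ids_all[counts > 0]
  dropped <- ids_all[counts == 0]
  n <- length(solved_ids) * np
  if (n == 0) stop("no tiles with correspondences to solve")
  if (n > opts$max_unknowns) stop("system exceeds max_unknowns")
  col_of <- setNames((seq_along(solved_ids) - 1) * np, solved_ids)

  m_tot <- sum(vapply(entries, function(e) nrow(e$P), integer(1)))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  W <- numeric(m_tot)
  row0 <- 0
  for (e in entries) {
    N <- nrow(e$P)
    if (N == 0) next
    bp <- model_basis(kind, e$P)
    bq <- model_basis(kind, e$Q)
    rows <- row0 + seq_len(N)
    ii <- c(ii, rep(rows, np), rep(rows, np))
    jj <- c(jj, rep(col_of[e$p_id] + seq_len(np), each = N),
                rep(col_of[e$q_id] + seq_len(np), each = N))
    xx <- c(xx, as.numeric(bp), -as.numeric(bq))
    W[rows] <- e$w
    row0 <- row0 + N
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m_tot, n))

  t0_x <- numeric(n); t0_y <- numeric(n)
  for (id in solved_ids) {
    af <- tile_init_affine(coll, coll$tiles[[id]], opts$init)
    t0 <- model_t0(kind, af)
    t0_x[col_of[id] + seq_len(np)] <- t0$x
    t0_y[col_of[id] + seq_len(np)] <- t0$y
  }
  sys <- structure(list(A = A, W = W,
                        b_x = numeric(m_tot), b_y = numeric(m_tot),
                        t0_x = t0_x, t0_y = t0_y,
                        model_kind = kind, col_of = col_of, nparam = np,
                        dropped = dropped, tolerance = opts$tolerance),
                   class = "solve_system")
  sys$gram_diag <- Matrix::diag(system_gram(sys))
  sys <- set_system_lambda(sys, opts)
  sys
}

# Best-fit affine of a whole transform chain over the tile frame.
chain_affine_approx <- function(tlist, width, height, refs = NULL) {
  ok <- all(vapply(tlist, function(t)
    t$kind %in% c("translation", "rigid", "similarity", "affine"), logical(1)))
  if (ok) return(tf_as_affine(tf_compose_affine(tlist)))
  gx <- seq(0, width, length.out = 4)
  gy <- seq(0, height, length.out = 4)
  g <- cbind(rep(gx, each = 4), rep(gy, times = 4))
  out <- tf_apply_list(tlist, g, refs)
  X <- cbind(g, 1)
  beta <- solve(crossprod(X), crossprod(X, out))
  list(M = t(beta[1:2, , drop = FALSE]), t = beta[3, ])
}

system_gram <- function(sys) {
  Matrix::crossprod(sys$A, sys$A * sys$W)
}

# Absolute per-column regularization from the relative factors in opts.
# Each parameter class is scaled by the mean gram diagonal of its own
# columns, so "relative" is meaningful per class (translation columns have
# O(1) basis entries while linear columns carry O(width^2)).
set_system_lambda <- function(sys, opts) {
  classes <- rep(model_lambda_classes(sys$model_kind),
                 times = length(sys$col_of))
  rel <- c(t = opts$lambda_translation, l = opts$lambda_linear,
           p = opts$lambda_polynomial)[classes]
  class_scale <- vapply(c(t = "t", l = "l", p = "p"), function(cl) {
    cols <- classes == cl
    if (any(cols)) mean(sys$gram_diag[cols]) else 0
  }, numeric(1))
  sys$lambda_diag <- as.numeric(rel) * class_scale[classes]
  if (all(sys$lambda_diag == 0))
    stop("all regularization factors are zero; K may be singular ",
         "(gauge freedom) - set at least one lambda > 0")
  sys
}

#' Solve the regularized normal equations
#'
#' Solves `K t = L` with `K = A' W A + Lambda` and
#' `L = Lambda t0 + A' W b` for each axis by sparse Cholesky
#' factorization, verifying the relative residual against the system
#' tolerance.
#'
#' @param sys A `solve_system` from [assemble_system()].
#' @return List with solution vectors `t_x`, `t_y`.
#' @export
solve_regularized <- function(sys) {
  if (all(sys$W == 0)) {
    # K = Lambda and L = Lambda t0: the solution is the initialization,
    # exactly
    return(list(t_x = sys$t0_x, t_y = sys$t0_y))
  }
  K <- system_gram(sys) + Matrix::Diagonal(x = sys$lambda_diag)
  AtW <- Matrix::t(sys$A * sys$W)
  L_x <- sys$lambda_diag * sys$t0_x + as.numeric(AtW %*% sys$b_x)
  L_y <- sys$lambda_diag * sys$t0_y + as.numeric(AtW %*% sys$b_y)
  K <- Matrix::forceSymmetric(K)
  fac <- tryCatch(Matrix::Cholesky(K, LDL = FALSE),
                  error = function(e)
                    stop("K is numerically singular; increase a lambda"))
  t_x <- as.numeric(Matrix::solve(fac, L_x))
  t_y <- as.numeric(Matrix::solve(fac, L_y))
  for (ax in list(list(t_x, L_x), list(t_y, L_y))) {
    Kt <- as.numeric(K %*% ax[[1]])
    denom <- max(sqrt(sum(ax[[2]]^2)), sqrt(sum(Kt^2)), 1e-300)
    rel <- sqrt(sum((Kt - ax[[2]])^2)) / denom
    if (rel > max(sys$tolerance, 1e-8) * 100)
      warning("solver relative residual ", format(rel), " above tolerance")
  }
  list(t_x = t_x, t_y = t_y)
}

extract_tile_transforms <- function(sys, sol) {
  np <- sys$nparam
  out <- list()
  for (id in names(sys$col_of)) {
    idx <- sys$col_of[id] + seq_len(np)
    out[[id]] <- params_to_transform(sys$model_kind, sol$t_x[idx], sol$t_y[idx])
  }
  out
}

match_graph_components <- function(entries, ids) {
  # connected components of the pair graph over `ids`, simple BFS
  adj <- setNames(vector("list", length(ids)), ids)
  for (e in entries) {
    if (!(e$p_id %in% ids) || !(e$q_id %in% ids) || nrow(e$P) == 0) next
    adj[[e$p_id]] <- c(adj[[e$p_id]], e$q_id)
    adj[[e$q_id]] <- c(adj[[e$q_id]], e$p_id)
  }
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  k <- 0
  for (id in ids) {
    if (!is.na(comp[id])) next
    k <- k + 1
    queue <- id
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, setdiff(adj[[v]], names(comp)[!is.na(comp)]))
    }
  }
  comp
}

#' Solve one section's 2D montage
#'
#' Assembles and solves the regularized system for section `z`, writes the
#' solved per-tile transforms into the tile specs (preserving a leading
#' lens reference transform), and summarizes residuals. Tiles with zero
#' correspondences (featureless resin/vessel tiles) are dropped. A
#' disconnected pair graph is solved jointly (the regularization keeps the
#' system definite) but flagged.
#'
#' @param coll A [tile_collection()], state at least lens-corrected.
#' @param matches Same-section [point_match_set()] in lens-corrected
#'   coordinates.
#' @param opts A [solve_options()].
#' @param z Section index to solve.
#' @return List: updated `coll`, per-tile `transforms`, `dropped`,
#'   `residuals` (per-pair stats), `median_residual`, `n_components`.
#' @export
solve_montage <- function(coll, matches, opts = solve_options(), z = NULL) {
  if (is.null(z)) z <- coll$sections[1]
  sec_ids <- names(coll$tiles)[vapply(coll$tiles, function(t) t$z == z,
                                      logical(1))]
  sec <- coll
  sec$tiles <- coll$tiles[sec_ids]
  sys <- assemble_system(matches, sec, opts)
  sol <- solve_regularized(sys)
  tfs <- extract_tile_transforms(sys, sol)
  comp <- match_graph_components(matches$entries, names(sys$col_of))
  for (id in names(tfs)) {
    old <- coll$tiles[[id]]$transforms
    lens <- if (length(old) > 0 && old[[1]]$kind == "reference") old[1] else list()
    coll$tiles[[id]]$transforms <- c(lens, list(tfs[[id]]))
  }
  coll$state <- "montaged"
  stats <- pair_residuals(coll, matches)
  list(coll = coll, transforms = tfs, dropped = sys$dropped,
       residuals = stats,
       median_residual = stats$section_median,
       n_components = max(comp, na.rm = TRUE))
}

# ---- per-section (3D) solving ----------------------------------------------

section_frames <- function(coll) {
  # bounding box of each section's montaged footprint, used as the virtual
  # section-tile frame for cross-section matches
  out <- list()
  for (z in coll$sections) {
    ids <- names(coll$tiles)[vapply(coll$tiles, function(t) t$z == z,
                                    logical(1))]
    pts <- do.call(rbind, lapply(ids, function(id) tile_footprint(coll, id)))
    out[[as.character(z)]] <- c(min(pts[, 1]), min(pts[, 2]),
                                max(pts[, 1]), max(pts[, 2]))
  }
  out
}

section_id_z <- function(id) as.integer(sub("^sec_", "", id))

# Assemble & solve one per-section stage. model: "similarity" (joint x/y,
# later re-orthogonalized for the rigid stage), "affine", or "tps".
# init: named list z -> transform used both as t0 and, for tps, to place
# node targets. lambda_mult: named per-z multiplier on the regularization.
solve_sections_stage <- function(cross_matches, frames, model, opts,
                                 init, lambda_mult = NULL, rigid = FALSE,
                                 grid_nodes = 25) {
  zs <- as.integer(names(frames))
  sec_ids <- sprintf("sec_%d", zs)
  entries <- Filter(function(e) e$p_id %in% sec_ids && e$q_id %in% sec_ids,
                    cross_matches$entries)
  if (length(entries) == 0) stop("no cross-section matches within the solved set")
  lam_of <- function(z) if (is.null(lambda_mult)) 1 else
    (lambda_mult[[as.character(z)]] %||% 1)

  if (model == "similarity") {
    np <- 4  # a, b, tx, ty with x' = a x - b y + tx ; y' = b x + a y + ty
    col_of <- setNames((seq_along(zs) - 1) * np, as.character(zs))
    m_tot <- 2 * sum(vapply(entries, function(e) nrow(e$P), integer(1)))
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    W <- numeric(m_tot); row0 <- 0
    for (e in entries) {
      N <- nrow(e$P)
      za <- as.character(section_id_z(e$p_id))
      zb <- as.character(section_id_z(e$q_id))
      ca <- col_of[za]; cb <- col_of[zb]
      rx <- row0 + seq_len(N); ry <- row0 + N + seq_len(N)
      add <- function(rows, cols, vals) {
        ii <<- c(ii, rows); jj <<- c(jj, cols); xx <<- c(xx, vals)
      }
      add(rep(rx, 3), rep(ca + c(1, 2, 3), each = N),
          c(e$P[, 1], -e$P[, 2], rep(1, N)))
      add(rep(rx, 3), rep(cb + c(1, 2, 3), each = N),
          c(-e$Q[, 1], e$Q[, 2], rep(-1, N)))
      add(rep(ry, 3), rep(ca + c(1, 2, 4), each = N),
          c(e$P[, 2], e$P[, 1], rep(1, N)))
      add(rep(ry, 3), rep(cb + c(1, 2, 4), each = N),
          c(-e$Q[, 2], -e$Q[, 1], rep(-1, N)))
      W[c(rx, ry)] <- rep(e$w, 2)
      row0 <- row0 + 2 * N
    }
    n <- length(zs) * np
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m_tot, n))
    t0 <- numeric(n); lam_class <- character(n)
    for (z in zs) {
      fr <- frames[[as.character(z)]]
      af <- tf_affine_approx(init[[as.character(z)]],
                             width = fr[3] - fr[1], height = fr[4] - fr[2])
      # similarity projection of the init affine
      a <- (af$M[1, 1] + af$M[2, 2]) / 2
      b <- (af$M[2, 1] - af$M[1, 2]) / 2
      t0[col_of[as.character(z)] + 1:4] <- c(a, b, af$t)
      lam_class[col_of[as.character(z)] + 1:4] <- c("l", "l", "t", "t")
    }
    gd <- Matrix::diag(Matrix::crossprod(A, A * W))
    scale_l <- mean(gd[lam_class == "l"]); scale_t <- mean(gd[lam_class == "t"])
    rel <- ifelse(lam_class == "l", opts$lambda_linear * scale_l,
                  opts$lambda_translation * scale_t)
    mult <- vapply(zs, lam_of, numeric(1))[rep(seq_along(zs), each = np)]
    lam <- rel * mult
    sys <- structure(list(A = A, W = W, b_x = numeric(m_tot),
                          b_y = NULL, t0_x = t0, t0_y = NULL,
                          lambda_diag = lam, tolerance = opts$tolerance),
                     class = "solve_system")
    K <- Matrix::forceSymmetric(Matrix::crossprod(A, A * W) +
                                Matrix::Diagonal(x = lam))
    sol <- as.numeric(Matrix::solve(K, lam * t0))
    out <- list()
    for (z in zs) {
      p <- sol[col_of[as.character(z)] + 1:4]
      if (rigid) {
        s <- sqrt(p[1]^2 + p[2]^2)
        if (s > 0) { p[1] <- p[1] / s; p[2] <- p[2] / s }
      }
      out[[as.character(z)]] <- tf_affine(rbind(c(p[1], -p[2]),
                                                c(p[2], p[1])),
                                          c(p[3], p[4]))
    }
    return(out)
  }

  if (model == "affine") {
    coll <- section_virtual_collection(frames, init)
    opts2 <- opts; opts2$model_kind <- "affine"; opts2$init <- "current"
    sys <- assemble_system(point_match_set(entries), coll, opts2)
    if (!is.null(lambda_mult)) {
      mult <- vapply(names(sys$col_of),
                     function(id) lam_of(section_id_z(id)), numeric(1))
      sys$lambda_diag <- sys$lambda_diag * rep(mult, each = sys$nparam)
    }
    sol <- solve_regularized(sys)
    tfs <- extract_tile_transforms(sys, sol)
    out <- list()
    for (id in names(tfs)) out[[as.character(section_id_z(id))]] <- tfs[[id]]
    # sections absent from the system keep their init
    for (z in zs) if (is.null(out[[as.character(z)]]))
      out[[as.character(z)]] <- init[[as.character(z)]]
    return(out)
  }

  if (model == "tps") {
    if (grid_nodes < 25 || grid_nodes > 49)
      stop("TPS stage requires 25-49 control nodes per section")
    gn <- floor(sqrt(grid_nodes))
    if (gn * gn != grid_nodes)
      stop("grid_nodes must be a perfect square (rectangular grid), e.g. 25, 36, 49")
    nodes <- list(); Eop <- list()
    for (z in zs) {
      fr <- frames[[as.character(z)]]
      gx <- seq(fr[1], fr[3], length.out = gn)
      gy <- seq(fr[2], fr[4], length.out = gn)
      nd <- cbind(rep(gx, each = gn), rep(gy, times = gn))
      nodes[[as.character(z)]] <- nd
    }
    np <- grid_nodes
    col_of <- setNames((seq_along(zs) - 1) * np, as.character(zs))
    m_tot <- sum(vapply(entries, function(e) nrow(e$P), integer(1)))
    n <- length(zs) * np
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    W <- numeric(m_tot); row0 <- 0
    for (e in entries) {
      N <- nrow(e$P)
      za <- as.character(section_id_z(e$p_id))
      zb <- as.character(section_id_z(e$q_id))
      Ea <- tps_eval_operator(e$P, nodes[[za]])
      Eb <- tps_eval_operator(e$Q, nodes[[zb]])
      rows <- row0 + seq_len(N)
      ii <- c(ii, rep(rows, np), rep(rows, np))
      jj <- c(jj, rep(col_of[za] + seq_len(np), each = N),
                  rep(col_of[zb] + seq_len(np), each = N))
      xx <- c(xx, as.numeric(Ea), -as.numeric(Eb))
      W[rows] <- e$w
      row0 <- row0 + N
    }
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m_tot, n))
    t0_x <- numeric(n); t0_y <- numeric(n)
    for (z in zs) {
      tgt <- tf_apply(init[[as.character(z)]], nodes[[as.character(z)]])
      t0_x[col_of[as.character(z)] + seq_len(np)] <- tgt[, 1]
      t0_y[col_of[as.character(z)] + seq_len(np)] <- tgt[, 2]
    }
    gram <- Matrix::crossprod(A, A * W)
    gmean <- mean(Matrix::diag(gram))
    mult <- vapply(zs, lam_of, numeric(1))[rep(seq_along(zs), each = np)]
    lam <- opts$lambda_polynomial * mult * gmean
    K <- Matrix::forceSymmetric(gram + Matrix::Diagonal(x = lam))
    fac <- Matrix::Cholesky(K, LDL = FALSE)
    t_x <- as.numeric(Matrix::solve(fac, lam * t0_x))
    t_y <- as.numeric(Matrix::solve(fac, lam * t0_y))
    out <- list()
    for (z in zs) {
      idx <- col_of[as.character(z)] + seq_len(np)
      out[[as.character(z)]] <- fit_tps_interp(nodes[[as.character(z)]],
                                               cbind(t_x[idx], t_y[idx]))
    }
    return(out)
  }
  stop("unknown per-section model: ", model)
}

section_virtual_collection <- function(frames, init) {
  tiles <- lapply(names(frames), function(zc) {
    fr <- frames[[zc]]
    ts <- tilespec(tile_id = sprintf("sec_%s", zc), z = as.integer(zc),
                   width = max(fr[3] - fr[1], 1),
                   height = max(fr[4] - fr[2], 1),
                   stage_position = c(0, 0),
                   transforms = list(init[[zc]]))
    ts
  })
  tile_collection("sections", tiles)
}

cross_match_residuals <- function(entries, transforms) {
  res <- numeric(0)
  for (e in entries) {
    Ta <- transforms[[as.character(section_id_z(e$p_id))]]
    Tb <- transforms[[as.character(section_id_z(e$q_id))]]
    if (is.null(Ta) || is.null(Tb)) next
    d <- tf_apply(Ta, e$P) - tf_apply(Tb, e$Q)
    res <- c(res, sqrt(rowSums(d^2)))
  }
  res
}

#' Progressive per-section 3D alignment
#'
#' A progressive sequence of rotational, affine, and thin-plate-spline
#' per-section solves: each stage is initialized by (and regularized
#' toward) the previous stage's solution, with the later, more deformable
#' stages increasingly regularized. The rotational stage solves a joint
#' linear similarity system and re-orthogonalizes to unit scale; the TPS
#' stage solves for the positions of a rectangular grid of 25-49 control
#' nodes per section.
#'
#' @param frames Named list (by z) of section bounding boxes
#'   `c(xmin, ymin, xmax, ymax)` in montaged full-resolution coordinates,
#'   e.g. from [section_frames()].
#' @param cross_matches Cross-section [point_match_set()] against virtual
#'   `sec_<z>` tiles in those frames.
#' @param stages Character vector, a prefix of
#'   `c("rigid", "affine", "thin_plate_spline")`.
#' @param opts A [solve_options()]; `lambda_linear` governs the rigid and
#'   affine stages, `lambda_polynomial` the TPS node regularization.
#' @param grid_nodes TPS control nodes per section (25-49, perfect square).
#' @param init Optional named list (by z) of starting per-section
#'   transforms (defaults to identity).
#' @param lambda_mult Optional named per-z multiplier on the regularization
#'   (used by [realign_subset()] to freeze neighbor sections).
#' @return List with `transforms` (named by z, final stage), `stage_medians`
#'   (median cross-section residual after each stage), and `stages`.
#' @export
solve_sections_progressive <- function(frames, cross_matches,
                                       stages = c("rigid", "affine",
                                                  "thin_plate_spline"),
                                       opts = solve_options(
                                         lambda_translation = 1e-7,
                                         lambda_linear = 1e-3,
                                         lambda_polynomial = 1e-2),
                                       grid_nodes = 25, init = NULL,
                                       lambda_mult = NULL) {
  zs <- as.integer(names(frames))
  if (is.null(init))
    init <- setNames(lapply(zs, function(z) tf_affine()), as.character(zs))
  if (length(zs) == 1)
    return(list(transforms = init, stage_medians = numeric(0), stages = character(0)))
  cur <- init
  meds <- setNames(numeric(length(stages)), stages)
  for (st in stages) {
    cur <- switch(st,
      rigid = solve_sections_stage(cross_matches, frames, "similarity", opts,
                                   init = cur, lambda_mult = lambda_mult,
                                   rigid = TRUE),
      affine = solve_sections_stage(cross_matches, frames, "affine", opts,
                                    init = cur, lambda_mult = lambda_mult),
      thin_plate_spline = solve_sections_stage(cross_matches, frames, "tps",
                                               opts, init = cur,
                                               lambda_mult = lambda_mult,
                                               grid_nodes = grid_nodes),
      stop("unknown stage: ", st))
    meds[st] <- median(cross_match_residuals(cross_matches$entries, cur))
  }
  list(transforms = cur, stage_medians = meds, stages = stages)
}

#' Re-align a subset of sections within an existing 3D alignment
#'
#' Re-solves only the requested sections plus a neighbor margin; the
#' margin sections' regularization is multiplied by `boost_factor` so they
#' stay effectively pinned to their current transforms, and sections
#' outside the margin are untouched.
#'
#' @param frames Section frames as in [solve_sections_progressive()].
#' @param cross_matches Cross-section matches.
#' @param current Named list (by z) of current per-section transforms.
#' @param z_set Integer sections to re-align.
#' @param boost_factor Regularization multiplier for margin neighbors.
#' @param margin How many neighbor sections (each side) to include, pinned.
#' @param ... Passed to [solve_sections_progressive()].
#' @return As [solve_sections_progressive()], with untouched sections
#'   carried through unchanged.
#' @export
realign_subset <- function(frames, cross_matches, current, z_set,
                           boost_factor = 1e6, margin = 2, ...) {
  zs <- as.integer(names(frames))
  missing <- setdiff(z_set, zs)
  if (length(missing) > 0)
    stop("z_set sections not in stack: ", paste(missing, collapse = ", "))
  if (length(z_set) == 0)
    return(list(transforms = current, stage_medians = numeric(0),
                stages = character(0)))
  in_margin <- zs[vapply(zs, function(z)
    any(abs(z - z_set) <= margin), logical(1))]
  sub_frames <- frames[as.character(in_margin)]
  lambda_mult <- setNames(
    lapply(in_margin, function(z) if (z %in% z_set) 1 else boost_factor),
    as.character(in_margin))
  res <- solve_sections_progressive(sub_frames, cross_matches,
                                    init = current[as.character(in_margin)],
                                    lambda_mult = lambda_mult, ...)
  out <- current
  for (zc in names(res$transforms)) out[[zc]] <- res$transforms[[zc]]
  list(transforms = out, stage_medians = res$stage_medians,
       stages = res$stages, realigned = in_margin)
}
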