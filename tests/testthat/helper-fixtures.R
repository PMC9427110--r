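# Shared fixtures: small synthetic sections, solved montages, and the
# gauge-aligned comparison used by parameter-recovery tests.

fixture_section <- function(rows = 3, cols = 3, tile_size = 300,
                            noise = 1, seed = 8, ...) {
  spec <- synthetic_spec(rows = rows, cols = cols, tile_size = tile_size,
                         translation_sd = 5, rotation_sd = 0.002,
                         scale_sd = 0.005, match_noise_sd = noise,
                         seed = seed, ...)
  sec <- make_section(spec, 0)
  sec$matches <- make_matches(sec$truth)
  sec$spec <- spec
  sec
}

# collection carrying the ground-truth transforms (the ideal solution)
truth_collection <- function(sec) {
  coll <- sec$coll
  for (id in names(coll$tiles))
    coll$tiles[[id]]$transforms <- list(sec$truth$transforms[[id]])
  coll
}

# max tile-corner error between solved and truth transforms after removing
# the global affine gauge (fit over all corners jointly)
gauge_corner_error <- function(solved_tfs, truth_tfs, tile_size) {
  ids <- names(solved_tfs)
  corners <- rbind(c(0, 0), c(tile_size, 0), c(tile_size, tile_size),
                   c(0, tile_size))
  S <- do.call(rbind, lapply(ids, function(id) tf_apply(solved_tfs[[id]], corners)))
  Tm <- do.call(rbind, lapply(ids, function(id) tf_apply(truth_tfs[[id]], corners)))
  g <- fit_transform("affine", S, Tm)
  max(sqrt(rowSums((tf_apply(g, S) - Tm)^2)))
}

# dense normal-equations oracle for a solve_system (one axis)
dense_solve_axis <- function(sys, b, t0) {
  Ad <- as.matrix(sys$A)
  K <- t(Ad) %*% (Ad * sys$W) + diag(sys$lambda_diag)
  as.numeric(solve(K, sys$lambda_diag * t0 + t(Ad) %*% (sys$W * b)))
}

radial_k1_for_corner_displacement <- function(tile_size, disp = 12) {
  r_corner <- tile_size / 2 * sqrt(2)
  disp / r_corner^3
}

calibration_fixture <- function(tile_size = 400, seed = 4, k1 = NULL) {
  if (is.null(k1)) k1 <- radial_k1_for_corner_displacement(tile_size)
  spec <- synthetic_spec(rows = 3, cols = 3, tile_size = tile_size,
                         overlap_frac = 0.5, translation_sd = 2,
                         rotation_sd = 5e-4, scale_sd = 1e-3,
                         match_noise_sd = 0.25, matches_per_pair = 60,
                         lens_model = list(kind = "radial", k1 = k1),
                         seed = seed)
  cal <- make_calibration_montage(spec)
  cal$matches_raw <- make_matches(cal$truth, frame = "raw")
  cal$spec <- spec
  cal
}

# truth lens-correction displacement on a grid, gauge-normalized the same
# way the estimator normalizes its field
truth_correction_field <- function(spec, grid_n = 10) {
  s <- spec$tile_size
  gx <- seq(0, s, length.out = grid_n)
  g <- cbind(rep(gx, each = grid_n), rep(gx, times = grid_n))
  d <- stitchforge:::lens_undistort(spec, g) - g
  list(grid = g, disp = stitchforge:::gauge_fix_displacement(g, d))
}

fixture_series <- function(n_sections = 4, seed = 7,
                           section_rotation_sd = 0.01,
                           section_translation_sd = 20, ...) {
  spec <- synthetic_spec(rows = 3, cols = 3, tile_size = 300,
                         n_sections = n_sections, translation_sd = 5,
                         match_noise_sd = 0,
                         section_rotation_sd = section_rotation_sd,
                         section_translation_sd = section_translation_sd,
                         seed = seed, ...)
  ser <- make_series(spec)
  ser$spec <- spec
  ser
}

solve_all_montages <- function(coll, matches,
                               opts = solve_options(lambda_linear = 1e-2)) {
  for (z in coll$sections)
    coll <- solve_montage(coll, matches, opts, z = z)$coll
  coll
}
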