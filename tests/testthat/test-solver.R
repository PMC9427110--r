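test_that("system assembly produces the documented sparse structure", {
  # 2 tiles, 5 matches, translation model: A is 5 x 2 with +1/-1 entries
  tiles <- list(tilespec("a", 0, 100, 100, stage_position = c(0, 0)),
                tilespec("b", 0, 100, 100, stage_position = c(87, 0)))
  coll <- tile_collection("two", tiles)
  P <- cbind(runif(5, 87, 100), runif(5, 0, 100))
  m <- point_match_set(list(stitchforge:::match_entry(
    "a", "b", P, cbind(P[, 1] - 87, P[, 2]))))
  sys <- assemble_system(m, coll, solve_options(model_kind = "translation"))
  A <- as.matrix(sys$A)
  expect_equal(dim(A), c(5, 2))
  expect_true(all(A[, 1] == 1) && all(A[, 2] == -1))
  # affine model: 3 unknowns per tile per axis system
  sec <- fixture_section(rows = 3, cols = 3, tile_size = 200, noise = 0)
  sysA <- assemble_system(sec$matches, sec$coll, solve_options())
  expect_equal(ncol(sysA$A), 3 * 9)
  # a tile with zero matches is dropped and absent from the index map
  m2 <- point_match_set(Filter(function(e)
    !grepl("r1_c1", e$p_id) && !grepl("r1_c1", e$q_id),
    sec$matches$entries))
  sys2 <- assemble_system(m2, sec$coll, solve_options())
  expect_true("t_z0_r1_c1" %in% sys2$dropped)
  expect_false("t_z0_r1_c1" %in% names(sys2$col_of))
  expect_error(solve_options(model_kind = "spline9"), "model_kind")
  expect_error(solve_options(lambda_translation = 0, lambda_linear = 0,
                             lambda_polynomial = 0), "positive")
})

test_that("regularized solve matches a dense oracle and honors limits", {
  sec <- fixture_section(rows = 3, cols = 3, tile_size = 300, noise = 1)
  sys <- assemble_system(sec$matches, sec$coll,
                         solve_options(lambda_linear = 1))
  sol <- solve_regularized(sys)
  # dense normal-equations oracle, both axes
  tx <- dense_solve_axis(sys, sys$b_x, sys$t0_x)
  ty <- dense_solve_axis(sys, sys$b_y, sys$t0_y)
  expect_lt(max(abs(sol$t_x - tx)) / max(abs(tx)), 1e-8)
  expect_lt(max(abs(sol$t_y - ty)) / max(abs(ty)), 1e-8)
  # K is positive definite for lambda > 0
  Ad <- as.matrix(sys$A)
  K <- t(Ad) %*% (Ad * sys$W) + diag(sys$lambda_diag)
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
  # lambda -> infinity forces the solution to its initialization
  sysL <- assemble_system(sec$matches, sec$coll,
                          solve_options(lambda_translation = 1e12,
                                        lambda_linear = 1e12))
  solL <- solve_regularized(sysL)
  expect_lt(max(abs(solL$t_x - sysL$t0_x)) / max(abs(sysL$t0_x)), 1e-6)
  expect_lt(max(abs(solL$t_y - sysL$t0_y)) / max(abs(sysL$t0_y)), 1e-6)
  # W = 0 returns t0 exactly: K t = lambda t0
  sysW <- sys
  sysW$W[] <- 0
  sysW$gram_diag <- Matrix::diag(stitchforge:::system_gram(sysW))
  solW <- solve_regularized(sysW)
  expect_equal(solW$t_x, sys$t0_x)
  expect_equal(solW$t_y, sys$t0_y)
})

test_that("montage solves recover truth on clean data and stay robust to noise", {
  # zero noise: residual at numerical floor, truth recovered up to the
  # regularization-fixed gauge
  sec <- fixture_section(rows = 3, cols = 3, tile_size = 300, noise = 0)
  opts <- solve_options(lambda_linear = 1e-8, lambda_translation = 1e-8)
  sol <- suppressWarnings(solve_montage(sec$coll, sec$matches, opts, z = 0))
  expect_lt(sol$median_residual, 1e-6)
  expect_lt(gauge_corner_error(sol$transforms, sec$truth$transforms, 300),
            1e-4)
  expect_equal(sol$coll$state, "montaged")
  # noise sd = 1: median residual at the noise floor, within 1.5 px
  secn <- fixture_section(rows = 5, cols = 5, tile_size = 300, noise = 1,
                          seed = 12)
  soln <- solve_montage(secn$coll, secn$matches,
                        solve_options(lambda_linear = 1e-2), z = 0)
  expect_lte(soln$median_residual, 1.5)
  # all-featureless section: nothing to solve
  spf <- synthetic_spec(rows = 2, cols = 2, tile_size = 100,
                        featureless_tile_frac = 1, seed = 5)
  secf <- make_section(spf, 0)
  expect_error(solve_montage(secf$coll, make_matches(secf$truth), z = 0),
               "no tiles")
})

test_that("progressive 3D stages are monotone and respect the node-grid range", {
  ser <- fixture_series(n_sections = 4, seed = 7)
  coll <- solve_all_montages(ser$coll, make_matches(ser$truth))
  cross <- make_cross_matches(ser$truth, z_window = 3, n_per_pair = 40)
  frames <- section_frames(coll)
  res <- solve_sections_progressive(frames, cross)
  meds <- res$stage_medians
  # per-section truth is rigid: the rigid stage already reaches the noise
  # floor and later, more deformable stages do not increase the residual
  expect_lt(meds[["rigid"]], 0.5)
  expect_lte(meds[["affine"]], meds[["rigid"]] + 1e-9)
  expect_lte(meds[["thin_plate_spline"]], meds[["affine"]] + 1e-9)
  expect_error(solve_sections_progressive(frames, cross, grid_nodes = 16),
               "25-49")
  expect_error(solve_sections_progressive(frames, cross, grid_nodes = 64),
               "25-49")
  # a 6x6 grid inside the allowed range is accepted
  res36 <- solve_sections_progressive(frames, cross, grid_nodes = 36)
  expect_length(res36$transforms, 4)
  # single section: identity, nothing to align
  one <- solve_sections_progressive(frames[1],
                                    cross)
  expect_equal(tf_as_affine(one$transforms[[1]])$M, diag(2))
})

test_that("subset realignment recovers a perturbed section without moving neighbors", {
  ser <- fixture_series(n_sections = 5, seed = 9)
  coll <- solve_all_montages(ser$coll, make_matches(ser$truth))
  cross <- make_cross_matches(ser$truth, z_window = 3, n_per_pair = 40)
  frames <- section_frames(coll)
  base <- solve_sections_progressive(frames, cross)
  cur <- base$transforms
  cur[["2"]] <- stitchforge:::compose_into_root(cur[["2"]],
                                                tf_translation(30, -10))
  re <- realign_subset(frames, cross, cur, z_set = 2L, boost_factor = 1e6)
  pts <- rbind(c(100, 100), c(700, 300), c(400, 650))
  expect_lt(max(abs(tf_apply(re$transforms[["2"]], pts) -
                    tf_apply(base$transforms[["2"]], pts))), 0.1)
  for (zc in c("0", "1", "3", "4")) {
    moved <- if (zc %in% names(cur)) max(abs(
      tf_apply(re$transforms[[zc]], pts) - tf_apply(cur[[zc]], pts))) else 0
    expect_lt(moved, 1e-3)
  }
  # empty z_set is a no-op; unknown z errors
  expect_identical(realign_subset(frames, cross, cur, integer(0))$transforms,
                   cur)
  expect_error(realign_subset(frames, cross, cur, z_set = 99L), "99")
})

test_that("disconnected montages are solved jointly but flagged", {
  sec <- fixture_section(rows = 1, cols = 4, tile_size = 100, noise = 0,
                        seed = 3)
  # cut the chain in the middle: two components
  keep <- Filter(function(e)
    !(grepl("c2$", e$p_id) && grepl("c3$", e$q_id)), sec$matches$entries)
  m <- point_match_set(keep)
  sol <- suppressWarnings(solve_montage(sec$coll, m,
    solve_options(lambda_linear = 1e-6), z = 0))
  expect_equal(sol$n_components, 2)
  expect_lt(sol$median_residual, 1e-3)
})
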