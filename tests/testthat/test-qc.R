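test_that("pair residuals are exact on planted configurations", {
  sec <- fixture_section(rows = 2, cols = 2, tile_size = 200, noise = 0)
  collT <- truth_collection(sec)
  expect_equal(pair_residuals(collT, sec$matches)$section_median, 0)
  # shifting one tile by +10 px in x makes all its pair means exactly 10
  shifted <- collT
  id <- "t_z0_r1_c1"
  af <- tf_as_affine(shifted$tiles[[id]]$transforms[[1]])
  shifted$tiles[[id]]$transforms <- list(tf_affine(af$M, af$t + c(10, 0)))
  pr <- pair_residuals(shifted, sec$matches)
  hit <- pr$pairs$p_id == id | pr$pairs$q_id == id
  expect_equal(pr$pairs$mean_px[hit], rep(10, sum(hit)), tolerance = 1e-9)
  # nm conversion uses the pixel size
  expect_equal(pr$section_median_nm, pr$section_median * 4)
})

test_that("one-sided unit noise gives the Rayleigh median residual", {
  sp <- synthetic_spec(rows = 1, cols = 2, tile_size = 1500,
                       overlap_frac = 0.45, translation_sd = 0,
                       rotation_sd = 0, scale_sd = 0, match_noise_sd = 1,
                       matches_per_pair = 4000, seed = 21)
  sec <- make_section(sp, 0)
  m <- make_matches(sec$truth)
  collT <- truth_collection(list(coll = sec$coll, truth = sec$truth))
  pts <- stitchforge:::match_residual_points(collT, m)
  # median of a Rayleigh(sigma = 1) is sqrt(2 log 2) ~ 1.1774
  expect_lt(abs(median(pts$r) - sqrt(2 * log(2))), 0.05)
})

test_that("seam detection finds planted shifts and ignores scatter", {
  sec <- fixture_section(rows = 3, cols = 3, tile_size = 200, noise = 0.5,
                        seed = 14)
  sol <- solve_montage(sec$coll, sec$matches,
                       solve_options(lambda_linear = 1e-2), z = 0)
  expect_equal(nrow(detect_seams(sol$coll, sec$matches, 5)), 0)
  # plant a 10 px shift of the center tile
  bad <- sol$coll
  id <- "t_z0_r2_c2"
  af <- tf_as_affine(bad$tiles[[id]]$transforms[[1]])
  bad$tiles[[id]]$transforms <- list(tf_affine(af$M, af$t + c(10, 0)))
  seams <- detect_seams(bad, sec$matches, 5)
  expect_gte(nrow(seams), 1)
  expect_true(any(grepl(id, seams$pairs)))
  # scattered isolated outliers below min_cluster form no seam
  m2 <- sec$matches
  for (k in c(1, 5, 9)) m2$entries[[k]]$Q[1, ] <- m2$entries[[k]]$Q[1, ] + 40
  expect_equal(nrow(detect_seams(sol$coll, m2, 5, min_cluster = 5)), 0)
})

test_that("gap detection flags lost neighbors and annotates resin tiles", {
  sec <- fixture_section(rows = 3, cols = 3, tile_size = 200, noise = 0,
                        seed = 15)
  sol <- solve_montage(sec$coll, sec$matches,
                       solve_options(lambda_linear = 1e-2), z = 0)
  expect_equal(nrow(detect_gaps(sec$coll, sol$coll, sec$matches)), 0)
  # translating a tile a full tile width away loses its neighbors
  bad <- sol$coll
  id <- "t_z0_r1_c1"
  af <- tf_as_affine(bad$tiles[[id]]$transforms[[1]])
  bad$tiles[[id]]$transforms <- list(tf_affine(af$M, af$t + c(-250, -250)))
  gaps <- detect_gaps(sec$coll, bad, sec$matches)
  expect_true(id %in% gaps$tile_id)
  expect_equal(gaps$reason[gaps$tile_id == id], "lost_neighbors")
  # a featureless tile with no matches is flagged but ignorable
  spf <- synthetic_spec(rows = 2, cols = 2, tile_size = 200,
                        translation_sd = 1, rotation_sd = 0, scale_sd = 0,
                        match_noise_sd = 0, seed = 16)
  secf <- make_section(spf, 0)
  secf$truth$featureless <- "t_z0_r1_c1"
  mf <- make_matches(secf$truth)
  collf <- truth_collection(list(coll = secf$coll, truth = secf$truth))
  gf <- detect_gaps(secf$coll, collf, mf)
  row <- gf[gf$tile_id == "t_z0_r1_c1", ]
  expect_equal(nrow(row), 1)
  expect_true(row$ignorable)
})

test_that("scale MAD is the median absolute deviation about the median", {
  mk <- function(scales) {
    tiles <- lapply(seq_along(scales), function(i)
      tilespec(paste0("t", i), 0, 100, 100,
               transforms = list(tf_affine(diag(c(scales[i], 1))))))
    tile_collection("m", tiles)
  }
  expect_equal(montage_mad(mk(rep(1, 20)))[["MAD_x"]], 0)
  # a single 1.1-scale tile among 99 unit tiles does not move the MAD
  expect_equal(montage_mad(mk(c(rep(1, 99), 1.1)))[["MAD_x"]], 0)
  half <- montage_mad(mk(c(rep(0.99, 10), rep(1.01, 10))))
  expect_equal(half[["MAD_x"]], 0.01)
  expect_equal(half[["median_scale_x"]], 1.00)
})

test_that("angular residuals equal planted rotations and a brute-force oracle", {
  with_seed(6, {
    P <- cbind(runif(200, 0, 1000), runif(200, 0, 1000))
  })
  cm <- point_match_set(list(stitchforge:::match_entry("sec_0", "sec_1",
                                                       P, P)))
  idt <- list("0" = tf_affine(), "1" = tf_affine())
  expect_equal(angular_residuals(idt, cm)$median, 0)
  # rotating section 1 by theta about section 0's centroid gives exactly
  # theta for every match
  theta <- 0.01
  ctr <- colMeans(P)
  R <- stitchforge:::rot2(theta)
  rot <- list("0" = tf_affine(),
              "1" = tf_affine(R, as.numeric(ctr - R %*% ctr)))
  ar <- angular_residuals(rot, cm)
  expect_equal(ar$median, theta, tolerance = 1e-9)
  # noisy case: equals the brute-force per-match computation exactly
  with_seed(7, Q <- P + matrix(rnorm(400), 200, 2))
  cm2 <- point_match_set(list(stitchforge:::match_entry("sec_0", "sec_1",
                                                        P, Q)))
  ar2 <- angular_residuals(idt, cm2)
  brute <- vapply(seq_len(200), function(k) {
    v1 <- P[k, ] - ctr; v2 <- Q[k, ] - ctr
    acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1))
  }, numeric(1))
  expect_identical(ar2$angles$angle, brute)
  expect_equal(ar2$median, median(brute))
  # the z-window excludes distant section pairs
  far <- point_match_set(list(stitchforge:::match_entry("sec_0", "sec_9",
                                                        P, P)))
  expect_equal(nrow(angular_residuals(idt, far, z_window = 3)$angles), 0)
})

test_that("QC reports aggregate metrics and gate pass/fail", {
  sec <- fixture_section(rows = 3, cols = 3, tile_size = 200, noise = 1,
                        seed = 18)
  sol <- solve_montage(sec$coll, sec$matches,
                       solve_options(lambda_linear = 1e-2), z = 0)
  png <- tempfile(fileext = ".png")
  rep <- qc_report(sol$coll, sec$matches, coll_pre = sec$coll, map_png = png)
  expect_true(rep$pass)
  expect_equal(nrow(rep$seams), 0)
  expect_equal(sum(!rep$gaps$ignorable), 0)
  expect_equal(rep$thresholds, c(residual_px = 5, mad = 0.005))
  expect_true(file.exists(png))
  # planted seam: report fails and localizes the defect
  bad <- sol$coll
  id <- "t_z0_r2_c2"
  af <- tf_as_affine(bad$tiles[[id]]$transforms[[1]])
  bad$tiles[[id]]$transforms <- list(tf_affine(af$M, af$t + c(12, 0)))
  rep2 <- qc_report(bad, sec$matches, coll_pre = sec$coll)
  expect_gte(nrow(rep2$seams), 1)
  expect_true(any(grepl(id, rep2$seams$pairs)))
  # metrics are pure functions: recomputation is identical
  rep3 <- qc_report(sol$coll, sec$matches, coll_pre = sec$coll)
  expect_identical(rep3$residuals, rep$residuals)
  expect_identical(rep3$mad, rep$mad)
})

test_that("seam detector hits planted shifts across seeds without false alarms", {
  hits <- 0; fps <- 0; n_trials <- 25
  for (s in seq_len(n_trials)) {
    sec <- fixture_section(rows = 3, cols = 3, tile_size = 200, noise = 1,
                          seed = 500 + s)
    sol <- solve_montage(sec$coll, sec$matches,
                         solve_options(lambda_linear = 1e-2), z = 0)
    if (nrow(detect_seams(sol$coll, sec$matches, 5)) > 0) fps <- fps + 1
    bad <- sol$coll
    id <- "t_z0_r2_c2"
    af <- tf_as_affine(bad$tiles[[id]]$transforms[[1]])
    bad$tiles[[id]]$transforms <- list(tf_affine(af$M, af$t + c(10, 0)))
    if (nrow(detect_seams(bad, sec$matches, 5)) > 0) hits <- hits + 1
  }
  expect_equal(hits, n_trials)   # 2x-threshold shifts always detected
  expect_lte(fps / n_trials, 0.02)
})
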