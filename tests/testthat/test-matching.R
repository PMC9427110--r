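test_that("tile-pair generation respects overlap and z-window rules", {
  sec <- make_section(synthetic_spec(rows = 2, cols = 2, tile_size = 100,
                                     overlap_frac = 0.13, translation_sd = 0,
                                     rotation_sd = 0, scale_sd = 0, seed = 1), 0)
  # 4 cardinal pairs; the corner overlap 0.13^2 = 0.0169 < 0.02 is excluded
  pairs <- generate_tile_pairs(sec$coll, min_overlap_frac = 0.02)
  expect_equal(nrow(pairs), 4)
  expect_true(all(pairs$relation == "same_section"))
  # lowering the threshold admits the two diagonal pairs
  pairs_all <- generate_tile_pairs(sec$coll, min_overlap_frac = 0.01)
  expect_equal(nrow(pairs_all), 6)
  sec12 <- make_section(synthetic_spec(rows = 1, cols = 2, tile_size = 100,
                                       translation_sd = 0, rotation_sd = 0,
                                       scale_sd = 0, seed = 1), 0)
  expect_equal(nrow(generate_tile_pairs(sec12$coll)), 1)
  # cross-section pairs skip missing z but bridge the gap within window
  ser <- make_series(synthetic_spec(rows = 1, cols = 1, tile_size = 50,
                                    n_sections = 6, missing_z = 2:4, seed = 1))
  cp <- generate_tile_pairs(ser$coll, z_window = 4, min_overlap_frac = 0.02)
  cross <- cp[cp$relation == "cross_section", ]
  expect_setequal(paste(cross$p_id, cross$q_id),
                  c("sec_0 sec_1", "sec_1 sec_5"))
  expect_equal(nrow(generate_tile_pairs(tile_collection("e"))), 0)
})

test_that("locally optimized RANSAC recovers a planted consensus exactly", {
  with_seed(5, {
    src <- cbind(runif(80, 0, 500), runif(80, 0, 500))
    M <- matrix(c(1.01, 0.02, -0.015, 0.99), 2, 2); tv <- c(30, -12)
    dst <- sweep(src %*% t(M), 2, tv, "+")
    P <- rbind(src, cbind(runif(20, 0, 500), runif(20, 0, 500)))
    Q <- rbind(dst, cbind(runif(20, 0, 500), runif(20, 0, 500)))
  })
  f <- filter_matches_ransac(P, Q, "affine", inlier_tol = 3, seed = 9)
  expect_setequal(f$inliers, 1:80)
  expect_equal(f$model$M, M, tolerance = 1e-6)
  expect_equal(f$model$t, tv, tolerance = 1e-6)
  # all candidates exact: everything is an inlier
  f2 <- filter_matches_ransac(src, dst, "affine", inlier_tol = 3, seed = 2)
  expect_length(f2$inliers, 80)
  # pure noise: no consensus of 8 at 1 px tolerance
  for (sd_i in 1:3) {
    with_seed(100 + sd_i, {
      Pn <- cbind(runif(100, 0, 1000), runif(100, 0, 1000))
      Qn <- cbind(runif(100, 0, 1000), runif(100, 0, 1000))
    })
    fn <- filter_matches_ransac(Pn, Qn, "affine", inlier_tol = 1,
                                seed = 200 + sd_i)
    expect_true(fn$unmatchable)
  }
})

test_that("3-sigma trimming removes gross outliers and nothing else", {
  # equal residuals: sd = 0, strict inequality removes none
  P <- cbind(seq(0, 90, 10), rep(0, 10))
  tr0 <- trim_matches(P, cbind(P[, 1] + 1, P[, 2]), "translation")
  expect_length(tr0$keep, 10)
  # 99 points with ~1 px residual plus one at 50 px: the outlier goes in
  # the first pass
  with_seed(8, {
    src <- cbind(runif(100, 0, 400), runif(100, 0, 400))
    dst <- src + matrix(rnorm(200, 0, 0.5), 100, 2)
    dst[17, ] <- dst[17, ] + c(50, 0)
  })
  tr <- trim_matches(src, dst, "affine")
  expect_false(17 %in% tr$keep)
  expect_length(tr$keep, 99)
  # empty input passes through
  e <- trim_matches(matrix(numeric(0), 0, 2), matrix(numeric(0), 0, 2))
  expect_length(e$keep, 0)
  # trimming never goes below the minimal sample size
  tiny <- trim_matches(rbind(c(0, 0), c(10, 0), c(0, 10)),
                       rbind(c(0, 0), c(10, 0), c(50, 50)), "affine")
  expect_length(tiny$keep, 3)
})

test_that("filter followed by trim is idempotent on its own output", {
  with_seed(13, {
    src <- cbind(runif(60, 0, 300), runif(60, 0, 300))
    dst <- src + matrix(rnorm(120, 0, 1), 60, 2)
    P <- rbind(src, cbind(runif(15, 0, 300), runif(15, 0, 300)))
    Q <- rbind(dst, cbind(runif(15, 0, 300), runif(15, 0, 300)))
  })
  f <- filter_matches_ransac(P, Q, "affine", inlier_tol = 4, seed = 3)
  tr <- trim_matches(P[f$inliers, ], Q[f$inliers, ], "affine")
  P1 <- P[f$inliers[tr$keep], ]; Q1 <- Q[f$inliers[tr$keep], ]
  f2 <- filter_matches_ransac(P1, Q1, "affine", inlier_tol = 4, seed = 4)
  expect_length(f2$inliers, nrow(P1))
  tr2 <- trim_matches(P1, Q1, "affine")
  expect_length(tr2$keep, nrow(P1))
})

test_that("keypoint candidates are accurate on self-matches and flag blanks", {
  sec <- make_section(synthetic_spec(rows = 1, cols = 1, tile_size = 128,
                                     translation_sd = 0, rotation_sd = 0,
                                     scale_sd = 0, seed = 5), 0)
  img <- render_tile_image(sec$coll$tiles[[1]], sec$truth)
  cand <- detect_candidates(img, img)
  expect_false(cand$low_content)
  expect_gt(nrow(cand$P), 50)
  d <- sqrt(rowSums((cand$P - cand$Q)^2))
  expect_gt(mean(d < 1), 0.9)
  # constant image: flagged low-content, empty candidates
  flat <- detect_candidates(matrix(128, 64, 64), img)
  expect_true(flat$low_content)
  expect_equal(nrow(flat$P), 0)
})

test_that("overlapping synthetic pairs yield a usable consensus", {
  sp <- synthetic_spec(rows = 1, cols = 2, tile_size = 256,
                       overlap_frac = 0.2, translation_sd = 2,
                       rotation_sd = 0.001, scale_sd = 0.001, seed = 5)
  sec <- make_section(sp, 0)
  ids <- names(sec$coll$tiles)
  i1 <- render_tile_image(sec$coll$tiles[[ids[1]]], sec$truth)
  i2 <- render_tile_image(sec$coll$tiles[[ids[2]]], sec$truth)
  m <- match_images(i1, i2, seed = 7)
  expect_false(m$unmatchable)
  expect_gte(nrow(m$P), sp$matches_per_pair / 2)
  gp <- tf_apply(sec$truth$transforms[[ids[1]]], m$P)
  gq <- tf_apply(sec$truth$transforms[[ids[2]]], m$Q)
  expect_lte(median(sqrt(rowSums((gp - gq)^2))), 2)
})

test_that("model recovery degrades gracefully with planted outliers", {
  with_seed(44, {
    src <- cbind(runif(100, 0, 400), runif(100, 0, 400))
    M <- matrix(c(1.005, 0.01, -0.01, 0.995), 2, 2)
    dst <- src %*% t(M) + matrix(rnorm(200, 0, 0.5), 100, 2)
  })
  base <- filter_matches_ransac(src, dst, "affine", inlier_tol = 3, seed = 1)
  err0 <- max(abs(base$model$M - M))
  with_seed(45, {
    n_out <- 30
    idx <- sample(100, n_out)
    dst_o <- dst
    dst_o[idx, ] <- cbind(runif(n_out, 0, 400), runif(n_out, 0, 400))
  })
  out <- filter_matches_ransac(src, dst_o, "affine", inlier_tol = 3, seed = 2)
  err1 <- max(abs(out$model$M - M))
  expect_lte(err1, 3 * max(err0, 1e-3))
})
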