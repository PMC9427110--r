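test_that("downsampled montage renders record a correct lift mapping", {
  sec <- fixture_section(rows = 2, cols = 2, tile_size = 64, noise = 0,
                        seed = 6)
  coll <- truth_collection(sec)
  r <- render_downsampled_montage(coll, 0, scale = 0.25, truth = sec$truth)
  expect_equal(dim(r$image),
               c(ceiling((r$bbox[4] - r$bbox[2]) * 0.25),
                 ceiling((r$bbox[3] - r$bbox[1]) * 0.25)))
  # lifted coordinates return to full resolution within the quantization
  # bound of half an output pixel
  p <- rbind(c(3, 7), c(10.5, 2))
  lifted <- r$lift(p)
  expect_equal(lifted, cbind(r$bbox[1] + p[, 1] / 0.25,
                             r$bbox[2] + p[, 2] / 0.25))
  # scale 1 on a single-tile section reproduces the tile image interior
  one <- make_section(synthetic_spec(rows = 1, cols = 1, tile_size = 48,
                                     translation_sd = 0, rotation_sd = 0,
                                     scale_sd = 0, seed = 2), 0)
  cone <- truth_collection(list(coll = one$coll, truth = one$truth))
  r1 <- render_downsampled_montage(cone, 0, scale = 1, truth = one$truth)
  img <- render_tile_image(one$coll$tiles[[1]], one$truth)
  expect_equal(r1$image[2:47, 2:47], img[2:47, 2:47], tolerance = 1e-9)
})

test_that("image-based section matching is consistent with the identity", {
  sp <- synthetic_spec(rows = 2, cols = 2, tile_size = 96, n_sections = 2,
                       translation_sd = 1, rotation_sd = 5e-4,
                       scale_sd = 5e-4, match_noise_sd = 0,
                       section_rotation_sd = 0, section_translation_sd = 0,
                       seed = 11)
  ser <- make_series(sp)
  # montage with truth transforms so neighboring sections carry the same
  # texture at the same global coordinates
  coll <- ser$coll
  for (id in names(coll$tiles))
    coll$tiles[[id]]$transforms <- list(ser$truth$transforms[[id]])
  ms <- match_sections(coll, z_window = 1, scale = 0.5, truth = ser$truth,
                       seed = 5)
  expect_equal(nrow(ms$unmatched), 0)
  e <- ms$matches$entries[[1]]
  expect_gte(nrow(e$P), 8)
  d <- sqrt(rowSums((e$P - e$Q)^2))
  expect_lte(median(d), 1 / 0.5)  # within the lift quantization bound
})

test_that("rough alignment improves stacking and tags every tile", {
  ser <- fixture_series(n_sections = 4, seed = 7)
  coll <- solve_all_montages(ser$coll, make_matches(ser$truth))
  cross <- make_cross_matches(ser$truth, z_window = 3, n_per_pair = 40)
  idt <- setNames(lapply(coll$sections, function(z) tf_affine()),
                  as.character(coll$sections))
  before <- angular_residuals(idt, cross)$median
  ra <- rough_align(coll, cross)
  after <- angular_residuals(ra$transforms, cross)$median
  expect_lte(after, before)
  expect_equal(ra$coll$state, "aligned3d")
  # the per-section transform is appended to every tile of its section
  for (id in names(ra$coll$tiles)) {
    n0 <- length(coll$tiles[[id]]$transforms)
    expect_length(ra$coll$tiles[[id]]$transforms, n0 + 1)
  }
  # identity truth: appended transforms stay near identity
  serz <- fixture_series(n_sections = 3, seed = 13,
                         section_rotation_sd = 0,
                         section_translation_sd = 0)
  collz <- solve_all_montages(serz$coll, make_matches(serz$truth))
  crossz <- make_cross_matches(serz$truth, z_window = 2, n_per_pair = 30)
  raz <- rough_align(collz, crossz)
  corners <- rbind(c(0, 0), c(900, 0), c(900, 900), c(0, 900))
  for (tz in raz$transforms)
    expect_lt(max(abs(tf_apply(tz, corners) - corners)), 0.5)
})

test_that("chunk registration recovers planted rigid-family offsets", {
  za <- as.character(0:4); zb <- as.character(2:6)
  chunk_a <- setNames(lapply(za, function(z) tf_affine()), za)
  with_seed(3, P <- cbind(runif(30, 0, 800), runif(30, 0, 800)))
  pm <- point_match_set(list(
    stitchforge:::match_entry("sec_2", "sec_900", P[1:10, ], P[1:10, ]),
    stitchforge:::match_entry("sec_3", "sec_901", P[11:20, ], P[11:20, ]),
    stitchforge:::match_entry("sec_4", "sec_902", P[21:30, ], P[21:30, ])))
  # chunk B internally shifted: registration must find the inverse
  chunk_b <- setNames(lapply(zb, function(z) tf_translation(-100, 40)), zb)
  reg <- register_chunks(chunk_a, chunk_b, pm, model = "translation")
  expect_equal(c(reg$tx, reg$ty), c(100, -40), tolerance = 1e-6)
  # rigid recovery of a rotated copy
  th <- 0.05
  R <- stitchforge:::rot2(-th)
  chunk_br <- setNames(lapply(zb, function(z) tf_affine(R)), zb)
  regr <- register_chunks(chunk_a, chunk_br, pm, model = "rigid")
  expect_equal(regr$theta, th, tolerance = 1e-8)
  # disjoint chunks cannot be registered
  expect_error(register_chunks(chunk_a,
                               setNames(list(tf_affine()), "9"), pm),
               "share no sections")
})

test_that("fusion interpolates the overlap and is continuous at its edges", {
  za <- as.character(0:5); zb <- as.character(3:8)
  chunk_a <- setNames(lapply(za, function(z) tf_affine()), za)
  chunk_b <- setNames(lapply(zb, function(z) tf_translation(-100, 0)), zb)
  reg <- tf_translation(100, 0)
  fused <- fuse_chunks(list(a = chunk_a, b = chunk_b),
                       list(root = "a",
                            edges = list(list(parent = "a", child = "b",
                                              transform = reg))))
  pts <- rbind(c(10, 10), c(500, 300))
  rooted_b <- tf_compose_affine(list(chunk_b[["4"]], reg))
  # identical mappings in the overlap: fused equals either chunk exactly
  expect_equal(tf_apply(fused[["3"]], pts), tf_apply(chunk_a[["3"]], pts),
               tolerance = 1e-9)
  expect_equal(tf_apply(fused[["5"]], pts), tf_apply(rooted_b, pts),
               tolerance = 1e-9)
  # mid-overlap is the arithmetic mean of the two mappings
  expect_equal(tf_apply(fused[["4"]], pts),
               (tf_apply(chunk_a[["4"]], pts) + tf_apply(rooted_b, pts)) / 2)
  # identical chunks fuse to themselves everywhere
  same <- fuse_chunks(list(a = chunk_a, b = chunk_a["3"]),
                      list(root = "a",
                           edges = list(list(parent = "a", child = "b",
                                             transform = tf_affine()))))
  expect_equal(tf_apply(same[["3"]], pts), tf_apply(chunk_a[["3"]], pts))
  # single-section overlap blends at exactly 0.5
  expect_equal(same[["3"]]$lambda_blend, 0.5)
  # cyclic layouts are rejected
  expect_error(fuse_chunks(list(a = chunk_a, b = chunk_b),
                           list(root = "a",
                                edges = list(
                                  list(parent = "a", child = "b",
                                       transform = reg),
                                  list(parent = "b", child = "a",
                                       transform = reg)))),
               "cycle")
})

test_that("fused TPS sections compose exactly into the root frame", {
  ctr <- rbind(c(0, 0), c(400, 0), c(0, 400), c(400, 400), c(200, 200))
  tps <- fit_transform("thin_plate_spline", ctr,
                       ctr + matrix(c(1, -2, 0, 2, 1, 0, 1, -1, 0.5, 0.5),
                                    5, 2))
  root_tf <- tf_similarity(1.1, 0.2, 30, -10)
  comp <- stitchforge:::compose_into_root(tps, root_tf)
  pts <- rbind(c(50, 60), c(333, 21), c(180, 350))
  expect_equal(tf_apply(comp, pts),
               tf_apply(root_tf, tf_apply(tps, pts)), tolerance = 1e-9)
})
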