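#' Specify a synthetic tile-grid acquisition
#'
#' Defines the study conditions for generated data: grid geometry, nominal
#' overlap, per-tile placement perturbations, correspondence noise and
#' outliers, featureless (resin/vessel) tiles, an optional lens-distortion
#' model, and per-section deformations for multi-section series.
#'
#' Placement-perturbation defaults (translation sd 20 px, rotation sd
#' 0.002 rad, per-axis scale sd 0.005) are the package's own choice of a
#' realistic stage-error magnitude; the grid geometry defaults (3840 px
#' tiles, 13% overlap) mirror common TEM acquisition settings.
#'
#' @param rows,cols Tile-grid dimensions.
#' @param tile_size Tile side length in pixels.
#' @param overlap_frac Nominal neighbor overlap fraction, in (0, 0.5).
#' @param n_sections Number of serial sections.
#' @param rotation_sd Per-tile rotation perturbation sd (radians).
#' @param translation_sd Per-tile translation perturbation sd (px).
#' @param scale_sd Per-tile per-axis scale perturbation sd.
#' @param match_noise_sd Gaussian noise sd (px) added to one side of each
#'   generated correspondence.
#' @param outlier_frac Fraction of correspondences per pair replaced by
#'   uniform outliers, in [0, 0.5).
#' @param matches_per_pair Correspondences generated per overlapping pair.
#' @param featureless_tile_frac Fraction of tiles with no texture (resin or
#'   vessel interior), which yield zero matches.
#' @param lens_model `"none"`, or `list(kind = "radial", k1 =, k2 =)` for a
#'   radial distortion about the tile center.
#' @param section_rotation_sd,section_translation_sd Per-section rigid
#'   deformation magnitudes for 3D series.
#' @param section_deform_amp Amplitude (px) of an additional smooth
#'   low-order per-section deformation.
#' @param missing_z Integer vector of absent section indices.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(rows = 2, cols = 2, tile_size = 3840,
                           overlap_frac = 0.13, n_sections = 1,
                           rotation_sd = 0.002, translation_sd = 20,
                           scale_sd = 0.005, match_noise_sd = 1,
                           outlier_frac = 0, matches_per_pair = 20,
                           featureless_tile_frac = 0, lens_model = "none",
                           section_rotation_sd = 0.005,
                           section_translation_sd = 30,
                           section_deform_amp = 0,
                           missing_z = integer(0), seed = 1) {
  if (overlap_frac <= 0 || overlap_frac > 0.5)
    stop("overlap_frac must be in (0, 0.5]")
  if (outlier_frac < 0 || outlier_frac >= 0.5)
    stop("outlier_frac must be in [0, 0.5)")
  sds <- c(rotation_sd, translation_sd, scale_sd, match_noise_sd,
           section_rotation_sd, section_translation_sd, section_deform_amp)
  if (any(sds < 0)) stop("perturbation magnitudes must be nonnegative")
  if (rows < 1 || cols < 1 || tile_size <= 0) stop("invalid grid geometry")
  structure(list(rows = rows, cols = cols, tile_size = tile_size,
                 overlap_frac = overlap_frac, n_sections = n_sections,
                 rotation_sd = rotation_sd, translation_sd = translation_sd,
                 scale_sd = scale_sd, match_noise_sd = match_noise_sd,
                 outlier_frac = outlier_frac,
                 matches_per_pair = matches_per_pair,
                 featureless_tile_frac = featureless_tile_frac,
                 lens_model = lens_model,
                 section_rotation_sd = section_rotation_sd,
                 section_translation_sd = section_translation_sd,
                 section_deform_amp = section_deform_amp,
                 missing_z = as.integer(missing_z), seed = as.integer(seed)),
            class = "synthetic_spec")
}

stage_nominal <- function(spec, r, c) {
  pitch <- (1 - spec$overlap_frac) * spec$tile_size
  c((c - 1) * pitch, (r - 1) * pitch)
}

# The lens distortion D maps ideal (corrected) local coordinates to raw
# image coordinates; the correction to estimate is its inverse.
lens_distort <- function(spec, pts) {
  lm <- spec$lens_model
  if (identical(lm, "none")) return(pts)
  if (!is.list(lm) || !identical(lm$kind, "radial"))
    stop("unknown lens_model")
  ctr <- c(spec$tile_size / 2, spec$tile_size / 2)
  u <- sweep(pts, 2, ctr)
  r2 <- rowSums(u^2)
  f <- 1 + lm$k1 * r2 + (lm$k2 %||% 0) * r2^2
  sweep(u * f, 2, ctr, "+")
}

# Inverse of the radial distortion (the true correction field), by Newton
# iteration on the radius.
lens_undistort <- function(spec, pts) {
  lm <- spec$lens_model
  if (identical(lm, "none")) return(pts)
  ctr <- c(spec$tile_size / 2, spec$tile_size / 2)
  u <- sweep(pts, 2, ctr)
  r_raw <- sqrt(rowSums(u^2))
  k1 <- lm$k1; k2 <- lm$k2 %||% 0
  r <- r_raw
  for (i in 1:50) {
    f <- r * (1 + k1 * r^2 + k2 * r^4) - r_raw
    fp <- 1 + 3 * k1 * r^2 + 5 * k2 * r^4
    r <- r - f / fp
  }
  scale <- ifelse(r_raw > 0, r / r_raw, 1)
  sweep(u * scale, 2, ctr, "+")
}

#' Generate one synthetic section with ground truth
#'
#' Tiles are laid out on the nominal stage grid
#' `stage(r, c) = ((c-1) (1-overlap) s, (r-1) (1-overlap) s)`; the ground
#' truth perturbs each placement by a small random rotation, per-axis scale,
#' and translation about the tile center, while the tile specs carry only
#' the nominal stage translation, so a solver starts from realistic
#' initialization error.
#'
#' @param spec A [synthetic_spec()].
#' @param z Section index.
#' @return List with `coll` (a [tile_collection()]) and `truth` (per-tile
#'   true transforms, featureless tile ids, and the spec).
#' @export
make_section <- function(spec, z = 0) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, z, 1), {
    tiles <- list(); truths <- list(); featureless <- character(0)
    s <- spec$tile_size
    ctr <- c(s / 2, s / 2)
    for (r in seq_len(spec$rows)) for (c in seq_len(spec$cols)) {
      id <- sprintf("t_z%d_r%d_c%d", z, r, c)
      stage <- stage_nominal(spec, r, c)
      theta <- rnorm(1, 0, spec$rotation_sd)
      sx <- rnorm(1, 1, spec$scale_sd); sy <- rnorm(1, 1, spec$scale_sd)
      dt <- rnorm(2, 0, spec$translation_sd)
      M <- rot2(theta) %*% diag(c(sx, sy))
      tv <- ctr - as.numeric(M %*% ctr) + stage + dt
      truths[[id]] <- tf_affine(M, tv)
      if (runif(1) < spec$featureless_tile_frac)
        featureless <- c(featureless, id)
      tiles[[length(tiles) + 1]] <- tilespec(
        tile_id = id, z = z, width = s, height = s,
        stage_position = stage,
        transforms = list(tf_translation(stage[1], stage[2])),
        image_ref = list(type = "synthetic", z = as.integer(z)),
        group_id = "lens0")
    }
    coll <- tile_collection(sprintf("synthetic_z%d", z), tiles)
    truth <- list(transforms = truths, featureless = featureless,
                  spec = spec, section_transforms = NULL)
    list(coll = coll, truth = truth)
  })
}

#' Generate point correspondences from ground truth
#'
#' For each pair of tiles whose true footprints overlap, samples points
#' uniformly in the true overlap region, maps them into each tile's local
#' frame through the inverse truth transforms, adds Gaussian noise to the
#' Q side, replaces `floor(outlier_frac * N)` Q points with uniform draws
#' over the tile, and omits pairs touching featureless tiles (which have no
#' texture to match).
#'
#' @param truth Ground truth from [make_section()].
#' @param spec The generating [synthetic_spec()].
#' @param frame `"lens_corrected"` (default) stores ideal local
#'   coordinates; `"raw"` pushes both sides through the lens distortion,
#'   as needed for calibration-montage input.
#' @return A [point_match_set()].
#' @export
make_matches <- function(truth, spec = truth$spec, frame = "lens_corrected") {
  ids <- names(truth$transforms)
  zs <- vapply(ids, function(id) as.integer(sub("^t_z(\\d+)_.*$", "\\1", id)),
               integer(1))
  with_seed(derive_seed(spec$seed, 2), {
    entries <- list()
    corners <- rbind(c(0, 0), c(spec$tile_size, 0),
                     c(spec$tile_size, spec$tile_size), c(0, spec$tile_size))
    feet <- lapply(ids, function(id) tf_apply(truth$transforms[[id]], corners))
    names(feet) <- ids
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (j <= i || zs[i] != zs[j]) next
      p_id <- ids[i]; q_id <- ids[j]
      if (p_id %in% truth$featureless || q_id %in% truth$featureless) next
      ov <- clip_convex(feet[[p_id]], feet[[q_id]])
      if (polygon_area(ov) < 1e-9) next
      g <- sample_in_convex(ov, spec$matches_per_pair)
      if (nrow(g) == 0) next
      P <- tf_apply(tf_invert(truth$transforms[[p_id]]), g)
      Q <- tf_apply(tf_invert(truth$transforms[[q_id]]), g)
      if (spec$match_noise_sd > 0)
        Q <- Q + matrix(rnorm(length(Q), 0, spec$match_noise_sd), ncol = 2)
      n_out <- floor(spec$outlier_frac * nrow(Q))
      if (n_out > 0) {
        idx <- sample(nrow(Q), n_out)
        Q[idx, ] <- cbind(runif(n_out, 0, spec$tile_size),
                          runif(n_out, 0, spec$tile_size))
      }
      if (frame == "raw") {
        P <- lens_distort(spec, P)
        Q <- lens_distort(spec, Q)
      }
      entries[[length(entries) + 1]] <- match_entry(p_id, q_id, P, Q)
    }
    point_match_set(entries)
  })
}

# Deterministic band-limited global texture: white noise blurred at two
# length scales (4 px and 32 px), rescaled to [0, 255]. Periodic by
# construction (FFT blur), so any global point can be sampled by wrapping.
.texture_cache <- new.env(parent = emptyenv())

texture_canvas <- function(seed, size = 1024) {
  key <- paste0(seed, "_", size)
  if (!is.null(.texture_cache[[key]])) return(.texture_cache[[key]])
  .texture_cache[[key]] <- texture_canvas_build(seed, size)
  .texture_cache[[key]]
}

texture_canvas_build <- function(seed, size) {
  with_seed(derive_seed(seed, 7), {
    noise <- matrix(rnorm(size * size), size, size)
    fine <- EBImage::gblur(noise, sigma = 4)
    coarse <- EBImage::gblur(noise, sigma = 32)
    tex <- fine + 3 * coarse
    tex <- (tex - min(tex)) / (max(tex) - min(tex)) * 255
    tex
  })
}

bilinear_sample <- function(img, x, y) {
  # img indexed [row, col] = [y + 1, x + 1]; clamp to valid range.
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 0), w - 1 - 1e-9)
  y <- pmin(pmax(y, 0), h - 1 - 1e-9)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0 + 1, x0 + 1)]
  i01 <- img[cbind(y0 + 1, pmin(x0 + 2, w))]
  i10 <- img[cbind(pmin(y0 + 2, h), x0 + 1)]
  i11 <- img[cbind(pmin(y0 + 2, h), pmin(x0 + 2, w))]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

sample_texture <- function(tex, pts, scale = 1) {
  # Periodic wrap of global coordinates onto the canvas.
  n <- nrow(tex)
  x <- (pts[, 1] * scale) %% n
  y <- (pts[, 2] * scale) %% n
  bilinear_sample(tex, x, y)
}

#' Render a synthetic tile image
#'
#' Samples the shared deterministic global texture through the tile's true
#' transform and the lens-distortion model, so overlapping tiles see the
#' same (distorted) content. Featureless tiles return near-constant
#' intensity.
#'
#' @param tile A [tilespec()].
#' @param truth Ground truth from [make_section()].
#' @param spec The generating [synthetic_spec()].
#' @return `height` x `width` numeric matrix of gray values in [0, 255].
#' @export
render_tile_image <- function(tile, truth, spec = truth$spec) {
  s <- spec$tile_size
  if (tile$tile_id %in% truth$featureless)
    return(matrix(128, s, s))
  tex <- texture_canvas(spec$seed)
  # raw pixel (x, y) shows content at ideal local coord undistort(x, y),
  # which sits at global coord T(undistort(x, y)).
  grid <- cbind(rep(seq_len(s) - 1, each = s), rep(seq_len(s) - 1, times = s))
  ideal <- lens_undistort(spec, grid)
  g <- tf_apply(truth$transforms[[tile$tile_id]], ideal)
  vals <- sample_texture(tex, g)
  matrix(vals, nrow = s, ncol = s, byrow = FALSE)
}

# Per-section deformation truth (montaged frame -> aligned frame).
make_section_deform <- function(spec, z) {
  with_seed(derive_seed(spec$seed, z, 3), {
    theta <- rnorm(1, 0, spec$section_rotation_sd)
    dt <- rnorm(2, 0, spec$section_translation_sd)
    ext <- spec$cols * spec$tile_size
    ctr <- c(ext / 2, ext / 2)
    M <- rot2(theta)
    tv <- ctr - as.numeric(M %*% ctr) + dt
    rigid <- tf_affine(M, tv)
    if (spec$section_deform_amp > 0) {
      # smooth low-order bend: quadratic displacement field over the section
      amp <- spec$section_deform_amp
      cx <- rnorm(3, 0, amp / ext^2); cy <- rnorm(3, 0, amp / ext^2)
      af <- tf_as_affine(rigid)
      coef <- rbind(c(af$t[1], af$M[1, 1], af$M[1, 2], cx),
                    c(af$t[2], af$M[2, 1], af$M[2, 2], cy))
      tf_polynomial2(coef)
    } else rigid
  })
}

#' Generate a synthetic serial-section series
#'
#' Each section gets its own montage ground truth plus a smooth per-section
#' deformation (the 3D truth); sections listed in `missing_z` are absent,
#' emulating lost sections.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `coll` (all sections' tiles) and `truth` (per-tile
#'   transforms, per-section deformations, featureless ids).
#' @export
make_series <- function(spec) {
  zs <- setdiff(seq_len(spec$n_sections) - 1L, spec$missing_z)
  tiles <- list(); truths <- list(); featureless <- character(0)
  section_transforms <- list()
  for (z in zs) {
    sec <- make_section(spec, z)
    tiles <- c(tiles, unname(sec$coll$tiles))
    truths <- c(truths, sec$truth$transforms)
    featureless <- c(featureless, sec$truth$featureless)
    section_transforms[[as.character(z)]] <- make_section_deform(spec, z)
  }
  coll <- tile_collection("synthetic_series", tiles)
  truth <- list(transforms = truths, featureless = featureless,
                spec = spec, section_transforms = section_transforms)
  list(coll = coll, truth = truth)
}

#' Generate cross-section correspondences from series ground truth
#'
#' Section-frame matches between sections within `z_window`, skipping
#' missing sections: for a shared aligned-frame point g, the entry pairs
#' `Sa^-1(g)` with `Sb^-1(g)` where `S` are the true per-section
#' deformations. Stored against virtual section tiles named `sec_<z>`.
#'
#' @param truth Series ground truth from [make_series()].
#' @param spec The generating [synthetic_spec()].
#' @param z_window Maximum section distance to pair.
#' @param n_per_pair Correspondences per section pair.
#' @return A [point_match_set()] in section (montaged-frame) coordinates.
#' @export
make_cross_matches <- function(truth, spec = truth$spec, z_window = 3,
                               n_per_pair = 40) {
  zs <- sort(as.integer(names(truth$section_transforms)))
  ext_x <- spec$cols * spec$tile_size
  ext_y <- spec$rows * spec$tile_size
  with_seed(derive_seed(spec$seed, 4), {
    entries <- list()
    for (i in seq_along(zs)) for (j in seq_along(zs)) {
      if (j <= i) next
      dz <- zs[j] - zs[i]
      if (dz < 1 || dz > z_window) next
      g <- cbind(runif(n_per_pair, 0.1 * ext_x, 0.9 * ext_x),
                 runif(n_per_pair, 0.1 * ext_y, 0.9 * ext_y))
      Sa <- truth$section_transforms[[as.character(zs[i])]]
      Sb <- truth$section_transforms[[as.character(zs[j])]]
      P <- invert_section_transform(Sa, g)
      Q <- invert_section_transform(Sb, g)
      if (spec$match_noise_sd > 0)
        Q <- Q + matrix(rnorm(length(Q), 0, spec$match_noise_sd), ncol = 2)
      entries[[length(entries) + 1]] <-
        match_entry(sprintf("sec_%d", zs[i]), sprintf("sec_%d", zs[j]), P, Q)
    }
    point_match_set(entries)
  })
}

invert_section_transform <- function(t, pts) {
  inv <- tf_invert(t)
  if (is.function(inv)) inv(pts) else tf_apply(inv, pts)
}

#' Generate a high-overlap calibration montage
#'
#' As [make_section()] but with overlap at or above 0.4 and a nonzero lens
#' model, emulating the daily calibration acquisitions used for lens
#' estimation. Warns if the requested overlap is below 0.3.
#'
#' @param spec A [synthetic_spec()]; `overlap_frac` should be >= 0.4.
#' @return As [make_section()].
#' @export
make_calibration_montage <- function(spec) {
  if (spec$overlap_frac < 0.3)
    warning("calibration overlap below 0.3; lens estimation may be unreliable")
  make_section(spec, z = 0)
}
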