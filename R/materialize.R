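# Rendering transformed tiles to flattened images and MIPmap pyramids.

tile_image <- function(coll, tile, truth = NULL) {
  ref <- tile$image_ref
  if (is.character(ref)) {
    if (!file.exists(ref)) return(NULL)
    img <- if (grepl("\\.tiff?$", ref, ignore.case = TRUE))
      tiff::readTIFF(ref) else stop("unsupported image format: ", ref)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(img * 255)
  }
  if (is.list(ref) && identical(ref$type, "synthetic") && !is.null(truth))
    return(render_tile_image(tile, truth))
  NULL
}

#' Render a bounding box of a section to an image
#'
#' Output pixel `(u, v)` maps to global point
#' `bbox_origin + (u, v) / scale`; each candidate tile whose transformed
#' footprint contains the point is sampled at the inverse-transformed
#' location with bilinear interpolation. Overlaps composite by
#' nearest-tile-center (deterministic, and seams stay visible to QC);
#' `composite = "mean"` averages instead. Background is 0.
#'
#' @param coll A [tile_collection()].
#' @param z Section index.
#' @param bbox `c(xmin, ymin, xmax, ymax)` in global px (default: section
#'   bounding box).
#' @param scale Output scale (1 = full resolution).
#' @param truth Optional synthetic ground truth supplying tile images.
#' @param composite `"nearest"` or `"mean"`.
#' @return List: `image` (matrix, gray 0-255), `bbox`, `scale`.
#' @export
render_bbox <- function(coll, z, bbox = NULL, scale = 1, truth = NULL,
                        composite = "nearest") {
  ids <- names(coll$tiles)[vapply(coll$tiles, function(t) t$z == z,
                                  logical(1))]
  if (length(ids) == 0) stop("no tiles at z = ", z)
  feet <- lapply(ids, function(id) tile_footprint(coll, id, from = "raw"))
  names(feet) <- ids
  if (is.null(bbox)) {
    pts <- do.call(rbind, feet)
    bbox <- c(min(pts[, 1]), min(pts[, 2]), max(pts[, 1]), max(pts[, 2]))
  }
  wd <- ceiling((bbox[3] - bbox[1]) * scale)
  ht <- ceiling((bbox[4] - bbox[2]) * scale)
  if (wd <= 0 || ht <= 0) stop("bbox has zero area")
  out <- matrix(0, ht, wd)
  wsum <- matrix(0, ht, wd)
  dmin <- matrix(Inf, ht, wd)
  gx <- bbox[1] + (seq_len(wd) - 1) / scale
  gy <- bbox[2] + (seq_len(ht) - 1) / scale
  g <- cbind(rep(gx, each = ht), rep(gy, times = wd))
  for (id in ids) {
    tile <- coll$tiles[[id]]
    img <- tile_image(coll, tile, truth)
    if (is.null(img)) next
    ft <- feet[[id]]
    inb <- points_in_convex(g, ft)
    if (!any(inb)) next
    tlist <- tile$transforms
    local <- invert_chain(tlist, g[inb, , drop = FALSE], coll$shared)
    ok <- local[, 1] >= 0 & local[, 1] <= tile$width - 1 &
          local[, 2] >= 0 & local[, 2] <= tile$height - 1
    if (!any(ok)) next
    vals <- bilinear_sample(img, local[ok, 1], local[ok, 2])
    ctr <- colMeans(ft)
    lin <- which(inb)[ok]
    d2 <- (g[lin, 1] - ctr[1])^2 + (g[lin, 2] - ctr[2])^2
    if (composite == "mean") {
      out[lin] <- out[lin] + vals
      wsum[lin] <- wsum[lin] + 1
    } else {
      closer <- d2 < dmin[lin]
      upd <- lin[closer]
      out[upd] <- vals[closer]
      dmin[upd] <- d2[closer]
      wsum[upd] <- 1
    }
  }
  if (composite == "mean") {
    hit <- wsum > 0
    out[hit] <- out[hit] / wsum[hit]
  }
  list(image = out, bbox = bbox, scale = scale)
}

invert_chain <- function(tlist, pts, refs = NULL) {
  # map global points back through a transform chain (last to first)
  for (t in rev(tlist)) {
    if (t$kind == "reference") t <- refs[[t$ref_id]]
    inv <- tf_invert(t, refs)
    pts <- if (is.function(inv)) inv(pts) else tf_apply(inv, pts)
  }
  pts
}

#' Build a MIPmap pyramid
#'
#' Level k is a 2x area-mean downsample of level k-1; level 0 is the
#' input. Odd trailing rows/columns are dropped (standard power-of-two
#' pyramid behavior).
#'
#' @param image Numeric matrix.
#' @param levels Number of levels including level 0.
#' @return List of matrices, names `level0`, `level1`, ...
#' @export
build_mipmaps <- function(image, levels = 4) {
  out <- list(level0 = image)
  cur <- image
  for (k in seq_len(levels - 1)) {
    h <- nrow(cur) %/% 2; w <- ncol(cur) %/% 2
    if (h < 1 || w < 1) break
    sub <- cur[seq_len(2 * h), seq_len(2 * w), drop = FALSE]
    cur <- (sub[seq(1, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE] +
            sub[seq(2, 2 * h, 2), seq(1, 2 * w, 2), drop = FALSE] +
            sub[seq(1, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE] +
            sub[seq(2, 2 * h, 2), seq(2, 2 * w, 2), drop = FALSE]) / 4
    out[[paste0("level", k)]] <- cur
  }
  out
}

#' Write a MIPmap pyramid to disk
#'
#' @param image Numeric matrix (gray 0-255).
#' @param out_dir Output directory.
#' @param levels Pyramid depth.
#' @param basename File prefix.
#' @return Character vector of written paths.
#' @export
write_mipmaps <- function(image, out_dir, levels = 4, basename = "mip") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pyr <- build_mipmaps(image, levels)
  paths <- character(0)
  for (k in seq_along(pyr)) {
    p <- file.path(out_dir, sprintf("%s_l%d.tif", basename, k - 1))
    tiff::writeTIFF(pmin(pmax(pyr[[k]] / 255, 0), 1), p,
                    bits.per.sample = 8)
    paths <- c(paths, p)
  }
  paths
}

#' Export flattened sections to disk
#'
#' One image per section, named `z%06d.tif`, plus a JSON sidecar with
#' bbox, scale, and pixel size. Missing sections are skipped with a log
#' message.
#'
#' @param coll A [tile_collection()].
#' @param z_range Integer sections to export.
#' @param out_dir Output directory.
#' @param scale Render scale.
#' @param truth Optional synthetic truth supplying tile images.
#' @return Character vector of written image paths.
#' @export
export_stack <- function(coll, z_range, out_dir, scale = 1, truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  meta <- list()
  for (z in z_range) {
    if (!z %in% coll$sections) {
      message("section z = ", z, " absent; skipped")
      next
    }
    r <- render_bbox(coll, z, scale = scale, truth = truth)
    p <- file.path(out_dir, sprintf("z%06d.tif", z))
    tiff::writeTIFF(pmin(pmax(r$image / 255, 0), 1), p, bits.per.sample = 8)
    paths <- c(paths, p)
    meta[[sprintf("z%06d", z)]] <- list(bbox = r$bbox, scale = r$scale,
      pixel_size_nm = median(vapply(coll$tiles, function(t) t$pixel_size,
                                    numeric(1))))
  }
  write_canonical_json(meta, file.path(out_dir, "sections.json"))
  paths
}
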