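# Automated stitching QC: residuals, seams, gaps, scale MAD, angular
# residuals. All metrics are pure functions of (tile specs, matches).

# Per-correspondence residuals with global positions, for seam clustering.
match_residual_points <- function(coll, matches) {
  rows <- list()
  for (e in matches$entries) {
    if (is.null(coll$tiles[[e$p_id]]) || is.null(coll$tiles[[e$q_id]])) next
    if (nrow(e$P) == 0) next
    gp <- tile_map_points(coll, e$p_id, e$P)
    gq <- tile_map_points(coll, e$q_id, e$Q)
    d <- gp - gq
    rows[[length(rows) + 1]] <- data.frame(
      p_id = e$p_id, q_id = e$q_id,
      x = (gp[, 1] + gq[, 1]) / 2, y = (gp[, 2] + gq[, 2]) / 2,
      r = sqrt(rowSums(d^2)),
      z = coll$tiles[[e$p_id]]$z)
  }
  if (length(rows) == 0)
    return(data.frame(p_id = character(0), q_id = character(0),
                      x = numeric(0), y = numeric(0), r = numeric(0),
                      z = integer(0)))
  do.call(rbind, rows)
}

#' Per-pair correspondence residual statistics
#'
#' The residual of a correspondence is the Euclidean distance between its
#' two mapped members after the current transforms; per pair the mean and
#' median are reported, and the section summary is the median over pair
#' means. Converted to nm via the tiles' pixel size.
#'
#' @param coll A [tile_collection()] with current transforms.
#' @param matches [point_match_set()] in lens-corrected local frames.
#' @return List: `pairs` (data frame of per-pair stats), `section_median`
#'   (px; median of pair means over all pairs), `section_median_nm`,
#'   `per_section` (named by z).
#' @export
pair_residuals <- function(coll, matches) {
  pts <- match_residual_points(coll, matches)
  if (nrow(pts) == 0)
    return(list(pairs = data.frame(), section_median = NA_real_,
                section_median_nm = NA_real_, per_section = numeric(0)))
  key <- paste(pts$p_id, pts$q_id)
  means <- tapply(pts$r, key, mean)
  meds <- tapply(pts$r, key, median)
  n <- tapply(pts$r, key, length)
  first <- !duplicated(key)
  pairs <- data.frame(p_id = pts$p_id[first], q_id = pts$q_id[first],
                      z = pts$z[first],
                      n = as.integer(n[key[first]]),
                      mean_px = as.numeric(means[key[first]]),
                      median_px = as.numeric(meds[key[first]]))
  px_nm <- median(vapply(coll$tiles, function(t) t$pixel_size, numeric(1)))
  pairs$mean_nm <- pairs$mean_px * px_nm
  per_section <- tapply(pairs$mean_px, pairs$z, median)
  sec_med <- median(pairs$mean_px)
  list(pairs = pairs, section_median = sec_med,
       section_median_nm = sec_med * px_nm,
       per_section = per_section)
}

#' Detect seams from clustered high-residual correspondences
#'
#' A seam shows up as a spatial cluster of correspondences whose residuals
#' exceed a threshold. High-residual points are single-link clustered at
#' `cluster_radius` (default twice the median match spacing); clusters of
#' at least `min_cluster` points are reported with their centroid and the
#' tile pairs involved.
#'
#' @param coll,matches As in [pair_residuals()].
#' @param residual_threshold Residual cutoff in px.
#' @param min_cluster Minimum cluster size to call a seam.
#' @param cluster_radius Single-link radius in global px (NULL = auto).
#' @return Data frame of seams (possibly 0 rows): centroid, size, pairs.
#' @export
detect_seams <- function(coll, matches, residual_threshold = 5,
                         min_cluster = 5, cluster_radius = NULL) {
  pts <- match_residual_points(coll, matches)
  empty <- data.frame(x = numeric(0), y = numeric(0), size = integer(0),
                      pairs = character(0))
  if (nrow(pts) == 0) return(empty)
  if (is.null(cluster_radius)) {
    xy <- cbind(pts$x, pts$y)
    sp <- if (nrow(xy) > 1) {
      sub <- xy[sample.int(nrow(xy), min(nrow(xy), 400)), , drop = FALSE]
      median(apply(as.matrix(dist(sub)) +
                     diag(Inf, nrow(sub)), 1, min))
    } else 1
    cluster_radius <- 2 * sp
  }
  hot <- pts[pts$r > residual_threshold, , drop = FALSE]
  if (nrow(hot) < min_cluster) return(empty)
  cl <- if (nrow(hot) == 1) 1 else
    cutree(hclust(dist(cbind(hot$x, hot$y)), method = "single"),
           h = cluster_radius)
  out <- list()
  for (k in unique(cl)) {
    idx <- which(cl == k)
    if (length(idx) < min_cluster) next
    prs <- unique(paste(hot$p_id[idx], hot$q_id[idx], sep = "|"))
    out[[length(out) + 1]] <- data.frame(
      x = mean(hot$x[idx]), y = mean(hot$y[idx]),
      size = length(idx), pairs = paste(prs, collapse = ";"))
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}

#' Detect stitching gaps from neighbor loss
#'
#' Compares each tile's neighbor set before stitching (nominal stage
#' footprints) and after (solved footprints): a tile is flagged if it lost
#' neighbors entirely or a retained neighbor's overlap fraction fell below
#' `min_overlap_frac`. Tiles with no correspondences (resin/film) are
#' annotated `ignorable`, mirroring how such regions are excluded from QC
#' failure.
#'
#' @param coll_pre Collection with pre-solve (stage) transforms.
#' @param coll_post Collection with solved transforms.
#' @param matches The matches used for solving.
#' @param min_overlap_frac Minimum retained overlap fraction of tile area.
#' @return Data frame: tile_id, reason, ignorable.
#' @export
detect_gaps <- function(coll_pre, coll_post, matches,
                        min_overlap_frac = 0.01) {
  ids <- names(coll_pre$tiles)
  matched <- character(0)
  for (e in matches$entries) if (nrow(e$P) > 0)
    matched <- c(matched, e$p_id, e$q_id)
  feet_pre <- lapply(ids, function(id) tile_footprint(coll_pre, id))
  names(feet_pre) <- ids
  feet_post <- lapply(ids, function(id)
    if (!is.null(coll_post$tiles[[id]])) tile_footprint(coll_post, id) else NULL)
  names(feet_post) <- ids
  out <- list()
  for (id in ids) {
    z <- coll_pre$tiles[[id]]$z
    area <- coll_pre$tiles[[id]]$width * coll_pre$tiles[[id]]$height
    nb <- ids[vapply(ids, function(o)
      o != id && coll_pre$tiles[[o]]$z == z &&
        overlap_area(feet_pre[[id]], feet_pre[[o]]) >
          min_overlap_frac * area, logical(1))]
    if (length(nb) == 0) next
    reason <- NULL
    if (is.null(feet_post[[id]])) {
      reason <- "dropped"
    } else {
      ov <- vapply(nb, function(o) {
        if (is.null(feet_post[[o]])) return(NA_real_)
        overlap_area(feet_post[[id]], feet_post[[o]]) / area
      }, numeric(1))
      ov <- ov[!is.na(ov)]
      if (length(ov) == 0 || any(ov <= 1e-12)) reason <- "lost_neighbors"
      else if (any(ov < min_overlap_frac)) reason <- "low_overlap"
    }
    if (!id %in% matched && is.null(reason)) reason <- "no_matches"
    if (!is.null(reason))
      out[[length(out) + 1]] <- data.frame(
        tile_id = id, reason = reason,
        ignorable = !id %in% matched)
  }
  if (length(out) == 0)
    return(data.frame(tile_id = character(0), reason = character(0),
                      ignorable = logical(0)))
  do.call(rbind, out)
}

#' Scale MAD statistic of a solved montage
#'
#' Per-tile x/y scale factors come from the QR-style decomposition of each
#' solved affine ([extract_scales()]); the statistic is the median absolute
#' deviation about the median scale, per axis. Large values indicate
#' solver-induced tile distortion.
#'
#' @param coll A montaged [tile_collection()].
#' @param z Section index (default: first).
#' @return Named vector: `MAD_x`, `MAD_y`, `median_scale_x`,
#'   `median_scale_y`.
#' @export
montage_mad <- function(coll, z = NULL) {
  if (is.null(z)) z <- coll$sections[1]
  ids <- names(coll$tiles)[vapply(coll$tiles, function(t) t$z == z,
                                  logical(1))]
  sc <- t(vapply(ids, function(id) {
    tlist <- coll$tiles[[id]]$transforms
    if (length(tlist) > 0 && tlist[[1]]$kind == "reference")
      tlist <- tlist[-1]
    extract_scales(tf_compose_affine(tlist))
  }, numeric(2)))
  med <- apply(sc, 2, median)
  mads <- apply(sweep(sc, 2, med), 2, function(d) median(abs(d)))
  c(MAD_x = mads[[1]], MAD_y = mads[[2]],
    median_scale_x = med[[1]], median_scale_y = med[[2]])
}

scales_mad <- function(transforms) {
  sc <- t(vapply(transforms, extract_scales, numeric(2)))
  med <- apply(sc, 2, median)
  mads <- apply(sweep(sc, 2, med), 2, function(d) median(abs(d)))
  c(MAD_x = mads[[1]], MAD_y = mads[[2]],
    median_scale_x = med[[1]], median_scale_y = med[[2]])
}

#' Angular residuals between aligned sections
#'
#' For each cross-section correspondence, the angle between the two
#' vectors from the first section's point centroid to the mapped point in
#' each section; the per-section value is the median over all that
#' section's pair matches within `z_window`. Small angles indicate good
#' global 3D alignment.
#'
#' @param transforms Named list (by z) of per-section transforms.
#' @param cross_matches Cross-section [point_match_set()] against
#'   `sec_<z>` virtual tiles.
#' @param z_window Maximum section distance to include.
#' @return List: `per_section` (named median angle, rad), `angles`
#'   (data frame of per-match angles), `median` (overall).
#' @export
angular_residuals <- function(transforms, cross_matches, z_window = 3) {
  rows <- list()
  for (e in cross_matches$entries) {
    za <- section_id_z(e$p_id); zb <- section_id_z(e$q_id)
    if (abs(zb - za) > z_window) next
    Ta <- transforms[[as.character(za)]]; Tb <- transforms[[as.character(zb)]]
    if (is.null(Ta) || is.null(Tb)) next
    pa <- tf_apply(Ta, e$P); qb <- tf_apply(Tb, e$Q)
    ctr <- colMeans(pa)
    v1 <- sweep(pa, 2, ctr); v2 <- sweep(qb, 2, ctr)
    dot <- rowSums(v1 * v2)
    nn <- sqrt(rowSums(v1^2) * rowSums(v2^2))
    ok <- nn > 0
    ang <- acos(pmin(pmax(dot[ok] / nn[ok], -1), 1))
    rows[[length(rows) + 1]] <- data.frame(z = za, z2 = zb, angle = ang)
  }
  if (length(rows) == 0)
    return(list(per_section = numeric(0),
                angles = data.frame(z = integer(0), z2 = integer(0),
                                    angle = numeric(0)),
                median = NA_real_))
  df <- do.call(rbind, rows)
  list(per_section = tapply(df$angle, df$z, median),
       angles = df, median = median(df$angle))
}

#' Full QC report for a montaged section
#'
#' Aggregates residual, seam, gap, and MAD metrics; pass requires the
#' section median residual and both MAD values within their thresholds and
#' no non-ignorable gaps. Optionally renders a tile-outline QC map
#' coloring gap tiles and seam locations.
#'
#' @param coll Montaged [tile_collection()].
#' @param matches The matches used for solving.
#' @param coll_pre Pre-solve collection for gap detection (NULL skips it).
#' @param residual_threshold Median-residual pass threshold (px).
#' @param mad_threshold MAD pass threshold per axis.
#' @param seam_min_cluster,seam_radius Seam clustering controls.
#' @param map_png Optional path: writes the QC map figure.
#' @param z Section (default: first in `coll`).
#' @return A `qc_report` list with all metrics, thresholds, and `pass`.
#' @export
qc_report <- function(coll, matches, coll_pre = NULL,
                      residual_threshold = 5, mad_threshold = 0.005,
                      seam_min_cluster = 5, seam_radius = NULL,
                      map_png = NULL, z = NULL) {
  if (is.null(z)) z <- coll$sections[1]
  sec <- collection_section(coll, z)
  sec_pre <- if (!is.null(coll_pre)) collection_section(coll_pre, z)
  res <- pair_residuals(sec, matches)
  seams <- detect_seams(sec, matches, residual_threshold,
                        min_cluster = seam_min_cluster,
                        cluster_radius = seam_radius)
  gaps <- if (!is.null(coll_pre))
    detect_gaps(sec_pre, sec, matches) else
    data.frame(tile_id = character(0), reason = character(0),
               ignorable = logical(0))
  mad <- montage_mad(coll, z)
  hard_gaps <- gaps[!gaps$ignorable, , drop = FALSE]
  pass <- isTRUE(res$section_median <= residual_threshold) &&
    mad[["MAD_x"]] <= mad_threshold && mad[["MAD_y"]] <= mad_threshold &&
    nrow(hard_gaps) == 0
  rep <- structure(list(z = z, residuals = res, seams = seams, gaps = gaps,
                        mad = mad,
                        thresholds = c(residual_px = residual_threshold,
                                       mad = mad_threshold),
                        pass = pass),
                   class = "qc_report")
  if (!is.null(map_png)) qc_map(coll, rep, map_png)
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> z =", x$z, if (x$pass) "PASS" else "FAIL", "\n")
  cat("  median residual:", format(x$residuals$section_median), "px (<=",
      x$thresholds[["residual_px"]], ")\n")
  cat("  MAD x/y:", format(x$mad[["MAD_x"]]), "/", format(x$mad[["MAD_y"]]),
      "(<=", x$thresholds[["mad"]], ")\n")
  cat("  seams:", nrow(x$seams), " gaps:", nrow(x$gaps), "\n")
  invisible(x)
}

# Tile-outline QC map: blue tile outlines, red gap tiles, orange seam
# centroids sized by cluster size.
qc_map <- function(coll, report, path) {
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  ids <- names(coll$tiles)[vapply(coll$tiles, function(t) t$z == report$z,
                                  logical(1))]
  feet <- lapply(ids, function(id) tile_footprint(coll, id))
  all_pts <- do.call(rbind, feet)
  graphics::plot(all_pts, type = "n", asp = 1, xlab = "x (px)",
                 ylab = "y (px)", main = sprintf("QC map, z = %d", report$z))
  gap_ids <- report$gaps$tile_id
  for (i in seq_along(ids)) {
    col <- if (ids[i] %in% gap_ids) "red" else "steelblue"
    graphics::polygon(feet[[i]], border = col,
                      col = grDevices::adjustcolor(col, 0.15))
  }
  if (nrow(report$seams) > 0)
    graphics::points(report$seams$x, report$seams$y, pch = 4, cex = 2,
                     lwd = 3, col = "darkorange")
  invisible(path)
}
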