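# Rough 3D alignment from downsampled montages, and fusion of
# independently aligned chunks.

#' Render a downsampled montage for cross-section matching
#'
#' Renders the full section bounding box at the given scale and records
#' the downsample-to-full-resolution mapping so matches found on the
#' render can be lifted back.
#'
#' @param coll Montaged [tile_collection()].
#' @param z Section index.
#' @param scale Render scale (production pipelines use 0.01; synthetic
#'   desk-scale sections warrant larger values).
#' @param truth Optional synthetic truth supplying tile images.
#' @return List: `image`, `bbox`, `scale`, and `lift(pts)` mapping render
#'   coordinates to full-resolution global coordinates.
#' @export
render_downsampled_montage <- function(coll, z, scale = 0.01, truth = NULL) {
  r <- render_bbox(coll, z, scale = scale, truth = truth)
  bbox <- r$bbox
  r$lift <- function(pts) {
    pts <- as_pts(pts)
    cbind(bbox[1] + pts[, 1] / scale, bbox[2] + pts[, 2] / scale)
  }
  r
}

#' Match neighboring sections on downsampled renders
#'
#' For each section pair within `z_window` (skipping missing sections),
#' runs the candidate/RANSAC/trim chain on the downsampled montage
#' renders and lifts the matches to full-resolution section coordinates,
#' stored against virtual `sec_<z>` tiles. Cross-section consensus uses a
#' similarity model to tolerate section-scale rotations.
#'
#' @param coll Montaged [tile_collection()].
#' @param z_window Maximum section distance to pair.
#' @param scale Render scale.
#' @param truth Optional synthetic truth supplying tile images.
#' @param seed Seed for the RANSAC sampling.
#' @return List: `matches` ([point_match_set()], full-resolution section
#'   frames), `unmatched` (data frame of failed pairs).
#' @export
match_sections <- function(coll, z_window = 3, scale = 0.25, truth = NULL,
                           seed = 1) {
  secs <- coll$sections
  renders <- list()
  for (z in secs)
    renders[[as.character(z)]] <-
      render_downsampled_montage(coll, z, scale, truth)
  entries <- list(); unmatched <- list()
  for (a in seq_along(secs)) for (b in seq_along(secs)) {
    if (b <= a) next
    dz <- secs[b] - secs[a]
    if (dz > z_window) next
    ra <- renders[[as.character(secs[a])]]
    rb <- renders[[as.character(secs[b])]]
    m <- match_images(ra$image, rb$image, model_kind = "similarity",
                      seed = derive_seed(seed, secs[a], secs[b]))
    if (m$unmatchable || nrow(m$P) == 0) {
      unmatched[[length(unmatched) + 1]] <-
        data.frame(z_a = secs[a], z_b = secs[b])
      next
    }
    entries[[length(entries) + 1]] <- match_entry(
      sprintf("sec_%d", secs[a]), sprintf("sec_%d", secs[b]),
      ra$lift(m$P), rb$lift(m$Q))
  }
  list(matches = point_match_set(entries),
       unmatched = if (length(unmatched)) do.call(rbind, unmatched) else
         data.frame(z_a = integer(0), z_b = integer(0)))
}

#' Rough 3D alignment of a montaged stack
#'
#' Runs the progressive rigid/affine/TPS per-section solve and appends
#' each solved per-section transform to every tile of its section; the
#' stack state becomes `aligned3d`.
#'
#' @param coll Montaged [tile_collection()].
#' @param cross_matches Cross-section matches in section frames.
#' @param grid_nodes TPS control nodes per section (25-49).
#' @param stages Progressive stage list.
#' @param opts Solve options for the per-section stages.
#' @return List: updated `coll`, per-section `transforms`,
#'   `stage_medians`.
#' @export
rough_align <- function(coll, cross_matches, grid_nodes = 25,
                        stages = c("rigid", "affine", "thin_plate_spline"),
                        opts = solve_options(lambda_translation = 1e-7,
                                             lambda_linear = 1e-3,
                                             lambda_polynomial = 1e-2)) {
  frames <- section_frames(coll)
  res <- solve_sections_progressive(frames, cross_matches, stages = stages,
                                    opts = opts, grid_nodes = grid_nodes)
  for (id in names(coll$tiles)) {
    z <- as.character(coll$tiles[[id]]$z)
    if (!is.null(res$transforms[[z]]))
      coll$tiles[[id]]$transforms <-
        c(coll$tiles[[id]]$transforms, list(res$transforms[[z]]))
  }
  coll$state <- "aligned3d"
  list(coll = coll, transforms = res$transforms,
       stage_medians = res$stage_medians)
}

#' Register two aligned chunks on their shared sections
#'
#' Fits the requested rigid-family model to corresponding positions of
#' shared-section cross-chunk correspondences, mapping chunk B's frame
#' into chunk A's.
#'
#' @param chunk_a,chunk_b Named lists (by z) of per-section transforms.
#' @param matches Section-frame [point_match_set()] for the shared
#'   sections (entries `sec_<z>` to itself across chunks use identical
#'   P/Q section coordinates).
#' @param model `"translation"`, `"rigid"`, `"similarity"`, or
#'   `"affine"`.
#' @return The fitted `transform` taking chunk B coordinates to chunk A.
#' @export
register_chunks <- function(chunk_a, chunk_b, matches,
                            model = "similarity") {
  shared <- intersect(names(chunk_a), names(chunk_b))
  if (length(shared) == 0) stop("chunks share no sections")
  src <- list(); dst <- list()
  for (e in matches$entries) {
    za <- as.character(section_id_z(e$p_id))
    if (!za %in% shared) next
    dst[[length(dst) + 1]] <- tf_apply(chunk_a[[za]], e$P)
    src[[length(src) + 1]] <- tf_apply(chunk_b[[za]], e$P)
  }
  if (length(src) == 0) {
    # fall back to section-frame grid points of the shared sections
    for (za in shared) {
      g <- as.matrix(expand.grid(seq(0, 1000, length.out = 5),
                                 seq(0, 1000, length.out = 5)))
      dst[[length(dst) + 1]] <- tf_apply(chunk_a[[za]], g)
      src[[length(src) + 1]] <- tf_apply(chunk_b[[za]], g)
    }
  }
  fit_transform(model, do.call(rbind, src), do.call(rbind, dst))
}

#' Fuse independently aligned chunks
#'
#' Given a layout tree (root chunk plus edges carrying each child's
#' transform into its parent's frame), maps every chunk into the root
#' frame and blends the overlap sections with interpolated transforms:
#' the blend weight is linear in z across the overlap (0 at the first
#' chunk's edge, 1 at the second's), so the fused mapping equals the
#' adjoining chunk exactly at either edge; a single-section overlap gets
#' weight 0.5.
#'
#' @param chunks Named list: chunk id -> named list (by z) of per-section
#'   transforms.
#' @param layout List: `root` (chunk id) and `edges` (list of
#'   `list(parent =, child =, transform =)`).
#' @return Named list (by z) of fused per-section transforms.
#' @export
fuse_chunks <- function(chunks, layout) {
  ids <- names(chunks)
  to_root <- setNames(vector("list", length(ids)), ids)
  to_root[[layout$root]] <- tf_affine()
  remaining <- layout$edges
  guard <- 0
  while (length(remaining) > 0) {
    progressed <- FALSE
    rest <- list()
    for (e in remaining) {
      if (!is.null(to_root[[e$parent]])) {
        if (!is.null(to_root[[e$child]])) stop("layout tree has a cycle")
        to_root[[e$child]] <- tf_compose_affine(
          list(e$transform, to_root[[e$parent]]))
        progressed <- TRUE
      } else rest <- c(rest, list(e))
    }
    remaining <- rest
    guard <- guard + 1
    if (!progressed || guard > 10000)
      stop("layout tree has a cycle or unreachable chunk")
  }
  # compose each chunk's per-section transforms into the root frame
  rooted <- list()
  for (cid in ids) {
    if (is.null(to_root[[cid]])) stop("chunk not reachable from root: ", cid)
    rooted[[cid]] <- lapply(chunks[[cid]], function(t)
      compose_into_root(t, to_root[[cid]]))
  }
  zs <- sort(unique(as.integer(unlist(lapply(rooted, names)))))
  fused <- list()
  for (z in zs) {
    zc <- as.character(z)
    owners <- ids[vapply(rooted, function(ch) !is.null(ch[[zc]]), logical(1))]
    if (length(owners) == 1) {
      fused[[zc]] <- rooted[[owners]][[zc]]
    } else {
      a <- owners[1]; b <- owners[2]
      ov <- sort(as.integer(intersect(names(rooted[[a]]), names(rooted[[b]]))))
      lam <- if (length(ov) == 1) 0.5 else
        (match(z, ov) - 1) / (length(ov) - 1)
      fused[[zc]] <- tf_interpolated(rooted[[a]][[zc]], rooted[[b]][[zc]],
                                     lam)
    }
  }
  fused
}

compose_into_root <- function(t, root_tf) {
  if (t$kind %in% c("translation", "rigid", "similarity", "affine"))
    return(tf_compose_affine(list(t, root_tf)))
  if (t$kind == "thin_plate_spline") {
    # an affine R after a TPS is again a TPS with mapped coefficients
    af <- tf_as_affine(root_tf)
    return(tf_tps(t$centers, a = as.numeric(af$M %*% t$a + af$t),
                  B = af$M %*% t$B, w = t$w %*% t(af$M)))
  }
  stop("cannot compose transform kind '", t$kind, "' into the root frame")
}
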