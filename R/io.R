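# JSON serialization of tile collections and point-match sets.
#
# The schema is self-defined (documented in the README): UTF-8 JSON with
# keys emitted in sorted order and full-precision numbers, so that
# write -> read -> write round trips are byte identical.

sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x) > 0) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else if (is.list(x)) {
    lapply(x, sort_keys)
  } else x
}

write_canonical_json <- function(x, path) {
  txt <- jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA,
                          null = "null", pretty = TRUE)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

transform_to_json <- function(t) {
  switch(t$kind,
    translation = list(kind = "translation", tx = t$tx, ty = t$ty),
    rigid = list(kind = "rigid", theta = t$theta, tx = t$tx, ty = t$ty),
    similarity = list(kind = "similarity", s = t$s, theta = t$theta,
                      tx = t$tx, ty = t$ty),
    affine = list(kind = "affine", M = unclass(t$M), t = t$t),
    polynomial2 = list(kind = "polynomial2", coef = unclass(t$coef)),
    thin_plate_spline = list(kind = "thin_plate_spline",
                             centers = unclass(t$centers), a = t$a,
                             B = unclass(t$B), w = unclass(t$w)),
    reference = list(kind = "reference", ref_id = t$ref_id),
    interpolated = list(kind = "interpolated", a = transform_to_json(t$a),
                        b = transform_to_json(t$b),
                        lambda_blend = t$lambda_blend),
    stop("unknown transform kind: ", t$kind)
  )
}

transform_from_json <- function(j, context = "") {
  kind <- j$kind
  if (is.null(kind) || !kind %in% TRANSFORM_KINDS)
    stop("schema error", context, ": unknown transform kind '", kind, "'")
  as_mat <- function(m, nc) matrix(unlist(m), ncol = nc, byrow = TRUE)
  switch(kind,
    translation = tf_translation(j$tx, j$ty),
    rigid = tf_rigid(j$theta, j$tx, j$ty),
    similarity = tf_similarity(j$s, j$theta, j$tx, j$ty),
    affine = tf_affine(as_mat(j$M, 2), unlist(j$t)),
    polynomial2 = tf_polynomial2(as_mat(j$coef, 6)),
    thin_plate_spline = tf_tps(as_mat(j$centers, 2), unlist(j$a),
                               as_mat(j$B, 2), as_mat(j$w, 2)),
    reference = tf_reference(j$ref_id),
    interpolated = tf_interpolated(transform_from_json(j$a, context),
                                   transform_from_json(j$b, context),
                                   j$lambda_blend)
  )
}

#' Write a tile collection to JSON
#'
#' @param coll A [tile_collection()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_tilespecs <- function(coll, path) {
  tiles <- lapply(unname(coll$tiles), function(t) {
    list(tile_id = t$tile_id, z = t$z, width = t$width, height = t$height,
         pixel_size_nm = t$pixel_size,
         stage_position = t$stage_position,
         transforms = lapply(t$transforms, transform_to_json),
         image_ref = t$image_ref, group_id = t$group_id)
  })
  ord <- order(vapply(tiles, `[[`, character(1), "tile_id"))
  shared <- lapply(coll$shared, transform_to_json)
  write_canonical_json(list(name = coll$name, state = coll$state,
                            tiles = tiles[ord], shared = shared), path)
}

#' Read a tile collection from JSON
#'
#' @param path File written by [write_tilespecs()].
#' @return A [tile_collection()].
#' @export
read_tilespecs <- function(path) {
  j <- jsonlite::read_json(path)
  tiles <- lapply(j$tiles, function(tj) {
    ts <- tilespec(tile_id = tj$tile_id, z = tj$z, width = tj$width,
                   height = tj$height, pixel_size = tj$pixel_size_nm,
                   stage_position = unlist(tj$stage_position),
                   transforms = lapply(tj$transforms, transform_from_json,
                                       context = paste0(" in tile ", tj$tile_id)),
                   image_ref = tj$image_ref, group_id = tj$group_id)
    ts
  })
  ids <- vapply(tiles, function(t) t$tile_id, character(1))
  if (anyDuplicated(ids))
    stop("integrity error: duplicate tile_id '",
         ids[duplicated(ids)][1], "' in ", path)
  shared <- lapply(j$shared, transform_from_json)
  tile_collection(name = j$name, tiles = tiles, state = j$state,
                  shared = shared)
}

#' Write a point-match set to JSON
#'
#' Entries are stored canonically ordered by `(p_id, q_id)`.
#'
#' @param pms A [point_match_set()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_matches <- function(pms, path) {
  entries <- lapply(pms$entries, function(e) {
    list(p_id = e$p_id, q_id = e$q_id,
         P = unclass(e$P), Q = unclass(e$Q), w = e$w)
  })
  write_canonical_json(list(matches = entries), path)
}

#' Read a point-match set from JSON
#'
#' @param path File written by [write_matches()].
#' @return A [point_match_set()].
#' @export
read_matches <- function(path) {
  j <- jsonlite::read_json(path)
  entries <- lapply(j$matches, function(e) {
    P <- matrix(as.numeric(unlist(e$P)), ncol = 2, byrow = TRUE)
    Q <- matrix(as.numeric(unlist(e$Q)), ncol = 2, byrow = TRUE)
    w <- as.numeric(unlist(e$w))
    if (is.null(w)) w <- numeric(0)
    if (nrow(P) != nrow(Q) || nrow(P) != length(w))
      stop("schema error: P, Q, w lengths differ for pair ",
           e$p_id, "/", e$q_id)
    match_entry(e$p_id, e$q_id, P, Q, w)
  })
  point_match_set(entries)
}
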