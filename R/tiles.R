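#' Create a tile specification
#'
#' One camera acquisition's metadata record: geometry, nominal stage
#' position, and the ordered transform list mapping the tile's local pixel
#' frame into the section (global) frame.
#'
#' @param tile_id Unique tile identifier.
#' @param z Integer section index.
#' @param width,height Tile dimensions in pixels.
#' @param pixel_size Physical pixel size in nm/px.
#' @param stage_position Length-2 nominal stage position (px, global frame).
#' @param transforms Ordered list of [transform][tf_affine] objects, applied
#'   first to last.
#' @param image_ref Image source: a file path, or a list descriptor for
#'   synthetic textures.
#' @param group_id Lens-calibration group label.
#' @return A `tilespec` object.
#' @export
tilespec <- function(tile_id, z, width, height, pixel_size = 4,
                     stage_position = c(0, 0), transforms = list(),
                     image_ref = NULL, group_id = "default") {
  if (width <= 0 || height <= 0) stop("tile width and height must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(tile_id = as.character(tile_id), z = as.integer(z),
                 width = as.numeric(width), height = as.numeric(height),
                 pixel_size = as.numeric(pixel_size),
                 stage_position = as.numeric(stage_position),
                 transforms = transforms, image_ref = image_ref,
                 group_id = as.character(group_id)),
            class = "tilespec")
}

#' Create a tile collection
#'
#' The in-memory analogue of an image stack: a named set of tiles, the
#' ordered section indices present (gaps allowed), a shared-transform
#' registry (lens corrections), and a pipeline state label.
#'
#' @param name Collection name.
#' @param tiles List of [tilespec()] objects.
#' @param state One of `"raw"`, `"lens_corrected"`, `"montaged"`,
#'   `"aligned3d"`, `"fused"`.
#' @param shared Named list of shared transforms referenced by tiles.
#' @return A `tile_collection` object.
#' @export
tile_collection <- function(name = "stack", tiles = list(), state = "raw",
                            shared = list()) {
  states <- c("raw", "lens_corrected", "montaged", "aligned3d", "fused")
  if (!state %in% states) stop("unknown collection state: ", state)
  ids <- vapply(tiles, function(t) t$tile_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate tile_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(tiles) <- ids
  zs <- sort(unique(vapply(tiles, function(t) t$z, integer(1))))
  structure(list(name = name, state = state, tiles = tiles,
                 sections = zs, shared = shared),
            class = "tile_collection")
}

#' @export
print.tile_collection <- function(x, ...) {
  cat("<tile_collection>", x$name, "state:", x$state, "\n")
  cat(" ", length(x$tiles), "tiles across", length(x$sections), "sections\n")
  invisible(x)
}

collection_section <- function(coll, z) {
  keep <- vapply(coll$tiles, function(t) t$z == z, logical(1))
  tile_collection(coll$name, unname(coll$tiles[keep]), coll$state, coll$shared)
}

#' Map local tile points to the global frame
#'
#' @param coll Tile collection (supplies the shared-transform registry).
#' @param tile_id Tile whose transform chain to apply.
#' @param pts N x 2 local points.
#' @param from Coordinate origin of `pts`: `"raw"` applies the full chain;
#'   `"lens_corrected"` skips a leading reference (lens) transform, since
#'   point matches are stored in lens-corrected coordinates.
#' @return N x 2 global points.
#' @export
tile_map_points <- function(coll, tile_id, pts, from = "lens_corrected") {
  tile <- coll$tiles[[tile_id]]
  if (is.null(tile)) stop("unknown tile: ", tile_id)
  tlist <- tile$transforms
  if (from == "lens_corrected" && length(tlist) > 0 &&
      tlist[[1]]$kind == "reference")
    tlist <- tlist[-1]
  tf_apply_list(tlist, pts, coll$shared)
}

tile_corners <- function(tile) {
  rbind(c(0, 0), c(tile$width, 0), c(tile$width, tile$height), c(0, tile$height))
}

tile_footprint <- function(coll, tile_id, from = "lens_corrected") {
  tile_map_points(coll, tile_id, tile_corners(coll$tiles[[tile_id]]), from = from)
}

#' Create a point-match set
#'
#' @param entries List of entries, each a list with `p_id`, `q_id`, `P`
#'   (N x 2, p's local frame), `Q` (N x 2, q's local frame), and `w`
#'   (length-N weights in (0, 1]).
#' @return A `point_match_set` object.
#' @export
point_match_set <- function(entries = list()) {
  seen <- character(0)
  for (e in entries) {
    if (e$p_id == e$q_id) stop("self-pair not allowed: ", e$p_id)
    if (nrow(as_pts(e$P)) != nrow(as_pts(e$Q)) ||
        nrow(as_pts(e$P)) != length(e$w))
      stop("P, Q, and w must have equal length for pair ", e$p_id, "/", e$q_id)
    key <- paste(sort(c(e$p_id, e$q_id)), collapse = "\r")
    if (key %in% seen) stop("duplicate pair: ", e$p_id, "/", e$q_id)
    seen <- c(seen, key)
  }
  entries <- canonical_match_order(entries)
  structure(list(entries = entries), class = "point_match_set")
}

match_entry <- function(p_id, q_id, P, Q, w = NULL) {
  P <- as_pts(P); Q <- as_pts(Q)
  if (is.null(w)) w <- rep(1, nrow(P))
  list(p_id = as.character(p_id), q_id = as.character(q_id),
       P = P, Q = Q, w = as.numeric(w))
}

canonical_match_order <- function(entries) {
  if (length(entries) == 0) return(entries)
  p <- vapply(entries, `[[`, character(1), "p_id")
  q <- vapply(entries, `[[`, character(1), "q_id")
  entries[order(p, q)]
}

#' @export
print.point_match_set <- function(x, ...) {
  n <- sum(vapply(x$entries, function(e) nrow(e$P), integer(1)))
  cat("<point_match_set>", length(x$entries), "pairs,", n, "correspondences\n")
  invisible(x)
}
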