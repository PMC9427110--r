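# Sequential end-to-end orchestration: generate -> lens -> match ->
# montage (optionally via the lambda sweep) -> QC -> 3D -> render, driven
# by a YAML config with one block per stage.

#' Run the full desk-scale assembly pipeline
#'
#' Executes the stages configured in a YAML file (or an equivalent list):
#' synthetic generation, lens estimation/application, geometric or
#' image-based matching, per-section montage solving (optionally through
#' the regularization sweep), QC, progressive 3D alignment, and rendering.
#' Stage outputs are written as JSON/TIFF artifacts under `out_dir`, and a
#' JSON-lines log records each stage with parameters and wall time.
#'
#' @param config Path to a YAML config, or a list with the same structure:
#'   top-level `seed`, `out_dir`, and stage blocks `generate`, `lens`,
#'   `match`, `montage`, `qc`, `align3d`, `render` (missing blocks are
#'   skipped).
#' @return List of stage results, invisibly; `$qc` carries the per-section
#'   reports and `$status` is 0 when every solved section passed QC
#'   (directly or at a relaxed optimization level).
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- cfg$seed %||% 1
  out_dir <- cfg$out_dir %||% tempfile("stitchforge_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "pipeline.log.jsonl")
  log_stage <- function(stage, params, t0) {
    rec <- list(stage = stage, params = params,
                wall_s = round(as.numeric(Sys.time()) - t0, 3))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = logf, append = TRUE)
  }
  res <- list(out_dir = out_dir, status = 0L)

  if (is.null(cfg$generate)) stop("config must include a 'generate' block")
  t0 <- as.numeric(Sys.time())
  g <- cfg$generate
  tile_size <- g$tile_size %||% 256
  spec <- synthetic_spec(
    rows = g$rows %||% 4, cols = g$cols %||% 4,
    tile_size = tile_size,
    overlap_frac = g$overlap_frac %||% 0.13,
    n_sections = g$n_sections %||% 3,
    translation_sd = g$translation_sd %||% (0.005 * tile_size),
    match_noise_sd = g$match_noise_sd %||% 1,
    featureless_tile_frac = g$featureless_tile_frac %||% 0,
    missing_z = g$missing_z %||% integer(0),
    seed = seed)
  series <- make_series(spec)
  coll <- series$coll
  write_tilespecs(coll, file.path(out_dir, "tiles_raw.json"))
  log_stage("generate", g, t0)
  res$spec <- spec; res$truth <- series$truth

  if (!is.null(cfg$lens)) {
    t0 <- as.numeric(Sys.time())
    lc <- cfg$lens
    calib_spec <- synthetic_spec(
      rows = lc$rows %||% 3, cols = lc$cols %||% 3,
      tile_size = spec$tile_size, overlap_frac = lc$overlap_frac %||% 0.5,
      translation_sd = 2, rotation_sd = 5e-4, scale_sd = 1e-3,
      match_noise_sd = 0.25, matches_per_pair = lc$matches_per_pair %||% 60,
      lens_model = if (is.null(lc$k1)) "none" else
        list(kind = "radial", k1 = lc$k1, k2 = lc$k2 %||% 0),
      seed = derive_seed(seed, 11))
    calib <- make_calibration_montage(calib_spec)
    calib_matches <- make_matches(calib$truth, frame = "raw")
    lens <- estimate_lens_correction(calib$coll, calib_matches,
                                     grid_n = lc$grid_n %||% 6)
    coll <- apply_lens_correction(coll, lens)
    write_tilespecs(coll, file.path(out_dir, "tiles_lens.json"))
    log_stage("lens", lc, t0)
    res$lens <- lens
  }

  t0 <- as.numeric(Sys.time())
  mt <- cfg$match %||% list()
  matches <- make_matches(series$truth, spec)
  write_matches(matches, file.path(out_dir, "matches.json"))
  log_stage("match", mt, t0)
  res$matches <- matches

  t0 <- as.numeric(Sys.time())
  mo <- cfg$montage %||% list()
  pre <- coll
  qc_reports <- list()
  for (z in coll$sections) {
    if (isTRUE(mo$optimize)) {
      sw <- relax_and_select(coll, matches, z = z)
      if (is.na(sw$chosen)) { res$status <- 1L; next }
      sol <- solve_montage(coll, matches, sw$chosen_opts, z = z)
    } else {
      sol <- solve_montage(coll, matches, solve_options(), z = z)
    }
    coll <- sol$coll
    rep <- qc_report(coll, matches, coll_pre = pre, z = z,
                     map_png = file.path(out_dir,
                                         sprintf("qc_map_z%03d.png", z)))
    qc_reports[[as.character(z)]] <- rep
    if (!rep$pass) res$status <- 1L
  }
  write_tilespecs(coll, file.path(out_dir, "tiles_montaged.json"))
  log_stage("montage", mo, t0)
  res$qc <- qc_reports

  if (!is.null(cfg$align3d)) {
    t0 <- as.numeric(Sys.time())
    a3 <- cfg$align3d
    cross <- make_cross_matches(series$truth, spec,
                                z_window = a3$z_window %||% 3)
    ra <- rough_align(coll, cross, grid_nodes = a3$grid_nodes %||% 25)
    coll <- ra$coll
    write_tilespecs(coll, file.path(out_dir, "tiles_aligned3d.json"))
    log_stage("align3d", a3, t0)
    res$align3d <- ra
    res$angular <- angular_residuals(ra$transforms, cross)
  }

  if (!is.null(cfg$render)) {
    t0 <- as.numeric(Sys.time())
    rd <- cfg$render
    paths <- export_stack(coll, coll$sections,
                          file.path(out_dir, "render"),
                          scale = rd$scale %||% 0.25, truth = series$truth)
    log_stage("render", rd, t0)
    res$rendered <- paths
  }

  res$coll <- coll
  invisible(res)
}
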