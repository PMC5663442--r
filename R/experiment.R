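#' Configure an end-to-end catchment experiment
#'
#' Bundles everything one run needs: the scene (a preset name or a
#' [scene_spec()]), the sampling cube, the reference heights, the analysis
#' conditions (horizon masking and background), the threshold fraction and
#' the seed. Validation is strict and names the offending field.
#'
#' @param scene preset name (see [preset_scene()]) or a `catchvol_scene_spec`.
#' @param grid list with `side_m`, `spacing_m` and optionally `center`;
#'   counts per axis are `round(side / spacing) + 1` and `side_m` must be an
#'   integer multiple of `spacing_m`.
#' @param reference_heights_m heights above ground (meters) at which
#'   reference snapshots are taken, at the horizontal centre of the grid.
#' @param mask_modes subset of `c("all", "above")`: compare full panoramas
#'   and/or only the above-horizon half.
#' @param backgrounds subset of `c("none", "uniform", "panorama")`; each
#'   background is a separate render of the world (the background changes
#'   what missed rays see), whereas mask modes reuse renders.
#' @param threshold_fraction fraction of the reference self-rotIDF maximum
#'   used as the per-meter gradient threshold (default 0.10).
#' @param width panorama width in pixels (384 full scale; smaller for
#'   desk-scale runs).
#' @param seed integer seed for the scene when `scene` is a preset name.
#' @return object of class `catchvol_config`.
#' @export
experiment_config <- function(scene = "site3_like",
                              grid = list(side_m = 2, spacing_m = 0.2),
                              reference_heights_m = c(0.1, 1),
                              mask_modes = "all",
                              backgrounds = "none",
                              threshold_fraction = 0.10,
                              width = 96L,
                              seed = 1L) {
  fail <- function(field, why) {
    stop(sprintf("invalid experiment config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (is.character(scene)) {
    scene <- preset_scene(scene, seed = seed)
  } else if (!inherits(scene, "catchvol_scene_spec")) {
    fail("scene", "must be a preset name or a scene_spec")
  }
  if (is.null(grid$side_m) || is.null(grid$spacing_m) ||
      grid$side_m <= 0 || grid$spacing_m <= 0)
    fail("grid", "must supply positive side_m and spacing_m")
  ratio <- grid$side_m / grid$spacing_m
  if (abs(ratio - round(ratio)) > 1e-9)
    fail("grid$side_m", "must be an integer multiple of spacing_m")
  if (is.null(grid$center))
    grid$center <- c(0, 0, grid$side_m / 2 + grid$spacing_m / 2)
  if (!is.numeric(reference_heights_m) || !length(reference_heights_m))
    fail("reference_heights_m", "must be a non-empty numeric vector")
  if (!all(mask_modes %in% c("all", "above")) || !length(mask_modes))
    fail("mask_modes", "must be a subset of c('all', 'above')")
  if (!all(backgrounds %in% c("none", "uniform", "panorama")) ||
      !length(backgrounds))
    fail("backgrounds", "must be a subset of c('none', 'uniform', 'panorama')")
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    fail("threshold_fraction", "must be in (0, 1]")
  if (width < 8 || width %% 2 != 0) fail("width", "must be an even number >= 8")
  structure(list(scene = scene, grid = grid,
                 reference_heights_m = reference_heights_m,
                 mask_modes = mask_modes, backgrounds = backgrounds,
                 threshold_fraction = threshold_fraction,
                 width = as.integer(width), seed = as.integer(seed)),
            class = "catchvol_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' @param path config file; fields as in [experiment_config()] (a scene
#'   may be given inline under `scene_spec` or as a preset name under
#'   `scene`).
#' @return a `catchvol_config`.
#' @export
read_experiment_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::read_json(path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  if (!is.null(x$scene_spec)) {
    x$scene <- do.call(scene_spec, x$scene_spec)
    x$scene_spec <- NULL
  }
  do.call(experiment_config, x)
}

# Polynomial rolling hash of a deparsed object; stable content fingerprint
# for manifests (not cryptographic).
.config_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a full catchment experiment
#'
#' Renders the sampling grid once per background condition, then, for every
#' reference height and mask mode: computes the translational IDF volume,
#' derives the gradient threshold from the reference image's self-rotIDF,
#' extracts the catchment volume, and writes the results (IDF CSV, axis
#' transect CSVs, catchment PLY/CSV/JSON) under `out_dir`, together with a
#' manifest recording the configuration, its hash, the seed, and the total
#' number of renders. Mask-mode conditions reuse renders; background
#' conditions re-render, because the background changes the scene itself.
#'
#' @param config a [experiment_config()].
#' @param out_dir output directory (created if missing). `NULL` skips all
#'   file output and returns results in memory only.
#' @param progress print progress messages.
#' @return invisibly, a list of class `catchvol_bundle`: `config`, `grid`,
#'   `n_renders`, and `results` — one entry per (background, reference
#'   height, mask mode) with the threshold, the IDF volume and the
#'   catchment.
#' @export
run_experiment <- function(config, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "catchvol_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  grid <- grid_from_side(config$grid$side_m, config$grid$spacing_m,
                         center = config$grid$center)
  z_lo <- grid$origin[3]
  ic <- (grid$counts[1:2] + 1L) %/% 2L
  results <- list()
  n_renders <- 0L
  for (bg in config$backgrounds) {
    spec <- config$scene
    spec$background$type <- bg
    scene <- make_scene(spec)
    stack <- render_grid(scene, grid, width = config$width,
                         progress = progress)
    n_renders <- n_renders + stack$n_renders
    for (height in config$reference_heights_m) {
      kz <- as.integer(round((height - z_lo) / grid$spacing)) + 1L
      if (kz < 1L || kz > grid$counts[3])
        stop(sprintf("reference height %g m falls outside the grid", height))
      ref_idx <- c(ic[1], ic[2], kz)
      reference <- stack$panos[[.linear_index(grid, ref_idx)]]
      for (mm in config$mask_modes) {
        mask <- if (mm == "all") NULL else
          horizon_mask(mm, height = config$width %/% 2L, width = config$width)
        threshold <- gradient_threshold(reference, mask,
                                        fraction = config$threshold_fraction)
        idf <- trans_idf(stack, ref_idx, mask_mode = mm)
        catch <- catchment_volume(idf, threshold)
        tag <- sprintf("bg-%s_ref-%gm_mask-%s", bg, height, mm)
        if (progress)
          message(sprintf("%s: threshold %.4g grey/m, %d successes",
                          tag, threshold, catch$counts[["success"]]))
        if (!is.null(out_dir)) {
          write_idf_csv(idf, file.path(out_dir, paste0("idf_", tag, ".csv")))
          for (ax in c("x", "y", "z")) {
            utils::write.csv(idf_transect(idf, ax),
                             file.path(out_dir,
                                       sprintf("transect_%s_%s.csv", ax, tag)),
                             row.names = FALSE)
          }
          write_catchment_ply(catch, file.path(out_dir, paste0("catchment_", tag, ".ply")))
          write_catchment_csv(catch, file.path(out_dir, paste0("catchment_", tag, ".csv")))
          write_catchment_json(catch, file.path(out_dir, paste0("catchment_", tag, ".json")))
        }
        results[[tag]] <- list(background = bg, reference_height_m = height,
                               mask_mode = mm, reference_index = ref_idx,
                               threshold = threshold, idf = idf,
                               catchment = catch)
      }
    }
  }
  bundle <- structure(list(config = config, grid = grid,
                           n_renders = n_renders, results = results),
                      class = "catchvol_bundle")
  if (!is.null(out_dir)) {
    manifest <- list(
      config_hash = .config_hash(unclass(config)),
      seed = config$seed,
      width = config$width,
      grid = list(center = grid$center, spacing = grid$spacing,
                  counts = grid$counts),
      n_renders = n_renders,
      conditions = lapply(results, function(r) {
        list(background = r$background,
             reference_height_m = r$reference_height_m,
             mask_mode = r$mask_mode,
             threshold_grey_per_m = r$threshold,
             success_count = as.numeric(r$catchment$counts[["success"]]),
             success_fraction = r$catchment$success_fraction)
      }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(bundle)
}

#' Compare two experimental conditions
#'
#' Takes two catchment volumes on the same grid (e.g. full-view vs
#' above-horizon, or uniform vs panorama background) and reports the
#' success counts, the signed difference, and the voxel sets unique to each
#' condition.
#'
#' @param a,b [catchment_volume()] results sharing the same grid, or
#'   single-condition entries from a [run_experiment()] bundle.
#' @param json_path optional path to write the report as JSON.
#' @return list with `count_a`, `count_b`, `diff` (a minus b), `only_a`,
#'   `only_b` (index matrices) and `shared` (count of voxels successful in
#'   both).
#' @export
compare_conditions <- function(a, b, json_path = NULL) {
  if (!inherits(a, "catchvol_catchment")) a <- a$catchment
  if (!inherits(b, "catchvol_catchment")) b <- b$catchment
  if (!all(a$grid$counts == b$grid$counts) ||
      a$grid$spacing != b$grid$spacing ||
      !all(abs(a$grid$center - b$grid$center) < 1e-12))
    stop("catchments are defined on different grids")
  sa <- a$status == "success"
  sb <- b$status == "success"
  rep_ <- list(count_a = sum(sa), count_b = sum(sb),
               diff = sum(sa) - sum(sb),
               shared = sum(sa & sb),
               only_a = which(sa & !sb, arr.ind = TRUE),
               only_b = which(sb & !sa, arr.ind = TRUE))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(count_a = rep_$count_a, count_b = rep_$count_b, diff = rep_$diff,
           shared = rep_$shared,
           only_a = nrow(rep_$only_a), only_b = nrow(rep_$only_b)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  rep_
}
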