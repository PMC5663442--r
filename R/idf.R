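#' Root-mean-square pixel difference between two panoramas
#'
#' The elementary image comparison: the square root of the mean squared
#' grey-level difference over the masked pixels, computed in double
#' precision on the 0-255 scale. Symmetric in its arguments; 0 for
#' identical images; at most 255 (all-black vs all-white).
#'
#' @param a,b greyscale matrices of equal dimensions, values in `[0, 255]`.
#' @param mask logical matrix of the same dimensions selecting the pixels
#'   to compare (default: all).
#' @return a single non-negative number in grey levels.
#' @export
rms_difference <- function(a, b, mask = NULL) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("panoramas must be matrices of identical dimensions")
  if (is.null(mask)) return(sqrt(mean((a - b)^2)))
  if (!all(dim(mask) == dim(a))) stop("mask dimensions must match the panoramas")
  if (!any(mask)) stop("mask selects no pixels")
  d <- a[mask] - b[mask]
  sqrt(mean(d * d))
}

#' Rotational image difference function (rotIDF)
#'
#' Entry `k + 1` is the r.m.s. difference between the reference panorama
#' rolled by `k` columns (each column = `360 / width` degrees of yaw) and
#' the comparison view, for `k = 0 .. width - 1`. The location of the
#' minimum gives the best-matching heading. The mask must be row-uniform
#' (whole rows kept or dropped) so that rolling commutes with masking.
#'
#' @param reference,current greyscale matrices of equal dimensions.
#' @param mask optional logical matrix; must consist of full rows.
#' @return numeric vector of length `ncol(reference)`, grey levels.
#' @export
rot_idf <- function(reference, current, mask = NULL) {
  if (!all(dim(reference) == dim(current)))
    stop("panoramas must have identical dimensions")
  if (!is.null(mask)) {
    row_ok <- apply(mask, 1, function(r) all(r) || !any(r))
    if (!all(row_ok))
      stop("rotIDF mask must be azimuth-uniform (whole rows)")
    keep <- mask[, 1]
    reference <- reference[keep, , drop = FALSE]
    current <- current[keep, , drop = FALSE]
    if (nrow(reference) == 0L) stop("mask selects no pixels")
  }
  w <- ncol(reference)
  vapply(seq_len(w) - 1L, function(k) {
    rms_difference(roll_azimuth(reference, k), current)
  }, numeric(1))
}

#' Maximum of the self-rotational IDF
#'
#' The maximum r.m.s. difference obtained by rotating a panorama against
#' itself over all column shifts. Zero only for images that are constant
#' along every row; that degenerate case makes the downstream gradient
#' threshold zero and is flagged with a warning there.
#'
#' @inheritParams rot_idf
#' @return a single non-negative number, grey levels.
#' @export
max_self_rot_idf <- function(reference, mask = NULL) {
  max(rot_idf(reference, reference, mask))
}

#' Gradient threshold from the reference image
#'
#' The per-meter gradient threshold used by the catchment hill climb: a
#' fraction (default 10%) of the maximum self-rotational image difference
#' of the reference image. This ties the sensitivity requirement to the
#' local image structure at the goal: a reference with strong rotational
#' contrast demands proportionally steeper translational gradients.
#'
#' @inheritParams rot_idf
#' @param fraction fraction of the self-rotIDF maximum, in `(0, 1]`.
#' @return threshold in grey levels per meter.
#' @export
gradient_threshold <- function(reference, mask = NULL, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  m <- max_self_rot_idf(reference, mask)
  if (m == 0)
    warning("constant reference image: gradient threshold is 0 and the ",
            "catchment reduces to unthresholded climbing")
  fraction * m
}

#' Render a panorama at every grid point
#'
#' Produces the panorama stack that the translational IDF and the
#' experiment pipeline reuse across reference choices: one greyscale
#' panorama per voxel, in linear voxel order (x fastest, then y, then z).
#'
#' @param scene a [make_scene()] result.
#' @param grid a [grid_spec()].
#' @param width panorama width in pixels; the height is `width / 2` and the
#'   cube faces default to `width / 3` pixels (128 at full size).
#' @param progress print a progress line every 200 renders.
#' @return object of class `catchvol_stack`: list with `panos` (list of
#'   greyscale matrices), `grid`, `width`, and `n_renders`.
#' @export
render_grid <- function(scene, grid, width = 384L, progress = FALSE) {
  pos <- grid_positions(grid)
  n <- nrow(pos)
  panos <- vector("list", n)
  for (i in seq_len(n)) {
    panos[[i]] <- render_panorama(scene, pos[i, ], width = width)
    if (progress && i %% 200L == 0L)
      message(sprintf("rendered %d / %d panoramas", i, n))
  }
  structure(list(panos = panos, grid = grid, width = as.integer(width),
                 n_renders = n), class = "catchvol_stack")
}

.linear_index <- function(grid, idx) {
  n <- grid$counts
  (idx[3] - 1L) * n[1] * n[2] + (idx[2] - 1L) * n[1] + idx[1]
}

#' Translational image difference function over a grid (transIDF)
#'
#' Compares the reference panorama (the one rendered at `reference_index`)
#' against the same-orientation panorama at every grid point, giving a 3D
#' volume of r.m.s. differences that rises smoothly away from the reference
#' location. The value at the reference voxel is exactly 0.
#'
#' @param stack a [render_grid()] result (render once, reuse across
#'   reference heights and mask modes).
#' @param reference_index integer triple, 1-based grid index of the
#'   reference panorama.
#' @param mask_mode `"all"` or `"above"` (above-horizon pixels only).
#' @return object of class `catchvol_idf`: list with `values` (3D array),
#'   `grid`, `reference_index`, `mask_mode`.
#' @export
trans_idf <- function(stack, reference_index, mask_mode = c("all", "above")) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(inherits(stack, "catchvol_stack"))
  n <- stack$grid$counts
  reference_index <- as.integer(reference_index)
  if (length(reference_index) != 3L || any(reference_index < 1L) ||
      any(reference_index > n))
    stop("reference_index outside grid")
  h <- stack$width %/% 2L
  mask <- if (mask_mode == "all") NULL else
    horizon_mask(mask_mode, height = h, width = stack$width)
  ref_lin <- .linear_index(stack$grid, reference_index)
  reference <- stack$panos[[ref_lin]]
  vals <- vapply(stack$panos, rms_difference, numeric(1), b = reference,
                 mask = mask)
  vals[ref_lin] <- 0
  structure(list(values = array(vals, n), grid = stack$grid,
                 reference_index = reference_index, mask_mode = mask_mode),
            class = "catchvol_idf")
}

#' @describeIn trans_idf render the grid and compute the volume in one call
#'   (for a single reference; use [render_grid()] + [trans_idf()] to reuse
#'   renders across references).
#' @inheritParams render_grid
#' @export
trans_idf_volume <- function(scene, grid, reference_index,
                             mask_mode = c("all", "above"), width = 384L) {
  trans_idf(render_grid(scene, grid, width = width), reference_index,
            mask_mode = mask_mode)
}

#' Extract an axis-parallel transect through an IDF volume
#'
#' @param idf a `catchvol_idf`.
#' @param axis `"x"`, `"y"` or `"z"`: the axis along which the transect runs.
#' @param at integer pair fixing the other two indices, in axis order with
#'   the transect axis removed (defaults to the reference indices).
#' @return data.frame with the grid index, world coordinate along the axis,
#'   and the IDF value.
#' @export
idf_transect <- function(idf, axis = c("x", "y", "z"), at = NULL) {
  axis <- match.arg(axis)
  ai <- match(axis, c("x", "y", "z"))
  others <- setdiff(1:3, ai)
  if (is.null(at)) at <- idf$reference_index[others]
  n <- idf$grid$counts
  idx <- matrix(0L, n[ai], 3)
  idx[, ai] <- seq_len(n[ai])
  idx[, others[1]] <- at[1]
  idx[, others[2]] <- at[2]
  pos <- grid_to_world(idf$grid, idx)
  data.frame(index = seq_len(n[ai]),
             coord_m = pos[, ai],
             value = idf$values[idx])
}

#' Serialize an IDF volume to plain text
#'
#' Writes a long-format CSV (`i, j, k, x_m, y_m, z_m, value`) plus a JSON
#' sidecar carrying the grid definition, the reference index and the mask
#' mode, so the volume can be reconstructed exactly.
#'
#' @param idf a `catchvol_idf`.
#' @param csv_path CSV path; the sidecar defaults to `<csv_path>.json`.
#' @param meta_path optional explicit sidecar path.
#' @return `read_idf_csv` returns a `catchvol_idf`.
#' @export
write_idf_csv <- function(idf, csv_path, meta_path = paste0(csv_path, ".json")) {
  n <- idf$grid$counts
  idx <- cbind(rep(seq_len(n[1]), times = n[2] * n[3]),
               rep(rep(seq_len(n[2]), each = n[1]), times = n[3]),
               rep(seq_len(n[3]), each = n[1] * n[2]))
  pos <- grid_to_world(idf$grid, idx)
  df <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   x_m = pos[, 1], y_m = pos[, 2], z_m = pos[, 3],
                   value = as.vector(idf$values))
  utils::write.csv(df, csv_path, row.names = FALSE)
  meta <- list(center = idf$grid$center, spacing = idf$grid$spacing,
               counts = idf$grid$counts, reference_index = idf$reference_index,
               mask_mode = idf$mask_mode)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

#' @rdname write_idf_csv
#' @export
read_idf_csv <- function(csv_path, meta_path = paste0(csv_path, ".json")) {
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(csv_path)
  grid <- grid_spec(meta$center, meta$spacing, meta$counts)
  vals <- array(NA_real_, grid$counts)
  vals[cbind(df$i, df$j, df$k)] <- df$value
  structure(list(values = vals, grid = grid,
                 reference_index = as.integer(meta$reference_index),
                 mask_mode = meta$mask_mode),
            class = "catchvol_idf")
}

#' Construct an IDF volume from explicit values
#'
#' Mainly for tests and synthetic gradients (e.g. an exact distance bowl):
#' wraps a numeric 3D array as a `catchvol_idf` over a given grid.
#'
#' @param values numeric 3D array matching `grid$counts`.
#' @inheritParams trans_idf
#' @export
idf_from_values <- function(values, grid, reference_index,
                            mask_mode = "all") {
  stopifnot(all(dim(values) == grid$counts))
  structure(list(values = values, grid = grid,
                 reference_index = as.integer(reference_index),
                 mask_mode = mask_mode),
            class = "catchvol_idf")
}
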