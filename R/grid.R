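#' Regular 3D sampling grids
#'
#' A grid is a regular lattice of camera positions, axis-aligned with the
#' world (x = east, y = north, z = up), defined by its centre, its spacing
#' in meters and the number of samples per axis. Index `(1, 1, 1)` sits at
#' the minimum corner; the index-to-world mapping is exact and invertible.
#'
#' @param center (x, y, z) of the grid centre in meters.
#' @param spacing sample spacing in meters (e.g. 0.1 or 0.2).
#' @param counts samples per axis, `(nx, ny, nz)` or a single number.
#' @return object of class `catchvol_grid`.
#' @seealso [grid_from_side()] for the side-length constructor.
#' @export
grid_spec <- function(center, spacing, counts) {
  stopifnot(length(center) == 3L, spacing > 0)
  counts <- as.integer(rep(counts, length.out = 3L))
  if (any(counts < 1L)) stop("grid counts must be >= 1")
  origin <- center - (counts - 1L) / 2 * spacing
  structure(list(center = center, spacing = spacing, counts = counts,
                 origin = origin), class = "catchvol_grid")
}

#' Grid from cube side length
#'
#' Counts per axis are `round(side / spacing) + 1`, inclusive of both
#' boundary planes: a 5 m side at 0.1 m spacing and a 10 m side at 0.2 m
#' spacing both give 51 samples per axis.
#'
#' @param side_m cube side length in meters (scalar or per-axis).
#' @inheritParams grid_spec
#' @return a `catchvol_grid`.
#' @export
grid_from_side <- function(side_m, spacing, center = c(0, 0, side_m[1] / 2)) {
  side_m <- rep(side_m, length.out = 3L)
  counts <- as.integer(round(side_m / spacing)) + 1L
  grid_spec(center = center, spacing = spacing, counts = counts)
}

#' Convert between grid indices and world coordinates
#'
#' Indices are 1-based integer triples; world coordinates are meters.
#'
#' @param grid a `catchvol_grid`.
#' @param idx integer triple or `n x 3` matrix of indices.
#' @param pos numeric triple or `n x 3` matrix of world positions.
#' @return `grid_to_world` gives positions; `world_to_grid` gives the
#'   nearest indices.
#' @export
grid_to_world <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3)
  sweep((idx - 1) * grid$spacing, 2, grid$origin, "+")
}

#' @rdname grid_to_world
#' @export
world_to_grid <- function(grid, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3)
  idx <- round(sweep(pos, 2, grid$origin, "-") / grid$spacing) + 1
  storage.mode(idx) <- "integer"
  idx
}

#' All grid positions as a matrix
#'
#' Rows enumerate voxels with the x index varying fastest, then y, then z —
#' the same order as R's array linearisation, so row `i` corresponds to
#' linear voxel index `i` of a `counts[1] x counts[2] x counts[3]` array.
#'
#' @param grid a `catchvol_grid`.
#' @return `prod(counts) x 3` matrix of world positions.
#' @export
grid_positions <- function(grid) {
  n <- grid$counts
  idx <- cbind(rep(seq_len(n[1]), times = n[2] * n[3]),
               rep(rep(seq_len(n[2]), each = n[1]), times = n[3]),
               rep(seq_len(n[3]), each = n[1] * n[2]))
  grid_to_world(grid, idx)
}

#' @export
print.catchvol_grid <- function(x, ...) {
  cat(sprintf("<catchvol_grid> %d x %d x %d at %.3g m spacing, centre (%g, %g, %g)\n",
              x$counts[1], x$counts[2], x$counts[3], x$spacing,
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}
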