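# 26-neighbour offsets in fixed lexicographic order (dz, then dy, then dx
# ascending) — the deterministic tie-break for equal steepest gradients.
.NEIGHBOR_OFFSETS <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  storage.mode(g) <- "integer"
  g
})
.NEIGHBOR_DIST <- sqrt(rowSums(.NEIGHBOR_OFFSETS^2))

#' Steepest descending neighbour of a voxel
#'
#' Evaluates the descending gradient `(V1 - Vn) / distance` toward each of
#' the up-to-26 in-grid neighbours of `idx` (x, y, z directions including
#' diagonals; `distance` is the Euclidean separation of the two grid
#' points, `spacing * sqrt(d)` for a d-axis diagonal). Returns the
#' steepest neighbour provided its gradient strictly exceeds `threshold`,
#' along with bookkeeping used by [hill_climb()] to classify failures: the
#' best descending in-grid gradient, and whether a one-sided extrapolation
#' suggests a supra-threshold descent out of the grid (possible only at the
#' boundary).
#'
#' @param idf a `catchvol_idf`.
#' @param idx integer triple, 1-based voxel index.
#' @param threshold gradient threshold in grey levels per meter; a step is
#'   taken only if its gradient is strictly greater.
#' @return list with `step` (NULL, or a list with `from`, `to`, `distance`
#'   in meters and `gradient` in grey levels/m), `best_gradient` (max
#'   descending in-grid gradient, -Inf if none descend), and
#'   `outward_candidate` (logical).
#' @export
steepest_descending_neighbor <- function(idf, idx, threshold) {
  n <- idf$grid$counts
  sp <- idf$grid$spacing
  idx <- as.integer(idx)
  v1 <- idf$values[idx[1], idx[2], idx[3]]
  nb <- sweep(.NEIGHBOR_OFFSETS, 2, idx, "+")
  ok <- nb[, 1] >= 1L & nb[, 1] <= n[1] &
        nb[, 2] >= 1L & nb[, 2] <= n[2] &
        nb[, 3] >= 1L & nb[, 3] <= n[3]
  grad <- rep(-Inf, nrow(nb))
  if (any(ok)) {
    vn <- idf$values[nb[ok, , drop = FALSE]]
    grad[ok] <- (v1 - vn) / (sp * .NEIGHBOR_DIST[ok])
  }
  best <- which.max(grad)  # first index wins ties: the fixed order above
  best_gradient <- grad[best]

  # out-of-grid directions: extrapolate one-sided through the opposite
  # in-grid neighbour; descending outward iff the IDF rises inward
  outward <- FALSE
  if (!all(ok)) {
    out_off <- .NEIGHBOR_OFFSETS[!ok, , drop = FALSE]
    opp <- sweep(-out_off, 2, idx, "+")
    opp_ok <- opp[, 1] >= 1L & opp[, 1] <= n[1] &
              opp[, 2] >= 1L & opp[, 2] <= n[2] &
              opp[, 3] >= 1L & opp[, 3] <= n[3]
    if (any(opp_ok)) {
      vo <- idf$values[opp[opp_ok, , drop = FALSE]]
      g_out <- (vo - v1) / (sp * .NEIGHBOR_DIST[!ok][opp_ok])
      outward <- any(g_out > threshold)
    }
  }

  step <- NULL
  if (best_gradient > threshold) {
    to <- nb[best, ]
    step <- list(from = idx, to = to,
                 distance = sp * .NEIGHBOR_DIST[best],
                 gradient = best_gradient)
  }
  list(step = step, best_gradient = best_gradient,
       outward_candidate = outward)
}

#' Hill climb on an IDF volume from one start voxel
#'
#' Repeatedly moves to the steepest descending 26-neighbour whose gradient
#' exceeds the threshold, until one of four terminal conditions: the
#' reference voxel is reached (`success`), no neighbour descends at all
#' (`false_minimum`), neighbours descend but none exceeds the threshold
#' (`subthreshold`), or the only supra-threshold descent points out of the
#' grid at the boundary (`left_volume`). The IDF value strictly decreases
#' along the path, so termination is guaranteed on a finite grid.
#'
#' @inheritParams steepest_descending_neighbor
#' @param start integer triple, 1-based start voxel.
#' @return list of class `catchvol_climb` with `path` (`n x 3` matrix of
#'   voxel indices) and `status` (one of `"success"`, `"false_minimum"`,
#'   `"subthreshold"`, `"left_volume"`).
#' @export
hill_climb <- function(idf, start, threshold) {
  n <- idf$grid$counts
  start <- as.integer(start)
  if (any(start < 1L) || any(start > n)) stop("start voxel outside grid")
  ref <- idf$reference_index
  cur <- start
  path <- list(cur)
  repeat {
    if (all(cur == ref)) {
      status <- "success"; break
    }
    sn <- steepest_descending_neighbor(idf, cur, threshold)
    if (is.null(sn$step)) {
      status <- if (sn$outward_candidate) "left_volume"
        else if (sn$best_gradient > 0) "subthreshold"
        else "false_minimum"
      break
    }
    cur <- sn$step$to
    path[[length(path) + 1L]] <- cur
  }
  structure(list(path = do.call(rbind, path), status = status),
            class = "catchvol_climb")
}

.STATUS_LEVELS <- c("success", "false_minimum", "subthreshold", "left_volume")

#' Extract the catchment volume of a reference image
#'
#' Runs a hill climb from every voxel of the grid and labels each voxel
#' with its terminal status; the success set — the voxels whose climbs
#' reach the reference location — is the catchment volume. Because climbs
#' are deterministic, a climb that steps onto an already-classified voxel
#' can inherit that voxel's status (memoization); the result is identical
#' to running every climb to its end, which `memoize = FALSE` does.
#'
#' @inheritParams steepest_descending_neighbor
#' @param memoize reuse the classification of voxels already visited.
#' @return object of class `catchvol_catchment`: `grid`, `status` (3D
#'   character array), `counts` (table of statuses), `success_fraction`,
#'   `threshold`, `reference_index`.
#' @export
catchment_volume <- function(idf, threshold, memoize = TRUE) {
  if (threshold == 0)
    warning("threshold 0: unthresholded climbing (no sensitivity limit)")
  n <- idf$grid$counts
  status <- array(NA_character_, n)
  for (k in seq_len(n[3])) for (j in seq_len(n[2])) for (i in seq_len(n[1])) {
    if (!is.na(status[i, j, k])) next
    cur <- c(i, j, k)
    visited <- list()
    terminal <- NULL
    repeat {
      if (memoize && !is.na(status[cur[1], cur[2], cur[3]])) {
        terminal <- status[cur[1], cur[2], cur[3]]
        break
      }
      visited[[length(visited) + 1L]] <- cur
      if (all(cur == idf$reference_index)) { terminal <- "success"; break }
      sn <- steepest_descending_neighbor(idf, cur, threshold)
      if (is.null(sn$step)) {
        terminal <- if (sn$outward_candidate) "left_volume"
          else if (sn$best_gradient > 0) "subthreshold"
          else "false_minimum"
        break
      }
      cur <- sn$step$to
    }
    for (v in visited) status[v[1], v[2], v[3]] <- terminal
  }
  counts <- table(factor(status, levels = .STATUS_LEVELS))
  structure(list(grid = idf$grid, status = status, counts = counts,
                 success_fraction = as.numeric(counts[["success"]]) / prod(n),
                 threshold = threshold,
                 reference_index = idf$reference_index),
            class = "catchvol_catchment")
}

#' @export
print.catchvol_catchment <- function(x, ...) {
  cat(sprintf(
    "<catchvol_catchment> %d / %d voxels reach the reference (%.1f%%), threshold %.4g grey/m\n",
    x$counts[["success"]], prod(x$grid$counts),
    100 * x$success_fraction, x$threshold))
  invisible(x)
}

# Trilinear interpolation of the IDF at continuous world points (n x 3),
# clamped to the grid hull.
.interp_idf <- function(idf, P) {
  n <- idf$grid$counts
  u <- sweep(P, 2, idf$grid$origin, "-") / idf$grid$spacing + 1
  u <- pmin(pmax(u, 1), matrix(n, nrow(P), 3, byrow = TRUE))
  i0 <- pmin(pmax(floor(u), 1), matrix(pmax(n - 1, 1), nrow(P), 3, byrow = TRUE))
  f <- u - i0
  v <- idf$values
  ix <- function(dx, dy, dz) {
    v[cbind(pmin(i0[, 1] + dx, n[1]),
            pmin(i0[, 2] + dy, n[2]),
            pmin(i0[, 3] + dz, n[3]))]
  }
  (1 - f[, 3]) * ((1 - f[, 2]) * ((1 - f[, 1]) * ix(0, 0, 0) + f[, 1] * ix(1, 0, 0)) +
                  f[, 2]       * ((1 - f[, 1]) * ix(0, 1, 0) + f[, 1] * ix(1, 1, 0))) +
  f[, 3]       * ((1 - f[, 2]) * ((1 - f[, 1]) * ix(0, 0, 1) + f[, 1] * ix(1, 0, 1)) +
                  f[, 2]       * ((1 - f[, 1]) * ix(0, 1, 1) + f[, 1] * ix(1, 1, 1)))
}

#' Continuous gradient descent on an interpolated IDF
#'
#' Cross-check for the discrete hill climb: steepest descent with a fixed
#' step length on the trilinearly interpolated IDF, with central
#' finite-difference gradients and no threshold. The run succeeds when it
#' comes within `stop_radius_m` of the reference location; it fails when it
#' steps outside the grid hull (`left_volume`), when the gradient norm
#' falls below `grad_tol` away from the reference, or when the step budget
#' is exhausted (both `false_minimum`).
#'
#' @param idf a `catchvol_idf`.
#' @param start continuous world point (x, y, z) inside the grid hull.
#' @param step_m step length in meters (default: a quarter of the grid
#'   spacing).
#' @param stop_radius_m success radius around the reference location
#'   (default: one grid spacing).
#' @param max_steps step budget.
#' @param grad_tol gradient-norm tolerance, grey levels per meter.
#' @return list of class `catchvol_descent` with `trace` (`n x 3` matrix of
#'   world points) and `status`.
#' @export
gradient_descent <- function(idf, start,
                             step_m = idf$grid$spacing / 4,
                             stop_radius_m = idf$grid$spacing,
                             max_steps = 5000L, grad_tol = 1e-8) {
  if (step_m <= 0) stop("step_m must be > 0")
  if (stop_radius_m <= 0) stop("stop_radius_m must be > 0")
  g <- idf$grid
  lo <- g$origin
  hi <- g$origin + (g$counts - 1L) * g$spacing
  p <- as.numeric(start)
  if (any(p < lo - 1e-12) || any(p > hi + 1e-12))
    stop("start point outside the grid hull")
  ref <- drop(grid_to_world(g, idf$reference_index))
  h <- g$spacing / 2
  trace <- list(p)
  status <- "false_minimum"
  for (s in seq_len(max_steps)) {
    if (sqrt(sum((p - ref)^2)) <= stop_radius_m) { status <- "success"; break }
    # central differences with samples clamped to the hull
    plus  <- matrix(p, 3, 3, byrow = TRUE) + diag(h, 3)
    minus <- matrix(p, 3, 3, byrow = TRUE) - diag(h, 3)
    plus  <- pmin(pmax(plus,  matrix(lo, 3, 3, byrow = TRUE)),
                  matrix(hi, 3, 3, byrow = TRUE))
    minus <- pmin(pmax(minus, matrix(lo, 3, 3, byrow = TRUE)),
                  matrix(hi, 3, 3, byrow = TRUE))
    fp <- .interp_idf(idf, plus)
    fm <- .interp_idf(idf, minus)
    dd <- sqrt(rowSums((plus - minus)^2))
    grad <- ifelse(dd > 0, (fp - fm) / dd, 0)
    gn <- sqrt(sum(grad^2))
    if (gn < grad_tol) { status <- "false_minimum"; break }
    p_new <- p - step_m * grad / gn
    if (any(p_new < lo) || any(p_new > hi)) { status <- "left_volume"; break }
    p <- p_new
    trace[[length(trace) + 1L]] <- p
  }
  structure(list(trace = do.call(rbind, trace), status = status),
            class = "catchvol_descent")
}

#' Gradient-descent success volume
#'
#' Runs [gradient_descent()] from the centre of every voxel and returns the
#' logical success array — the continuous counterpart of the thresholdless
#' hill-climb catchment, used to check that the two algorithms identify the
#' same basin of attraction.
#'
#' @inheritParams gradient_descent
#' @return logical 3D array over the grid.
#' @export
gradient_descent_volume <- function(idf, step_m = idf$grid$spacing / 4,
                                    stop_radius_m = idf$grid$spacing,
                                    max_steps = 5000L) {
  n <- idf$grid$counts
  pos <- grid_positions(idf$grid)
  ok <- logical(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    ok[i] <- gradient_descent(idf, pos[i, ], step_m = step_m,
                              stop_radius_m = stop_radius_m,
                              max_steps = max_steps)$status == "success"
  }
  array(ok, n)
}

#' Export a catchment volume
#'
#' `write_catchment_ply` writes the success voxels as an ASCII PLY point
#' cloud for external 3D viewers; `write_catchment_csv` writes every voxel
#' with its status; `write_catchment_json` writes the summary (threshold,
#' per-status counts, success fraction).
#'
#' @param catchment a [catchment_volume()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_catchment_ply <- function(catchment, path) {
  ok <- which(catchment$status == "success", arr.ind = TRUE)
  pos <- grid_to_world(catchment$grid, ok)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(pos)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  if (nrow(pos))
    writeLines(sprintf("%.6f %.6f %.6f", pos[, 1], pos[, 2], pos[, 3]), con)
  invisible(path)
}

#' @rdname write_catchment_ply
#' @export
write_catchment_csv <- function(catchment, path) {
  n <- catchment$grid$counts
  idx <- cbind(rep(seq_len(n[1]), times = n[2] * n[3]),
               rep(rep(seq_len(n[2]), each = n[1]), times = n[3]),
               rep(seq_len(n[3]), each = n[1] * n[2]))
  pos <- grid_to_world(catchment$grid, idx)
  df <- data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
                   x_m = pos[, 1], y_m = pos[, 2], z_m = pos[, 3],
                   status = as.vector(catchment$status))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catchment_ply
#' @export
write_catchment_json <- function(catchment, path) {
  x <- list(threshold_grey_per_m = catchment$threshold,
            reference_index = catchment$reference_index,
            counts = as.list(catchment$counts),
            success_fraction = catchment$success_fraction,
            grid = list(center = catchment$grid$center,
                        spacing = catchment$grid$spacing,
                        counts = catchment$grid$counts))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
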