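# Independent reference implementations used as oracles. These are written
# as literal, loop-based transcriptions and share no code with the package
# internals they check.

# r.m.s. pixel difference by explicit double loop
oracle_rms <- function(a, b, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(a), ncol(a))
  total <- 0
  count <- 0
  for (r in seq_len(nrow(a))) {
    for (c in seq_len(ncol(a))) {
      if (mask[r, c]) {
        d <- a[r, c] - b[r, c]
        total <- total + d * d
        count <- count + 1
      }
    }
  }
  sqrt(total / count)
}

# steepest-gradient hill climb, transcribed step by step: at the current
# grid point with value V1, examine every neighbour (x, y, z directions
# including diagonals), compute (V1 - Vn) / distance with distance the
# Euclidean separation of the grid points, move to the steepest neighbour
# if its gradient strictly exceeds the threshold, repeat.
oracle_hill_climb <- function(values, start, ref, spacing, threshold) {
  n <- dim(values)
  cur <- start
  path <- list(cur)
  repeat {
    if (all(cur == ref)) return(list(path = path, status = "success"))
    v1 <- values[cur[1], cur[2], cur[3]]
    best_g <- -Inf
    best_nb <- NULL
    any_out_descending <- FALSE
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nb <- cur + c(dx, dy, dz)
      dist <- spacing * sqrt(dx^2 + dy^2 + dz^2)
      if (any(nb < 1) || any(nb > n)) {
        # one-sided outward check through the opposite neighbour
        opp <- cur - c(dx, dy, dz)
        if (all(opp >= 1) && all(opp <= n)) {
          vo <- values[opp[1], opp[2], opp[3]]
          if ((vo - v1) / dist > threshold) any_out_descending <- TRUE
        }
        next
      }
      g <- (v1 - values[nb[1], nb[2], nb[3]]) / dist
      if (g > best_g) {
        best_g <- g
        best_nb <- nb
      }
    }
    if (best_g > threshold) {
      cur <- best_nb
      path[[length(path) + 1]] <- cur
    } else if (any_out_descending) {
      return(list(path = path, status = "left_volume"))
    } else if (best_g > 0) {
      return(list(path = path, status = "subthreshold"))
    } else {
      return(list(path = path, status = "false_minimum"))
    }
  }
}

# pinhole ray direction through a face pixel, from explicit per-face
# formulas (world axes: x east, y north, z up; image rows top to bottom)
oracle_face_direction <- function(face, row, col, res, fov_deg = 95) {
  t <- tan(fov_deg / 2 * pi / 180)
  a <- ((col - 0.5) / res * 2 - 1) * t   # image right
  b <- (1 - (row - 0.5) / res * 2) * t   # image up
  d <- switch(face,
    north = c(a, 1, b),
    east  = c(1, -a, b),
    south = c(-a, -1, b),
    west  = c(-1, a, b),
    up    = c(a, -b, 1),
    down  = c(a, b, -1))
  d / sqrt(sum(d^2))
}

# smallest positive ray parameter hitting a sphere, by direct quadratic
oracle_sphere_hit <- function(origin, dir, center, radius) {
  p <- origin - center
  b <- 2 * sum(p * dir)
  c0 <- sum(p * p) - radius^2
  disc <- b^2 - 4 * c0
  if (disc < 0) return(Inf)
  ts <- (-b + c(-1, 1) * sqrt(disc)) / 2
  ts <- ts[ts > 1e-9]
  if (length(ts)) min(ts) else Inf
}

# exact Euclidean-distance bowl: the convex test IDF
bowl_idf <- function(grid, ref_idx) {
  pos <- grid_positions(grid)
  ref <- drop(grid_to_world(grid, ref_idx))
  d <- sqrt(rowSums(sweep(pos, 2, ref)^2))
  idf_from_values(array(d, grid$counts), grid, ref_idx)
}

# random integer-valued IDF volume with the reference forced to the minimum
random_idf <- function(counts, ref_idx = NULL) {
  if (is.null(ref_idx)) ref_idx <- sapply(counts, function(n) sample(n, 1))
  vals <- array(runif(prod(counts), 0, 100), counts)
  vals[ref_idx[1], ref_idx[2], ref_idx[3]] <- 0
  idf_from_values(vals, grid_spec(c(0, 0, 2), 0.5, counts), ref_idx)
}
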