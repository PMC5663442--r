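test_that("steepest descending neighbour on a bowl always approaches the goal", {
  grid <- grid_spec(c(0, 0, 2), 0.5, c(5, 5, 5))
  ref <- c(3L, 3L, 3L)
  idf <- bowl_idf(grid, ref)
  for (i in 1:10) {
    idx <- c(sample(5, 1), sample(5, 1), sample(5, 1))
    if (all(idx == ref)) next
    sn <- steepest_descending_neighbor(idf, idx, 0)
    expect_false(is.null(sn$step))
    d_now <- sqrt(sum((idx - ref)^2))
    d_next <- sqrt(sum((sn$step$to - ref)^2))
    expect_lt(d_next, d_now)
    # exhaustive check of the maximizer
    best <- -Inf
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      nb <- idx + c(dx, dy, dz)
      if (all(c(dx, dy, dz) == 0) || any(nb < 1) || any(nb > 5)) next
      g <- (idf$values[idx[1], idx[2], idx[3]] -
              idf$values[nb[1], nb[2], nb[3]]) /
        (0.5 * sqrt(dx^2 + dy^2 + dz^2))
      best <- max(best, g)
    }
    expect_equal(sn$step$gradient, best)
  }
})

test_that("a uniform IDF has no descending neighbour anywhere", {
  grid <- grid_spec(c(0, 0, 2), 0.5, c(3, 3, 3))
  idf <- idf_from_values(array(5, c(3, 3, 3)), grid, c(2, 2, 2))
  sn <- steepest_descending_neighbor(idf, c(1, 2, 3), 0)
  expect_null(sn$step)
  expect_false(sn$outward_candidate)
})

test_that("a threshold above the steepest slope blocks every step", {
  grid <- grid_spec(c(0, 0, 2), 0.5, c(5, 5, 5))
  idf <- bowl_idf(grid, c(3L, 3L, 3L))
  # bowl slope is 1 grey level per meter by construction
  for (i in 1:5) {
    idx <- c(sample(5, 1), sample(5, 1), sample(5, 1))
    if (all(idx == c(3, 3, 3))) next
    expect_null(steepest_descending_neighbor(idf, idx, 2)$step)
  }
})

test_that("hill climbs on a convex bowl reach the reference from everywhere", {
  grid <- grid_spec(c(0, 0, 2), 0.5, c(3, 3, 3))
  idf <- bowl_idf(grid, c(2L, 2L, 2L))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    cl <- hill_climb(idf, c(i, j, k), 0)
    expect_equal(cl$status, "success")
  }
  cl0 <- hill_climb(idf, c(2, 2, 2), 0)
  expect_equal(nrow(cl0$path), 1L)
  expect_error(hill_climb(idf, c(0, 1, 1), 0), "outside grid")
})

test_that("success paths strictly descend and step between 26-neighbours", {
  set.seed(21)
  for (rep in 1:20) {
    idf <- random_idf(c(4, 4, 4), c(2L, 3L, 2L))
    cl <- hill_climb(idf, c(4, 4, 4), 0)
    v <- idf$values[cl$path]
    if (nrow(cl$path) > 1) {
      expect_true(all(diff(v) < 0))
      steps <- abs(diff(cl$path))
      expect_true(all(steps <= 1))
      expect_true(all(rowSums(steps) >= 1))
    }
  }
})

test_that("hill climbs match the literal gradient-formula transcription", {
  set.seed(22)
  for (rep in 1:300) {
    counts <- sample(2:4, 3, replace = TRUE)
    idf <- random_idf(counts)
    threshold <- sample(c(0, 1, 5, 20), 1)
    start <- sapply(counts, function(n) sample(n, 1))
    got <- hill_climb(idf, start, threshold)
    want <- oracle_hill_climb(idf$values, start, idf$reference_index,
                              idf$grid$spacing, threshold)
    expect_equal(got$status, want$status)
    expect_equal(got$path, do.call(rbind, want$path), ignore_attr = TRUE)
  }
})

test_that("a plateau shell around the bowl strands exactly the outer voxels", {
  grid <- grid_spec(c(0, 0, 2), 0.5, c(5, 5, 5))
  ref <- c(3L, 3L, 3L)
  idf <- bowl_idf(grid, ref)
  # flatten the IDF at Chebyshev radius 1 and 2 to the radius-2 bowl value:
  # climbs from the outer shell step inward but stall on the plateau
  cheb <- array(0L, c(5, 5, 5))
  for (i in 1:5) for (j in 1:5) for (k in 1:5)
    cheb[i, j, k] <- max(abs(c(i, j, k) - ref))
  plateau_value <- max(idf$values[cheb == 2])
  idf$values[cheb <= 2 & cheb >= 1] <- plateau_value
  suppressWarnings(cv <- catchment_volume(idf, 0))
  for (i in 1:5) for (j in 1:5) for (k in 1:5) {
    want <- oracle_hill_climb(idf$values, c(i, j, k), ref,
                              grid$spacing, 0)$status
    expect_equal(cv$status[i, j, k], want)
  }
  # the inner shell still borders the reference and drops straight in;
  # everything beyond it stalls on the plateau
  expect_equal(sum(cv$status == "success"), 27L)
  expect_equal(sum(cv$status == "false_minimum"), 125L - 27L)
})

test_that("catchment extraction labels the whole grid and memoizes safely", {
  grid <- grid_spec(c(0, 0, 2), 0.5, c(3, 3, 3))
  flat <- idf_from_values(array(1, c(3, 3, 3)), grid, c(2L, 2L, 2L))
  flat$values[2, 2, 2] <- 0
  suppressWarnings(cv <- catchment_volume(flat, 0))
  expect_equal(sum(cv$status == "success"), 27L)  # all climb into the dip
  uniform <- idf_from_values(array(1, c(3, 3, 3)), grid, c(2L, 2L, 2L))
  suppressWarnings(cvu <- catchment_volume(uniform, 0))
  expect_equal(sum(cvu$status == "success"), 1L)
  expect_equal(as.vector(cvu$counts["false_minimum"]), 26)

  set.seed(23)
  for (rep in 1:10) {
    idf <- random_idf(c(4, 3, 4))
    thr <- runif(1, 0, 10)
    a <- catchment_volume(idf, thr, memoize = TRUE)
    b <- catchment_volume(idf, thr, memoize = FALSE)
    expect_identical(a$status, b$status)
  }
})

test_that("raising the threshold never enlarges the catchment", {
  set.seed(24)
  for (rep in 1:10) {
    idf <- random_idf(c(4, 4, 3))
    prev <- NULL
    for (thr in c(0, 2, 5, 10, 25)) {
      suppressWarnings(cv <- catchment_volume(idf, thr))
      ok <- cv$status == "success"
      if (!is.null(prev)) expect_true(all(!ok | prev))  # ok subset of prev
      prev <- ok
    }
  }
})

test_that("gradient descent converges on the bowl and respects the hull", {
  grid <- grid_spec(c(0, 0, 2), 0.5, c(5, 5, 5))
  ref <- c(3L, 3L, 3L)
  idf <- bowl_idf(grid, ref)
  ref_pos <- drop(grid_to_world(grid, ref))
  gd0 <- gradient_descent(idf, ref_pos)
  expect_equal(gd0$status, "success")
  expect_equal(nrow(gd0$trace), 1L)
  set.seed(25)
  for (rep in 1:5) {
    start <- ref_pos + runif(3, -0.9, 0.9)
    gd <- gradient_descent(idf, start)
    expect_equal(gd$status, "success")
    d <- sqrt(rowSums(sweep(gd$trace, 2, ref_pos)^2))
    expect_true(all(diff(d) < 1e-9))  # monotone approach on the exact bowl
  }
  expect_error(gradient_descent(idf, ref_pos, step_m = 0), "step_m")
  expect_error(gradient_descent(idf, ref_pos, stop_radius_m = -1), "stop_radius")
  expect_error(gradient_descent(idf, c(50, 0, 0)), "outside the grid hull")
  # a ramp pushes the walker across the hull boundary
  ramp <- idf_from_values(array(rep(1:5, times = 25) * 1.0, c(5, 5, 5)),
                          grid, ref)
  gd_out <- gradient_descent(ramp, ref_pos + c(-0.8, 0, 0),
                             stop_radius_m = 0.05)
  expect_equal(gd_out$status, "left_volume")
})

test_that("catchment exports round-trip their content", {
  grid <- grid_spec(c(0, 0, 2), 0.5, c(3, 3, 3))
  idf <- bowl_idf(grid, c(2L, 2L, 2L))
  suppressWarnings(cv <- catchment_volume(idf, 0))
  ply <- tempfile(fileext = ".ply")
  write_catchment_ply(cv, ply)
  lines <- readLines(ply)
  expect_equal(lines[1], "ply")
  n_vert <- as.integer(sub("element vertex ", "",
                           grep("element vertex", lines, value = TRUE)))
  expect_equal(n_vert, 27L)
  body <- read.table(text = lines[(which(lines == "end_header") + 1):length(lines)])
  expect_equal(nrow(body), 27L)
  csv <- tempfile(fileext = ".csv")
  write_catchment_csv(cv, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 27L)
  expect_true(all(df$status == "success"))
  js <- tempfile(fileext = ".json")
  write_catchment_json(cv, js)
  x <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(x$counts$success, 27L)
  expect_equal(x$success_fraction, 1)
})
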