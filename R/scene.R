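#' Specify a procedural outdoor scene
#'
#' Builds a validated scene specification: a textured ground plane, trees
#' (cylindrical trunks carrying spherical canopies), optional small ground
#' clutter, a sun that casts hard shadows, a uniform sky, and an optional
#' distant background sphere. Together with its seed the specification fully
#' determines the scene, so renders are reproducible.
#'
#' Shading is ambient-only: every surface shows its albedo as a grey level,
#' darkened by a constant factor where the line to the sun is occluded.
#' There is no specular component and no sky gradient; the shadow structure
#' is what gives near-ground views their fine-scale contrast.
#'
#' @param seed integer; drives the ground texture and background texture.
#' @param ground_extent half-width of the textured ground plane in meters;
#'   rays missing the plane fall through to the background.
#' @param ground_texture list with `noise_scale` (correlation length of the
#'   ground albedo pattern, meters), `albedo_lo`, `albedo_hi` (reflectance
#'   bounds in `[0, 1]`).
#' @param trees list of trees; each a list with `position` (x, y in meters),
#'   `trunk_radius`, `trunk_height`, `canopy_radius` (meters) and `albedo`.
#' @param clutter list of small ground objects; each a list with `position`,
#'   `radius` (meters) and `albedo`.
#' @param sun list with `azimuth_deg` (compass, 0 = north, clockwise),
#'   `elevation_deg` in `[0, 90]`, and `shadow_darkening`, the factor in
#'   `[0, 1]` multiplying the albedo of sun-occluded surface points
#'   (1 disables shadows).
#' @param sky_color RGB triple in `[0, 255]` returned for rays that hit
#'   nothing (when no background sphere is configured).
#' @param background list with `type` (`"none"`, `"uniform"` or
#'   `"panorama"`), `color` (RGB, used by `"uniform"`) and
#'   `sphere_radius_m` (radius of the distant panorama sphere, default 500).
#' @return object of class `catchvol_scene_spec`.
#' @seealso [make_scene()], [preset_scene()]
#' @export
scene_spec <- function(seed = 1L,
                       ground_extent = 50,
                       ground_texture = list(noise_scale = 0.5,
                                             albedo_lo = 0.25,
                                             albedo_hi = 0.75),
                       trees = list(),
                       clutter = list(),
                       sun = list(azimuth_deg = 315,
                                  elevation_deg = 45,
                                  shadow_darkening = 0.5),
                       sky_color = c(135, 206, 250),
                       background = list(type = "none")) {
  ground_texture <- utils::modifyList(
    list(noise_scale = 0.5, albedo_lo = 0.25, albedo_hi = 0.75), ground_texture)
  sun <- utils::modifyList(
    list(azimuth_deg = 315, elevation_deg = 45, shadow_darkening = 0.5), sun)
  background <- utils::modifyList(
    list(type = "none", color = c(160, 200, 235), sphere_radius_m = 500),
    background)
  spec <- structure(
    list(seed = as.integer(seed), ground_extent = ground_extent,
         ground_texture = ground_texture, trees = trees, clutter = clutter,
         sun = sun, sky_color = sky_color, background = background),
    class = "catchvol_scene_spec")
  validate_scene_spec(spec)
  spec
}

#' Validate a scene specification
#'
#' Checks every field of a [scene_spec()] and stops with an error naming the
#' offending field.
#'
#' @param spec a `catchvol_scene_spec` (or a bare list with the same fields).
#' @return the spec, invisibly, if valid.
#' @export
validate_scene_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid scene spec: field '%s' %s", field, why), call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(spec$seed)) fail("seed", "must be a single integer")
  if (!num1(spec$ground_extent) || spec$ground_extent <= 0)
    fail("ground_extent", "must be > 0")
  gt <- spec$ground_texture
  if (!num1(gt$noise_scale) || gt$noise_scale <= 0)
    fail("ground_texture$noise_scale", "must be > 0")
  for (f in c("albedo_lo", "albedo_hi")) {
    if (!num1(gt[[f]]) || gt[[f]] < 0 || gt[[f]] > 1)
      fail(paste0("ground_texture$", f), "must be in [0, 1]")
  }
  if (gt$albedo_lo > gt$albedo_hi)
    fail("ground_texture$albedo_lo", "must be <= albedo_hi")
  for (i in seq_along(spec$trees)) {
    tr <- spec$trees[[i]]
    nm <- sprintf("trees[[%d]]", i)
    if (!is.numeric(tr$position) || length(tr$position) != 2L)
      fail(paste0(nm, "$position"), "must be (x, y) in meters")
    for (f in c("trunk_radius", "trunk_height", "canopy_radius")) {
      if (!num1(tr[[f]]) || tr[[f]] <= 0) fail(paste0(nm, "$", f), "must be > 0")
    }
    if (!num1(tr$albedo) || tr$albedo < 0 || tr$albedo > 1)
      fail(paste0(nm, "$albedo"), "must be in [0, 1]")
  }
  for (i in seq_along(spec$clutter)) {
    cl <- spec$clutter[[i]]
    nm <- sprintf("clutter[[%d]]", i)
    if (!is.numeric(cl$position) || length(cl$position) != 2L)
      fail(paste0(nm, "$position"), "must be (x, y) in meters")
    if (!num1(cl$radius) || cl$radius <= 0) fail(paste0(nm, "$radius"), "must be > 0")
    if (!num1(cl$albedo) || cl$albedo < 0 || cl$albedo > 1)
      fail(paste0(nm, "$albedo"), "must be in [0, 1]")
  }
  if (!num1(spec$sun$elevation_deg) ||
      spec$sun$elevation_deg < 0 || spec$sun$elevation_deg > 90)
    fail("sun$elevation_deg", "must be in [0, 90]")
  if (!num1(spec$sun$azimuth_deg)) fail("sun$azimuth_deg", "must be numeric")
  if (!num1(spec$sun$shadow_darkening) ||
      spec$sun$shadow_darkening < 0 || spec$sun$shadow_darkening > 1)
    fail("sun$shadow_darkening", "must be in [0, 1]")
  if (!is.numeric(spec$sky_color) || length(spec$sky_color) != 3L ||
      any(spec$sky_color < 0 | spec$sky_color > 255))
    fail("sky_color", "must be an RGB triple in [0, 255]")
  bg <- spec$background
  if (!bg$type %in% c("none", "uniform", "panorama"))
    fail("background$type", "must be one of 'none', 'uniform', 'panorama'")
  if (bg$type == "uniform" &&
      (!is.numeric(bg$color) || length(bg$color) != 3L ||
       any(bg$color < 0 | bg$color > 255)))
    fail("background$color", "must be an RGB triple in [0, 255]")
  if (bg$type == "panorama" &&
      (!num1(bg$sphere_radius_m) || bg$sphere_radius_m <= 0))
    fail("background$sphere_radius_m", "must be > 0")
  invisible(spec)
}

#' Build a renderable scene from a specification
#'
#' Expands the specification into flat primitive tables (a ground plane,
#' cylinders for trunks, spheres for canopies and clutter) plus the sun
#' direction and the background shader. The result is immutable; tracing
#' rays against it is a pure function of (scene, origin, direction).
#'
#' @param spec a validated [scene_spec()].
#' @return object of class `catchvol_scene`.
#' @export
make_scene <- function(spec) {
  validate_scene_spec(spec)
  cyl <- matrix(numeric(0), ncol = 5,
                dimnames = list(NULL, c("cx", "cy", "r", "h", "albedo")))
  sph <- matrix(numeric(0), ncol = 5,
                dimnames = list(NULL, c("cx", "cy", "cz", "r", "albedo")))
  # declaration order fixes nearest-hit tie-breaking: ground, then per tree
  # trunk and canopy in list order, then clutter
  for (tr in spec$trees) {
    cyl <- rbind(cyl, c(tr$position[1], tr$position[2],
                        tr$trunk_radius, tr$trunk_height, tr$albedo))
    sph <- rbind(sph, c(tr$position[1], tr$position[2],
                        tr$trunk_height + 0.5 * tr$canopy_radius,
                        tr$canopy_radius, tr$albedo))
  }
  for (cl in spec$clutter) {
    sph <- rbind(sph, c(cl$position[1], cl$position[2],
                        0.4 * cl$radius, cl$radius, cl$albedo))
  }
  az <- spec$sun$azimuth_deg * pi / 180
  el <- spec$sun$elevation_deg * pi / 180
  sun_dir <- c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
  structure(list(spec = spec, cylinders = cyl, spheres = sph,
                 sun_dir = sun_dir), class = "catchvol_scene")
}

#' @export
print.catchvol_scene <- function(x, ...) {
  cat(sprintf(
    "<catchvol_scene> seed %d | %d trees, %d clutter | background: %s\n",
    x$spec$seed, length(x$spec$trees), length(x$spec$clutter),
    x$spec$background$type))
  invisible(x)
}

.RAY_EPS <- 1e-9  # ray-primitive intersection tolerance, meters

# Nearest intersection of rays with one sphere. Origins may be a single
# point (recycled) or one per ray. Returns Inf for misses.
.isect_sphere <- function(ox, oy, oz, dx, dy, dz, cx, cy, cz, r) {
  px <- ox - cx; py <- oy - cy; pz <- oz - cz
  b <- px * dx + py * dy + pz * dz
  c <- px * px + py * py + pz * pz - r * r
  disc <- b * b - c
  t <- rep(Inf, length(dx))
  ok <- disc >= 0
  if (any(ok)) {
    s <- sqrt(disc[ok])
    t1 <- -b[ok] - s
    t2 <- -b[ok] + s
    tt <- ifelse(t1 > .RAY_EPS, t1, ifelse(t2 > .RAY_EPS, t2, Inf))
    t[ok] <- tt
  }
  t
}

# Nearest intersection with a finite vertical cylinder (side wall plus top
# cap disc; the bottom meets the ground plane).
.isect_cylinder <- function(ox, oy, oz, dx, dy, dz, cx, cy, r, h) {
  px <- ox - cx; py <- oy - cy
  a <- dx * dx + dy * dy
  b <- px * dx + py * dy
  c <- px * px + py * py - r * r
  t <- rep(Inf, length(dx))
  ok <- a > 0
  disc <- b * b - a * c
  hit <- ok & disc >= 0
  if (any(hit)) {
    s <- sqrt(disc[hit])
    ah <- a[hit]
    t1 <- (-b[hit] - s) / ah
    t2 <- (-b[hit] + s) / ah
    oz_h <- if (length(oz) == 1L) oz else oz[hit]
    dz_h <- dz[hit]
    z1 <- oz_h + t1 * dz_h
    z2 <- oz_h + t2 * dz_h
    good1 <- t1 > .RAY_EPS & z1 >= 0 & z1 <= h
    good2 <- t2 > .RAY_EPS & z2 >= 0 & z2 <= h
    t[hit] <- ifelse(good1, t1, ifelse(good2, t2, Inf))
  }
  # top cap at z = h
  up <- dz != 0
  tc <- rep(Inf, length(dx))
  tc[up] <- (h - (if (length(oz) == 1L) oz else oz[up])) / dz[up]
  hx <- ox + tc * dx - cx
  hy <- oy + tc * dy - cy
  cap <- is.finite(tc) & tc > .RAY_EPS & (hx * hx + hy * hy) <= r * r
  pmin(t, ifelse(cap, tc, Inf))
}

# Is the (single) point inside any solid primitive? Returns the primitive's
# albedo, or NA if outside all.
.inside_albedo <- function(scene, p) {
  sph <- scene$spheres
  if (nrow(sph)) {
    d2 <- (p[1] - sph[, "cx"])^2 + (p[2] - sph[, "cy"])^2 + (p[3] - sph[, "cz"])^2
    i <- which(d2 < sph[, "r"]^2)
    if (length(i)) return(sph[i[1], "albedo"])
  }
  cyl <- scene$cylinders
  if (nrow(cyl)) {
    d2 <- (p[1] - cyl[, "cx"])^2 + (p[2] - cyl[, "cy"])^2
    i <- which(d2 < cyl[, "r"]^2 & p[3] >= 0 & p[3] <= cyl[, "h"])
    if (length(i)) return(cyl[i[1], "albedo"])
  }
  NA_real_
}

# TRUE where the segment from point P toward the sun is blocked by a solid
# primitive (the ground cannot occlude a sun above the horizon).
.sun_occluded <- function(scene, px, py, pz) {
  d <- scene$sun_dir
  n <- length(px)
  occ <- rep(FALSE, n)
  dx <- rep(d[1], n); dy <- rep(d[2], n); dz <- rep(d[3], n)
  sph <- scene$spheres
  for (i in seq_len(nrow(sph))) {
    todo <- !occ
    if (!any(todo)) break
    t <- .isect_sphere(px[todo], py[todo], pz[todo], dx[todo], dy[todo], dz[todo],
                       sph[i, "cx"], sph[i, "cy"], sph[i, "cz"], sph[i, "r"])
    occ[todo] <- is.finite(t)
  }
  cyl <- scene$cylinders
  for (i in seq_len(nrow(cyl))) {
    todo <- !occ
    if (!any(todo)) break
    t <- .isect_cylinder(px[todo], py[todo], pz[todo], dx[todo], dy[todo], dz[todo],
                         cyl[i, "cx"], cyl[i, "cy"], cyl[i, "r"], cyl[i, "h"])
    occ[todo] <- is.finite(t)
  }
  occ
}

# Synthetic distant panorama texture: an azimuth-dependent treeline
# silhouette over a dark ground band, paler sky above. Periodic in azimuth
# via a unit-circle embedding of the noise coordinates.
.background_texture <- function(az_rad, el_deg, seed, sky_color) {
  n <- length(az_rad)
  skyline <- 2 + 8 * value_noise(3 * cos(az_rad), 3 * sin(az_rad),
                                 seed + 9001L, scale = 1, octaves = 3L)
  shade <- 0.6 + 0.5 * value_noise(6 * cos(az_rad), 6 * sin(az_rad),
                                   seed + 9017L, scale = 1, octaves = 2L)
  col <- matrix(0, n, 3)
  below <- el_deg < 0
  tree <- !below & el_deg < skyline
  sky <- !below & !tree
  if (any(below)) col[below, ] <- outer(shade[below], c(95, 82, 62))
  if (any(tree))  col[tree, ]  <- outer(shade[tree], c(52, 66, 44))
  if (any(sky)) {
    pale <- 0.85 * sky_color + 0.15 * 210
    col[sky, ] <- matrix(pale, sum(sky), 3, byrow = TRUE)
  }
  pmin(pmax(col, 0), 255)
}

#' Trace rays through a scene
#'
#' Returns the colour of the nearest primitive along each ray: its albedo as
#' a grey level (times 255), multiplied by the shadow darkening factor where
#' the hit point is occluded from the sun. Rays hitting nothing take the
#' background sphere texture if one is configured, the uniform background
#' colour, or the sky colour.
#'
#' @param scene a [make_scene()] result.
#' @param origin numeric length-3 point in meters (shared by all rays). If
#'   it lies inside a solid primitive that primitive's colour is returned
#'   for every ray.
#' @param directions unit vectors: either length 3 or an `n x 3` matrix.
#' @return `n x 3` matrix of RGB values in `[0, 255]`.
#' @export
ray_trace <- function(scene, origin, directions) {
  stopifnot(inherits(scene, "catchvol_scene"), length(origin) == 3L)
  if (is.null(dim(directions))) directions <- matrix(directions, ncol = 3)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-6)) stop("directions must be unit vectors")
  n <- nrow(directions)

  inside <- .inside_albedo(scene, origin)
  if (!is.na(inside)) {
    return(matrix(inside * 255, n, 3))
  }

  dx <- directions[, 1]; dy <- directions[, 2]; dz <- directions[, 3]
  ox <- origin[1]; oy <- origin[2]; oz <- origin[3]
  t_best <- rep(Inf, n)
  alb <- rep(NA_real_, n)

  # ground plane z = 0, textured within ground_extent
  gext <- scene$spec$ground_extent
  down <- dz < 0
  tg <- rep(Inf, n)
  tg[down] <- -oz / dz[down]
  gx <- ox + tg * dx
  gy <- oy + tg * dy
  gok <- is.finite(tg) & tg > .RAY_EPS & abs(gx) <= gext & abs(gy) <= gext
  if (any(gok)) {
    gt <- scene$spec$ground_texture
    ga <- gt$albedo_lo + (gt$albedo_hi - gt$albedo_lo) *
      value_noise(gx[gok], gy[gok], scene$spec$seed,
                  scale = gt$noise_scale, octaves = 3L)
    t_best[gok] <- tg[gok]
    alb[gok] <- ga
  }

  cyl <- scene$cylinders
  for (i in seq_len(nrow(cyl))) {
    t <- .isect_cylinder(ox, oy, oz, dx, dy, dz,
                         cyl[i, "cx"], cyl[i, "cy"], cyl[i, "r"], cyl[i, "h"])
    w <- t < t_best
    t_best[w] <- t[w]
    alb[w] <- cyl[i, "albedo"]
  }
  sph <- scene$spheres
  for (i in seq_len(nrow(sph))) {
    t <- .isect_sphere(ox, oy, oz, dx, dy, dz,
                       sph[i, "cx"], sph[i, "cy"], sph[i, "cz"], sph[i, "r"])
    w <- t < t_best
    t_best[w] <- t[w]
    alb[w] <- sph[i, "albedo"]
  }

  col <- matrix(0, n, 3)
  hit <- is.finite(t_best)
  if (any(hit)) {
    sd <- scene$spec$sun$shadow_darkening
    shade <- alb[hit]
    if (sd < 1) {
      hx <- ox + t_best[hit] * dx[hit]
      hy <- oy + t_best[hit] * dy[hit]
      hz <- oz + t_best[hit] * dz[hit]
      # lift the shadow-ray origin off the surface to avoid self-intersection
      occ <- .sun_occluded(scene,
                           hx + 1e-6 * scene$sun_dir[1],
                           hy + 1e-6 * scene$sun_dir[2],
                           hz + 1e-6 * scene$sun_dir[3])
      shade[occ] <- shade[occ] * sd
    }
    col[hit, ] <- shade * 255
  }
  miss <- !hit
  if (any(miss)) {
    bg <- scene$spec$background
    if (bg$type == "panorama") {
      # far intersection with the background sphere centred at the origin of
      # the world (scene centre, ground level)
      R <- bg$sphere_radius_m
      b <- ox * dx[miss] + oy * dy[miss] + oz * dz[miss]
      c0 <- ox^2 + oy^2 + oz^2 - R^2
      t <- -b + sqrt(pmax(b * b - c0, 0))
      hx <- ox + t * dx[miss]; hy <- oy + t * dy[miss]; hz <- oz + t * dz[miss]
      az <- atan2(hx, hy)
      el <- asin(pmin(pmax(hz / R, -1), 1)) * 180 / pi
      col[miss, ] <- .background_texture(az, el, scene$spec$seed,
                                         scene$spec$sky_color)
    } else if (bg$type == "uniform") {
      col[miss, ] <- matrix(bg$color, sum(miss), 3, byrow = TRUE)
    } else {
      col[miss, ] <- matrix(scene$spec$sky_color, sum(miss), 3, byrow = TRUE)
    }
  }
  col
}

#' Rotate scene content about a vertical axis
#'
#' Rotates tree and clutter positions (and the sun azimuth) clockwise by
#' `angle_deg` about the vertical axis through `center`. Used to check
#' rotational equivariance of the renderer: rotating the world by one column
#' step of the panorama should circularly shift the rendered panorama.
#'
#' @param spec a [scene_spec()].
#' @param angle_deg clockwise (compass) rotation angle in degrees.
#' @param center (x, y) of the rotation axis, default the world origin.
#' @return a new `catchvol_scene_spec`.
#' @export
rotate_scene_spec <- function(spec, angle_deg, center = c(0, 0)) {
  validate_scene_spec(spec)
  a <- -angle_deg * pi / 180  # compass-clockwise = mathematically negative
  rot <- function(p) {
    q <- p - center
    center + c(cos(a) * q[1] - sin(a) * q[2], sin(a) * q[1] + cos(a) * q[2])
  }
  spec$trees <- lapply(spec$trees, function(tr) { tr$position <- rot(tr$position); tr })
  spec$clutter <- lapply(spec$clutter, function(cl) { cl$position <- rot(cl$position); cl })
  spec$sun$azimuth_deg <- spec$sun$azimuth_deg + angle_deg
  spec
}

#' Read and write scene specifications
#'
#' Scene specifications serialize to YAML or JSON (chosen by file
#' extension). Reading validates the result.
#'
#' @param spec a [scene_spec()].
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_scene_spec` returns a validated `catchvol_scene_spec`.
#' @export
write_scene_spec <- function(spec, path) {
  validate_scene_spec(spec)
  x <- unclass(spec)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported spec format: ", path)
  invisible(path)
}

#' @rdname write_scene_spec
#' @export
read_scene_spec <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else stop("unsupported spec format: ", path)
  x$trees <- lapply(x$trees, function(tr) { tr$position <- as.numeric(tr$position); tr })
  x$clutter <- lapply(x$clutter, function(cl) { cl$position <- as.numeric(cl$position); cl })
  do.call(scene_spec, x)
}
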