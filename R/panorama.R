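#' @keywords internal
#' Camera bases for the six cube faces. World axes: x = east, y = north,
#' z = up. `f` is the view direction, `r` the image-right vector, `u` the
#' image-up vector.
.CUBE_FACES <- list(
  north = list(f = c(0, 1, 0),  r = c(1, 0, 0),  u = c(0, 0, 1)),
  east  = list(f = c(1, 0, 0),  r = c(0, -1, 0), u = c(0, 0, 1)),
  south = list(f = c(0, -1, 0), r = c(-1, 0, 0), u = c(0, 0, 1)),
  west  = list(f = c(-1, 0, 0), r = c(0, 1, 0),  u = c(0, 0, 1)),
  up    = list(f = c(0, 0, 1),  r = c(1, 0, 0),  u = c(0, -1, 0)),
  down  = list(f = c(0, 0, -1), r = c(1, 0, 0),  u = c(0, 1, 0))
)

.CUBE_FOV_DEG <- 95  # per-face field of view; the 5 deg beyond 90 is overlap margin

#' Render a six-camera cube-map
#'
#' Renders six square perspective views (north, east, south, west, up,
#' down), each with a 95 x 95 degree field of view, from one position. The
#' cameras are grid-aligned: x points east, y north, z up.
#'
#' @param scene a [make_scene()] result.
#' @param position (x, y, z) in meters. Must be above the ground plane
#'   unless `allow_below_ground` is TRUE.
#' @param face_res pixels per face side (default 128).
#' @param allow_below_ground permit positions with z < 0.
#' @return object of class `catchvol_cubemap`: list of six
#'   `face_res x face_res x 3` RGB arrays plus the position.
#' @export
render_cubemap <- function(scene, position, face_res = 128L,
                           allow_below_ground = FALSE) {
  stopifnot(length(position) == 3L, face_res >= 2L)
  if (position[3] < 0 && !allow_below_ground)
    stop("camera position is below the ground plane (z < 0)")
  th <- tan(.CUBE_FOV_DEG / 2 * pi / 180)
  # pixel centres at half-integer offsets, mapped to [-1, 1]
  s <- ((seq_len(face_res) - 0.5) / face_res) * 2 - 1
  sx <- rep(s, times = face_res)          # column-major: x fastest
  sy <- rep(s, each = face_res)
  faces <- lapply(.CUBE_FACES, function(fc) {
    d <- cbind(fc$f[1] + th * (sx * fc$r[1] + sy * fc$u[1]),
               fc$f[2] + th * (sx * fc$r[2] + sy * fc$u[2]),
               fc$f[3] + th * (sx * fc$r[3] + sy * fc$u[3]))
    d <- d / sqrt(rowSums(d^2))
    col <- ray_trace(scene, position, d)
    # rows of the raster run top-to-bottom; sy increases with image-up
    arr <- array(0, c(face_res, face_res, 3))
    for (ch in 1:3) {
      m <- matrix(col[, ch], face_res, face_res)  # [x, y_up]
      arr[, , ch] <- t(m)[face_res:1, ]           # -> [row(top first), col]
    }
    arr
  })
  structure(list(faces = faces, position = position, face_res = face_res,
                 fov_deg = .CUBE_FOV_DEG), class = "catchvol_cubemap")
}

# Direction of the ray through face pixel centre (row, col), for tests and
# for the inverse mapping used by the equirectangular projector.
.face_pixel_direction <- function(face_name, row, col, face_res,
                                  fov_deg = .CUBE_FOV_DEG) {
  fc <- .CUBE_FACES[[face_name]]
  th <- tan(fov_deg / 2 * pi / 180)
  sx <- ((col - 0.5) / face_res) * 2 - 1
  sy <- 1 - ((row - 0.5) / face_res) * 2
  d <- fc$f + th * (sx * fc$r + sy * fc$u)
  d / sqrt(sum(d^2))
}

#' Project a cube-map to an equirectangular panorama
#'
#' Maps the six cube faces onto a `width/2 x width` raster with azimuth on
#' the horizontal axis (column centre azimuth `(c - 0.5) * 360 / width`
#' degrees, 0 = north, clockwise through east) and elevation on the
#' vertical axis (row centre elevation `90 - (r - 0.5) * 180 / height`).
#' Each output pixel selects the face whose axis dominates its view
#' direction and samples it bilinearly (or nearest-neighbour).
#'
#' @param cubemap a [render_cubemap()] result.
#' @param width output width in pixels (default 384, giving 192 rows).
#' @param interp `"bilinear"` (default) or `"nearest"`.
#' @return RGB array `height x width x 3`, class `catchvol_panorama`.
#' @export
cubemap_to_equirect <- function(cubemap, width = 384L, interp = "bilinear") {
  stopifnot(inherits(cubemap, "catchvol_cubemap"),
            width %% 2 == 0, interp %in% c("bilinear", "nearest"))
  height <- width %/% 2L
  res <- cubemap$face_res
  th <- tan(cubemap$fov_deg / 2 * pi / 180)

  az <- ((seq_len(width) - 0.5) / width) * 2 * pi       # compass, radians
  el <- (0.5 - (seq_len(height) - 0.5) / height) * pi   # +pi/2 .. -pi/2
  AZ <- matrix(az, height, width, byrow = TRUE)
  EL <- matrix(el, height, width)
  dx <- c(sin(AZ) * cos(EL))
  dy <- c(cos(AZ) * cos(EL))
  dz <- c(sin(EL))

  # dominant-axis face selection
  ax <- abs(dx); ay <- abs(dy); az3 <- abs(dz)
  face_id <- ifelse(az3 >= ax & az3 >= ay,
                    ifelse(dz > 0, 5L, 6L),
                    ifelse(ax >= ay,
                           ifelse(dx > 0, 2L, 4L),
                           ifelse(dy > 0, 1L, 3L)))
  out <- matrix(0, height * width, 3)
  for (id in 1:6) {
    sel <- face_id == id
    if (!any(sel)) next
    fc <- .CUBE_FACES[[id]]
    df <- dx[sel] * fc$f[1] + dy[sel] * fc$f[2] + dz[sel] * fc$f[3]
    a <- (dx[sel] * fc$r[1] + dy[sel] * fc$r[2] + dz[sel] * fc$r[3]) / (df * th)
    b <- (dx[sel] * fc$u[1] + dy[sel] * fc$u[2] + dz[sel] * fc$u[3]) / (df * th)
    # continuous pixel coordinates (1-based centres)
    px <- (a + 1) / 2 * res + 0.5
    py <- (1 - b) / 2 * res + 0.5
    img <- cubemap$faces[[id]]
    if (interp == "nearest") {
      ri <- pmin(pmax(round(py), 1L), res)
      ci <- pmin(pmax(round(px), 1L), res)
      for (ch in 1:3) out[sel, ch] <- img[cbind(ri, ci, ch)]
    } else {
      r0 <- pmin(pmax(floor(py), 1L), res - 1L)
      c0 <- pmin(pmax(floor(px), 1L), res - 1L)
      fr <- pmin(pmax(py - r0, 0), 1)
      fc2 <- pmin(pmax(px - c0, 0), 1)
      for (ch in 1:3) {
        v00 <- img[cbind(r0, c0, ch)]
        v01 <- img[cbind(r0, c0 + 1L, ch)]
        v10 <- img[cbind(r0 + 1L, c0, ch)]
        v11 <- img[cbind(r0 + 1L, c0 + 1L, ch)]
        out[sel, ch] <- (v00 * (1 - fc2) + v01 * fc2) * (1 - fr) +
          (v10 * (1 - fc2) + v11 * fc2) * fr
      }
    }
  }
  pano <- array(0, c(height, width, 3))
  for (ch in 1:3) pano[, , ch] <- matrix(out[, ch], height, width)
  structure(pano, class = "catchvol_panorama", position = cubemap$position)
}

#' Flatten an RGB panorama to 8-bit greyscale
#'
#' Uses the ITU-R BT.601 luma weights (0.299 R + 0.587 G + 0.114 B), the
#' standard colour-to-grey conversion, rounded to the nearest integer and
#' clipped to `[0, 255]`. Greyscale input is returned unchanged, so the
#' conversion is idempotent.
#'
#' @param pano RGB array `h x w x 3` or an already-grey `h x w` matrix.
#' @return integer-valued matrix `h x w` in `[0, 255]`.
#' @export
to_grayscale <- function(pano) {
  if (is.matrix(pano)) return(pano)
  stopifnot(length(dim(pano)) == 3L, dim(pano)[3] == 3L)
  d <- dim(pano)
  g <- 0.299 * pano[, , 1] + 0.587 * pano[, , 2] + 0.114 * pano[, , 3]
  matrix(pmin(pmax(round(g), 0), 255), d[1], d[2])
}

#' Roll a panorama in azimuth
#'
#' Circularly shifts the columns by `k` steps of `360 / ncol` degrees each;
#' positive `k` rotates the view clockwise (content moves left-to-right...
#' concretely, column `c` of the result is column `c - k` of the input,
#' wrapped). `k` is reduced modulo the width, so `k = 0` and `k = ncol`
#' are identities.
#'
#' @param pano greyscale matrix or RGB array.
#' @param k integer column shift.
#' @return panorama of the same shape.
#' @export
roll_azimuth <- function(pano, k) {
  w <- if (is.matrix(pano)) ncol(pano) else dim(pano)[2]
  k <- ((as.integer(k) %% w) + w) %% w
  if (k == 0L) return(pano)
  idx <- c((w - k + 1L):w, 1L:(w - k))
  if (is.matrix(pano)) pano[, idx] else pano[, idx, , drop = FALSE]
}

#' Horizon masks
#'
#' Boolean rasters selecting the above-horizon half (positive elevation,
#' top half of rows), the below-horizon half, or all pixels. The horizon
#' lies exactly on the boundary between the two middle rows, so the halves
#' partition the raster with equal pixel counts.
#'
#' @param keep one of `"above"`, `"below"`, `"all"`.
#' @param height,width raster dimensions (default 192 x 384).
#' @return logical matrix `height x width`.
#' @export
horizon_mask <- function(keep = c("all", "above", "below"),
                         height = 192L, width = 384L) {
  keep <- match.arg(keep)
  m <- matrix(TRUE, height, width)
  if (keep == "above") m[(height %/% 2L + 1L):height, ] <- FALSE
  if (keep == "below") m[1:(height %/% 2L), ] <- FALSE
  m
}

#' Render a greyscale panorama in one call
#'
#' Convenience wrapper: cube-map render, equirectangular projection and
#' greyscale flattening. `face_res` defaults to `width / 3`, preserving the
#' 128-pixel faces of the full-size 384-column panorama at reduced widths.
#'
#' @inheritParams render_cubemap
#' @inheritParams cubemap_to_equirect
#' @return greyscale matrix `width/2 x width`.
#' @export
render_panorama <- function(scene, position, width = 384L,
                            face_res = max(8L, as.integer(round(width / 3))),
                            interp = "bilinear") {
  to_grayscale(cubemap_to_equirect(
    render_cubemap(scene, position, face_res = face_res),
    width = width, interp = interp))
}

#' Read and write greyscale panoramas as 8-bit PNG
#'
#' @param pano greyscale matrix in `[0, 255]`.
#' @param path PNG file path.
#' @return `read_panorama_png` returns a greyscale matrix in `[0, 255]`.
#' @export
write_panorama_png <- function(pano, path) {
  stopifnot(is.matrix(pano))
  png::writePNG(pano / 255, path)
  invisible(path)
}

#' @rdname write_panorama_png
#' @export
read_panorama_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- to_grayscale(img[, , 1:3] * 255)
  else img <- round(img * 255)
  img
}

#' Batch manifest for panoramas on disk
#'
#' A manifest is a CSV with columns `x_m`, `y_m`, `z_m`, `file` locating
#' each panorama image in the world.
#'
#' @param positions `n x 3` matrix of camera positions (meters).
#' @param files character vector of PNG paths, one per position.
#' @param path CSV path to write.
#' @return `read_panorama_manifest` returns a data.frame.
#' @export
write_panorama_manifest <- function(positions, files, path) {
  stopifnot(nrow(positions) == length(files))
  df <- data.frame(x_m = positions[, 1], y_m = positions[, 2],
                   z_m = positions[, 3], file = files)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panorama_manifest
#' @export
read_panorama_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
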