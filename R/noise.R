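#' Seeded band-limited value noise
#'
#' Deterministic multi-octave value noise on a 2D lattice, used for the
#' ground-plane texture and the distant background panorama. The lattice
#' values come from a coordinate hash, so the field is a pure function of
#' (x, y, seed) and needs no stored state: identical inputs give
#' bit-identical output on a given platform.
#'
#' @param x,y numeric vectors of sample coordinates (meters).
#' @param seed integer seed; different seeds give independent fields.
#' @param scale correlation length in meters of the base octave.
#' @param octaves number of octaves; each halves the wavelength and the
#'   amplitude.
#' @return numeric vector in `[0, 1]`, same length as `x`.
#' @keywords internal
value_noise <- function(x, y, seed, scale = 1, octaves = 3L) {
  stopifnot(length(x) == length(y), scale > 0, octaves >= 1L)
  out <- numeric(length(x))
  amp <- 1
  total <- 0
  for (o in seq_len(octaves)) {
    out <- out + amp * .value_noise_octave(x / scale, y / scale, seed + 131L * o)
    total <- total + amp
    amp <- amp / 2
    x <- x * 2
    y <- y * 2
  }
  out / total
}

# Hash integer lattice coordinates to [0,1). The sine-fract construction is
# the standard shader-style hash; adequate statistical quality for texture.
.lattice_hash <- function(ix, iy, seed) {
  s <- sin(ix * 127.1 + iy * 311.7 + seed * 74.7) * 43758.5453123
  s - floor(s)
}

.value_noise_octave <- function(u, v, seed) {
  iu <- floor(u); iv <- floor(v)
  fu <- u - iu;   fv <- v - iv
  # smoothstep weights keep the field C1 so nearby views differ smoothly
  wu <- fu * fu * (3 - 2 * fu)
  wv <- fv * fv * (3 - 2 * fv)
  h00 <- .lattice_hash(iu,     iv,     seed)
  h10 <- .lattice_hash(iu + 1, iv,     seed)
  h01 <- .lattice_hash(iu,     iv + 1, seed)
  h11 <- .lattice_hash(iu + 1, iv + 1, seed)
  (h00 * (1 - wu) + h10 * wu) * (1 - wv) + (h01 * (1 - wu) + h11 * wu) * wv
}
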