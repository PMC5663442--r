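# Shared fixtures, rendered lazily once per test session. The site3-like
# stack (11^3 voxels at 0.2 m, 96-pixel-wide panoramas) backs both the
# hill-climb/gradient-descent comparison and the reference-height and
# horizon-masking properties.

.fixtures <- new.env(parent = emptyenv())

site3_grid <- function() grid_from_side(2, 0.2, center = c(0, 0, 1.2))

site3_stack <- function() {
  if (is.null(.fixtures$site3_stack)) {
    scene <- make_scene(preset_scene("site3_like", seed = 1L))
    .fixtures$site3_stack <- render_grid(scene, site3_grid(), width = 96L)
  }
  .fixtures$site3_stack
}

site3_reference <- function(kz) {
  stack <- site3_stack()
  ic <- (stack$grid$counts[1:2] + 1L) %/% 2L
  c(ic[1], ic[2], as.integer(kz))
}

# a small random greyscale panorama for image-level tests
random_pano <- function(h = 16L, w = 32L) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}
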