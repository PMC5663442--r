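test_that("scene spec validation names the offending field", {
  expect_error(scene_spec(ground_extent = -1), "ground_extent")
  expect_error(scene_spec(ground_texture = list(albedo_lo = 1.5)), "albedo_lo")
  expect_error(scene_spec(sun = list(elevation_deg = 120)), "elevation_deg")
  expect_error(scene_spec(sun = list(shadow_darkening = -0.1)), "shadow_darkening")
  expect_error(scene_spec(trees = list(list(position = c(0, 0), trunk_radius = 0,
                                            trunk_height = 1, canopy_radius = 1,
                                            albedo = 0.5))),
               "trunk_radius")
  expect_error(scene_spec(sky_color = c(300, 0, 0)), "sky_color")
  expect_error(scene_spec(background = list(type = "stars")), "background\\$type")
})

test_that("rays that hit nothing return the sky colour exactly", {
  sc <- make_scene(scene_spec(sky_color = c(12, 34, 56)))
  col <- ray_trace(sc, c(0, 0, 1), c(0, 0, 1))
  expect_equal(drop(col), c(12, 34, 56))
  # horizontal rays beyond the ground extent also miss
  sc2 <- make_scene(scene_spec(ground_extent = 5, sky_color = c(12, 34, 56)))
  col2 <- ray_trace(sc2, c(0, 0, 1), c(1, 0, 0))
  expect_equal(drop(col2), c(12, 34, 56))
})

test_that("constant-albedo ground renders a single shade everywhere", {
  spec <- scene_spec(ground_extent = 500,
                     ground_texture = list(albedo_lo = 0.5, albedo_hi = 0.5))
  p <- render_panorama(make_scene(spec), c(0, 0, 1), width = 96)
  # rows well below the horizon; the first rows under it blend with the sky
  # visible beyond the far edge of the (finite) ground plane
  below <- p[30:48, ]
  expect_equal(length(unique(as.vector(below))), 1L)
  expect_equal(below[1, 1], 128)  # round(0.5 * 255)
  # straight down from 1 m: the unshadowed ground shade
  col <- ray_trace(make_scene(spec), c(0, 0, 1), c(0, 0, -1))
  expect_equal(drop(col), rep(0.5 * 255, 3))
})

test_that("identical spec and seed give bit-identical renders", {
  p1 <- render_panorama(make_scene(preset_scene("site1_like", 7L)),
                        c(0.3, -0.2, 0.8), width = 96)
  p2 <- render_panorama(make_scene(preset_scene("site1_like", 7L)),
                        c(0.3, -0.2, 0.8), width = 96)
  expect_identical(p1, p2)
})

test_that("sun-occluded ground points are darkened by the shadow factor", {
  # canopy sphere centred at (0, 2, 1.75); the sun stands in the north at
  # 45 degrees elevation, so the shadow falls south of the tree and the sun
  # line from ground point (0, 0.25, 0) passes through the sphere centre
  spec <- scene_spec(ground_extent = 50,
                     ground_texture = list(albedo_lo = 0.6, albedo_hi = 0.6),
                     trees = list(list(position = c(0, 2), trunk_radius = 0.01,
                                       trunk_height = 1.5, canopy_radius = 0.5,
                                       albedo = 0.2)),
                     sun = list(azimuth_deg = 0, elevation_deg = 45,
                                shadow_darkening = 0.3))
  sc <- make_scene(spec)
  sun_dir <- c(0, cos(pi / 4), sin(pi / 4))
  center <- c(0, 2, 1.5 + 0.25)  # trunk_height + canopy_radius / 2
  shadowed <- c(0, 0.25, 0)
  lit <- c(3, -3, 0)
  expect_lt(oracle_sphere_hit(shadowed, sun_dir, center, 0.5), Inf)
  expect_equal(oracle_sphere_hit(lit, sun_dir, center, 0.5), Inf)
  col_shadow <- ray_trace(sc, shadowed + c(0, 0, 1), c(0, 0, -1))
  col_lit <- ray_trace(sc, lit + c(0, 0, 1), c(0, 0, -1))
  expect_equal(drop(col_shadow), rep(0.6 * 0.3 * 255, 3))
  expect_equal(drop(col_lit), rep(0.6 * 255, 3))
})

test_that("disabling shadow darkening only brightens shadow pixels", {
  spec <- preset_scene("site1_like", 3L)
  p_shadow <- render_panorama(make_scene(spec), c(0, 0, 0.5), width = 96)
  spec$sun$shadow_darkening <- 1
  p_flat <- render_panorama(make_scene(spec), c(0, 0, 0.5), width = 96)
  expect_true(all(p_flat >= p_shadow))
  expect_gt(sum(p_flat != p_shadow), 0)  # the preset does cast shadows
})

test_that("an origin inside a solid primitive returns that primitive's colour", {
  spec <- scene_spec(trees = list(list(position = c(0, 0), trunk_radius = 0.5,
                                       trunk_height = 2, canopy_radius = 1,
                                       albedo = 0.25)))
  sc <- make_scene(spec)
  col <- ray_trace(sc, c(0, 0, 1), rbind(c(0, 0, 1), c(1, 0, 0)))
  expect_equal(col, matrix(0.25 * 255, 2, 3))
})

test_that("rotating the world about the camera shifts the panorama by columns", {
  # uniform ground so that only the (rotated) trees and sun matter
  spec <- preset_scene("four_landmarks", 1L)
  spec$sun <- list(azimuth_deg = 120, elevation_deg = 55, shadow_darkening = 0.5)
  pos <- c(0, 0, 1.5)
  p <- render_panorama(make_scene(spec), pos, width = 96)
  # a quarter turn is exact: the face rasters map onto each other
  p90 <- render_panorama(make_scene(rotate_scene_spec(spec, 90)), pos, width = 96)
  expect_identical(p90, roll_azimuth(p, 24))
  # a one-column turn agrees up to interpolation error, small vs contrast
  p1 <- render_panorama(make_scene(rotate_scene_spec(spec, 360 / 96)), pos,
                        width = 96)
  expect_lt(mean(abs(p1 - roll_azimuth(p, 1))), 0.05 * sd(p))
})

test_that("scene specs round-trip through YAML and JSON", {
  spec <- preset_scene("site1_like", 5L)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_scene_spec(spec, path)
    back <- read_scene_spec(path)
    expect_equal(unclass(back), unclass(spec), tolerance = 1e-12)
  }
})

test_that("the shipped preset files match the in-code presets", {
  for (nm in c("site1_like", "site3_like", "four_landmarks")) {
    path <- system.file("extdata", paste0(nm, ".yaml"), package = "catchvol")
    expect_true(nzchar(path))
    expect_equal(unclass(read_scene_spec(path)),
                 unclass(preset_scene(nm, 1L)), tolerance = 1e-12)
  }
})
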