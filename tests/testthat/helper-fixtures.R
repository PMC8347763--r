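# shared fixtures: small rasters and reduced scene configurations

toy_raster <- function(values, pixel = 30, origin_x = 0,
                       origin_y = nrow(as.matrix(values)) * pixel) {
  grid_raster(as.matrix(values), origin_x, origin_y, pixel)
}

# default synthetic scene restricted to the dates a fusion test needs
fusion_scene <- function(seed, doys = c(174L, 206L, 230L, 254L), ...) {
  generate_scene(scene_config(seed = seed, doys = doys, ...))
}

# small 48x48 layout (two plots, contrasting background) for pipeline tests
small_scene_config <- function(seed = 0L, ...) {
  px <- 30; top <- 48 * px
  rect_cells <- function(nm, r0, r1, c0, c1)
    rect_polygon(nm, (c0 - 1) * px, c1 * px, top - r1 * px, top - (r0 - 1) * px)
  scene_config(
    fine_shape = c(48L, 48L), ratios = c(8L, 16L),
    plots = list(
      list(name = "A", polygon = rect_cells("A", 9, 24, 9, 24), cover = "cotton_a"),
      list(name = "C", polygon = rect_cells("C", 29, 44, 21, 36), cover = "cotton_c")),
    background = list(
      list(rect = c(1L, 8L, 1L, 48L), cover = "crop_early"),
      list(rect = c(45L, 48L, 1L, 48L), cover = "fallow")),
    track_spacing = 30, point_spacing = 15,
    seed = seed, ...)
}

expect_raster_equal <- function(a, b, tol = 0) {
  expect_true(same_grid(a, b))
  if (tol == 0) expect_identical(a$values, b$values)
  else expect_lt(max(abs(a$values - b$values), na.rm = TRUE), tol)
}
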