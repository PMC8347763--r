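# units below: fine pixel = 1 m so areas can be read as fine-cell counts

test_that("pixel_overlaps computes exact areas and applies the 1% rule", {
  coarse <- toy_raster(matrix(0.5, 2, 2), pixel = 8) # two rows, two cols of 8x8
  # plot exactly equal to the top-left coarse pixel
  p1 <- rect_polygon("P1", 0, 8, 8, 16)
  ov1 <- pixel_overlaps(p1, coarse)
  expect_identical(nrow(ov1), 1L)
  expect_equal(ov1$s_p, 64)
  expect_equal(ov1$coverage, 1)
  # plot covering pixel 1 fully and the left half of its right neighbor
  p2 <- rect_polygon("P2", 0, 12, 8, 16)
  ov2 <- pixel_overlaps(p2, coarse)
  expect_equal(ov2$coverage, c(1, 0.5))
  expect_identical(ov2$col, c(1L, 2L)) # row-major order
  # a 0.5%-coverage tab dipping into a third pixel below is excluded
  p3 <- plot_polygon("P3", cbind(c(0, 0.32, 0.32, 12, 12, 0),
                                 c(7, 7, 8, 8, 16, 16)))
  ov3 <- pixel_overlaps(p3, coarse)
  expect_identical(nrow(ov3), 2L)
  # and is included at a lower threshold
  ov3b <- pixel_overlaps(p3, coarse, min_coverage = 0.001)
  expect_identical(nrow(ov3b), 3L)
  # warning when nothing reaches the threshold
  tiny <- rect_polygon("T", 0, 0.5, 15.5, 16)
  expect_warning(ovt <- pixel_overlaps(tiny, coarse), "coverage")
  expect_identical(nrow(ovt), 0L)
})

test_that("m_par follows the purity-times-share product", {
  expect_equal(m_par(64, 64, 64), 1)           # plot = one pure pixel
  expect_equal(m_par(64, 64, 256), 0.25)       # one of 4 tiled pure pixels
  expect_equal(sum(rep(m_par(64, 64, 256), 4)), 1)
  expect_equal(m_par(32, 64, 96), 1 / 6)       # hand evaluation
  expect_error(m_par(1, 0, 1), "positive")
  expect_error(m_par(10, 8, 9), "min")
})

test_that("ndvi_pro measures relative discrepancy with a degenerate-zero rule", {
  expect_equal(ndvi_pro(0.7, 0.7), 0)
  expect_equal(ndvi_pro(0.5, 0.8), 0.375)
  expect_warning(z <- ndvi_pro(0, 0), "defining")
  expect_equal(z, 0)
})

test_that("compute_mdi reproduces the hand-evaluated two-pixel example", {
  # fine grid 16x8 of 1 m; coarse 2x1 of 8 m; plot = pixel 1 plus left half
  # of pixel 2; plot NDVI 0.8, background 0.2; coarse pixel 2 mixed at 0.5
  fine_v <- matrix(0.2, 8, 16)
  fine_v[, 1:12] <- 0.8
  fine <- grid_raster(fine_v, 0, 8, 1)
  coarse <- grid_raster(matrix(c(0.8, 0.5), 1, 2), 0, 8, 8)
  plot <- rect_polygon("toy", 0, 12, 0, 8)
  res <- compute_mdi(plot, coarse, fine)
  cmp <- res$components
  expect_equal(cmp$m_par, c(2 / 3, 1 / 6))
  expect_equal(cmp$ndvi_l, c(0.8, 0.8))
  expect_equal(cmp$ndvi_pro, c(0, 0.375))
  expect_equal(res$mdi, 0.0625)
})

test_that("MDI is zero for pure, consistent plots and lies in [0, 1]", {
  # plot tiling 4 pure coarse pixels with uniform NDVI
  fine <- grid_raster(matrix(0.8, 16, 16), 0, 16, 1)
  coarse <- grid_raster(matrix(0.8, 2, 2), 0, 16, 8)
  plot <- rect_polygon("sq", 0, 16, 0, 16)
  res <- compute_mdi(plot, coarse, fine)
  expect_equal(res$mdi, 0)
  expect_true(all(res$components$ndvi_pro == 0))
})

test_that("MDI decreases monotonically as the background matches the plot", {
  fine_v <- matrix(NA_real_, 8, 16)
  plot <- rect_polygon("toy", 0, 12, 0, 8)
  prev <- Inf
  for (bg in c(0.2, 0.4, 0.6, 0.8)) {
    fv <- matrix(bg, 8, 16); fv[, 1:12] <- 0.8
    fine <- grid_raster(fv, 0, 8, 1)
    coarse <- block_aggregate(fine, 8)
    m <- compute_mdi(plot, coarse, fine)$mdi
    expect_true(m >= 0 && m <= 1)
    expect_lte(m, prev)
    prev <- m
  }
  expect_equal(prev, 0) # background == plot: perfect agreement
})

test_that("boundary-cut plots mix more at coarser resolution (seeded replicates)", {
  # a plot offset by half a ratio-8 pixel, contrasting background; the MDI
  # at ratio 16 should be at least the MDI at ratio 8 in most replicates
  wins <- 0L
  for (seed in 1:8) {
    cfg <- mixing_ladder_config(doys = 230L)
    cfg$seed <- seed
    cfg$amp_jitter_sd <- 0.05 # mild within-plot texture
    sc <- make_mixing_ladder(cfg, offsets = 120)[[1]]
    pl <- sc$plots[[1]]
    m8 <- compute_mdi(pl, stack_at(sc$coarse[["8"]], 230),
                      stack_at(sc$fine, 230))$mdi
    m16 <- compute_mdi(pl, stack_at(sc$coarse[["16"]], 230),
                       stack_at(sc$fine, 230))$mdi
    expect_true(m8 >= 0 && m8 <= 1 && m16 >= 0 && m16 <= 1)
    if (m16 >= m8) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("mdi_series reports one MDI per shared date", {
  sc <- fusion_scene(seed = 3, doys = c(174L, 206L, 230L))
  ser <- mdi_series(sc$plots[[1]], sc$coarse[["8"]], sc$fine)
  expect_identical(ser$doy, c(174L, 206L, 230L))
  expect_true(all(is.finite(ser$mdi)))
  expect_true(all(ser$mdi >= 0 & ser$mdi <= 1))
})
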