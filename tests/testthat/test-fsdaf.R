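test_that("delineate crops to whole coarse pixels and flags region cells", {
  r <- toy_raster(matrix(seq_len(64) / 64, 8, 8), pixel = 1)
  # full extent: identity
  d <- delineate(r, NULL, ratio = 4)
  expect_raster_equal(d$raster, r)
  expect_true(all(d$inside))
  # region covering fine cells rows/cols 1..6 (a 6x6 block), ratio 4:
  # crop snaps out to the full 8x8 (whole coarse pixels)
  reg <- rect_polygon("R", 0, 6, 2, 8)
  d2 <- delineate(r, reg, ratio = 4)
  expect_identical(dim(d2$raster$values), c(8L, 8L))
  expect_identical(sum(d2$inside), 36L)
  # disjoint region
  expect_error(delineate(r, rect_polygon("X", 100, 110, 0, 10), 4), "intersect")
})

test_that("classify_fine recovers separable clusters and exact block fractions", {
  v <- matrix(0.2, 8, 8); v[, 5:8] <- 0.8
  cm <- classify_fine(toy_raster(v, pixel = 1), 2, seed = 1, ratio = 4)
  expect_identical(unique(as.vector(cm$labels[, 1:4])), 1L)
  expect_identical(unique(as.vector(cm$labels[, 5:8])), 2L)
  # each 4x4 block is pure: fractions are 0/1
  expect_equal(cm$fractions,
               matrix(c(1, 1, 0, 0, 0, 0, 1, 1), ncol = 2))
  # constant image, single class
  cm1 <- classify_fine(toy_raster(matrix(0.5, 4, 4)), 1, ratio = 2)
  expect_true(all(cm1$labels == 1L))
  expect_true(all(cm1$fractions == 1))
  expect_error(classify_fine(toy_raster(matrix(0.5, 4, 4)), 2, ratio = 2),
               "degenerate")
})

test_that("classify_fine fractions equal exhaustive label counts", {
  set.seed(21)
  vals <- sample(c(0.1, 0.5, 0.9), 16, replace = TRUE)
  r <- toy_raster(matrix(vals, 4, 4), pixel = 1)
  cm <- classify_fine(r, 3, seed = 2, ratio = 4)
  # single coarse pixel: fractions = value counts / 16 (classes sorted by center)
  counts <- table(factor(vals, levels = c(0.1, 0.5, 0.9)))
  expect_equal(as.vector(cm$fractions), as.vector(counts) / 16)
  # determinism
  cm2 <- classify_fine(r, 3, seed = 2, ratio = 4)
  expect_identical(cm$labels, cm2$labels)
})

test_that("coarse_change is the elementwise difference", {
  a <- toy_raster(matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2))
  b <- toy_raster(matrix(c(0.4, 0.2, 0.3, -0.1), 2, 2))
  expect_equal(coarse_change(a, a)$values, matrix(0, 2, 2))
  expect_equal(coarse_change(a, b)$values, b$values - a$values)
  expect_error(coarse_change(a, toy_raster(matrix(0, 3, 3))), "same grid")
})

test_that("temporal_prediction solves uniform and block-diagonal systems exactly", {
  # single class, uniform change
  f1 <- toy_raster(matrix(runif(16, 0.2, 0.4), 4, 4), pixel = 1)
  cm <- classify_fine(f1, 1, ratio = 2)
  dc <- toy_raster(matrix(0.07, 2, 2), pixel = 2)
  tp <- temporal_prediction(f1, dc, cm, 2)
  expect_equal(unname(tp$delta_class), 0.07)
  expect_equal(tp$tp_fine$values, f1$values + 0.07)
  expect_equal(tp$residual$values, matrix(0, 2, 2))
  # two classes occupying disjoint coarse pixels
  v <- matrix(0.2, 4, 4); v[, 3:4] <- 0.8
  f2 <- toy_raster(v, pixel = 1)
  cm2 <- classify_fine(f2, 2, seed = 0, ratio = 2)
  dcv <- matrix(c(0.05, 0.05, -0.03, -0.03), 2, 2)
  tp2 <- temporal_prediction(f2, toy_raster(dcv, pixel = 2), cm2, 2)
  expect_equal(unname(tp2$delta_class), c(0.05, -0.03))
})

test_that("temporal_prediction matches a normal-equations oracle on mixed fractions", {
  # 4 coarse pixels (ratio 2), 2 classes with mixed fractions
  lab <- matrix(c(1, 1, 2, 1,
                  2, 2, 1, 1,
                  1, 2, 2, 2,
                  1, 1, 2, 1), 4, 4, byrow = TRUE)
  vals <- ifelse(lab == 1, 0.3, 0.7)
  f1 <- toy_raster(vals, pixel = 1)
  cm <- classify_fine(f1, 2, seed = 0, ratio = 2)
  dcv <- matrix(c(0.10, 0.02, -0.04, 0.06), 2, 2)
  tp <- temporal_prediction(f1, toy_raster(dcv, pixel = 2), cm, 2)
  # independent normal-equations solve from hand-counted fractions
  Fm <- t(vapply(1:4, function(k) {
    i <- c(1, 3, 1, 3)[k]; j <- c(1, 1, 3, 3)[k] # column-major coarse order
    blk <- lab[i:(i + 1), j:(j + 1)]
    c(mean(blk == 1), mean(blk == 2))
  }, numeric(2)))
  oracle <- solve(t(Fm) %*% Fm, t(Fm) %*% as.vector(dcv))
  expect_equal(unname(tp$delta_class), as.vector(oracle), tolerance = 1e-10)
  # residual invariant: delta_c - block mean of the implied fine change
  implied <- block_aggregate(toy_raster(tp$tp_fine$values - vals, pixel = 1), 2)
  expect_equal(tp$residual$values, dcv - implied$values, tolerance = 1e-12)
})

test_that("thin-plate spline reproduces constants, affine fields and control points", {
  coarse <- toy_raster(matrix(0.42, 4, 4), pixel = 4)
  fine <- toy_raster(matrix(0, 16, 16), pixel = 1)
  expect_lt(max(abs(tps_prediction(coarse, fine)$values - 0.42)), 1e-8)
  # affine field
  cc <- pixel_centers(coarse)
  av <- outer(cc$y, cc$x, function(y, x) 0.1 + 0.002 * x - 0.003 * y)
  ar <- grid_raster(av, 0, 16, 4)
  pred <- tps_prediction(ar, fine)
  fc <- pixel_centers(fine)
  truth <- outer(fc$y, fc$x, function(y, x) 0.1 + 0.002 * x - 0.003 * y)
  expect_lt(max(abs(pred$values - truth)), 1e-8)
  # exact interpolation at control points with smoothing 0
  set.seed(9)
  rv <- matrix(runif(16), 4, 4)
  rr <- grid_raster(rv, 0, 16, 4)
  fit <- tps_fit(rep(cc$x, each = 4), rep(cc$y, times = 4), as.vector(rv))
  at_ctrl <- tps_eval(fit, rep(cc$x, each = 4), rep(cc$y, times = 4))
  expect_lt(max(abs(at_ctrl - as.vector(rv))), 1e-8)
  # degenerate configurations
  expect_error(tps_fit(c(0, 1), c(0, 0), c(1, 2)), "at least 3")
  expect_error(tps_fit(c(0, 1, 2), c(0, 0, 0), c(1, 2, 3)), "collinear")
})

test_that("distribute_residuals allocates by guidance scores with exact block means", {
  # homogeneous single-class block: every fine pixel receives the residual
  f1 <- toy_raster(matrix(0.5, 4, 4), pixel = 1)
  cm <- classify_fine(f1, 1, ratio = 2)
  dc <- toy_raster(matrix(c(0.08, -0.02, 0.04, 0), 2, 2), pixel = 2)
  # build a tpred with zero delta_class so the residual equals dc
  tp <- temporal_prediction(f1, toy_raster(matrix(0, 2, 2), pixel = 2), cm, 2)
  tp$residual <- dc
  sp <- toy_raster(matrix(0.5, 4, 4), pixel = 1) # no discrepancy anywhere
  alloc <- distribute_residuals(tp, sp, f1, 2)
  for (i in 1:2) for (j in 1:2)
    expect_equal(alloc$values[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)],
                 matrix(dc$values[i, j], 2, 2))
  # zero residual -> zero allocation
  tp$residual <- toy_raster(matrix(0, 2, 2), pixel = 2)
  expect_equal(distribute_residuals(tp, sp, f1, 2)$values, matrix(0, 4, 4))
})

test_that("distribute_residuals matches the hand-evaluated normalization rule", {
  # one coarse pixel (ratio 2), single class so homogeneity = 1 everywhere;
  # discrepancies 0.04, 0.02, 0.01, 0 give scores 0, 0.5, 0.75, 1 (+ epsilon)
  f1 <- toy_raster(matrix(0.5, 2, 2), pixel = 1)
  cm <- classify_fine(f1, 1, ratio = 2)
  tp <- temporal_prediction(f1, toy_raster(matrix(0), pixel = 2), cm, 2)
  rho <- 0.09
  tp$residual <- toy_raster(matrix(rho), pixel = 2)
  sp <- toy_raster(matrix(0.5 + c(0.04, 0.02, 0.01, 0), 2, 2), pixel = 1)
  alloc <- distribute_residuals(tp, sp, f1, 2)
  score <- pmax(1 - c(0.04, 0.02, 0.01, 0) / 0.04, 1e-6)
  expected <- rho * score * 4 / sum(score)
  expect_equal(as.vector(alloc$values), expected, tolerance = 1e-12)
  expect_equal(mean(alloc$values), rho, tolerance = 1e-12)
})

test_that("neighborhood_refine preserves constant changes and honors n_similar = 1", {
  set.seed(4)
  f1 <- toy_raster(matrix(runif(25), 5, 5), pixel = 1)
  prelim <- toy_raster(f1$values + 0.12, pixel = 1)
  out <- neighborhood_refine(prelim, f1, fusion_params(n_similar = 5), ratio = 2)
  expect_equal(out$values, f1$values + 0.12, tolerance = 1e-12)
  # n_similar = 1: the pixel itself (distance 0) is always the most similar
  prelim2 <- toy_raster(f1$values + matrix(rnorm(25, 0, 0.05), 5, 5), pixel = 1)
  out2 <- neighborhood_refine(prelim2, f1, fusion_params(n_similar = 1), ratio = 2)
  expect_equal(out2$values, prelim2$values, tolerance = 1e-12)
})

test_that("neighborhood_refine matches a brute-force similar-set oracle", {
  set.seed(14)
  f1v <- matrix(runif(25), 5, 5)
  ch <- matrix(rnorm(25, 0, 0.1), 5, 5)
  f1 <- toy_raster(f1v, pixel = 1)
  prelim <- toy_raster(f1v + ch, pixel = 1)
  n_similar <- 3; radius <- 2
  out <- neighborhood_refine(prelim, f1, fusion_params(n_similar = n_similar,
                                                       window_radius = radius))
  oracle <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    cand <- expand.grid(a = max(1, i - radius):min(5, i + radius),
                        b = max(1, j - radius):min(5, j + radius))
    sdist <- abs(f1v[cbind(cand$a, cand$b)] - f1v[i, j])
    gdist <- sqrt((cand$a - i)^2 + (cand$b - j)^2)
    rowmaj <- (cand$a - 1) * 5 + (cand$b - 1)
    ord <- order(sdist, gdist, rowmaj)[seq_len(n_similar)]
    w <- 1 / (1 + gdist[ord])
    oracle[i, j] <- f1v[i, j] + sum(w * ch[cbind(cand$a, cand$b)][ord]) / sum(w)
  }
  expect_equal(out$values, oracle, tolerance = 1e-12)
})

test_that("fsdaf_fuse satisfies identity and uniform-shift equivariance", {
  sc <- fusion_scene(seed = 7)
  f1 <- stack_at(sc$fine, 174)
  c1 <- stack_at(sc$coarse[["8"]], 174)
  fused <- fsdaf_fuse(fusion_inputs(f1, c1, c1, 8))
  expect_lt(max(abs(fused$values - f1$values)), 1e-6)
  c2 <- c1; c2$values <- c2$values + 0.1
  fused2 <- fsdaf_fuse(fusion_inputs(f1, c1, c2, 8))
  expect_lt(max(abs(fused2$values - (f1$values + 0.1))), 1e-6)
})

test_that("fsdaf_fuse is deterministic and beats naive baselines on synthetic truth", {
  sc <- fusion_scene(seed = 19)
  f1 <- stack_at(sc$fine, 206)
  cst <- sc$coarse[["8"]]
  inp <- fusion_inputs(f1, stack_at(cst, 206), stack_at(cst, 230), 8)
  fused <- fsdaf_fuse(inp)
  expect_identical(fused$values, fsdaf_fuse(inp)$values)
  truth <- stack_at(sc$truth_fine, 230)
  rmse_f <- raster_rmse(fused, truth)
  expect_lt(rmse_f, raster_rmse(nn_upsample(stack_at(cst, 230), 8), truth))
  expect_lt(rmse_f, raster_rmse(tps_prediction(stack_at(cst, 230), f1), truth))
})

test_that("fusion respects grid-alignment preconditions", {
  sc <- fusion_scene(seed = 1, doys = c(174L, 230L))
  f1 <- stack_at(sc$fine, 174)
  c8 <- stack_at(sc$coarse[["8"]], 174)
  c16 <- stack_at(sc$coarse[["16"]], 174)
  expect_error(fusion_inputs(f1, c8, c16, 8), "same grid")
  expect_error(fusion_inputs(f1, c16, c16, 8), "coarsened")
})
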