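test_that("rasterize_yield averages points per cell", {
  one <- data.frame(x = 1.2, y = 3.4, yield = 2.5)
  r <- rasterize_yield(one, cell = 0.5)
  expect_equal(sum(is.finite(r$values)), 1)
  expect_equal(r$values[is.finite(r$values)], 2.5)
  two <- data.frame(x = c(1.1, 1.2), y = c(3.3, 3.4), yield = c(3, 5))
  r2 <- rasterize_yield(two, cell = 0.5)
  expect_equal(r2$values[is.finite(r2$values)], 4)
  # points laid on cell centers reproduce exactly
  g <- expand.grid(x = seq(0.25, 1.75, 0.5), y = seq(0.25, 1.75, 0.5))
  g$yield <- seq_len(nrow(g))
  rg <- rasterize_yield(g, cell = 0.5, origin_x = 0, origin_y = 2)
  expect_equal(rg$values[cbind(floor((2 - g$y) / 0.5) + 1,
                               floor(g$x / 0.5) + 1)], g$yield)
  expect_error(rasterize_yield(one[0, ]), "no yield points")
})

test_that("filter_outliers applies the leave-one-out three-sigma rule", {
  # equal values: sd = 0, deviation 0 is not > 0, nothing removed
  eq <- data.frame(x = 1:9, y = 0, yield = rep(4, 9))
  expect_identical(nrow(filter_outliers(eq, window = 9)), 9L)
  # reference neighborhood: candidate 6.0 removed, candidate 4.3 kept
  nb <- c(4.0, 4.2, 3.8, 4.1, 3.9, 4.0, 4.1, 3.9, 4.2)
  for (cand in c(6.0, 4.3)) {
    tr <- data.frame(x = 1:10, y = 0, yield = c(nb[1:5], cand, nb[6:9]))
    kept <- attr(filter_outliers(tr, window = 21), "kept")
    m <- mean(nb); s <- sd(nb)
    expect_identical(kept[6], !(abs(cand - m) > 3 * s))
  }
  expect_error(filter_outliers(eq, window = 2), "window")
})

test_that("filter_outliers removes planted spikes, keeps clean points, idempotent", {
  # bounded (uniform) noise keeps every clean point within ~1.7 local SD, so
  # the planted-outlier property is well-posed: no clean point can reach the
  # 3-SD removal threshold, while planted spikes sit at >= 5 local SD
  # (the phase shift starts/ends the track at zero trend slope, so the
  # asymmetric end windows see no systematic trend offset)
  set.seed(31)
  n <- 400
  base <- 3 + 0.6 * sin(seq(pi / 2, 6 * pi + pi / 2, length.out = n)) +
    runif(n, -0.2, 0.2)
  spikes <- c(40, 170, 290)
  track <- data.frame(x = seq_len(n), y = 0, yield = base)
  # plant spikes of >= 5 local SD
  for (i in spikes) {
    nb <- track$yield[setdiff(max(1, i - 10):min(n, i + 10), i)]
    track$yield[i] <- mean(nb) + 6 * sd(nb)
  }
  clean <- filter_outliers(track, window = 21)
  kept <- attr(clean, "kept")
  expect_false(any(kept[spikes]))
  expect_true(all(kept[-spikes]))
  again <- filter_outliers(clean, window = 21)
  expect_identical(nrow(again), nrow(clean))
  expect_true(all(attr(again, "kept")))
})

test_that("pair_ndvi_yield averages yield cells within each NDVI footprint", {
  ndvi <- toy_raster(matrix(c(0.5, 0.7), 1, 2), pixel = 2)
  # 4 yield cells of 1 m per NDVI pixel
  yv <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 2, 4)
  yld <- grid_raster(yv, 0, 2, 1)
  pr <- pair_ndvi_yield(ndvi, yld)
  expect_equal(pr$ndvi, c(0.5, 0.7))
  expect_equal(pr$yield, c(mean(c(1, 2, 3, 4)), mean(c(10, 20, 30, 40))))
  # uniform yield: every pair identical
  yldu <- grid_raster(matrix(5, 2, 4), 0, 2, 1)
  expect_equal(unique(pair_ndvi_yield(ndvi, yldu)$yield), 5)
  # checkerboard halves average arithmetically
  ych <- grid_raster(matrix(c(2, 6, 6, 2, 2, 6, 6, 2), 2, 4), 0, 2, 1)
  expect_equal(pair_ndvi_yield(ndvi, ych)$yield, c(4, 4))
  expect_error(pair_ndvi_yield(ndvi, toy_raster(matrix(1, 2, 2), pixel = 2)),
               "finer")
})

test_that("fit_yield_model recovers exact and noisy linear relations", {
  x <- seq(0.1, 0.9, length.out = 20)
  exact <- data.frame(ndvi = x, yield = 2 * x + 1)
  f <- fit_yield_model(exact)
  expect_equal(f$a, 2); expect_equal(f$b, 1)
  expect_equal(f$r2, 1); expect_equal(f$rmse, 0)
  expect_error(fit_yield_model(data.frame(ndvi = rep(0.5, 5), yield = 1:5)),
               "constant")
  # parameter recovery under noise
  set.seed(41)
  xr <- runif(500, 0.2, 0.9)
  noisy <- data.frame(ndvi = xr, yield = 2.5 * xr + 0.3 + rnorm(500, 0, 0.1))
  fn <- fit_yield_model(noisy)
  expect_true(fn$a > 2.4 && fn$a < 2.6)
  expect_true(fn$b > 0.25 && fn$b < 0.35)
  # residual orthogonality (normal equations)
  res <- noisy$yield - (fn$a * noisy$ndvi + fn$b)
  expect_lt(abs(sum(res * noisy$ndvi)), 1e-9)
  expect_lt(abs(sum(res)), 1e-9)
})

test_that("r2_adj is 1 for affine agreement, ~0 for independence, scale-free", {
  set.seed(51)
  ref <- runif(100, 0.2, 0.9)
  expect_equal(r2_adj(ref, ref), 1)
  expect_equal(r2_adj(1.7 * ref - 0.3, ref), 1)
  ind <- runif(1000); ref2 <- runif(1000)
  expect_lt(r2_adj(ind, ref2), 0.01)
  # affine invariance in both arguments
  f <- 0.8 * ref + rnorm(100, 0, 0.05)
  expect_equal(r2_adj(f, ref), r2_adj(2 * f + 1, 0.5 * ref - 2))
  expect_error(r2_adj(ref, rep(0.5, 100)), "constant")
  # the literal printed variance ratio is exposed but unbounded
  expect_equal(r2_adj(ref, ref, literal = TRUE), 1)
  expect_gt(r2_adj(0.1 * (ref - mean(ref)) + mean(ref), ref, literal = TRUE), 1)
})

test_that("correlation_by_date peaks where yield is generated and nulls out when shuffled", {
  sc <- fusion_scene(seed = 23, doys = c(174L, 206L, 230L, 254L),
                     yield_noise_sd = 0, noise_sd_fine = 0)
  pl <- sc$plots[[1]]
  yr <- rasterize_yield(sc$yield[sc$yield$plot == "A", ], cell = 0.5)
  corr <- correlation_by_date(list(fine = sc$fine), yr, pl)
  expect_identical(corr$doy, c(174L, 206L, 230L, 254L))
  # yield derives from peak NDVI: correlation at the peak date is near-perfect
  expect_gt(corr$r[corr$doy == 230], 0.99)
  expect_equal(which.max(corr$r), match(230L, corr$doy))
  # shuffled yield kills the correlation
  set.seed(1)
  shuf <- sc$yield[sc$yield$plot == "A", ]
  shuf$yield <- sample(shuf$yield)
  corr2 <- correlation_by_date(list(fine = sc$fine), rasterize_yield(shuf, cell = 0.5), pl)
  expect_true(all(abs(corr2$r) < 0.1))
})

test_that("correlation_by_date matches a direct Pearson oracle on a 3-date toy", {
  set.seed(61)
  sc <- fusion_scene(seed = 61, doys = c(174L, 206L, 230L))
  pl <- sc$plots[[1]]
  yr <- rasterize_yield(sc$yield[sc$yield$plot == "A", ], cell = 0.5)
  corr <- correlation_by_date(sc$fine, yr, pl)
  for (k in seq_len(nrow(corr))) {
    pr <- pair_ndvi_yield(stack_at(sc$fine, corr$doy[k]), yr, pl)
    n <- nrow(pr)
    num <- sum((pr$ndvi - mean(pr$ndvi)) * (pr$yield - mean(pr$yield)))
    den <- sqrt(sum((pr$ndvi - mean(pr$ndvi))^2) * sum((pr$yield - mean(pr$yield))^2))
    expect_equal(corr$r[k], num / den)
    expect_identical(corr$n[k], n)
  }
})
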