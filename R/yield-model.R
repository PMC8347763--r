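#' Rasterize yield-monitor points onto a regular grid
#'
#' Each cell takes the mean of the points falling inside it; cells with no
#' point are nodata. The default 0.5 m cell follows common yield-mapping
#' practice.
#'
#' @param pts data.frame with columns x, y, yield.
#' @param cell cell size, meters (default 0.5).
#' @param origin_x,origin_y optional grid origin (top-left outer corner);
#'   defaults snap the point bounding box outward to whole cells.
#' @return [grid_raster] of mean yield per cell.
#' @export
rasterize_yield <- function(pts, cell = 0.5, origin_x = NULL, origin_y = NULL) {
  if (nrow(pts) == 0L) stop("no yield points to rasterize", call. = FALSE)
  if (is.null(origin_x)) origin_x <- floor(min(pts$x) / cell) * cell
  if (is.null(origin_y)) origin_y <- ceiling(max(pts$y) / cell) * cell
  nc <- max(1L, ceiling((max(pts$x) - origin_x) / cell))
  nr <- max(1L, ceiling((origin_y - min(pts$y)) / cell))
  j <- pmin(pmax(floor((pts$x - origin_x) / cell) + 1L, 1L), nc)
  i <- pmin(pmax(floor((origin_y - pts$y) / cell) + 1L, 1L), nr)
  idx <- (j - 1L) * nr + i
  sums <- tapply(pts$yield, idx, sum)
  counts <- tapply(pts$yield, idx, length)
  m <- matrix(NA_real_, nr, nc)
  m[as.integer(names(sums))] <- as.numeric(sums) / as.numeric(counts)
  grid_raster(m, origin_x, origin_y, cell)
}

#' Moving-window 3-SD outlier filter for yield-monitor tracks
#'
#' Implements the standard yield-monitor cleaning rule: for each point,
#' the mean and standard deviation of the surrounding `window` points
#' along the harvest track are computed *excluding the candidate*
#' (leave-one-out; including it would mask large spikes in small windows),
#' and the point is removed iff its deviation from that mean exceeds
#' 3 standard deviations. A single pass over the original values is made,
#' so removals do not influence one another.
#'
#' @param pts data.frame with columns x, y, yield, ordered along the
#'   harvest track.
#' @param window odd window length (candidate plus neighbors); default 21.
#'   If larger than the record count, all other points are used.
#' @param n_sd removal threshold in standard deviations (default 3).
#' @return filtered data.frame; removed rows are dropped. The logical
#'   attribute `kept` records the per-row decision.
#' @export
filter_outliers <- function(pts, window = 21L, n_sd = 3) {
  n <- nrow(pts)
  if (window < 3L) stop("`window` must be >= 3", call. = FALSE)
  if (n == 0L) return(pts)
  half <- as.integer(window) %/% 2L
  y <- pts$yield
  keep <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    nb <- y[setdiff(lo:hi, i)]
    if (length(nb) < 2L) { keep[i] <- TRUE; next }
    m <- mean(nb); s <- stats::sd(nb)
    keep[i] <- !(abs(y[i] - m) > n_sd * s)
  }
  out <- pts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kept") <- keep
  out
}

#' Pair fine NDVI pixels with mean yield over their footprints
#'
#' For every NDVI pixel whose center lies inside the plot, the 0.5 m (or
#' finer) yield cells falling within the pixel footprint are averaged;
#' pixels with no yield cells are dropped.
#'
#' @param ndvi fine NDVI [grid_raster].
#' @param yld yield [grid_raster] at a finer resolution.
#' @param plot a [plot_polygon], or `NULL` to use the full NDVI extent.
#' @return data.frame with columns row, col, ndvi, yield.
#' @export
pair_ndvi_yield <- function(ndvi, yld, plot = NULL) {
  stopifnot_grid_raster(ndvi); stopifnot_grid_raster(yld)
  if (yld$pixel_size >= ndvi$pixel_size)
    stop("yield raster must be finer than the NDVI raster", call. = FALSE)
  p <- ndvi$pixel_size
  ctr <- center_matrix(ndvi)
  inside <- if (is.null(plot)) rep(TRUE, nrow(ctr))
            else points_in_polygon(plot, ctr[, 1], ctr[, 2])
  nr <- nrow(ndvi$values); nc <- ncol(ndvi$values)
  # NDVI cell index of every finite yield cell center
  yc <- center_matrix(yld)
  yv <- as.vector(yld$values)
  oky <- is.finite(yv)
  iy <- floor((ndvi$origin_y - yc[oky, 2]) / p) + 1L
  jy <- floor((yc[oky, 1] - ndvi$origin_x) / p) + 1L
  inrange <- iy >= 1L & iy <= nr & jy >= 1L & jy <= nc
  idx <- (jy[inrange] - 1L) * nr + iy[inrange]
  vals <- yv[oky][inrange]
  ymean <- tapply(vals, idx, mean)
  cell <- as.integer(names(ymean))
  keep <- inside[cell] & is.finite(as.vector(ndvi$values)[cell])
  cell <- cell[keep]
  if (length(cell) == 0L) stop("no NDVI/yield pairs found", call. = FALSE)
  i <- (cell - 1L) %% nr + 1L
  j <- (cell - 1L) %/% nr + 1L
  out <- data.frame(row = i, col = j,
                    ndvi = as.vector(ndvi$values)[cell],
                    yield = as.numeric(ymean)[keep])
  out <- out[order(out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the linear NDVI-to-yield model
#'
#' Ordinary least squares `yield = a * ndvi + b`. `r2` is the squared
#' Pearson correlation of fitted and observed yields, `rmse` the root
#' mean squared residual.
#'
#' @param pairs data.frame with columns ndvi, yield (>= 3 rows,
#'   non-constant ndvi).
#' @return object of class `yield_model_fit`: a, b, r2, rmse, n.
#' @export
fit_yield_model <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 NDVI/yield pairs", call. = FALSE)
  x <- pairs$ndvi; y <- pairs$yield
  if (stats::sd(x) == 0) stop("degenerate fit: NDVI values are constant", call. = FALSE)
  fit <- stats::lm.fit(cbind(1, x), y)
  b <- fit$coefficients[1]; a <- fit$coefficients[2]
  res <- fit$residuals
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  structure(list(a = unname(a), b = unname(b), r2 = r2,
                 rmse = sqrt(mean(res^2)), n = length(y)),
            class = "yield_model_fit")
}

#' @export
print.yield_model_fit <- function(x, ...) {
  cat(sprintf("<yield_model_fit> yield = %.4f * NDVI + %.4f | R2 = %.4f, RMSE = %.4f, n = %d\n",
              x$a, x$b, x$r2, x$rmse, x$n))
  invisible(x)
}

#' Agreement of fused NDVI with the fine reference
#'
#' The coefficient of determination of the least-squares regression of the
#' fused values on the reference values (equivalently the squared Pearson
#' correlation), in \[0, 1\]; closer to 1 means better fusion. With
#' `literal = TRUE` the raw printed variance ratio
#' `sum((reference - mean(reference))^2) / sum((fused - mean(reference))^2)`
#' is returned instead for comparison; note that ratio is not bounded by 1
#' and is not a goodness-of-fit statistic.
#'
#' @param fused fused NDVI values.
#' @param reference reference (fine) NDVI values, non-constant.
#' @param literal return the literal variance-ratio form instead.
#' @return numeric scalar.
#' @export
r2_adj <- function(fused, reference, literal = FALSE) {
  if (length(fused) != length(reference) || length(fused) < 3L)
    stop("fused and reference must have equal length >= 3", call. = FALSE)
  ok <- is.finite(fused) & is.finite(reference)
  fused <- fused[ok]; reference <- reference[ok]
  if (stats::sd(reference) == 0)
    stop("degenerate: reference values are constant", call. = FALSE)
  if (literal) {
    xbar <- mean(reference)
    return(sum((reference - xbar)^2) / sum((fused - xbar)^2))
  }
  stats::cor(fused, reference)^2
}

#' Per-date correlation between NDVI stacks and yield
#'
#' For each date of each input stack, pairs the stack's NDVI raster with
#' the yield raster over the plot and computes the Pearson correlation.
#' Dates with fewer than 3 pairs are reported as `NA`.
#'
#' @param stacks a [scene_stack] or named list of them.
#' @param yld yield [grid_raster] (finer than the NDVI grids).
#' @param plot a [plot_polygon] or `NULL`.
#' @return data.frame with columns stack, doy, r, n.
#' @export
correlation_by_date <- function(stacks, yld, plot = NULL) {
  if (inherits(stacks, "scene_stack")) stacks <- list(stack = stacks)
  if (is.null(names(stacks))) names(stacks) <- sprintf("stack_%d", seq_along(stacks))
  out <- list()
  for (nm in names(stacks)) {
    st <- stacks[[nm]]
    for (d in st$doys) {
      pr <- tryCatch(pair_ndvi_yield(stack_at(st, d), yld, plot),
                     error = function(e) NULL)
      if (is.null(pr) || nrow(pr) < 3L || stats::sd(pr$ndvi) == 0) {
        out[[length(out) + 1L]] <- data.frame(stack = nm, doy = d,
                                              r = NA_real_, n = if (is.null(pr)) 0L else nrow(pr))
      } else {
        out[[length(out) + 1L]] <- data.frame(stack = nm, doy = d,
                                              r = stats::cor(pr$ndvi, pr$yield),
                                              n = nrow(pr))
      }
    }
  }
  do.call(rbind, out)
}
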