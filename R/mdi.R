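#' Overlap of a plot with the coarse pixels it touches
#'
#' Computes, for every coarse pixel whose footprint the plot covers by at
#' least `min_coverage` (default 1%), the exact polygon-square
#' intersection area `s_p`, the pure-pixel area `s_w`, and the coverage
#' `s_p / s_w`. Pixels are numbered left to right, top to bottom
#' (row-major), and returned in that order.
#'
#' @param plot a [plot_polygon].
#' @param coarse a coarse [grid_raster].
#' @param min_coverage inclusion threshold on `s_p / s_w`.
#' @return data.frame with columns pixel_id, row, col, s_p, s_w, coverage.
#'   Zero rows (with a warning) if no pixel reaches the threshold.
#' @export
pixel_overlaps <- function(plot, coarse, min_coverage = 0.01) {
  stopifnot_grid_raster(coarse)
  nr <- nrow(coarse$values); nc <- ncol(coarse$values)
  p <- coarse$pixel_size
  bb <- polygon_bbox(plot)
  if (bb["xmax"] <= coarse$origin_x || bb["xmin"] >= coarse$origin_x + nc * p ||
      bb["ymax"] <= coarse$origin_y - nr * p || bb["ymin"] >= coarse$origin_y)
    stop("plot does not intersect the raster extent", call. = FALSE)
  c0 <- max(1L, floor((bb["xmin"] - coarse$origin_x) / p) + 1L)
  c1 <- min(nc, ceiling((bb["xmax"] - coarse$origin_x) / p))
  r0 <- max(1L, floor((coarse$origin_y - bb["ymax"]) / p) + 1L)
  r1 <- min(nr, ceiling((coarse$origin_y - bb["ymin"]) / p))
  s_w <- p * p
  rows <- integer(0); cols <- integer(0); sp <- numeric(0)
  for (i in r0:r1) {
    ymax <- coarse$origin_y - (i - 1) * p
    ymin <- ymax - p
    for (j in c0:c1) {
      xmin <- coarse$origin_x + (j - 1) * p
      a <- polygon_rect_intersection_area(plot, xmin, xmin + p, ymin, ymax)
      if (a / s_w >= min_coverage) {
        rows <- c(rows, i); cols <- c(cols, j); sp <- c(sp, min(a, s_w))
      }
    }
  }
  if (length(rows) == 0L)
    warning(sprintf("plot '%s': no coarse pixel reaches %.0f%% coverage",
                    plot$name, 100 * min_coverage))
  data.frame(pixel_id = seq_along(rows), row = rows, col = cols,
             s_p = sp, s_w = rep(s_w, length(rows)), coverage = sp / s_w)
}

#' Mixed pixel area ratio of one coarse pixel
#'
#' `m_par = (s_p / s_w) * (s_p / s_y)`: the product of the pixel's plot
#' coverage and the share of the plot falling in the pixel. For a plot
#' that exactly tiles pure pixels the values sum to 1 over its pixels.
#'
#' @param s_p intersection area of the pixel with the plot (m^2).
#' @param s_w area of one pure coarse pixel (m^2).
#' @param s_y area of the plot (m^2).
#' @return dimensionless ratio in \[0, 1\].
#' @export
m_par <- function(s_p, s_w, s_y) {
  if (any(s_w <= 0) || any(s_y <= 0))
    stop("s_w and s_y must be positive", call. = FALSE)
  if (any(s_p < 0) || any(s_p > pmin(s_w, s_y) + 1e-9 * pmin(s_w, s_y)))
    stop("s_p must lie in [0, min(s_w, s_y)]", call. = FALSE)
  (s_p / s_w) * (s_p / s_y)
}

#' Relative coarse/fine NDVI discrepancy of one pixel
#'
#' `|ndvi_m - ndvi_l| / max(ndvi_l, ndvi_m)`. When neither value is
#' positive (a non-vegetated degenerate case) the ratio is defined as 0
#' with a warning.
#'
#' @param ndvi_m coarse-pixel NDVI.
#' @param ndvi_l fine NDVI summarized over the pixel-plot footprint.
#' @return dimensionless value; in \[0, 1\] for nonnegative inputs.
#' @export
ndvi_pro <- function(ndvi_m, ndvi_l) {
  mx <- pmax(ndvi_m, ndvi_l)
  out <- abs(ndvi_m - ndvi_l) / mx
  bad <- !is.na(mx) & mx <= 0
  if (any(bad)) {
    warning("ndvi_pro: max(ndvi_l, ndvi_m) <= 0; defining the ratio as 0")
    out[bad] <- 0
  }
  out
}

#' Mixed Degree Index of a plot at one coarse resolution
#'
#' Sums `m_par * ndvi_pro` over the coarse pixels overlapping the plot by
#' at least 1% coverage. `ndvi_l` for a pixel is the mean of fine NDVI
#' over the pixel-plot intersection footprint (fine pixels whose centers
#' fall inside both), contrasting the coarse signal against the plot's own
#' fine signal rather than against the whole (possibly mixed) pixel. An
#' index of 0 means every included pixel agrees with the plot signal
#' (pure/consistent); values grow toward 1 with mixing.
#'
#' @param plot a [plot_polygon].
#' @param coarse_ndvi coarse NDVI [grid_raster].
#' @param fine_ndvi fine NDVI [grid_raster] on the aligned fine grid.
#' @return object of class `mdi_result`: `plot_name`, `resolution`,
#'   `components` (per-pixel data.frame), `mdi` (NA if no pixel included).
#' @export
compute_mdi <- function(plot, coarse_ndvi, fine_ndvi) {
  stopifnot_grid_raster(coarse_ndvi); stopifnot_grid_raster(fine_ndvi)
  ov <- pixel_overlaps(plot, coarse_ndvi)
  s_y <- polygon_area(plot)
  if (nrow(ov) == 0L) {
    return(structure(list(plot_name = plot$name,
                          resolution = coarse_ndvi$pixel_size,
                          components = ov, mdi = NA_real_),
                     class = "mdi_result"))
  }
  p <- coarse_ndvi$pixel_size
  fc <- center_matrix(fine_ndvi)
  fin <- points_in_polygon(plot, fc[, 1], fc[, 2])
  fvals <- as.vector(fine_ndvi$values)
  ndvi_m <- ndvi_l <- numeric(nrow(ov))
  for (k in seq_len(nrow(ov))) {
    i <- ov$row[k]; j <- ov$col[k]
    ndvi_m[k] <- coarse_ndvi$values[i, j]
    xmin <- coarse_ndvi$origin_x + (j - 1) * p
    ymax <- coarse_ndvi$origin_y - (i - 1) * p
    sel <- fin & fc[, 1] >= xmin & fc[, 1] <= xmin + p &
      fc[, 2] <= ymax & fc[, 2] >= ymax - p
    vals <- fvals[sel]
    ndvi_l[k] <- if (any(is.finite(vals))) mean(vals[is.finite(vals)]) else NA_real_
  }
  comp <- ov
  comp$m_par <- m_par(ov$s_p, ov$s_w, s_y)
  comp$ndvi_m <- ndvi_m
  comp$ndvi_l <- ndvi_l
  comp$ndvi_pro <- ndvi_pro(ndvi_m, ndvi_l)
  structure(list(plot_name = plot$name, resolution = coarse_ndvi$pixel_size,
                 components = comp,
                 mdi = sum(comp$m_par * comp$ndvi_pro)),
            class = "mdi_result")
}

#' @export
print.mdi_result <- function(x, ...) {
  cat(sprintf("<mdi_result> plot '%s' at %g m: MDI = %s over %d pixel(s)\n",
              x$plot_name, x$resolution,
              if (is.na(x$mdi)) "NA" else sprintf("%.4f", x$mdi),
              nrow(x$components)))
  invisible(x)
}

#' Seasonal MDI curve of a plot
#'
#' Computes the MDI at every shared observation date of a coarse and a
#' fine NDVI stack.
#'
#' @param plot a [plot_polygon].
#' @param coarse_stack,fine_stack [scene_stack] objects.
#' @return data.frame with columns doy, mdi.
#' @export
mdi_series <- function(plot, coarse_stack, fine_stack) {
  doys <- intersect(coarse_stack$doys, fine_stack$doys)
  vals <- vapply(doys, function(d) {
    compute_mdi(plot, stack_at(coarse_stack, d), stack_at(fine_stack, d))$mdi
  }, numeric(1))
  data.frame(doy = doys, mdi = vals)
}
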