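#' Construct a grid raster
#'
#' A `grid_raster` is a rectangular 2-D array of values on a square-pixel
#' planar grid. The origin is the outer corner of the pixel at row 1,
#' column 1 (the north-west corner under the usual north-up convention:
#' x increases with column, y decreases with row). Nodata cells are `NA`.
#'
#' @param values numeric matrix (row-major image; row 1 is the northern edge).
#' @param origin_x,origin_y planar coordinates of the outer corner of the
#'   top-left pixel, in meters.
#' @param pixel_size edge length of a (square) pixel, meters. Must be > 0.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, origin_x = 0, origin_y = nrow(values) * pixel_size,
                        pixel_size = 30) {
  values <- as.matrix(values)
  if (!is.numeric(values) || length(values) == 0L)
    stop("`values` must be a non-empty numeric matrix", call. = FALSE)
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  storage.mode(values) <- "double"
  structure(
    list(values = values, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), pixel_size = as.numeric(pixel_size)),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_raster> %d x %d pixels of %g m, origin (%g, %g)\n",
              nrow(v), ncol(v), x$pixel_size, x$origin_x, x$origin_y))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%.4g, %.4g], %d nodata\n",
                min(fin), max(fin), sum(is.na(v))))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

is_grid_raster <- function(x) inherits(x, "grid_raster")

stopifnot_grid_raster <- function(x, arg = deparse(substitute(x))) {
  if (!is_grid_raster(x)) stop(sprintf("`%s` must be a grid_raster", arg), call. = FALSE)
  invisible(x)
}

#' Do two rasters share the same grid?
#' @param a,b grid_raster objects.
#' @param tol coordinate tolerance in meters.
#' @return logical scalar.
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    abs(a$pixel_size - b$pixel_size) < tol
}

#' Planar coordinates of pixel centers
#'
#' @param r a grid_raster.
#' @return list with `x` (length ncol) and `y` (length nrow) center
#'   coordinates, and `xy` an n-by-2 matrix in row-major pixel order.
#' @export
pixel_centers <- function(r) {
  stopifnot_grid_raster(r)
  nr <- nrow(r$values); nc <- ncol(r$values); p <- r$pixel_size
  x <- r$origin_x + (seq_len(nc) - 0.5) * p
  y <- r$origin_y - (seq_len(nr) - 0.5) * p
  list(x = x, y = y,
       xy = cbind(x = rep(x, times = nr), y = rep(y, each = nc)))
}

# row-major (row 1 first) center matrix; cheaper direct form used internally
center_matrix <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values); p <- r$pixel_size
  x <- r$origin_x + (seq_len(nc) - 0.5) * p
  y <- r$origin_y - (seq_len(nr) - 0.5) * p
  cbind(x = rep(x, each = nr), y = rep(y, times = nc)) # column-major like matrix storage
}

#' Compute NDVI from red and near-infrared reflectance rasters
#'
#' NDVI = (NIR - Red) / (NIR + Red). Pixels where the denominator is zero
#' become nodata (`NA`): a 0/0 ratio carries no vegetation information.
#'
#' @param red,nir grid_raster objects of reflectance in \[0, 1\], same grid.
#' @return grid_raster of NDVI in \[-1, 1\].
#' @export
compute_ndvi <- function(red, nir) {
  stopifnot_grid_raster(red); stopifnot_grid_raster(nir)
  if (!same_grid(red, nir)) stop("red and nir rasters are not on the same grid", call. = FALSE)
  den <- nir$values + red$values
  out <- (nir$values - red$values) / den
  out[!is.na(den) & den == 0] <- NA_real_
  grid_raster(out, red$origin_x, red$origin_y, red$pixel_size)
}

#' Aggregate a fine raster to a coarse grid by block means
#'
#' Each coarse cell is the mean of its `ratio` x `ratio` block of fine
#' pixels, ignoring nodata. This is the forward model used throughout for a
#' coarse sensor footprint (unweighted mean; no point-spread function).
#'
#' @param fine grid_raster whose dimensions are divisible by `ratio`.
#' @param ratio positive integer edge ratio (coarse / fine pixel size).
#' @return grid_raster on the coarse grid (same origin, pixel_size * ratio).
#' @export
block_aggregate <- function(fine, ratio) {
  stopifnot_grid_raster(fine)
  ratio <- check_ratio(ratio)
  v <- fine$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% ratio != 0L || nc %% ratio != 0L)
    stop(sprintf("raster dimensions %dx%d not divisible by ratio %d", nr, nc, ratio),
         call. = FALSE)
  cr <- nr %/% ratio; cc <- nc %/% ratio
  dim(v) <- c(ratio, cr, ratio, cc)
  out <- apply(v, c(2, 4), function(b) {
    b <- b[!is.na(b)]
    if (length(b)) mean(b) else NA_real_
  })
  grid_raster(out, fine$origin_x, fine$origin_y, fine$pixel_size * ratio)
}

#' Nearest-neighbor upsample of a coarse raster onto its fine grid
#'
#' Replicates every coarse cell into a `ratio` x `ratio` block of fine
#' pixels. Used as a naive fusion baseline.
#'
#' @param coarse grid_raster.
#' @param ratio positive integer.
#' @return grid_raster with pixel_size / ratio.
#' @export
nn_upsample <- function(coarse, ratio) {
  stopifnot_grid_raster(coarse)
  ratio <- check_ratio(ratio)
  v <- coarse$values
  out <- v[rep(seq_len(nrow(v)), each = ratio), rep(seq_len(ncol(v)), each = ratio),
           drop = FALSE]
  grid_raster(out, coarse$origin_x, coarse$origin_y, coarse$pixel_size / ratio)
}

check_ratio <- function(ratio) {
  if (length(ratio) != 1L || !is.finite(ratio) || ratio < 1 || ratio != round(ratio))
    stop("`ratio` must be a single positive integer", call. = FALSE)
  as.integer(ratio)
}

#' Resample a coarse raster onto the integer-aligned grid of a fine raster
#'
#' The target grid is the fine grid coarsened by `ratio` (same origin,
#' pixel size fine * ratio). Each target cell takes the value of the input
#' coarse cell whose center is nearest to the target cell center
#' (nearest-neighbor resampling). This is the sanctioned path for bringing
#' off-grid coarse imagery into the exact integer-proportion alignment the
#' fusion and MDI stages require.
#'
#' @param coarse grid_raster to resample (any aligned or shifted grid).
#' @param fine grid_raster defining the fine grid and extent.
#' @param ratio positive integer; fine dims must be divisible by it.
#' @return grid_raster on the target coarse grid.
#' @export
resample_to_integer_grid <- function(coarse, fine, ratio) {
  stopifnot_grid_raster(coarse); stopifnot_grid_raster(fine)
  ratio <- check_ratio(ratio)
  nrf <- nrow(fine$values); ncf <- ncol(fine$values)
  if (nrf %% ratio != 0L || ncf %% ratio != 0L)
    stop("fine raster dimensions not divisible by ratio", call. = FALSE)
  # extent coverage check
  fx0 <- fine$origin_x; fx1 <- fine$origin_x + ncf * fine$pixel_size
  fy1 <- fine$origin_y; fy0 <- fine$origin_y - nrf * fine$pixel_size
  cx0 <- coarse$origin_x; cx1 <- coarse$origin_x + ncol(coarse$values) * coarse$pixel_size
  cy1 <- coarse$origin_y; cy0 <- coarse$origin_y - nrow(coarse$values) * coarse$pixel_size
  tol <- 1e-9 * max(1, abs(fx1), abs(fy1))
  if (cx0 > fx0 + tol || cx1 < fx1 - tol || cy0 > fy0 + tol || cy1 < fy1 - tol)
    stop("coarse raster extent does not cover the fine extent", call. = FALSE)
  tp <- fine$pixel_size * ratio
  nrt <- nrf %/% ratio; nct <- ncf %/% ratio
  tx <- fx0 + (seq_len(nct) - 0.5) * tp
  ty <- fy1 - (seq_len(nrt) - 0.5) * tp
  # nearest input cell index per target center
  ci <- pmin(pmax(round((cy1 - ty) / coarse$pixel_size + 0.5), 1), nrow(coarse$values))
  cj <- pmin(pmax(round((tx - cx0) / coarse$pixel_size + 0.5), 1), ncol(coarse$values))
  out <- coarse$values[ci, cj, drop = FALSE]
  grid_raster(out, fx0, fy1, tp)
}

#' Clip raster values into a range
#' @param r grid_raster.
#' @param lo,hi bounds.
#' @return grid_raster with values clamped to \[lo, hi\].
#' @export
clip_values <- function(r, lo = -1, hi = 1) {
  stopifnot_grid_raster(r)
  r$values <- pmin(pmax(r$values, lo), hi)
  r
}

#' Root-mean-square difference between two rasters on the same grid
#' @param a,b grid_raster objects.
#' @return RMSE over pixels finite in both.
#' @export
raster_rmse <- function(a, b) {
  if (!same_grid(a, b)) stop("rasters not on the same grid", call. = FALSE)
  d <- a$values - b$values
  sqrt(mean(d[is.finite(d)]^2))
}
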