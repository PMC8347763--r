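#' Fit a thin-plate spline to scattered point data
#'
#' Classic 2-D thin-plate spline with radial kernel U(r) = r^2 log(r)
#' (U(0) = 0) plus an affine part, solved from the standard augmented
#' system. With `smoothing = 0` the surface interpolates the control
#' values exactly; `smoothing > 0` adds lambda * I to the kernel block and
#' relaxes the fit. Coordinates are rescaled internally by the median
#' inter-point spacing for numerical conditioning. Constants and affine
#' fields are reproduced exactly by the affine part.
#'
#' @param x,y control-point coordinates.
#' @param v control values.
#' @param smoothing non-negative smoothing parameter lambda.
#' @return object of class `tps_fit`.
#' @export
tps_fit <- function(x, y, v, smoothing = 0) {
  keep <- is.finite(x) & is.finite(y) & is.finite(v)
  x <- x[keep]; y <- y[keep]; v <- v[keep]
  n <- length(x)
  if (n < 3L) stop("thin-plate spline needs at least 3 control points", call. = FALSE)
  if (smoothing < 0) stop("`smoothing` must be >= 0", call. = FALSE)
  # collinearity check via rank of [1 x y]
  P <- cbind(1, x, y)
  if (qr(P)$rank < 3L)
    stop("thin-plate spline control points are collinear", call. = FALSE)
  scale <- stats::median(stats::dist(cbind(x, y)[seq_len(min(n, 64L)), , drop = FALSE]))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  xs <- x / scale; ys <- y / scale
  K <- tps_kernel(xs, ys, xs, ys)
  Ps <- cbind(1, xs, ys)
  A <- rbind(cbind(K + diag(smoothing, n), Ps),
             cbind(t(Ps), matrix(0, 3, 3)))
  rhs <- c(v, 0, 0, 0)
  sol <- solve(A, rhs)
  structure(list(w = sol[seq_len(n)], a = sol[n + 1:3],
                 xs = xs, ys = ys, scale = scale),
            class = "tps_fit")
}

tps_kernel <- function(x1, y1, x2, y2) {
  d2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  out <- 0.5 * d2 * log(pmax(d2, .Machine$double.xmin))
  out[d2 == 0] <- 0
  out
}

#' Evaluate a fitted thin-plate spline
#' @param fit a [tps_fit].
#' @param x,y evaluation coordinates (vectors of equal length).
#' @return numeric vector of surface values.
#' @export
tps_eval <- function(fit, x, y) {
  xs <- x / fit$scale; ys <- y / fit$scale
  K <- tps_kernel(xs, ys, fit$xs, fit$ys)
  drop(K %*% fit$w) + fit$a[1] + fit$a[2] * xs + fit$a[3] * ys
}

#' Thin-plate-spline prediction of a fine raster from a coarse raster
#'
#' Fits a TPS to the coarse pixel-center values and evaluates it at every
#' fine pixel center (the spatial-prediction step of the fusion
#' algorithm).
#'
#' @param coarse a [grid_raster] supplying control points.
#' @param fine_grid a [grid_raster] defining the evaluation grid (values
#'   ignored).
#' @param smoothing non-negative smoothing parameter.
#' @return [grid_raster] on the fine grid.
#' @export
tps_prediction <- function(coarse, fine_grid, smoothing = 0) {
  stopifnot_grid_raster(coarse); stopifnot_grid_raster(fine_grid)
  cc <- center_matrix(coarse)
  v <- as.vector(coarse$values)
  fit <- tps_fit(cc[, 1], cc[, 2], v, smoothing)
  fc <- center_matrix(fine_grid)
  out <- tps_eval(fit, fc[, 1], fc[, 2])
  grid_raster(matrix(out, nrow = nrow(fine_grid$values)),
              fine_grid$origin_x, fine_grid$origin_y, fine_grid$pixel_size)
}
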