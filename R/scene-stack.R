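#' Construct a date-indexed stack of rasters on one grid
#'
#' All rasters must share origin and pixel size; DOY keys must be strictly
#' increasing integers in \[1, 366\]. `ratio` records the integer edge
#' ratio of this stack's pixels to the reference fine pixels (1 for a fine
#' stack, 8 for 240 m / 30 m, 16 for 480 m / 30 m).
#'
#' @param rasters named list of [grid_raster]; names are DOYs.
#' @param ratio positive integer coarse/fine edge ratio metadata.
#' @return object of class `scene_stack`.
#' @export
scene_stack <- function(rasters, ratio = 1L) {
  ratio <- check_ratio(ratio)
  doys <- as.integer(names(rasters))
  if (length(rasters) == 0L) stop("empty stack", call. = FALSE)
  if (anyNA(doys)) stop("stack raster names must be integer DOYs", call. = FALSE)
  if (any(doys < 1L | doys > 366L)) stop("DOYs must lie in [1, 366]", call. = FALSE)
  if (is.unsorted(doys, strictly = TRUE)) stop("DOYs must be strictly increasing",
                                               call. = FALSE)
  for (r in rasters) stopifnot_grid_raster(r)
  r1 <- rasters[[1]]
  for (r in rasters[-1])
    if (!same_grid(r, r1)) stop("all stack rasters must share one grid", call. = FALSE)
  structure(list(rasters = rasters, doys = doys, ratio = ratio),
            class = "scene_stack")
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack> %d dates (DOY %d..%d), ratio %d, %d x %d pixels\n",
              length(x$doys), min(x$doys), max(x$doys), x$ratio,
              nrow(x$rasters[[1]]$values), ncol(x$rasters[[1]]$values)))
  invisible(x)
}

#' Fetch the raster at a given DOY
#' @param stack a [scene_stack].
#' @param doy integer day of year; must be an observed date.
#' @return [grid_raster].
#' @export
stack_at <- function(stack, doy) {
  i <- match(as.integer(doy), stack$doys)
  if (is.na(i)) stop(sprintf("DOY %d not in stack (have: %s)", doy,
                             paste(stack$doys, collapse = ", ")), call. = FALSE)
  stack$rasters[[i]]
}
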