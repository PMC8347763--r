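#' Fusion tuning parameters
#'
#' Knobs for the six-step fusion. Defaults follow common practice in the
#' spatiotemporal-fusion literature: 4 land-cover classes, 20 similar
#' neighbors, a search window of one coarse footprint, exact (unsmoothed)
#' thin-plate-spline interpolation.
#'
#' @param n_classes number of land-cover classes for the unmixing step.
#' @param n_similar number of spectrally similar neighbors in the
#'   refinement step.
#' @param window_radius search-window half-width in fine pixels; `NULL`
#'   means "use the coarse/fine ratio".
#' @param tps_smoothing non-negative TPS smoothing parameter.
#' @param seed integer seed for the classification initialization.
#' @return object of class `fusion_params`.
#' @export
fusion_params <- function(n_classes = 4L, n_similar = 20L, window_radius = NULL,
                          tps_smoothing = 0, seed = 0L) {
  stopifnot(n_classes >= 1L, n_similar >= 1L, tps_smoothing >= 0)
  if (!is.null(window_radius)) stopifnot(window_radius >= 1L)
  structure(list(n_classes = as.integer(n_classes),
                 n_similar = as.integer(n_similar),
                 window_radius = if (is.null(window_radius)) NULL else as.integer(window_radius),
                 tps_smoothing = tps_smoothing, seed = as.integer(seed)),
            class = "fusion_params")
}

#' Bundle the inputs of one fusion run
#'
#' @param fine_t1 fine-resolution NDVI raster at the reference date.
#' @param coarse_t1,coarse_t2 coarse NDVI rasters at the reference and
#'   target dates, on the fine grid coarsened by `ratio`.
#' @param ratio positive integer coarse/fine pixel edge ratio.
#' @param params a [fusion_params].
#' @return object of class `fusion_inputs`.
#' @export
fusion_inputs <- function(fine_t1, coarse_t1, coarse_t2, ratio,
                          params = fusion_params()) {
  stopifnot_grid_raster(fine_t1)
  stopifnot_grid_raster(coarse_t1); stopifnot_grid_raster(coarse_t2)
  ratio <- check_ratio(ratio)
  if (!same_grid(coarse_t1, coarse_t2))
    stop("coarse rasters are not on the same grid", call. = FALSE)
  nrf <- nrow(fine_t1$values); ncf <- ncol(fine_t1$values)
  if (nrf %% ratio != 0L || ncf %% ratio != 0L ||
      nrow(coarse_t1$values) != nrf %/% ratio ||
      ncol(coarse_t1$values) != ncf %/% ratio ||
      abs(coarse_t1$origin_x - fine_t1$origin_x) > 1e-6 ||
      abs(coarse_t1$origin_y - fine_t1$origin_y) > 1e-6 ||
      abs(coarse_t1$pixel_size - fine_t1$pixel_size * ratio) > 1e-9)
    stop("coarse grid is not the fine grid coarsened by `ratio`", call. = FALSE)
  structure(list(fine_t1 = fine_t1, coarse_t1 = coarse_t1, coarse_t2 = coarse_t2,
                 ratio = ratio, params = params),
            class = "fusion_inputs")
}

#' Crop a fine raster to a region, snapped outward to whole coarse pixels
#'
#' Step 1 of the fusion pipeline: delineate the study area on the fine
#' reference image. The crop covers the region's bounding box expanded to
#' whole coarse pixels; cells outside the region stay in the raster (they
#' provide fusion context) and are flagged in the returned `inside` mask.
#'
#' @param fine_t1 fine [grid_raster].
#' @param region a [plot_polygon] or `NULL` for the full extent.
#' @param ratio positive integer coarse/fine ratio to snap to.
#' @return list with `raster` (cropped [grid_raster]) and `inside`
#'   (logical matrix flagging cells whose centers fall in the region).
#' @export
delineate <- function(fine_t1, region = NULL, ratio = 1L) {
  stopifnot_grid_raster(fine_t1)
  ratio <- check_ratio(ratio)
  nr <- nrow(fine_t1$values); nc <- ncol(fine_t1$values)
  if (is.null(region)) {
    return(list(raster = fine_t1, inside = matrix(TRUE, nr, nc)))
  }
  bb <- polygon_bbox(region)
  p <- fine_t1$pixel_size
  # fine index ranges covered by the bbox
  c0 <- floor((bb["xmin"] - fine_t1$origin_x) / p) + 1
  c1 <- ceiling((bb["xmax"] - fine_t1$origin_x) / p)
  r0 <- floor((fine_t1$origin_y - bb["ymax"]) / p) + 1
  r1 <- ceiling((fine_t1$origin_y - bb["ymin"]) / p)
  if (c1 < 1 || c0 > nc || r1 < 1 || r0 > nr)
    stop("region does not intersect the raster extent", call. = FALSE)
  c0 <- max(c0, 1); r0 <- max(r0, 1); c1 <- min(c1, nc); r1 <- min(r1, nr)
  # snap outward to whole coarse pixels
  r0 <- (ceiling(r0 / ratio) - 1L) * ratio + 1L
  c0 <- (ceiling(c0 / ratio) - 1L) * ratio + 1L
  r1 <- ceiling(r1 / ratio) * ratio
  c1 <- ceiling(c1 / ratio) * ratio
  r1 <- min(r1, nr); c1 <- min(c1, nc)
  vals <- fine_t1$values[r0:r1, c0:c1, drop = FALSE]
  out <- grid_raster(vals,
                     fine_t1$origin_x + (c0 - 1) * p,
                     fine_t1$origin_y - (r0 - 1) * p, p)
  ctr <- center_matrix(out)
  inside <- matrix(points_in_polygon(region, ctr[, 1], ctr[, 2]),
                   nrow = nrow(vals))
  list(raster = out, inside = inside)
}

#' Classify the fine reference image into land-cover classes
#'
#' One-dimensional k-means on the fine NDVI values (the unmixing
#' classification of the fusion algorithm), deterministic for a fixed
#' seed. Classes are relabeled in order of increasing cluster center.
#' Per-coarse-pixel class fractions are obtained by counting fine labels
#' within each coarse block.
#'
#' @param fine_t1 fine [grid_raster].
#' @param n_classes number of classes; must not exceed the number of
#'   distinct finite values.
#' @param seed integer seed.
#' @param ratio coarse/fine ratio used for the fraction table.
#' @return object of class `class_map`: `labels` (integer matrix, 1-based,
#'   `NA` for nodata), `fractions` (coarse-cell x class matrix, rows in
#'   column-major coarse order, each row summing to 1), `centers`.
#' @export
classify_fine <- function(fine_t1, n_classes, seed = 0L, ratio = 1L) {
  stopifnot_grid_raster(fine_t1)
  ratio <- check_ratio(ratio)
  v <- as.vector(fine_t1$values)
  ok <- is.finite(v)
  ndistinct <- length(unique(v[ok]))
  if (n_classes > ndistinct)
    stop(sprintf("degenerate classes: n_classes = %d exceeds %d distinct values",
                 n_classes, ndistinct), call. = FALSE)
  if (n_classes > sum(ok))
    stop("n_classes exceeds the number of valid pixels", call. = FALSE)
  labels <- rep(NA_integer_, length(v))
  if (n_classes == 1L) {
    labels[ok] <- 1L
    centers <- mean(v[ok])
  } else {
    km <- local_seed(seed, stats::kmeans(v[ok], centers = n_classes,
                                         nstart = 10L, iter.max = 100L))
    ord <- order(km$centers[, 1])
    relabel <- integer(n_classes); relabel[ord] <- seq_len(n_classes)
    labels[ok] <- relabel[km$cluster]
    centers <- sort(km$centers[, 1])
  }
  lab_mat <- matrix(labels, nrow = nrow(fine_t1$values))
  fractions <- class_fractions(lab_mat, n_classes, ratio)
  structure(list(labels = lab_mat, fractions = fractions, centers = centers,
                 n_classes = as.integer(n_classes), ratio = ratio),
            class = "class_map")
}

# evaluate expr under a local RNG state
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# per-coarse-cell class fractions; rows in column-major coarse order
class_fractions <- function(lab_mat, n_classes, ratio) {
  nr <- nrow(lab_mat); nc <- ncol(lab_mat)
  crows <- nr %/% ratio; ccols <- nc %/% ratio
  block_i <- (seq_len(nr) - 1L) %/% ratio + 1L
  block_j <- (seq_len(nc) - 1L) %/% ratio + 1L
  cell <- matrix(block_i, nr, nc) + (matrix(block_j, nr, nc, byrow = TRUE) - 1L) * crows
  frac <- matrix(0, crows * ccols, n_classes)
  for (k in seq_len(n_classes)) {
    cnt <- tabulate(cell[!is.na(lab_mat) & lab_mat == k], nbins = crows * ccols)
    frac[, k] <- cnt
  }
  tot <- rowSums(frac)
  tot[tot == 0] <- 1
  frac / tot
}

#' Coarse-resolution temporal change between two dates
#' @param coarse_t1,coarse_t2 [grid_raster] objects on one grid.
#' @return [grid_raster] of `coarse_t2 - coarse_t1`.
#' @export
coarse_change <- function(coarse_t1, coarse_t2) {
  stopifnot_grid_raster(coarse_t1); stopifnot_grid_raster(coarse_t2)
  if (!same_grid(coarse_t1, coarse_t2))
    stop("coarse rasters are not on the same grid", call. = FALSE)
  grid_raster(coarse_t2$values - coarse_t1$values,
              coarse_t1$origin_x, coarse_t1$origin_y, coarse_t1$pixel_size)
}

#' Temporal prediction of the fine image at the target date
#'
#' Solves per-class NDVI changes from the linear unmixing system
#' (class fractions) x (per-class change) ~ (coarse change) by ordinary
#' least squares (ridge fallback with lambda = 1e-6 and a warning if the
#' fraction matrix is rank deficient), adds each pixel's class change to
#' the fine reference, and records the residual left at every coarse
#' pixel: the observed coarse change minus the change implied by the
#' temporal prediction,
#' `residual = delta_c - block_aggregate(tp_fine - fine_t1, ratio)`.
#' On scenes where the coarse image is the exact block mean of the fine
#' image this equals `coarse_t2 - block_aggregate(tp_fine, ratio)`; unlike
#' that form it leaves a zero residual whenever the coarse scene does not
#' change, so a no-change fusion returns the reference image exactly even
#' when the two sensors disagree radiometrically.
#'
#' @param fine_t1 fine [grid_raster] at the reference date.
#' @param delta_c coarse [grid_raster] of temporal change.
#' @param cmap a `class_map` from [classify_fine()].
#' @param ratio coarse/fine ratio.
#' @return object of class `temporal_prediction` with `tp_fine`,
#'   `residual`, `delta_class` and the class map.
#' @export
temporal_prediction <- function(fine_t1, delta_c, cmap, ratio) {
  stopifnot_grid_raster(fine_t1); stopifnot_grid_raster(delta_c)
  ratio <- check_ratio(ratio)
  F_mat <- cmap$fractions
  dc <- as.vector(delta_c$values)
  ok <- is.finite(dc) & rowSums(F_mat) > 0
  Fo <- F_mat[ok, , drop = FALSE]
  qrF <- qr(Fo)
  if (qrF$rank < ncol(Fo)) {
    warning("rank-deficient class-fraction system; falling back to ridge (lambda = 1e-6)")
    delta_class <- solve(crossprod(Fo) + diag(1e-6, ncol(Fo)), crossprod(Fo, dc[ok]))
    delta_class <- drop(delta_class)
  } else {
    delta_class <- qr.coef(qrF, dc[ok])
  }
  tp_vals <- fine_t1$values + matrix(delta_class[cmap$labels], nrow = nrow(fine_t1$values))
  tp_fine <- grid_raster(tp_vals, fine_t1$origin_x, fine_t1$origin_y, fine_t1$pixel_size)
  implied <- block_aggregate(grid_raster(tp_vals - fine_t1$values, fine_t1$origin_x,
                                         fine_t1$origin_y, fine_t1$pixel_size), ratio)
  residual <- grid_raster(delta_c$values - implied$values,
                          delta_c$origin_x, delta_c$origin_y, delta_c$pixel_size)
  structure(list(tp_fine = tp_fine, residual = residual,
                 delta_class = delta_class, cmap = cmap),
            class = "temporal_prediction")
}

block_apply_mat <- function(m, ratio, fun) {
  nr <- nrow(m); nc <- ncol(m)
  dim(m) <- c(ratio, nr %/% ratio, ratio, nc %/% ratio)
  apply(m, c(2, 4), fun)
}

block_expand_mat <- function(m, ratio) {
  m[rep(seq_len(nrow(m)), each = ratio), rep(seq_len(ncol(m)), each = ratio),
    drop = FALSE]
}

#' Distribute coarse residuals over fine pixels
#'
#' Each coarse pixel's residual is spread across its ratio^2 fine pixels
#' with weights proportional to a guidance score
#' `max(1e-6, homogeneity * (1 - |sp_fine - tp_fine| / max block discrepancy))`:
#' pixels whose temporal prediction already agrees with the spatial (TPS)
#' prediction, and pixels in homogeneous neighborhoods, absorb less of the
#' residual. Weights are normalized within each coarse pixel so the block
#' mean of the allocation equals the coarse residual exactly.
#'
#' @param tpred a `temporal_prediction`.
#' @param sp_fine fine [grid_raster]: the TPS spatial prediction.
#' @param fine_t1 fine reference [grid_raster].
#' @param ratio coarse/fine ratio.
#' @return fine [grid_raster] of allocated residuals.
#' @export
distribute_residuals <- function(tpred, sp_fine, fine_t1, ratio) {
  stopifnot_grid_raster(sp_fine)
  ratio <- check_ratio(ratio)
  tp <- tpred$tp_fine$values
  disc <- abs(sp_fine$values - tp)
  labels <- tpred$cmap$labels
  labs <- labels
  labs[is.na(labs)] <- -1L
  homog <- .cpp_homogeneity(labs, ratio)
  maxd <- block_expand_mat(block_apply_mat(disc, ratio, function(b) max(b, na.rm = TRUE)),
                           ratio)
  rel <- ifelse(maxd > 0, 1 - disc / maxd, 1)
  score <- pmax(homog * rel, 1e-6) # matrix first: pmax keeps dims of arg 1
  ssum <- block_expand_mat(block_apply_mat(score, ratio, sum), ratio)
  rho <- block_expand_mat(tpred$residual$values, ratio)
  alloc <- rho * score * ratio^2 / ssum
  grid_raster(alloc, fine_t1$origin_x, fine_t1$origin_y, fine_t1$pixel_size)
}

#' Refine the preliminary prediction with neighborhood information
#'
#' For each fine pixel, up to `n_similar` spectrally similar pixels
#' (smallest reference-NDVI difference; ties broken by spatial proximity,
#' then row-major order) are selected inside a square window, and the
#' final change is their inverse-distance-weighted mean preliminary
#' change. The pixel itself is always its own most similar neighbor, so
#' `n_similar = 1` keeps the preliminary change.
#'
#' @param prelim_fine fine [grid_raster]: temporal prediction plus
#'   allocated residual.
#' @param fine_t1 fine reference [grid_raster].
#' @param params a [fusion_params]; `window_radius = NULL` uses `ratio`.
#' @param ratio coarse/fine ratio (fallback window radius).
#' @return fine [grid_raster]: the refined prediction.
#' @export
neighborhood_refine <- function(prelim_fine, fine_t1, params = fusion_params(),
                                ratio = 1L) {
  stopifnot_grid_raster(prelim_fine); stopifnot_grid_raster(fine_t1)
  radius <- if (is.null(params$window_radius)) check_ratio(ratio) else params$window_radius
  change <- prelim_fine$values - fine_t1$values
  refined <- .cpp_refine(change, fine_t1$values, params$n_similar, radius)
  grid_raster(fine_t1$values + refined,
              fine_t1$origin_x, fine_t1$origin_y, fine_t1$pixel_size)
}

#' Six-step flexible spatiotemporal fusion
#'
#' Predicts the fine-resolution NDVI image at the target date t2 from one
#' fine reference image at t1 and coarse images at t1 and t2:
#' (1) delineation (handled upstream / full extent here), (2) coarse
#' temporal change, (3) class-wise temporal prediction with per-coarse-
#' pixel residuals, (4) thin-plate-spline spatial prediction, (5) residual
#' distribution guided by the TPS prediction and local homogeneity,
#' (6) neighborhood refinement. Output NDVI is clipped to \[-1, 1\].
#'
#' @param inputs a [fusion_inputs] bundle.
#' @return fine [grid_raster] at t2, with a `diagnostics` attribute
#'   (per-class change, residual summary, effective class count).
#' @export
fsdaf_fuse <- function(inputs) {
  if (!inherits(inputs, "fusion_inputs")) stop("`inputs` must be a fusion_inputs object",
                                               call. = FALSE)
  p <- inputs$params
  fine_t1 <- inputs$fine_t1
  ratio <- inputs$ratio
  # cap classes at the number of distinct values so near-constant scenes fuse
  ndistinct <- length(unique(as.vector(fine_t1$values)[is.finite(fine_t1$values)]))
  k <- min(p$n_classes, ndistinct)
  cmap <- classify_fine(fine_t1, k, seed = p$seed, ratio = ratio)
  dc <- coarse_change(inputs$coarse_t1, inputs$coarse_t2)
  tpred <- temporal_prediction(fine_t1, dc, cmap, ratio)
  sp <- tps_prediction(inputs$coarse_t2, fine_t1, p$tps_smoothing)
  alloc <- distribute_residuals(tpred, sp, fine_t1, ratio)
  prelim <- grid_raster(tpred$tp_fine$values + alloc$values,
                        fine_t1$origin_x, fine_t1$origin_y, fine_t1$pixel_size)
  fused <- neighborhood_refine(prelim, fine_t1, p, ratio = ratio)
  fused <- clip_values(fused, -1, 1)
  attr(fused, "diagnostics") <- list(
    delta_class = tpred$delta_class,
    n_classes_used = k,
    residual_mean_abs = mean(abs(tpred$residual$values), na.rm = TRUE),
    residual_max_abs = max(abs(tpred$residual$values), na.rm = TRUE))
  fused
}
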