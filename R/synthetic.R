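#' Seasonal double-logistic growth curve
#'
#' NDVI season model: a logistic rise to a plateau followed by a logistic
#' fall (e.g. defoliation/harvest), `base + amplitude * (rise - fall)`,
#' clipped to \[0, 1\].
#'
#' @param base off-season NDVI (>= 0).
#' @param amplitude seasonal amplitude; `base + amplitude <= 1`.
#' @param rise_mid,fall_mid DOY of the rise and fall midpoints
#'   (`rise_mid < fall_mid`).
#' @param rise_rate,fall_rate logistic rates, per day.
#' @return object of class `growth_curve`.
#' @export
growth_curve <- function(base, amplitude, rise_mid, rise_rate, fall_mid, fall_rate) {
  stopifnot(base >= 0, amplitude >= 0, base + amplitude <= 1)
  if (amplitude > 0 && rise_mid >= fall_mid)
    stop("rise_mid must precede fall_mid", call. = FALSE)
  structure(list(base = base, amplitude = amplitude,
                 rise_mid = rise_mid, rise_rate = rise_rate,
                 fall_mid = fall_mid, fall_rate = fall_rate),
            class = "growth_curve")
}

#' Evaluate a growth curve
#' @param c a [growth_curve].
#' @param doy day(s) of year in \[1, 366\] (fractional values allowed, for
#'   per-pixel phase jitter).
#' @param amp_scale optional per-evaluation amplitude multiplier.
#' @return NDVI value(s) in \[0, 1\].
#' @export
growth_value <- function(c, doy, amp_scale = 1) {
  if (any(doy < 1 | doy > 366)) stop("doy must lie in [1, 366]", call. = FALSE)
  v <- c$base + c$amplitude * amp_scale *
    (1 / (1 + exp(-c$rise_rate * (doy - c$rise_mid))) -
     1 / (1 + exp(-c$fall_rate * (doy - c$fall_mid))))
  pmin(pmax(v, 0), 1)
}

#' Default cover-type growth curves
#'
#' The cotton curves were calibrated so that the default season, observed
#' on the 8-day fine-image cadence, reproduces the reference phenology:
#' rapid growth from DOY 174, plateau by DOY 206, peak at DOY 230,
#' established decline by DOY 254 (the late fall midpoint mimics
#' September defoliation). Surrounding covers green up earlier or later so
#' that coarse pixels straddling plot boundaries mix contrasting signals.
#'
#' @return named list of [growth_curve] objects.
#' @export
default_cover_types <- function() {
  list(
    cotton_a   = growth_curve(0.12, 0.65, 186, 0.20, 260, 0.28),
    cotton_b   = growth_curve(0.12, 0.60, 186, 0.20, 258, 0.28),
    cotton_c   = growth_curve(0.12, 0.62, 189, 0.20, 260, 0.28),
    crop_early = growth_curve(0.15, 0.55,  80, 0.15, 175, 0.15),
    crop_late  = growth_curve(0.13, 0.55, 210, 0.12, 300, 0.10),
    fallow     = growth_curve(0.15, 0.00, 100, 0.10, 300, 0.10),
    road       = growth_curve(0.08, 0.00, 100, 0.10, 300, 0.10)
  )
}

cellrect <- function(r0, r1, c0, c1, pixel, top) {
  # planar rectangle covering fine cells rows r0..r1, cols c0..c1 (1-based)
  c(xmin = (c0 - 1) * pixel, xmax = c1 * pixel,
    ymin = top - r1 * pixel, ymax = top - (r0 - 1) * pixel)
}

#' Synthetic scene configuration
#'
#' Describes a fine grid partitioned into crop plots and background
#' covers, the observation calendar, sensor noise, and the yield ground
#' truth. Defaults emulate the reference study layout: three cotton plots
#' — A pixel-aligned with the ratio-8 coarse grid, B irregular and split
#' in two sections by a road strip covering roughly 13% of its bounding
#' area, C offset by half a coarse pixel — surrounded by early- and
#' late-season crops, fallow land and roads; fine images every 8 days
#' across the season; coarse imagery at 8x and 16x the fine pixel.
#'
#' @param fine_shape c(rows, cols) of the fine grid; divisible by every
#'   ratio.
#' @param fine_pixel fine pixel size, meters.
#' @param ratios integer coarse/fine ratios.
#' @param doys observation days of year.
#' @param cover_types named list of [growth_curve] objects.
#' @param plots list of `list(name, polygon, cover)` entries.
#' @param background list of `list(rect = c(r0, r1, c0, c1), cover)` paint
#'   instructions applied before the plots; cells not painted get
#'   `base_cover`.
#' @param base_cover default cover name.
#' @param noise_sd_fine,noise_sd_coarse additive Gaussian observation
#'   noise, NDVI units.
#' @param amp_jitter_sd,phase_jitter_sd per-pixel landscape heterogeneity:
#'   SD of the (spatially smoothed) multiplicative amplitude jitter and of
#'   the phase jitter in days. Part of the ground truth, not of the
#'   observation noise.
#' @param yield_a,yield_b,yield_noise_sd linear yield ground truth:
#'   yield = yield_a * peak NDVI + yield_b + N(0, yield_noise_sd).
#' @param track_spacing,point_spacing harvest-track geometry, meters.
#' @param seed integer seed.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(fine_shape = c(96L, 96L), fine_pixel = 30,
                         ratios = c(8L, 16L), doys = seq(126L, 302L, by = 8L),
                         cover_types = default_cover_types(),
                         plots = NULL, background = NULL,
                         base_cover = "crop_late",
                         noise_sd_fine = 0.01, noise_sd_coarse = 0.02,
                         amp_jitter_sd = 0.08, phase_jitter_sd = 3,
                         yield_a = 2.5, yield_b = 0.3, yield_noise_sd = 0.1,
                         track_spacing = 15, point_spacing = 10,
                         seed = 0L) {
  fine_shape <- as.integer(fine_shape)
  for (r in ratios)
    if (any(fine_shape %% as.integer(r) != 0L))
      stop("fine_shape must be divisible by every ratio", call. = FALSE)
  stopifnot(noise_sd_fine >= 0, noise_sd_coarse >= 0, yield_noise_sd >= 0)
  top <- fine_shape[1] * fine_pixel
  if (is.null(plots)) {
    mk <- function(nm, r0, r1, c0, c1) {
      b <- cellrect(r0, r1, c0, c1, fine_pixel, top)
      rect_polygon(nm, b["xmin"], b["xmax"], b["ymin"], b["ymax"])
    }
    bN <- cellrect(9, 26, 53, 88, fine_pixel, top)
    bS <- cellrect(32, 44, 61, 88, fine_pixel, top)
    ringN <- cbind(c(bN["xmin"], bN["xmax"], bN["xmax"], bN["xmin"]),
                   c(bN["ymin"], bN["ymin"], bN["ymax"], bN["ymax"]))
    ringS <- cbind(c(bS["xmin"], bS["xmax"], bS["xmax"], bS["xmin"]),
                   c(bS["ymin"], bS["ymin"], bS["ymax"], bS["ymax"]))
    plots <- list(
      list(name = "A", polygon = mk("A", 9, 40, 9, 40), cover = "cotton_a"),
      list(name = "B",
           polygon = plot_polygon("B", list(ringN, ringS), orient = FALSE),
           cover = "cotton_b"),
      list(name = "C", polygon = mk("C", 53, 84, 13, 44), cover = "cotton_c"))
  }
  if (is.null(background)) {
    nr <- fine_shape[1]; nc <- fine_shape[2]
    background <- list(
      list(rect = c(1L, 8L, 1L, nc), cover = "crop_early"),
      list(rect = c(1L, nr, 1L, 8L), cover = "crop_early"),
      list(rect = c(85L, nr, 1L, nc), cover = "fallow"),
      list(rect = c(1L, nr, 48L, 49L), cover = "road"),
      list(rect = c(27L, 31L, 53L, 88L), cover = "road"))
  }
  structure(list(fine_shape = fine_shape, fine_pixel = fine_pixel,
                 ratios = as.integer(ratios), doys = as.integer(doys),
                 cover_types = cover_types, plots = plots,
                 background = background, base_cover = base_cover,
                 noise_sd_fine = noise_sd_fine, noise_sd_coarse = noise_sd_coarse,
                 amp_jitter_sd = amp_jitter_sd, phase_jitter_sd = phase_jitter_sd,
                 yield_a = yield_a, yield_b = yield_b,
                 yield_noise_sd = yield_noise_sd,
                 track_spacing = track_spacing, point_spacing = point_spacing,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# 3x3 box smoothing with edge clamping
smooth_field <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + pad[di + seq_len(nr), dj + seq_len(nc)]
  acc / 9
}

build_cover_map <- function(cfg) {
  nr <- cfg$fine_shape[1]; nc <- cfg$fine_shape[2]
  names_cov <- names(cfg$cover_types)
  cover <- matrix(match(cfg$base_cover, names_cov), nr, nc)
  for (b in cfg$background) {
    r <- b$rect
    cover[r[1]:r[2], r[3]:r[4]] <- match(b$cover, names_cov)
  }
  grid <- grid_raster(matrix(0, nr, nc), 0, nr * cfg$fine_pixel, cfg$fine_pixel)
  ctr <- center_matrix(grid)
  xmax <- nc * cfg$fine_pixel; ymax <- nr * cfg$fine_pixel
  for (p in cfg$plots) {
    bb <- polygon_bbox(p$polygon)
    if (bb["xmin"] < 0 || bb["ymin"] < 0 || bb["xmax"] > xmax || bb["ymax"] > ymax)
      stop(sprintf("plot '%s' extends outside the scene extent", p$name), call. = FALSE)
    inside <- points_in_polygon(p$polygon, ctr[, 1], ctr[, 2])
    cover[matrix(inside, nr, nc)] <- match(p$cover, names_cov)
  }
  if (anyNA(cover)) stop("unknown cover type referenced", call. = FALSE)
  cover
}

# serpentine harvest track through a polygon
harvest_track <- function(poly, track_spacing, point_spacing) {
  bb <- polygon_bbox(poly)
  ys <- seq(bb["ymax"] - track_spacing / 2, bb["ymin"] + track_spacing / 4,
            by = -track_spacing)
  xs0 <- seq(bb["xmin"] + point_spacing / 2, bb["xmax"] - point_spacing / 4,
             by = point_spacing)
  out <- list()
  for (k in seq_along(ys)) {
    xs <- if (k %% 2L == 1L) xs0 else rev(xs0)
    keep <- points_in_polygon(poly, xs, rep(ys[k], length(xs)))
    if (any(keep)) out[[length(out) + 1L]] <- cbind(x = xs[keep], y = ys[k])
  }
  do.call(rbind, out)
}

#' Generate a fully specified synthetic scene
#'
#' Builds, deterministically for a fixed seed: the noise-free fine NDVI
#' truth of every cover at every observation date (including the per-pixel
#' amplitude/phase heterogeneity, which is landscape truth, not noise);
#' the observed fine stack (truth plus Gaussian noise, clipped to
#' \[0, 1\]); coarse stacks per ratio (block mean of the truth plus
#' Gaussian noise, clipped to \[-1, 1\]); the plot polygons; and
#' yield-monitor points along serpentine harvest tracks with
#' `yield = yield_a * peak NDVI + yield_b + noise`.
#'
#' @param cfg a [scene_config].
#' @return a scene bundle: list with `fine`, `truth_fine` ([scene_stack]),
#'   `coarse` (named list of [scene_stack] by ratio), `plots`,
#'   `yield` (data.frame x, y, yield in track order), `peak_truth`
#'   ([grid_raster]), `cover` (integer matrix), `config`.
#' @export
generate_scene <- function(cfg) {
  if (!inherits(cfg, "scene_config")) stop("`cfg` must be a scene_config", call. = FALSE)
  local_seed(cfg$seed, {
    nr <- cfg$fine_shape[1]; nc <- cfg$fine_shape[2]
    px <- cfg$fine_pixel
    top <- nr * px
    cover <- build_cover_map(cfg)
    amp <- if (cfg$amp_jitter_sd > 0)
      pmin(pmax(1 + smooth_field(matrix(stats::rnorm(nr * nc, 0, cfg$amp_jitter_sd * 3),
                                        nr, nc)), 0.6), 1.4)
    else matrix(1, nr, nc)
    phase <- if (cfg$phase_jitter_sd > 0)
      smooth_field(matrix(stats::rnorm(nr * nc, 0, cfg$phase_jitter_sd * 3), nr, nc))
    else matrix(0, nr, nc)
    truth <- list(); fine <- list()
    for (d in cfg$doys) {
      tv <- matrix(NA_real_, nr, nc)
      for (k in seq_along(cfg$cover_types)) {
        sel <- cover == k
        if (!any(sel)) next
        dd <- pmin(pmax(d - phase[sel], 1), 366)
        tv[sel] <- growth_value(cfg$cover_types[[k]], dd, amp_scale = amp[sel])
      }
      truth[[as.character(d)]] <- grid_raster(tv, 0, top, px)
      ov <- tv + if (cfg$noise_sd_fine > 0) stats::rnorm(nr * nc, 0, cfg$noise_sd_fine) else 0
      fine[[as.character(d)]] <- grid_raster(pmin(pmax(ov, 0), 1), 0, top, px)
    }
    truth_stack <- scene_stack(truth, ratio = 1L)
    fine_stack <- scene_stack(fine, ratio = 1L)
    coarse <- list()
    for (ratio in cfg$ratios) {
      cr <- list()
      for (d in cfg$doys) {
        agg <- block_aggregate(truth[[as.character(d)]], ratio)
        if (cfg$noise_sd_coarse > 0)
          agg$values <- agg$values + stats::rnorm(length(agg$values), 0,
                                                  cfg$noise_sd_coarse)
        cr[[as.character(d)]] <- clip_values(agg, -1, 1)
      }
      coarse[[as.character(ratio)]] <- scene_stack(cr, ratio = ratio)
    }
    # per-pixel peak (over observation dates) of the truth
    peak <- truth[[1]]$values
    for (t in truth[-1]) peak <- pmax(peak, t$values)
    peak_r <- grid_raster(peak, 0, top, px)
    # yield monitor points along harvest tracks in each plot
    pts <- list()
    for (p in cfg$plots) {
      tr <- harvest_track(p$polygon, cfg$track_spacing, cfg$point_spacing)
      if (is.null(tr) || nrow(tr) == 0L) next
      i <- pmin(pmax(floor((top - tr[, "y"]) / px) + 1L, 1L), nr)
      j <- pmin(pmax(floor(tr[, "x"] / px) + 1L, 1L), nc)
      truth_yield <- cfg$yield_a * peak[cbind(i, j)] + cfg$yield_b
      noise <- if (cfg$yield_noise_sd > 0)
        stats::rnorm(length(truth_yield), 0, cfg$yield_noise_sd) else 0
      pts[[length(pts) + 1L]] <- data.frame(
        x = tr[, "x"], y = tr[, "y"],
        yield = pmax(truth_yield + noise, 0), plot = p$name)
    }
    yield <- if (length(pts)) do.call(rbind, pts) else
      data.frame(x = numeric(0), y = numeric(0), yield = numeric(0),
                 plot = character(0))
    rownames(yield) <- NULL
    list(fine = fine_stack, truth_fine = truth_stack, coarse = coarse,
         plots = lapply(cfg$plots, `[[`, "polygon"),
         yield = yield, peak_truth = peak_r, cover = cover, config = cfg)
  })
}

#' Pixel-aligned single-plot configuration for mixing experiments
#'
#' A noise- and jitter-free scene with one square cotton plot on a
#' contrasting fallow background, aligned with the ratio-8 coarse grid.
#' Used as the base of the mixing ladder.
#'
#' @param contrast_cover background cover name (default "fallow").
#' @param doys observation dates (default the peak date only).
#' @return [scene_config].
#' @export
mixing_ladder_config <- function(contrast_cover = "fallow", doys = 230L) {
  scene_config(
    fine_shape = c(96L, 96L), ratios = c(8L, 16L), doys = doys,
    plots = list(list(name = "P",
                      polygon = rect_polygon("P", 960, 1920, 960, 1920),
                      cover = "cotton_a")),
    background = list(), base_cover = contrast_cover,
    noise_sd_fine = 0, noise_sd_coarse = 0,
    amp_jitter_sd = 0, phase_jitter_sd = 0)
}

#' Generate a ladder of scenes with a plot boundary sweeping a coarse pixel
#'
#' Returns one scene per offset, identical except that the named plot (its
#' polygon and the crop it carries) is shifted eastward by the offset.
#' Offsets should be multiples of the fine pixel so the shifted boundary
#' stays on the fine grid. Used for mixing-monotonicity experiments: as a
#' pixel-aligned plot slides across a coarse pixel, boundary pixels mix
#' more and the Mixed Degree Index must not decrease.
#'
#' @param cfg a [scene_config] (e.g. [mixing_ladder_config()]).
#' @param offsets numeric vector of eastward shifts, meters.
#' @param plot_name which plot to shift (default the first).
#' @return list of scene bundles, one per offset.
#' @export
make_mixing_ladder <- function(cfg, offsets, plot_name = cfg$plots[[1]]$name) {
  idx <- which(vapply(cfg$plots, `[[`, "", "name") == plot_name)
  if (length(idx) != 1L) stop("plot_name not found in config", call. = FALSE)
  lapply(offsets, function(dx) {
    cfg2 <- cfg
    cfg2$plots[[idx]]$polygon <- translate_polygon(cfg$plots[[idx]]$polygon, dx)
    generate_scene(cfg2)
  })
}
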