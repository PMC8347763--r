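#' Run the full synthetic-scene pipeline
#'
#' Executes the stages end to end: (1) simulate a scene and write its
#' rasters, plots and yield track; (2) per-plot phenology and reference /
#' peak date selection; (3) fusion of every (ratio, reference stage)
#' combination toward the peak date; (4) per-plot MDI at each ratio;
#' (5) yield cleaning, rasterization and the NDVI-to-yield fit per fused
#' product, plus per-date yield correlations. Every produced file is
#' listed in `manifest.json` with its stage and md5 checksum; the run is
#' deterministic for a fixed seed.
#'
#' @param config a named list, or path to a JSON file with the same
#'   structure. Recognized fields: `outdir` (required), `seed`,
#'   `scene` (named scalar overrides passed to [scene_config()]),
#'   `fusion` (overrides passed to [fusion_params()]),
#'   `stage_thresholds` (rise/plateau/end_fraction overrides).
#' @return the manifest, invisibly: list with `files` data.frame and
#'   per-stage results (`stages`, `fits`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config),
                                   call. = FALSE)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (is.null(config$outdir))
    stop("invalid config: missing required field 'outdir'", call. = FALSE)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)

  scn_args <- if (is.null(config$scene)) list() else as.list(config$scene)
  scn_args$seed <- seed
  cfg <- do.call(scene_config, scn_args)
  fus_args <- if (is.null(config$fusion)) list() else as.list(config$fusion)
  if (is.null(fus_args$seed)) fus_args$seed <- seed
  fparams <- do.call(fusion_params, fus_args)
  thr <- if (is.null(config$stage_thresholds)) list() else as.list(config$stage_thresholds)

  files <- list()
  note <- function(path, stage) files[[length(files) + 1L]] <<-
    data.frame(file = path, stage = stage)

  # -- simulate -------------------------------------------------------------
  scene <- generate_scene(cfg)
  scdir <- file.path(outdir, "scene")
  trdir <- file.path(scdir, "truth")
  dir.create(trdir, recursive = TRUE, showWarnings = FALSE)
  for (d in cfg$doys) {
    p <- file.path(scdir, sprintf("fine_%03d.asc", d))
    write_raster(stack_at(scene$fine, d), p); note(p, "simulate")
    p <- file.path(trdir, sprintf("truth_%03d.asc", d))
    write_raster(stack_at(scene$truth_fine, d), p); note(p, "simulate")
    for (ratio in cfg$ratios) {
      p <- file.path(scdir, sprintf("coarse%d_%03d.asc", ratio, d))
      write_raster(stack_at(scene$coarse[[as.character(ratio)]], d), p)
      note(p, "simulate")
    }
  }
  p <- file.path(scdir, "plots.geojson"); write_plots(scene$plots, p); note(p, "simulate")
  p <- file.path(scdir, "yield.csv")
  utils::write.csv(scene$yield, p, row.names = FALSE); note(p, "simulate")

  # -- phenology ------------------------------------------------------------
  stage_rows <- list()
  stage_by_plot <- list()
  for (pl in scene$plots) {
    s <- extract_series(scene$fine, pl)
    st <- do.call(identify_stages, c(list(s = s, obs_doys = cfg$doys), thr))
    stage_by_plot[[pl$name]] <- st
    stage_rows[[length(stage_rows) + 1L]] <- data.frame(
      plot = pl$name, early_doy = st$early_doy, middle_doy = st$middle_doy,
      peak_doy = st$peak_doy, end_doy = st$end_doy)
  }
  stages_df <- do.call(rbind, stage_rows)
  p <- file.path(outdir, "stages.csv")
  utils::write.csv(stages_df, p, row.names = FALSE); note(p, "phenology")
  # scene-wide reference dates: majority/first plot selection
  ref <- stage_by_plot[[1]]
  ref_doys <- c(early = ref$early_doy, middle = ref$middle_doy, end = ref$end_doy)
  peak_doy <- ref$peak_doy

  # -- fuse: each ratio x reference stage, target = peak date ---------------
  fudir <- file.path(outdir, "fused")
  dir.create(fudir, showWarnings = FALSE)
  fused_store <- list()
  for (ratio in cfg$ratios) {
    cst <- scene$coarse[[as.character(ratio)]]
    for (stg in names(ref_doys)) {
      t1 <- ref_doys[[stg]]
      inp <- fusion_inputs(stack_at(scene$fine, t1), stack_at(cst, t1),
                           stack_at(cst, peak_doy), ratio, fparams)
      fz <- fsdaf_fuse(inp)
      fused_store[[sprintf("%d_%s", ratio, stg)]] <- fz
      p <- file.path(fudir, sprintf("fused_r%02d_%s_ref%03d_to%03d.asc",
                                    ratio, stg, t1, peak_doy))
      write_raster(fz, p); note(p, "fuse")
    }
  }

  # -- mdi ------------------------------------------------------------------
  mdi_rows <- list()
  for (ratio in cfg$ratios) {
    cst <- scene$coarse[[as.character(ratio)]]
    for (pl in scene$plots) {
      res <- compute_mdi(pl, stack_at(cst, peak_doy), stack_at(scene$fine, peak_doy))
      mdi_rows[[length(mdi_rows) + 1L]] <- data.frame(
        plot = pl$name, resolution = res$resolution, doy = peak_doy,
        n_pixels = nrow(res$components), mdi = res$mdi)
    }
  }
  mdi_df <- do.call(rbind, mdi_rows)
  p <- file.path(outdir, "mdi.csv")
  utils::write.csv(mdi_df, p, row.names = FALSE); note(p, "mdi")

  # -- yield model ----------------------------------------------------------
  clean <- filter_outliers(scene$yield)
  p <- file.path(outdir, "yield_clean.csv")
  utils::write.csv(clean, p, row.names = FALSE); note(p, "yield-fit")
  # one 0.5 m yield raster per plot (a scene-wide raster would be huge)
  yrs <- lapply(scene$plots, function(pl)
    rasterize_yield(clean[clean$plot == pl$name, , drop = FALSE], cell = 0.5))
  names(yrs) <- vapply(scene$plots, function(pl) pl$name, "")
  fits <- list()
  for (key in names(fused_store)) {
    pr <- do.call(rbind, lapply(seq_along(scene$plots), function(i)
      pair_ndvi_yield(fused_store[[key]], yrs[[i]], scene$plots[[i]])))
    fit <- fit_yield_model(pr)
    fits[[key]] <- list(a = fit$a, b = fit$b, r2 = fit$r2, rmse = fit$rmse,
                        n = fit$n)
  }
  p <- file.path(outdir, "yield_fit.json")
  jsonlite::write_json(fits, p, auto_unbox = TRUE, digits = NA); note(p, "yield-fit")
  corr <- correlation_by_date(list(fine = scene$fine), yrs[[1]], scene$plots[[1]])
  p <- file.path(outdir, "correlation.csv")
  utils::write.csv(corr, p, row.names = FALSE); note(p, "yield-fit")

  # -- manifest -------------------------------------------------------------
  fdf <- do.call(rbind, files)
  fdf$md5 <- unname(tools::md5sum(fdf$file))
  manifest <- list(seed = seed, files = fdf, stages = stages_df,
                   reference_doys = as.list(ref_doys), peak_doy = peak_doy)
  jsonlite::write_json(
    list(seed = seed, peak_doy = peak_doy, reference_doys = as.list(ref_doys),
         files = fdf),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  manifest$fits <- fits
  invisible(manifest)
}

#' Command-line entry point
#'
#' Dispatches `fusionyield <simulate|fuse|mdi|phenology|yield-fit|run>`;
#' see the shipped `inst/cli/fusionyield` launcher. Each subcommand is a
#' thin wrapper over the exported functions, reading/writing the package's
#' plain-text formats.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
fy_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: fusionyield <command> [options]",
    "commands:",
    "  run        --config cfg.json",
    "  simulate   --config cfg.json  (scene only)",
    "  fuse       --fine-t1 F.asc --coarse-t1 C1.asc --coarse-t2 C2.asc",
    "             --ratio N --out fused.asc [--classes 4 --similar 20",
    "             --window N --seed 0]",
    "  mdi        --plots plots.geojson --coarse C.asc --fine F.asc --out mdi.csv",
    "  phenology  --stack stack.json --plots plots.geojson --out stages.csv",
    "  yield-fit  --ndvi fused.asc --yield yield.csv --plot plots.geojson --out fit.json",
    "  yield-clean --in yield.csv --window 21 --out clean.csv",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  need <- function(...) {
    for (k in c(...)) if (is.null(opts[[k]]))
      stop(sprintf("%s: missing required flag --%s", cmd, k), call. = FALSE)
  }
  status <- 0L
  switch(cmd,
    run = { need("config"); run_pipeline(opts$config) },
    simulate = {
      need("config")
      config <- jsonlite::fromJSON(opts$config, simplifyVector = TRUE)
      if (is.null(config$outdir)) stop("invalid config: missing 'outdir'", call. = FALSE)
      scn <- if (is.null(config$scene)) list() else as.list(config$scene)
      if (!is.null(config$seed)) scn$seed <- as.integer(config$seed)
      scene <- generate_scene(do.call(scene_config, scn))
      dir.create(opts$config_outdir <- config$outdir, recursive = TRUE,
                 showWarnings = FALSE)
      for (d in scene$config$doys)
        write_raster(stack_at(scene$fine, d),
                     file.path(config$outdir, sprintf("fine_%03d.asc", d)))
      write_plots(scene$plots, file.path(config$outdir, "plots.geojson"))
      write_yield_points(scene$yield, file.path(config$outdir, "yield.csv"))
    },
    fuse = {
      need("fine-t1", "coarse-t1", "coarse-t2", "ratio", "out")
      params <- fusion_params(
        n_classes = as.integer(opts$classes %||% 4L),
        n_similar = as.integer(opts$similar %||% 20L),
        window_radius = if (is.null(opts$window)) NULL else as.integer(opts$window),
        seed = as.integer(opts$seed %||% 0L))
      inp <- fusion_inputs(read_raster(opts[["fine-t1"]]),
                           read_raster(opts[["coarse-t1"]]),
                           read_raster(opts[["coarse-t2"]]),
                           as.integer(opts$ratio), params)
      fused <- fsdaf_fuse(inp)
      di <- attr(fused, "diagnostics")
      message(sprintf("fused: %d classes, delta_class = [%s], mean |residual| = %.4g",
                      di$n_classes_used,
                      paste(sprintf("%.4f", di$delta_class), collapse = ", "),
                      di$residual_mean_abs))
      write_raster(fused, opts$out)
    },
    mdi = {
      need("plots", "coarse", "fine", "out")
      plots <- read_plots(opts$plots)
      coarse <- read_raster(opts$coarse); fine <- read_raster(opts$fine)
      rows <- list()
      for (pl in plots) {
        res <- compute_mdi(pl, coarse, fine)
        cmp <- res$components
        cmp$plot <- pl$name; cmp$resolution <- res$resolution; cmp$mdi <- res$mdi
        rows[[length(rows) + 1L]] <- cmp
      }
      utils::write.csv(do.call(rbind, rows), opts$out, row.names = FALSE)
    },
    phenology = {
      need("stack", "plots", "out")
      lst <- jsonlite::fromJSON(opts$stack, simplifyVector = TRUE)
      rasters <- lapply(lst$file, read_raster)
      names(rasters) <- lst$doy
      st <- scene_stack(rasters)
      plots <- read_plots(opts$plots)
      rows <- lapply(plots, function(pl) {
        sel <- identify_stages(extract_series(st, pl))
        data.frame(plot = pl$name, early_doy = sel$early_doy,
                   middle_doy = sel$middle_doy, peak_doy = sel$peak_doy,
                   end_doy = sel$end_doy)
      })
      utils::write.csv(do.call(rbind, rows), opts$out, row.names = FALSE)
    },
    "yield-fit" = {
      need("ndvi", "yield", "out")
      ndvi <- read_raster(opts$ndvi)
      pts <- filter_outliers(read_yield_points(opts$yield),
                             window = as.integer(opts$window %||% 21L))
      yr <- rasterize_yield(pts, cell = as.numeric(opts$cell %||% 0.5))
      plot <- if (is.null(opts$plot)) NULL else read_plots(opts$plot)[[1]]
      fit <- fit_yield_model(pair_ndvi_yield(ndvi, yr, plot))
      jsonlite::write_json(list(a = fit$a, b = fit$b, r2 = fit$r2,
                                rmse = fit$rmse, n = fit$n),
                           opts$out, auto_unbox = TRUE, digits = NA)
    },
    "yield-clean" = {
      need("in", "out")
      pts <- read_yield_points(opts[["in"]])
      write_yield_points(filter_outliers(pts, window = as.integer(opts$window %||% 21L)),
                         opts$out)
    },
    { message(usage); status <- 1L })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop(sprintf("flag --%s needs a value", key), call. = FALSE)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
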