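#' Read a raster from an ESRI ASCII grid file
#'
#' Reads the plain-text ESRI ASCII Grid dialect (`.asc`): a header of
#' `ncols`, `nrows`, `xllcorner`/`yllcorner` (or `xllcenter`/`yllcenter`),
#' `cellsize` and optional `nodata_value`, followed by rows of values from
#' the northern edge southward. Non-square pixels (a `dx`/`dy` header) are
#' rejected: the whole pipeline assumes square pixels.
#'
#' @param path file path.
#' @param format raster format name; only `"asc"` (ESRI ASCII grid) is
#'   supported in this build.
#' @return a [grid_raster]; nodata cells are `NA`.
#' @export
read_raster <- function(path, format = "asc") {
  if (!identical(tolower(format), "asc"))
    stop(sprintf("unsupported raster format '%s' (only 'asc' is available)", format),
         call. = FALSE)
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*[A-Za-z]", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1L
  }
  if (!is.null(hdr$dx) || !is.null(hdr$dy)) {
    if (!isTRUE(all.equal(hdr$dx, hdr$dy)))
      stop("unsupported grid: non-square pixels", call. = FALSE)
    hdr$cellsize <- hdr$dx
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header", call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows); cs <- hdr$cellsize
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nr * nc) stop("ASCII grid body does not match header dimensions",
                                    call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  if (!is.null(hdr$xllcorner)) {
    ox <- hdr$xllcorner; oy <- hdr$yllcorner + nr * cs
  } else {
    ox <- hdr$xllcenter - cs / 2; oy <- hdr$yllcenter - cs / 2 + nr * cs
  }
  grid_raster(m, ox, oy, cs)
}

#' Write a raster as an ESRI ASCII grid file
#'
#' Values are written with 17 significant digits so that
#' `read_raster(write_raster(r))` reproduces them bit for bit.
#'
#' @param r a [grid_raster].
#' @param path output path (parent directory must exist).
#' @param nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(r, path, nodata = -9999) {
  stopifnot_grid_raster(r)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)), call. = FALSE)
  v <- r$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10f", r$origin_x),
    sprintf("yllcorner %.10f", r$origin_y - nr * r$pixel_size),
    sprintf("cellsize %.10f", r$pixel_size),
    sprintf("nodata_value %g", nodata)
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  ok <- tryCatch({
    writeLines(c(hdr, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(path))
    stop(sprintf("could not write raster to %s", path), call. = FALSE)
  invisible(path)
}

#' Read plot boundary polygons from a GeoJSON file
#'
#' Accepts a FeatureCollection of Polygon or MultiPolygon features carrying
#' a name property (`name`, `Name`, `id` or `plot`). Coordinates must be in
#' the same planar system as the rasters. Rings with self-intersections
#' (bow-ties) are rejected.
#'
#' @param path GeoJSON file path.
#' @return list of [plot_polygon] objects in file order.
#' @export
read_plots <- function(path) {
  if (!file.exists(path)) stop(sprintf("plot file not found: %s", path), call. = FALSE)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    geom <- f$geometry
    props <- f$properties
    nm <- NULL
    for (k in c("name", "Name", "id", "plot")) {
      if (!is.null(props[[k]])) { nm <- as.character(props[[k]]); break }
    }
    if (is.null(nm)) nm <- sprintf("plot_%d", length(out) + 1L)
    ring_list <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop(sprintf("unsupported geometry type '%s'", geom$type), call. = FALSE))
    rings <- list()
    for (poly in ring_list) {
      for (k in seq_along(poly)) {
        ring <- do.call(rbind, lapply(poly[[k]], function(pt) as.numeric(pt[1:2])))
        rings[[length(rings) + 1L]] <- orient_ring(close_open_ring(ring), hole = k > 1L)
      }
    }
    out[[length(out) + 1L]] <- plot_polygon(nm, rings)
  }
  out
}

#' Write plot polygons to a GeoJSON file
#' @param plots list of [plot_polygon] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plots <- function(plots, path) {
  feats <- lapply(plots, function(p) {
    coords <- lapply(p$rings, function(r) {
      r <- rbind(r, r[1, , drop = FALSE]) # GeoJSON rings are closed
      lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
    })
    list(type = "Feature",
         properties = list(name = p$name),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read yield-monitor points from CSV
#'
#' Expects columns `x`, `y`, `yield` (planar meters; yield in mass per
#' area). Row order is taken as the harvest-track acquisition order, which
#' the moving-window outlier filter relies on.
#'
#' @param path CSV path.
#' @return data.frame with columns x, y, yield.
#' @export
read_yield_points <- function(path) {
  if (!file.exists(path)) stop(sprintf("yield file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- c("x", "y", "yield")
  if (!all(need %in% names(df)))
    stop("yield CSV must have columns x, y, yield", call. = FALSE)
  df[need]
}

#' Write yield points to CSV
#' @param pts data.frame with x, y, yield.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_yield_points <- function(pts, path) {
  utils::write.csv(pts[c("x", "y", "yield")], path, row.names = FALSE)
  invisible(path)
}
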