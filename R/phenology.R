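#' Construct an NDVI time series
#' @param doy strictly increasing integer days of year.
#' @param value NDVI values in \[-1, 1\].
#' @param label series identity (plot or product name).
#' @return object of class `ndvi_series` (a data.frame).
#' @export
ndvi_series <- function(doy, value, label = "series") {
  doy <- as.integer(doy)
  if (length(doy) != length(value)) stop("doy and value lengths differ", call. = FALSE)
  if (is.unsorted(doy, strictly = TRUE)) stop("DOYs must be strictly increasing",
                                              call. = FALSE)
  fin <- value[is.finite(value)]
  if (length(fin) && (min(fin) < -1 || max(fin) > 1))
    stop("NDVI values must lie in [-1, 1]", call. = FALSE)
  structure(data.frame(doy = doy, value = as.numeric(value)),
            label = label, class = c("ndvi_series", "data.frame"))
}

#' Mean NDVI of a plot at every stack date
#'
#' Averages, per date, the fine pixels whose centers fall inside the plot
#' polygon.
#'
#' @param stack a fine [scene_stack].
#' @param plot a [plot_polygon].
#' @return an [ndvi_series] labeled with the plot name.
#' @export
extract_series <- function(stack, plot) {
  r1 <- stack$rasters[[1]]
  ctr <- center_matrix(r1)
  inside <- points_in_polygon(plot, ctr[, 1], ctr[, 2])
  if (!any(inside))
    stop(sprintf("plot '%s' contains no pixel centers", plot$name), call. = FALSE)
  vals <- vapply(stack$rasters, function(r) {
    v <- as.vector(r$values)[inside]
    mean(v[is.finite(v)])
  }, numeric(1))
  ndvi_series(stack$doys, vals, label = plot$name)
}

#' Linear interpolation of a series to every integer day
#'
#' Piecewise-linear values at every integer DOY between the first and last
#' observation; observations are reproduced exactly.
#'
#' @param s an [ndvi_series] with at least 2 observations.
#' @return daily [ndvi_series].
#' @export
interpolate_daily <- function(s) {
  if (nrow(s) < 2L) stop("interpolation needs at least 2 observations", call. = FALSE)
  days <- seq(min(s$doy), max(s$doy))
  out <- stats::approx(s$doy, s$value, xout = days, method = "linear")$y
  ndvi_series(days, out, label = attr(s, "label"))
}

#' Finite-difference derivative of a daily series
#'
#' Central differences in the interior, one-sided at the ends; units are
#' NDVI per day. The result is not itself NDVI, so it is returned as a
#' plain data.frame (doy, value).
#'
#' @param s a daily [ndvi_series] (length >= 2).
#' @return data.frame with columns doy, value (NDVI/day).
#' @export
derivative <- function(s) {
  n <- nrow(s)
  if (n < 2L) stop("derivative needs at least 2 points", call. = FALSE)
  v <- s$value; d <- s$doy
  out <- numeric(n)
  out[1] <- (v[2] - v[1]) / (d[2] - d[1])
  out[n] <- (v[n] - v[n - 1]) / (d[n] - d[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    out[i] <- (v[i + 1] - v[i - 1]) / (d[i + 1] - d[i - 1])
  }
  data.frame(doy = d, value = out)
}

rolling_mean <- function(x, width) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- width %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Select early / middle / end reference dates and the season peak
#'
#' Works on the daily-interpolated series and its smoothed derivative:
#' * `peak_doy` — observation date of maximum NDVI;
#' * `early_doy` — first observation date at which the smoothed derivative
#'   exceeds `rise_threshold` (rapid growth begins);
#' * `middle_doy` — observation date closest to the first day, after the
#'   rise, at which the derivative drops below `plateau_threshold` (growth
#'   settles to a steady rate);
#' * `end_doy` — first observation date after the peak at which the
#'   derivative is <= 0 and NDVI has fallen below `end_fraction` of the
#'   peak value (decline established).
#'
#' All selected dates snap to the supplied observation dates, since a
#' reference image must actually exist. Ordering
#' early < middle <= peak <= end is enforced; a series with no interior
#' peak (monotone) raises a stage-detection error.
#'
#' @param s an [ndvi_series] of observations (not necessarily daily).
#' @param obs_doys integer dates with actual fine images; defaults to the
#'   series' own dates.
#' @param rise_threshold NDVI/day derivative marking the onset of rapid
#'   growth (default 0.004).
#' @param plateau_threshold NDVI/day derivative marking the plateau
#'   (default 0.002).
#' @param end_fraction fraction of peak NDVI below which the season is
#'   considered ended (default 0.9).
#' @param smooth_window width (days) of the rolling mean applied to the
#'   derivative (default 15).
#' @return object of class `stage_selection`: early_doy, middle_doy,
#'   end_doy, peak_doy.
#' @export
identify_stages <- function(s, obs_doys = s$doy, rise_threshold = 0.004,
                            plateau_threshold = 0.002, end_fraction = 0.9,
                            smooth_window = 15L) {
  obs_doys <- sort(as.integer(obs_doys))
  daily <- interpolate_daily(s)
  der <- derivative(daily)
  sm <- rolling_mean(der$value, smooth_window)
  v <- daily$value; d <- daily$doy
  imax <- which.max(v)
  if (imax <= 1L || imax >= length(v))
    stop("stage detection failed: series is monotone (no interior peak)", call. = FALSE)
  obs_vals <- v[match(obs_doys, d)]
  peak_doy <- obs_doys[which.max(obs_vals)]
  # early: first obs date with smoothed derivative above the rise threshold
  obs_der <- sm[match(obs_doys, d)]
  iearly <- which(obs_der > rise_threshold & obs_doys <= peak_doy)[1]
  if (is.na(iearly))
    stop("stage detection failed: no rapid-growth onset found", call. = FALSE)
  early_doy <- obs_doys[iearly]
  # middle: first day after the rise where derivative falls below plateau
  after_rise <- which(d > early_doy & d <= peak_doy & sm < plateau_threshold)[1]
  if (is.na(after_rise))
    stop("stage detection failed: no plateau found before the peak", call. = FALSE)
  middle_doy <- obs_doys[which.min(abs(obs_doys - d[after_rise]))]
  # end: first obs after peak with non-positive derivative and NDVI below
  # end_fraction of the peak
  peak_val <- max(obs_vals)
  cand <- obs_doys[obs_doys > peak_doy]
  end_doy <- NA_integer_
  for (dd in cand) {
    k <- match(dd, d)
    if (!is.na(k) && sm[k] <= 0 && v[k] < end_fraction * peak_val) {
      end_doy <- dd; break
    }
  }
  if (is.na(end_doy))
    stop("stage detection failed: no established decline after the peak", call. = FALSE)
  if (!(early_doy < middle_doy && middle_doy <= peak_doy && peak_doy <= end_doy))
    stop(sprintf(
      "stage detection failed: inconsistent ordering (early %d, middle %d, peak %d, end %d)",
      early_doy, middle_doy, peak_doy, end_doy), call. = FALSE)
  structure(list(early_doy = early_doy, middle_doy = middle_doy,
                 end_doy = end_doy, peak_doy = peak_doy),
            class = "stage_selection")
}

#' @export
print.stage_selection <- function(x, ...) {
  cat(sprintf("<stage_selection> early %d | middle %d | peak %d | end %d\n",
              x$early_doy, x$middle_doy, x$peak_doy, x$end_doy))
  invisible(x)
}
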