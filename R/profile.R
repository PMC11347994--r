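#' Depth profile of pesticide content
#'
#' Averages a per-pixel content value (an abundance column from MCR-ALS, or
#' a peak-intensity map) over all lateral pixels within contiguous depth
#' bins — the "intensity at the same micron was averaged" view behind the
#' depth-content heat maps.
#'
#' @param content numeric vector of per-pixel content values, row-major by
#'   (depth, lateral), or an `abundance_map` column given via `component`.
#' @param cube a [hypermap] (supplies the grid geometry), or a list with
#'   `n_depth`, `n_lateral`, `depth_step_um`, `time_h`.
#' @param bin_um bin width in micrometres; default one pixel row
#'   (`depth_step_um`). Must be positive and not exceed the depth extent.
#' @param component column to use when `content` is a matrix.
#' @return a `depth_profile`: list with `depth_bins` (two-column matrix of
#'   lower/upper edges, um), `mean_content`, `n_pixels` per bin, `time_h`.
#' @export
depth_profile <- function(content, cube, bin_um = NULL, component = 1L) {
  if (is.matrix(content)) content <- content[, component]
  geo <- if (inherits(cube, "hypermap"))
    list(n_depth = cube$n_depth, n_lateral = cube$n_lateral,
         depth_step_um = cube$depth_step_um, time_h = cube$time_h)
  else cube
  npx <- geo$n_depth * geo$n_lateral
  if (length(content) != npx)
    stop_domain("content length must equal n_depth * n_lateral")
  extent <- (geo$n_depth - 1L) * geo$depth_step_um
  if (is.null(bin_um)) bin_um <- geo$depth_step_um
  if (bin_um <= 0) stop_domain("bin_um must be > 0")
  if (bin_um > max(extent, geo$depth_step_um))
    stop_domain("bin_um exceeds the depth extent")
  depths <- rep((seq_len(geo$n_depth) - 1L) * geo$depth_step_um,
                each = geo$n_lateral)
  n_bins <- max(1L, ceiling((extent + 1e-9) / bin_um))
  bin_idx <- pmin(floor(depths / bin_um) + 1L, n_bins)
  mean_content <- as.numeric(tapply(content, factor(bin_idx, levels = seq_len(n_bins)),
                                    mean))
  counts <- as.integer(table(factor(bin_idx, levels = seq_len(n_bins))))
  mean_content[counts == 0L] <- 0
  structure(list(depth_bins = cbind(lower = (seq_len(n_bins) - 1L) * bin_um,
                                    upper = seq_len(n_bins) * bin_um),
                 mean_content = mean_content,
                 n_pixels = counts,
                 time_h = geo$time_h),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> t = %g h, %d bins over [0, %g] um, peak content %.4g\n",
              x$time_h, nrow(x$depth_bins), max(x$depth_bins),
              max(x$mean_content)))
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ..., type = "l") {
  mid <- rowMeans(x$depth_bins)
  graphics::plot(mid, x$mean_content, type = type,
                 xlab = "Depth (um)", ylab = "Mean content (a.u.)",
                 main = sprintf("t = %g h", x$time_h), ...)
  invisible(x)
}

#' Total-content penetration curve over time
#'
#' Per time point, the mean of the depth-profile content values (the
#' per-cube average of the MCR-ALS result); the curve of relative total
#' content versus time, on which the non-monotone "weakening" of penetration
#' shows as a local decrease.
#'
#' @param profiles list of `depth_profile`s, one per time point, with
#'   consistent binning.
#' @param mean_over `"bins"` (default: mean of bin means) or `"pixels"`
#'   (pixel-count-weighted mean).
#' @return a `penetration_curve`: list with `times_h`, `total_content`,
#'   optional `trend` (see [bspline_trend]).
#' @export
total_content_curve <- function(profiles, mean_over = c("bins", "pixels")) {
  mean_over <- match.arg(mean_over)
  if (length(profiles) < 2L) stop_domain("need at least 2 time points")
  b1 <- profiles[[1L]]$depth_bins
  for (p in profiles)
    if (!isTRUE(all.equal(p$depth_bins, b1)))
      stop_domain("profiles have inconsistent depth binning")
  times <- vapply(profiles, function(p) p$time_h, 0)
  if (any(diff(times) <= 0)) stop_domain("profiles must be in increasing time order")
  total <- vapply(profiles, function(p) {
    if (mean_over == "bins") mean(p$mean_content)
    else sum(p$mean_content * p$n_pixels) / sum(p$n_pixels)
  }, 0)
  structure(list(times_h = times, total_content = total, trend = NULL),
            class = "penetration_curve")
}

#' @export
print.penetration_curve <- function(x, ...) {
  cat(sprintf("<penetration_curve> %d time points (%g-%g h), content range [%.4g, %.4g]\n",
              length(x$times_h), min(x$times_h), max(x$times_h),
              min(x$total_content), max(x$total_content)))
  invisible(x)
}

#' @export
plot.penetration_curve <- function(x, ...) {
  graphics::plot(x$times_h, x$total_content, pch = 16,
                 xlab = "Time (h)", ylab = "Total content (a.u.)", ...)
  if (!is.null(x$trend))
    graphics::lines(x$trend$grid, x$trend$values, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Cubic B-spline trend fit
#'
#' Least-squares cubic regression spline with `df` basis functions
#' (intercept included in the basis), evaluated on `grid` — the smooth trend
#' drawn through the content-change curves. With `df = n` the fit
#' interpolates the data; functions already in the spline space (e.g.
#' straight lines) are reproduced exactly.
#'
#' @param x data abscissae (e.g. times in hours).
#' @param y data values.
#' @param df number of basis functions, `4 <= df <= length(x)` for the cubic
#'   default (6 suits the standard 10-point time course: smooth but able to
#'   express the dip).
#' @param grid evaluation points; default 200 points spanning `range(x)`.
#' @return list with `grid`, `values` (trend on the grid), `fitted` (at the
#'   data points), `df`.
#' @export
bspline_trend <- function(x, y, df = 6L, grid = NULL) {
  n <- length(x)
  if (length(y) != n) stop_domain("x and y lengths differ")
  if (df > n) stop_domain("df must not exceed the number of points")
  if (df < 4L) stop_domain("cubic B-spline basis needs df >= 4")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 200L)
  knots <- if (df > 4L) stats::quantile(x, probs = seq_len(df - 4L) / (df - 3L),
                                        names = FALSE) else NULL
  B <- splines::bs(x, knots = knots, degree = 3L, intercept = TRUE,
                   Boundary.knots = range(x))
  fit <- stats::lm.fit(B, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  Bg <- splines::bs(grid, knots = knots, degree = 3L, intercept = TRUE,
                    Boundary.knots = range(x))
  list(grid = grid, values = as.numeric(Bg %*% beta),
       fitted = as.numeric(B %*% beta), df = df)
}

#' Add a B-spline trend to a penetration curve
#' @param curve a `penetration_curve`.
#' @inheritParams bspline_trend
#' @return the curve with its `trend` element filled in.
#' @export
curve_with_trend <- function(curve, df = 6L, grid = NULL) {
  curve$trend <- bspline_trend(curve$times_h, curve$total_content,
                               df = df, grid = grid)
  curve
}

#' Peak-intensity content map of a cube
#'
#' Fallback content read-out when unmixing is skipped: per-pixel maximum
#' baseline-corrected intensity in a characteristic-band window.
#'
#' @param cube a [hypermap] (assumed baseline-corrected).
#' @param center_cm1 band center (cm^-1), e.g. 1380 for thiram.
#' @param half_window_cm1 half-window (cm^-1), default 10.
#' @return numeric vector of per-pixel peak intensities (row-major).
#' @export
peak_content <- function(cube, center_cm1, half_window_cm1 = 10) {
  ax <- unclass(cube$axis)
  sel <- ax >= center_cm1 - half_window_cm1 & ax <= center_cm1 + half_window_cm1
  if (!any(sel)) stop_domain("window does not intersect the cube axis")
  apply(cube$spectra[, sel, drop = FALSE], 1L, max)
}
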