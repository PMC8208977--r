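#' Bivariate-normal reference bandwidth
#'
#' The reference ("ad hoc") smoothing parameter for a bivariate normal
#' kernel, `h_ref = sqrt(0.5 * (var(x) + var(y))) * n^(-1/6)`. The pipeline
#' fixes one h per temporal scale as the mean of `h_ref` over all
#' individual-by-window point sets at that scale (overridable, e.g. to the
#' values a given study reports).
#'
#' @param x,y point coordinates in metres.
#' @return bandwidth in metres.
#' @export
reference_bandwidth <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  v <- 0.5 * (var(x) + var(y))
  if (v == 0) stop("all points identical: zero-variance point set")
  sqrt(v) * length(x)^(-1 / 6)
}

#' Kernel-density home range
#'
#' Bivariate normal kernel density of a point set on a regular grid; the
#' home range is the smallest set of highest-density cells holding at least
#' `level` of the (discretized) probability mass, and its area is the cell
#' count times the cell area.
#'
#' @param x,y fix coordinates, metres. At least 2 distinct points.
#' @param h smoothing parameter (kernel SD), metres.
#' @param cell grid cell size, metres (default 250).
#' @param level isopleth probability level (default 0.95).
#' @param extent optional `c(xmin, xmax, ymin, ymax)`; default is the point
#'   bounding box padded by `3 * h` (grown automatically if smaller).
#' @return object of class `home_range`: density grid, logical membership
#'   matrix of the isopleth region, `h`, `level` and `area_km2`.
#' @export
kde_home_range <- function(x, y, h, cell = 250, level = 0.95, extent = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || (length(unique(x)) == 1 && length(unique(y)) == 1))
    stop("need >= 2 distinct points for a kernel home range")
  if (!is.numeric(h) || h <= 0) stop("h must be > 0")
  pad <- 3 * h
  ext <- c(min(x) - pad, max(x) + pad, min(y) - pad, max(y) + pad)
  if (!is.null(extent)) {
    grown <- extent[1] > ext[1] || extent[2] < ext[2] ||
      extent[3] > ext[3] || extent[4] < ext[4]
    ext <- c(min(extent[1], ext[1]), max(extent[2], ext[2]),
             min(extent[3], ext[3]), max(extent[4], ext[4]))
    if (grown)
      message("home-range extent grown to hold 3h padding")
  }
  gx <- seq(ext[1] + cell / 2, ext[2], by = cell)
  gy <- seq(ext[3] + cell / 2, ext[4], by = cell)
  ## separable kernel: D[i,j] = mean_k dnorm(gx_i - x_k) * dnorm(gy_j - y_k)
  Wx <- outer(gx, x, function(g, p) dnorm(g - p, sd = h))
  Wy <- outer(gy, y, function(g, p) dnorm(g - p, sd = h))
  D <- (Wx %*% t(Wy)) / length(x)
  mass <- D * cell^2
  ord <- order(D, decreasing = TRUE)
  cm <- cumsum(mass[ord]) / sum(mass)
  ncell <- which(cm >= level)[1]
  member <- matrix(FALSE, nrow(D), ncol(D))
  member[ord[seq_len(ncell)]] <- TRUE
  structure(list(density = raster_grid(D, origin = c(ext[1], ext[3]),
                                       cell = cell, label = "ud"),
                 member = member, h = h, level = level,
                 n_points = length(x),
                 area_km2 = ncell * cell^2 / 1e6),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat("<home_range> ", x$level * 100, "% isopleth, h = ", x$h, " m, ",
      x$n_points, " fixes\n  area = ", signif(x$area_km2, 5), " km^2 (",
      sum(x$member), " cells of ", x$density$cell, " m)\n", sep = "")
  invisible(x)
}

## is a point inside the isopleth region? (by its cell)
hr_contains <- function(hr, x, y) {
  g <- hr$density
  i <- floor((x - g$origin[1]) / g$cell) + 1
  j <- floor((y - g$origin[2]) / g$cell) + 1
  ok <- i >= 1 & i <= nrow(g$values) & j >= 1 & j <= ncol(g$values)
  out <- rep(FALSE, length(x))
  out[ok] <- hr$member[cbind(i[ok], j[ok])]
  out
}

#' Site fidelity: home-range overlap between consecutive time steps
#'
#' Proportion of the preceding step's home range that is re-used:
#' `area(region_t intersect region_t-1) / area(region_t-1)`. Both ranges
#' must share one grid geometry (build them with a common `extent` and
#' `cell`); a symmetric intersection-over-union variant is available.
#'
#' @param hr_t,hr_prev `home_range` objects on a common grid.
#' @param method `"previous"` (default; denominator = previous area) or
#'   `"union"` (intersection over union).
#' @return overlap proportion in `[0, 1]`.
#' @export
site_fidelity <- function(hr_t, hr_prev, method = c("previous", "union")) {
  method <- match.arg(method)
  gt <- hr_t$density; gp <- hr_prev$density
  if (!isTRUE(all.equal(gt$origin, gp$origin)) || gt$cell != gp$cell ||
      !identical(dim(gt$values), dim(gp$values)))
    stop("home ranges are not on a common grid geometry")
  inter <- sum(hr_t$member & hr_prev$member)
  denom <- switch(method,
                  previous = sum(hr_prev$member),
                  union = sum(hr_t$member | hr_prev$member))
  inter / denom
}

## KDE pair on a shared grid covering both point sets (used for fidelity)
kde_pair <- function(x1, y1, x2, y2, h, cell = 250, level = 0.95) {
  pad <- 3 * h
  ext <- c(min(x1, x2) - pad, max(x1, x2) + pad,
           min(y1, y2) - pad, max(y1, y2) + pad)
  list(kde_home_range(x1, y1, h, cell, level, extent = ext),
       kde_home_range(x2, y2, h, cell, level, extent = ext))
}
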