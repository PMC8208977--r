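#' Construct a regular raster grid
#'
#' Minimal single-band raster container in the same planar metre frame as
#' the trajectories: a value matrix indexed `[x, y]` with a lower-left
#' origin and square cells. `NA` cells are masked.
#'
#' @param values numeric matrix; rows index x (west to east), columns index
#'   y (south to north).
#' @param origin numeric `c(x, y)` of the lower-left corner, metres.
#' @param cell cell size in metres.
#' @param label layer label, e.g. `"ndvi_2016-03"` or `"hfi"`.
#' @param time_index optional month index for monthly layers.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell = 1000,
                        label = "layer", time_index = NA_integer_) {
  values <- as.matrix(values)
  if (!is.numeric(cell) || cell <= 0) stop("cell size must be > 0")
  structure(list(values = values, origin = as.numeric(origin),
                 cell = as.numeric(cell), label = label,
                 time_index = time_index),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat("<raster_grid> ", x$label, ": ", nrow(v), " x ", ncol(v),
      " cells of ", x$cell, " m; ", sum(is.na(v)), " masked\n", sep = "")
  cat("  origin (", x$origin[1], ", ", x$origin[2], "), value range [",
      signif(min(v, na.rm = TRUE), 4), ", ",
      signif(max(v, na.rm = TRUE), 4), "]\n", sep = "")
  invisible(x)
}

## cell-centre coordinate vectors
raster_centres <- function(r) {
  list(x = r$origin[1] + (seq_len(nrow(r$values)) - 0.5) * r$cell,
       y = r$origin[2] + (seq_len(ncol(r$values)) - 0.5) * r$cell)
}

## raster value at planar points (nearest cell); NA outside the extent
raster_value_at <- function(r, x, y) {
  i <- floor((x - r$origin[1]) / r$cell) + 1
  j <- floor((y - r$origin[2]) / r$cell) + 1
  ok <- i >= 1 & i <= nrow(r$values) & j >= 1 & j <= ncol(r$values)
  out <- rep(NA_real_, length(x))
  out[ok] <- r$values[cbind(i[ok], j[ok])]
  out
}

#' Temperature seasonality layer
#'
#' Per-cell standard deviation of mean monthly temperature across 12 aligned
#' monthly layers (population SD, n = 12). Cells missing in any month are
#' masked.
#'
#' @param monthly_temps list of 12 aligned `raster_grid` layers.
#' @return a `raster_grid` labelled `"temperature_seasonality"`.
#' @export
temperature_seasonality <- function(monthly_temps) {
  stopifnot(length(monthly_temps) == 12)
  dims <- vapply(monthly_temps, function(r) dim(r$values), integer(2))
  if (any(dims != dims[, 1])) stop("monthly layers are not aligned")
  arr <- array(unlist(lapply(monthly_temps, `[[`, "values")),
               dim = c(dim(monthly_temps[[1]]$values), 12))
  m <- apply(arr, c(1, 2), mean)            # NA propagates -> mask
  sd_pop <- sqrt(apply(sweep(arr, c(1, 2), m)^2, c(1, 2), mean))
  raster_grid(sd_pop, monthly_temps[[1]]$origin, monthly_temps[[1]]$cell,
              label = "temperature_seasonality")
}

#' Forward gap-fill of a monthly NDVI sequence
#'
#' A cell missing in month m takes that cell's value from month m - 1 after
#' month m - 1 has itself been filled; leading missing values stay masked.
#' Observed values are never altered.
#'
#' @param monthly_ndvi time-ordered list of `raster_grid` layers.
#' @return list with `monthly` (filled layers) and `annual` (per-cell mean
#'   of the filled layers; cells with no observation in any month stay
#'   masked, with a warning).
#' @export
ndvi_gapfill <- function(monthly_ndvi) {
  stopifnot(length(monthly_ndvi) >= 1)
  filled <- monthly_ndvi
  for (m in seq_along(filled)[-1]) {
    v <- filled[[m]]$values
    miss <- is.na(v)
    v[miss] <- filled[[m - 1]]$values[miss]
    filled[[m]]$values <- v
  }
  arr <- array(unlist(lapply(filled, `[[`, "values")),
               dim = c(dim(filled[[1]]$values), length(filled)))
  annual_v <- apply(arr, c(1, 2), function(z) {
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)
  })
  if (any(is.na(annual_v)))
    warning(sum(is.na(annual_v)),
            " cell(s) missing in every month; masked in annual NDVI",
            call. = FALSE)
  list(monthly = filled,
       annual = raster_grid(annual_v, filled[[1]]$origin, filled[[1]]$cell,
                            label = "ndvi_annual"))
}

#' Mean raster value within a home range
#'
#' Mean over raster cells whose centres fall inside the 95% region of the
#' home range; masked raster cells are excluded. Invariant to padding the
#' raster with masked cells.
#'
#' @param r a `raster_grid`.
#' @param hr a `home_range` (see [kde_home_range()]).
#' @return scalar mean, or `NA` (with a warning) when no unmasked cell
#'   centre lies inside the region.
#' @export
mean_within_range <- function(r, hr) {
  stopifnot(inherits(r, "raster_grid"), inherits(hr, "home_range"))
  cc <- raster_centres(r)
  idx <- which(!is.na(r$values), arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("raster fully masked within range; NA returned", call. = FALSE)
    return(NA_real_)
  }
  px <- cc$x[idx[, 1]]; py <- cc$y[idx[, 2]]
  inside <- hr_contains(hr, px, py)
  if (!any(inside)) {
    warning("no unmasked raster cell centre inside home range; NA returned",
            call. = FALSE)
    return(NA_real_)
  }
  mean(r$values[idx[inside, , drop = FALSE]])
}

#' Standardize a column of values
#'
#' Predictor mode (default): centre and scale, `(x - mean)/sd`. For
#' responses expressed in "standard deviation units" a scale-only mode
#' (`x / sd`) is available.
#'
#' @param x numeric vector with at least two distinct values.
#' @param center logical; subtract the mean first (default `TRUE`).
#' @param name column name used in error messages.
#' @return standardized vector with attributes `center` and `scale` for
#'   exact back-transformation.
#' @export
standardize <- function(x, center = TRUE, name = deparse(substitute(x))) {
  ok <- !is.na(x)
  s <- sd(x[ok])
  if (!is.finite(s) || s == 0)
    stop("cannot standardize '", name, "': zero variance")
  ctr <- if (center) mean(x[ok]) else 0
  structure((x - ctr) / s, center = ctr, scale = s)
}

#' Read / write plain-text rasters (ESRI ASCII grid)
#'
#' Text fixtures and interchange format for single-band layers: a 6-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows of values, north row first.
#'
#' @param r a `raster_grid`; `path` a file path.
#' @return `read_raster_ascii` returns a `raster_grid`.
#' @export
write_raster_ascii <- function(r, path) {
  v <- r$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", nrow(v)), paste("nrows", ncol(v)),
               paste("xllcorner", r$origin[1]), paste("yllcorner", r$origin[2]),
               paste("cellsize", r$cell), "NODATA_value -9999"), con)
  vv <- v; vv[is.na(vv)] <- -9999
  for (j in rev(seq_len(ncol(v))))   # north row first
    writeLines(paste(vv[, j], collapse = " "), con)
  invisible(path)
}

#' @rdname write_raster_ascii
#' @param label layer label for the returned grid.
#' @export
read_raster_ascii <- function(path, label = basename(path)) {
  ln <- readLines(path)
  hdr <- strsplit(trimws(ln[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  nx <- val[["ncols"]]; ny <- val[["nrows"]]
  rows <- lapply(ln[7:(6 + ny)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]]))
  m <- matrix(NA_real_, nx, ny)
  for (k in seq_len(ny)) m[, ny - k + 1] <- rows[[k]]
  m[m == val[["nodata_value"]]] <- NA
  raster_grid(m, origin = c(val[["xllcorner"]], val[["yllcorner"]]),
              cell = val[["cellsize"]], label = label)
}
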