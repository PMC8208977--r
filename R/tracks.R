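#' Read GPS fix tables into trajectories
#'
#' Reads a delimited text file of GPS fixes (one row per fix) and returns a
#' list of per-individual trajectories, time-sorted, with local clock time
#' attached and coordinates in a single planar metre frame. Longitude /
#' latitude input is projected with a transverse-Mercator projection centred
#' on the data centroid (or a user-supplied centre).
#'
#' @param path delimited text file with a header row.
#' @param col_map named list mapping the roles `id`, `time`, `x`, `y` (and
#'   optionally `sex`, `region`) to column names in the file.
#' @param sep field separator.
#' @param tz_offset_hours fixed offset (hours) added to the UTC timestamp to
#'   obtain local clock time; local time drives the day/night split.
#' @param lonlat logical; if `TRUE` the x/y columns are longitude/latitude
#'   in degrees and are projected to metres.
#' @param proj_centre optional `c(lon0, lat0)` projection centre; default is
#'   the centroid of all fixes.
#' @return named list of `trajectory` data frames (columns `individual_id`,
#'   `sex`, `region`, `t_utc`, `t_local`, `x`, `y`, `burst`), one per
#'   individual with at least two fixes.
#' @export
read_tracks <- function(path, col_map = list(id = "id", time = "timestamp",
                                             x = "x", y = "y",
                                             sex = "sex", region = "region"),
                        sep = ",", tz_offset_hours = 0, lonlat = FALSE,
                        proj_centre = NULL) {
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("id", "time", "x", "y")
  miss <- setdiff(need, names(col_map))
  if (length(miss)) stop("col_map must name columns for: ",
                         paste(miss, collapse = ", "))
  for (role in need) {
    if (!col_map[[role]] %in% names(raw))
      stop("column '", col_map[[role]], "' (", role, ") not found in ", path)
  }
  ts_chr <- as.character(raw[[col_map$time]])
  t_utc <- as.POSIXct(rep(NA_real_, length(ts_chr)), origin = "1970-01-01",
                      tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    todo <- is.na(t_utc)
    if (!any(todo)) break
    t_utc[todo] <- as.POSIXct(strptime(ts_chr[todo], fmt, tz = "UTC"))
  }
  bad <- which(is.na(t_utc))
  if (length(bad)) stop("unparseable timestamp at data line(s): ",
                        paste(head(bad, 5), collapse = ", "))
  x <- as.numeric(raw[[col_map$x]]); y <- as.numeric(raw[[col_map$y]])
  badc <- which(!is.finite(x) | !is.finite(y))
  if (length(badc)) stop("non-finite coordinate at data line(s): ",
                         paste(head(badc, 5), collapse = ", "))
  if (lonlat) {
    ctr <- proj_centre %||% c(mean(x), mean(y))
    pm <- project_tmerc(x, y, lon0 = ctr[1], lat0 = ctr[2])
    x <- pm$x; y <- pm$y
  }
  df <- data.frame(
    individual_id = as.character(raw[[col_map$id]]),
    sex = if (!is.null(col_map$sex) && col_map$sex %in% names(raw))
      as.character(raw[[col_map$sex]]) else NA_character_,
    region = if (!is.null(col_map$region) && col_map$region %in% names(raw))
      as.character(raw[[col_map$region]]) else NA_character_,
    t_utc = t_utc, x = x, y = y, stringsAsFactors = FALSE)
  df$t_local <- df$t_utc + tz_offset_hours * 3600
  out <- lapply(split(df, df$individual_id), function(d) {
    d <- d[order(d$t_utc), , drop = FALSE]
    dup <- duplicated(d$t_utc)
    if (any(dup)) {
      warning(sum(dup), " duplicate timestamp(s) for individual '",
              d$individual_id[1], "'; keeping first occurrence", call. = FALSE)
      d <- d[!dup, , drop = FALSE]
    }
    if (nrow(d) < 2) {
      warning("individual '", d$individual_id[1],
              "' has < 2 fixes; excluded", call. = FALSE)
      return(NULL)
    }
    new_trajectory(d)
  })
  out[!vapply(out, is.null, logical(1))]
}

new_trajectory <- function(d) {
  d <- d[, c("individual_id", "sex", "region", "t_utc", "t_local", "x", "y")]
  d$burst <- NA_integer_
  rownames(d) <- NULL
  class(d) <- c("trajectory", "data.frame")
  d
}

## Spherical transverse Mercator centred on (lon0, lat0); degrees -> metres.
## Adequate for regional extents; a full datum pipeline is out of scope.
project_tmerc <- function(lon, lat, lon0, lat0, R = 6371008.8) {
  lam <- (lon - lon0) * pi / 180
  phi <- lat * pi / 180
  phi0 <- lat0 * pi / 180
  B <- cos(phi) * sin(lam)
  list(x = R * atanh(B),
       y = R * (atan2(tan(phi), cos(lam)) - phi0))
}

#' Sequential speed filter
#'
#' Removes likely GPS fix errors: walking the track in time order, any fix
#' whose straight-line speed from the previous *retained* fix exceeds
#' `v_max_kmh` is dropped and the next fix is tested against the same
#' retained predecessor. The first fix is always retained. Idempotent.
#'
#' @param traj a `trajectory`.
#' @param v_max_kmh speed threshold in km/h (default 7).
#' @return the filtered `trajectory` (bursts reset to unsegmented).
#' @export
filter_speed <- function(traj, v_max_kmh = 7) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(v_max_kmh) || v_max_kmh <= 0)
    stop("v_max_kmh must be > 0")
  n <- nrow(traj)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  t_num <- as.numeric(traj$t_utc)
  for (i in seq_len(n)[-1]) {
    dt_h <- (t_num[i] - t_num[last]) / 3600
    d_km <- sqrt((traj$x[i] - traj$x[last])^2 +
                 (traj$y[i] - traj$y[last])^2) / 1000
    if (dt_h > 0 && d_km / dt_h <= v_max_kmh) {
      keep[i] <- TRUE
      last <- i
    }
  }
  out <- traj[keep, , drop = FALSE]
  out$burst <- NA_integer_
  rownames(out) <- NULL
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Fix-interval regularity report
#'
#' For each individual, the fraction of inter-fix intervals at most 2 h and
#' at most 3 h, plus a pooled row (`individual_id = "ALL"`). Used to verify
#' that fixes are near-hourly before step/turn construction.
#'
#' @param trajs list of `trajectory` objects.
#' @return data frame with columns `individual_id`, `n_intervals`,
#'   `frac_within_2h`, `frac_within_3h`.
#' @export
regularity_report <- function(trajs) {
  if (length(trajs) == 0)
    return(data.frame(individual_id = character(), n_intervals = integer(),
                      frac_within_2h = numeric(), frac_within_3h = numeric()))
  rows <- lapply(trajs, function(tr) {
    dt <- diff(as.numeric(tr$t_utc)) / 3600
    data.frame(individual_id = tr$individual_id[1],
               n_intervals = length(dt),
               frac_within_2h = mean(dt <= 2),
               frac_within_3h = mean(dt <= 3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  all_dt <- unlist(lapply(trajs, function(tr) diff(as.numeric(tr$t_utc)) / 3600))
  rbind(out, data.frame(individual_id = "ALL", n_intervals = length(all_dt),
                        frac_within_2h = mean(all_dt <= 2),
                        frac_within_3h = mean(all_dt <= 3)))
}

#' Split a trajectory into bursts at large time gaps
#'
#' Bursts are maximal runs of fixes whose internal inter-fix gaps are all at
#' most `gap_max_hours`; steps and turning angles are never constructed
#' across a burst boundary. Never reorders or drops fixes.
#'
#' @param traj a `trajectory`.
#' @param gap_max_hours maximum within-burst gap, hours (default 2).
#' @return the `trajectory` with its `burst` column populated (1, 2, ...).
#' @export
segment_bursts <- function(traj, gap_max_hours = 2) {
  stopifnot(inherits(traj, "trajectory"))
  if (!is.numeric(gap_max_hours) || gap_max_hours <= 0)
    stop("gap_max_hours must be > 0")
  dt <- diff(as.numeric(traj$t_utc)) / 3600
  traj$burst <- cumsum(c(1L, as.integer(dt > gap_max_hours)))
  traj
}

#' Write trajectories back to delimited text
#'
#' @param trajs list of `trajectory` objects.
#' @param path output file.
#' @export
write_tracks <- function(trajs, path) {
  df <- do.call(rbind, lapply(trajs, as.data.frame))
  df$t_utc <- format(df$t_utc, "%Y-%m-%dT%H:%M:%S")
  df$t_local <- format(df$t_local, "%Y-%m-%dT%H:%M:%S")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
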