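#' Movement distance in a window
#'
#' Sum of consecutive-fix Euclidean displacements (the step lengths), in
#' km. Steps never bridge burst gaps, so bursts are concatenated without
#' adding distance across missing data.
#'
#' @param steps a `step_series` restricted to the window of interest.
#' @return distance in km, or `NA` when the window holds no step.
#' @export
movement_distance <- function(steps) {
  if (nrow(steps) == 0) return(NA_real_)
  sum(steps$step) / 1000
}

#' Diurnality index
#'
#' For each calendar day d (local clock), `D_d = (day - night) / total`
#' where day is the summed length of steps starting in [06:00, 18:00) and
#' night the rest; the window index is the mean of `D_d` over days with
#' nonzero total distance. +1 is exclusively diurnal movement, -1
#' exclusively nocturnal.
#'
#' @param steps a `step_series` restricted to the window; `t_start` is the
#'   local clock time of each step's start fix.
#' @param day_start,day_end day window bounds in hours (defaults 6 and 18).
#' @return index in [-1, 1], or `NA` when every day has zero distance.
#' @export
diurnality <- function(steps, day_start = 6, day_end = 18) {
  if (nrow(steps) == 0) return(NA_real_)
  hr <- as.integer(format(steps$t_start, "%H"))
  is_day <- hr >= day_start & hr < day_end
  day_lab <- format(steps$t_start, "%Y-%m-%d")
  tot <- tapply(steps$step, day_lab, sum)
  dd <- tapply(steps$step * ifelse(is_day, 1, -1), day_lab, sum)
  keep <- tot > 0
  if (!any(keep)) return(NA_real_)
  mean(dd[keep] / tot[keep])
}

#' Proportion of steps decoded as exploratory
#'
#' @param states factor of decoded states for the steps in the window.
#' @return proportion in [0, 1], or `NA` with no decoded step.
#' @export
exploratory_proportion <- function(states) {
  states <- states[!is.na(states)]
  if (length(states) == 0) return(NA_real_)
  mean(states == "exploratory")
}

window_label <- function(t, scale) {
  format(t, if (scale == "monthly") "%Y-%m" else "%Y")
}

## fraction of window hours that contain at least one fix
window_coverage <- function(t_local, label, scale) {
  hours <- length(unique(format(t_local, "%Y-%m-%d %H")))
  if (scale == "monthly") {
    first <- as.POSIXct(paste0(label, "-01 00:00:00"), tz = "UTC")
    nh <- as.numeric(difftime(seq(first, by = "month", length.out = 2)[2],
                              first, units = "hours"))
  } else {
    first <- as.POSIXct(paste0(label, "-01-01 00:00:00"), tz = "UTC")
    nh <- as.numeric(difftime(seq(first, by = "year", length.out = 2)[2],
                              first, units = "hours"))
  }
  hours / nh
}

#' Assemble the behavior table
#'
#' One record per individual and time step (calendar month or calendar
#' year) holding the five behaviors: movement distance, 95% KDE home-range
#' area, site fidelity (overlap with the preceding consecutive step,
#' missing at the first retained step), diurnality, and the proportion of
#' steps decoded exploratory; plus, when rasters are supplied, the mean of
#' each covariate within the home range.
#'
#' Inclusion rules: monthly records require at least `min_coverage` of the
#' month's hours to carry a fix; annual records require a full calendar
#' year, i.e. every one of the 12 months at `min_coverage`. Exclusions are
#' recorded in the `exclusions` attribute.
#'
#' @param trajs list of speed-filtered, burst-segmented `trajectory`s.
#' @param steps pooled `step_series` built from `trajs`.
#' @param states decoded states aligned with `steps` (see
#'   [viterbi_decode()]); `NULL` leaves `exploratory_prop` missing.
#' @param scale `"monthly"` or `"annual"`.
#' @param h fixed KDE smoothing parameter (m); `NULL` (default) uses the
#'   mean reference bandwidth over all retained windows at this scale.
#' @param cell KDE grid cell (m). @param min_coverage monthly inclusion
#'   threshold. @param rasters optional covariate raster set, see
#'   [generate_rasters()] for the expected layout.
#' @param fidelity_method passed to [site_fidelity()].
#' @return data frame of class `behavior_table`; attributes `h_used` and
#'   `exclusions`.
#' @export
assemble_behavior_table <- function(trajs, steps, states = NULL,
                                    scale = c("monthly", "annual"),
                                    h = NULL, cell = 250,
                                    min_coverage = 0.5, rasters = NULL,
                                    fidelity_method = "previous") {
  scale <- match.arg(scale)
  stopifnot(inherits(steps, "step_series"))
  if (!is.null(states)) stopifnot(length(states) == nrow(steps))
  excl <- list()
  wins <- list()   # retained windows: list of (id, label, fixes idx, steps idx)
  for (tr in trajs) {
    id <- tr$individual_id[1]
    mlab <- window_label(tr$t_local, "monthly")
    mcov <- vapply(unique(mlab), function(l)
      window_coverage(tr$t_local[mlab == l], l, "monthly"), 0)
    ok_month <- names(mcov)[mcov >= min_coverage]
    for (l in setdiff(unique(mlab), ok_month))
      excl[[length(excl) + 1]] <- data.frame(
        individual_id = id, window = l,
        reason = sprintf("coverage %.2f < %.2f", mcov[[l]], min_coverage))
    labs <- if (scale == "monthly") ok_month else {
      yrs <- unique(substr(ok_month, 1, 4))
      full <- yrs[vapply(yrs, function(y)
        sum(startsWith(ok_month, y)) == 12, TRUE)]
      for (y in setdiff(unique(window_label(tr$t_local, "annual")), full))
        excl[[length(excl) + 1]] <- data.frame(
          individual_id = id, window = y,
          reason = "not a full calendar year of fixes")
      full
    }
    for (l in labs) {
      fx <- which(window_label(tr$t_local, scale) == l)
      wins[[length(wins) + 1]] <- list(id = id, label = l,
                                       sex = tr$sex[1], region = tr$region[1],
                                       x = tr$x[fx], y = tr$y[fx],
                                       t = tr$t_local[fx])
    }
  }
  if (!length(wins)) stop("no individual-window passes the inclusion rules")

  ## fixed smoothing parameter for this scale
  h_used <- h %||% mean(vapply(wins, function(w)
    reference_bandwidth(w$x, w$y), 0))

  skey <- paste(steps$individual_id, window_label(steps$t_start, scale))
  rows <- vector("list", length(wins))
  hrs <- vector("list", length(wins))
  for (k in seq_along(wins)) {
    w <- wins[[k]]
    sidx <- which(skey == paste(w$id, w$label))
    hr <- kde_home_range(w$x, w$y, h = h_used, cell = cell)
    hrs[[k]] <- hr
    st <- steps[sidx, , drop = FALSE]
    class(st) <- class(steps)
    rows[[k]] <- data.frame(
      individual_id = w$id, sex = w$sex, region = w$region,
      scale = scale, window = w$label,
      n_fixes = length(w$x),
      distance_km = movement_distance(st),
      home_range_km2 = hr$area_km2,
      site_fidelity = NA_real_,
      diurnality = diurnality(st),
      exploratory_prop = if (is.null(states)) NA_real_ else
        exploratory_proportion(states[sidx]),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  ## site fidelity between consecutive retained windows of one individual
  for (k in seq_along(wins)) {
    w <- wins[[k]]
    prev_lab <- prev_window(w$label, scale)
    j <- which(vapply(wins, function(v)
      v$id == w$id && v$label == prev_lab, TRUE))
    if (length(j) == 1) {
      pr <- kde_pair(w$x, w$y, wins[[j]]$x, wins[[j]]$y,
                     h = h_used, cell = cell)
      tab$site_fidelity[k] <- site_fidelity(pr[[1]], pr[[2]],
                                            method = fidelity_method)
    }
  }

  ## covariate extraction within the home range
  if (!is.null(rasters)) {
    tab$hfi <- tab$temperature_seasonality <- tab$rainfall <-
      tab$ndvi <- NA_real_
    for (k in seq_along(wins)) {
      hr <- hrs[[k]]; l <- wins[[k]]$label
      tab$hfi[k] <- mean_within_range(rasters$hfi, hr)
      tab$temperature_seasonality[k] <-
        mean_within_range(rasters$temperature_seasonality, hr)
      if (scale == "monthly") {
        if (!is.null(rasters$rainfall_monthly[[l]]))
          tab$rainfall[k] <- mean_within_range(rasters$rainfall_monthly[[l]], hr)
        if (!is.null(rasters$ndvi_monthly[[l]]))
          tab$ndvi[k] <- mean_within_range(rasters$ndvi_monthly[[l]], hr)
      } else {
        tab$rainfall[k] <- mean_within_range(rasters$rainfall_annual, hr)
        tab$ndvi[k] <- mean_within_range(rasters$ndvi_annual, hr)
      }
    }
  }

  attr(tab, "h_used") <- h_used
  attr(tab, "exclusions") <- if (length(excl))
    do.call(rbind, c(excl, list(make.row.names = FALSE))) else
      data.frame(individual_id = character(), window = character(),
                 reason = character())
  class(tab) <- c("behavior_table", "data.frame")
  tab
}

prev_window <- function(label, scale) {
  if (scale == "annual") return(as.character(as.integer(label) - 1))
  y <- as.integer(substr(label, 1, 4)); m <- as.integer(substr(label, 6, 7))
  if (m == 1) sprintf("%d-12", y - 1) else sprintf("%d-%02d", y, m - 1)
}

#' @export
print.behavior_table <- function(x, ...) {
  cat("<behavior_table> ", x$scale[1], " scale: ", nrow(x), " records, ",
      length(unique(x$individual_id)), " individuals; h = ",
      round(attr(x, "h_used")), " m; ", nrow(attr(x, "exclusions")),
      " window(s) excluded\n", sep = "")
  print(head(as.data.frame(x), 6))
  invisible(x)
}
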