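#' Simulation configuration
#'
#' Defaults emulate the study population this package was developed around:
#' 96 collared individuals in 7 regions at 1-h fix intervals over 18
#' months, a 2-state switching walk (encamped: short steps, weak
#' persistence; exploratory: long, persistent steps), day-favouring
#' diurnal modulation of the transition logits, home-range attraction, and
#' among-individual variation in four latent movement modifiers
#' (log step scale, exploratory-transition logit, diurnal amplitude, log
#' attraction weight).
#'
#' @param n_individuals,months,n_regions population structure.
#' @param fixes_per_hour fix rate (1 = hourly).
#' @param sex_ratio probability an individual is male.
#' @param hmm an `hmm_params` with the base emission and transition
#'   parameters.
#' @param Sigma_I_sim 4x4 PSD among-individual covariance of the latent
#'   modifiers, in the order above.
#' @param beta_sim named covariate effects on the exploratory-transition
#'   logit per SD of the raster value; names must match raster layers
#'   (`hfi`, `ndvi`).
#' @param diurnal_amplitude mean amplitude of the hour-of-day harmonic on
#'   the transition logits (> 0 favours daytime exploration).
#' @param attraction_rho home-range centre bias weight in [0, 1).
#' @param raster_spec list: `nx`, `ny` (cells), `cell` (m), `n_bumps`,
#'   `smoothness` (m), `ndvi_missing_frac`.
#' @param start first fix time (local clock).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 96, months = 18, n_regions = 7,
                       fixes_per_hour = 1, sex_ratio = 0.5,
                       hmm = hmm_params(mu = c(100, 1000),
                                        sigma = c(80, 600),
                                        ang_mean = c(0, 0),
                                        kappa = c(0.5, 2),
                                        Gamma = matrix(c(0.9, 0.1, 0.1, 0.9),
                                                       2, 2)),
                       Sigma_I_sim = default_sigma_i_sim(),
                       beta_sim = c(hfi = -0.5, ndvi = 0.5),
                       diurnal_amplitude = 0.8, attraction_rho = 0.3,
                       raster_spec = list(nx = 60, ny = 60, cell = 2000,
                                          n_bumps = 25, smoothness = 15000,
                                          ndvi_missing_frac = 0.1),
                       start = as.POSIXct("2016-01-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(hmm, "hmm_params"),
            sex_ratio >= 0, sex_ratio <= 1,
            attraction_rho >= 0, attraction_rho < 1)
  Sigma_I_sim <- as.matrix(Sigma_I_sim)
  ev <- eigen(Sigma_I_sim, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("Sigma_I_sim must be positive semi-definite")
  structure(list(n_individuals = n_individuals, months = months,
                 n_regions = n_regions, fixes_per_hour = fixes_per_hour,
                 sex_ratio = sex_ratio, hmm = hmm,
                 Sigma_I_sim = Sigma_I_sim, beta_sim = beta_sim,
                 diurnal_amplitude = diurnal_amplitude,
                 attraction_rho = attraction_rho,
                 raster_spec = raster_spec, start = start),
            class = "sim_config")
}

## latent order: log step scale, transition logit, diurnal amplitude,
## log attraction. Step scale and transition logit correlate (0.7): one
## dominant axis tying distance, home range and exploratory behavior.
default_sigma_i_sim <- function() {
  sds <- c(0.25, 0.5, 0.25, 0.3)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- 0.7
  diag(sds) %*% R %*% diag(sds)
}

## smooth random field: sum of Gaussian bumps, rescaled to [lo, hi]
smooth_field <- function(spec, lo, hi, centre_pull = 0) {
  nx <- spec$nx; ny <- spec$ny; cell <- spec$cell
  cx <- (seq_len(nx) - 0.5) * cell
  cy <- (seq_len(ny) - 0.5) * cell
  f <- matrix(0, nx, ny)
  for (b in seq_len(spec$n_bumps)) {
    bx <- runif(1, 0, nx * cell); by <- runif(1, 0, ny * cell)
    amp <- rnorm(1)
    f <- f + amp * outer(exp(-(cx - bx)^2 / (2 * spec$smoothness^2)),
                         exp(-(cy - by)^2 / (2 * spec$smoothness^2)))
  }
  rng <- range(f)
  v <- if (diff(rng) < 1e-12) matrix(mean(c(lo, hi)), nx, ny) else
    lo + (f - rng[1]) / diff(rng) * (hi - lo)
  v
}

#' Generate a synthetic covariate raster set
#'
#' Smooth random fields (sums of Gaussian bumps) scaled to plausible
#' ranges: static human-footprint and temperature-seasonality layers, an
#' annual-rainfall layer, and monthly rainfall and NDVI layers carrying a
#' shared seasonal sinusoid plus field noise. A configurable fraction of
#' NDVI cells is masked each month to exercise the gap-fill rule.
#'
#' @param spec raster spec, see [sim_config()].
#' @param months character vector of month labels, `"YYYY-MM"`.
#' @param seed integer seed; identical seeds give identical rasters.
#' @return list: `hfi`, `temperature_seasonality`, `rainfall_annual`,
#'   `rainfall_monthly` (named list), `ndvi_monthly` (named list, masked
#'   cells as `NA`).
#' @export
generate_rasters <- function(spec, months, seed = 1) {
  if (spec$nx <= 0 || spec$ny <= 0 || spec$cell <= 0)
    stop("raster dimensions and cell size must be positive")
  set.seed(seed)
  mk <- function(v, label, ti = NA_integer_)
    raster_grid(v, origin = c(0, 0), cell = spec$cell, label = label,
                time_index = ti)
  out <- list(
    hfi = mk(smooth_field(spec, 0, 50), "hfi"),
    temperature_seasonality =
      mk(smooth_field(spec, 0.3, 2), "temperature_seasonality"),
    rainfall_annual = mk(smooth_field(spec, 1500, 3000), "rainfall_annual"))
  mnum <- as.integer(substr(months, 6, 7))
  season <- sin(2 * pi * (mnum - 3) / 12)     # wet-season peak around March
  base_rain <- smooth_field(spec, 2, 8)
  base_ndvi <- smooth_field(spec, 0.5, 0.85)
  rainfall_monthly <- ndvi_monthly <- setNames(vector("list", length(months)),
                                               months)
  for (m in seq_along(months)) {
    rv <- pmax(base_rain * (1 + 0.6 * season[m]) +
                 matrix(rnorm(spec$nx * spec$ny, sd = 0.3), spec$nx), 0)
    rainfall_monthly[[m]] <- mk(rv, paste0("rainfall_", months[m]), m)
    nv <- pmin(pmax(base_ndvi + 0.05 * season[m] +
                      matrix(rnorm(spec$nx * spec$ny, sd = 0.02), spec$nx),
                    0), 1)
    if (spec$ndvi_missing_frac > 0)
      nv[runif(length(nv)) < spec$ndvi_missing_frac] <- NA
    ndvi_monthly[[m]] <- mk(nv, paste0("ndvi_", months[m]), m)
  }
  c(out, list(rainfall_monthly = rainfall_monthly,
              ndvi_monthly = ndvi_monthly))
}

month_seq <- function(start, months) {
  format(seq(start, by = "month", length.out = months), "%Y-%m")
}

#' Simulate a GPS-collared population with known ground truth
#'
#' Each individual draws a 4-vector of latent modifiers from
#' `Sigma_I_sim`, is assigned a region and a home-range centre, and moves
#' by a 2-state switching biased correlated random walk at hourly fixes:
#' the state chain's transition logits carry covariate terms (standardized
#' raster value at the current position times `beta_sim`), an hour-of-day
#' harmonic scaled by the individual's diurnal amplitude, and the
#' individual's transition modifier; step lengths are gamma draws for the
#' current state scaled by the individual's step modifier, and bearings
#' are von Mises draws centred on a rho-weighted compromise between the
#' previous bearing and the bearing to the centre.
#'
#' @param cfg a [sim_config()].
#' @param rasters a raster set from [generate_rasters()] (gap-filled NDVI
#'   is used for the covariate effect; missing cells contribute 0).
#' @param seed integer seed.
#' @return list: `trajs` (list of `trajectory`), `truth` (per-individual
#'   latent effects, centres, true state sequences, generating config).
#' @export
simulate_population <- function(cfg, rasters, seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  months <- month_seq(cfg$start, cfg$months)
  t_end <- seq(cfg$start, by = "month", length.out = cfg$months + 1)[cfg$months + 1]
  times <- seq(cfg$start, t_end - 3600, by = 3600 / cfg$fixes_per_hour)
  n_t <- length(times)
  hour <- as.integer(format(times, "%H"))
  mlab <- format(times, "%Y-%m")
  harmonic <- cos(2 * pi * (hour - 12) / 24)

  ext <- c(cfg$raster_spec$nx, cfg$raster_spec$ny) * cfg$raster_spec$cell
  ## region centres on an inner ring of the landscape
  th <- 2 * pi * (seq_len(cfg$n_regions) - 1) / cfg$n_regions
  rc <- cbind(ext[1] / 2 + 0.3 * ext[1] * cos(th),
              ext[2] / 2 + 0.3 * ext[2] * sin(th))
  region_of <- rep_len(seq_len(cfg$n_regions), cfg$n_individuals)

  ## standardized covariate lookups
  z_of <- function(r) {
    v <- r$values
    (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
  }
  z_hfi <- rasters$hfi
  z_hfi$values <- z_of(rasters$hfi)
  z_ndvi <- lapply(rasters$ndvi_monthly, function(r) {
    r$values <- z_of(r); r$values[is.na(r$values)] <- 0; r
  })
  b_hfi <- unname(cfg$beta_sim["hfi"] %||% 0)
  b_ndvi <- unname(cfg$beta_sim["ndvi"] %||% 0)
  if (is.na(b_hfi)) b_hfi <- 0
  if (is.na(b_ndvi)) b_ndvi <- 0

  L <- chol_psd(cfg$Sigma_I_sim)
  U <- matrix(rnorm(cfg$n_individuals * 4), cfg$n_individuals) %*% L
  colnames(U) <- c("log_step", "trans_logit", "diurnal", "log_attraction")
  sexes <- ifelse(runif(cfg$n_individuals) < cfg$sex_ratio, "male", "female")
  base_l12 <- qlogis(cfg$hmm$Gamma[1, 2])
  base_l21 <- qlogis(cfg$hmm$Gamma[2, 1])
  shape <- (cfg$hmm$mu / cfg$hmm$sigma)^2
  rate0 <- cfg$hmm$mu / cfg$hmm$sigma^2

  n_clamped <- 0L
  trajs <- vector("list", cfg$n_individuals)
  states_all <- vector("list", cfg$n_individuals)
  centres <- matrix(NA_real_, cfg$n_individuals, 2)
  for (i in seq_len(cfg$n_individuals)) {
    u <- U[i, ]
    centre <- rc[region_of[i], ] + rnorm(2, sd = 0.02 * ext[1])
    centres[i, ] <- centre
    amp <- cfg$diurnal_amplitude + u["diurnal"]
    rho <- min(cfg$attraction_rho * exp(u["log_attraction"]), 0.95)
    rate <- rate0 / exp(u["log_step"])   # scales the state step means
    x <- numeric(n_t); y <- numeric(n_t)
    s <- integer(n_t)
    x[1] <- centre[1]; y[1] <- centre[2]
    s[1] <- 1L
    bearing <- runif(1, -pi, pi)
    mi <- match(mlab, months)
    for (t in 2:n_t) {
      cov_term <- b_hfi * raster_value_at(z_hfi, x[t - 1], y[t - 1]) +
        b_ndvi * raster_value_at(z_ndvi[[mi[t]]], x[t - 1], y[t - 1])
      if (is.na(cov_term)) cov_term <- 0
      mod <- cov_term + amp * harmonic[t] + u["trans_logit"]
      p12 <- plogis(base_l12 + mod)
      p21 <- plogis(base_l21 - mod)
      s[t] <- if (s[t - 1] == 1L) {
        if (runif(1) < p12) 2L else 1L
      } else {
        if (runif(1) < p21) 1L else 2L
      }
      st <- s[t]
      len <- rgamma(1, shape = shape[st], rate = rate[st])
      to_centre <- atan2(centre[2] - y[t - 1], centre[1] - x[t - 1])
      vx <- (1 - rho) * cos(bearing) + rho * cos(to_centre)
      vy <- (1 - rho) * sin(bearing) + rho * sin(to_centre)
      target <- atan2(vy, vx)
      bearing <- rvonmises(1, target, cfg$hmm$kappa[st])
      x[t] <- x[t - 1] + len * cos(bearing)
      y[t] <- y[t - 1] + len * sin(bearing)
      if (x[t] < 0 || x[t] > ext[1] || y[t] < 0 || y[t] > ext[2]) {
        x[t] <- min(max(x[t], 0), ext[1])
        y[t] <- min(max(y[t], 0), ext[2])
        n_clamped <- n_clamped + 1L
      }
    }
    id <- sprintf("ele%03d", i)
    d <- data.frame(individual_id = id, sex = sexes[i],
                    region = sprintf("region%d", region_of[i]),
                    t_utc = times, t_local = times, x = x, y = y,
                    stringsAsFactors = FALSE)
    trajs[[i]] <- new_trajectory(d)
    names(trajs)[i] <- id
    states_all[[i]] <- factor(STATE_NAMES[s], levels = STATE_NAMES)
  }
  if (n_clamped > 0)
    warning(n_clamped, " position(s) clamped at the raster edge",
            call. = FALSE)
  names(trajs) <- vapply(trajs, function(t) t$individual_id[1], "")
  names(states_all) <- names(trajs)
  list(trajs = trajs,
       truth = list(u = U, centres = centres, region = region_of,
                    sex = sexes, states = states_all, months = months,
                    cfg = cfg, seed = seed))
}

## matrix square root M with t(M) %*% M = S, valid for any PSD S
## (including singular and exactly-zero matrices)
chol_psd <- function(S) {
  L <- try(chol(S), silent = TRUE)
  if (inherits(L, "try-error")) {
    e <- eigen(S, symmetric = TRUE)
    if (any(e$values < -1e-8)) stop("covariance matrix is not PSD")
    L <- diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
  }
  L
}

#' Simulate a behavior table from the hierarchical model
#'
#' Draws data directly from the Gaussian mixed model the fitting functions
#' assume: `y = X beta + u_individual + r_region + m_month + e`, with
#' among-individual effects drawn from `Sigma_I` (a scalar gives a
#' univariate table, a p x p matrix a p-trait table), iid region and month
#' intercepts, and residuals from `Sigma_resid`. Continuous covariates are
#' standard normal; sex is a per-individual Bernoulli. The generating
#' effects are returned as ground truth for recovery tests.
#'
#' @param n_ind,n_months,n_regions design sizes (every individual is
#'   observed in every month).
#' @param beta fixed-effect sizes: a named vector (univariate) or a
#'   p-column matrix with rownames naming predictors; allowed names are
#'   `sex` and any continuous covariate label.
#' @param Sigma_I among-individual (co)variance (scalar or matrix).
#' @param V_region,V_month scalar variances of the region / month
#'   intercepts (shared across traits).
#' @param Sigma_resid residual (co)variance (scalar or matrix).
#' @param traits trait names for the multivariate case.
#' @param sex_ratio probability male. @param seed integer seed.
#' @return list: `table` (data frame with response column(s), `sex`, the
#'   continuous covariates, `individual_id`, `region`, `window`) and
#'   `truth` (all generating effects and components).
#' @export
simulate_behavior_table <- function(n_ind = 96, n_months = 18,
                                    n_regions = 7, beta = NULL,
                                    Sigma_I = 0.3, V_region = 0.05,
                                    V_month = 0.1, Sigma_resid = 0.6,
                                    traits = c("distance", "home_range",
                                               "diurnality", "exploratory"),
                                    sex_ratio = 0.5, seed = 1) {
  set.seed(seed)
  Sigma_I <- as.matrix(Sigma_I)
  Sigma_resid <- as.matrix(Sigma_resid)
  p <- nrow(Sigma_I)
  stopifnot(nrow(Sigma_resid) == p, V_region >= 0, V_month >= 0)
  if (p > 1) stopifnot(length(traits) == p) else traits <- "y"
  n <- n_ind * n_months
  ind <- rep(seq_len(n_ind), each = n_months)
  mon <- rep(seq_len(n_months), n_ind)
  reg <- rep_len(seq_len(n_regions), n_ind)[ind]
  sex <- ifelse(runif(n_ind) < sex_ratio, "male", "female")[ind]

  if (is.null(beta)) beta <- matrix(0, 0, p)
  if (is.vector(beta)) beta <- matrix(beta, ncol = p,
                                      dimnames = list(names(beta), NULL))
  covars <- setdiff(rownames(beta), "sex")
  Xc <- matrix(rnorm(n * length(covars)), n,
               dimnames = list(NULL, covars))
  fixed <- matrix(0, n, p)
  if ("sex" %in% rownames(beta))
    fixed <- fixed + (sex == "male") %o% beta["sex", ]
  for (cv in covars) fixed <- fixed + Xc[, cv] %o% beta[cv, ]

  u <- matrix(rnorm(n_ind * p), n_ind) %*% chol_psd(Sigma_I)
  r <- matrix(rnorm(n_regions * p, sd = sqrt(V_region)), n_regions)
  m <- matrix(rnorm(n_months * p, sd = sqrt(V_month)), n_months)
  e <- matrix(rnorm(n * p), n) %*% chol_psd(Sigma_resid)
  Y <- fixed + u[ind, , drop = FALSE] + r[reg, , drop = FALSE] +
    m[mon, , drop = FALSE] + e
  colnames(Y) <- traits

  tab <- data.frame(individual_id = sprintf("ele%03d", ind),
                    sex = sex, region = sprintf("region%d", reg),
                    window = sprintf("m%02d", mon),
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(Xc), as.data.frame(Y))
  list(table = tab,
       truth = list(beta = beta, u = u, r = r, m = m, e = e,
                    Sigma_I = Sigma_I, V_region = V_region,
                    V_month = V_month, Sigma_resid = Sigma_resid,
                    traits = traits, seed = seed))
}
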