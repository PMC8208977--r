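STATE_NAMES <- c("encamped", "exploratory")

#' Parameters of the 2-state movement HMM
#'
#' Emission distributions are gamma step lengths (parametrized by mean and
#' SD, converted internally to shape/rate) and von Mises turning angles,
#' with an optional point mass at exact-zero step length per state. State 1
#' is "encamped" (short steps, weak directional persistence), state 2
#' "exploratory"; the exploratory state is defined as the one with the
#' larger step-length mean, which resolves label switching after fitting.
#'
#' @param mu,sigma gamma step-length mean and SD per state, metres (> 0).
#' @param ang_mean von Mises turning-angle mean per state, radians.
#' @param kappa von Mises concentration per state (>= 0).
#' @param Gamma 2x2 transition probability matrix, rows on the simplex.
#' @param zero_mass per-state probability of an exact-zero step, in [0, 1).
#' @param delta initial state distribution; default the stationary
#'   distribution of `Gamma`.
#' @return object of class `hmm_params`.
#' @export
hmm_params <- function(mu, sigma, ang_mean = c(0, 0), kappa,
                       Gamma, zero_mass = c(0, 0), delta = NULL) {
  stopifnot(length(mu) == 2, length(sigma) == 2, length(kappa) == 2,
            length(ang_mean) == 2, length(zero_mass) == 2)
  if (any(mu <= 0) || any(sigma <= 0)) stop("mu and sigma must be > 0")
  if (any(kappa < 0)) stop("kappa must be >= 0")
  if (any(zero_mass < 0) || any(zero_mass >= 1))
    stop("zero_mass must be in [0, 1)")
  Gamma <- as.matrix(Gamma)
  if (!identical(dim(Gamma), c(2L, 2L)) || any(Gamma < 0) ||
      any(abs(rowSums(Gamma) - 1) > 1e-8))
    stop("Gamma must be 2x2 with rows summing to 1")
  delta <- delta %||% stationary_dist(Gamma)
  structure(list(mu = mu, sigma = sigma, ang_mean = wrap_angle(ang_mean),
                 kappa = kappa, Gamma = Gamma, zero_mass = zero_mass,
                 delta = delta / sum(delta)),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat("<hmm_params> 2-state movement model\n")
  tab <- rbind(`step mean (m)` = x$mu, `step SD (m)` = x$sigma,
               `angle mean (rad)` = x$ang_mean, kappa = x$kappa,
               `zero mass` = x$zero_mass)
  colnames(tab) <- STATE_NAMES
  print(round(tab, 4))
  cat("transition matrix:\n")
  print(round(x$Gamma, 4))
  cat("initial distribution:", round(x$delta, 4), "\n")
  invisible(x)
}

stationary_dist <- function(Gamma) {
  ## left eigenvector of a 2x2 stochastic matrix, closed form
  p12 <- Gamma[1, 2]; p21 <- Gamma[2, 1]
  if (p12 + p21 == 0) return(c(0.5, 0.5))
  c(p21, p12) / (p12 + p21)
}

#' Build a step series from a burst-segmented trajectory
#'
#' Step i is the displacement from fix i to fix i + 1 within one burst; the
#' turning angle is the signed change in bearing between consecutive steps
#' (counter-clockwise positive, in (-pi, pi]), undefined at the first step
#' of each burst. Bursts of fewer than 2 fixes contribute no steps.
#'
#' @param traj a `trajectory` with bursts populated (see [segment_bursts()]).
#' @return data frame of class `step_series`: `individual_id`, `burst`,
#'   `t_start` (local clock), `step` (m), `angle` (rad or NA), `zero_flag`.
#' @export
build_step_series <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  if (anyNA(traj$burst)) stop("bursts not populated; run segment_bursts()")
  out <- lapply(split(seq_len(nrow(traj)), traj$burst), function(idx) {
    if (length(idx) < 2) return(NULL)
    dx <- diff(traj$x[idx]); dy <- diff(traj$y[idx])
    len <- sqrt(dx^2 + dy^2)
    bearing <- atan2(dy, dx)
    ang <- c(NA_real_, wrap_angle(diff(bearing)))
    ## a zero-length step has no bearing: its own angle and the next
    ## step's angle are undefined
    zero <- len == 0
    ang[zero] <- NA
    ang[c(FALSE, zero[-length(zero)])] <- NA
    data.frame(individual_id = traj$individual_id[idx[1]],
               burst = traj$burst[idx[1]],
               t_start = traj$t_local[idx[-length(idx)]],
               step = len, angle = ang, zero_flag = zero,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out[!vapply(out, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(individual_id = character(), burst = integer(),
                      t_start = as.POSIXct(character(), tz = "UTC"),
                      step = numeric(), angle = numeric(),
                      zero_flag = logical())
  class(out) <- c("step_series", "data.frame")
  out
}

## per-step log emission densities, n x 2; missing angles contribute 1
emission_logdens <- function(params, steps) {
  n <- nrow(steps)
  ld <- matrix(0, n, 2)
  has_ang <- !is.na(steps$angle)
  for (s in 1:2) {
    shape <- (params$mu[s] / params$sigma[s])^2
    rate <- params$mu[s] / params$sigma[s]^2
    l <- numeric(n)
    zero <- steps$step == 0
    if (any(zero)) {
      l[zero] <- if (params$zero_mass[s] > 0) log(params$zero_mass[s]) else -Inf
    }
    l[!zero] <- log1p(-params$zero_mass[s]) +
      dgamma(steps$step[!zero], shape = shape, rate = rate, log = TRUE)
    l[has_ang] <- l[has_ang] +
      dvonmises(steps$angle[has_ang], params$ang_mean[s], params$kappa[s],
                log = TRUE)
    ld[, s] <- l
  }
  ld
}

burst_starts <- function(steps) {
  key <- paste(steps$individual_id, steps$burst)
  which(!duplicated(key))
}

#' Forward log-likelihood of a step series
#'
#' Scaled forward recursion, run independently over each burst of each
#' individual (bursts multiply; the chain restarts at the initial
#' distribution at every burst start). The emission density is the
#' zero-mass-mixed gamma step-length density times the von Mises
#' turning-angle density, with missing angles contributing a factor of 1.
#'
#' @param params an `hmm_params`.
#' @param steps a `step_series`.
#' @return scalar log-likelihood.
#' @export
forward_loglik <- function(params, steps) {
  stopifnot(inherits(params, "hmm_params"))
  if (nrow(steps) == 0) return(0)
  ll <- hmm_forward_cpp(emission_logdens(params, steps), params$Gamma,
                        params$delta, burst_starts(steps))
  if (is.nan(ll)) stop("non-finite HMM log-likelihood")
  ll
}

## unconstrained working parametrization <-> hmm_params
## (log mu/sigma; angle mean and kappa jointly via (kappa cos m, kappa sin m);
##  logit off-diagonal transition probabilities; logit zero mass if estimated)
hmm_par2work <- function(p, est_zero) {
  w <- c(log(p$mu), log(p$sigma),
         p$kappa * cos(p$ang_mean), p$kappa * sin(p$ang_mean),
         qlogis(pmin(pmax(c(p$Gamma[1, 2], p$Gamma[2, 1]), 1e-6), 1 - 1e-6)))
  if (est_zero) w <- c(w, qlogis(pmin(pmax(p$zero_mass, 1e-6), 1 - 1e-6)))
  w
}

hmm_work2par <- function(w, est_zero) {
  u <- w[5:6]; v <- w[7:8]
  kappa <- sqrt(u^2 + v^2)
  ang <- ifelse(kappa > 0, atan2(v, u), 0)
  off <- plogis(w[9:10])
  zm <- if (est_zero) plogis(w[11:12]) else c(0, 0)
  hmm_params(mu = exp(w[1:2]), sigma = exp(w[3:4]), ang_mean = ang,
             kappa = kappa,
             Gamma = matrix(c(1 - off[1], off[1], off[2], 1 - off[2]),
                            2, 2, byrow = TRUE),
             zero_mass = zm)
}

## moment-based start: split steps at the median, method-of-moments gamma
hmm_moment_start <- function(steps) {
  len <- steps$step[steps$step > 0]
  med <- stats::median(len)
  lo <- len[len <= med]; hi <- len[len > med]
  mstart <- function(z) c(mean(z), max(sd(z), 0.1 * mean(z), 1e-6))
  m1 <- mstart(lo); m2 <- mstart(hi)
  hmm_params(mu = c(m1[1], m2[1]), sigma = c(m1[2], m2[2]),
             ang_mean = c(0, 0), kappa = c(0.5, 1),
             Gamma = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
}

#' Fit the 2-state movement HMM by maximum likelihood
#'
#' Numerically maximizes [forward_loglik()] over an unconstrained working
#' parametrization (log step mean/SD, turning-angle mean and concentration
#' via their Cartesian pair, logit transition probabilities), taking the
#' best of `n_restarts` optimizations from a moment-based start and random
#' perturbations of it. States are label-resolved so that "exploratory" is
#' the state with the larger step-length mean. One pooled fit across
#' individuals is the default analysis choice; pass a subset of steps for
#' per-individual fits. The zero-inflation mass is only estimated when the
#' data contain exact-zero steps.
#'
#' @param steps a `step_series` (>= 50 steps).
#' @param n_restarts number of optimizer starts (default 10).
#' @param seed integer seed for the start perturbations.
#' @param start optional `hmm_params` start (used as the unperturbed start).
#' @return object of class `elehmm`: fitted `hmm_params`, log-likelihood,
#'   convergence report, and the data used.
#' @export
fit_hmm <- function(steps, n_restarts = 10, seed = 1, start = NULL) {
  stopifnot(inherits(steps, "step_series"))
  if (nrow(steps) < 50) stop("need >= 50 steps to fit the HMM")
  est_zero <- any(steps$step == 0)
  base <- start %||% hmm_moment_start(steps)
  if (est_zero && all(base$zero_mass == 0))
    base$zero_mass <- rep(mean(steps$step == 0), 2)
  w0 <- hmm_par2work(base, est_zero)
  bs <- burst_starts(steps)
  negll <- function(w) {
    p <- try(hmm_work2par(w, est_zero), silent = TRUE)
    if (inherits(p, "try-error")) return(1e10)
    ld <- suppressWarnings(emission_logdens(p, steps))
    if (any(is.nan(ld))) return(1e10)   # overflowed proposal; reject
    ll <- hmm_forward_cpp(ld, p$Gamma, p$delta, bs)
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  best <- NULL
  conv <- data.frame(restart = seq_len(n_restarts), loglik = NA_real_,
                     converged = FALSE)
  for (r in seq_len(n_restarts)) {
    w <- if (r == 1) w0 else w0 + rnorm(length(w0), sd = 0.3)
    fit <- try(optim(w, negll, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    conv$loglik[r] <- -fit$value
    conv$converged[r] <- fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !any(conv$converged))
    stop("no HMM restart converged; log-likelihoods: ",
         paste(signif(conv$loglik, 6), collapse = ", "))
  params <- hmm_work2par(best$par, est_zero)
  ## label resolution: exploratory = larger step mean
  if (params$mu[1] > params$mu[2]) params <- hmm_permute(params)
  if (max(params$kappa) > 50 || min(diag(params$Gamma)) < 1e-4)
    warning("parameter at or near boundary; data may not support 2 states",
            call. = FALSE)
  structure(list(params = params, loglik = -best$value,
                 n_steps = nrow(steps), n_par = length(best$par),
                 restarts = conv, est_zero = est_zero, steps = steps),
            class = "elehmm")
}

hmm_permute <- function(p) {
  hmm_params(mu = rev(p$mu), sigma = rev(p$sigma),
             ang_mean = rev(p$ang_mean), kappa = rev(p$kappa),
             Gamma = p$Gamma[2:1, 2:1], zero_mass = rev(p$zero_mass))
}

#' @export
print.elehmm <- function(x, ...) {
  cat("2-state movement HMM fit:", x$n_steps, "steps, log-likelihood",
      round(x$loglik, 2), "\n")
  print(x$params)
  cat(sum(x$restarts$converged), "of", nrow(x$restarts),
      "restarts converged\n")
  invisible(x)
}

#' @export
logLik.elehmm <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_steps,
            class = "logLik")
}

#' @export
coef.elehmm <- function(object, ...) {
  p <- object$params
  c(mu_encamped = p$mu[1], mu_exploratory = p$mu[2],
    sigma_encamped = p$sigma[1], sigma_exploratory = p$sigma[2],
    ang_mean_encamped = p$ang_mean[1], ang_mean_exploratory = p$ang_mean[2],
    kappa_encamped = p$kappa[1], kappa_exploratory = p$kappa[2],
    gamma_11 = p$Gamma[1, 1], gamma_22 = p$Gamma[2, 2])
}

#' Viterbi decoding of movement states
#'
#' Most likely state path under the model, computed exactly per burst by
#' dynamic programming; ties are broken toward the encamped state.
#'
#' @param params an `hmm_params` or a fitted `elehmm`.
#' @param steps a `step_series`; defaults to the steps stored in a fit.
#' @return factor vector of decoded states, one per step.
#' @export
viterbi_decode <- function(params, steps = NULL) {
  if (inherits(params, "elehmm")) {
    steps <- steps %||% params$steps
    params <- params$params
  }
  stopifnot(inherits(params, "hmm_params"))
  if (nrow(steps) == 0)
    return(factor(character(), levels = STATE_NAMES))
  idx <- hmm_viterbi_cpp(emission_logdens(params, steps), params$Gamma,
                         params$delta, burst_starts(steps))
  factor(STATE_NAMES[idx], levels = STATE_NAMES)
}

#' Simulate a step series from HMM parameters
#'
#' States follow the Markov chain (`delta`, `Gamma`); lengths and angles are
#' drawn from the state's gamma / von Mises emissions (with the state's
#' zero mass). A single burst, hourly steps. Used for model validation.
#'
#' @param params an `hmm_params`.
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @param t0 start time of the first step (local clock).
#' @return list with `steps` (a `step_series`) and `states` (true states).
#' @export
simulate_hmm_track <- function(params, n_steps, seed = 1,
                               t0 = as.POSIXct("2016-01-01 00:00:00",
                                               tz = "UTC")) {
  stopifnot(inherits(params, "hmm_params"), is_count(n_steps))
  set.seed(seed)
  s <- integer(n_steps)
  s[1] <- sample(1:2, 1, prob = params$delta)
  for (i in seq_len(n_steps)[-1])
    s[i] <- sample(1:2, 1, prob = params$Gamma[s[i - 1], ])
  shape <- (params$mu / params$sigma)^2
  rate <- params$mu / params$sigma^2
  len <- rgamma(n_steps, shape = shape[s], rate = rate[s])
  zm <- params$zero_mass[s]
  len[runif(n_steps) < zm] <- 0
  ang <- rep(NA_real_, n_steps)
  for (st in 1:2) {
    k <- which(s == st)
    if (length(k))
      ang[k] <- rvonmises(length(k), params$ang_mean[st], params$kappa[st])
  }
  ang[1] <- NA  # first step of the burst has no turning angle
  ang[len == 0] <- NA
  ang[c(FALSE, (len == 0)[-n_steps])] <- NA
  steps <- data.frame(individual_id = "sim", burst = 1L,
                      t_start = t0 + 3600 * (seq_len(n_steps) - 1),
                      step = len, angle = ang, zero_flag = len == 0,
                      stringsAsFactors = FALSE)
  class(steps) <- c("step_series", "data.frame")
  list(steps = steps, states = factor(STATE_NAMES[s], levels = STATE_NAMES))
}
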