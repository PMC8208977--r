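# Independent oracles and fixture builders used across the suite.

# Brute-force HMM likelihood: sum over all 2^n state paths of
# delta[s1] e1(s1) * prod Gamma[s_{i-1}, s_i] e_i(s_i).
# Emission densities computed directly from the distributions, not via
# the package's emission code path.
enum_emission <- function(params, steps) {
  n <- nrow(steps)
  e <- matrix(NA_real_, n, 2)
  for (s in 1:2) {
    shape <- (params$mu[s] / params$sigma[s])^2
    rate <- params$mu[s] / params$sigma[s]^2
    for (i in seq_len(n)) {
      len <- steps$step[i]
      d <- if (len == 0) params$zero_mass[s] else
        (1 - params$zero_mass[s]) * dgamma(len, shape = shape, rate = rate)
      if (!is.na(steps$angle[i])) {
        a <- steps$angle[i]
        d <- d * exp(params$kappa[s] * cos(a - params$ang_mean[s])) /
          (2 * pi * besselI(params$kappa[s], 0))
      }
      e[i, s] <- d
    }
  }
  e
}

# bursts are independent: the chain restarts at delta in each
enum_loglik <- function(params, steps) {
  sum(vapply(split(seq_len(nrow(steps)), steps$burst), function(idx)
    enum_loglik_one(params, steps[idx, , drop = FALSE]), 0))
}

enum_loglik_one <- function(params, steps) {
  e <- enum_emission(params, steps)
  n <- nrow(steps)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- params$delta[s[1]] * e[1, s[1]]
    if (n > 1) for (i in 2:n)
      pr <- pr * params$Gamma[s[i - 1], s[i]] * e[i, s[i]]
    tot <- tot + pr
  }
  log(tot)
}

enum_viterbi <- function(params, steps) {
  unlist(lapply(split(seq_len(nrow(steps)), steps$burst), function(idx)
    enum_viterbi_one(params, steps[idx, , drop = FALSE])), use.names = FALSE)
}

enum_viterbi_one <- function(params, steps) {
  e <- enum_emission(params, steps)
  n <- nrow(steps)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  best <- -Inf; best_s <- NULL
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- log(params$delta[s[1]]) + log(e[1, s[1]])
    if (n > 1) for (i in 2:n)
      pr <- pr + log(params$Gamma[s[i - 1], s[i]]) + log(e[i, s[i]])
    if (pr > best) { best <- pr; best_s <- unname(s) }
  }
  best_s
}

# random small HMM instance (params + steps, possibly several bursts)
random_hmm_instance <- function(n_steps) {
  mu <- sort(runif(2, 50, 2000))
  p <- hmm_params(mu = mu, sigma = runif(2, 30, 800),
                  ang_mean = runif(2, -pi, pi), kappa = runif(2, 0, 3),
                  Gamma = {
                    a <- runif(1, 0.05, 0.95); b <- runif(1, 0.05, 0.95)
                    matrix(c(1 - a, a, b, 1 - b), 2, 2, byrow = TRUE)
                  })
  n_bursts <- sample(1:2, 1)
  burst <- sort(sample(seq_len(n_bursts), n_steps, replace = TRUE))
  steps <- data.frame(individual_id = "t", burst = burst,
                      t_start = as.POSIXct("2016-01-01", tz = "UTC") +
                        3600 * seq_len(n_steps),
                      step = rgamma(n_steps, 2, rate = 1 / 500),
                      angle = ifelse(duplicated(burst),
                                     runif(n_steps, -pi, pi), NA),
                      zero_flag = FALSE)
  class(steps) <- c("step_series", "data.frame")
  list(params = p, steps = steps)
}

# trajectory builder from coordinate/time vectors
make_traj <- function(x, y, t, id = "a", sex = "female", region = "r1") {
  d <- data.frame(individual_id = id, sex = sex, region = region,
                  t_utc = t, t_local = t, x = x, y = y,
                  stringsAsFactors = FALSE)
  d$burst <- NA_integer_
  class(d) <- c("trajectory", "data.frame")
  d
}

hourly <- function(n, start = "2016-01-01 00:00:00")
  as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1)

# step series builder with explicit local start times
make_steps <- function(len, t_start, angle = NA, id = "a", burst = 1L) {
  s <- data.frame(individual_id = id, burst = burst, t_start = t_start,
                  step = len, angle = angle, zero_flag = len == 0,
                  stringsAsFactors = FALSE)
  class(s) <- c("step_series", "data.frame")
  s
}

well_separated_params <- function()
  hmm_params(mu = c(100, 1000), sigma = c(80, 600), ang_mean = c(0, 0),
             kappa = c(0.5, 2),
             Gamma = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
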