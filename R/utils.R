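`%||%` <- function(a, b) if (is.null(a)) b else a

#' @useDynLib elemove, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats acf dgamma dnorm optim quantile rbinom rgamma rnorm runif
#'   rWishart sd setNames var rmultinom
#' @importFrom utils read.csv write.csv head
NULL

## von Mises density and sampler (no circular-statistics package required).
## Density uses the exponentially scaled Bessel function for stability at
## large concentration.
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  stopifnot(all(kappa >= 0))
  ld <- kappa * (cos(x - mu) - 1) -
    log(2 * pi) - log(besselI(kappa, 0, expon.scaled = TRUE))
  if (log) ld else exp(ld)
}

## Best & Fisher (1979) rejection sampler; kappa = 0 falls back to uniform.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 1e-8) {
    return(runif(n, -pi, pi))
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      take <- seq_len(min(sum(ok), n - got))
      out[got + take] <- th[take]
      got <- got + length(take)
    }
  }
  wrap_angle(out + mu)
}

## wrap to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

## mean and equal-tailed 95% interval of a vector of posterior draws
post_summary <- function(x, probs = c(0.025, 0.975)) {
  q <- quantile(x, probs = probs, names = FALSE)
  c(mean = mean(x), lower = q[1], upper = q[2])
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 1 && x == round(x)
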