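#' MCMC run settings
#'
#' The full preset matches the analysis this package reproduces (850,000
#' iterations, 50,000 burn-in, thinning 400); the test preset keeps the
#' same retained-draw count (2,000) at a fraction of the cost and is the
#' default for interactive work and the test suite.
#'
#' @param n_iter,burnin,thin iteration counts; `thin` must divide
#'   `n_iter - burnin`.
#' @return list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 8500, burnin = 500, thin = 4) {
  stopifnot(n_iter > burnin, thin >= 1,
            (n_iter - burnin) %% thin == 0)
  structure(list(n_iter = n_iter, burnin = burnin, thin = thin),
            class = "mcmc_control")
}

#' @rdname mcmc_control
#' @export
mcmc_control_full <- function() mcmc_control(850000, 50000, 400)

## default priors: residual inverse-gamma (V = 1, nu = 0.002);
## random effects parameter-expanded (V = 1, nu = 1, alpha_V = 625)
default_prior <- function() {
  list(resid = list(V = 1, nu = 0.002),
       random = list(V = 1, nu = 1, alpha_V = 625),
       beta_V = 1e8)
}

#' Fit a Bayesian Gaussian mixed model by conjugate Gibbs sampling
#'
#' Univariate linear mixed model for one behavior: fixed effects plus
#' independent random intercepts per grouping factor, Gaussian residuals.
#' The sampler uses conjugate normal updates for coefficients and random
#' intercepts, scaled-inverse-chi-squared updates for variances, and
#' parameter expansion for the random-effect variances (working multiplier
#' with a normal(0, alpha_V) prior), which keeps mixing healthy when a
#' variance is near zero. The response (after the optional log transform)
#' and all continuous predictors are standardized internally; factors
#' enter as treatment-coded dummies. Reported random-effect variances are
#' on the effective (expanded) scale.
#'
#' @param formula model formula, e.g.
#'   `distance_km ~ sex + ndvi + hfi + temperature_seasonality + rainfall`.
#' @param data a `behavior_table` or plain data frame; rows with missing
#'   response or predictors are dropped (logged via message).
#' @param random character vector of grouping columns, e.g.
#'   `c("individual_id", "region", "window")`.
#' @param transform `"identity"` or `"log"` (applied to the response
#'   before standardization; log is the default choice for strictly
#'   positive right-skewed areas).
#' @param control an [mcmc_control()]. @param seed integer seed.
#' @param prior prior list (see `default_prior`); `NULL` for defaults.
#' @param scale_response,center_response standardization of the response;
#'   `center_response = FALSE` gives pure "SD units" scaling.
#' @param fixed_variances optional named list
#'   (`resid` plus one entry per random term) freezing all variances:
#'   the sampler then draws only coefficients and intercepts from their
#'   exact conditional posteriors (used for conjugate-submodel checks).
#' @return object of class `eleglmm` holding the retained draws (fixed
#'   effects and variance components), the design, and scaling metadata.
#' @export
fit_univariate <- function(formula, data,
                           random = intersect(c("individual_id", "region",
                                                "window"), names(data)),
                           transform = c("identity", "log"),
                           control = mcmc_control(), seed = 1,
                           prior = NULL, scale_response = TRUE,
                           center_response = TRUE,
                           fixed_variances = NULL) {
  transform <- match.arg(transform)
  prior <- prior %||% default_prior()
  resp_name <- all.vars(formula)[1]
  vars <- c(all.vars(formula), random)
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  if (transform == "log") keep <- keep & data[[resp_name]] > 0
  if (any(!keep))
    message(sum(!keep), " row(s) dropped (missing response/predictor",
            if (transform == "log") " or non-positive response", ")")
  d <- data[keep, , drop = FALSE]
  y_raw <- d[[resp_name]]
  if (transform == "log") y_raw <- log(y_raw)
  resp_center <- if (center_response) mean(y_raw) else 0
  resp_scale <- if (scale_response) sd(y_raw) else 1
  y <- (y_raw - resp_center) / resp_scale

  ## standardize continuous predictors in place; record scaling
  rhs_vars <- setdiff(all.vars(formula), resp_name)
  cov_scaling <- list()
  for (v in rhs_vars) {
    if (is.numeric(d[[v]])) {
      z <- standardize(d[[v]], name = v)
      cov_scaling[[v]] <- c(center = attr(z, "center"),
                            scale = attr(z, "scale"),
                            min = min(d[[v]]), max = max(d[[v]]))
      d[[v]] <- as.numeric(z)
    }
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(formula)), d)
  groups <- lapply(random, function(g) factor(d[[g]]))
  names(groups) <- random

  draws <- gibbs_univariate(y, X, groups, control, seed, prior,
                            fixed_variances)
  structure(list(draws = draws, X = X, y = y, groups = groups,
                 formula = formula, random = random,
                 transform = transform,
                 scaling = list(resp_center = resp_center,
                                resp_scale = resp_scale,
                                covariates = cov_scaling),
                 control = control, seed = seed, prior = prior,
                 n_obs = length(y)),
            class = "eleglmm")
}

## All location effects (beta and every random-intercept block, on the
## parameter-expanded working scale) are drawn in one joint Gaussian
## update from the mixed-model equations; single-site updates mix
## arbitrarily slowly when a fixed effect is confounded with a grouping
## factor (e.g. sex, constant within individual). The normal-equation
## blocks are precomputed once; only the working multipliers rescale them.
gibbs_univariate <- function(y, X, groups, control, seed, prior,
                             fixed_variances = NULL) {
  set.seed(seed)
  n <- length(y); p <- ncol(X)
  K <- length(groups)
  gi <- lapply(groups, function(g) as.integer(g))
  q <- vapply(gi, max, 0L)
  ng <- lapply(seq_len(K), function(k) tabulate(gi[[k]], q[k]))
  fixed <- !is.null(fixed_variances)

  ## block offsets in theta = (beta, v_1, ..., v_K)
  D <- p + sum(q)
  off <- cumsum(c(p, q))
  blk <- lapply(seq_len(K), function(k) (off[k] + 1):off[k + 1])

  ## fixed cross-product blocks of the design [X, Z_1, ..., Z_K]
  XtX <- crossprod(X)
  Xty <- as.numeric(crossprod(X, y))
  XtZ <- lapply(seq_len(K), function(k) t(rowsum(X, gi[[k]])))   # p x q_k
  Zty <- lapply(seq_len(K), function(k) rowsum_vec(y, gi[[k]], q[k]))
  ZtZ <- list()
  for (k in seq_len(K)) for (j in seq_len(K)) if (j < k)
    ZtZ[[paste(k, j)]] <- unclass(table(gi[[k]], gi[[j]]))

  alpha <- rep(1, K)
  vtil <- rep(1, K)                       # working-scale variances
  Ve <- var(y)
  if (fixed) {
    Ve <- fixed_variances$resid
    vtil <- vapply(names(groups), function(g) fixed_variances[[g]], 0)
  }
  nu0 <- prior$resid$nu; V0 <- prior$resid$V
  nu1 <- prior$random$nu; V1 <- prior$random$V
  aV <- prior$random$alpha_V

  n_keep <- (control$n_iter - control$burnin) / control$thin
  par_names <- c(colnames(X), paste0("V_", names(groups)), "V_resid")
  out <- matrix(NA_real_, n_keep, length(par_names),
                dimnames = list(NULL, par_names))
  row <- 0L
  v <- lapply(q, function(qk) rep(0, qk))
  beta <- rep(0, p)

  for (it in seq_len(control$n_iter)) {
    ## joint (beta, v) | variances, alpha
    Q <- matrix(0, D, D)
    rhs <- numeric(D)
    Q[1:p, 1:p] <- XtX / Ve + diag(1 / prior$beta_V, p)
    rhs[1:p] <- Xty / Ve
    for (k in seq_len(K)) {
      bk <- blk[[k]]
      Q[1:p, bk] <- alpha[k] * XtZ[[k]] / Ve
      Q[bk, 1:p] <- t(Q[1:p, bk])
      Q[bk, bk] <- diag(alpha[k]^2 * ng[[k]] / Ve + 1 / vtil[k], q[k])
      rhs[bk] <- alpha[k] * Zty[[k]] / Ve
      for (j in seq_len(K)) if (j < k) {
        Q[bk, blk[[j]]] <- alpha[k] * alpha[j] * ZtZ[[paste(k, j)]] / Ve
        Q[blk[[j]], bk] <- t(Q[bk, blk[[j]]])
      }
    }
    ch <- chol(Q)
    mu <- backsolve(ch, forwardsolve(t(ch), rhs))
    theta <- as.numeric(mu + backsolve(ch, rnorm(D)))
    beta <- theta[1:p]
    for (k in seq_len(K)) v[[k]] <- theta[blk[[k]]]
    fit_fix <- as.numeric(X %*% beta)

    if (!fixed) {
      ## working variances, expansion multipliers, residual variance
      for (k in seq_len(K)) {
        vtil[k] <- 1 / rgamma(1, (nu1 + q[k]) / 2,
                              rate = (nu1 * V1 + sum(v[[k]]^2)) / 2)
        res <- y - fit_fix
        for (j in setdiff(seq_len(K), k))
          res <- res - alpha[j] * v[[j]][gi[[j]]]
        w <- v[[k]][gi[[k]]]
        prec_a <- sum(w^2) / Ve + 1 / aV
        mean_a <- sum(w * res) / Ve / prec_a
        alpha[k] <- rnorm(1, mean_a, sqrt(1 / prec_a))
      }
      e <- y - fit_fix
      for (k in seq_len(K)) e <- e - alpha[k] * v[[k]][gi[[k]]]
      Ve <- 1 / rgamma(1, (nu0 + n) / 2, rate = (nu0 * V0 + sum(e^2)) / 2)
    }

    if (it > control$burnin && (it - control$burnin) %% control$thin == 0) {
      row <- row + 1L
      out[row, ] <- c(beta, alpha^2 * vtil, Ve)
    }
  }
  out
}

## fast grouped sum returning a vector indexed 1..q
rowsum_vec <- function(x, gi, q) {
  s <- numeric(q)
  rs <- rowsum(x, gi)
  s[as.integer(rownames(rs))] <- rs
  s
}

#' @export
print.eleglmm <- function(x, ...) {
  cat("Bayesian Gaussian mixed model (Gibbs):",
      deparse(x$formula), "\n")
  cat("  ", x$n_obs, " obs; random intercepts: ",
      paste(x$random, collapse = ", "), "; transform: ", x$transform,
      "\n  ", nrow(x$draws), " retained draws (",
      x$control$n_iter, "/", x$control$burnin, "/", x$control$thin, ")\n",
      sep = "")
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' @export
coef.eleglmm <- function(object, ...) colMeans(object$draws)

#' @export
summary.eleglmm <- function(object, ...) {
  fe <- fixed_effect_summary(object)
  vc_names <- grep("^V_", colnames(object$draws), value = TRUE)
  vc <- t(apply(object$draws[, vc_names, drop = FALSE], 2, post_summary))
  r <- repeatability(object)
  r2 <- r_squared(object)
  ess <- effective_sample_size(object)
  out <- list(fixed = fe, variances = vc, repeatability = r,
              r_squared = r2, ess = ess,
              low_ess = any(ess[vc_names] < 100))
  class(out) <- "summary.eleglmm"
  out
}

#' @export
print.summary.eleglmm <- function(x, ...) {
  cat("Fixed effects (standardized scale):\n")
  print(x$fixed, digits = 3)
  cat("\nVariance components:\n")
  print(round(x$variances, 4))
  cat("\nAdjusted repeatability R_adj:",
      sprintf("%.3f (%.3f, %.3f)", x$repeatability["mean"],
              x$repeatability["lower"], x$repeatability["upper"]), "\n")
  cat(sprintf("R2: marginal %.3f, conditional %.3f\n",
              x$r_squared["marginal", "mean"],
              x$r_squared["conditional", "mean"]))
  if (x$low_ess)
    cat("NOTE: low effective sample size (< 100) on a variance component;",
        "treat this model's estimates with caution\n")
  invisible(x)
}

#' Adjusted repeatability
#'
#' Proportion of phenotypic variance attributable to among-individual
#' differences after controlling for the fixed effects:
#' `V_individual / (V_individual + V_region [+ V_month] + V_residual)`,
#' computed per posterior draw and summarized by its mean, kernel-density
#' mode and equal-tailed 95% interval.
#'
#' @param fit an `eleglmm`.
#' @param individual name of the individual-level random term.
#' @return named vector `mean`, `mode`, `lower`, `upper`.
#' @export
repeatability <- function(fit, individual = "individual_id") {
  dr <- fit$draws
  vind <- dr[, paste0("V_", individual)]
  vtot <- rowSums(dr[, grep("^V_", colnames(dr)), drop = FALSE])
  r <- vind / vtot
  s <- post_summary(r)
  dens <- stats::density(r)
  c(mean = unname(s["mean"]), mode = dens$x[which.max(dens$y)],
    lower = unname(s["lower"]), upper = unname(s["upper"]))
}

#' Fixed-effect summary table
#'
#' Posterior mean, equal-tailed 95% credible interval and a significance
#' flag (interval excludes zero) for each coefficient, on the
#' standardized scale so effect sizes are comparable across traits.
#'
#' @param fit an `eleglmm` (or `eleglmm_mv`; coefficients are then
#'   labelled `trait.coefficient`).
#' @return data frame with columns `coefficient`, `mean`, `lower`,
#'   `upper`, `significant`.
#' @export
fixed_effect_summary <- function(fit) {
  b <- beta_draws(fit)
  s <- t(apply(b, 2, post_summary))
  data.frame(coefficient = colnames(b), mean = s[, "mean"],
             lower = s[, "lower"], upper = s[, "upper"],
             significant = s[, "lower"] > 0 | s[, "upper"] < 0,
             row.names = NULL)
}

beta_draws <- function(fit) {
  if (inherits(fit, "eleglmm_mv")) {
    d <- fit$beta_draws
    m <- do.call(cbind, lapply(seq_len(dim(d)[3]), function(tr) {
      b <- d[, , tr, drop = FALSE][, , 1]
      colnames(b) <- paste(fit$traits[tr], colnames(fit$X), sep = ".")
      b
    }))
    return(m)
  }
  fit$draws[, colnames(fit$X), drop = FALSE]
}

#' Percent change in a response across a covariate's observed range
#'
#' Predicted response at the covariate's observed maximum versus minimum,
#' other covariates at their means and factors at the reference level,
#' back-transformed to the raw response scale (undoing standardization
#' and any log transform), reported as `100 * (high - low) / low` with a
#' posterior credible interval.
#'
#' @param fit an `eleglmm`. @param covariate covariate name.
#' @return named vector `mean`, `lower`, `upper` (percent).
#' @export
percent_change <- function(fit, covariate) {
  sc <- fit$scaling$covariates[[covariate]]
  if (is.null(sc) || !covariate %in% colnames(fit$X))
    stop("covariate '", covariate, "' is not in the fitted model")
  z_lo <- (sc["min"] - sc["center"]) / sc["scale"]
  z_hi <- (sc["max"] - sc["center"]) / sc["scale"]
  b <- fit$draws[, colnames(fit$X), drop = FALSE]
  x0 <- colMeans(fit$X)            # covariates at standardized mean
  x0[grep("^sex", names(x0))] <- 0 # factors at reference level
  lp0 <- as.numeric(b %*% x0)
  bc <- b[, covariate]
  back <- function(lp) {
    r <- lp * fit$scaling$resp_scale + fit$scaling$resp_center
    if (fit$transform == "log") exp(r) else r
  }
  lo <- back(lp0 + bc * (z_lo - x0[covariate]))
  hi <- back(lp0 + bc * (z_hi - x0[covariate]))
  post_summary(100 * (hi - lo) / lo)
}

#' Marginal and conditional R-squared
#'
#' Per draw, the fixed-effect linear-predictor variance over the data
#' `V_fixed = var(X beta)` gives `marginal = V_fixed / (V_fixed +
#' sum(V_random) + V_resid)` and `conditional = (V_fixed + sum(V_random))
#' / (same denominator)`.
#'
#' @param fit an `eleglmm`.
#' @return matrix with rows `marginal`, `conditional` and columns `mean`,
#'   `lower`, `upper`.
#' @export
r_squared <- function(fit) {
  b <- fit$draws[, colnames(fit$X), drop = FALSE]
  lp <- fit$X %*% t(b)
  vfix <- apply(lp, 2, var)
  vr <- rowSums(fit$draws[, paste0("V_", fit$random), drop = FALSE])
  ve <- fit$draws[, "V_resid"]
  denom <- vfix + vr + ve
  rbind(marginal = post_summary(vfix / denom),
        conditional = post_summary((vfix + vr) / denom))
}

#' Effective sample size of MCMC draws
#'
#' Geyer's initial-positive-sequence estimator: the autocorrelation time
#' is `-1 + 2 * sum(G_m)` over consecutive non-negative pairs
#' `G_m = rho_2m + rho_2m+1`, truncated at the first negative pair.
#'
#' @param x a fitted `eleglmm`/`eleglmm_mv` (all parameters), a draws
#'   matrix, or a single chain.
#' @return named vector of ESS values.
#' @export
effective_sample_size <- function(x) {
  if (inherits(x, "eleglmm")) x <- x$draws
  if (inherits(x, "eleglmm_mv"))
    x <- cbind(beta_draws(x), V_I = x$cov_draws[[1]][, 1, 1])
  if (is.matrix(x)) return(apply(x, 2, ess1))
  ess1(x)
}

ess1 <- function(x) {
  n <- length(x)
  stopifnot(n >= 10)
  if (var(x) == 0) {
    warning("constant chain: ESS undefined, reported as 0", call. = FALSE)
    return(0)
  }
  rho <- as.numeric(acf(x, lag.max = min(n - 1, 2000),
                        plot = FALSE)$acf)  # rho[1] is lag 0
  tau <- 0
  m <- 1
  while (m + 1 <= length(rho)) {
    g <- rho[m] + rho[m + 1]
    if (g < 0) break
    tau <- tau + 2 * g
    m <- m + 2
  }
  tau <- max(tau - 1, 1e-12)
  min(n / tau, n)
}
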