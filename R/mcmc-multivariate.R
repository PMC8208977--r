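#' Fit the multi-response hierarchical model
#'
#' Gaussian multi-response mixed model on the monthly behavior table:
#' every trait gets the same fixed-effect design, and unstructured
#' covariance matrices are fitted at the individual, region, month and
#' residual (within-individual) levels. The Gibbs sampler uses
#' matrix-normal conditional updates for the coefficient block and the
#' per-group random vectors, and conjugate inverse-Wishart updates for
#' each covariance level (weakly informative scale `0.01 * I`, degrees of
#' freedom `n_traits + 1`). Traits and continuous predictors are
#' standardized internally. Default trait set: the four behaviors with
#' nonzero monthly repeatability (site fidelity excluded).
#'
#' @param data data frame with one row per individual-month.
#' @param traits response columns (standardized internally), in the order
#'   to be used for all reported matrices.
#' @param fixed character vector of fixed-effect columns (continuous or
#'   factor).
#' @param random character vector of grouping columns; the first is
#'   treated as the individual (among-individual) level.
#' @param transform named character vector of per-trait transforms
#'   (`"log"` entries are log-transformed before standardization).
#' @param control an [mcmc_control()]. @param seed integer seed.
#' @param prior list with `df0` and `S0_scale` for every level.
#' @return object of class `eleglmm_mv`: `beta_draws`
#'   (draw x coefficient x trait), `cov_draws` (per level: draw x p x p),
#'   design and scaling metadata.
#' @export
fit_multivariate <- function(data,
                             traits = c("distance", "home_range",
                                        "diurnality", "exploratory"),
                             fixed = intersect(c("sex", "ndvi", "hfi",
                                                 "temperature_seasonality",
                                                 "rainfall"), names(data)),
                             random = intersect(c("individual_id", "region",
                                                  "window"), names(data)),
                             transform = NULL,
                             control = mcmc_control(), seed = 1,
                             prior = list(df0 = length(traits) + 1,
                                          S0_scale = 0.01)) {
  stopifnot(all(traits %in% names(data)), length(random) >= 1)
  p <- length(traits)
  keep <- stats::complete.cases(data[, c(traits, fixed, random), drop = FALSE])
  if (any(!keep)) message(sum(!keep), " row(s) dropped (missing values)")
  d <- data[keep, , drop = FALSE]

  Y <- matrix(NA_real_, nrow(d), p, dimnames = list(NULL, traits))
  for (j in seq_len(p)) {
    yj <- d[[traits[j]]]
    tr_j <- if (is.null(transform)) NA_character_ else
      unname(transform[traits[j]])
    if (identical(tr_j, "log")) yj <- log(yj)
    Y[, j] <- as.numeric(standardize(yj, name = traits[j]))
  }
  for (v in fixed) if (is.numeric(d[[v]]))
    d[[v]] <- as.numeric(standardize(d[[v]], name = v))
  X <- if (length(fixed))
    stats::model.matrix(stats::as.formula(paste("~", paste(fixed, collapse = "+"))), d)
  else matrix(1, nrow(d), 1, dimnames = list(NULL, "(Intercept)"))
  groups <- lapply(random, function(g) factor(d[[g]]))
  names(groups) <- random

  res <- gibbs_multivariate(Y, X, groups, control, seed, prior)
  structure(list(beta_draws = res$beta, cov_draws = res$cov,
                 traits = traits, X = X, Y = Y, random = random,
                 control = control, seed = seed, prior = prior,
                 n_obs = nrow(d)),
            class = "eleglmm_mv")
}

gibbs_multivariate <- function(Y, X, groups, control, seed, prior) {
  set.seed(seed)
  n <- nrow(Y); p <- ncol(Y); k <- ncol(X)
  K <- length(groups)
  gi <- lapply(groups, function(g) as.integer(g))
  q <- vapply(gi, max, 0L)
  ng <- lapply(seq_len(K), function(kk) tabulate(gi[[kk]], q[kk]))
  XtX <- crossprod(X)
  XtX_inv <- solve(XtX)
  L_xtx <- t(chol(XtX_inv))    # lower
  S0 <- diag(prior$S0_scale, p)
  df0 <- prior$df0

  B <- matrix(0, k, p)
  U <- lapply(q, function(qk) matrix(0, qk, p))
  Sig <- lapply(seq_len(K), function(kk) diag(p))
  R <- diag(p)

  n_keep <- (control$n_iter - control$burnin) / control$thin
  beta_out <- array(NA_real_, c(n_keep, k, p),
                    dimnames = list(NULL, colnames(X), colnames(Y)))
  cov_out <- lapply(seq_len(K + 1), function(kk)
    array(NA_real_, c(n_keep, p, p)))
  names(cov_out) <- c(names(groups), "residual")
  row <- 0L

  riw <- function(df, S) {
    ## inverse-Wishart draw via stats::rWishart on the inverse scale
    chol2inv(chol(rWishart(1, df, chol2inv(chol(S)))[, , 1]))
  }

  ranef_rows <- function(excl = 0L) {
    s <- matrix(0, n, p)
    for (kk in seq_len(K)) if (kk != excl)
      s <- s + U[[kk]][gi[[kk]], , drop = FALSE]
    s
  }

  for (it in seq_len(control$n_iter)) {
    Rinv <- chol2inv(chol(R))

    ## coefficient block: matrix-normal conditional (flat prior)
    Yr <- Y - ranef_rows()
    Bhat <- XtX_inv %*% crossprod(X, Yr)
    B <- Bhat + L_xtx %*% matrix(rnorm(k * p), k, p) %*% chol(R)
    fit_fix <- X %*% B

    ## random vectors per level, batched over groups with equal size
    for (kk in seq_len(K)) {
      res <- Y - fit_fix - ranef_rows(excl = kk)
      Sinv <- chol2inv(chol(Sig[[kk]]))
      S <- rowsum(res, gi[[kk]])                # q x p group sums
      Sfull <- matrix(0, q[kk], p)
      Sfull[as.integer(rownames(S)), ] <- S
      M <- Sfull %*% Rinv                       # q x p
      for (nj in unique(ng[[kk]])) {
        idx <- which(ng[[kk]] == nj)
        Prec <- nj * Rinv + Sinv
        ch <- chol(Prec)                        # upper
        mu <- t(backsolve(ch, forwardsolve(t(ch), t(M[idx, , drop = FALSE]))))
        Z <- matrix(rnorm(length(idx) * p), p)
        U[[kk]][idx, ] <- mu + t(backsolve(ch, Z))
      }
      Sig[[kk]] <- riw(df0 + q[kk], S0 + crossprod(U[[kk]]))
    }

    ## residual covariance
    E <- Y - fit_fix - ranef_rows()
    R <- riw(df0 + n, S0 + crossprod(E))

    if (it > control$burnin && (it - control$burnin) %% control$thin == 0) {
      row <- row + 1L
      beta_out[row, , ] <- B
      for (kk in seq_len(K)) cov_out[[kk]][row, , ] <- Sig[[kk]]
      cov_out[[K + 1]][row, , ] <- R
    }
  }
  list(beta = beta_out, cov = cov_out)
}

#' @export
print.eleglmm_mv <- function(x, ...) {
  cat("Multi-response Gaussian mixed model (Gibbs): ",
      length(x$traits), " traits [", paste(x$traits, collapse = ", "),
      "], ", x$n_obs, " obs\n  covariance levels: ",
      paste(names(x$cov_draws), collapse = ", "), "; ",
      dim(x$beta_draws)[1], " retained draws\n", sep = "")
  cat("posterior-mean among-individual matrix:\n")
  print(round(apply(x$cov_draws[[1]], c(2, 3), mean), 3))
  invisible(x)
}

#' Among-individual correlations and variances
#'
#' Per-draw correlations `r_I(x, y) = COV_I(x, y) / sqrt(V_I(x) V_I(y))`
#' from the among-individual covariance level, summarized by posterior
#' means and equal-tailed 95% intervals. The returned object prints in the
#' conventional layout: among-individual variances on the diagonal,
#' covariances below, correlations above, credible intervals in
#' parentheses.
#'
#' @param fit an `eleglmm_mv` (or a draw x p x p array of among-individual
#'   matrices).
#' @return list of class `ai_correlations`: matrices `estimate`, `lower`,
#'   `upper` (diagonal = V_I, lower triangle = COV_I, upper = r_I).
#' @export
among_individual_correlations <- function(fit) {
  arr <- if (inherits(fit, "eleglmm_mv")) fit$cov_draws[[1]] else fit
  traits <- if (inherits(fit, "eleglmm_mv")) fit$traits else
    paste0("trait", seq_len(dim(fit)[2]))
  p <- dim(arr)[2]
  est <- lo <- hi <- matrix(NA_real_, p, p, dimnames = list(traits, traits))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    x <- if (i == j) arr[, i, i] else if (i > j) arr[, i, j] else
      arr[, i, j] / sqrt(arr[, i, i] * arr[, j, j])
    s <- post_summary(x)
    est[i, j] <- s["mean"]; lo[i, j] <- s["lower"]; hi[i, j] <- s["upper"]
  }
  structure(list(estimate = est, lower = lo, upper = hi, traits = traits),
            class = "ai_correlations")
}

#' @export
print.ai_correlations <- function(x, digits = 2, ...) {
  p <- length(x$traits)
  out <- matrix("", p, p, dimnames = list(x$traits, x$traits))
  for (i in seq_len(p)) for (j in seq_len(p)) {
    star <- if (i != j && (x$lower[i, j] > 0 || x$upper[i, j] < 0)) "*" else ""
    out[i, j] <- sprintf("%.*f (%.*f, %.*f)%s", digits, x$estimate[i, j],
                         digits, x$lower[i, j], digits, x$upper[i, j], star)
  }
  cat("Among-individual (co)variance matrix",
      "(diagonal V_I; below COV_I; above r_I; * = CI excludes 0):\n")
  print(out, quote = FALSE)
  invisible(x)
}

#' Behavioral-syndrome eigen axes
#'
#' Eigen decomposition of the posterior-mean among-individual covariance
#' matrix gives the point axes; each posterior draw's matrix is then
#' decomposed, its eigenvectors sign-aligned to the point axes (positive
#' dot product), and loading-wise and eigenvalue-share quantiles give 95%
#' credible intervals. The sign convention makes the largest-magnitude
#' loading of each point axis positive.
#'
#' @param fit an `eleglmm_mv` or a draw x p x p array.
#' @return list of class `syndrome_axes`: `values`, `shares`, `loadings`
#'   (point estimates), `share_ci` and `loading_ci` (2.5/97.5% bounds),
#'   and the per-draw aligned arrays.
#' @export
eigen_syndrome <- function(fit) {
  arr <- if (inherits(fit, "eleglmm_mv")) fit$cov_draws[[1]] else fit
  traits <- if (inherits(fit, "eleglmm_mv")) fit$traits else
    paste0("trait", seq_len(dim(fit)[2]))
  p <- dim(arr)[2]; ndraw <- dim(arr)[1]
  M <- apply(arr, c(2, 3), mean)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- eg$vectors
  for (j in seq_len(p)) if (V[which.max(abs(V[, j])), j] < 0)
    V[, j] <- -V[, j]
  lam <- pmax(eg$values, 0)
  shares <- lam / sum(lam)

  load_draws <- array(NA_real_, c(ndraw, p, p))
  share_draws <- matrix(NA_real_, ndraw, p)
  for (d in seq_len(ndraw)) {
    S <- arr[d, , ]
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    W <- e$vectors
    for (j in seq_len(p)) if (sum(W[, j] * V[, j]) < 0) W[, j] <- -W[, j]
    load_draws[d, , ] <- W
    lv <- pmax(e$values, 0)
    share_draws[d, ] <- lv / sum(lv)
  }
  lci <- apply(load_draws, c(2, 3), quantile, probs = c(0.025, 0.975))
  sci <- apply(share_draws, 2, quantile, probs = c(0.025, 0.975))
  if (shares[1] > 0 && ncol(sci) >= 2 && sci[1, 1] <= sci[2, 2])
    warning("top-two eigenvalue credible intervals overlap; ",
            "leading-axis identity is uncertain", call. = FALSE)
  dimnames(V) <- list(traits, paste0("PC", seq_len(p)))
  structure(list(values = lam, shares = shares, loadings = V,
                 share_ci = sci, loading_ci = lci,
                 share_draws = share_draws, loading_draws = load_draws,
                 traits = traits),
            class = "syndrome_axes")
}

#' @export
print.syndrome_axes <- function(x, ...) {
  p <- length(x$values)
  cat("Behavioral-syndrome axes (among-individual covariance):\n")
  cat("eigenvalue shares:",
      paste(sprintf("PC%d %.2f (%.2f, %.2f)", seq_len(p), x$shares,
                    x$share_ci[1, ], x$share_ci[2, ]), collapse = "; "), "\n")
  cat("loadings (point estimates):\n")
  print(round(x$loadings, 3))
  invisible(x)
}
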