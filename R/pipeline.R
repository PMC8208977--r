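#' Pipeline configuration
#'
#' Defaults follow the analysis conventions this package encodes: 7 km/h
#' speed filter, 2-h burst gap, 95% isopleth, 250-m KDE grid,
#' 06:00-18:00 day window, 50% monthly coverage, and the documented prior
#' and MCMC settings. Any entry can be overridden.
#'
#' @param ... overrides of the default entries.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ## input: either tracks_path (+ optional raster paths) or simulate
    tracks_path = NULL, simulate = TRUE,
    n_individuals = 12, months = 6, n_regions = 4, seed = 1,
    v_max_kmh = 7, gap_max_hours = 2,
    scale = "monthly",                 # "monthly", "annual" or "both"
    h = NULL, cell = 250, isopleth = 0.95, min_coverage = 0.5,
    n_restarts = 10,
    mcmc = mcmc_control(),
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Orchestrates: ingest or simulate tracks -> speed filter -> burst
#' segmentation -> regularity report -> pooled HMM fit and Viterbi
#' decoding -> behavior tables with covariate extraction -> univariate
#' mixed models per behavior (effect-size, repeatability and R2 tables)
#' -> multi-response model on the monthly traits with among-individual
#' correlations and syndrome axes. Deterministic given `cfg$seed`. When
#' `cfg$out_dir` is set, all summary tables are written as delimited text
#' plus a JSON manifest.
#'
#' @param cfg a [pipeline_config()].
#' @return (invisibly) a list with every intermediate and final object.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  stage <- function(name, expr) {
    res <- try(expr, silent = TRUE)
    if (inherits(res, "try-error"))
      stop("pipeline stage '", name, "' failed: ",
           attr(res, "condition")$message, call. = FALSE)
    res
  }

  ## -- ingest ---------------------------------------------------------
  inp <- stage("ingest", {
    if (!is.null(cfg$tracks_path)) {
      list(trajs = read_tracks(cfg$tracks_path), rasters = NULL, truth = NULL)
    } else if (isTRUE(cfg$simulate)) {
      sc <- sim_config(n_individuals = cfg$n_individuals,
                       months = cfg$months, n_regions = cfg$n_regions)
      ras <- generate_rasters(sc$raster_spec,
                              month_seq(sc$start, sc$months),
                              seed = cfg$seed)
      pop <- simulate_population(sc, ras, seed = cfg$seed)
      list(trajs = pop$trajs, rasters = ras, truth = pop$truth)
    } else stop("no tracks_path and simulate = FALSE")
  })

  ## -- clean ----------------------------------------------------------
  trajs <- stage("clean", lapply(inp$trajs, function(tr)
    segment_bursts(filter_speed(tr, cfg$v_max_kmh), cfg$gap_max_hours)))
  reg <- stage("regularity", regularity_report(trajs))

  ## -- HMM ------------------------------------------------------------
  steps <- stage("steps", {
    s <- do.call(rbind, c(lapply(trajs, build_step_series),
                          list(make.row.names = FALSE)))
    class(s) <- c("step_series", "data.frame")
    s
  })
  hmm_fit <- stage("hmm", fit_hmm(steps, n_restarts = cfg$n_restarts,
                                  seed = cfg$seed))
  states <- stage("decode", viterbi_decode(hmm_fit$params, steps))

  ## -- covariate layers ----------------------------------------------
  rasters <- inp$rasters
  if (!is.null(rasters)) {
    nd <- stage("ndvi_gapfill", ndvi_gapfill(rasters$ndvi_monthly))
    rasters$ndvi_monthly <- nd$monthly
    rasters$ndvi_annual <- nd$annual
  }

  ## -- behavior tables -----------------------------------------------
  scales <- if (cfg$scale == "both") c("monthly", "annual") else cfg$scale
  tables <- list()
  for (sc in scales)
    tables[[sc]] <- stage(paste0("metrics_", sc),
      assemble_behavior_table(trajs, steps, states, scale = sc,
                              h = cfg$h, cell = cfg$cell,
                              min_coverage = cfg$min_coverage,
                              rasters = rasters))

  ## -- univariate models ---------------------------------------------
  responses <- c(distance_km = "identity", home_range_km2 = "log",
                 site_fidelity = "identity", diurnality = "identity",
                 exploratory_prop = "identity")
  covnames <- c("sex", "ndvi", "hfi", "temperature_seasonality", "rainfall")
  fits <- list(); effects <- list(); rep_rows <- list()
  for (sc in names(tables)) {
    tab <- tables[[sc]]
    fx <- intersect(covnames, names(tab))
    rnd <- if (sc == "monthly") c("individual_id", "region", "window") else
      c("individual_id", "region")
    for (resp in names(responses)) {
      if (all(is.na(tab[[resp]]))) next
      f <- stats::as.formula(paste(resp, "~", paste(fx, collapse = "+")))
      fit <- stage(paste("fit", sc, resp),
                   fit_univariate(f, tab, random = rnd,
                                  transform = responses[[resp]],
                                  control = cfg$mcmc, seed = cfg$seed))
      fits[[paste(sc, resp, sep = ".")]] <- fit
      fe <- fixed_effect_summary(fit)
      fe$response <- resp; fe$scale <- sc
      effects[[length(effects) + 1]] <- fe
      r <- repeatability(fit)
      rr2 <- r_squared(fit)
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        scale = sc, behavior = resp, R_adj = r["mean"],
        lower = r["lower"], upper = r["upper"],
        R2_marginal = rr2["marginal", "mean"],
        R2_conditional = rr2["conditional", "mean"], row.names = NULL)
    }
  }
  effects_tab <- do.call(rbind, effects)
  repeat_tab <- do.call(rbind, rep_rows)

  ## -- multi-response model and syndrome axes -------------------------
  mv <- ai <- synd <- NULL
  if ("monthly" %in% names(tables)) {
    tabm <- tables$monthly
    mv <- stage("multivariate",
      fit_multivariate(tabm,
                       traits = c("distance_km", "home_range_km2",
                                  "diurnality", "exploratory_prop"),
                       fixed = intersect(covnames, names(tabm)),
                       random = c("individual_id", "region", "window"),
                       transform = c(home_range_km2 = "log"),
                       control = cfg$mcmc, seed = cfg$seed))
    ai <- among_individual_correlations(mv)
    synd <- eigen_syndrome(mv)
  }

  out <- list(config = cfg, trajs = trajs, regularity = reg,
              steps = steps, hmm = hmm_fit, states = states,
              tables = tables, fits = fits, effects = effects_tab,
              repeatability = repeat_tab, mv = mv,
              ai_correlations = ai, syndrome = synd,
              truth = inp$truth)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(out, cfg$out_dir)
  invisible(out)
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) write.csv(x, file.path(dir, f), row.names = FALSE)
  wcsv(out$regularity, "regularity_report.csv")
  for (sc in names(out$tables)) {
    wcsv(as.data.frame(out$tables[[sc]]), paste0("behavior_", sc, ".csv"))
    wcsv(attr(out$tables[[sc]], "exclusions"),
         paste0("exclusions_", sc, ".csv"))
  }
  wcsv(out$effects, "fixed_effects.csv")
  wcsv(out$repeatability, "repeatability.csv")
  p <- out$hmm$params
  jsonlite::write_json(
    list(mu = p$mu, sigma = p$sigma, ang_mean = p$ang_mean,
         kappa = p$kappa, Gamma = p$Gamma, zero_mass = p$zero_mass,
         delta = p$delta, loglik = out$hmm$loglik),
    file.path(dir, "hmm_params.json"), digits = NA, auto_unbox = TRUE)
  if (!is.null(out$ai_correlations)) {
    ai <- out$ai_correlations
    m <- matrix(sprintf("%.3f (%.3f, %.3f)", ai$estimate, ai$lower, ai$upper),
                nrow(ai$estimate), dimnames = dimnames(ai$estimate))
    wcsv(cbind(trait = rownames(m), as.data.frame(m)), "ai_matrix.csv")
  }
  if (!is.null(out$syndrome)) {
    s <- out$syndrome
    ld <- data.frame(trait = s$traits, s$loadings,
                     PC1_lower = s$loading_ci[1, , 1],
                     PC1_upper = s$loading_ci[2, , 1])
    wcsv(ld, "syndrome_loadings.csv")
    wcsv(data.frame(axis = paste0("PC", seq_along(s$shares)),
                    share = s$shares, lower = s$share_ci[1, ],
                    upper = s$share_ci[2, ]), "syndrome_shares.csv")
  }
  excl_n <- sum(vapply(out$tables,
                       function(t) nrow(attr(t, "exclusions")), 0))
  jsonlite::write_json(
    list(seed = out$config$seed,
         config = out$config[setdiff(names(out$config),
                                     c("mcmc", "out_dir"))],
         mcmc = unclass(out$config$mcmc),
         h_used = lapply(out$tables, attr, "h_used"),
         n_individuals = length(out$trajs),
         n_steps = nrow(out$steps),
         n_excluded_windows = excl_n,
         package_version = as.character(utils::packageVersion("elemove"))),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE,
    null = "null")
  invisible(dir)
}
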