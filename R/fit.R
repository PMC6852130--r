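#' Prepare aggregated survey data for model fitting
#'
#' Converts an aggregated survey table (see [aggregate_surveys()]) into the
#' index/response structure the sampler consumes: integer indices for class,
#' formation, bioregion, month, year and plot; globally standardized rainfall
#' and nonnative-cover covariates; and the response matrix (counts for
#' richness, `log(cover + 0.001)` for cover).
#'
#' @param data Aggregated survey tibble.
#' @param response `"richness"` or `"cover"`.
#' @return A list of class `vb_model_data` with elements `index` (tibble of
#'   integer indices and standardized covariates), `Y` (response matrix),
#'   `levels` (label vectors), `formation_of`, and `scaling`.
#' @export
prepare_model_data <- function(data, response = c("richness", "cover")) {
  response <- match.arg(response)
  std <- standardize_covariates(data)
  scaling <- attr(std, "scaling")
  cls <- sort(unique(as.character(data$vegetation_class)))
  fmn <- sort(unique(as.character(data$vegetation_formation)))
  brg <- sort(unique(as.character(data$bioregion)))
  yrs <- sort(unique(data$year))
  plt <- sort(unique(as.character(data$plot_id)))
  map <- dplyr::distinct(data, .data$vegetation_class, .data$vegetation_formation)
  if (anyDuplicated(map$vegetation_class)) {
    stop("each vegetation class must map to exactly one formation")
  }
  formation_of <- match(map$vegetation_formation[match(cls, map$vegetation_class)], fmn)
  index <- tibble::tibble(
    class = match(as.character(data$vegetation_class), cls),
    bioregion = match(as.character(data$bioregion), brg),
    month = as.integer(data$month),
    year = match(data$year, yrs),
    plot = match(as.character(data$plot_id), plt),
    r = std$rainfall_std,
    e = std$nonnative_std
  )
  gf <- growth_forms()
  if (response == "richness") {
    Y <- as.matrix(data[, paste0("richness_", gf)])
    if (any(Y < 0) || any(Y != round(Y))) {
      stop("richness responses must be non-negative integers")
    }
  } else {
    cv <- as.matrix(data[, paste0("cover_", gf)])
    if (any(cv < 0)) stop("cover responses must be >= 0")
    Y <- log(cv + 0.001)
  }
  colnames(Y) <- gf
  structure(list(
    index = index, Y = Y, response = response,
    levels = list(class = cls, formation = fmn, bioregion = brg,
                  year = yrs, plot = plt),
    formation_of = formation_of, scaling = scaling
  ), class = "vb_model_data")
}

vb_cpp_data <- function(mdata, spec) {
  list(
    n = nrow(mdata$index), G = 6L,
    V = spec$n_classes, Fm = spec$n_formations, B = spec$n_bioregions,
    Ny = spec$n_years, P = spec$n_plots,
    variant = if (spec$variant == "dynamic") 1L else 0L,
    response = if (spec$response == "cover") 1L else 0L,
    lkj_shape = spec$lkj_shape, halfnormal_scale = spec$halfnormal_scale,
    vague_sd = spec$vague_sd,
    v = mdata$index$class - 1L, b = mdata$index$bioregion - 1L,
    m = mdata$index$month - 1L, yy = mdata$index$year - 1L,
    p = mdata$index$plot - 1L, fmap = spec$formation_of - 1L,
    r = mdata$index$r, e = mdata$index$e,
    Y = unname(mdata$Y)
  )
}

# flat names for a stored block; labels is a list of dimension label vectors,
# combined column-major (first dimension varying fastest) to match the
# flattening of the constrained arrays
flat_names <- function(block, labels) {
  grids <- expand.grid(labels, stringsAsFactors = FALSE)
  paste0(block, "[", do.call(paste, c(grids, sep = ",")), "]")
}

stored_blocks <- function(spec, pars) {
  G <- growth_forms()
  blocks <- list(
    alpha = list(G),
    theta = list(spec$formation_labels, G),
    beta = list(spec$class_labels, G),
    delta = list(spec$bioregion_labels, G),
    iota = list(G),
    epsilon = list(G),
    zeta = list(spec$year_labels, G),
    sigma_class = list(G), sigma_formation = list(G),
    sigma_rain = list(G), sigma_year = list(G), sigma_plot = list(G),
    sigma_resid = list(G)
  )
  if (spec$variant == "dynamic") {
    blocks$gamma <- list(month.abb, spec$bioregion_labels, G)
    blocks$sigma_rw <- list(spec$bioregion_labels, G)
  } else {
    blocks$gamma <- list(spec$bioregion_labels, G)
    blocks$kappa <- list(month.abb, G)
    blocks$sigma_bioregion <- list(G)
    blocks$sigma_month <- list(G)
  }
  if (spec$response == "cover") blocks$sigma_obs <- list(G)
  if (pars == "all") blocks$eta <- list(spec$plot_labels, G)
  blocks
}

# constrained parameters with vector blocks as plain numeric vectors
constrain_params <- function(theta, ptr, include_latent = FALSE) {
  cp <- vb_constrain(theta, ptr, include_latent)
  for (nm in names(cp)) {
    d <- dim(cp[[nm]])
    if (!is.null(d) && length(d) == 2 && d[2] == 1L) cp[[nm]] <- as.numeric(cp[[nm]])
  }
  cp
}

collect_constrained <- function(theta, ptr, blocks) {
  cp <- vb_constrain(theta, ptr)
  out <- lapply(names(blocks), function(nm) {
    if (nm == "corr") return(NULL)
    as.numeric(cp[[nm]])
  })
  names(out) <- names(blocks)
  # residual correlations: lower triangle of Phi
  phi <- cp$Phi
  corr <- phi[lower.tri(phi)]
  c(unlist(out, use.names = FALSE), corr)
}

#' Fit the multivariate hierarchical benchmark model
#'
#' Samples the posterior of the Poisson (richness) or lognormal (cover)
#' hierarchical model with the built-in No-U-Turn sampler. All hierarchical
#' deviations and the survey-level multivariate-normal overdispersion use a
#' non-centered parameterization; the residual correlation matrix uses a
#' Cholesky/partial-correlation parameterization under the LKJ prior.
#' Chains run sequentially and are fully reproducible given `seed`.
#'
#' @param data Aggregated survey tibble (see [aggregate_surveys()]) or a
#'   prepared `vb_model_data` object.
#' @param response `"richness"` or `"cover"`.
#' @param variant `"static"` (regionally consistent month effects) or
#'   `"dynamic"` (bioregion-specific monthly random walks).
#' @param chains,iter,warmup Sampler configuration. The reference
#'   configuration of 4 chains x 5,000 + 5,000 is available via
#'   `iter = 5000, warmup = 5000`; the default 1,000 + 1,000 suits
#'   desk-scale data.
#' @param seed Integer seed; identical seeds and configuration give
#'   identical draws.
#' @param adapt_delta Target acceptance statistic (default 0.8).
#' @param max_treedepth Maximum tree depth (default 10).
#' @param pars `"population"` stores all population-level parameters and the
#'   year effects; `"all"` additionally stores per-plot effects.
#' @param lkj_shape,halfnormal_scale,vague_sd Prior constants, see
#'   [vb_model_spec()].
#' @param divergence_warn_frac Warn if the post-warmup divergent-transition
#'   fraction exceeds this threshold (default 0.02).
#' @param warm_start Optional adapted metric from a previous comparable fit
#'   (`fit$sampler$metric`): reuses its (dense + diagonal) mass matrix and
#'   step size so `warmup` can be reduced to step-size tuning only.
#' @param verbose Print per-chain progress.
#' @return A `vb_fit` object: draw matrix (`draws`), `chain` index vector,
#'   the model `spec`, covariate `scaling`, sampler metadata, and the
#'   prepared data (`model_data`).
#' @export
fit_benchmark_model <- function(data, response = c("richness", "cover"),
                                variant = c("static", "dynamic"),
                                chains = 4, iter = 1000, warmup = 1000,
                                seed = 1L, adapt_delta = 0.8,
                                max_treedepth = 10L,
                                pars = c("population", "all"),
                                lkj_shape = 4, halfnormal_scale = 2,
                                vague_sd = 10,
                                divergence_warn_frac = 0.02,
                                warm_start = NULL,
                                verbose = FALSE) {
  response <- match.arg(response)
  variant <- match.arg(variant)
  pars <- match.arg(pars)
  mdata <- if (inherits(data, "vb_model_data")) data
    else prepare_model_data(data, response)
  if (mdata$response != response) {
    stop("prepared data is for response '", mdata$response, "'")
  }
  lv <- mdata$levels
  spec <- vb_model_spec(
    response = response, variant = variant,
    n_classes = length(lv$class), n_formations = length(lv$formation),
    n_bioregions = length(lv$bioregion), n_years = length(lv$year),
    n_plots = length(lv$plot), formation_of = mdata$formation_of,
    lkj_shape = lkj_shape, halfnormal_scale = halfnormal_scale,
    vague_sd = vague_sd,
    class_labels = lv$class, formation_labels = lv$formation,
    bioregion_labels = lv$bioregion, year_labels = as.character(lv$year),
    plot_labels = lv$plot
  )
  ptr <- vb_data_ptr(vb_cpp_data(mdata, spec))
  lay <- vb_layout(ptr)
  dim_total <- lay$total
  off <- lay$offsets

  # dense-metric subspace: every population-level block (posterior
  # collinearity between intercepts, hierarchical means and scales is what
  # limits the stable step size); the per-plot and per-survey latent fields
  # keep a diagonal metric
  block_sizes <- list(
    alpha = 6L, ztheta = spec$n_formations * 6L, zbeta = spec$n_classes * 6L,
    zgam = spec$n_bioregions * 6L, zkap = 72L, zw = 12L * spec$n_bioregions * 6L,
    zdelta = spec$n_bioregions * 6L, iota = 6L, eps = 6L,
    zyear = spec$n_years * 6L,
    lsv = 6L, lsf = 6L, lsb = 6L, lsm = 6L, lsrwb = spec$n_bioregions * 6L,
    lsr = 6L, lsy = 6L, lsp = 6L, lss = 6L, lsobs = 6L, phiy = 15L
  )
  dense_idx <- unlist(lapply(names(block_sizes), function(nm) {
    o <- off[[nm]]
    if (is.null(o) || o < 0) return(integer(0))
    o + seq_len(block_sizes[[nm]]) - 1L
  }), use.names = FALSE)

  blocks <- stored_blocks(spec, pars)
  par_names <- c(
    unlist(lapply(names(blocks), function(nm) flat_names(nm, blocks[[nm]])),
           use.names = FALSE),
    {
      gfs <- growth_forms()
      pr <- utils::combn(6, 2)
      paste0("corr[", gfs[pr[1, ]], ",", gfs[pr[2, ]], "]")
    }
  )

  init_theta <- function() {
    th <- stats::rnorm(dim_total, 0, 0.1)
    a0 <- if (response == "richness") log(colMeans(mdata$Y) + 0.1)
      else colMeans(mdata$Y)
    th[off$alpha + 1:6] <- a0 + stats::rnorm(6, 0, 0.05)
    for (nm in c("lsv", "lsf", "lsb", "lsm", "lsrwb", "lsr", "lsy", "lsp",
                 "lss", "lsobs")) {
      o <- off[[nm]]
      if (o >= 0) {
        len <- if (nm == "lsrwb") spec$n_bioregions * 6L else 6L
        th[o + seq_len(len)] <- log(0.3) + stats::rnorm(len, 0, 0.05)
      }
    }
    th[off$phiy + 1:15] <- stats::rnorm(15, 0, 0.02)
    th
  }

  results <- vector("list", chains)
  metric_out <- NULL
  for (ch in seq_len(chains)) {
    set.seed((as.integer(seed) + 104729L * ch) %% 2147483399L)
    t0 <- Sys.time()
    res <- vb_nuts(init_theta(), ptr, as.integer(warmup), as.integer(iter),
                   adapt_delta, as.integer(max_treedepth),
                   verbose = FALSE, dense_idx = as.integer(dense_idx),
                   init_var = if (is.null(warm_start)) numeric(0)
                     else warm_start$var,
                   init_dense = if (is.null(warm_start)) numeric(0)
                     else warm_start$dense,
                   init_stepsize = if (is.null(warm_start)) 0
                     else warm_start$stepsize)
    if (ch == 1L) {
      metric_out <- list(var = res$metric_var, dense = res$metric_dense,
                         stepsize = res$stepsize)
    }
    cd <- matrix(NA_real_, iter, length(par_names))
    for (k in seq_len(iter)) {
      cd[k, ] <- collect_constrained(res$draws[k, ], ptr, blocks)
    }
    colnames(cd) <- par_names
    results[[ch]] <- list(draws = cd, stepsize = res$stepsize,
                          divergences = res$divergences,
                          treedepth = res$treedepth)
    if (verbose) {
      message(sprintf(
        "chain %d: %.1fs, stepsize %.3g, mean treedepth %.1f, %d divergence(s)",
        ch, as.numeric(difftime(Sys.time(), t0, units = "secs")),
        res$stepsize, mean(res$treedepth), res$divergences))
    }
    rm(res)
  }
  draws <- do.call(rbind, lapply(results, `[[`, "draws"))
  chain_id <- rep(seq_len(chains), each = iter)
  n_div <- sum(vapply(results, `[[`, integer(1), "divergences"))
  div_frac <- n_div / (chains * iter)
  meta <- list(chains = chains, iter = iter, warmup = warmup, seed = seed,
               metric = metric_out,
               adapt_delta = adapt_delta, max_treedepth = max_treedepth,
               stepsizes = vapply(results, `[[`, numeric(1), "stepsize"),
               mean_treedepth = mean(unlist(lapply(results, `[[`, "treedepth"))),
               divergences = n_div, divergence_frac = div_frac)
  if (div_frac > divergence_warn_frac) {
    warning(sprintf(
      "%.1f%% of post-warmup transitions were divergent; posterior may be biased (consider raising adapt_delta)",
      100 * div_frac))
    meta$divergence_warning <- TRUE
  }
  structure(list(draws = draws, chain = chain_id, spec = spec,
                 scaling = mdata$scaling, model_data = mdata,
                 sampler = meta), class = "vb_fit")
}

#' @export
print.vb_fit <- function(x, ...) {
  cat("<vb_fit> ", x$spec$response, " model, ", x$spec$variant, " variant\n",
      sep = "")
  cat("  ", x$sampler$chains, " chains x ", x$sampler$iter,
      " iterations (", x$sampler$warmup, " warmup), ",
      ncol(x$draws), " stored parameters\n", sep = "")
  cat("  divergent transitions: ", x$sampler$divergences, "\n", sep = "")
  invisible(x)
}

#' Tidy posterior summaries of a fitted benchmark model
#'
#' @param x A `vb_fit`.
#' @param conf_level Width of the posterior credible interval (default 0.9).
#' @param ... Unused.
#' @return A tibble with one row per stored parameter: posterior mean, sd,
#'   median, interval bounds.
#' @export
tidy.vb_fit <- function(x, conf_level = 0.9, ...) {
  a <- (1 - conf_level) / 2
  qs <- apply(x$draws, 2, stats::quantile, probs = c(a, 0.5, 1 - a),
              names = FALSE)
  tibble::tibble(
    term = colnames(x$draws),
    estimate = colMeans(x$draws),
    std.error = apply(x$draws, 2, stats::sd),
    conf.low = qs[1, ], median = qs[2, ], conf.high = qs[3, ]
  )
}

#' One-row summary of a fitted benchmark model
#'
#' @param x A `vb_fit`.
#' @param ... Unused.
#' @return A tibble with sampler and convergence summaries (max split-Rhat,
#'   min effective sample size, divergent transitions).
#' @export
glance.vb_fit <- function(x, ...) {
  d <- mcmc_diagnostics(x)
  tibble::tibble(
    response = x$spec$response, variant = x$spec$variant,
    n_surveys = nrow(x$model_data$index),
    chains = x$sampler$chains, iter = x$sampler$iter,
    max_rhat = max(d$rhat, na.rm = TRUE),
    min_neff = min(d$neff, na.rm = TRUE),
    divergences = x$sampler$divergences
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
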