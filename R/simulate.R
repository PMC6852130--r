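# Synthetic data generation from the full generative model: used for all
# testing and calibration in place of the (external) plot archive.

derive_seed <- function(seed, k) {
  (as.integer(seed) %% 2147483399L + 7919L * as.integer(k)) %% 2147483399L + 1L
}

#' Define a simulation scenario
#'
#' A scenario fixes the study conditions for synthetic data: index
#' dimensions, survey design, per-bioregion rainfall regime, the
#' nonnative-cover distribution, and the true-parameter policy. Default true
#' intercepts and covariate effects are the published state-wide estimates
#' for the six growth forms (mean richness 1, 6, 5, 1, 6, 2 and rainfall /
#' nonnative multipliers per growth form), giving realistic count and cover
#' magnitudes; hierarchical deviations are drawn from their priors using
#' field-plausible scale values fixed by the scenario.
#'
#' @param response `"richness"` or `"cover"`.
#' @param variant `"static"` or `"dynamic"`.
#' @param n_classes,n_formations,n_bioregions,n_years Index dimensions.
#' @param n_plots Number of distinct plots.
#' @param surveys_per_plot Surveys per plot (total surveys =
#'   `n_plots * surveys_per_plot`).
#' @param months Months surveys can fall in (default all 12).
#' @param rainfall_mean,rainfall_sd Per-bioregion mean and sd of 12-month
#'   rainfall totals (mm); recycled to `n_bioregions`. Defaults span a
#'   400-900 mm gradient with 20% relative sd.
#' @param nonnative_zero_prob Probability a survey has 0% nonnative cover.
#' @param nonnative_mean Mean nonnative cover (%) when nonzero (exponential).
#' @param true_params Optional fully specified parameter set; when given,
#'   [draw_true_params()] returns it unchanged.
#' @param alpha,iota,epsilon True fixed values of the intercepts and effect
#'   grand means (log scale, 6-vectors).
#' @param sigmas Named list of true scale 6-vectors (recycled from scalars):
#'   `class`, `formation`, `bioregion`, `month`, `rw`, `rain`, `year`,
#'   `plot`, `resid`, `obs`.
#' @param lkj_shape LKJ shape for drawing the true correlation matrix.
#' @return A list of class `vb_scenario`.
#' @export
simulation_scenario <- function(response = c("richness", "cover"),
                                variant = c("static", "dynamic"),
                                n_classes = 5, n_formations = 2,
                                n_bioregions = 3, n_years = 5,
                                n_plots = 500, surveys_per_plot = 2,
                                months = 1:12,
                                rainfall_mean = NULL, rainfall_sd = NULL,
                                nonnative_zero_prob = 0.6,
                                nonnative_mean = 10,
                                true_params = NULL,
                                alpha = NULL, iota = NULL, epsilon = NULL,
                                sigmas = list(),
                                lkj_shape = 4) {
  response <- match.arg(response)
  variant <- match.arg(variant)
  stopifnot(n_classes >= 1, n_formations >= 1, n_bioregions >= 1,
            n_years >= 1, n_plots >= 1, surveys_per_plot >= 1)
  if (is.null(rainfall_mean)) {
    rainfall_mean <- seq(400, 900, length.out = n_bioregions)
  }
  rainfall_mean <- rep_len(rainfall_mean, n_bioregions)
  if (is.null(rainfall_sd)) rainfall_sd <- 0.2 * rainfall_mean
  rainfall_sd <- rep_len(rainfall_sd, n_bioregions)
  # published state-wide growth-form estimates as true study conditions
  if (is.null(alpha)) {
    alpha <- if (response == "richness") log(c(1, 6, 5, 1, 6, 2))
      else log(c(0.05, 2.63, 8.25, 0.19, 6.43, 3.01))
  }
  if (is.null(iota)) {
    iota <- if (response == "richness") log(c(1.19, 1.20, 1.16, 1.24, 1.16, 1.05))
      else log(c(1.90, 1.45, 1.66, 2.17, 1.22, 1.11))
  }
  if (is.null(epsilon)) {
    epsilon <- if (response == "richness") log(c(0.95, 0.99, 0.98, 0.96, 0.88, 0.96))
      else log(c(1.10, 1.10, 1.19, 1.18, 0.97, 1.07))
  }
  sg <- function(name, default) rep_len(sigmas[[name]] %||% default, 6)
  sig <- list(
    class = sg("class", 0.4), formation = sg("formation", 0.3),
    bioregion = sg("bioregion", 0.2), month = sg("month", 0.15),
    rw = sg("rw", 0.15), rain = sg("rain", 0.1), year = sg("year", 0.15),
    plot = sg("plot", 0.3), resid = sg("resid", 0.3), obs = sg("obs", 0.7)
  )
  structure(list(
    response = response, variant = variant,
    n_classes = as.integer(n_classes), n_formations = as.integer(n_formations),
    n_bioregions = as.integer(n_bioregions), n_years = as.integer(n_years),
    n_plots = as.integer(n_plots), surveys_per_plot = as.integer(surveys_per_plot),
    months = as.integer(months),
    formation_of = ((seq_len(n_classes) - 1L) %% as.integer(n_formations)) + 1L,
    rainfall_mean = rainfall_mean, rainfall_sd = rainfall_sd,
    nonnative_zero_prob = nonnative_zero_prob, nonnative_mean = nonnative_mean,
    true_params = true_params, alpha = alpha, iota = iota, epsilon = epsilon,
    sigmas = sig, lkj_shape = lkj_shape
  ), class = "vb_scenario")
}

# sample a correlation matrix with density proportional to |Phi|^shape
# (vine construction over canonical partial correlations)
rlkj_corr <- function(K, shape) {
  eta <- shape + 1
  prtl <- matrix(0, K, K)
  R <- diag(K)
  for (k in seq_len(K - 1)) {
    for (i in seq(k + 1, K)) {
      b <- eta + (K - 1 - k) / 2
      p <- 2 * stats::rbeta(1, b, b) - 1
      prtl[k, i] <- p
      if (k > 1) {
        for (l in seq(k - 1, 1)) {
          p <- p * sqrt((1 - prtl[l, i]^2) * (1 - prtl[l, k]^2)) +
            prtl[l, i] * prtl[l, k]
        }
      }
      R[k, i] <- R[i, k] <- p
    }
  }
  R
}

#' Draw (or return) the true parameter set of a scenario
#'
#' Returns `scenario$true_params` unchanged when supplied. Otherwise fixes
#' `alpha`, `iota`, `epsilon` and all scales from the scenario and draws the
#' remaining fields from their model priors: class deviations around their
#' formation means, formation means around zero, seasonal terms (random walk
#' for the dynamic variant), bioregion rainfall slopes around `iota`, year
#' and plot deviations, and the residual correlation matrix from the LKJ
#' distribution with the scenario's shape.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed; identical seeds give identical parameter sets.
#' @return A parameter set (see [validate_param_set()]).
#' @export
draw_true_params <- function(scenario, seed = 1L) {
  if (!is.null(scenario$true_params)) return(scenario$true_params)
  set.seed(derive_seed(seed, 1L))
  G <- 6L
  sc <- scenario
  sig <- sc$sigmas
  rmat <- function(nr, sd_vec, center = 0) {
    matrix(stats::rnorm(nr * G, 0, rep(sd_vec, each = nr)), nr, G) + center
  }
  theta <- rmat(sc$n_formations, sig$formation)
  beta <- theta[sc$formation_of, , drop = FALSE] + rmat(sc$n_classes, sig$class)
  params <- list(
    alpha = sc$alpha, theta = theta, beta = beta,
    delta = rmat(sc$n_bioregions, sig$rain,
                 center = matrix(sc$iota, sc$n_bioregions, G, byrow = TRUE)),
    iota = sc$iota, epsilon = sc$epsilon,
    zeta = rmat(sc$n_years, sig$year), eta = rmat(sc$n_plots, sig$plot),
    sigma_class = sig$class, sigma_formation = sig$formation,
    sigma_rain = sig$rain, sigma_year = sig$year, sigma_plot = sig$plot,
    sigma_resid = sig$resid, Phi = rlkj_corr(G, sc$lkj_shape)
  )
  if (sc$variant == "dynamic") {
    srw <- matrix(rep(sig$rw, each = sc$n_bioregions), sc$n_bioregions, G)
    gamma <- array(0, dim = c(12, sc$n_bioregions, G))
    walk <- c(7L, 8L, 9L, 10L, 11L, 12L, 1L, 2L, 3L, 4L, 5L)
    for (b in seq_len(sc$n_bioregions)) {
      s <- srw[b, ]
      gamma[walk[1], b, ] <- stats::rnorm(G, 0, s)
      for (k in 2:11) {
        gamma[walk[k], b, ] <- stats::rnorm(G, gamma[walk[k - 1], b, ], s)
      }
      gamma[6, b, ] <- stats::rnorm(G, (gamma[5, b, ] + gamma[7, b, ]) / 2, s)
    }
    params$gamma <- gamma
    params$sigma_rw <- srw
  } else {
    params$gamma <- rmat(sc$n_bioregions, sig$bioregion)
    params$kappa <- rmat(12L, sig$month)
    params$sigma_bioregion <- sig$bioregion
    params$sigma_month <- sig$month
  }
  if (sc$response == "cover") params$sigma_obs <- sig$obs
  params
}

#' Simulate plot surveys from the generative model
#'
#' Runs the model forward: assigns plots to vegetation-class/bioregion
#' combinations, draws survey dates, rainfall and nonnative cover, builds
#' the linear predictor, adds multivariate-normal overdispersion, draws
#' richness (Poisson) or cover (lognormal minus the 0.001 offset, floored at
#' 0), and expands the responses into per-species records with deterministic
#' pseudo-species names (`sp_<growthform>_<k>`). Nonnative cover is emitted
#' as nonnative records so that aggregation recovers it.
#'
#' @param scenario A [simulation_scenario()].
#' @param params True parameter set (see [draw_true_params()]).
#' @param seed Integer seed.
#' @return A list of class `vb_simulation`: `records` (species records),
#'   `surveys` (survey covariates), `aggregated` (the response table, as
#'   produced by [aggregate_surveys()]), and `truth` (true parameters,
#'   latent log rates, and index table) for recovery checks.
#' @export
simulate_surveys <- function(scenario, params, seed = 1L) {
  set.seed(derive_seed(seed, 2L))
  sc <- scenario
  G <- 6L
  gf <- growth_forms()
  n <- sc$n_plots * sc$surveys_per_plot
  plot_class <- sample.int(sc$n_classes, sc$n_plots, replace = TRUE)
  plot_bio <- sample.int(sc$n_bioregions, sc$n_plots, replace = TRUE)
  plot_idx <- rep(seq_len(sc$n_plots), each = sc$surveys_per_plot)
  idx <- tibble::tibble(
    class = plot_class[plot_idx],
    bioregion = plot_bio[plot_idx],
    month = sample(sc$months, n, replace = TRUE),
    year = sample.int(sc$n_years, n, replace = TRUE),
    plot = plot_idx
  )
  r_mm <- pmax(0, stats::rnorm(n, sc$rainfall_mean[idx$bioregion],
                               sc$rainfall_sd[idx$bioregion]))
  e_pct <- ifelse(stats::runif(n) < sc$nonnative_zero_prob, 0,
                  pmin(100, stats::rexp(n, 1 / sc$nonnative_mean)))
  # standardize exactly as model preparation will (population sd)
  std <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  idx$r <- std(r_mm)
  idx$e <- std(e_pct)
  mu <- linear_predictor(params, idx, variant = sc$variant)
  Lsig <- t(chol(params$Phi)) * params$sigma_resid
  odisp <- t(Lsig %*% matrix(stats::rnorm(n * G), G, n))
  log_lambda <- mu + odisp
  if (sc$response == "richness") {
    Y <- matrix(stats::rpois(n * G, exp(log_lambda)), n, G)
  } else {
    zl <- log_lambda + matrix(stats::rnorm(n * G, 0,
                                           rep(params$sigma_obs, each = n)), n, G)
    Y <- pmax(exp(zl) - 0.001, 0)
  }
  colnames(Y) <- gf

  surveys <- tibble::tibble(
    survey_id = sprintf("s%05d", seq_len(n)),
    plot_id = sprintf("p%04d", idx$plot),
    vegetation_class = sprintf("class_%02d", idx$class),
    vegetation_formation = sprintf("formation_%02d", sc$formation_of[idx$class]),
    bioregion = sprintf("bioregion_%02d", idx$bioregion),
    month = idx$month, year = 2000L + idx$year,
    rainfall_12mo = r_mm
  )

  # expand to species records
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    if (sc$response == "richness") {
      counts <- Y[i, ]
      gfs <- rep(gf, counts)
      ks <- unlist(lapply(counts, seq_len), use.names = FALSE)
      covs <- if (length(gfs) > 0) {
        round(pmin(100, stats::rexp(length(gfs), 1 / 5)), 2)
      } else numeric(0)
    } else {
      gfs <- character(0); ks <- integer(0); covs <- numeric(0)
      for (g in seq_len(G)) {
        zg <- Y[i, g]
        if (zg > 0) {
          m_g <- max(1L, ceiling(zg / 50))
          gfs <- c(gfs, rep(gf[g], m_g))
          ks <- c(ks, seq_len(m_g))
          covs <- c(covs, rep(zg / m_g, m_g))
        }
      }
    }
    native <- rep(TRUE, length(gfs))
    if (e_pct[i] > 0) {
      m_nn <- max(1L, ceiling(e_pct[i] / 50))
      gfs <- c(gfs, rep("forb", m_nn))
      ks <- c(ks, seq_len(m_nn))
      covs <- c(covs, rep(e_pct[i] / m_nn, m_nn))
      native <- c(native, rep(FALSE, m_nn))
    }
    if (length(gfs) == 0) { rec[i] <- list(NULL); next }
    rec[[i]] <- tibble::tibble(
      survey_id = surveys$survey_id[i],
      species = ifelse(native, paste0("sp_", gfs, "_", ks),
                       paste0("nn_", gfs, "_", ks)),
      native = native, growth_form = gfs, cover = covs
    )
  }
  records <- dplyr::bind_rows(rec)
  aggregated <- aggregate_surveys(records, surveys)
  structure(list(
    records = records, surveys = surveys, aggregated = aggregated,
    truth = list(params = params, log_lambda = log_lambda, mu = mu,
                 index = idx, response_matrix = Y,
                 rainfall_mm = r_mm, nonnative_pct = e_pct)
  ), class = "vb_simulation")
}

#' Simulate daily rainfall series per bioregion
#'
#' Generates one daily series per bioregion whose annual (calendar-year)
#' totals are normal with the scenario's per-bioregion mean and sd
#' (truncated at 0), spread uniformly over the days of each year. A
#' zero-variance regime gives exactly constant annual totals.
#'
#' @param scenario A [simulation_scenario()].
#' @param seed Integer seed.
#' @param years Calendar years to cover (default 1990:2015).
#' @return A tibble with columns `location_id` (bioregion label), `date`,
#'   `mm`.
#' @export
simulate_rainfall <- function(scenario, seed = 1L, years = 1990:2015) {
  set.seed(derive_seed(seed, 3L))
  out <- vector("list", scenario$n_bioregions)
  for (b in seq_len(scenario$n_bioregions)) {
    totals <- pmax(0, stats::rnorm(length(years), scenario$rainfall_mean[b],
                                   scenario$rainfall_sd[b]))
    dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
                 as.Date(sprintf("%d-12-31", max(years))), by = "day")
    yr <- as.integer(format(dates, "%Y"))
    ndays <- as.numeric(table(yr))
    mm <- totals[match(yr, years)] / ndays[match(yr, sort(unique(yr)))]
    out[[b]] <- tibble::tibble(
      location_id = sprintf("bioregion_%02d", b), date = dates, mm = mm)
  }
  dplyr::bind_rows(out)
}
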