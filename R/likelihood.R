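#' Linear predictor of the benchmark model
#'
#' Computes the 6-vector linear predictor for each survey: intercept +
#' vegetation-class deviation + seasonal term + rainfall effect + nonnative
#' cover effect + year deviation + plot deviation, all on the log scale.
#' The dynamic variant uses the month-by-bioregion term `gamma[m, b, ]`; the
#' static variant uses `gamma[b, ] + kappa[m, ]`.
#'
#' @param params Parameter set (see [validate_param_set()]).
#' @param index Data frame with one row per survey and integer columns
#'   `class`, `bioregion`, `month`, `year`, `plot`, plus numeric standardized
#'   covariates `r` (rainfall) and `e` (nonnative cover).
#' @param variant `"dynamic"` or `"static"`.
#' @return An `n x 6` matrix of linear predictors (log scale), columns in
#'   [growth_forms()] order.
#' @export
linear_predictor <- function(params, index, variant = c("static", "dynamic")) {
  variant <- match.arg(variant)
  need <- c("class", "bioregion", "month", "year", "plot", "r", "e")
  miss <- setdiff(need, names(index))
  if (length(miss) > 0) stop("index is missing columns: ", paste(miss, collapse = ", "))
  v <- as.integer(index$class); b <- as.integer(index$bioregion)
  m <- as.integer(index$month); yy <- as.integer(index$year)
  p <- as.integer(index$plot)
  rng_ok <- function(i, n, what) {
    if (any(i < 1 | i > n)) stop(what, " index out of range 1..", n)
  }
  rng_ok(v, nrow(params$beta), "class")
  rng_ok(b, nrow(params$delta), "bioregion")
  rng_ok(m, 12L, "month")
  rng_ok(yy, nrow(params$zeta), "year")
  rng_ok(p, nrow(params$eta), "plot")
  n <- length(v)
  G <- length(params$alpha)
  mu <- matrix(params$alpha, n, G, byrow = TRUE) + params$beta[v, , drop = FALSE]
  if (variant == "dynamic") {
    gm <- matrix(params$gamma[cbind(rep(m, G), rep(b, G),
                                    rep(seq_len(G), each = n))], n, G)
    mu <- mu + gm
  } else {
    mu <- mu + params$gamma[b, , drop = FALSE] + params$kappa[m, , drop = FALSE]
  }
  mu <- mu + index$r * params$delta[b, , drop = FALSE] +
    outer(index$e, params$epsilon) +
    params$zeta[yy, , drop = FALSE] + params$eta[p, , drop = FALSE]
  colnames(mu) <- growth_forms()
  mu
}

#' Observation log-likelihood
#'
#' Log-likelihood of observed growth-form vectors given latent rates:
#' Poisson for species richness (`y ~ Poisson(lambda)`), lognormal for
#' summed cover (`log(z + 0.001) ~ Normal(log lambda, sigma)`). The 0.001
#' offset is added before the log so that zero cover is finite (it equals a
#' Box-Cox transform with exponent 0 and shift 0.001).
#'
#' @param values Observed responses: a 6-vector or an `n x 6` matrix.
#'   Richness must be non-negative integers; cover must be >= 0 percent.
#' @param lambda Latent rates, same shape as `values`, strictly positive:
#'   Poisson means for richness, lognormal medians for cover.
#' @param sigma 6-vector of lognormal observation sds (cover only).
#' @param kind `"richness"` or `"cover"`.
#' @return The summed log-likelihood (scalar), including normalizing
#'   constants.
#' @export
observation_loglik <- function(values, lambda, sigma = NULL,
                               kind = c("richness", "cover")) {
  kind <- match.arg(kind)
  values <- rbind(values); lambda <- rbind(lambda)
  stopifnot(identical(dim(values), dim(lambda)))
  if (any(lambda <= 0)) stop("lambda must be strictly positive")
  if (kind == "richness") {
    if (any(values < 0) || any(values != round(values))) {
      stop("richness values must be non-negative integers")
    }
    sum(stats::dpois(values, lambda, log = TRUE))
  } else {
    if (any(values < 0)) stop("cover values must be >= 0")
    if (is.null(sigma)) stop("sigma is required for the cover likelihood")
    if (any(sigma <= 0)) stop("sigma must be strictly positive")
    sig <- matrix(sigma, nrow(values), ncol(values), byrow = TRUE)
    sum(stats::dnorm(log(values + 0.001), mean = log(lambda), sd = sig, log = TRUE))
  }
}

#' Unnormalized LKJ log-density of a correlation matrix
#'
#' Returns `a * log det(Phi)`: the log of a density proportional to the
#' determinant of the correlation matrix raised to the shape parameter `a`.
#' Larger `a` concentrates mass on the identity (no residual correlation).
#'
#' @param Phi A valid correlation matrix (symmetric, unit diagonal, positive
#'   definite).
#' @param shape Shape parameter `a` (>= 0).
#' @return Unnormalized log-density (scalar).
#' @export
#' @examples
#' lkj_log_density(diag(6), 4)              # 0
#' r <- 0.3
#' lkj_log_density(matrix(c(1, r, r, 1), 2), 4)  # 4 * log(1 - r^2)
lkj_log_density <- function(Phi, shape) {
  if (!is.matrix(Phi) || nrow(Phi) != ncol(Phi) ||
      max(abs(Phi - t(Phi))) > 1e-8 || max(abs(diag(Phi) - 1)) > 1e-8) {
    stop("Phi must be a square symmetric matrix with unit diagonal")
  }
  ch <- tryCatch(chol(Phi), error = function(e) NULL)
  if (is.null(ch)) stop("Phi must be positive definite")
  shape * 2 * sum(log(diag(ch)))
}

#' Random-walk log-prior for one bioregion's monthly effects
#'
#' First-order random-walk prior over calendar months: the walk starts in
#' July (`gamma[7, ] ~ N(0, sigma)`), steps month-to-month from August
#' through May (`gamma[m, ] ~ N(gamma[prev, ], sigma)`), and June is tied to
#' its neighbours (`gamma[6, ] ~ N((gamma[5, ] + gamma[7, ]) / 2, sigma)`)
#' so the seasonal cycle closes smoothly.
#'
#' @param gamma_mb `12 x 6` matrix of month effects for one bioregion, rows
#'   indexed by calendar month 1-12.
#' @param sigma_rw 6-vector of random-walk innovation sds (> 0).
#' @return Summed log-density over the 12 terms and 6 growth forms.
#' @export
random_walk_logprior <- function(gamma_mb, sigma_rw) {
  if (!is.matrix(gamma_mb) || nrow(gamma_mb) != 12) {
    stop("gamma_mb must be a 12 x G matrix with all 12 months present")
  }
  if (any(!is.finite(gamma_mb))) stop("gamma_mb must be finite for all 12 months")
  if (any(sigma_rw <= 0)) return(-Inf)
  G <- ncol(gamma_mb)
  sig <- matrix(sigma_rw, 12, G, byrow = TRUE)
  walk <- c(7L, 8L, 9L, 10L, 11L, 12L, 1L, 2L, 3L, 4L, 5L)
  mean_mat <- matrix(0, 12, G)
  mean_mat[walk[-1], ] <- gamma_mb[walk[-length(walk)], ]
  mean_mat[6L, ] <- (gamma_mb[5L, ] + gamma_mb[7L, ]) / 2
  sum(stats::dnorm(gamma_mb, mean = mean_mat, sd = sig, log = TRUE))
}

#' Joint log-prior of the hierarchical model
#'
#' Sums every prior term of the model: hierarchical normal priors for class
#' deviations (centred on their formation mean), formation means, seasonal
#' terms (random walk per bioregion in the dynamic variant; exchangeable
#' bioregion and month intercepts in the static variant), bioregion rainfall
#' slopes centred on the grand mean, vague normals on the rainfall grand
#' mean and the nonnative-cover effect, exchangeable year and plot effects,
#' half-normal priors on all scale vectors, and the LKJ prior on the
#' residual correlation matrix. The intercept `alpha` carries an improper
#' flat prior and contributes 0. If `latent` is supplied, the multivariate
#' normal overdispersion density of `log_lambda` around `mu` is added.
#'
#' @param params Parameter set (constrained scale).
#' @param spec A [vb_model_spec()].
#' @param latent Optional list with `log_lambda` and `mu` (`n x 6` matrices)
#'   to include the survey-level MVN overdispersion term.
#' @return Log-prior (scalar); `-Inf` when any scale is non-positive.
#' @export
hierarchical_logprior <- function(params, spec, latent = NULL) {
  sig_names <- grep("^sigma_", names(params), value = TRUE)
  for (s in sig_names) if (any(params[[s]] <= 0)) return(-Inf)
  validate_param_set(params, spec)
  G <- spec$n_growthforms
  hn <- function(x, scale) sum(stats::dnorm(x, 0, scale, log = TRUE) + log(2))
  nm <- function(x, mean, sd_vec) {
    sum(stats::dnorm(x, mean, matrix(sd_vec, nrow(rbind(x)), G, byrow = TRUE),
                     log = TRUE))
  }
  s2 <- spec$halfnormal_scale
  lp <- 0
  lp <- lp + nm(params$beta, params$theta[spec$formation_of, , drop = FALSE],
                params$sigma_class)
  lp <- lp + nm(params$theta, 0, params$sigma_formation)
  if (spec$variant == "dynamic") {
    for (b in seq_len(spec$n_bioregions)) {
      lp <- lp + random_walk_logprior(params$gamma[, b, ], params$sigma_rw[b, ])
    }
    lp <- lp + hn(params$sigma_rw, s2)
  } else {
    lp <- lp + nm(params$gamma, 0, params$sigma_bioregion)
    lp <- lp + nm(params$kappa, 0, params$sigma_month)
    lp <- lp + hn(params$sigma_bioregion, s2) + hn(params$sigma_month, s2)
  }
  iota_mat <- matrix(params$iota, spec$n_bioregions, G, byrow = TRUE)
  lp <- lp + nm(params$delta, iota_mat, params$sigma_rain)
  lp <- lp + sum(stats::dnorm(params$iota, 0, spec$vague_sd, log = TRUE))
  lp <- lp + sum(stats::dnorm(params$epsilon, 0, spec$vague_sd, log = TRUE))
  lp <- lp + nm(params$zeta, 0, params$sigma_year)
  lp <- lp + nm(params$eta, 0, params$sigma_plot)
  lp <- lp + hn(params$sigma_class, s2) + hn(params$sigma_formation, s2) +
    hn(params$sigma_rain, s2) + hn(params$sigma_year, s2) +
    hn(params$sigma_plot, s2) + hn(params$sigma_resid, s2)
  if (spec$response == "cover") lp <- lp + hn(params$sigma_obs, s2)
  lp <- lp + lkj_log_density(params$Phi, spec$lkj_shape)
  if (!is.null(latent)) {
    Sigma_chol <- t(chol(params$Phi)) * params$sigma_resid  # lower Cholesky of Sigma
    resid <- latent$log_lambda - latent$mu
    z <- forwardsolve(Sigma_chol, t(resid))
    n <- nrow(resid)
    lp <- lp - 0.5 * sum(z^2) - n * sum(log(diag(Sigma_chol))) -
      n * G * 0.5 * log(2 * pi)
  }
  lp
}

#' Multiplicative interpretation of a log-scale coefficient
#'
#' Slopes in the model act on log richness or log cover, so a coefficient
#' `c` multiplies the expected response by `exp(c)` per one-standard-deviation
#' increase in the (standardized) covariate.
#'
#' @param coefficient Numeric vector of log-scale slopes.
#' @return A tibble with `coefficient`, `factor = exp(coefficient)`, and
#'   `percent = (factor - 1) * 100`.
#' @export
#' @examples
#' effect_multiplier(log(1.19))  # +19% per sd
#' effect_multiplier(0)          # no change
effect_multiplier <- function(coefficient) {
  f <- exp(coefficient)
  tibble::tibble(coefficient = coefficient, factor = f, percent = (f - 1) * 100)
}
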