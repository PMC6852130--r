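small_params <- function(variant = "static", seed = 3) {
  sc <- simulation_scenario(variant = variant, n_classes = 3, n_formations = 2,
                            n_bioregions = 2, n_years = 2, n_plots = 4,
                            surveys_per_plot = 1)
  list(params = draw_true_params(sc, seed = seed),
       spec = vb_model_spec("richness", variant, n_classes = 3,
                            n_formations = 2, n_bioregions = 2, n_years = 2,
                            n_plots = 4, formation_of = sc$formation_of))
}

test_that("linear predictor reduces to alpha in the null case", {
  sp <- small_params()
  p <- sp$params
  p$beta[] <- 0; p$theta[] <- 0; p$gamma[] <- 0; p$kappa[] <- 0
  p$delta[] <- 0; p$epsilon[] <- 0; p$zeta[] <- 0; p$eta[] <- 0
  idx <- tibble::tibble(class = 1, bioregion = 1, month = 5, year = 1,
                        plot = 1, r = 0, e = 0)
  mu <- linear_predictor(p, idx, "static")
  expect_equal(unname(mu[1, ]), unname(p$alpha))
})

test_that("linear predictor matches hand arithmetic on one survey", {
  sp <- small_params()
  p <- sp$params
  idx <- tibble::tibble(class = 2, bioregion = 2, month = 11, year = 1,
                        plot = 3, r = 0.7, e = -0.4)
  mu <- linear_predictor(p, idx, "static")
  manual <- p$alpha + p$beta[2, ] + p$gamma[2, ] + p$kappa[11, ] +
    0.7 * p$delta[2, ] + (-0.4) * p$epsilon + p$zeta[1, ] + p$eta[3, ]
  expect_equal(unname(mu[1, ]), unname(manual))

  dynp <- small_params("dynamic")$params
  mu_d <- linear_predictor(dynp, idx, "dynamic")
  manual_d <- dynp$alpha + dynp$beta[2, ] + dynp$gamma[11, 2, ] +
    0.7 * dynp$delta[2, ] - 0.4 * dynp$epsilon + dynp$zeta[1, ] + dynp$eta[3, ]
  expect_equal(unname(mu_d[1, ]), unname(manual_d))

  bad <- idx; bad$month <- 13
  expect_error(linear_predictor(p, bad, "static"), "out of range")
})

test_that("static nests in dynamic when gamma decomposes additively", {
  sp <- small_params("static")
  p <- sp$params
  dynp <- p
  gam <- array(0, dim = c(12, 2, 6))
  for (m in 1:12) for (b in 1:2) gam[m, b, ] <- p$gamma[b, ] + p$kappa[m, ]
  dynp$gamma <- gam
  dynp$kappa <- NULL
  dynp$sigma_rw <- matrix(0.2, 2, 6)
  set.seed(5)
  idx <- tibble::tibble(class = sample(3, 20, TRUE),
                        bioregion = sample(2, 20, TRUE),
                        month = sample(12, 20, TRUE),
                        year = sample(2, 20, TRUE), plot = sample(4, 20, TRUE),
                        r = rnorm(20), e = rnorm(20))
  expect_equal(linear_predictor(p, idx, "static"),
               linear_predictor(dynp, idx, "dynamic"))
})

test_that("observation log-likelihood matches textbook densities", {
  # Poisson(1) at 0 across six growth forms: -6
  expect_equal(observation_loglik(rep(0, 6), rep(1, 6), kind = "richness"), -6)
  # cover zero evaluates the normal density at log(0.001), finite
  ll0 <- observation_loglik(rep(0, 6), rep(1, 6), sigma = rep(1, 6),
                            kind = "cover")
  expect_true(is.finite(ll0))
  expect_equal(ll0, 6 * (-0.5 * log(2 * pi) - 0.5 * log(0.001)^2))

  set.seed(12)
  y <- matrix(rpois(30, 4), 5, 6)
  lam <- matrix(rexp(30, 1 / 4) + 0.1, 5, 6)
  # term-by-term oracle written from the pmf
  oracle <- sum(y * log(lam) - lam - lfactorial(y))
  expect_equal(observation_loglik(y, lam, kind = "richness"), oracle)

  z <- matrix(rexp(30, 1 / 10), 5, 6)
  sig <- runif(6, 0.4, 1.5)
  oracle_c <- 0
  for (i in 1:5) for (g in 1:6) {
    x <- log(z[i, g] + 0.001)
    m <- log(lam[i, g])
    oracle_c <- oracle_c - 0.5 * log(2 * pi) - log(sig[g]) -
      (x - m)^2 / (2 * sig[g]^2)
  }
  expect_equal(observation_loglik(z, lam, sigma = sig, kind = "cover"), oracle_c)

  expect_error(observation_loglik(c(1.5, 0, 0, 0, 0, 0), rep(1, 6),
                                  kind = "richness"), "integers")
  expect_error(observation_loglik(rep(-1, 6), rep(1, 6), sigma = rep(1, 6),
                                  kind = "cover"), ">= 0")
})

test_that("LKJ log-density follows a * log det(Phi)", {
  expect_equal(lkj_log_density(diag(6), 4), 0)
  expect_equal(lkj_log_density(diag(6), 1), 0)
  for (r in c(-0.6, 0.2, 0.85)) {
    Phi <- matrix(c(1, r, r, 1), 2)
    expect_equal(lkj_log_density(Phi, 4), 4 * log(1 - r^2))
  }
  # general case against a determinant oracle
  set.seed(2)
  Phi6 <- vegbench:::rlkj_corr(6, 4)
  expect_equal(lkj_log_density(Phi6, 4), 4 * determinant(Phi6)$modulus[[1]])
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(lkj_log_density(bad, 4), "positive definite")
})

test_that("random-walk prior follows the July start and June linkage", {
  sig <- rep(0.5, 6)
  flat <- matrix(0, 12, 6)
  expect_equal(random_walk_logprior(flat, sig),
               12 * 6 * dnorm(0, 0, 0.5, log = TRUE))

  # June exactly midway between May and July maximizes the June term
  set.seed(8)
  g <- matrix(rnorm(72, 0, 0.3), 12, 6)
  g_mid <- g; g_mid[6, ] <- (g[5, ] + g[7, ]) / 2
  g_off <- g_mid; g_off[6, ] <- g_mid[6, ] + 0.2
  expect_gt(random_walk_logprior(g_mid, sig), random_walk_logprior(g_off, sig))

  # term-by-term oracle over the walk order Jul, Aug, ..., May, then June
  oracle <- 0
  walk <- c(7, 8, 9, 10, 11, 12, 1, 2, 3, 4, 5)
  for (gg in 1:6) {
    oracle <- oracle + dnorm(g[7, gg], 0, sig[gg], log = TRUE)
    for (k in 2:11) {
      oracle <- oracle + dnorm(g[walk[k], gg], g[walk[k - 1], gg], sig[gg],
                               log = TRUE)
    }
    oracle <- oracle + dnorm(g[6, gg], (g[5, gg] + g[7, gg]) / 2, sig[gg],
                             log = TRUE)
  }
  expect_equal(random_walk_logprior(g, sig), oracle)
  expect_error(random_walk_logprior(g[1:11, ], sig), "12")
})

test_that("hierarchical log-prior sums every stated term", {
  for (variant in c("static", "dynamic")) {
    sp <- small_params(variant)
    p <- sp$params; spec <- sp$spec
    spec$variant <- variant
    lp <- hierarchical_logprior(p, spec)
    # independent term-by-term summation
    hn <- function(x, s) sum(dnorm(x, 0, s, log = TRUE) + log(2))
    nmv <- function(x, mean, sd6) {
      x <- rbind(x); mean <- rbind(mean)
      s <- 0
      for (i in seq_len(nrow(x))) for (g in 1:6) {
        s <- s + dnorm(x[i, g], if (nrow(mean) == 1) mean[1, g] else mean[i, g],
                       sd6[g], log = TRUE)
      }
      s
    }
    oracle <- nmv(p$beta, p$theta[spec$formation_of, ], p$sigma_class) +
      nmv(p$theta, matrix(0, 2, 6), p$sigma_formation) +
      nmv(p$delta, matrix(p$iota, 2, 6, byrow = TRUE), p$sigma_rain) +
      sum(dnorm(p$iota, 0, 10, log = TRUE)) +
      sum(dnorm(p$epsilon, 0, 10, log = TRUE)) +
      nmv(p$zeta, matrix(0, 2, 6), p$sigma_year) +
      nmv(p$eta, matrix(0, 4, 6), p$sigma_plot) +
      hn(p$sigma_class, 2) + hn(p$sigma_formation, 2) + hn(p$sigma_rain, 2) +
      hn(p$sigma_year, 2) + hn(p$sigma_plot, 2) + hn(p$sigma_resid, 2) +
      lkj_log_density(p$Phi, 4)
    if (variant == "static") {
      oracle <- oracle + nmv(p$gamma, matrix(0, 2, 6), p$sigma_bioregion) +
        nmv(p$kappa, matrix(0, 12, 6), p$sigma_month) +
        hn(p$sigma_bioregion, 2) + hn(p$sigma_month, 2)
    } else {
      for (b in 1:2) {
        oracle <- oracle + random_walk_logprior(p$gamma[, b, ], p$sigma_rw[b, ])
      }
      oracle <- oracle + hn(p$sigma_rw, 2)
    }
    expect_equal(lp, oracle)
  }
})

test_that("non-positive scales reject the state and removing a term shifts the prior by that term", {
  sp <- small_params()
  p <- sp$params
  bad <- p; bad$sigma_class[2] <- -0.1
  expect_equal(hierarchical_logprior(bad, sp$spec), -Inf)

  # additivity probe: zeroing one class deviation changes the log-prior by
  # exactly the difference of that class's normal terms
  p2 <- p
  p2$beta[1, ] <- p$theta[sp$spec$formation_of[1], ]
  diff_terms <- sum(dnorm(p2$beta[1, ], p$theta[sp$spec$formation_of[1], ],
                          p$sigma_class, log = TRUE)) -
    sum(dnorm(p$beta[1, ], p$theta[sp$spec$formation_of[1], ],
              p$sigma_class, log = TRUE))
  expect_equal(hierarchical_logprior(p2, sp$spec) -
                 hierarchical_logprior(p, sp$spec), diff_terms)
})

test_that("effect multipliers convert log-scale slopes to percent change", {
  out <- effect_multiplier(0)
  expect_equal(out$factor, 1)
  expect_equal(out$percent, 0)
  out <- effect_multiplier(log(c(1.19, 0.95)))
  expect_equal(out$factor, c(1.19, 0.95))
  expect_equal(out$percent, c(19, -5))
})
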