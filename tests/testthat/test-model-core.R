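# checks on the compiled joint density, its gradient, and the sampler

test_that("compiled gradient matches numerical differentiation", {
  set.seed(42)
  for (cfg in list(c("richness", "static"), c("richness", "dynamic"),
                   c("cover", "static"), c("cover", "dynamic"))) {
    tm <- toy_model(response = cfg[1], variant = cfg[2])
    d <- tm$layout$total
    off <- tm$layout$offsets
    theta <- rnorm(d, 0, 0.3)
    res <- vegbench:::vb_lp_grad(theta, tm$ptr, TRUE)
    idx <- sort(unique(c(sample.int(d, 40),
                         off$phiy + 1:15, off$lss + 1:6, off$iota + 1:6,
                         if (off$lsrwb >= 0) off$lsrwb + 1:12,
                         if (off$lsobs >= 0) off$lsobs + 1:6)))
    h <- 1e-5
    num <- vapply(idx, function(k) {
      tp <- theta; tm_ <- theta
      tp[k] <- tp[k] + h; tm_[k] <- tm_[k] - h
      (vegbench:::vb_lp_grad(tp, tm$ptr, FALSE)$lp -
         vegbench:::vb_lp_grad(tm_, tm$ptr, FALSE)$lp) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(num - res$grad[idx]) / pmax(1, abs(num))), 1e-5)
  }
})

test_that("sampler density equals observation loglik plus hierarchical logprior", {
  # log-density parity: the compiled posterior decomposes into exactly the
  # documented likelihood and prior, evaluated by the plain-R implementations
  set.seed(99)
  for (cfg in list(c("richness", "static"), c("cover", "dynamic"))) {
    tm <- toy_model(response = cfg[1], variant = cfg[2])
    theta <- rnorm(tm$layout$total, 0, 0.25)
    res <- vegbench:::vb_lp_grad(theta, tm$ptr, FALSE)
    cp <- vegbench:::constrain_params(theta, tm$ptr, include_latent = TRUE)
    vals <- if (cfg[1] == "richness") tm$md$Y else exp(tm$md$Y) - 0.001
    ll_r <- observation_loglik(vals, exp(cp$log_lambda), sigma = cp$sigma_obs,
                               kind = cfg[1])
    expect_equal(res$loglik, ll_r, tolerance = 1e-10)
    prm <- cp[setdiff(names(cp), c("L_Phi", "mu", "log_lambda", "u"))]
    lp_r <- hierarchical_logprior(prm, tm$spec,
                                  latent = list(log_lambda = cp$log_lambda,
                                                mu = cp$mu))
    expect_equal(res$logprior, lp_r, tolerance = 1e-10)
    expect_equal(res$lp, res$loglik + res$logprior + res$logjac)
    # linear predictor parity
    mu_r <- linear_predictor(prm, tm$md$index, cfg[2])
    expect_equal(max(abs(mu_r - cp$mu)), 0, tolerance = 1e-12)
  }
})

test_that("seeded sampling is exactly reproducible", {
  tm <- toy_model(n_plots = 10)
  th0 <- rnorm(tm$layout$total, 0, 0.1)
  set.seed(123)
  r1 <- vegbench:::vb_nuts(th0, tm$ptr, 50L, 30L, 0.8, 6L)
  set.seed(123)
  r2 <- vegbench:::vb_nuts(th0, tm$ptr, 50L, 30L, 0.8, 6L)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$stepsize, r2$stepsize)
})

test_that("a short fit runs end to end and stores every parameter block", {
  sc <- simulation_scenario(n_classes = 2, n_formations = 1, n_bioregions = 2,
                            n_years = 2, n_plots = 40, surveys_per_plot = 2)
  pars <- draw_true_params(sc, seed = 2)
  sim <- simulate_surveys(sc, pars, seed = 2)
  fit <- suppressWarnings(
    fit_benchmark_model(sim$aggregated, "richness", "static",
                        chains = 2, iter = 60, warmup = 80, seed = 9))
  expect_s3_class(fit, "vb_fit")
  expect_true(all(is.finite(fit$draws)))
  nm <- colnames(fit$draws)
  for (blk in c("alpha", "beta", "theta", "gamma", "kappa", "delta", "iota",
                "epsilon", "zeta", "sigma_class", "sigma_resid", "corr")) {
    expect_true(any(startsWith(nm, paste0(blk, "["))), info = blk)
  }
  expect_equal(nrow(fit$draws), 120)
  expect_equal(length(fit$chain), 120)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "conf.low", "conf.high") %in% names(td)))
  g <- glance(fit)
  expect_equal(g$chains, 2)
  # identical seed reproduces the fit draws
  fit2 <- suppressWarnings(
    fit_benchmark_model(sim$aggregated, "richness", "static",
                        chains = 2, iter = 60, warmup = 80, seed = 9))
  expect_identical(fit$draws, fit2$draws)
})

test_that("a strong simulated residual correlation is recovered with its sign", {
  sc <- simulation_scenario(n_classes = 3, n_formations = 1, n_bioregions = 2,
                            n_years = 2, n_plots = 150, surveys_per_plot = 2,
                            sigmas = list(resid = 0.5))
  pars <- draw_true_params(sc, seed = 21)
  Phi <- diag(6)
  Phi[2, 3] <- Phi[3, 2] <- 0.9  # forb-grass
  pars$Phi <- Phi
  sim <- simulate_surveys(sc, pars, seed = 21)
  fit <- suppressWarnings(fit_benchmark_model(
    sim$aggregated, "richness", "static",
    chains = 1, iter = 200, warmup = 300, seed = 8))
  est <- mean(fit$draws[, "corr[forb,grass]"])
  expect_gt(est, 0.3)
})

test_that("the lognormal cover model fits and stores observation scales", {
  sc <- simulation_scenario(response = "cover", n_classes = 2,
                            n_formations = 1, n_bioregions = 2, n_years = 2,
                            n_plots = 30, surveys_per_plot = 2)
  pars <- draw_true_params(sc, seed = 4)
  sim <- simulate_surveys(sc, pars, seed = 4)
  fit <- fit_benchmark_model(sim$aggregated, "cover", "static",
                             chains = 1, iter = 50, warmup = 80, seed = 3)
  expect_true(any(startsWith(colnames(fit$draws), "sigma_obs[")))
  expect_true(all(is.finite(fit$draws)))
})
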