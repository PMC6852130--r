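static_fixture <- function(S = 200, delta_sign = +1) {
  spec <- vb_model_spec("richness", "static", n_classes = 2, n_formations = 1,
                        n_bioregions = 2, n_years = 2, n_plots = 3,
                        formation_of = c(1L, 1L),
                        class_labels = c("c1", "c2"),
                        formation_labels = "f1",
                        bioregion_labels = c("b1", "b2"))
  params <- list(
    alpha = log(c(5, 5, 5, 5, 5, 5)),
    theta = matrix(0.1, 1, 6),
    beta = matrix(c(0, 0.3), 2, 6),
    gamma = matrix(c(0.05, -0.05), 2, 6),
    kappa = matrix(0, 12, 6),
    delta = matrix(delta_sign * 0.2, 2, 6),
    iota = rep(delta_sign * 0.2, 6),
    epsilon = rep(-0.1, 6),
    zeta = matrix(0, 2, 6), eta = matrix(0, 3, 6),
    sigma_class = rep(0.3, 6), sigma_formation = rep(0.3, 6),
    sigma_bioregion = rep(0.2, 6), sigma_month = rep(0.1, 6),
    sigma_rain = rep(0.1, 6), sigma_year = rep(0.1, 6),
    sigma_plot = rep(0.2, 6), sigma_resid = rep(0.25, 6),
    Phi = diag(6)
  )
  list(fit = degenerate_fit(params, spec, toy_scaling(), S = S),
       params = params, spec = spec)
}

test_that("grid enumeration reproduces combinatorial counts", {
  g <- enumerate_benchmark_grid(paste0("b", 1:3), paste0("c", 1:5),
                                mode = "static")
  expect_equal(g$summary$n_cells, 15L)
  expect_equal(nrow(g$cells), 15L)
  gd <- enumerate_benchmark_grid("b1", "c1", mode = "dynamic")
  expect_equal(gd$summary$n_cells, 12L)
  expect_equal(gd$summary$benchmarks_per_response, 12L * 6L * 3L)
  expect_error(enumerate_benchmark_grid("b1", c("c1", "c1")), "duplicate")
  expect_error(enumerate_benchmark_grid(character(0), "c1"), "non-empty")
})

test_that("benchmark quantiles follow a sort-based oracle and are monotone", {
  s <- matrix(rep(1:100, 6), 100, 6)
  q <- benchmark_quantiles(s, c(0.55, 0.65, 0.75))
  manual_q7 <- function(x, p) {
    x <- sort(x); h <- (length(x) - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  }
  expect_equal(unname(q[, 1]),
               vapply(c(0.55, 0.65, 0.75), function(p) manual_q7(1:100, p),
                      numeric(1)))
  const <- matrix(7, 150, 6)
  expect_true(all(benchmark_quantiles(const) == 7))
  set.seed(21)
  rnd <- matrix(rexp(600), 100, 6)
  qr <- benchmark_quantiles(rnd)
  expect_true(all(diff(qr[, 1]) >= 0))
  expect_true(all(apply(qr, 2, function(col) !is.unsorted(col))))
  expect_error(benchmark_quantiles(rnd[1:50, ]), "floor")
  expect_error(benchmark_quantiles(rnd, c(0.75, 0.55)), "increasing")
})

test_that("cell distributions are plug-in exp(mu) for point-mass draws", {
  fx <- static_fixture()
  smp <- cell_distribution(fx$fit, "b1", "c1", rainfall_mm = 600,
                           nonnative_pct = 0,
                           include_overdispersion = FALSE)
  # raw 600 mm standardizes to 0; raw 0% nonnative standardizes to -0.5
  mu <- fx$params$alpha + fx$params$beta[1, ] + fx$params$gamma[1, ] +
    0 * fx$params$delta[1, ] + (-0.5) * fx$params$epsilon
  expect_equal(unname(smp[1, ]), unname(exp(mu)))
  expect_true(all(apply(smp, 2, function(x) length(unique(x)) == 1)))

  # alpha-only richness cell: constant 5
  fx2 <- static_fixture()
  p2 <- fx$params
  p2$beta[] <- 0; p2$theta[] <- 0; p2$gamma[] <- 0; p2$delta[] <- 0
  p2$iota[] <- 0; p2$epsilon[] <- 0
  fit2 <- degenerate_fit(p2, fx$spec, toy_scaling())
  smp2 <- cell_distribution(fit2, "b1", "c1", rainfall_mm = 600,
                            include_overdispersion = FALSE)
  expect_equal(unname(smp2[1, ]), rep(5, 6))

  # overdispersion strictly increases spread
  set.seed(33)
  smp_od <- cell_distribution(fx$fit, "b1", "c1", rainfall_mm = 600,
                              include_overdispersion = TRUE)
  expect_true(all(apply(smp_od, 2, var) > apply(smp, 2, var)))
  expect_error(cell_distribution(fx$fit, "b9", "c1", rainfall_mm = 600),
               "unknown bioregion")
})

test_that("benchmark tables have the combinatorial row count and rainfall monotonicity", {
  fx <- static_fixture(delta_sign = +1)
  levels <- tidyr::expand_grid(bioregion = c("b1", "b2"),
                               vegetation_class = c("c1", "c2"))
  levels$q10 <- 400; levels$q50 <- 600; levels$q90 <- 800
  g <- enumerate_benchmark_grid(c("b1", "b2"), c("c1", "c2"), mode = "static")
  tb <- build_benchmark_table(fx$fit, g, levels,
                              include_overdispersion = FALSE)
  expect_equal(nrow(tb), 4 * 1 * 6 * 3)  # cells x levels x growth forms x quantiles
  expect_true(all(tb$value >= 0))
  # quantile monotonicity within every key
  mono <- tb |>
    dplyr::group_by(bioregion, vegetation_class, rainfall_level, growth_form) |>
    dplyr::summarise(ok = !is.unsorted(value[order(quantile)]), .groups = "drop")
  expect_true(all(mono$ok))

  # dynamic-style rainfall levels: positive delta makes above-average >= average
  # >= below-average; emulate by evaluating the same static cell at the three
  # rainfall levels directly
  for (cellr in list(c("b1", "c1"), c("b2", "c2"))) {
    vals <- vapply(c(400, 600, 800), function(mm) {
      cell_distribution(fx$fit, cellr[1], cellr[2], rainfall_mm = mm,
                        include_overdispersion = FALSE)[1, "forb"]
    }, numeric(1))
    expect_true(all(diff(vals) > 0))
  }

  # point-mass draws with overdispersion off: benchmark equals plug-in exp(mu)
  # for every quantile
  one <- tb[tb$bioregion == "b1" & tb$vegetation_class == "c1" &
              tb$growth_form == "fern", ]
  expect_equal(length(unique(one$value)), 1L)

  # permutation of the grid only permutes rows
  g2 <- list(cells = g$cells[4:1, ])
  tb2 <- build_benchmark_table(fx$fit, g2, levels,
                               include_overdispersion = FALSE)
  key <- function(x) paste(x$bioregion, x$vegetation_class, x$growth_form,
                           x$quantile)
  expect_equal(tb2$value[order(key(tb2))], tb$value[order(key(tb))])

  expect_error(build_benchmark_table(fx$fit, g, levels[-1, ]),
               "missing rainfall")
})

test_that("unobserved classes are extrapolated from their formation mean", {
  fx <- static_fixture()
  levels <- tibble::tibble(bioregion = "b1", vegetation_class = "cx",
                           q10 = 400, q50 = 600, q90 = 800)
  cells <- tibble::tibble(bioregion = "b1", vegetation_class = "cx",
                          vegetation_formation = "f1")
  tb <- build_benchmark_table(fx$fit, cells, levels,
                              include_overdispersion = FALSE)
  expect_true(all(tb$extrapolated))
  # beta is replaced by theta of the formation
  mu <- fx$params$alpha + fx$params$theta[1, ] + fx$params$gamma[1, ] +
    (-0.5) * fx$params$epsilon
  expect_equal(tb$value[tb$growth_form == "fern"][1], exp(mu)[1])
})

test_that("comparison against elicited benchmarks reports overlap and differences", {
  bm <- tidyr::expand_grid(
    bioregion = "b1", vegetation_class = c("c1", "c2"),
    growth_form = "forb", quantile = c(0.55, 0.65, 0.75))
  bm$mode <- "static"; bm$response <- "richness"
  bm$value <- ifelse(bm$vegetation_class == "c1",
                     c(4, 5, 6)[match(bm$quantile, c(0.55, 0.65, 0.75))],
                     c(20, 21, 22)[match(bm$quantile, c(0.55, 0.65, 0.75))])
  el <- tibble::tibble(
    bioregion = "b1", vegetation_class = c("c1", "c2", "c3"),
    growth_form = "forb",
    mean = c(5, 10, 1), lo10 = c(4, 8, 0), hi90 = c(6, 12, 2))
  expect_warning(cmp <- compare_to_elicited(bm, el), "no modeled counterpart")
  c1 <- cmp[cmp$vegetation_class == "c1", ]
  expect_true(c1$overlap)
  expect_equal(c1$difference, 0)
  c2 <- cmp[cmp$vegetation_class == "c2", ]
  expect_false(c2$overlap)        # modeled 20-22 vs elicited 8-12: disjoint
  expect_equal(c2$difference, 21 - 10)
  expect_equal(nrow(attr(cmp, "unmatched")), 1L)
})
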