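# shared builders for small in-code fixtures

toy_records <- function() {
  tibble::tibble(
    survey_id = "s1",
    species = c("forb_a", "forb_b", "grass_a", "weed_x"),
    native = c(TRUE, TRUE, TRUE, FALSE),
    growth_form = c("forb", "forb", "grass", "forb"),
    cover = c(10, 20, 5, 7)
  )
}

toy_surveys <- function(ids = "s1") {
  tibble::tibble(
    survey_id = ids,
    plot_id = paste0("p_", ids),
    vegetation_class = "wet_forest",
    vegetation_formation = "forest",
    bioregion = "coastal",
    month = 3L,
    year = 2005L,
    rainfall_12mo = 800
  )
}

# a small prepared model with its compiled data pointer
toy_model <- function(response = "richness", variant = "static", seed = 7,
                      n_classes = 4, n_formations = 2, n_bioregions = 2,
                      n_years = 3, n_plots = 15, surveys_per_plot = 2) {
  sc <- simulation_scenario(response = response, variant = variant,
                            n_classes = n_classes, n_formations = n_formations,
                            n_bioregions = n_bioregions, n_years = n_years,
                            n_plots = n_plots,
                            surveys_per_plot = surveys_per_plot)
  pars <- draw_true_params(sc, seed = seed)
  sim <- simulate_surveys(sc, pars, seed = seed)
  md <- vegbench:::prepare_model_data(sim$aggregated, response)
  lv <- md$levels
  spec <- vb_model_spec(response, variant,
                        n_classes = length(lv$class),
                        n_formations = length(lv$formation),
                        n_bioregions = length(lv$bioregion),
                        n_years = length(lv$year), n_plots = length(lv$plot),
                        formation_of = md$formation_of)
  ptr <- vegbench:::vb_data_ptr(vegbench:::vb_cpp_data(md, spec))
  list(scenario = sc, params = pars, sim = sim, md = md, spec = spec, ptr = ptr,
       layout = vegbench:::vb_layout(ptr))
}

# fabricate a vb_fit whose draws are S copies of one parameter set
degenerate_fit <- function(params, spec, scaling, S = 200) {
  blocks <- vegbench:::stored_blocks(spec, "population")
  vals <- unlist(lapply(names(blocks), function(nm) as.numeric(params[[nm]])),
                 use.names = FALSE)
  nms <- unlist(lapply(names(blocks),
                       function(nm) vegbench:::flat_names(nm, blocks[[nm]])),
                use.names = FALSE)
  gfs <- growth_forms()
  pr <- utils::combn(6, 2)
  corr <- params$Phi[lower.tri(params$Phi)]
  nms <- c(nms, paste0("corr[", gfs[pr[1, ]], ",", gfs[pr[2, ]], "]"))
  vals <- c(vals, corr)
  draws <- matrix(rep(vals, each = S), S, length(vals))
  colnames(draws) <- nms
  structure(list(draws = draws, chain = rep(1L, S), spec = spec,
                 scaling = scaling, model_data = NULL,
                 sampler = list(chains = 1L, iter = S, warmup = 0L,
                                divergences = 0L)),
            class = "vb_fit")
}

toy_scaling <- function() {
  covariate_scaling(c("rainfall_std", "nonnative_std"), mean = c(600, 5),
                    sd = c(200, 10))
}
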