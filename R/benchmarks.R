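#' Extract posterior draws of one parameter block
#'
#' @param fit A `vb_fit`.
#' @param name Block name (e.g. `"alpha"`, `"beta"`, `"gamma"`, `"corr"`).
#' @return An array with first dimension the draws; remaining dimensions as
#'   in the parameter definition (e.g. classes x growth forms for `beta`).
#' @export
extract_block <- function(fit, name) {
  stopifnot(inherits(fit, "vb_fit"))
  if (name == "corr") {
    idx <- grep("^corr\\[", colnames(fit$draws))
    if (length(idx) != 15) stop("correlation draws not found")
    return(fit$draws[, idx, drop = FALSE])
  }
  pars <- if (any(startsWith(colnames(fit$draws), "eta["))) "all" else "population"
  blocks <- stored_blocks(fit$spec, pars)
  labels <- blocks[[name]]
  if (is.null(labels)) stop("no stored block named '", name, "'")
  nms <- flat_names(name, labels)
  idx <- match(nms, colnames(fit$draws))
  if (anyNA(idx)) stop("stored draws are missing columns for '", name, "'")
  dims <- vapply(labels, length, integer(1))
  out <- fit$draws[, idx, drop = FALSE]
  array(out, dim = c(nrow(out), dims),
        dimnames = c(list(NULL), labels))
}

# rebuild the lower Cholesky factor of Sigma for each draw
sigma_chol_draws <- function(fit) {
  corr <- extract_block(fit, "corr")
  sr <- extract_block(fit, "sigma_resid")
  S <- nrow(corr)
  pr <- utils::combn(6, 2)
  out <- vector("list", S)
  Phi <- diag(6)
  for (s in seq_len(S)) {
    Phi[lower.tri(Phi)] <- 0
    for (k in 1:15) {
      Phi[pr[2, k], pr[1, k]] <- corr[s, k]
      Phi[pr[1, k], pr[2, k]] <- corr[s, k]
    }
    diag(Phi) <- 1
    L <- t(chol(Phi))
    out[[s]] <- L * sr[s, ]
  }
  out
}

#' Enumerate the benchmark grid
#'
#' Builds the list of grid cells over which benchmarks are computed: one
#' cell per bioregion-class combination (static mode) or per
#' bioregion-class-month combination (dynamic mode), together with the
#' benchmark counts those cells imply (6 growth forms; 3 rainfall levels in
#' dynamic mode, 1 in static mode; 2 response types).
#'
#' @param bioregions Character vector of bioregion labels.
#' @param classes Character vector of vegetation-class labels (no duplicates).
#' @param months Months to include in dynamic mode (default all 12).
#' @param mode `"static"` or `"dynamic"`.
#' @return A list with `cells` (tibble) and `summary` (named list:
#'   `n_cells`, `benchmarks_per_response`, `total_benchmarks` across both
#'   response types).
#' @export
#' @examples
#' enumerate_benchmark_grid(paste0("b", 1:18), paste0("c", 1:95),
#'                          mode = "static")$summary
enumerate_benchmark_grid <- function(bioregions, classes, months = 1:12,
                                     mode = c("static", "dynamic")) {
  mode <- match.arg(mode)
  if (length(bioregions) == 0 || length(classes) == 0) {
    stop("bioregions and classes must be non-empty")
  }
  if (anyDuplicated(classes)) {
    stop("duplicate vegetation-class labels: ",
         paste(unique(classes[duplicated(classes)]), collapse = ", "))
  }
  if (anyDuplicated(bioregions)) stop("duplicate bioregion labels")
  if (mode == "dynamic") {
    stopifnot(all(months %in% 1:12))
    cells <- tidyr::expand_grid(bioregion = bioregions,
                                vegetation_class = classes,
                                month = as.integer(months))
    n_levels <- 3L
  } else {
    cells <- tidyr::expand_grid(bioregion = bioregions,
                                vegetation_class = classes)
    n_levels <- 1L
  }
  n_cells <- nrow(cells)
  per_resp <- n_cells * 6L * n_levels
  list(cells = cells,
       summary = list(n_cells = n_cells,
                      benchmarks_per_response = per_resp,
                      total_benchmarks = 2L * per_resp))
}

#' Posterior benchmark distribution for one grid cell
#'
#' For each posterior draw, evaluates the cell's expected response for a new
#' plot: intercept + class deviation + seasonal term + rainfall effect at the
#' requested level + nonnative-cover effect at raw 0% (both mapped through
#' the stored covariate scaling), optionally plus survey-level MVN
#' overdispersion, new-year and new-plot deviations, and observation noise,
#' then transforms to the response scale (counts for richness; percent cover
#' with the 0.001 offset subtracted and floored at 0).
#'
#' @param fit A `vb_fit`.
#' @param bioregion,vegetation_class Cell labels. A class absent from the
#'   fitted data is extrapolated from its formation mean (supply
#'   `vegetation_formation`).
#' @param month Calendar month 1-12 (dynamic variant). For the static
#'   variant the month intercept is set to its prior mean of zero (an
#'   average month) unless a month is given.
#' @param rainfall_mm Rainfall level in raw mm (12-month accumulation).
#' @param nonnative_pct Raw nonnative cover percent (default 0).
#' @param vegetation_formation Formation label, required when extrapolating.
#' @param include_overdispersion Add MVN(0, Sigma) survey-level deviations
#'   (default TRUE).
#' @param include_year,include_plot Add new-year / new-plot normal deviations
#'   (default FALSE: benchmarks describe an average year and plot).
#' @param include_observation Add observation noise: Poisson draws for
#'   richness, lognormal noise for cover (default FALSE).
#' @param odisp Internal: precomputed overdispersion draws (S x 6).
#' @return An `S x 6` matrix of response-scale values, columns
#'   [growth_forms()].
#' @export
cell_distribution <- function(fit, bioregion, vegetation_class, month = NULL,
                              rainfall_mm, nonnative_pct = 0,
                              vegetation_formation = NULL,
                              include_overdispersion = TRUE,
                              include_year = FALSE, include_plot = FALSE,
                              include_observation = FALSE,
                              odisp = NULL) {
  spec <- fit$spec
  S <- nrow(fit$draws)
  bi <- match(bioregion, spec$bioregion_labels)
  if (is.na(bi)) stop("unknown bioregion '", bioregion, "'")
  vi <- match(vegetation_class, spec$class_labels)
  extrapolated <- is.na(vi)
  alpha <- extract_block(fit, "alpha")
  if (!extrapolated) {
    beta_v <- extract_block(fit, "beta")[, vi, ]
  } else {
    if (is.null(vegetation_formation)) {
      stop("class '", vegetation_class,
           "' was not observed; supply vegetation_formation to extrapolate")
    }
    fi <- match(vegetation_formation, spec$formation_labels)
    if (is.na(fi)) stop("unknown formation '", vegetation_formation, "'")
    beta_v <- extract_block(fit, "theta")[, fi, ]
  }
  if (spec$variant == "dynamic") {
    if (is.null(month)) stop("dynamic benchmarks require a month")
    season <- extract_block(fit, "gamma")[, month, bi, ]
  } else {
    season <- extract_block(fit, "gamma")[, bi, ]
    if (!is.null(month)) season <- season + extract_block(fit, "kappa")[, month, ]
  }
  r_std <- standardize_value(fit$scaling, "rainfall_std", rainfall_mm)
  e_std <- standardize_value(fit$scaling, "nonnative_std", nonnative_pct)
  delta_b <- extract_block(fit, "delta")[, bi, ]
  epsilon <- extract_block(fit, "epsilon")
  mu <- alpha + beta_v + season + r_std * delta_b + e_std * epsilon
  if (include_year) {
    sy <- extract_block(fit, "sigma_year")
    mu <- mu + matrix(stats::rnorm(S * 6), S, 6) * sy
  }
  if (include_plot) {
    sp <- extract_block(fit, "sigma_plot")
    mu <- mu + matrix(stats::rnorm(S * 6), S, 6) * sp
  }
  if (include_overdispersion) {
    if (is.null(odisp)) {
      Ls <- sigma_chol_draws(fit)
      z <- matrix(stats::rnorm(S * 6), 6, S)
      odisp <- t(vapply(seq_len(S), function(s) as.numeric(Ls[[s]] %*% z[, s]),
                        numeric(6)))
    }
    mu <- mu + odisp
  }
  if (fit$spec$response == "richness") {
    out <- exp(mu)
    if (include_observation) {
      out <- matrix(stats::rpois(S * 6, out), S, 6)
    }
  } else {
    if (include_observation) {
      so <- extract_block(fit, "sigma_obs")
      mu <- mu + matrix(stats::rnorm(S * 6), S, 6) * so
    }
    out <- pmax(exp(mu) - 0.001, 0)
  }
  colnames(out) <- growth_forms()
  attr(out, "extrapolated") <- extrapolated
  out
}

#' Marginal benchmark quantiles of a cell sample
#'
#' Empirical quantiles per growth form, computed independently for each
#' column (multivariate quantiles are deliberately not attempted: a joint
#' quantile has no single-number summary per growth form).
#'
#' @param sample An `S x 6` matrix from [cell_distribution()].
#' @param quantiles Strictly increasing probabilities in (0, 1); default
#'   `c(0.55, 0.65, 0.75)` for lower through higher benchmarks.
#' @param floor_n Minimum sample size (default 100).
#' @return Matrix `length(quantiles) x 6` of benchmark values.
#' @export
benchmark_quantiles <- function(sample, quantiles = c(0.55, 0.65, 0.75),
                                floor_n = 100) {
  sample <- as.matrix(sample)
  if (nrow(sample) < floor_n) {
    stop("sample has ", nrow(sample), " draws; floor is ", floor_n)
  }
  if (any(quantiles <= 0 | quantiles >= 1) || is.unsorted(quantiles, strictly = TRUE)) {
    stop("quantiles must be strictly increasing within (0, 1)")
  }
  q <- apply(sample, 2, stats::quantile, probs = quantiles, names = FALSE, type = 7)
  q <- matrix(q, nrow = length(quantiles))
  dimnames(q) <- list(paste0("q", round(quantiles * 100)), colnames(sample))
  q
}

#' Build a benchmark table over a grid
#'
#' Applies [cell_distribution()] and [benchmark_quantiles()] to every grid
#' cell. Static mode evaluates each bioregion-class cell at its average
#' (50th-quantile) rainfall; dynamic mode emits below-average, average and
#' above-average levels (10th/50th/90th rainfall quantiles) for each
#' bioregion-class-month cell. All benchmarks are computed at raw 0%
#' nonnative cover (mapped through the stored covariate scaling).
#'
#' @param fit A `vb_fit` (static variant for `mode = "static"`, dynamic
#'   variant for `mode = "dynamic"`).
#' @param grid Output of [enumerate_benchmark_grid()], or its `cells` tibble.
#'   An optional `vegetation_formation` column enables extrapolation of
#'   unobserved classes.
#' @param rainfall_levels Tibble with `bioregion`, `vegetation_class`,
#'   `q10`, `q50`, `q90` (see [impute_rainfall_levels()]).
#' @param quantiles Benchmark quantiles (default 55th/65th/75th).
#' @param nonnative_pct Raw nonnative cover (default 0).
#' @inheritParams cell_distribution
#' @return A tibble of class `vb_benchmarks`: one row per cell x rainfall
#'   level x growth form x quantile, with columns `mode`, `response`,
#'   `bioregion`, `vegetation_class`, `month`, `rainfall_level`,
#'   `growth_form`, `quantile`, `value`, `extrapolated`.
#' @export
build_benchmark_table <- function(fit, grid, rainfall_levels,
                                  quantiles = c(0.55, 0.65, 0.75),
                                  nonnative_pct = 0,
                                  include_overdispersion = TRUE,
                                  include_year = FALSE, include_plot = FALSE,
                                  include_observation = FALSE) {
  cells <- if (is.data.frame(grid)) grid else grid$cells
  mode <- if ("month" %in% names(cells)) "dynamic" else "static"
  if (mode == "dynamic" && fit$spec$variant != "dynamic") {
    stop("dynamic benchmarks require a dynamic-variant fit")
  }
  key_cells <- paste(cells$bioregion, cells$vegetation_class, sep = "\r")
  key_lv <- paste(rainfall_levels$bioregion, rainfall_levels$vegetation_class,
                  sep = "\r")
  hit <- match(key_cells, key_lv)
  if (anyNA(hit)) {
    bad <- unique(key_cells[is.na(hit)])
    stop("missing rainfall levels for ", length(bad), " cell(s): ",
         paste(gsub("\r", " / ", utils::head(bad, 5)), collapse = "; "))
  }
  S <- nrow(fit$draws)
  odisp <- NULL
  if (include_overdispersion) {
    Ls <- sigma_chol_draws(fit)
    z <- matrix(stats::rnorm(S * 6), 6, S)
    odisp <- t(vapply(seq_len(S), function(s) as.numeric(Ls[[s]] %*% z[, s]),
                      numeric(6)))
  }
  levels_use <- if (mode == "dynamic") {
    c(below_average = "q10", average = "q50", above_average = "q90")
  } else {
    c(average = "q50")
  }
  out <- vector("list", nrow(cells) * length(levels_use))
  k <- 0L
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    lv <- rainfall_levels[hit[i], ]
    for (j in seq_along(levels_use)) {
      mm_col <- levels_use[[j]]
      smp <- cell_distribution(
        fit,
        bioregion = ci$bioregion, vegetation_class = ci$vegetation_class,
        month = if (mode == "dynamic") ci$month else NULL,
        rainfall_mm = lv[[mm_col]], nonnative_pct = nonnative_pct,
        vegetation_formation = if ("vegetation_formation" %in% names(ci))
          ci$vegetation_formation else NULL,
        include_overdispersion = include_overdispersion,
        include_year = include_year, include_plot = include_plot,
        include_observation = include_observation,
        odisp = odisp)
      q <- benchmark_quantiles(smp, quantiles, floor_n = min(100, S))
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        bioregion = ci$bioregion, vegetation_class = ci$vegetation_class,
        month = if (mode == "dynamic") ci$month else NA_integer_,
        rainfall_level = names(levels_use)[j],
        growth_form = rep(growth_forms(), each = length(quantiles)),
        quantile = rep(quantiles, times = 6),
        value = as.numeric(q),
        extrapolated = attr(smp, "extrapolated")
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res <- dplyr::mutate(res, mode = mode, response = fit$spec$response,
                       .before = 1)
  class(res) <- c("vb_benchmarks", class(res))
  res
}

#' Compare modeled benchmarks with expert-elicited benchmarks
#'
#' Joins a static benchmark table against expert-elicited values per
#' bioregion, vegetation class and growth form, and reports whether the
#' modeled 55th-75th quantile band intersects the elicited 10th-90th
#' percentile range, plus the signed midpoint difference (modeled 65th
#' quantile minus elicited mean).
#'
#' @param benchmarks A static `vb_benchmarks` table (quantiles 0.55, 0.65,
#'   0.75 present).
#' @param elicited Tibble with columns `bioregion`, `vegetation_class`,
#'   `growth_form`, `mean`, `lo10`, `hi90`.
#' @return A tibble with modeled and elicited bands, `overlap`, and
#'   `difference`. Elicited keys with no modeled counterpart are attached as
#'   attribute `"unmatched"` and flagged with a warning.
#' @export
compare_to_elicited <- function(benchmarks, elicited) {
  need <- c("bioregion", "vegetation_class", "growth_form", "mean", "lo10", "hi90")
  miss <- setdiff(need, names(elicited))
  if (length(miss) > 0) stop("elicited is missing columns: ", paste(miss, collapse = ", "))
  wide <- benchmarks |>
    dplyr::filter(.data$quantile %in% c(0.55, 0.65, 0.75)) |>
    dplyr::mutate(qname = paste0("q", round(.data$quantile * 100))) |>
    dplyr::select("bioregion", "vegetation_class", "growth_form", "qname", "value") |>
    tidyr::pivot_wider(names_from = "qname", values_from = "value")
  joined <- dplyr::inner_join(
    tibble::as_tibble(elicited), wide,
    by = c("bioregion", "vegetation_class", "growth_form"))
  unmatched <- dplyr::anti_join(
    tibble::as_tibble(elicited), wide,
    by = c("bioregion", "vegetation_class", "growth_form"))
  if (nrow(unmatched) > 0) {
    warning(nrow(unmatched), " elicited benchmark(s) had no modeled counterpart")
  }
  out <- joined |>
    dplyr::mutate(
      overlap = .data$q55 <= .data$hi90 & .data$q75 >= .data$lo10,
      difference = .data$q65 - .data$mean
    )
  attr(out, "unmatched") <- unmatched
  out
}
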