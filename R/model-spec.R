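#' Model specification for the benchmark model
#'
#' Describes one model: which response (species richness, Poisson; or summed
#' cover, lognormal), which seasonal variant (dynamic = regionally varying
#' monthly trends under a first-order random-walk prior; static = regionally
#' consistent month intercepts), the index dimensions, and the prior
#' constants.
#'
#' @param response `"richness"` or `"cover"`.
#' @param variant `"dynamic"` or `"static"`.
#' @param n_classes,n_formations,n_bioregions,n_years,n_plots Dimension counts
#'   (all >= 1).
#' @param formation_of Integer vector of length `n_classes`: the formation
#'   index of each vegetation class (classes are nested in formations).
#' @param lkj_shape LKJ shape `a` (>= 0): the correlation-matrix prior density
#'   is proportional to `|Phi|^a`. Default 4, concentrating prior mass toward
#'   the identity.
#' @param halfnormal_scale Scale of the half-normal priors on all standard
#'   deviations (default 2).
#' @param vague_sd Standard deviation of the vague zero-mean normal priors on
#'   the rainfall grand mean and the nonnative-cover effect (default 10).
#' @param class_labels,formation_labels,bioregion_labels,year_labels,plot_labels
#'   Optional label vectors for pretty output; defaults are generated.
#' @return An object of class `vb_model_spec`.
#' @export
vb_model_spec <- function(response = c("richness", "cover"),
                          variant = c("static", "dynamic"),
                          n_classes, n_formations, n_bioregions,
                          n_years, n_plots, formation_of,
                          lkj_shape = 4, halfnormal_scale = 2, vague_sd = 10,
                          class_labels = NULL, formation_labels = NULL,
                          bioregion_labels = NULL, year_labels = NULL,
                          plot_labels = NULL) {
  response <- match.arg(response)
  variant <- match.arg(variant)
  dims <- c(n_classes = n_classes, n_formations = n_formations,
            n_bioregions = n_bioregions, n_years = n_years, n_plots = n_plots)
  if (any(dims < 1)) stop("all dimension counts must be >= 1")
  formation_of <- as.integer(formation_of)
  if (length(formation_of) != n_classes ||
      any(formation_of < 1 | formation_of > n_formations)) {
    stop("formation_of must map each of the ", n_classes,
         " classes to a formation in 1..", n_formations)
  }
  if (lkj_shape < 0) stop("lkj_shape must be >= 0")
  if (halfnormal_scale <= 0 || vague_sd <= 0) stop("prior scales must be > 0")
  structure(list(
    response = response, variant = variant,
    n_growthforms = 6L, n_classes = as.integer(n_classes),
    n_formations = as.integer(n_formations),
    n_bioregions = as.integer(n_bioregions),
    n_years = as.integer(n_years), n_plots = as.integer(n_plots),
    n_months = 12L, formation_of = formation_of,
    lkj_shape = lkj_shape, halfnormal_scale = halfnormal_scale,
    vague_sd = vague_sd,
    class_labels = class_labels %||% paste0("class_", seq_len(n_classes)),
    formation_labels = formation_labels %||% paste0("formation_", seq_len(n_formations)),
    bioregion_labels = bioregion_labels %||% paste0("bioregion_", seq_len(n_bioregions)),
    year_labels = year_labels %||% paste0("year_", seq_len(n_years)),
    plot_labels = plot_labels %||% paste0("plot_", seq_len(n_plots))
  ), class = "vb_model_spec")
}

#' @export
print.vb_model_spec <- function(x, ...) {
  cat("<vb_model_spec> ", x$response, ", ", x$variant, " variant\n", sep = "")
  cat("  classes: ", x$n_classes, " in ", x$n_formations, " formations; ",
      x$n_bioregions, " bioregions; ", x$n_years, " years; ",
      x$n_plots, " plots\n", sep = "")
  cat("  priors: LKJ a = ", x$lkj_shape, ", half-normal scale = ",
      x$halfnormal_scale, ", vague sd = ", x$vague_sd, "\n", sep = "")
  invisible(x)
}

#' Validate a parameter set against a model specification
#'
#' A parameter set is a named list holding every model parameter on the
#' constrained scale: `alpha` (6), `beta` (classes x 6), `theta`
#' (formations x 6), seasonal terms (`gamma` of dim `c(12, B, 6)` plus
#' `sigma_rw` `B x 6` for the dynamic variant; `gamma` `B x 6`, `kappa`
#' `12 x 6`, `sigma_bioregion`, `sigma_month` for the static variant),
#' `delta` (B x 6), `iota` (6), `epsilon` (6), `zeta` (years x 6), `eta`
#' (plots x 6), scale vectors `sigma_class`, `sigma_formation`,
#' `sigma_rain`, `sigma_year`, `sigma_plot`, residual scales `sigma_resid`
#' (6), correlation matrix `Phi` (6 x 6), and `sigma_obs` (6, cover only).
#'
#' @param params Named list of parameter values.
#' @param spec A [vb_model_spec()].
#' @return `params`, invisibly, after checking shapes and constraints.
#' @export
validate_param_set <- function(params, spec) {
  G <- spec$n_growthforms
  chk <- function(name, dim_expected) {
    x <- params[[name]]
    if (is.null(x)) stop("param set is missing '", name, "'")
    d <- if (is.null(dim(x))) length(x) else dim(x)
    if (!identical(as.integer(d), as.integer(dim_expected))) {
      stop("'", name, "' has dimension (", paste(d, collapse = ","),
           "); expected (", paste(dim_expected, collapse = ","), ")")
    }
  }
  chk("alpha", G); chk("beta", c(spec$n_classes, G))
  chk("theta", c(spec$n_formations, G))
  if (spec$variant == "dynamic") {
    chk("gamma", c(12L, spec$n_bioregions, G))
    chk("sigma_rw", c(spec$n_bioregions, G))
  } else {
    chk("gamma", c(spec$n_bioregions, G)); chk("kappa", c(12L, G))
    chk("sigma_bioregion", G); chk("sigma_month", G)
  }
  chk("delta", c(spec$n_bioregions, G)); chk("iota", G); chk("epsilon", G)
  chk("zeta", c(spec$n_years, G)); chk("eta", c(spec$n_plots, G))
  for (s in c("sigma_class", "sigma_formation", "sigma_rain", "sigma_year",
              "sigma_plot", "sigma_resid")) chk(s, G)
  if (spec$response == "cover") chk("sigma_obs", G)
  chk("Phi", c(G, G))
  sig_names <- grep("^sigma_", names(params), value = TRUE)
  for (s in sig_names) {
    if (any(params[[s]] <= 0)) stop("'", s, "' must be strictly positive")
  }
  Phi <- params$Phi
  if (max(abs(Phi - t(Phi))) > 1e-8 || max(abs(diag(Phi) - 1)) > 1e-8) {
    stop("Phi must be a symmetric correlation matrix with unit diagonal")
  }
  ev <- min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("Phi must be positive definite")
  invisible(params)
}
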