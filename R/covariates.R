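#' Standardize model covariates
#'
#' Centres and scales the rainfall and nonnative-cover covariates to mean 0,
#' sd 1 over the supplied surveys, storing the scaling so that predictions
#' (e.g. benchmarks at raw 0% nonnative cover, or at a named rainfall level
#' in mm) can be mapped onto the fitted scale later. The population
#' (n-denominator) standard deviation is used, so two points standardize to
#' exactly -1 and +1.
#'
#' @param data Aggregated survey tibble (see [aggregate_surveys()]).
#' @param vars Named character vector: names are output column suffixes,
#'   values are input columns. Default standardizes `rainfall_12mo` to
#'   `rainfall_std` and `nonnative_cover` to `nonnative_std`.
#' @return `data` with the standardized columns appended and the scaling
#'   attached as attribute `"scaling"` (see [covariate_scaling()]).
#' @export
standardize_covariates <- function(data,
                                   vars = c(rainfall_std = "rainfall_12mo",
                                            nonnative_std = "nonnative_cover")) {
  stopifnot(is.data.frame(data))
  if (nrow(data) < 2) stop("need at least 2 surveys to standardize covariates")
  sc <- list()
  out <- tibble::as_tibble(data)
  for (i in seq_along(vars)) {
    src <- vars[[i]]
    dst <- names(vars)[i]
    x <- data[[src]]
    if (is.null(x)) stop("column '", src, "' not found")
    m <- mean(x)
    s <- sqrt(mean((x - m)^2))
    if (!is.finite(s) || s <= 0) {
      stop("covariate '", src, "' is constant (sd = 0); cannot standardize")
    }
    out[[dst]] <- (x - m) / s
    sc[[dst]] <- c(mean = m, sd = s)
  }
  attr(out, "scaling") <- covariate_scaling(
    variable = names(sc),
    mean = vapply(sc, `[[`, numeric(1), "mean"),
    sd = vapply(sc, `[[`, numeric(1), "sd")
  )
  out
}

#' Covariate scaling object
#'
#' Records the mean and sd used to standardize each covariate so raw values
#' (such as 0% nonnative cover, or a rainfall quantile in mm) can be placed
#' on the model scale at prediction time, and model-scale values can be
#' mapped back.
#'
#' @param variable Character vector of standardized-column names.
#' @param mean,sd Numeric vectors of the same length; `sd` must be > 0.
#' @return A tibble of class `vb_scaling`.
#' @export
covariate_scaling <- function(variable, mean, sd) {
  stopifnot(length(variable) == length(mean), length(mean) == length(sd))
  if (any(sd <= 0)) stop("scaling sd must be > 0")
  structure(tibble::tibble(variable = variable, mean = mean, sd = sd),
            class = c("vb_scaling", "tbl_df", "tbl", "data.frame"))
}

scaling_row <- function(scaling, variable) {
  i <- match(variable, scaling$variable)
  if (is.na(i)) {
    stop("no scaling stored for '", variable, "' (have: ",
         paste(scaling$variable, collapse = ", "), ")")
  }
  scaling[i, ]
}

#' Map raw covariate values onto the standardized model scale
#'
#' @param scaling A [covariate_scaling()] object.
#' @param variable Which standardized variable (e.g. `"rainfall_std"`).
#' @param x Raw values (e.g. mm of rainfall, percent nonnative cover).
#' @return Standardized values.
#' @export
standardize_value <- function(scaling, variable, x) {
  r <- scaling_row(scaling, variable)
  unname((x - r$mean) / r$sd)
}

#' Map standardized values back to the raw covariate scale
#'
#' Inverse of [standardize_value()]; the round trip is the identity up to
#' floating-point error.
#'
#' @inheritParams standardize_value
#' @param z Standardized values.
#' @return Raw-scale values.
#' @export
destandardize_value <- function(scaling, variable, z) {
  r <- scaling_row(scaling, variable)
  unname(z * r$sd + r$mean)
}
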