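# Readers and writers for the package's CSV dialects (UTF-8, header row,
# ISO-8601 dates) and a JSON persistence format for posterior draws.

#' Read species records from CSV
#'
#' Columns: `survey_id`, `species`, `native` (logical), `cover` (percent) or
#' `cover_class` (ordinal label, converted through `bbca_map`), optionally
#' `growth_form`.
#'
#' @param path CSV file path.
#' @param bbca_map Named label-to-percent map used when a `cover_class`
#'   column is present (default [default_bbca_map()]).
#' @return A tibble of species records.
#' @export
read_plot_records <- function(path, bbca_map = default_bbca_map()) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!"cover" %in% names(x)) {
    if (!"cover_class" %in% names(x)) {
      stop("records need a 'cover' or 'cover_class' column")
    }
    x$cover <- bbca_to_cover(x$cover_class, bbca_map, survey_id = x$survey_id)
  }
  x$native <- as.logical(x$native)
  x
}

#' Read a growth-form lookup table from CSV
#'
#' Columns: `species`, `growth_form` (one of [growth_forms()]).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_growth_form_lookup <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("species", "growth_form") %in% names(x))) {
    stop("lookup CSV needs columns species, growth_form")
  }
  x
}

#' Read survey metadata from CSV
#'
#' Columns: `survey_id`, `plot_id`, `vegetation_class`,
#' `vegetation_formation`, `bioregion`, `month`, `year`, `rainfall_12mo`,
#' optionally `survey_date` (ISO-8601).
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_surveys <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read a daily rainfall series from CSV
#'
#' Columns: `location_id`, `date` (ISO-8601), `mm`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_rainfall_series <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("location_id", "date", "mm") %in% names(x))) {
    stop("rainfall CSV needs columns location_id, date, mm")
  }
  x$date <- as.Date(x$date)
  x
}

#' Write an aggregated survey table, benchmark table, or comparison report
#'
#' Plain `readr::write_csv` wrappers kept for a stable on-disk dialect.
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_vegbench_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(x)
}

#' Persist posterior draws to JSON
#'
#' Writes a self-describing file holding the draw matrix with parameter
#' names, the chain index, the model specification, the covariate scaling,
#' and the sampler metadata, so a fit can be reloaded without refitting.
#'
#' @param fit A `vb_fit`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "vb_fit"))
  spec <- fit$spec
  payload <- list(
    format = "vegbench-draws-v1",
    parameters = colnames(fit$draws),
    chain = fit$chain,
    draws = unname(as.matrix(fit$draws)),
    spec = unclass(spec),
    scaling = as.data.frame(fit$scaling),
    sampler = fit$sampler
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Reload posterior draws persisted with [write_draws()]
#'
#' @param path JSON path.
#' @return A `vb_fit` (without the original `model_data`; benchmark
#'   construction works, refitting does not).
#' @export
read_draws <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$format, "vegbench-draws-v1")) {
    stop("not a vegbench draws file: ", path)
  }
  draws <- as.matrix(x$draws)
  colnames(draws) <- x$parameters
  spec <- x$spec
  class(spec) <- "vb_model_spec"
  scaling <- covariate_scaling(x$scaling$variable, x$scaling$mean, x$scaling$sd)
  structure(list(draws = draws, chain = as.integer(x$chain), spec = spec,
                 scaling = scaling, model_data = NULL, sampler = x$sampler),
            class = "vb_fit")
}
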