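#' Plot a benchmark table
#'
#' Displays benchmark quantile bands per growth form. Static tables show one
#' band per bioregion-class cell; dynamic tables show seasonal trajectories
#' by month, coloured by rainfall level.
#'
#' @param object A `vb_benchmarks` table.
#' @param cells Optional tibble of `bioregion`, `vegetation_class` rows to
#'   display (defaults to the first 4 cells).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vb_benchmarks <- function(object, cells = NULL, ...) {
  tb <- tibble::as_tibble(object)
  if (is.null(cells)) {
    cells <- dplyr::distinct(tb, .data$bioregion, .data$vegetation_class) |>
      utils::head(4)
  }
  tb <- dplyr::semi_join(tb, cells, by = c("bioregion", "vegetation_class"))
  tb$cell <- paste(tb$bioregion, tb$vegetation_class, sep = "\n")
  if (unique(object$mode)[1] == "dynamic") {
    wide <- tidyr::pivot_wider(tb, names_from = "quantile",
                               values_from = "value", names_prefix = "q")
    qcols <- sort(grep("^q0\\.", names(wide), value = TRUE))
    ggplot2::ggplot(wide, ggplot2::aes(x = .data$month,
                                       colour = .data$rainfall_level,
                                       fill = .data$rainfall_level)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data[[qcols[1]]],
                                        ymax = .data[[qcols[length(qcols)]]]),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line(ggplot2::aes(y = .data[[qcols[2]]])) +
      ggplot2::facet_grid(cell ~ growth_form, scales = "free_y") +
      ggplot2::scale_x_continuous(breaks = c(1, 4, 7, 10)) +
      ggplot2::labs(x = "month", y = unique(tb$response),
                    colour = "rainfall", fill = "rainfall") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tb, ggplot2::aes(x = .data$growth_form, y = .data$value,
                                     group = .data$growth_form)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(ggplot2::aes(shape = factor(.data$quantile))) +
      ggplot2::facet_wrap(~cell, scales = "free_y") +
      ggplot2::labs(x = "growth form", y = unique(tb$response),
                    shape = "quantile") +
      ggplot2::theme_minimal()
  }
}

#' Plot posterior scale parameters of a fitted model
#'
#' Caterpillar plot of the posterior standard-deviation vectors: how much
#' variation each model component (class, formation, bioregion, month, year,
#' plot, residual) explains per growth form.
#'
#' @param object A `vb_fit`.
#' @param conf_level Credible-interval width (default 0.9).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vb_fit <- function(object, conf_level = 0.9, ...) {
  td <- tidy(object, conf_level = conf_level)
  td <- td[grepl("^sigma_", td$term), ]
  td$component <- sub("^sigma_([a-z]+)\\[.*$", "\\1", td$term)
  td$growth_form <- sub("^.*\\[(?:.*,)?([a-z]+)\\]$", "\\1", td$term)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high), height = 0.2) +
    ggplot2::facet_wrap(~growth_form) +
    ggplot2::labs(x = "posterior sd (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a comparison against expert-elicited benchmarks
#'
#' Shows the modeled 55th-75th quantile band (open points at the 65th) next
#' to the elicited mean and 10th-90th range (solid points) per growth form
#' and cell.
#'
#' @param comparison Output of [compare_to_elicited()].
#' @return A ggplot object.
#' @export
plot_elicited_comparison <- function(comparison) {
  cmp <- tibble::as_tibble(comparison)
  cmp$cell <- paste(cmp$bioregion, cmp$vegetation_class, sep = "\n")
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$growth_form)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean, ymin = .data$lo10,
                                          ymax = .data$hi90),
                             position = ggplot2::position_nudge(x = -0.12)) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$q65, ymin = .data$q55,
                                          ymax = .data$q75),
                             shape = 1,
                             position = ggplot2::position_nudge(x = 0.12)) +
    ggplot2::facet_wrap(~cell, scales = "free_y") +
    ggplot2::labs(x = "growth form", y = "benchmark value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
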