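#' Accumulated rainfall over the months preceding a survey
#'
#' Sums daily rainfall over a calendar-anchored, half-open window ending the
#' day before `survey_date`: the window starts on the same calendar date
#' `months` months earlier (rolled back within the month when that date does
#' not exist, e.g. windows crossing 29 February) and excludes the survey day
#' itself. The default 12-month window is the model covariate; 3- and
#' 36-month windows are available through `months` but are not used in
#' modelling because they are strongly correlated with the 12-month total.
#'
#' @param series Daily rainfall: a data frame with columns `date` (Date) and
#'   `mm` (non-negative), at daily resolution.
#' @param survey_date Date (or one coercible via `as.Date`) of the survey.
#' @param months Window length in calendar months (default 12).
#' @return Accumulated rainfall in mm over the window.
#' @export
#' @examples
#' s <- tibble::tibble(date = seq(as.Date("1998-01-01"), as.Date("2001-12-31"), 1),
#'                     mm = 1)
#' accumulate_rainfall(s, as.Date("2000-03-01"))  # leap window: 366
accumulate_rainfall <- function(series, survey_date, months = 12) {
  stopifnot(is.data.frame(series), all(c("date", "mm") %in% names(series)))
  survey_date <- as.Date(survey_date)
  stopifnot(length(survey_date) == 1, !is.na(survey_date))
  if (any(series$mm < 0, na.rm = TRUE)) stop("rainfall mm must be >= 0")
  start <- survey_date %m-% base::months(as.integer(months))
  window <- seq(start, survey_date - 1, by = "day")
  idx <- match(window, series$date)
  if (anyNA(idx)) {
    missing_days <- window[is.na(idx)]
    stop("rainfall series does not cover the accumulation window: missing ",
         length(missing_days), " day(s) from ", min(missing_days),
         " to ", max(missing_days))
  }
  sum(series$mm[idx])
}

#' Historical quantiles of accumulated rainfall for a survey month
#'
#' For each year in `years`, accumulates rainfall over the 12 months prior to
#' the first day of `month`, then returns empirical quantiles of that annual
#' sample. The 10th/50th/90th quantiles define the below-average, average and
#' above-average rainfall levels used for dynamic benchmarks. Quantiles use
#' linear interpolation of order statistics (R type 7).
#'
#' @inheritParams accumulate_rainfall
#' @param month Survey month, 1-12; accumulation is anchored at its first day.
#' @param years Integer vector of anchor years (e.g. `1900:2015`).
#' @param probs Quantile probabilities in (0, 1); default `c(0.1, 0.5, 0.9)`.
#' @param months Accumulation window length (default 12).
#' @return Named numeric vector of quantiles (names like `"q10"`).
#' @export
historical_rainfall_quantiles <- function(series, month, years,
                                          probs = c(0.1, 0.5, 0.9),
                                          months = 12) {
  stopifnot(length(month) == 1, month %in% 1:12)
  if (any(probs <= 0 | probs >= 1)) stop("quantile probabilities must lie in (0, 1)")
  years <- as.integer(years)
  if (length(years) < 2) stop("need at least 2 usable years for historical quantiles")
  anchors <- as.Date(sprintf("%d-%02d-01", years, month))
  acc <- vapply(anchors, function(d) accumulate_rainfall(series, d, months = months),
                numeric(1))
  q <- stats::quantile(acc, probs = probs, type = 7, names = FALSE)
  names(q) <- paste0("q", round(probs * 100))
  q
}

#' Impute rainfall levels for unobserved bioregion-class combinations
#'
#' Fits three separate additive linear regressions (one per quantile: q10,
#' q50, q90) of observed rainfall levels on bioregion and vegetation class,
#' then predicts levels for every target combination. Observed combinations
#' keep their observed values (`source = "observed"`); unobserved ones get
#' regression predictions (`source = "imputed"`). Imputed triples that come
#' out inverted (q10 > q50 etc., possible because the three regressions are
#' independent) are re-sorted, with a warning recording the affected cells.
#'
#' @param observed Tibble with columns `bioregion`, `vegetation_class`,
#'   `q10`, `q50`, `q90` (mm), one row per observed combination.
#' @param targets Tibble with columns `bioregion`, `vegetation_class` listing
#'   the combinations to return (typically the full grid).
#' @return Tibble `targets` + `q10`, `q50`, `q90`, `source`.
#' @export
impute_rainfall_levels <- function(observed, targets) {
  need <- c("bioregion", "vegetation_class", "q10", "q50", "q90")
  miss <- setdiff(need, names(observed))
  if (length(miss) > 0) stop("observed is missing columns: ", paste(miss, collapse = ", "))
  stopifnot(all(c("bioregion", "vegetation_class") %in% names(targets)))
  bad_b <- setdiff(unique(targets$bioregion), unique(observed$bioregion))
  bad_v <- setdiff(unique(targets$vegetation_class), unique(observed$vegetation_class))
  if (length(bad_b) + length(bad_v) > 0) {
    stop("cannot impute: factor level(s) absent from observed data - ",
         if (length(bad_b)) paste0("bioregion: ", paste(bad_b, collapse = ", "), " "),
         if (length(bad_v)) paste0("class: ", paste(bad_v, collapse = ", ")))
  }
  obs <- dplyr::mutate(tibble::as_tibble(observed),
                       bioregion = factor(.data$bioregion),
                       vegetation_class = factor(.data$vegetation_class))
  tgt <- tibble::as_tibble(targets)
  newd <- data.frame(
    bioregion = factor(tgt$bioregion, levels = levels(obs$bioregion)),
    vegetation_class = factor(tgt$vegetation_class, levels = levels(obs$vegetation_class))
  )
  one_factor_b <- nlevels(obs$bioregion) < 2
  one_factor_v <- nlevels(obs$vegetation_class) < 2
  for (qq in c("q10", "q50", "q90")) {
    form <- if (one_factor_b && one_factor_v) stats::as.formula(paste(qq, "~ 1"))
      else if (one_factor_b) stats::as.formula(paste(qq, "~ vegetation_class"))
      else if (one_factor_v) stats::as.formula(paste(qq, "~ bioregion"))
      else stats::as.formula(paste(qq, "~ bioregion + vegetation_class"))
    fit <- stats::lm(form, data = obs)
    tgt[[qq]] <- as.numeric(stats::predict(fit, newdata = newd))
  }
  key_obs <- paste(observed$bioregion, observed$vegetation_class, sep = "\r")
  key_tgt <- paste(tgt$bioregion, tgt$vegetation_class, sep = "\r")
  hit <- match(key_tgt, key_obs)
  tgt$source <- ifelse(is.na(hit), "imputed", "observed")
  for (qq in c("q10", "q50", "q90")) {
    tgt[[qq]][!is.na(hit)] <- observed[[qq]][hit[!is.na(hit)]]
  }
  qm <- as.matrix(tgt[, c("q10", "q50", "q90")])
  inverted <- qm[, 1] > qm[, 2] | qm[, 2] > qm[, 3]
  if (any(inverted)) {
    qm[inverted, ] <- t(apply(qm[inverted, , drop = FALSE], 1, sort))
    tgt$q10 <- qm[, 1]; tgt$q50 <- qm[, 2]; tgt$q90 <- qm[, 3]
    warning(sum(inverted), " imputed rainfall triple(s) were inverted and re-sorted: ",
            paste(utils::head(paste(tgt$bioregion[inverted],
                                    tgt$vegetation_class[inverted]), 5),
                  collapse = "; "))
  }
  tgt
}
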