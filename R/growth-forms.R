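#' The six growth-form categories
#'
#' Every native taxon is assigned to one of six plant growth forms. All
#' 6-vectors and response columns in the package use this fixed alphabetical
#' order: fern, forb, grass (grasses and grass-like), other (not otherwise
#' classified), shrub, tree.
#'
#' @return Character vector of the six growth-form labels, in canonical order.
#' @export
#' @examples
#' growth_forms()
growth_forms <- function() {
  c("fern", "forb", "grass", "other", "shrub", "tree")
}

#' Assign growth forms to species records
#'
#' Joins a species-to-growth-form lookup onto per-species plot records.
#' Species missing from the lookup are flagged (growth form `NA`); flagged
#' native records are excluded from richness/cover aggregation downstream.
#'
#' @param records A data frame of species records with at least columns
#'   `survey_id`, `species`. Any existing `growth_form` column is replaced.
#' @param lookup A data frame with columns `species` and `growth_form`, the
#'   latter restricted to the six categories of [growth_forms()].
#' @return A tibble: `records` with columns `growth_form` (character, `NA`
#'   when unmatched) and `flagged` (logical). The number of unmatched records
#'   is attached as attribute `n_unmatched`.
#' @export
#' @examples
#' recs <- tibble::tibble(survey_id = 1, species = c("a", "b"), native = TRUE,
#'                        cover = c(5, 10))
#' lk <- tibble::tibble(species = "a", growth_form = "forb")
#' assign_growth_forms(recs, lk)
assign_growth_forms <- function(records, lookup) {
  stopifnot(is.data.frame(records), all(c("survey_id", "species") %in% names(records)))
  if (!is.data.frame(lookup) || nrow(lookup) == 0L) {
    stop("growth-form lookup is empty: supply a non-empty species/growth_form table")
  }
  if (!all(c("species", "growth_form") %in% names(lookup))) {
    stop("lookup must have columns 'species' and 'growth_form'")
  }
  bad <- setdiff(unique(lookup$growth_form), growth_forms())
  if (length(bad) > 0) {
    stop("lookup contains invalid growth-form categories: ",
         paste(bad, collapse = ", "),
         " (allowed: ", paste(growth_forms(), collapse = ", "), ")")
  }
  if (anyDuplicated(lookup$species)) {
    stop("lookup maps some species to more than one growth form: ",
         paste(unique(lookup$species[duplicated(lookup$species)]), collapse = ", "))
  }
  out <- records
  out$growth_form <- NULL
  out <- dplyr::left_join(out, dplyr::select(lookup, "species", "growth_form"),
                          by = "species")
  out$flagged <- is.na(out$growth_form)
  out <- tibble::as_tibble(out)
  attr(out, "n_unmatched") <- sum(out$flagged)
  out
}

#' Braun-Blanquet cover-abundance midpoint map
#'
#' Default conversion from ordinal Braun-Blanquet cover-abundance (BBCA)
#' classes to percent cover, using conventional class midpoints. The map is
#' deliberately pluggable: survey programs use several BBCA dialects, and any
#' label-to-percent table can be passed to [bbca_to_cover()] instead.
#'
#' @return A named numeric vector mapping class labels to percent cover.
#' @export
default_bbca_map <- function() {
  c("r" = 0.1, "+" = 0.5, "1" = 2.5, "2" = 15, "3" = 37.5, "4" = 62.5, "5" = 87.5)
}

#' Convert ordinal cover-class labels to percent cover
#'
#' Deterministic table lookup from BBCA-style ordinal labels to percent
#' cover values.
#'
#' @param labels Character vector of cover-class labels.
#' @param mapping Named numeric vector (label -> percent in \[0, 100\]);
#'   default [default_bbca_map()].
#' @param survey_id Optional vector (recycled) giving survey context for
#'   error messages on unknown labels.
#' @return Numeric vector of percent covers.
#' @export
#' @examples
#' bbca_to_cover(c("5", "2"), c("5" = 87.5, "2" = 15))
bbca_to_cover <- function(labels, mapping = default_bbca_map(), survey_id = NULL) {
  if (length(mapping) == 0 || is.null(names(mapping))) {
    stop("BBCA mapping must be a non-empty named numeric vector")
  }
  if (any(!is.finite(mapping)) || any(mapping < 0 | mapping > 100)) {
    stop("BBCA mapping values must be percents in [0, 100]; got: ",
         paste(mapping[!is.finite(mapping) | mapping < 0 | mapping > 100],
               collapse = ", "))
  }
  labels <- as.character(labels)
  unknown <- !(labels %in% names(mapping))
  if (any(unknown)) {
    ctx <- if (!is.null(survey_id)) {
      sid <- rep_len(survey_id, length(labels))
      paste0(" (survey ", paste(unique(sid[unknown]), collapse = ", "), ")")
    } else ""
    stop("unknown cover-class label(s): ",
         paste(unique(labels[unknown]), collapse = ", "), ctx)
  }
  unname(mapping[labels])
}

#' Aggregate species records to per-survey growth-form vectors
#'
#' Computes, for each survey, native species richness and summed native
#' percent cover per growth form, plus total nonnative cover irrespective of
#' growth form. Richness counts distinct native species per growth form (a
#' species recorded in several strata counts once); cover sums every cover
#' entry (strata add). Summed cover can exceed 100% through overlapping
#' foliage; that is expected and preserved.
#'
#' @param records Species records (see [assign_growth_forms()]) with columns
#'   `survey_id`, `species`, `native` (logical), `growth_form`, `cover`
#'   (numeric percent in \[0, 100\] per record).
#' @param surveys One row per survey: `survey_id`, `plot_id`,
#'   `vegetation_class`, `vegetation_formation`, `bioregion`, `month` (1-12),
#'   `year`, `rainfall_12mo` (mm). Extra columns are carried through.
#' @return A tibble with one row per survey: the survey columns, six
#'   `richness_*` counts, six `cover_*` sums, and `nonnative_cover`.
#'   Surveys with no records get all-zero vectors.
#' @export
aggregate_surveys <- function(records, surveys) {
  stopifnot(is.data.frame(records), is.data.frame(surveys))
  need_s <- c("survey_id", "plot_id", "vegetation_class", "vegetation_formation",
              "bioregion", "month", "year", "rainfall_12mo")
  miss <- setdiff(need_s, names(surveys))
  if (length(miss) > 0) stop("surveys is missing columns: ", paste(miss, collapse = ", "))
  need_r <- c("survey_id", "species", "native", "growth_form", "cover")
  miss <- setdiff(need_r, names(records))
  if (length(miss) > 0) stop("records is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(surveys$month)) || any(surveys$month < 1 | surveys$month > 12)) {
    stop("survey month must be in 1..12")
  }
  if (any(surveys$rainfall_12mo < 0, na.rm = TRUE)) stop("rainfall_12mo must be >= 0")
  cov <- records$cover
  if (any(!is.finite(cov)) || any(cov < 0 | cov > 100)) {
    stop("record-level cover must be a percent in [0, 100]")
  }
  dup_map <- dplyr::distinct(surveys, .data$vegetation_class, .data$vegetation_formation)
  if (anyDuplicated(dup_map$vegetation_class)) {
    stop("each vegetation class must map to exactly one formation")
  }

  gf <- growth_forms()
  nat <- dplyr::filter(records, .data$native, !is.na(.data$growth_form))
  nat$growth_form <- factor(nat$growth_form, levels = gf)

  rich <- nat |>
    dplyr::distinct(.data$survey_id, .data$growth_form, .data$species) |>
    dplyr::count(.data$survey_id, .data$growth_form, .drop = FALSE, name = "richness") |>
    tidyr::pivot_wider(names_from = "growth_form", values_from = "richness",
                       names_prefix = "richness_", values_fill = 0L)
  cvr <- nat |>
    dplyr::group_by(.data$survey_id, .data$growth_form, .drop = FALSE) |>
    dplyr::summarise(cover = sum(.data$cover), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "growth_form", values_from = "cover",
                       names_prefix = "cover_", values_fill = 0)
  nn <- records |>
    dplyr::filter(!.data$native) |>
    dplyr::group_by(.data$survey_id) |>
    dplyr::summarise(nonnative_cover = sum(.data$cover), .groups = "drop")

  out <- surveys |>
    tibble::as_tibble() |>
    dplyr::left_join(rich, by = "survey_id") |>
    dplyr::left_join(cvr, by = "survey_id") |>
    dplyr::left_join(nn, by = "survey_id")
  for (g in gf) {
    rc <- paste0("richness_", g)
    cc <- paste0("cover_", g)
    if (!rc %in% names(out)) out[[rc]] <- 0L
    if (!cc %in% names(out)) out[[cc]] <- 0
    out[[rc]][is.na(out[[rc]])] <- 0L
    out[[cc]][is.na(out[[cc]])] <- 0
  }
  if (!"nonnative_cover" %in% names(out)) out$nonnative_cover <- 0
  out$nonnative_cover[is.na(out$nonnative_cover)] <- 0
  out
}
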