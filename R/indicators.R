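#' The twenty evaluation indicators
#'
#' Names of the vegetation and soil indicators that form the evaluation
#' matrix: four diversity indices, understory cover, species and perennial
#' counts, the dominant species' importance value, soil texture (clay, silt
#' and total sand, the sum of the five sand fractions), water content, bulk
#' density, total porosity, and six nutrient indicators.
#'
#' @return Character vector of length 20.
#' @export
indicator_names <- function() {
  c("shannon", "simpson", "pielou", "margalef", "cover", "n_species",
    "dominant_iv", "n_perennial", "clay", "silt", "sand", "water_content",
    "bulk_density", "total_porosity", "total_N", "total_P", "total_K",
    "available_N", "available_P", "available_K")
}

#' Default indicator polarity
#'
#' Direction of each indicator's effect on restoration quality: `positive`
#' indicators improve the evaluation as they increase; `negative` ones
#' (soil bulk density, total sand content) improve it as they decrease.
#' The dominant-species importance value defaults to positive; override via
#' the `overrides` argument where a more even community is preferred.
#'
#' @param overrides Named character vector of `"positive"` / `"negative"`
#'   entries replacing the defaults.
#' @return Named character vector over [indicator_names()].
#' @export
#' @examples
#' indicator_polarity(c(dominant_iv = "negative"))
indicator_polarity <- function(overrides = NULL) {
  pol <- setNames(rep("positive", length(indicator_names())), indicator_names())
  pol[c("bulk_density", "sand")] <- "negative"
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(pol))
    if (length(bad) > 0) {
      abort(paste("unknown indicator(s) in polarity overrides:",
                  paste(bad, collapse = ", ")))
    }
    if (!all(overrides %in% c("positive", "negative"))) {
      abort("polarity must be 'positive' or 'negative'.")
    }
    pol[names(overrides)] <- overrides
  }
  pol
}

#' Assemble the site-level indicator matrix
#'
#' Combines quadrat and soil tables into the sites x 20 evaluation matrix:
#' per-site diversity indices, mean total quadrat cover, species and
#' perennial counts, maximum species importance value, and site-aggregated
#' soil indicators (with `sand` the sum of the five sand fractions).
#'
#' @param quadrats Quadrat observation tibble (see [generate_study()]).
#' @param soil Soil sample tibble.
#' @param annotations Species annotations for the composition counts.
#' @return A tibble with `plot_id`, `land_type`, and the twenty
#'   [indicator_names()] columns; no missing cells.
#' @export
#' @examples
#' study <- generate_study(effects = effect_profile(seed = 4))
#' build_indicator_matrix(study$quadrats, study$soil)
build_indicator_matrix <- function(quadrats, soil,
                                   annotations = default_species_pool()) {
  div <- diversity_indices(quadrats)
  iv <- importance_values(quadrats)
  comp <- composition_summary(iv, annotations = annotations)
  cover <- quadrats |>
    group_by(.data$plot_id, .data$quadrat_id) |>
    summarise(qc = sum(.data$cover), .groups = "drop_last") |>
    summarise(cover = mean(.data$qc), .groups = "drop")
  dom <- iv |>
    group_by(.data$plot_id) |>
    summarise(dominant_iv = max(.data$importance_value), .groups = "drop")
  sites <- site_aggregate(soil)$site |>
    mutate(sand = .data$very_fine_sand + .data$fine_sand +
             .data$medium_sand + .data$coarse_sand + .data$very_coarse_sand)

  out <- div |>
    left_join(cover, by = "plot_id") |>
    left_join(select(comp$per_plot, "plot_id", n_species = "richness",
                     "n_perennial"), by = "plot_id") |>
    left_join(dom, by = "plot_id") |>
    left_join(sites, by = intersect(c("plot_id", "land_type"), names(sites))) |>
    select(all_of(intersect(c("plot_id", "land_type"), names(div))),
           all_of(indicator_names()))
  if (anyNA(out)) {
    bad <- out$plot_id[rowSums(is.na(out)) > 0]
    abort(paste("indicator matrix has missing cells for plot(s):",
                paste(bad, collapse = ", ")))
  }
  out
}
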