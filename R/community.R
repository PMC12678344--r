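#' Species importance values within plots
#'
#' The importance value (IV) summarises the dominance of each species in a
#' plot as the mean of its relative density, relative frequency and relative
#' cover, each expressed in percent:
#' \deqn{IV = (RD + RF + RC) / 3}
#' Relative density is the species' share of total abundance, relative
#' frequency its share of summed quadrat frequencies (frequency = proportion
#' of quadrats in which the species occurs), and relative cover its share of
#' total cover. By construction the importance values of a plot sum to 100.
#'
#' @param quadrats A quadrat-observation tibble with columns `plot_id`,
#'   `quadrat_id`, `species`, `abundance`, `cover` (see [generate_study()]).
#'   Rows are species presences; a species' frequency is the fraction of the
#'   plot's quadrats in which it appears.
#'
#' @return A tibble with one row per (plot, species): `plot_id`, `species`,
#'   `relative_density`, `relative_frequency`, `relative_cover`,
#'   `importance_value`, all on a 0–100 scale.
#' @export
#' @examples
#' study <- generate_study(effects = effect_profile(seed = 2))
#' iv <- importance_values(study$quadrats)
#' # importance values sum to 100 within each plot
#' dplyr::count(iv, plot_id, wt = importance_value)
importance_values <- function(quadrats) {
  need <- c("plot_id", "quadrat_id", "species", "abundance", "cover")
  if (!all(need %in% names(quadrats))) {
    abort(paste("quadrats must have columns:", paste(need, collapse = ", ")))
  }
  totals <- quadrats |>
    group_by(.data$plot_id) |>
    summarise(total_abund = sum(.data$abundance),
              n_quadrat = dplyr::n_distinct(.data$quadrat_id),
              .groups = "drop")
  if (any(totals$total_abund <= 0)) {
    bad <- totals$plot_id[totals$total_abund <= 0]
    abort(paste("all abundances are zero in plot(s):", paste(bad, collapse = ", ")))
  }
  quadrats |>
    group_by(.data$plot_id, .data$species) |>
    summarise(abund = sum(.data$abundance),
              freq = dplyr::n_distinct(.data$quadrat_id),
              cov = sum(.data$cover),
              .groups = "drop_last") |>
    mutate(relative_density = .data$abund / sum(.data$abund) * 100,
           relative_frequency = .data$freq / sum(.data$freq) * 100,
           relative_cover = if (sum(.data$cov) > 0)
             .data$cov / sum(.data$cov) * 100 else .data$relative_density,
           importance_value = (.data$relative_density +
                                 .data$relative_frequency +
                                 .data$relative_cover) / 3) |>
    ungroup() |>
    select("plot_id", "species", "relative_density", "relative_frequency",
           "relative_cover", "importance_value")
}

#' Diversity profile of one abundance vector
#'
#' Computes the four community diversity indices used throughout the
#' package from a single vector of species abundances:
#' Shannon \eqn{H = -\sum p_i \ln p_i} (nats), inverse Simpson
#' \eqn{D = 1 / \sum p_i^2} (effective number of dominant species), Pielou
#' evenness \eqn{J = H / \ln S}, and Margalef richness
#' \eqn{(S - 1) / \ln N}, where \eqn{p_i} are relative abundances, \eqn{S}
#' the species count and \eqn{N} the total abundance.
#'
#' @param abundance Numeric vector of species abundances (zeros dropped).
#' @param simpson One of `"inverse"` (default, \eqn{1/\sum p^2}) or
#'   `"gini"` (\eqn{1 - \sum p^2}).
#'
#' @return A one-row tibble: `richness`, `abundance`, `shannon`, `simpson`,
#'   `pielou`, `margalef`. `pielou` is `NA` for a single-species community,
#'   where evenness is undefined.
#' @export
#' @examples
#' diversity_profile(c(50, 30, 20))
diversity_profile <- function(abundance, simpson = c("inverse", "gini")) {
  simpson <- match.arg(simpson)
  if (any(abundance < 0)) abort("abundances must be non-negative.")
  abundance <- abundance[abundance > 0]
  if (length(abundance) == 0) abort("at least one abundance must be positive.")
  n_total <- sum(abundance)
  s <- length(abundance)
  if (n_total <= 1) abort("Margalef index requires total abundance N > 1.")
  p <- abundance / n_total
  h <- -sum(p * log(p))
  d2 <- sum(p^2)
  tibble::tibble(
    richness = s,
    abundance = n_total,
    shannon = h,
    simpson = if (simpson == "inverse") 1 / d2 else 1 - d2,
    pielou = if (s > 1) h / log(s) else NA_real_,
    margalef = (s - 1) / log(n_total)
  )
}

#' Per-plot diversity indices
#'
#' Aggregates quadrat observations to plot-level species abundances and
#' applies [diversity_profile()] to every plot.
#'
#' @inheritParams importance_values
#' @inheritParams diversity_profile
#' @return A tibble with one row per plot: `plot_id` (and `land_type` if
#'   present in the input) plus the [diversity_profile()] columns.
#' @export
#' @examples
#' study <- generate_study(effects = effect_profile(seed = 2))
#' diversity_indices(study$quadrats)
diversity_indices <- function(quadrats, simpson = c("inverse", "gini")) {
  simpson <- match.arg(simpson)
  keys <- intersect(c("plot_id", "land_type"), names(quadrats))
  quadrats |>
    group_by(across(all_of(keys)), .data$species) |>
    summarise(abund = sum(.data$abundance), .groups = "drop_last") |>
    summarise(diversity_profile(.data$abund, simpson = simpson),
              .groups = "drop")
}

#' Community composition summary
#'
#' Summarises a species importance-value table into per-plot composition
#' (richness, life-form counts, families, genera, dominant species) and
#' study-wide totals (species, genera, families, family shares). A species
#' counts for a plot iff its importance value there is positive; a species
#' is dominant in a plot iff its importance value reaches
#' `dominant_threshold` (default 10 on the 0–100 IV scale).
#'
#' @param iv Long importance-value tibble with columns `plot_id`, `species`,
#'   `importance_value` — e.g. the output of [importance_values()], or a
#'   published IV table.
#' @param annotations Species annotations (`species`, `genus`, `family`,
#'   `life_form`); defaults to [default_species_pool()]. May be omitted if
#'   `iv` already carries those columns.
#' @param dominant_threshold Minimum importance value for dominance.
#'
#' @return A list of class `composition_summary`:
#'   \describe{
#'     \item{per_plot}{tibble: `plot_id`, `richness`, `n_annual`,
#'       `n_perennial`, `n_genus`, `n_family`, `dominants` (list-column of
#'       species names, ordered by decreasing IV).}
#'     \item{overall}{one-row tibble: `n_species`, `n_genus`, `n_family`.}
#'     \item{family_composition}{tibble: `family`, `n_species`,
#'       `share_pct`.}
#'   }
#' @export
#' @examples
#' comp <- composition_summary(kubuqi_importance_values())
#' comp$overall
composition_summary <- function(iv, annotations = default_species_pool(),
                                dominant_threshold = 10) {
  need <- c("plot_id", "species", "importance_value")
  if (!all(need %in% names(iv))) {
    abort(paste("iv must have columns:", paste(need, collapse = ", ")))
  }
  if (!all(c("genus", "family", "life_form") %in% names(iv))) {
    iv <- left_join(iv, annotations, by = "species")
  }
  unannotated <- unique(iv$species[is.na(iv$family) | is.na(iv$genus)])
  if (length(unannotated) > 0) {
    abort(paste("species missing family/genus annotation:",
                paste(unannotated, collapse = ", ")))
  }
  present <- filter(iv, .data$importance_value > 0)

  per_plot <- present |>
    group_by(.data$plot_id) |>
    summarise(
      richness = dplyr::n_distinct(.data$species),
      n_annual = dplyr::n_distinct(.data$species[.data$life_form == "annual"]),
      n_perennial = dplyr::n_distinct(.data$species[.data$life_form == "perennial"]),
      n_genus = dplyr::n_distinct(.data$genus),
      n_family = dplyr::n_distinct(.data$family),
      dominants = list(
        .data$species[order(-.data$importance_value)][
          sort(.data$importance_value, decreasing = TRUE) >= dominant_threshold]),
      .groups = "drop"
    )

  overall <- present |>
    summarise(n_species = dplyr::n_distinct(.data$species),
              n_genus = dplyr::n_distinct(.data$genus),
              n_family = dplyr::n_distinct(.data$family))

  family_composition <- present |>
    distinct(.data$species, .data$family) |>
    dplyr::count(.data$family, name = "n_species") |>
    mutate(share_pct = .data$n_species / sum(.data$n_species) * 100) |>
    arrange(dplyr::desc(.data$n_species))

  structure(list(per_plot = per_plot, overall = overall,
                 family_composition = family_composition,
                 dominant_threshold = dominant_threshold),
            class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("<composition_summary>\n")
  cat(sprintf("  %d species, %d genera, %d families\n",
              x$overall$n_species, x$overall$n_genus, x$overall$n_family))
  cat("  per-plot richness:",
      paste(sprintf("%s=%d", x$per_plot$plot_id, x$per_plot$richness),
            collapse = ", "), "\n")
  invisible(x)
}
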