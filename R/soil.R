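#' Particle-size classes for sandy soils
#'
#' The seven classes used throughout the package, after the USDA-style
#' grading applied to laser-diffraction particle-size data from sandy
#' soils. Note the clay boundary is kept at 0.02 mm (merging the
#' conventional clay and fine-silt ranges), as graded in the source texture
#' tables; bins are half-open `[lower, upper)` except the last, which
#' includes 2 mm.
#'
#' @return A tibble with `fraction`, `lower_mm`, `upper_mm`.
#' @export
#' @examples
#' particle_bins()
particle_bins <- function() {
  tibble::tibble(
    fraction = particle_fraction_names(),
    lower_mm = c(0, 0.02, 0.05, 0.1, 0.25, 0.5, 1),
    upper_mm = c(0.02, 0.05, 0.1, 0.25, 0.5, 1, 2)
  )
}

#' Bin a particle-size distribution into the seven texture fractions
#'
#' Assigns each (size, mass) record to one of the seven classes of
#' [particle_bins()] and returns mass percentages. Mass is conserved:
#' fractions are non-negative and sum to exactly 100.
#'
#' @param sizes Numeric vector of particle diameters in mm; each must lie in
#'   (0, 2].
#' @param masses Numeric vector of masses (any unit), same length as
#'   `sizes`; must be non-negative and not all zero.
#' @param bins A bin table as returned by [particle_bins()] (strictly
#'   increasing edges).
#'
#' @return A one-row tibble with one percentage column per fraction.
#' @export
#' @examples
#' bin_particle_distribution(c(0.01, 1.5), c(1, 1)) # 50% clay, 50% very coarse sand
bin_particle_distribution <- function(sizes, masses, bins = particle_bins()) {
  if (length(sizes) != length(masses)) {
    abort("sizes and masses must have the same length.")
  }
  bad <- which(sizes <= 0 | sizes > max(bins$upper_mm))
  if (length(bad) > 0) {
    abort(sprintf("particle size out of (0, %g] mm at record(s): %s (sizes: %s)",
                  max(bins$upper_mm), paste(bad, collapse = ", "),
                  paste(signif(sizes[bad], 3), collapse = ", ")))
  }
  if (any(masses < 0)) abort("masses must be non-negative.")
  if (sum(masses) <= 0) abort("total mass must be positive.")
  edges <- c(bins$lower_mm, max(bins$upper_mm))
  idx <- findInterval(sizes, edges, rightmost.closed = TRUE, left.open = FALSE)
  tot <- vapply(seq_len(nrow(bins)),
                function(b) sum(masses[idx == b]), numeric(1))
  out <- as.list(tot / sum(tot) * 100)
  names(out) <- bins$fraction
  tibble::as_tibble(out)
}

#' Total porosity from bulk density
#'
#' Converts soil bulk density to total porosity assuming a fixed mineral
#' particle density: `porosity = (1 - BD / PD) * 100`.
#'
#' @param bulk_density Bulk density in g cm^-3; must satisfy
#'   `0 < BD <= particle_density`.
#' @param particle_density Mineral particle density in g cm^-3
#'   (default 2.65, quartz-dominated sand).
#' @return Total porosity in percent.
#' @export
#' @examples
#' porosity_from_bulk_density(1.5) # 43.4 %
porosity_from_bulk_density <- function(bulk_density, particle_density = 2.65) {
  if (any(bulk_density <= 0)) abort("bulk density must be positive.")
  if (any(bulk_density > particle_density)) {
    abort("bulk density cannot exceed the particle density.")
  }
  (1 - bulk_density / particle_density) * 100
}

#' Aggregate soil samples to site-level indicator means
#'
#' Averages soil-profile samples within each site (plot): first the
#' sampling points within each depth interval, then the depth means with
#' equal weight (the intervals are equally thick), producing one composite
#' profile per site. Per-depth means are returned alongside.
#'
#' @param soil Soil sample tibble with `plot_id`, `depth`, and numeric
#'   indicator columns (see [generate_study()]); `point_id` and `land_type`
#'   are carried if present.
#' @param depths Character vector of the depth labels every site must have;
#'   defaults to the distinct depths present in `soil`.
#'
#' @return A list with `site` (one row per plot: indicator means) and
#'   `by_depth` (one row per plot x depth).
#' @export
#' @examples
#' study <- generate_study(effects = effect_profile(seed = 3))
#' site_aggregate(study$soil)$site
site_aggregate <- function(soil, depths = unique(soil$depth)) {
  if (!all(c("plot_id", "depth") %in% names(soil))) {
    abort("soil must have plot_id and depth columns.")
  }
  gaps <- soil |>
    distinct(.data$plot_id) |>
    tidyr::expand_grid(depth = depths) |>
    dplyr::anti_join(distinct(soil, .data$plot_id, .data$depth),
                     by = c("plot_id", "depth"))
  if (nrow(gaps) > 0) {
    abort(paste("missing depth interval(s):",
                paste(sprintf("%s@%s", gaps$plot_id, gaps$depth), collapse = ", ")))
  }
  keys <- intersect(c("plot_id", "land_type"), names(soil))
  num_cols <- setdiff(names(soil)[vapply(soil, is.numeric, logical(1))],
                      c("point", "depth_idx"))
  by_depth <- soil |>
    group_by(across(all_of(c(keys, "depth")))) |>
    summarise(across(all_of(num_cols), mean), .groups = "drop")
  site <- by_depth |>
    group_by(across(all_of(keys))) |>
    summarise(across(all_of(num_cols), mean), .groups = "drop")
  list(site = site, by_depth = by_depth)
}

#' Control-relative change of an indicator
#'
#' Expresses a treatment mean relative to a control mean as a ratio and a
#' relative increase in percent: `ratio = t / c`,
#' `relative_increase = (t - c) / c * 100`.
#'
#' @param treatment Numeric vector of treatment means.
#' @param control Control mean (positive scalar or vector recycled against
#'   `treatment`).
#' @return A tibble with `treatment`, `control`, `ratio`,
#'   `relative_increase`.
#' @export
#' @examples
#' change_vs_control(34.9, 11.27) # the 209.67 % understory cover increase
change_vs_control <- function(treatment, control) {
  if (any(control <= 0)) abort("control mean must be positive.")
  tibble::tibble(
    treatment = treatment,
    control = control,
    ratio = treatment / control,
    relative_increase = (treatment - control) / control * 100
  )
}
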