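#' Generate a synthetic plantation / bare-sand study
#'
#' Draws one complete synthetic field survey under a nested sampling design:
#' a quadrat table of understory species observations (abundance, height,
#' cover, presence) and a soil-profile table (seven particle-size fractions,
#' water content, bulk density, derived total porosity, and six nutrient
#' indicators) for every land type x site x sampling point x depth
#' combination. The statistical structure — land-type ordered effects, depth
#' gradients, site-level random effects, observation noise, skewed species
#' abundances — is controlled by the [effect_profile()].
#'
#' All randomness flows from `effects$seed`; identical design, profile and
#' seed give byte-identical tables. Particle fractions are renormalised to
#' sum to exactly 100 per sample. Quadrat cover is a binomial count out of a
#' 10 x 10 grid of squares, so it is always an integer percentage.
#'
#' @param design A [study_design()].
#' @param effects An [effect_profile()].
#'
#' @return A list with class `synthetic_study`:
#'   \describe{
#'     \item{quadrats}{tibble of species observations, one row per
#'       (plot, quadrat, species) with positive abundance.}
#'     \item{soil}{tibble, one row per (plot, point, depth).}
#'     \item{design, effects}{the inputs, for provenance.}
#'   }
#' @export
#' @examples
#' study <- generate_study(study_design(), effect_profile(seed = 7))
#' nrow(study$soil) # 108 under the default design
generate_study <- function(design = study_design(),
                           effects = effect_profile()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_profile"))
  missing_types <- setdiff(design$land_types,
                           intersect(names(effects$cover_mean), names(effects$richness)))
  if (length(missing_types) > 0) {
    abort(paste("effect profile lacks cover/richness for land types:",
                paste(missing_types, collapse = ", ")))
  }
  if (any(effects$richness[design$land_types] > nrow(design$species_pool))) {
    abort("expected richness exceeds the species pool size.")
  }
  if (any(effects$noise_sd < 0)) abort("noise_sd must be non-negative.")

  withr::with_seed(effects$seed, {
    soil <- generate_soil(design, effects)
    quadrats <- generate_quadrats(design, effects)
  })
  structure(list(quadrats = quadrats, soil = soil,
                 design = design, effects = effects),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat("  quadrat records: ", nrow(x$quadrats), "\n")
  cat("  soil samples:    ", nrow(x$soil), "\n")
  cat("  seed:            ", x$effects$seed, "\n")
  invisible(x)
}

generate_soil <- function(design, effects) {
  inds <- soil_indicator_names()
  fracs <- particle_fraction_names()
  mean_tab <- effects$soil_surface_mean
  grid <- tidyr::expand_grid(
    land_type = design$land_types,
    site = seq_len(design$sites_per_type),
    point = seq_len(design$points_per_site),
    depth_idx = seq_along(design$depths)
  )

  # site-level random effects, one per (plot, indicator)
  plots <- unique(paste0(grid$land_type, "-", grid$site))
  site_eff <- matrix(rnorm(length(plots) * length(inds)),
                     nrow = length(plots), dimnames = list(plots, inds))
  site_eff <- sweep(site_eff, 2, effects$noise_sd[inds], `*`)

  vals <- matrix(NA_real_, nrow = nrow(grid), ncol = length(inds),
                 dimnames = list(NULL, inds))
  plot_id <- paste0(grid$land_type, "-", grid$site)
  for (ind in inds) {
    mu0 <- setNames(as.numeric(mean_tab[mean_tab$indicator == ind,
                                        design$land_types]),
                    design$land_types)
    mu <- mu0[grid$land_type] +
      effects$depth_slope[[ind]] * (grid$depth_idx - 1) +
      site_eff[cbind(plot_id, ind)]
    vals[, ind] <- mu + rnorm(nrow(grid), 0, effects$noise_sd[[ind]])
  }

  # non-negativity floors, then exact closure of the particle fractions
  vals[, fracs] <- pmax(vals[, fracs], 0.001)
  vals[, fracs] <- vals[, fracs] / rowSums(vals[, fracs]) * 100
  vals[, "water_content"] <- pmax(vals[, "water_content"], 0.1)
  vals[, "bulk_density"] <- pmin(pmax(vals[, "bulk_density"], 0.5), 2.6)
  nutr <- c("total_N", "total_P", "total_K",
            "available_N", "available_P", "available_K")
  vals[, nutr] <- pmax(vals[, nutr], 0.001)

  dplyr::bind_cols(
    tibble::tibble(
      plot_id = plot_id,
      land_type = grid$land_type,
      point_id = paste0("P", grid$point),
      depth = design$depths[grid$depth_idx]
    ),
    tibble::as_tibble(vals)
  ) |>
    mutate(total_porosity = porosity_from_bulk_density(.data$bulk_density))
}

generate_quadrats <- function(design, effects) {
  pool <- design$species_pool
  # rank-weighted selection keeps early-pool species shared across sites,
  # emulating a handful of widespread dominants
  sel_w <- 1 / seq_len(nrow(pool))
  out <- list()
  for (lt in design$land_types) {
    for (s in seq_len(design$sites_per_type)) {
      plot_id <- paste0(lt, "-", s)
      s_rich <- effects$richness[[lt]]
      idx <- sample.int(nrow(pool), s_rich, prob = sel_w)
      spp <- pool[idx, ]
      # skewed site-level mean abundances -> uneven importance values
      lambda <- rlnorm(s_rich, meanlog = log(6), sdlog = 1)
      base_height <- rlnorm(s_rich, meanlog = log(15), sdlog = 0.3)
      site_cover <- min(max(effects$cover_mean[[lt]] +
                              rnorm(1, 0, effects$noise_sd[["cover"]]), 1), 99)
      for (q in seq_len(design$quadrats_per_site)) {
        n_k <- rpois(s_rich, lambda)
        keep <- n_k > 0
        if (!any(keep)) next
        grid_squares <- rbinom(1, 100, site_cover / 100)
        share <- n_k[keep] / sum(n_k[keep])
        out[[length(out) + 1]] <- tibble::tibble(
          plot_id = plot_id,
          land_type = lt,
          quadrat_id = paste0("Q", q),
          species = spp$species[keep],
          genus = spp$genus[keep],
          family = spp$family[keep],
          life_form = spp$life_form[keep],
          abundance = n_k[keep],
          height = round(base_height[keep] * rlnorm(sum(keep), 0, 0.15), 1),
          cover = round(grid_squares * share, 2),
          present = TRUE
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Planted truth of an effect profile
#'
#' Reads back, from the generator configuration alone, what a successful
#' analysis should recover: the implied quality ordering of the land types,
#' the set of indicators given a nonzero between-type effect (named as they
#' appear in the downstream indicator matrix), and the single indicator with
#' the strongest planted signal-to-noise ratio at site level.
#'
#' The ordering averages polarity-adjusted ranks across all configured
#' indicators (cover, richness and site-level soil means); bulk density and
#' the sand fractions count as negative-effect. If every indicator is
#' constant across land types there is no implied ordering and `ordering` is
#' `NULL`. The top driver maximises the between-type spread of site-level
#' means divided by the site-level standard deviation (site random effect
#' plus averaged observation noise).
#'
#' @param effects An [effect_profile()].
#' @param design A [study_design()] (supplies replication used in the
#'   signal-to-noise calculation).
#'
#' @return A list with `ordering` (character or `NULL`), `drivers`
#'   (character), `top_driver` (character scalar or `NULL`), and `snr`
#'   (named numeric, site-level signal-to-noise per mapped indicator).
#' @export
#' @examples
#' planted_truth(effect_profile())$ordering
planted_truth <- function(effects, design = study_design()) {
  stopifnot(inherits(effects, "effect_profile"))
  types <- names(effects$cover_mean)
  n_agg <- design$points_per_site * nrow(design$depth_edges)
  mean_tab <- effects$soil_surface_mean
  mean_depth_steps <- mean(seq_len(nrow(design$depth_edges)) - 1)

  # site-level type means and sds on the downstream indicator scale
  site_mean <- function(ind) {
    m <- setNames(as.numeric(mean_tab[mean_tab$indicator == ind, types]), types)
    m + effects$depth_slope[[ind]] * mean_depth_steps
  }
  site_sd <- function(ind) {
    effects$noise_sd[[ind]] * sqrt(1 + 1 / n_agg)
  }

  fracs <- particle_fraction_names()
  sand_fracs <- setdiff(fracs, c("clay", "silt"))
  means <- list(
    cover = effects$cover_mean[types],
    n_species = as.numeric(effects$richness[types]),
    sand = colSums(do.call(rbind, lapply(sand_fracs, site_mean)))
  )
  sds <- c(
    cover = sqrt(effects$noise_sd[["cover"]]^2 +
                   mean(effects$cover_mean[types] / 100 *
                          (1 - effects$cover_mean[types] / 100)) * 100 /
                   design$quadrats_per_site),
    n_species = 0.5,  # nominal sampling loss of rare species
    sand = sqrt(sum(vapply(sand_fracs, site_sd, numeric(1))^2))
  )
  direct <- c("clay", "silt", "water_content", "bulk_density",
              "total_N", "total_P", "total_K",
              "available_N", "available_P", "available_K")
  for (ind in direct) {
    means[[ind]] <- site_mean(ind)
    sds[[ind]] <- site_sd(ind)
  }
  negative <- c("bulk_density", "sand")

  spread <- vapply(means, function(m) max(m) - min(m), numeric(1))
  drivers <- names(spread)[spread > 1e-12]
  snr <- spread[drivers] / sds[drivers]

  if (length(drivers) == 0) {
    return(list(ordering = NULL, drivers = character(0),
                top_driver = NULL, snr = numeric(0)))
  }

  rank_mat <- vapply(drivers, function(ind) {
    m <- means[[ind]]
    if (ind %in% negative) m <- -m
    rank(-m, ties.method = "average")
  }, numeric(length(types)))
  ordering <- types[order(rowMeans(rank_mat))]

  list(ordering = ordering, drivers = drivers,
       top_driver = names(snr)[which.max(snr)], snr = snr)
}

#' Write / read study tables as CSV
#'
#' `write_study()` writes `quadrats.csv` and `soil.csv` into a directory;
#' `read_quadrats()` and `read_soil()` read them back with typed columns.
#'
#' @param study A `synthetic_study` or a list with `quadrats` and `soil`
#'   tibbles.
#' @param dir Output directory (created if missing).
#' @return `write_study()` returns the two file paths invisibly; the readers
#'   return tibbles.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qf <- file.path(dir, "quadrats.csv")
  sf <- file.path(dir, "soil.csv")
  readr::write_csv(study$quadrats, qf)
  readr::write_csv(study$soil, sf)
  invisible(c(quadrats = qf, soil = sf))
}

#' @rdname write_study
#' @param path Path to a CSV written by [write_study()].
#' @export
read_quadrats <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plot_id = "c", land_type = "c", quadrat_id = "c", species = "c",
    genus = "c", family = "c", life_form = "c", abundance = "i",
    height = "d", cover = "d", present = "l"
  ))
}

#' @rdname write_study
#' @export
read_soil <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    plot_id = "c", land_type = "c", point_id = "c", depth = "c",
    .default = "d"
  ))
}
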