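#' Default understory species pool
#'
#' Twenty herbaceous species typical of the understory that regenerates
#' beneath sand-fixing shrub plantations (*Caragana korshinskii*, *Salix
#' psammophila*, *Hedysarum scoparium*) and on bare shifting sand in the
#' temperate deserts of the middle Yellow River basin. Each species carries
#' its genus, family and life form; the pool is deliberately dominated by
#' Asteraceae, Fabaceae, Amaranthaceae and Poaceae, the families that carry
#' most of the richness in such systems.
#'
#' @return A tibble with columns `species`, `genus`, `family`, `life_form`
#'   (`"annual"` or `"perennial"`).
#' @export
#' @examples
#' default_species_pool()
default_species_pool <- function() {
  tibble::tribble(
    ~species,                  ~genus,         ~family,          ~life_form,
    "Artemisia frigida",       "Artemisia",    "Asteraceae",     "perennial",
    "Artemisia desertorum",    "Artemisia",    "Asteraceae",     "perennial",
    "Artemisia capillaris",    "Artemisia",    "Asteraceae",     "annual",
    "Artemisia annua",         "Artemisia",    "Asteraceae",     "annual",
    "Aster hispidus",          "Aster",        "Asteraceae",     "annual",
    "Ixeris polycephala",      "Ixeris",       "Asteraceae",     "perennial",
    "Lespedeza bicolor",       "Lespedeza",    "Fabaceae",       "perennial",
    "Sophora alopecuroides",   "Sophora",      "Fabaceae",       "perennial",
    "Astragalus laxmannii",    "Astragalus",   "Fabaceae",       "perennial",
    "Oxytropis racemosa",      "Oxytropis",    "Fabaceae",       "perennial",
    "Agriophyllum squarrosum", "Agriophyllum", "Amaranthaceae",  "annual",
    "Bassia scoparia",         "Bassia",       "Amaranthaceae",  "annual",
    "Salsola collina",         "Salsola",      "Amaranthaceae",  "annual",
    "Suaeda glauca",           "Suaeda",       "Amaranthaceae",  "annual",
    "Setaria viridis",         "Setaria",      "Poaceae",        "annual",
    "Stipa caucasica",         "Stipa",        "Poaceae",        "perennial",
    "Agropyron mongolicum",    "Agropyron",    "Poaceae",        "perennial",
    "Tribulus terrestris",     "Tribulus",     "Zygophyllaceae", "annual",
    "Euphorbia humifusa",      "Euphorbia",    "Euphorbiaceae",  "annual",
    "Incarvillea sinensis",    "Incarvillea",  "Bignoniaceae",   "annual"
  )
}

#' Nested sampling design of a plantation / bare-sand comparison
#'
#' Describes the spatially nested layout the generator emulates: a set of
#' ordered land types (three shrub plantations and a bare-sand control by
#' default), replicate 30 m x 30 m sites per type, soil sampling points per
#' site each cored over contiguous 20 cm depth intervals, and 1 m^2
#' vegetation quadrats per site. The default design yields
#' 4 x 3 x 3 x 3 = 108 soil samples and 12 x 5 = 60 quadrats.
#'
#' @param land_types Character vector of land-type labels, ordered from the
#'   expected best-restored to the control.
#' @param sites_per_type Number of replicate sites per land type.
#' @param points_per_site Number of soil sampling points per site.
#' @param depths Character vector of contiguous half-open depth intervals in
#'   cm, formatted `"top-bottom"`.
#' @param quadrats_per_site Number of vegetation quadrats per site.
#' @param species_pool Tibble of candidate understory species (see
#'   [default_species_pool()]); must have unique `species` names and columns
#'   `species`, `genus`, `family`, `life_form`.
#'
#' @return An object of class `study_design` (a list with the above fields).
#' @export
#' @examples
#' d <- study_design()
#' d$land_types
study_design <- function(land_types = c("CK", "SP", "HS", "BS"),
                         sites_per_type = 3,
                         points_per_site = 3,
                         depths = c("0-20", "20-40", "40-60"),
                         quadrats_per_site = 5,
                         species_pool = default_species_pool()) {
  counts <- c(sites_per_type = sites_per_type,
              points_per_site = points_per_site,
              quadrats_per_site = quadrats_per_site)
  if (any(counts < 1) || any(counts != floor(counts))) {
    abort("sites_per_type, points_per_site and quadrats_per_site must be positive integers.")
  }
  if (length(land_types) < 2 || anyDuplicated(land_types) > 0) {
    abort("land_types must be at least two unique labels.")
  }
  edges <- parse_depths(depths)
  need <- c("species", "genus", "family", "life_form")
  if (!all(need %in% names(species_pool))) {
    abort(paste("species_pool must have columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(species_pool$species) > 0) {
    abort("species_pool entries must be unique by species name.")
  }
  if (!all(species_pool$life_form %in% c("annual", "perennial"))) {
    abort("life_form must be 'annual' or 'perennial'.")
  }
  structure(
    list(land_types = land_types,
         sites_per_type = as.integer(sites_per_type),
         points_per_site = as.integer(points_per_site),
         depths = depths,
         depth_edges = edges,
         quadrats_per_site = as.integer(quadrats_per_site),
         species_pool = tibble::as_tibble(species_pool)),
    class = "study_design"
  )
}

# "0-20","20-40" -> matrix of [top, bottom); enforces contiguity in cm
parse_depths <- function(depths) {
  m <- regmatches(depths, regexec("^([0-9.]+)-([0-9.]+)$", depths))
  if (any(lengths(m) != 3)) abort("depths must look like '0-20', '20-40', ...")
  edges <- t(vapply(m, function(x) as.numeric(x[2:3]), numeric(2)))
  colnames(edges) <- c("top", "bottom")
  if (any(edges[, "bottom"] <= edges[, "top"])) {
    abort("each depth interval must have bottom > top.")
  }
  if (nrow(edges) > 1 && any(edges[-1, "top"] != edges[-nrow(edges), "bottom"])) {
    abort("depth intervals must be contiguous and non-overlapping.")
  }
  edges
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  cat("  land types:      ", paste(x$land_types, collapse = " > "), "\n")
  cat("  sites/type:      ", x$sites_per_type, "\n")
  cat("  points/site:     ", x$points_per_site, "\n")
  cat("  depths (cm):     ", paste(x$depths, collapse = ", "), "\n")
  cat("  quadrats/site:   ", x$quadrats_per_site, "\n")
  cat("  species pool:    ", nrow(x$species_pool), "species\n")
  n_soil <- length(x$land_types) * x$sites_per_type * x$points_per_site *
    nrow(x$depth_edges)
  cat("  soil samples:    ", n_soil, "\n")
  invisible(x)
}

soil_indicator_names <- function() {
  c("clay", "silt", "very_fine_sand", "fine_sand", "medium_sand",
    "coarse_sand", "very_coarse_sand", "water_content", "bulk_density",
    "total_N", "total_P", "total_K", "available_N", "available_P",
    "available_K")
}

particle_fraction_names <- function() {
  c("clay", "silt", "very_fine_sand", "fine_sand", "medium_sand",
    "coarse_sand", "very_coarse_sand")
}

# Default surface-depth (0-20 cm) soil means per land type. Particle-size
# fractions follow the published depth-wise texture table for these
# plantations; water content, bulk density and nutrients are plausible
# values consistent with the reported orderings (fines and nutrients
# CK > SP > HS > BS; bulk density BS > HS > CK > SP) and control-relative
# fold changes for such sandy soils.
default_soil_surface_means <- function() {
  tibble::tribble(
    ~indicator,          ~CK,    ~SP,    ~HS,    ~BS,
    "clay",              0.63,   0.42,   0.31,   0.12,
    "silt",              1.17,   0.94,   0.85,   0.52,
    "very_fine_sand",    5.76,   4.84,   3.85,   2.04,
    "fine_sand",        73.17,  73.47,  74.53,  74.83,
    "medium_sand",      16.64,  17.01,  17.11,  18.65,
    "coarse_sand",       2.12,   2.79,   2.81,   3.26,
    "very_coarse_sand",  0.51,   0.53,   0.54,   0.58,
    "water_content",     7.0,    6.6,    6.2,    5.0,
    "bulk_density",      1.43,   1.40,   1.47,   1.60,
    "total_N",           0.32,   0.25,   0.18,   0.10,
    "total_P",           0.30,   0.26,   0.22,   0.18,
    "total_K",          21.5,   20.5,   19.5,   18.0,
    "available_N",      20.0,   16.0,   12.0,    8.0,
    "available_P",       4.0,    3.8,    2.6,    2.0,
    "available_K",     110.0,   95.0,   80.0,   60.0
  )
}

default_depth_slopes <- function() {
  # fraction slopes sum to zero so the closed composition stays exact at depth
  c(clay = -0.21, silt = -0.20, very_fine_sand = -1.00, fine_sand = -1.47,
    medium_sand = 2.00, coarse_sand = 0.80, very_coarse_sand = 0.08,
    water_content = 0.50, bulk_density = 0.04, total_N = -0.04,
    total_P = -0.03, total_K = -0.50, available_N = -2.00,
    available_P = -0.40, available_K = -12.0)
}

default_noise_sd <- function() {
  c(clay = 0.03, silt = 0.03, very_fine_sand = 0.20, fine_sand = 0.45,
    medium_sand = 0.35, coarse_sand = 0.18, very_coarse_sand = 0.02,
    water_content = 0.40, bulk_density = 0.04, total_N = 0.02,
    total_P = 0.02, total_K = 0.50, available_N = 1.00,
    available_P = 0.25, available_K = 6.0, cover = 1.6)
}

#' Effect profile driving the synthetic study generator
#'
#' Specifies the "planted truth" of a synthetic study: per-land-type mean
#' understory cover and expected species richness, surface-depth soil
#' indicator means, a signed per-depth-step gradient for each soil
#' indicator, and per-indicator noise standard deviations. The defaults
#' emulate a restoration gradient in which the *C. korshinskii* plantation
#' (CK) outperforms *S. psammophila* (SP) and *H. scoparium* (HS), with bare
#' sand (BS) worst: cover 34.9 / 26.13 / 20.2 / 11.27 %, richness
#' 14 / 13 / 11 / 7 species, fine particles and nutrients ordered
#' CK > SP > HS > BS and bulk density BS > HS > CK > SP.
#'
#' Noise enters at two levels: a site-level random effect and an
#' observation-level error, both with the indicator's `noise_sd` (cover
#' noise is a site-level shift in percentage points; quadrat-level cover is
#' a binomial count out of a 10 x 10 grid). Bulk density and total porosity
#' are generated jointly via `porosity = (1 - BD / 2.65) * 100` with the
#' mineral particle density fixed at 2.65 g cm^-3.
#'
#' @param cover_mean Named numeric, mean understory cover (%) per land type.
#' @param richness Named integer, expected species richness per land type.
#' @param soil_surface_mean Tibble: column `indicator` plus one numeric
#'   column per land type, giving the surface-depth (first interval) mean.
#' @param depth_slope Named numeric, signed change per depth step for each
#'   soil indicator (units of the indicator per 20 cm layer).
#' @param noise_sd Named numeric, standard deviation per indicator
#'   (including `"cover"`).
#' @param seed Integer seed; all stochastic draws flow from this one value.
#'
#' @return An object of class `effect_profile`.
#' @export
#' @examples
#' eff <- effect_profile(seed = 1)
#' eff$cover_mean
effect_profile <- function(cover_mean = c(CK = 34.9, SP = 26.13, HS = 20.2, BS = 11.27),
                           richness = c(CK = 14, SP = 13, HS = 11, BS = 7),
                           soil_surface_mean = default_soil_surface_means(),
                           depth_slope = default_depth_slopes(),
                           noise_sd = default_noise_sd(),
                           seed = 20L) {
  if (any(cover_mean < 0 | cover_mean > 100)) {
    abort("cover_mean must lie in [0, 100].")
  }
  if (any(noise_sd < 0)) abort("noise_sd must be non-negative.")
  if (any(richness < 1)) abort("richness must be at least 1 per land type.")
  missing_sd <- setdiff(c(soil_indicator_names(), "cover"), names(noise_sd))
  if (length(missing_sd) > 0) {
    abort(paste("noise_sd missing entries for:", paste(missing_sd, collapse = ", ")))
  }
  missing_slope <- setdiff(soil_indicator_names(), names(depth_slope))
  if (length(missing_slope) > 0) {
    abort(paste("depth_slope missing entries for:", paste(missing_slope, collapse = ", ")))
  }
  if (!all(soil_indicator_names() %in% soil_surface_mean$indicator)) {
    abort("soil_surface_mean must contain every soil indicator row.")
  }
  structure(
    list(cover_mean = cover_mean,
         richness = richness,
         soil_surface_mean = tibble::as_tibble(soil_surface_mean),
         depth_slope = depth_slope,
         noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "effect_profile"
  )
}

#' @export
print.effect_profile <- function(x, ...) {
  cat("<effect_profile>\n")
  cat("  cover means (%): ",
      paste(sprintf("%s=%.2f", names(x$cover_mean), x$cover_mean), collapse = ", "), "\n")
  cat("  richness:        ",
      paste(sprintf("%s=%d", names(x$richness), x$richness), collapse = ", "), "\n")
  cat("  soil indicators: ", nrow(x$soil_surface_mean), "\n")
  cat("  seed:            ", x$seed, "\n")
  invisible(x)
}
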