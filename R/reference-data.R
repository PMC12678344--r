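#' Reference tables from a Kubuqi Desert plantation evaluation
#'
#' Small reference datasets from a field evaluation of three sand-fixing
#' shrub plantations — *Caragana korshinskii* (CK), *Salix psammophila*
#' (SP), *Hedysarum scoparium* (HS) — against a bare-sand control (BS) in
#' the Kubuqi Desert. They serve as worked-example inputs and as fixed
#' oracles for the package's arithmetic (importance values summing to 100,
#' communalities from loadings, weights from communalities, ranking).
#'
#' * `kubuqi_importance_values()`: species importance values (0–100) per
#'   land type, long format, with genus/family annotations. Absent species
#'   are omitted (IV 0).
#' * `kubuqi_cover_means()`: mean understory vegetation cover (%) and its
#'   standard deviation per land type.
#' * `kubuqi_pca_table()`: the published PCA weighting of the twenty
#'   evaluation indicators — loadings on the two retained components,
#'   communality, weight — plus the component eigenvalues in attribute
#'   `"eigenvalues"`.
#' * `kubuqi_relevance()`: equal-weight and weighted grey relevance per
#'   land type.
#' * `kubuqi_clay_depth_means()`: clay content (%) by land type and depth.
#'
#' @return Tibbles; see above.
#' @name kubuqi_reference
NULL

#' @rdname kubuqi_reference
#' @export
kubuqi_importance_values <- function() {
  long <- tibble::tribble(
    ~species,                  ~CK,   ~SP,   ~HS,   ~BS,
    "Artemisia frigida",        2.19,    NA,    NA,    NA,
    "Artemisia desertorum",    12.98, 17.54, 28.50, 20.26,
    "Artemisia capillaris",     1.95,  2.03,  4.11,    NA,
    "Artemisia annua",          3.10,    NA,    NA,    NA,
    "Aster hispidus",             NA,    NA, 17.66, 15.25,
    "Ixeris polycephala",         NA,    NA,  6.43,  1.56,
    "Lespedeza bicolor",       17.60,  8.12,  3.88,  6.82,
    "Sophora alopecuroides",    3.71,    NA,    NA,    NA,
    "Astragalus laxmannii",     3.52,  2.70,  3.61,    NA,
    "Oxytropis racemosa",         NA,  1.58,    NA,    NA,
    "Agriophyllum squarrosum",  5.25,  3.66,  2.00, 15.87,
    "Bassia scoparia",          3.39,    NA,    NA,    NA,
    "Salsola collina",          5.18, 26.90,    NA,    NA,
    "Suaeda glauca",              NA,  2.11,    NA,    NA,
    "Setaria viridis",         12.17,  8.25, 16.80, 35.52,
    "Stipa caucasica",          5.36,  7.74,  4.53,    NA,
    "Agropyron mongolicum",     1.83,  4.17,  5.41,  4.72,
    "Tribulus terrestris",     21.77,    NA,  7.07,    NA,
    "Euphorbia humifusa",         NA, 12.35,    NA,    NA,
    "Incarvillea sinensis",       NA,  2.85,    NA,    NA
  )
  long |>
    tidyr::pivot_longer(c("CK", "SP", "HS", "BS"), names_to = "plot_id",
                        values_to = "importance_value") |>
    filter(!is.na(.data$importance_value)) |>
    left_join(default_species_pool(), by = "species") |>
    select("plot_id", "species", "genus", "family", "life_form",
           "importance_value")
}

#' @rdname kubuqi_reference
#' @export
kubuqi_cover_means <- function() {
  tibble::tibble(
    land_type = c("CK", "SP", "HS", "BS"),
    cover_mean = c(34.9, 26.13, 20.2, 11.27),
    cover_sd = c(2.18, 1.71, 1.26, 1.2)
  )
}

#' @rdname kubuqi_reference
#' @export
kubuqi_pca_table <- function() {
  tab <- tibble::tribble(
    ~indicator,       ~PC1,   ~PC2,  ~communality, ~weight,
    "shannon",         0.908,  0.269, 0.896, 0.0508,
    "simpson",         0.921,  0.355, 0.975, 0.0553,
    "pielou",          0.634, -0.091, 0.410, 0.0233,
    "margalef",        0.843,  0.497, 0.958, 0.0544,
    "cover",           0.893,  0.368, 0.933, 0.0529,
    "n_species",       0.895,  0.423, 0.980, 0.0556,
    "dominant_iv",    -0.115, -0.751, 0.578, 0.0328,
    "n_perennial",     0.888,  0.431, 0.975, 0.0553,
    "clay",            0.928, -0.257, 0.927, 0.0526,
    "silt",            0.982, -0.047, 0.967, 0.0549,
    "sand",           -0.982,  0.132, 0.981, 0.0557,
    "water_content",   0.044,  0.984, 0.970, 0.0550,
    "bulk_density",   -0.875,  0.213, 0.812, 0.0461,
    "total_porosity",  0.844, -0.154, 0.737, 0.0418,
    "total_N",         0.894, -0.363, 0.932, 0.0529,
    "total_P",         0.949, -0.192, 0.938, 0.0532,
    "total_K",         0.967, -0.162, 0.961, 0.0545,
    "available_N",     0.799, -0.516, 0.904, 0.0513,
    "available_P",     0.920, -0.001, 0.846, 0.0480,
    "available_K",     0.892, -0.387, 0.946, 0.0537
  )
  attr(tab, "eigenvalues") <- c(PC1 = 14.37, PC2 = 3.254)
  tab
}

#' @rdname kubuqi_reference
#' @export
kubuqi_relevance <- function() {
  tibble::tibble(
    land_type = c("CK", "SP", "HS", "BS"),
    equal_weight_relevance = c(0.8539, 0.7818, 0.6982, 0.5812),
    weighted_relevance = c(0.8574, 0.7790, 0.6883, 0.5637)
  )
}

#' @rdname kubuqi_reference
#' @export
kubuqi_clay_depth_means <- function() {
  tibble::tribble(
    ~land_type, ~`0-20`, ~`20-40`, ~`40-60`,
    "CK", 0.63, 0.48, 0.21,
    "SP", 0.42, 0.26, 0.15,
    "HS", 0.31, 0.18, 0.08,
    "BS", 0.12, 0.07, 0.03
  ) |>
    tidyr::pivot_longer(-"land_type", names_to = "depth", values_to = "clay")
}
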