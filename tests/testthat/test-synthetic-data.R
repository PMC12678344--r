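test_that("default design yields the nested sample counts", {
  study <- generate_study(study_design(), effect_profile(seed = 101))
  expect_equal(nrow(study$soil), 108)  # 4 types x 3 sites x 3 points x 3 depths
  expect_equal(nrow(dplyr::distinct(study$soil, plot_id)), 12)
  quadrat_groups <- dplyr::distinct(study$quadrats, plot_id, quadrat_id)
  expect_equal(nrow(quadrat_groups), 60)  # 12 plots x 5 quadrats
  counts <- dplyr::count(dplyr::distinct(study$soil, land_type, plot_id,
                                         point_id, depth), land_type)
  expect_true(all(counts$n == 27))
})

test_that("generated tables satisfy their structural contracts", {
  study <- generate_study(study_design(), effect_profile(seed = 102))
  fr <- as.matrix(study$soil[c("clay", "silt", "very_fine_sand", "fine_sand",
                               "medium_sand", "coarse_sand", "very_coarse_sand")])
  expect_true(all(abs(rowSums(fr) - 100) < 1e-9))
  expect_true(all(fr >= 0))
  expect_true(all(study$quadrats$abundance >= 1))
  expect_true(all(study$quadrats$abundance == floor(study$quadrats$abundance)))
  expect_true(all(study$quadrats$cover >= 0 & study$quadrats$cover <= 100))
  expect_true(all(study$soil$bulk_density > 0 & study$soil$bulk_density <= 2.65))
  # porosity is tied to bulk density through the fixed particle density
  expect_equal(study$soil$total_porosity,
               (1 - study$soil$bulk_density / 2.65) * 100)
})

test_that("generation is deterministic in the seed and sensitive to it", {
  a <- generate_study(study_design(), effect_profile(seed = 7))
  b <- generate_study(study_design(), effect_profile(seed = 7))
  c <- generate_study(study_design(), effect_profile(seed = 8))
  expect_identical(a$quadrats, b$quadrats)
  expect_identical(a$soil, b$soil)
  expect_false(identical(a$soil, c$soil))
  expect_false(identical(a$quadrats, c$quadrats))
})

test_that("invalid designs and profiles are rejected", {
  expect_error(effect_profile(noise_sd = replace(default_noise_sd(), "clay", -1)),
               "non-negative")
  small_pool <- default_species_pool()[1:5, ]
  expect_error(
    generate_study(study_design(species_pool = small_pool), effect_profile(seed = 1)),
    "species pool"
  )
  expect_error(study_design(depths = c("0-20", "30-40")), "contiguous")
  expect_error(study_design(sites_per_type = 0), "positive integers")
})

test_that("zero-noise depth profiles reproduce the configured means and slopes", {
  eff <- effect_profile(seed = 5,
                        noise_sd = setNames(rep(0, 16),
                                            names(default_noise_sd())))
  study <- generate_study(study_design(), eff)
  agg <- site_aggregate(study$soil)$by_depth
  slopes <- sandfix:::default_depth_slopes()
  surf <- sandfix:::default_soil_surface_means()
  for (ind in c("clay", "total_N", "medium_sand", "water_content")) {
    ck <- agg[agg$plot_id == "CK-1", ]
    ck <- ck[order(ck$depth), ]
    mu0 <- surf[[ "CK" ]][surf$indicator == ind]
    expect_equal(ck[[ind]], mu0 + slopes[[ind]] * (0:2), tolerance = 1e-12)
    # depth-gradient sign matches the configured slope sign exactly
    expect_true(all(sign(diff(ck[[ind]])) == sign(slopes[[ind]])))
  }
})

test_that("raising a configured nutrient mean raises the realized mean in expectation", {
  base <- effect_profile(seed = 1)
  raised_tab <- base$soil_surface_mean
  raised_tab$HS[raised_tab$indicator == "total_P"] <-
    raised_tab$HS[raised_tab$indicator == "total_P"] + 0.1
  diffs <- vapply(1:100, function(s) {
    lo <- generate_study(study_design(), effect_profile(seed = s))
    hi <- generate_study(study_design(),
                         effect_profile(soil_surface_mean = raised_tab, seed = s))
    mean(hi$soil$total_P[hi$soil$land_type == "HS"]) -
      mean(lo$soil$total_P[lo$soil$land_type == "HS"])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("planted_truth reads the ordering and drivers off the configuration", {
  truth <- planted_truth(effect_profile(seed = 1))
  expect_equal(truth$ordering, c("CK", "SP", "HS", "BS"))
  expect_true(all(c("cover", "n_species", "clay", "silt", "bulk_density") %in%
                    truth$drivers))
  expect_true(truth$top_driver %in% truth$drivers)

  # all-equal means: no ordering is implied
  flat_tab <- sandfix:::default_soil_surface_means()
  for (ty in c("CK", "SP", "HS")) flat_tab[[ty]] <- flat_tab$BS
  flat <- effect_profile(cover_mean = c(CK = 20, SP = 20, HS = 20, BS = 20),
                         richness = c(CK = 9, SP = 9, HS = 9, BS = 9),
                         soil_surface_mean = flat_tab, seed = 1)
  expect_null(planted_truth(flat)$ordering)
  expect_length(planted_truth(flat)$drivers, 0)

  # only cover varying: cover is the sole driver
  cover_only <- effect_profile(richness = c(CK = 9, SP = 9, HS = 9, BS = 9),
                               soil_surface_mean = flat_tab, seed = 1)
  expect_equal(planted_truth(cover_only)$drivers, "cover")
  expect_equal(planted_truth(cover_only)$top_driver, "cover")
})

test_that("study tables round-trip through CSV", {
  study <- generate_study(study_design(), effect_profile(seed = 103))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  q <- read_quadrats(file.path(dir, "quadrats.csv"))
  s <- read_soil(file.path(dir, "soil.csv"))
  expect_equal(as.data.frame(q), as.data.frame(study$quadrats))
  expect_equal(as.data.frame(s), as.data.frame(study$soil), tolerance = 1e-12)
})
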