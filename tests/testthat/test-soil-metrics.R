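test_that("particle binning handles point masses and conserves mass", {
  one <- bin_particle_distribution(0.3, 10)
  expect_equal(one$medium_sand, 100)
  expect_equal(sum(as.numeric(one)), 100, tolerance = 1e-9)

  two <- bin_particle_distribution(c(0.01, 1.5), c(1, 1))
  expect_equal(two$clay, 50)
  expect_equal(two$very_coarse_sand, 50)

  # boundary sizes go to the upper bin (half-open [lower, upper)), 2 mm in last
  edge <- bin_particle_distribution(c(0.02, 0.05, 2), c(1, 1, 1))
  expect_equal(edge$silt, 100 / 3, tolerance = 1e-9)
  expect_equal(edge$very_fine_sand, 100 / 3, tolerance = 1e-9)
  expect_equal(edge$very_coarse_sand, 100 / 3, tolerance = 1e-9)
})

test_that("binning a large random distribution matches direct per-bin summation", {
  withr::with_seed(3, {
    sizes <- runif(1000, 1e-4, 2)
    masses <- rexp(1000)
  })
  got <- bin_particle_distribution(sizes, masses)
  expect_equal(sum(as.numeric(got)), 100, tolerance = 1e-9)
  bins <- particle_bins()
  for (b in seq_len(nrow(bins))) {
    upper_closed <- b == nrow(bins)
    in_bin <- sizes >= bins$lower_mm[b] &
      (sizes < bins$upper_mm[b] | (upper_closed & sizes <= bins$upper_mm[b]))
    expect_equal(got[[bins$fraction[b]]],
                 sum(masses[in_bin]) / sum(masses) * 100, tolerance = 1e-9)
  }
  # permutation invariance
  perm <- sample(length(sizes))
  expect_equal(bin_particle_distribution(sizes[perm], masses[perm]), got,
               tolerance = 1e-12)
})

test_that("out-of-range particle sizes are rejected with their record index", {
  expect_error(bin_particle_distribution(c(0.5, 2.5), c(1, 1)), "2")
  expect_error(bin_particle_distribution(c(0, 0.5), c(1, 1)), "1")
  expect_error(bin_particle_distribution(0.5, -1), "non-negative")
  expect_error(bin_particle_distribution(c(0.1, 0.2), c(0, 0)), "positive")
})

test_that("porosity follows the fixed particle-density relation", {
  expect_equal(porosity_from_bulk_density(2.65), 0)
  expect_equal(porosity_from_bulk_density(1.325), 50)
  expect_equal(porosity_from_bulk_density(1.5), 43.39623, tolerance = 1e-5)
  expect_error(porosity_from_bulk_density(2.7), "exceed")
  expect_error(porosity_from_bulk_density(0), "positive")
})

test_that("site aggregation averages points within depths, then depths", {
  # published clay depth means collapse to the site means used downstream
  clay <- kubuqi_clay_depth_means() |>
    dplyr::mutate(plot_id = land_type, point_id = "P1")
  agg <- site_aggregate(clay)
  ck <- agg$site$clay[agg$site$plot_id == "CK"]
  bs <- agg$site$clay[agg$site$plot_id == "BS"]
  expect_equal(ck, 0.44, tolerance = 1e-9)
  expect_equal(bs, 0.0733, tolerance = 1e-3)

  # a constant indicator aggregates to itself, in any row order
  soil <- generate_study(effects = effect_profile(seed = 9))$soil
  soil$constant <- 3.14
  agg2 <- site_aggregate(soil)
  expect_true(all(agg2$site$constant == 3.14))
  shuffled <- soil[withr::with_seed(1, sample(nrow(soil))), ]
  agg3 <- site_aggregate(shuffled)
  expect_equal(dplyr::arrange(agg3$site, plot_id),
               dplyr::arrange(agg2$site, plot_id), tolerance = 1e-12)

  # aggregation is linear in each indicator
  soil2 <- soil
  soil2$clay <- 2 * soil2$clay + 1
  agg4 <- site_aggregate(soil2)
  expect_equal(agg4$site$clay, 2 * agg2$site$clay + 1, tolerance = 1e-12)
})

test_that("missing depth intervals are reported by name", {
  soil <- generate_study(effects = effect_profile(seed = 9))$soil
  holed <- soil[!(soil$plot_id == "HS-2" & soil$depth == "20-40"), ]
  expect_error(site_aggregate(holed), "HS-2@20-40")
})

test_that("control-relative change matches its definition", {
  id <- change_vs_control(5, 5)
  expect_equal(id$ratio, 1)
  expect_equal(id$relative_increase, 0)
  dbl <- change_vs_control(10, 5)
  expect_equal(dbl$relative_increase, 100)
  # site-mean clay of the best plantation vs bare sand: six-fold
  clay <- change_vs_control(0.44, mean(c(0.12, 0.07, 0.03)))
  expect_equal(clay$ratio, 6, tolerance = 1e-9)
  expect_error(change_vs_control(1, 0), "positive")
})
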