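test_that("importance values behave in degenerate and symmetric communities", {
  # monoculture
  iv1 <- importance_values(make_quadrats("a", 5))
  expect_equal(iv1$importance_value, 100)
  # two species with identical density, frequency and cover
  iv2 <- importance_values(make_quadrats(c("a", "b"), c(3, 3), cover = c(2, 2)))
  expect_equal(iv2$importance_value, c(50, 50))
  # all-zero abundance is an error
  expect_error(importance_values(make_quadrats(c("a", "b"), c(0, 0))),
               "all abundances are zero")
})

test_that("importance values sum to 100 within every plot", {
  # the published community table satisfies the contract column by column
  ref <- kubuqi_importance_values()
  sums <- dplyr::count(ref, plot_id, wt = importance_value)
  expect_equal(sums$n, rep(100, 4), tolerance = 0.005)

  # and so does any random community (property over seeds)
  withr::with_seed(42, {
    for (i in 1:20) {
      iv <- importance_values(random_community(n_species = sample(2:8, 1)))
      expect_equal(sum(iv$importance_value), 100, tolerance = 1e-9)
    }
  })
})

test_that("diversity indices match their closed forms", {
  u <- diversity_profile(rep(25, 4))  # uniform S = 4, N = 100
  expect_equal(u$shannon, log(4), tolerance = 1e-9)
  expect_equal(u$simpson, 4, tolerance = 1e-9)
  expect_equal(u$pielou, 1, tolerance = 1e-9)
  expect_equal(u$margalef, 3 / log(100), tolerance = 1e-9)

  d <- diversity_profile(c(5, 3, 2))  # p = (0.5, 0.3, 0.2), N = 10
  expect_equal(d$shannon, 1.0296530, tolerance = 1e-6)
  expect_equal(d$simpson, 2.6315789, tolerance = 1e-6)
  expect_equal(d$pielou, 0.9372306, tolerance = 1e-6)
  expect_equal(d$margalef, 0.8685890, tolerance = 1e-6)

  s1 <- diversity_profile(c(12))  # single species
  expect_equal(s1$shannon, 0)
  expect_equal(s1$simpson, 1)
  expect_true(is.na(s1$pielou))
  expect_equal(s1$margalef, 0)

  expect_error(diversity_profile(c(1)), "N > 1")
  expect_error(diversity_profile(c(0, 0)), "positive")
  expect_equal(diversity_profile(c(5, 5), simpson = "gini")$simpson, 0.5)
})

test_that("diversity indices agree with an independent implementation", {
  skip_if_not_installed("vegan")
  withr::with_seed(7, {
    for (i in 1:10) {
      x <- rpois(sample(2:5, 1), 8) + 1
      d <- diversity_profile(x)
      expect_equal(d$shannon, unname(vegan::diversity(x, "shannon")),
                   tolerance = 1e-12)
      expect_equal(d$simpson, unname(vegan::diversity(x, "invsimpson")),
                   tolerance = 1e-12)
    }
  })
})

test_that("diversity index inequalities hold over random communities", {
  withr::with_seed(11, {
    for (i in 1:25) {
      s <- sample(2:10, 1)
      x <- rpois(s, 5) + 1
      d <- diversity_profile(x)
      # Shannon is maximal for the uniform community of the same richness
      expect_lte(d$shannon, log(length(x)) + 1e-12)
      expect_gte(d$simpson, 1)
      expect_lte(d$simpson, length(x) + 1e-12)
      expect_gt(d$margalef, 0)
    }
  })
})

test_that("composition summary reproduces the published community structure", {
  comp <- composition_summary(kubuqi_importance_values())
  rich <- setNames(comp$per_plot$richness, comp$per_plot$plot_id)
  expect_equal(rich[c("CK", "SP", "HS", "BS")],
               c(CK = 14, SP = 13, HS = 11, BS = 7))
  expect_equal(comp$overall$n_species, 20)
  expect_equal(comp$overall$n_genus, 17)
  expect_equal(comp$overall$n_family, 7)
  ast <- comp$family_composition$share_pct[
    comp$family_composition$family == "Asteraceae"]
  expect_equal(ast, 30)
  top4 <- c("Asteraceae", "Fabaceae", "Amaranthaceae", "Poaceae")
  expect_equal(sum(comp$family_composition$share_pct[
    comp$family_composition$family %in% top4]), 85)
  # dominants at the IV >= 10 threshold
  sp_dom <- comp$per_plot$dominants[[which(comp$per_plot$plot_id == "SP")]]
  expect_setequal(sp_dom, c("Salsola collina", "Artemisia desertorum",
                            "Euphorbia humifusa"))
  ck_dom <- comp$per_plot$dominants[[which(comp$per_plot$plot_id == "CK")]]
  expect_true("Tribulus terrestris" %in% ck_dom)
  hs_dom <- comp$per_plot$dominants[[which(comp$per_plot$plot_id == "HS")]]
  expect_false("Tribulus terrestris" %in% hs_dom)  # IV 7.07 < 10 there
})

test_that("composition summary demands annotations", {
  iv <- tibble::tibble(plot_id = "A", species = "mystery plant",
                       importance_value = 100)
  expect_error(composition_summary(iv), "mystery plant")
})
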