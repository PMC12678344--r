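test_that("a planted linear signal is fit well and pure noise is not", {
  withr::with_seed(55, {
    x <- tibble::as_tibble(matrix(rnorm(80 * 5), 80, 5,
                                  dimnames = list(NULL, paste0("v", 1:5))))
    y <- 3 * x$v1 + rnorm(80, 0, 0.1)
    y_null <- sample(y)
  })
  fit <- fit_rf_cv(x, y, fast_rf(seed = 1, mtry_grid = 1:5))
  expect_gt(fit$r_squared, 0.9)
  expect_gte(fit$rmse, 0)
  expect_lte(fit$r_squared, 1)

  null_fit <- fit_rf_cv(x, y_null, fast_rf(seed = 1, mtry_grid = 1:5))
  expect_lt(null_fit$r_squared, 0.2)
})

test_that("splitting, mtry selection and diagnostics behave", {
  study <- generate_study(effects = effect_profile(seed = 41))
  im <- build_indicator_matrix(study$quadrats, study$soil)
  g <- suppressWarnings(gra_evaluate(im))
  cfg <- rf_config(mtry_grid = 3:15, n_trees = 150, n_permutations = 10,
                   seed = 2)
  fit <- fit_rf_cv(im, g$site_scores$weighted, cfg)
  # 7:3 stratified split: every land type keeps 2 of 3 sites in training
  expect_equal(length(fit$train_idx), 8)
  expect_equal(length(fit$test_idx), 4)
  train_types <- table(im$land_type[fit$train_idx])
  expect_true(all(train_types == 2))
  # the grid of 3..15 fits within the 20 predictors and is used unchanged
  expect_equal(fit$cv$mtry, 3:15)
  expect_true(fit$mtry %in% 3:15)
  # determinism in the seed
  fit2 <- fit_rf_cv(im, g$site_scores$weighted, cfg)
  expect_identical(fit$mtry, fit2$mtry)
  expect_identical(fit$r_squared, fit2$r_squared)

  expect_warning(
    fit_rf_cv(im[, 1:6], g$site_scores$weighted,
              rf_config(mtry_grid = 3:15, n_trees = 50, seed = 1)),
    "truncated")
  expect_error(fit_rf_cv(im, rep(1, 12), cfg), "constant")
  expect_error(fit_rf_cv(im[1:5, ], g$site_scores$weighted[1:5], cfg),
               "at least 10")
})

test_that("permutation p-values separate planted drivers from noise", {
  withr::with_seed(77, {
    x <- tibble::as_tibble(matrix(rnorm(40 * 4), 40, 4,
                                  dimnames = list(NULL, c("driver", "n1", "n2", "n3"))))
    y <- 3 * x$driver + rnorm(40, 0, 0.3)
  })
  fit <- fit_rf_cv(x, y, fast_rf(seed = 3, n_permutations = 200, mtry_grid = 1:4))
  imp <- permutation_importance_test(fit)
  tab <- imp$importance
  expect_equal(tab$predictor[1], "driver")
  expect_lte(tab$p_value[tab$predictor == "driver"], 0.05)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  # stars agree with the alpha mapping
  expect_true(all((tab$p_value < 0.001) == (tab$stars == "***")))

  # a single permutation with importance below the original gives p = 0
  fit1 <- fit_rf_cv(x, y, fast_rf(seed = 4, n_permutations = 1, mtry_grid = 1:4))
  imp1 <- permutation_importance_test(fit1)
  expect_equal(imp1$importance$p_value[imp1$importance$predictor == "driver"], 0)
  # the +1 correction can never give p = 0
  impc <- permutation_importance_test(
    fit1, modifyList(fit1$config, list(plus_one = TRUE)))
  expect_gt(min(impc$importance$p_value), 0)
})

test_that("a dominant planted driver tops the importance ranking across seeds", {
  tops <- vapply(1:10, function(s) {
    withr::with_seed(1000 + s, {
      x <- tibble::as_tibble(matrix(rnorm(30 * 5), 30, 5,
                                    dimnames = list(NULL, c("driver", paste0("n", 1:4)))))
      y <- 3 * x$driver + rnorm(30, 0, 0.3)
    })
    fit <- fit_rf_cv(x, y, fast_rf(seed = s, n_permutations = 1, mtry_grid = 1:3))
    imp <- permutation_importance_test(fit)
    imp$importance$predictor[1]
  }, character(1))
  expect_gte(sum(tops == "driver"), 9)
})

test_that("null-predictor p-values are approximately uniform", {
  ps <- vapply(1:100, function(s) {
    withr::with_seed(2000 + s, {
      x <- tibble::as_tibble(matrix(rnorm(20 * 3), 20, 3,
                                    dimnames = list(NULL, paste0("v", 1:3))))
      y <- rnorm(20)
    })
    fit <- fit_rf_cv(x, y, fast_rf(seed = s, n_permutations = 30,
                                   mtry_grid = 1:2, n_trees = 60))
    imp <- permutation_importance_test(fit)
    imp$importance$p_value[imp$importance$predictor == "v1"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.2)
  # and individually exceed 0.05 about 95% of the time
  expect_gte(mean(ps > 0.05), 0.85)
})
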