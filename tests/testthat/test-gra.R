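test_that("grey relational coefficients match hand-computed cases", {
  # ref (1,1); A deviates in h=2, B in h=1; dmin = 0, dmax = 0.5
  xi <- grey_relational_coefficients(rbind(A = c(1, 0.5), B = c(0.5, 1)),
                                     reference = c(1, 1))
  expect_equal(xi["A", ], c(1, 1 / 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(xi["B", ], c(1 / 3, 1), tolerance = 1e-12, ignore_attr = TRUE)

  # an object identical to the reference scores 1 everywhere
  xi2 <- grey_relational_coefficients(rbind(A = c(1, 1), B = c(0.2, 0.9)),
                                      reference = c(1, 1))
  expect_true(all(xi2["A", ] == 1))

  # all sequences identical to the reference: every coefficient is 1
  xi3 <- grey_relational_coefficients(rbind(c(1, 2), c(1, 2)),
                                      reference = c(1, 2))
  expect_true(all(xi3 == 1))
  expect_equal(relevance(xi3)$gamma, c(1, 1))

  # the worst deviation with dmin = 0 and rho = 0.5 scores rho/(1+rho) = 1/3
  xi4 <- grey_relational_coefficients(rbind(c(0, 1)), reference = c(1, 1))
  expect_equal(min(xi4), 1 / 3, tolerance = 1e-12)
})

test_that("coefficients are invariant to relabeling and deviation scaling", {
  withr::with_seed(17, {
    x <- matrix(runif(12), 3, 4, dimnames = list(c("a", "b", "c"), NULL))
    ref <- apply(x, 2, max)  # dmin = 0
    xi <- grey_relational_coefficients(x, ref)
    perm <- c(3, 1, 2)
    expect_equal(grey_relational_coefficients(x[perm, ], ref), xi[perm, ],
                 tolerance = 1e-12)
    # scaling all deviations by c > 0 (dmin = 0 case) leaves xi unchanged
    x_scaled <- sweep(sweep(x, 2, ref), 1:2, 2.7, `*`) + rep(ref, each = 3)
    expect_equal(grey_relational_coefficients(x_scaled, ref), xi,
                 tolerance = 1e-12)
  })
})

test_that("vectorized coefficients equal the literal three-loop oracle", {
  withr::with_seed(23, {
    for (i in 1:100) {
      m <- sample(2:4, 1); n <- sample(2:5, 1)
      x <- matrix(runif(m * n), m, n)
      ref <- apply(x, 2, max)
      expect_equal(grey_relational_coefficients(x, ref),
                   gra_oracle(x, ref), tolerance = 1e-12)
    }
  })
})

test_that("relevance reduces correctly under uniform and custom weights", {
  xi <- rbind(A = c(1, 1 / 3), B = c(0.6, 0.9))
  rel <- relevance(xi)
  expect_equal(rel$gamma, rel$weighted)  # uniform weights: R = gamma
  expect_equal(rel$gamma[1], 2 / 3, tolerance = 1e-9)
  relw <- relevance(xi, weights = c(0.8, 0.2))
  expect_equal(relw$weighted[1], 0.8666667, tolerance = 1e-6)
  expect_equal(relw$gamma[1], 0.6666667, tolerance = 1e-6)

  expect_error(relevance(xi, weights = c(1, 1, 1)), "length")
  expect_error(relevance(xi, weights = c(0.9, 0.2)), "sum to 1")
  expect_error(relevance(xi, weights = c(-0.2, 1.2)), "non-negative")
})

test_that("ranking is descending with competition ties", {
  r <- rank_objects(c(CK = 0.8574, SP = 0.7790, HS = 0.6883, BS = 0.5637))
  expect_equal(r$object, c("CK", "SP", "HS", "BS"))
  expect_equal(r$rank, 1:4)
  expect_equal(rank_objects(c(only = 0.5))$rank, 1)
  tie <- rank_objects(c(a = 0.7, b = 0.7, c = 0.2))
  expect_equal(tie$rank, c(1, 1, 3))
})

test_that("full GRA evaluation is coherent end to end", {
  study <- generate_study(effects = effect_profile(seed = 31))
  im <- build_indicator_matrix(study$quadrats, study$soil)
  res <- suppressWarnings(gra_evaluate(im))
  expect_s3_class(res, "gra_result")
  expect_equal(sort(res$scores$object), sort(unique(im$land_type)))
  expect_true(all(res$xi > 0 & res$xi <= 1))
  expect_true(all(res$scores$gamma > 0 & res$scores$gamma <= 1))
  expect_true(all(res$scores$weighted > 0 & res$scores$weighted <= 1))
  # gamma is the row mean of the coefficients
  expect_equal(res$scores$gamma,
               rowMeans(res$xi)[res$scores$object], ignore_attr = TRUE)
  # per-site scores exist for all 12 sites
  expect_equal(nrow(res$site_scores), 12)

  # equal weights collapse the weighted relevance onto gamma
  eq <- suppressWarnings(gra_evaluate(im, weights = "equal"))
  expect_equal(eq$scores$weighted, eq$scores$gamma, tolerance = 1e-12)

  # the all-ones reference is an upper bound for every normalized value
  ones <- suppressWarnings(gra_evaluate(im, reference = "ones"))
  expect_true(all(ones$xi > 0 & ones$xi <= 1))

  td <- tidy(res)
  expect_named(td, c("object", "equal_weight_relevance",
                     "weighted_relevance", "rank"))
})
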