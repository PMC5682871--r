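# Mixed models and the Snijders & Bosker explained-variance statistic.

test_that("log transform handles zeros, round-trips, and rejects negatives", {
  tab <- data.frame(animal_id = "A", fibrosis_pct = c(0, 57))
  lt <- logFibrosis(tab)
  expect_equal(lt$log_fibrosis[1], log(0.1))
  expect_equal(logFibrosis(tab, offset = 0)$log_fibrosis[2], log(57))
  expect_equal(exp(lt$log_fibrosis) - attr(lt, "logOffset"),
               tab$fibrosis_pct, tolerance = 1e-12)
  expect_error(logFibrosis(data.frame(animal_id = "A", fibrosis_pct = -1)),
               "nonnegative")
})

test_that("null model recovers components on a large generated cohort", {
  tab <- generateCohort(CohortSpec(nAnimals = 300, sectionsPerAnimal = 20,
                                   beta0 = 0, beta1 = 0, sigma2 = 1.0,
                                   tau00 = 0.25, seed = 21))
  fit <- fitNullModel(logFibrosis(tab, offset = 0))
  expect_false(fit@components@pooled)
  expect_lt(abs(fit@components@sigma2 - 1.0), 0.1)
  expect_lt(abs(fit@components@tau00 - 0.25), 0.05)
})

test_that("degenerate designs reduce to the closed-form decomposition", {
  # identical responses: zero everywhere, pooled
  flat <- data.frame(animal_id = rep(c("A", "B"), each = 3),
                     fibrosis_pct = rep(5, 6))
  f0 <- fitNullModel(flat)
  expect_true(f0@components@pooled)
  expect_equal(totalVariance(f0), 0, tolerance = 1e-12)
  # two animals at -1 / +1 with no within-animal noise: ML tau00 = 1
  tab <- data.frame(animal_id = rep(c("A", "B"), each = 4),
                    fibrosis_pct = exp(rep(c(-1, 1), each = 4)))
  f1 <- fitNullModel(logFibrosis(tab, offset = 0))
  expect_equal(f1@components@sigma2, 0, tolerance = 1e-10)
  expect_equal(f1@components@tau00, 1, tolerance = 1e-10)
})

test_that("perfect predictor drives the full total to zero and R2 to 100", {
  tab <- generateCohort(CohortSpec(nAnimals = 10, sectionsPerAnimal = 6,
                                   beta1 = 1, sigma2 = 0.5, tau00 = 0,
                                   beta0 = 0, seed = 4))
  tab <- logFibrosis(tab, offset = 0)
  tab$perfect <- tab$log_fibrosis
  full <- fitFullModel(tab, "perfect")
  null <- fitNullModel(tab)
  expect_lt(totalVariance(full), 1e-6)
  expect_gt(r2SnijdersBosker(full, null), 99.99)
})

test_that("slope is recovered within two standard errors", {
  cs <- CohortSpec(nAnimals = 100, sectionsPerAnimal = 10, beta0 = 0,
                   beta1 = 0.5, sigma2 = 1, tau00 = 0.25, seed = 13)
  fit <- fitFullModel(logFibrosis(generateCohort(cs), offset = 0),
                      "covariate")
  se <- sqrt(1 / (1000 - 2))  # approximate: sd(x) = 1, residual sd = 1
  expect_lt(abs(fit@beta[["covariate"]] - 0.5), 2 * 2 * se)
})

test_that("constant covariates and missing columns are rejected", {
  tab <- generateCohort(CohortSpec(nAnimals = 4, sectionsPerAnimal = 3))
  tab$flat <- 1
  expect_error(fitFullModel(tab, "flat"), "constant")
  expect_error(fitFullModel(tab, "absent"), "not found")
  expect_message(
    fitFullModel({tab$half <- tab$covariate; tab$half[1] <- NA; tab},
                 "half"), "dropped")
})

test_that("explained variance follows its defining ratio", {
  null <- VarianceComponents(1.2, 0.51)
  expect_equal(r2SnijdersBosker(null, null), 0)
  full <- VarianceComponents(0.62, 0.07)
  expect_equal(r2SnijdersBosker(full, VarianceComponents(1.71, 0, TRUE)),
               100 * (1 - 0.69 / 1.71))
  expect_warning(r2SnijdersBosker(VarianceComponents(2, 0.1), null),
                 "negative")
  expect_error(r2SnijdersBosker(full, VarianceComponents(0, 0, TRUE)),
               "positive")
})

test_that("R2 is invariant to shifting the response by a constant", {
  tab <- generateCohort(CohortSpec(nAnimals = 12, sectionsPerAnimal = 6,
                                   beta1 = 0.4, seed = 6))
  tab <- logFibrosis(tab, offset = 0)
  r2a <- r2SnijdersBosker(fitFullModel(tab, "covariate"), fitNullModel(tab))
  tab$log_fibrosis <- tab$log_fibrosis + 5
  r2b <- r2SnijdersBosker(fitFullModel(tab, "covariate"), fitNullModel(tab))
  expect_equal(r2a, r2b, tolerance = 1e-6)
})

test_that("compareAll reports a null row plus one row per covariate", {
  tab <- generateCohort(CohortSpec(nAnimals = 10, sectionsPerAnimal = 6,
                                   beta1 = 0.8, sigma2 = 0.4, seed = 2))
  set.seed(1)
  tab$noise <- rnorm(nrow(tab))
  res <- compareAll(tab, c("covariate", "noise"))
  expect_equal(res$covariate, c("(null)", "covariate", "noise"))
  expect_equal(res$r2_pct[1], 0)
  # the informative covariate explains strictly more than pure noise
  expect_gt(res$r2_pct[2], res$r2_pct[3])
  expect_equal(res$r2_display, as.integer(round(res$r2_pct)))
  expect_error(compareAll(tab, c("covariate", "covariate")), "duplicate")
  onlyNull <- compareAll(tab, character(0))
  expect_equal(nrow(onlyNull), 1)
})

test_that("generator tau00 = 0 triggers the pooled branch in most fits", {
  pooled <- vapply(1:20, function(s) {
    tab <- generateCohort(CohortSpec(nAnimals = 15, sectionsPerAnimal = 8,
                                     beta0 = 0, beta1 = 0, sigma2 = 1,
                                     tau00 = 0, seed = 400 + s))
    fitNullModel(logFibrosis(tab, offset = 0))@components@pooled
  }, logical(1))
  expect_gt(mean(pooled), 0.5)
  # and the pooled totals estimate sigma2 consistently
  totals <- vapply(1:20, function(s) {
    tab <- generateCohort(CohortSpec(nAnimals = 15, sectionsPerAnimal = 8,
                                     beta0 = 0, beta1 = 0, sigma2 = 1,
                                     tau00 = 0, seed = 400 + s))
    totalVariance(fitNullModel(logFibrosis(tab, offset = 0)))
  }, numeric(1))
  expect_lt(abs(mean(totals) - 1), 0.15)
})
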