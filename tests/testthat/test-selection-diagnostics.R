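test_that("WAIC matches direct evaluation of its formula", {
  # zero-variance draws: lppd = log 0.5, penalty = 0
  ll <- matrix(log(0.5), nrow = 4, ncol = 1)
  w <- waic(ll)
  expect_equal(w$waic, -2 * log(0.5), tolerance = 1e-12)
  expect_equal(w$penalty, 0)

  # two draws, hand arithmetic
  ll <- matrix(log(c(0.2, 0.8)), ncol = 1)
  lppd <- log(mean(c(0.2, 0.8)))
  pen <- var(log(c(0.2, 0.8)))
  expect_equal(waic(ll)$waic, -2 * (lppd - pen), tolerance = 1e-12)

  # decomposition: penalty non-negative, components add up
  set.seed(4)
  ll <- matrix(log(runif(200, 0.05, 0.9)), nrow = 20)
  w <- waic(ll)
  expect_gte(w$penalty, 0)
  expect_equal(w$waic, -2 * (w$lppd - w$penalty))
  expect_error(waic(matrix(c(1, NaN), 2)), "non-finite")
})

test_that("Gelman-Rubin Rhat detects mixed and unmixed chains", {
  set.seed(11)
  x <- rnorm(2000)
  expect_lt(abs(gelmanRhat(x, rep(1:2, each = 1000)) - 1), 0.05)
  separated <- c(rnorm(100, 0, 1), rnorm(100, 10, 1))
  expect_gt(gelmanRhat(separated, rep(1:2, each = 100)), 1.1)
  # frozen chains are not assessable, not converged
  expect_true(is.na(gelmanRhat(rep(1, 50), rep(1:2, each = 25))))
  expect_error(gelmanRhat(rnorm(10), rep(1, 10)), "2 chains")
})

test_that("credible-interval significance follows the percentile rule", {
  expect_true(isSignificant(runif(100, 0.1, 2)))
  set.seed(2)
  expect_false(isSignificant(rnorm(1000)))
  # 100 values whose 2.5th percentile is negative despite a positive bulk
  draws <- c(-0.01, -0.008, -0.005, -0.002, seq_len(96))
  expect_lt(quantile(draws, 0.025), 0)
  expect_false(isSignificant(draws))
})

test_that("Bayesian p-values behave at the degenerate extremes and are seeded", {
  # replicates forced equal to the observed data: psi ~ 1, p ~ 1, all y = 1
  h <- makeHistory(nSites = 3, nYears = 1, maxVisits = 3, seed = 21)
  h@visits$y <- 1L
  n <- 40
  big <- matrix(35, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- manualFit(h, big, big, z = matrix(1L, n, nrow(h@siteYears)))
  for (s in c("freeman_tukey", "chi_square"))
    for (g in c("sites", "replicates"))
      expect_equal(bayesP(fit, s, g, seed = 1), 1.0)

  # vocabulary errors and seed determinism on a real fit
  expect_error(bayesP(fit, "anderson_darling"), "arg")
  out <- simHistory(smallConfig(seed = 22, nSites = 60))
  f <- sampleOccupancy(occuModelSpec("ll", "habitat_of_site",
                                     c("list_length", "observer")),
                       out$history, chains = 2, iterations = 800,
                       burnIn = 300, thin = 1, seed = 5)
  p1 <- bayesP(f, "freeman_tukey", "sites", seed = 9)
  p2 <- bayesP(f, "freeman_tukey", "sites", seed = 9)
  expect_identical(p1, p2)
  expect_gte(p1, 0)
  expect_lte(p1, 1)
})

test_that("the packaged grid has 18 unique specs led by the full model", {
  grid <- defaultModelGrid()
  expect_length(grid, 18L)
  ids <- vapply(grid, function(s) s@id, character(1))
  expect_false(anyDuplicated(ids) > 0)
  full <- grid[[1]]
  expect_setequal(full@occupancyTerms,
                  c("year", "habitat_of_site", "distance_to_large_forest",
                    "site_size"))
  expect_setequal(full@detectionTerms,
                  c("list_length", "habitat_of_observation", "observer"))
  # every other spec omits at least one term of the full model
  nTerms <- vapply(grid, function(s)
    length(s@occupancyTerms) + length(s@detectionTerms), integer(1))
  expect_true(all(nTerms[-1] < nTerms[1]))
})

test_that("model selection returns a complete, deterministic WAIC ladder", {
  out <- simHistory(smallConfig(seed = 23, nSites = 80))
  grid <- list(occuModelSpec("full", c("habitat_of_site", "site_size"),
                             c("list_length", "observer")),
               occuModelSpec("int"))
  sel <- selectTopModel(grid, out$history, chains = 2, iterations = 800,
                        burnIn = 300, thin = 1, seed = 3)
  expect_equal(nrow(sel$ladder), 2L)
  expect_named(sel$ladder, c("spec_id", "waic", "lppd", "penalty",
                             "converged", "max_rhat", "n_terms"))
  expect_equal(sel$topSpec, sel$ladder$spec_id[1])
  expect_true(!is.unsorted(sel$ladder$waic))
  # single-spec grid returns that spec
  one <- selectTopModel(grid[2], out$history, chains = 2,
                        iterations = 800, burnIn = 300, thin = 1, seed = 3)
  expect_equal(one$topSpec, "int")
  # same seed -> byte-identical ladder
  sel2 <- selectTopModel(grid, out$history, chains = 2, iterations = 800,
                         burnIn = 300, thin = 1, seed = 3)
  expect_identical(sel$ladder, sel2$ladder)
})

test_that("fit reports carry coefficient summaries and diagnostics", {
  out <- simHistory(smallConfig(seed = 24, nSites = 60))
  fit <- sampleOccupancy(occuModelSpec("m", "site_size",
                                       c("list_length", "observer")),
                         out$history, chains = 2, iterations = 800,
                         burnIn = 300, thin = 1, seed = 4)
  rep <- fitReport(fit, ppc = TRUE, ppcSeed = 2)
  expect_true(all(c("submodel", "term", "mean", "sd", "lower", "upper",
                    "significant") %in% names(rep$coefficients)))
  expect_true("sigma_sq_obs" %in% rep$coefficients$term)
  expect_length(rep$bayes_p, 4L)
  expect_true(all(rep$bayes_p >= 0 & rep$bayes_p <= 1))
  expect_true(rep$detection_baseline["mean"] > 0 &&
                rep$detection_baseline["mean"] < 1)
})

test_that("posterior serialization round-trips losslessly", {
  out <- simHistory(smallConfig(seed = 25, nSites = 30, nObservers = 10))
  fit <- sampleOccupancy(occuModelSpec("m", "habitat_of_site",
                                       c("list_length", "observer")),
                         out$history, chains = 2, iterations = 300,
                         burnIn = 100, thin = 2, seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  writeFit(fit, f)
  fit2 <- readFit(f, out$history)
  expect_equal(fit2@beta, fit@beta)
  expect_equal(fit2@alpha, fit@alpha)
  expect_equal(fit2@observerEffects, fit@observerEffects)
  expect_equal(fit2@sigmaSqObs, fit@sigmaSqObs)
  expect_identical(fit2@z, fit@z)
  expect_equal(fit2@pointwiseLogLik, fit@pointwiseLogLik)
  expect_identical(fit2@chain, fit@chain)
  expect_equal(fit2@spec, fit@spec)
})
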