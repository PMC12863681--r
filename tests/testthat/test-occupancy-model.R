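test_that("marginal log-likelihood matches hand-computed closed forms", {
  # one site, one year, one visit; psi = p = 0.5
  h <- makeHistory(nSites = 1, nYears = 1, maxVisits = 1, seed = 5)
  v <- visitTable(h)
  expect_equal(nrow(v), 1L)
  spec <- occuModelSpec("int")
  params <- list(beta = 0, alpha = 0)

  h@visits$y <- 0L
  # psi*(1-p) + (1-psi) = 0.75
  expect_equal(marginalLogLik(spec, params, h), log(0.75),
               tolerance = 1e-12)
  h@visits$y <- 1L
  # psi*p = 0.25
  expect_equal(marginalLogLik(spec, params, h), log(0.25),
               tolerance = 1e-12)
})

test_that("marginalized likelihood equals brute-force enumeration over latent states", {
  specs <- list(
    occuModelSpec("int"),
    occuModelSpec("occ", c("habitat_of_site", "distance_to_large_forest"),
                  c("list_length")),
    occuModelSpec("full", c("year", "habitat_of_site",
                            "distance_to_large_forest", "site_size"),
                  c("list_length", "habitat_of_observation", "observer")))
  for (i in 1:30) {
    spec <- specs[[1 + i %% 3]]
    h <- makeHistory(nSites = 2 + i %% 4, nYears = 1 + i %% 2,
                     maxVisits = 4, seed = 1000 + i)
    params <- randomParams(spec, h, seed = 2000 + i)
    expect_equal(sum(marginalLogLik(spec, params, h)),
                 bruteForceLogLik(spec, params, h), tolerance = 1e-10)
  }
})

test_that("site-years without visits contribute exactly zero", {
  h <- makeHistory(nSites = 5, nYears = 2, maxVisits = 3, seed = 77)
  spec <- occuModelSpec("int")
  ll <- marginalLogLik(spec, list(beta = 0.3, alpha = -0.2), h)
  empty <- setdiff(h@siteYears$unit, visitTable(h)$unit)
  expect_true(length(empty) > 0)
  expect_equal(ll[empty], rep(0, length(empty)))
})

test_that("posterior sampling recovers known occupancy and detection", {
  # 200 sites, 1 year, 10 visits each, true psi = 0.8, p = 0.3
  set.seed(10)
  n <- 200; J <- 10
  z <- rbinom(n, 1, 0.8)
  y <- matrix(rbinom(n * J, 1, rep(z, each = J) * 0.3), nrow = J)
  rows <- list()
  for (i in seq_len(n)) for (j in seq_len(J))
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = sprintf("S%03d", i), year = 2020L, visit_index = j,
      observer_id = "o1", observer = 1L, y = y[j, i],
      list_length_raw = 1L + (j %% 3),
      habitat_of_observation = "non_forest", unit = i,
      stringsAsFactors = FALSE)
  v <- do.call(rbind, rows)
  v$list_length_std <- as.numeric(standardizeCovariate(
    as.numeric(v$list_length_raw)))
  sy <- data.frame(site_id = sprintf("S%03d", seq_len(n)), year = 2020L,
                   unit = seq_len(n))
  dist <- seq(100, 3000, length.out = n); area <- seq(5, 60, length.out = n)
  h <- new("DetectionHistory", focalSpecies = "focal", visits = v,
           siteCovariates = data.frame(
             site_id = sy$site_id, habitat_of_site = "non_forest",
             distance_raw = dist,
             distance_std = as.numeric(standardizeCovariate(dist)),
             area_raw = area,
             area_std = as.numeric(standardizeCovariate(area)),
             stringsAsFactors = FALSE),
           siteYears = sy, years = 2020L, observers = "o1",
           transforms = list(list_length = c(center = 0, scale = 1),
                             distance = c(center = 0, scale = 1),
                             area = c(center = 0, scale = 1)))
  fit <- sampleOccupancy(occuModelSpec("int"), h, chains = 3,
                         iterations = 6000, burnIn = 3000, thin = 3,
                         seed = 99)
  expect_equal(nDraws(fit), 3 * (6000 - 3000) / 3)
  expect_lt(abs(mean(plogis(fit@beta[, 1])) - 0.8), 0.1)
  expect_lt(abs(mean(plogis(fit@alpha[, 1])) - 0.3), 0.05)
  # detection implies occupancy in every draw
  det <- unique(v$unit[v$y == 1])
  expect_true(all(fit@z[, det] == 1L))
  # same seed twice: bit-identical posterior
  fit2 <- sampleOccupancy(occuModelSpec("int"), h, chains = 3,
                          iterations = 6000, burnIn = 3000, thin = 3,
                          seed = 99)
  expect_identical(fit@beta, fit2@beta)
  expect_identical(fit@alpha, fit2@alpha)
  expect_identical(fit@z, fit2@z)
  expect_identical(fit@pointwiseLogLik, fit2@pointwiseLogLik)
})

test_that("degenerate histories are rejected with advice", {
  h <- makeHistory(seed = 3)
  h@visits$y <- 1L
  expect_error(sampleOccupancy(occuModelSpec("int"), h),
               "inclusion criteria")
  h@visits$y <- 0L
  expect_error(sampleOccupancy(occuModelSpec("int"), h),
               "inclusion criteria")
  h <- makeHistory(seed = 3)
  expect_error(sampleOccupancy(occuModelSpec("int"), h, thin = 0),
               "thin")
})

test_that("posterior predictions follow the inverse-logit closed forms", {
  h <- makeHistory(seed = 8)
  beta <- matrix(c(-1, 0, 1), ncol = 1,
                 dimnames = list(NULL, "(Intercept)"))
  fit <- manualFit(h, beta, beta,
                   z = matrix(1L, 3, nrow(h@siteYears)))
  pr <- predictLinear(fit, data.frame(row.names = 1), "occupancy")
  expect_equal(drop(pr), plogis(c(-1, 0, 1)), tolerance = 1e-12)

  # all-zero coefficients give probability one-half everywhere
  fit0 <- manualFit(h, beta * 0, beta * 0,
                    z = matrix(1L, 3, nrow(h@siteYears)))
  expect_true(all(predictLinear(fit0, data.frame(row.names = 1),
                                "detection") == 0.5))
  # unknown covariates are refused
  expect_error(predictLinear(fit, data.frame(site_size = 10), "occupancy"),
               "absent from the fitted spec")
})

test_that("detection curves rise monotonically with a positive list-length effect", {
  h <- makeHistory(seed = 9, nSites = 6, maxVisits = 4)
  spec <- occuModelSpec("ll", character(), "list_length")
  set.seed(1)
  alpha <- cbind(`(Intercept)` = rnorm(50, 0, 0.3),
                 list_length = abs(rnorm(50, 0.8, 0.2)))
  beta <- matrix(0, 50, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- manualFit(h, beta, alpha, z = matrix(1L, 50, nrow(h@siteYears)))
  fit@spec <- spec
  pr <- predictLinear(fit, data.frame(list_length = 1:20), "detection")
  expect_true(all(diff(colMeans(pr)) > 0))
})
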