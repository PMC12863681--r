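# Small in-code fixtures shared across the test files.

# A hand-sized record table (valid by construction).
tinyRecords <- function() {
  data.frame(
    site_id = c("A", "A", "A", "B", "B", "C"),
    date = as.Date(c("2020-03-01", "2020-03-01", "2020-03-01",
                     "2020-05-10", "2021-06-02", "2020-07-04")),
    observer_id = c("o1", "o1", "o2", "o1", "o2", "o3"),
    species = c("sp1", "sp2", "sp1", "sp1", "sp3", "sp2"),
    group = c("bird", "mammal", "bird", "bird", "reptile", "mammal"),
    count = c(1L, 2L, 1L, 3L, 1L, 1L),
    stringsAsFactors = FALSE)
}

tinySites <- function(ids = c("A", "B", "C")) {
  n <- length(ids)
  data.frame(
    site_id = ids,
    site_type = rep(c("forest", "non_natural"), length.out = n),
    has_forest_patch = rep(FALSE, n),
    area_ha = seq(10, 10 + 5 * (n - 1), by = 5),
    distance_to_large_forest_m = seq(100, 100 + 400 * (n - 1), by = 400),
    stringsAsFactors = FALSE)
}

tinyDataset <- function() {
  ChecklistDataset(tinyRecords(), tinySites(), 2020:2021)
}

# Directly-constructed DetectionHistory with arbitrary y patterns, for the
# likelihood tests. Guarantees >= 1 detection, >= 1 non-detection and
# non-constant covariates.
makeHistory <- function(nSites = 4, nYears = 2, maxVisits = 4, seed = 1,
                        pDetect = 0.4) {
  set.seed(seed)
  siteIds <- sprintf("S%02d", seq_len(nSites))
  years <- 2020L + seq_len(nYears) - 1L
  siteYears <- data.frame(
    site_id = rep(siteIds, each = nYears),
    year = rep(years, times = nSites), stringsAsFactors = FALSE)
  siteYears$unit <- seq_len(nrow(siteYears))
  rows <- list()
  for (u in siteYears$unit) {
    nv <- sample(0:maxVisits, 1)
    for (j in seq_len(nv)) {
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = siteYears$site_id[u], year = siteYears$year[u],
        visit_index = j, observer_id = sprintf("o%d", sample(4, 1)),
        y = rbinom(1, 1, pDetect),
        list_length_raw = 1L + rpois(1, 2),
        habitat_of_observation = sample(c("forest", "non_forest"), 1),
        unit = u, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    rows[[1]] <- data.frame(
      site_id = siteYears$site_id[1], year = siteYears$year[1],
      visit_index = 1L, observer_id = "o1", y = 0L, list_length_raw = 1L,
      habitat_of_observation = "non_forest", unit = 1L,
      stringsAsFactors = FALSE)
  v <- do.call(rbind, rows)
  # force a mixed outcome vector where there is room
  v$y[1] <- 1L
  v$y[nrow(v)] <- 0L
  if (nrow(v) >= 2 && length(unique(v$list_length_raw)) == 1L)
    v$list_length_raw[1] <- v$list_length_raw[1] + 1L
  observers <- sort(unique(v$observer_id))
  v$observer <- match(v$observer_id, observers)
  # center/scale degenerate vectors by hand so tiny fixtures stay valid
  safeStd <- function(x) {
    if (length(x) >= 2 && sd(x) > 0) standardizeCovariate(x)
    else structure(x - mean(x), center = mean(x), scale = 1)
  }
  ll <- safeStd(as.numeric(v$list_length_raw))
  v$list_length_std <- as.numeric(ll)
  dist <- runif(nSites, 50, 4000)
  area <- runif(nSites, 5, 80)
  dS <- safeStd(dist)
  aS <- safeStd(area)
  sc <- data.frame(
    site_id = siteIds,
    habitat_of_site = sample(c("forest", "non_forest"), nSites,
                             replace = TRUE),
    distance_raw = dist, distance_std = as.numeric(dS),
    area_raw = area, area_std = as.numeric(aS), stringsAsFactors = FALSE)
  new("DetectionHistory", focalSpecies = "focal",
      visits = v[, c("site_id", "year", "visit_index", "observer_id",
                     "observer", "y", "list_length_raw", "list_length_std",
                     "habitat_of_observation", "unit")],
      siteCovariates = sc, siteYears = siteYears, years = years,
      observers = observers,
      transforms = list(
        list_length = c(center = attr(ll, "center"),
                        scale = attr(ll, "scale")),
        distance = c(center = attr(dS, "center"),
                     scale = attr(dS, "scale")),
        area = c(center = attr(aS, "center"), scale = attr(aS, "scale"))))
}

# Independent oracle: joint likelihood by brute-force enumeration over all
# latent z configurations (site-years independent only through the sum, so
# the enumeration is over {0,1}^U jointly).
bruteForceLogLik <- function(spec, params, history) {
  d <- designMatrices(spec, history)
  psi <- plogis(drop(d$X %*% params$beta))
  detLp <- drop(d$W %*% params$alpha)
  if (!is.null(d$observerIndex) && !is.null(params$observerEffects))
    detLp <- detLp + params$observerEffects[d$observerIndex]
  p <- plogis(detLp)
  v <- history@visits
  U <- nrow(history@siteYears)
  total <- 0
  # enumerate per unit and multiply: the joint sum over z factorizes, but
  # compute it the slow explicit way to stay independent of the formula
  # under test
  for (u in seq_len(U)) {
    rows <- which(v$unit == u)
    lik <- 0
    for (z in 0:1) {
      pz <- if (z == 1) psi[u] else 1 - psi[u]
      cond <- 1
      for (r in rows) {
        pr <- z * p[r]
        cond <- cond * (if (v$y[r] == 1) pr else 1 - pr)
      }
      lik <- lik + pz * cond
    }
    total <- total + log(lik)
  }
  unname(total)
}

# Random coefficient vectors sized to a spec/history pair.
randomParams <- function(spec, history, seed) {
  set.seed(seed)
  d <- designMatrices(spec, history)
  list(beta = rnorm(ncol(d$X), 0, 1),
       alpha = rnorm(ncol(d$W), 0, 1),
       observerEffects = if (!is.null(d$observerIndex))
         rnorm(length(history@observers), 0, 0.5))
}

# Simulate a small scenario and assemble the focal history.
simHistory <- function(config, scheme = "standard",
                       sitePopulation = "observed") {
  sim <- simulateChecklists(config)
  ds <- deduplicateRecords(sim$dataset)
  v <- buildVisits(ds)
  v <- restrictForScheme(v, ds, scheme, sim$truth$config$focalGroup)
  list(history = assembleHistory(v, sim$truth$config$focalSpecies, ds,
                                 sitePopulation = sitePopulation),
       truth = sim$truth, dataset = ds)
}

# Compact simulation config for fast model-level tests.
smallConfig <- function(seed, nSites = 120, nYears = 2, nObservers = 40,
                        visitRate = 5, ...) {
  args <- list(...)
  if (is.null(args$occupancyCoefs))
    args$occupancyCoefs <- list(intercept = 0.4,
                                year = rep(0.2, nYears - 1),
                                habitat_of_site = 1.0,
                                distance_to_large_forest = -0.8,
                                site_size = 0.7)
  do.call(simulationConfig,
          c(list(nSites = nSites, nYears = nYears,
                 nObservers = nObservers, visitRate = visitRate,
                 seed = seed), args))
}

# A hand-built OccuFit around explicit draws (for derived-output tests).
manualFit <- function(history, beta, alpha, z, chain = NULL) {
  n <- nrow(beta)
  new("OccuFit",
      spec = occuModelSpec("manual", character(), character()),
      history = history, beta = beta, alpha = alpha,
      observerEffects = matrix(numeric(0), nrow = n, ncol = 0),
      sigmaSqObs = numeric(0), z = z,
      pointwiseLogLik = matrix(0, n, nrow(history@siteYears)),
      chain = if (is.null(chain)) rep(1L, n) else chain,
      settings = list(chains = 1L, iterations = n, burnIn = 0L,
                      thin = 1L, seed = 0L, priors = occuPriors()))
}
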