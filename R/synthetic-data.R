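#' Default species pool for the checklist generator
#'
#' A fixed multi-group species pool (all five groups represented) with
#' commonness weights decaying within each group and a per-species constant
#' occupancy probability for the non-focal "filler" species that pad the
#' checklists. Group-level weights reflect the reporting shares typical of
#' plantation recording programs: birds dominate, mammals and reptiles
#' follow, and plants and insects are minority groups — so discarding the
#' latter two removes only a small fraction of checklists.
#'
#' @return data.frame with columns \code{species}, \code{group},
#'   \code{weight}, \code{psi}.
#' @export
defaultSpeciesPool <- function() {
  sizes <- c(bird = 18, mammal = 10, reptile = 6, plant = 16, insect = 10)
  groupShare <- c(bird = 1.0, mammal = 0.5, reptile = 0.35, plant = 0.25,
                  insect = 0.2)
  pool <- do.call(rbind, lapply(names(sizes), function(g) {
    n <- sizes[[g]]
    data.frame(species = sprintf("%s_%02d", g, seq_len(n)), group = g,
               weight = groupShare[[g]] *
                 exp(seq(log(2), log(0.1), length.out = n)),
               stringsAsFactors = FALSE)
  }))
  pool$psi <- 0.3 + 0.6 * pool$weight / max(pool$weight)
  rownames(pool) <- NULL
  pool
}

#' Configuration of the synthetic checklist generator
#'
#' Defines a generative process emulating opportunistic plantation
#' checklist data: a site universe with forest/non-natural sites, annual
#' closure seasons, Poisson numbers of visits per site-year, short species
#' lists, heterogeneous observers, and one focal species following the full
#' occupancy/detection model with observer random effects. Defaults emulate
#' the structure of a large plantation recording scheme: ~390 sites over 5
#' years, ~370 observers, 6-8 visits per surveyed site-year, mean list
#' length ~2.4, 28% of sites surveyed in a single year.
#'
#' @param nSites,nYears,nObservers dimensions of the study.
#' @param propForestSites fraction of sites that are forest sites.
#' @param propPatchSites fraction of non-natural sites with a forest patch.
#' @param visitRate Poisson mean of visits per surveyed site-year.
#' @param occupancyCoefs list (logit scale): \code{intercept}, \code{year}
#'   (length nYears - 1, contrasts to the first season),
#'   \code{habitat_of_site}, \code{distance_to_large_forest},
#'   \code{site_size} (the latter two apply to covariates standardized over
#'   the simulated site universe).
#' @param detectionCoefs list (logit scale): \code{intercept},
#'   \code{list_length} (standardized), \code{habitat_of_observation}.
#' @param sigmaObs sd of the zero-mean normal observer effects.
#' @param speciesPool filler-species pool (see [defaultSpeciesPool()]);
#'   must contain all five groups.
#' @param listLengthRate Poisson mean of extra species per visit (list
#'   length = 1 + Poisson draw).
#' @param oneYearSiteFraction fraction of sites surveyed in one season only.
#' @param observerSpecialization NULL (every observer records all groups)
#'   or a list of \code{list(groups = , weight = )} patterns sampled per
#'   observer.
#' @param dedicatedObserverSkew >= 0; 0 assigns visits to observers
#'   uniformly, larger values concentrate visits on a small dedicated set
#'   (weights proportional to rank^-skew).
#' @param distanceMeanM exponential mean of distance to large forest (m).
#' @param areaMeanLog,areaSdLog log-normal parameters of site area (ha).
#' @param obsForestProbForest,obsForestProbPatch probability a visit to a
#'   forest site (site with a patch) is made in the forested part.
#' @param focalSpecies,focalGroup name and group of the focal species.
#' @param firstYear first calendar year.
#' @param seed integer seed; fixed seed means byte-identical output.
#' @return validated config (list of class \code{"occuSimConfig"}).
#' @export
simulationConfig <- function(
    nSites = 390, nYears = 5, nObservers = 370,
    propForestSites = 0.05, propPatchSites = 0.15, visitRate = 7,
    occupancyCoefs = list(intercept = 0.5,
                          year = c(0.3, -0.3, 0.5, -0.2)[seq_len(max(nYears - 1, 0))],
                          habitat_of_site = 1.0,
                          distance_to_large_forest = -0.8,
                          site_size = 0.7),
    detectionCoefs = list(intercept = qlogis(0.2), list_length = 0.5,
                          habitat_of_observation = -0.5),
    sigmaObs = 0.75, speciesPool = defaultSpeciesPool(),
    listLengthRate = 1.4, oneYearSiteFraction = 0.28,
    observerSpecialization = NULL, dedicatedObserverSkew = 0,
    distanceMeanM = 2000, areaMeanLog = log(30), areaSdLog = 0.6,
    obsForestProbForest = 0.8, obsForestProbPatch = 0.3,
    focalSpecies = "monitor_lizard", focalGroup = "reptile",
    firstYear = 2020, seed = 1) {
  cfg <- as.list(environment())
  fr <- c(propForestSites, propPatchSites, oneYearSiteFraction,
          obsForestProbForest, obsForestProbPatch)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (visitRate <= 0 || listLengthRate <= 0)
    stop("rates must be positive")
  if (!all(.GROUPS %in% speciesPool$group))
    stop("species pool must contain all five groups: ",
         paste(setdiff(.GROUPS, speciesPool$group), collapse = ", "))
  if (nYears > 1 && length(occupancyCoefs$year) != nYears - 1)
    stop("occupancyCoefs$year must have length nYears - 1")
  if (!focalGroup %in% .GROUPS) stop("unknown focal group ", focalGroup)
  if (focalSpecies %in% speciesPool$species)
    stop("focal species must not be in the filler pool")
  class(cfg) <- "occuSimConfig"
  cfg
}

#' Simulate an opportunistic checklist dataset with known truth
#'
#' Draws site covariates, the focal species' latent occupancy states from
#' the configured occupancy model, visits with observers and dates, focal
#' detections from the configured detection model (with observer random
#' effects), and filler-list content from the species pool conditioned on
#' the fillers' own latent presence — so no species is ever recorded at a
#' site-year where its true state is absent. The emitted records contain
#' only presences, exactly like real opportunistic data; list length is
#' 1 + a Poisson draw, and a detected focal species occupies one of those
#' list slots.
#'
#' @param config an \code{"occuSimConfig"} from [simulationConfig()].
#' @return list with \code{dataset} (a [ChecklistDataset-class]) and
#'   \code{truth} (site covariates, per-site-year latent states of focal
#'   and filler species, observer effects and groups, the baseline psi and
#'   p, and the config).
#' @export
simulateChecklists <- function(config) {
  stopifnot(inherits(config, "occuSimConfig"))
  cfg <- config
  set.seed(cfg$seed)
  years <- cfg$firstYear + seq_len(cfg$nYears) - 1L

  ## -- sites ----------------------------------------------------------
  siteId <- sprintf("S%04d", seq_len(cfg$nSites))
  isForest <- runif(cfg$nSites) < cfg$propForestSites
  patch <- !isForest & runif(cfg$nSites) < cfg$propPatchSites
  area <- rlnorm(cfg$nSites, cfg$areaMeanLog, cfg$areaSdLog)
  area[isForest] <- area[isForest] * 5
  dist <- rexp(cfg$nSites, 1 / cfg$distanceMeanM)
  sites <- data.frame(
    site_id = siteId,
    site_type = ifelse(isForest, "forest", "non_natural"),
    has_forest_patch = patch, area_ha = round(area, 2),
    distance_to_large_forest_m = round(dist, 1),
    stringsAsFactors = FALSE)
  sites$habitat_of_site <- ifelse(isForest | patch, "forest", "non_forest")
  dStd <- as.numeric(scale(sites$distance_to_large_forest_m))
  aStd <- as.numeric(scale(sites$area_ha))

  ## -- latent occupancy of the focal species --------------------------
  oc <- cfg$occupancyCoefs
  yearEff <- c(0, if (cfg$nYears > 1) oc$year)
  lp <- outer(oc$intercept + oc$habitat_of_site *
                (sites$habitat_of_site == "forest") +
                oc$distance_to_large_forest * dStd +
                oc$site_size * aStd,
              yearEff, `+`)
  psi <- plogis(pmin(pmax(lp, -.LOGIT_CLIP), .LOGIT_CLIP))
  zFocal <- matrix(rbinom(length(psi), 1L, psi), nrow = cfg$nSites,
                   dimnames = list(siteId, years))

  ## -- latent presence of the filler species --------------------------
  pool <- cfg$speciesPool
  nPool <- nrow(pool)
  zPool <- array(rbinom(nPool * cfg$nSites * cfg$nYears, 1L,
                        rep(pool$psi, times = cfg$nSites * cfg$nYears)),
                 dim = c(nPool, cfg$nSites, cfg$nYears),
                 dimnames = list(pool$species, siteId, years))

  ## -- observers ------------------------------------------------------
  obsId <- sprintf("O%04d", seq_len(cfg$nObservers))
  eta <- rnorm(cfg$nObservers, 0, cfg$sigmaObs)
  obsWeight <- if (cfg$dedicatedObserverSkew > 0)
    seq_len(cfg$nObservers)^(-cfg$dedicatedObserverSkew)
  else rep(1, cfg$nObservers)
  if (is.null(cfg$observerSpecialization)) {
    obsGroups <- rep(list(.GROUPS), cfg$nObservers)
  } else {
    pats <- cfg$observerSpecialization
    wts <- vapply(pats, `[[`, numeric(1), "weight")
    pick <- sample.int(length(pats), cfg$nObservers, replace = TRUE,
                       prob = wts)
    obsGroups <- lapply(pats[pick], `[[`, "groups")
  }

  ## -- visits ---------------------------------------------------------
  nOne <- round(cfg$oneYearSiteFraction * cfg$nSites)
  oneYearSites <- sample.int(cfg$nSites, nOne)
  soloYear <- sample.int(cfg$nYears, cfg$nSites, replace = TRUE)
  vs <- vector("list", cfg$nSites * cfg$nYears)
  k <- 0L
  for (i in seq_len(cfg$nSites)) {
    yrs <- if (i %in% oneYearSites) soloYear[i] else seq_len(cfg$nYears)
    for (t in yrs) {
      nv <- rpois(1, cfg$visitRate)
      if (nv == 0) next
      k <- k + 1L
      vs[[k]] <- data.frame(
        site = i, yearIdx = t,
        day = sample.int(360, min(nv, 360)),
        obs = sample.int(cfg$nObservers, min(nv, 360), replace = TRUE,
                         prob = obsWeight))
    }
  }
  v <- do.call(rbind, vs[seq_len(k)])
  nV <- nrow(v)
  inForest <- ifelse(isForest[v$site], runif(nV) < cfg$obsForestProbForest,
                     patch[v$site] & runif(nV) < cfg$obsForestProbPatch)
  L <- 1L + rpois(nV, cfg$listLengthRate)
  llStd <- as.numeric(scale(L))

  ## -- focal detections -----------------------------------------------
  dc <- cfg$detectionCoefs
  detLp <- dc$intercept + dc$list_length * llStd +
    dc$habitat_of_observation * inForest + eta[v$obs]
  p <- plogis(pmin(pmax(detLp, -.LOGIT_CLIP), .LOGIT_CLIP))
  recordsFocal <- vapply(seq_len(nV), function(j)
    cfg$focalGroup %in% obsGroups[[v$obs[j]]], logical(1))
  yFocal <- rbinom(nV, 1L, zFocal[cbind(v$site, v$yearIdx)] * p *
                     recordsFocal)

  ## -- list content ---------------------------------------------------
  grpOfPool <- pool$group
  recs <- vector("list", nV)
  for (j in seq_len(nV)) {
    nFill <- L[j] - yFocal[j]
    chosen <- integer(0)
    if (nFill > 0) {
      avail <- which(zPool[, v$site[j], v$yearIdx[j]] == 1L &
                       grpOfPool %in% obsGroups[[v$obs[j]]])
      if (length(avail))
        chosen <- avail[sample.int(length(avail),
                                   min(nFill, length(avail)),
                                   prob = pool$weight[avail])]
    }
    spp <- c(if (yFocal[j]) cfg$focalSpecies, pool$species[chosen])
    if (!length(spp)) next
    recs[[j]] <- data.frame(
      site_id = siteId[v$site[j]],
      date = as.character(as.Date(sprintf("%d-01-01", years[v$yearIdx[j]]))
                          + v$day[j] - 1L),
      observer_id = obsId[v$obs[j]],
      species = spp,
      group = c(if (yFocal[j]) cfg$focalGroup, grpOfPool[chosen]),
      count = 1L + rpois(length(spp), 0.3),
      in_forest = inForest[j], stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  records$date <- as.Date(records$date)
  rownames(records) <- NULL

  dataset <- ChecklistDataset(records, sites, years)
  truth <- list(
    sites = cbind(sites, distance_std = dStd, area_std = aStd),
    psi = psi, zFocal = zFocal, zPool = zPool,
    observerEffects = setNames(eta, obsId),
    observerGroups = setNames(obsGroups, obsId),
    psiBaseline = plogis(oc$intercept),
    pBaseline = plogis(dc$intercept),
    listLengthCenter = mean(L), listLengthScale = sd(L),
    config = cfg)
  list(dataset = dataset, truth = truth)
}

#' Named library of generator scenarios
#'
#' Ships ready-made configurations: \code{kal_like} (the default structure:
#' ~390 sites, 5 seasons, ~370 observers, short lists, 28% one-year
#' sites), \code{kal_like_small} (300 sites, baseline detection 0.2,
#' moderate effects — the parameter-recovery workhorse),
#' \code{high_detection} and \code{low_detection} (baseline p 0.5 and
#' 0.05), \code{no_covariate_effects} (intercepts only), and
#' \code{scheme_sensitivity} (observer group-specialization so the four
#' non-detection schemes genuinely differ).
#'
#' @return named list of \code{"occuSimConfig"} objects.
#' @export
scenarioLibrary <- function() {
  list(
    kal_like = simulationConfig(seed = 101),
    kal_like_small = simulationConfig(
      nSites = 300, nObservers = 150, sigmaObs = 0.75, seed = 202),
    high_detection = simulationConfig(
      nSites = 150, nYears = 3, nObservers = 80,
      occupancyCoefs = list(intercept = 0.5, year = c(0.3, -0.3),
                            habitat_of_site = 1.0,
                            distance_to_large_forest = -0.8,
                            site_size = 0.7),
      detectionCoefs = list(intercept = 0, list_length = 0.5,
                            habitat_of_observation = -0.5),
      seed = 303),
    low_detection = simulationConfig(
      nSites = 150, nYears = 3, nObservers = 80,
      occupancyCoefs = list(intercept = 0.5, year = c(0.3, -0.3),
                            habitat_of_site = 1.0,
                            distance_to_large_forest = -0.8,
                            site_size = 0.7),
      detectionCoefs = list(intercept = qlogis(0.05), list_length = 0.5,
                            habitat_of_observation = -0.5),
      seed = 404),
    no_covariate_effects = simulationConfig(
      nSites = 150, nYears = 3, nObservers = 80,
      occupancyCoefs = list(intercept = 0.4, year = c(0, 0),
                            habitat_of_site = 0,
                            distance_to_large_forest = 0, site_size = 0),
      detectionCoefs = list(intercept = qlogis(0.25), list_length = 0,
                            habitat_of_observation = 0),
      sigmaObs = 0, seed = 505),
    scheme_sensitivity = simulationConfig(
      nSites = 120, nYears = 3, nObservers = 100,
      occupancyCoefs = list(intercept = 0.5, year = c(0.3, -0.3),
                            habitat_of_site = 1.0,
                            distance_to_large_forest = -0.8,
                            site_size = 0.7),
      observerSpecialization = list(
        list(groups = .GROUPS, weight = 0.4),
        list(groups = c("bird", "mammal", "reptile"), weight = 0.15),
        list(groups = "bird", weight = 0.15),
        list(groups = c("bird", "plant"), weight = 0.10),
        list(groups = c("plant", "insect"), weight = 0.20)),
      seed = 606))
}

#' Write a simulated dataset to the standard file schemas
#'
#' Emits the records and sites tables in exactly the delimited formats that
#' [readRecords()] and [readSites()] ingest (so a simulated study round-trips
#' through the file interface), together with a structured-text truth file
#' (site covariates, latent states, observer effects) and the generating
#' configuration.
#'
#' @param sim result of [simulateChecklists()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written: \code{records.csv},
#'   \code{sites.csv}, \code{truth.txt}, \code{config.txt}.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("records.csv", "sites.csv", "truth.txt",
                            "config.txt"))
  rec <- sim$dataset@records
  rec$date <- format(rec$date, "%Y-%m-%d")
  write.csv(rec, paths[1], row.names = FALSE, quote = FALSE)
  sites <- sim$dataset@sites
  write.csv(sites[, c("site_id", "site_type", "has_forest_patch",
                      "area_ha", "distance_to_large_forest_m")],
            paths[2], row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  con <- file(paths[3], "w")
  writeLines(c("# simulated truth", "", "## zFocal (site x year)"), con)
  write.csv(cbind(site_id = rownames(truth$zFocal),
                  as.data.frame(truth$zFocal)), con, row.names = FALSE)
  writeLines(c("", "## observer effects"), con)
  write.csv(data.frame(observer_id = names(truth$observerEffects),
                       eta = truth$observerEffects), con,
            row.names = FALSE)
  writeLines(c("", sprintf("psi_baseline: %.10g", truth$psiBaseline),
               sprintf("p_baseline: %.10g", truth$pBaseline)), con)
  close(con)
  cfg <- truth$config
  cfg$speciesPool <- NULL  # reproducible from defaultSpeciesPool()
  dput(unclass(cfg), paths[4])
  invisible(paths)
}
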