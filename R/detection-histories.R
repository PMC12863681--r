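#' Build visits (checklists) from deduplicated records
#'
#' A visit is a unique (site, date, observer) combination with at least one
#' record: the replicate unit of the detection submodel. Its list length is
#' the number of distinct species reported, across all groups present in the
#' working dataset. The habitat of observation is taken from the record-level
#' \code{in_forest} flag when supplied; otherwise it defaults to forest for
#' forest sites and non-forest for all other sites. A forest observation at
#' a site without forest habitat is inconsistent and is coerced to
#' non-forest with a warning.
#'
#' @param dataset a deduplicated [ChecklistDataset-class].
#' @return data.frame of visits with columns \code{site_id}, \code{date},
#'   \code{year}, \code{observer_id}, \code{list_length},
#'   \code{habitat_of_observation} and a list-column \code{species}.
#' @export
buildVisits <- function(dataset) {
  rec <- dataset@records
  if (!nrow(rec))
    return(data.frame(site_id = character(), date = as.Date(character()),
                      year = integer(), observer_id = character(),
                      list_length = integer(),
                      habitat_of_observation = character()))
  key <- paste(rec$site_id, rec$date, rec$observer_id, sep = "\r")
  first <- !duplicated(key)
  sp <- split(rec$species, factor(key, levels = key[first]))
  sp <- lapply(sp, unique)
  flag <- tapply(rec$in_forest, factor(key, levels = key[first]),
                 function(f) if (all(is.na(f))) NA else any(f, na.rm = TRUE))
  v <- data.frame(site_id = rec$site_id[first], date = rec$date[first],
                  year = as.integer(format(rec$date[first], "%Y")),
                  observer_id = rec$observer_id[first],
                  stringsAsFactors = FALSE)
  v$list_length <- vapply(sp, length, integer(1))
  siteType <- setNames(dataset@sites$site_type, dataset@sites$site_id)
  siteHab <- setNames(dataset@sites$habitat_of_site, dataset@sites$site_id)
  default <- ifelse(siteType[v$site_id] == "forest", "forest", "non_forest")
  hab <- ifelse(is.na(flag), default, ifelse(flag, "forest", "non_forest"))
  bad <- hab == "forest" & siteHab[v$site_id] != "forest"
  if (any(bad)) {
    warning(sum(bad), " visit(s) flagged as forest observations at sites ",
            "without forest habitat; coerced to non_forest")
    hab[bad] <- "non_forest"
  }
  v$habitat_of_observation <- as.vector(hab)
  v$species <- unname(sp)
  rownames(v) <- NULL
  v
}

#' Restrict visits under a non-detection generation scheme
#'
#' Because observers kept no fixed species lists, a non-detection ("the
#' species was not on this checklist") can be generated in several ways.
#' \code{standard} keeps every visit. \code{nondet3grp} discards plant and
#' insect records, recomputes list lengths over the three remaining groups
#' and drops visits left empty. \code{nondet3grp_obs1grp} additionally keeps
#' only visits by observers who recorded the focal species' group at least
#' once anywhere in the dataset; \code{nondet3grp_obs3grp} keeps only
#' observers who recorded all three study groups. Observer eligibility is
#' judged over the whole dataset, not per year.
#'
#' @param visits visits from [buildVisits()].
#' @param dataset the [ChecklistDataset-class] the visits were built from
#'   (source of the species-to-group map and observer histories).
#' @param scheme one of \code{"standard"}, \code{"nondet3grp"},
#'   \code{"nondet3grp_obs1grp"}, \code{"nondet3grp_obs3grp"}.
#' @param focalGroup group of the focal species; must be \code{"bird"},
#'   \code{"mammal"} or \code{"reptile"}.
#' @return the restricted visits data.frame (same columns).
#' @export
restrictForScheme <- function(visits, dataset,
                              scheme = c("standard", "nondet3grp",
                                         "nondet3grp_obs1grp",
                                         "nondet3grp_obs3grp"),
                              focalGroup) {
  scheme <- match.arg(scheme)
  if (scheme == "standard") return(visits)
  if (!focalGroup %in% .STUDY_GROUPS)
    stop("focalGroup must be one of ", paste(.STUDY_GROUPS, collapse = ", "),
         " (study species are birds, mammals and reptiles)")
  rec <- dataset@records
  spGroup <- setNames(rec$group, rec$species)
  spGroup <- spGroup[!duplicated(names(spGroup))]
  keepSpecies <- function(s) s[spGroup[s] %in% .STUDY_GROUPS]
  v <- visits
  v$species <- lapply(v$species, keepSpecies)
  v$list_length <- vapply(v$species, length, integer(1))
  v <- v[v$list_length > 0L, , drop = FALSE]
  if (scheme != "nondet3grp") {
    obsGroups <- tapply(rec$group, rec$observer_id,
                        function(g) unique(g), simplify = FALSE)
    eligible <- if (scheme == "nondet3grp_obs1grp") {
      names(obsGroups)[vapply(obsGroups, function(g) focalGroup %in% g,
                              logical(1))]
    } else {
      names(obsGroups)[vapply(obsGroups,
                              function(g) all(.STUDY_GROUPS %in% g),
                              logical(1))]
    }
    v <- v[v$observer_id %in% eligible, , drop = FALSE]
  }
  rownames(v) <- NULL
  v
}

#' Standardize a covariate to mean 0, sd 1
#'
#' Centers and scales with the sample standard deviation (n - 1
#' denominator), recording the affine transform in the \code{"center"} and
#' \code{"scale"} attributes so predictions can later be expressed on the
#' natural scale. A constant covariate carries no information and is an
#' error.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return standardized numeric vector with attributes \code{center},
#'   \code{scale}.
#' @export
standardizeCovariate <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values to standardize")
  if (!all(is.finite(x))) stop("non-finite covariate value")
  s <- sd(x)
  if (s == 0) stop("constant covariate cannot be standardized")
  m <- mean(x)
  structure((x - m) / s, center = m, scale = s)
}

#' Assemble a per-species detection history
#'
#' Builds the ragged detection/non-detection array for one focal species:
#' y = 1 where the visit's checklist includes the species, 0 otherwise;
#' visits are grouped into site-year units (calendar-year closure). Site
#' covariates (distance to large forest, site size) and list length are
#' standardized over the units used for fitting; observers get dense integer
#' indices. Seasons with no visits at a site remain in the unit grid (they
#' keep a latent occupancy state but contribute no detection data).
#'
#' @param visits visits (possibly scheme-restricted).
#' @param focalSpecies species name; must occur in the dataset.
#' @param dataset the parent [ChecklistDataset-class].
#' @param sitePopulation \code{"observed"} (default) restricts the fitted
#'   statistical population to sites with at least one visit; \code{"all"}
#'   keeps every site in the site table.
#' @return a [DetectionHistory-class].
#' @export
assembleHistory <- function(visits, focalSpecies, dataset,
                            sitePopulation = c("observed", "all")) {
  sitePopulation <- match.arg(sitePopulation)
  if (!focalSpecies %in% dataset@records$species)
    stop("focal species ", sQuote(focalSpecies), " absent from the dataset")
  years <- dataset@years
  sites <- dataset@sites
  if (sitePopulation == "observed")
    sites <- sites[sites$site_id %in% visits$site_id, , drop = FALSE]
  sites <- sites[order(sites$site_id), , drop = FALSE]
  v <- visits[visits$site_id %in% sites$site_id, , drop = FALSE]
  if (!nrow(v)) stop("no visits at the fitted sites")

  v$y <- vapply(v$species, function(s) as.integer(focalSpecies %in% s),
                integer(1))
  v <- v[order(v$site_id, v$year, v$date, v$observer_id), , drop = FALSE]
  ukey <- paste(v$site_id, v$year, sep = "\r")
  v$visit_index <- stats::ave(seq_len(nrow(v)), ukey,
                              FUN = seq_along)

  siteYears <- data.frame(
    site_id = rep(sites$site_id, each = length(years)),
    year = rep(years, times = nrow(sites)), stringsAsFactors = FALSE)
  siteYears$unit <- seq_len(nrow(siteYears))
  v$unit <- siteYears$unit[match(paste(v$site_id, v$year, sep = "\r"),
                                 paste(siteYears$site_id, siteYears$year,
                                       sep = "\r"))]

  observers <- sort(unique(v$observer_id))
  v$observer <- match(v$observer_id, observers)

  llStd <- standardizeCovariate(as.numeric(v$list_length))
  dStd <- standardizeCovariate(sites$distance_to_large_forest_m)
  aStd <- standardizeCovariate(sites$area_ha)
  transforms <- list(
    list_length = c(center = attr(llStd, "center"),
                    scale = attr(llStd, "scale")),
    distance = c(center = attr(dStd, "center"), scale = attr(dStd, "scale")),
    area = c(center = attr(aStd, "center"), scale = attr(aStd, "scale")))

  visitsOut <- data.frame(
    site_id = v$site_id, year = v$year, visit_index = v$visit_index,
    observer_id = v$observer_id, observer = v$observer, y = v$y,
    list_length_raw = as.integer(v$list_length),
    list_length_std = as.numeric(llStd),
    habitat_of_observation = v$habitat_of_observation,
    unit = v$unit, stringsAsFactors = FALSE)
  rownames(visitsOut) <- NULL
  siteCov <- data.frame(
    site_id = sites$site_id, habitat_of_site = sites$habitat_of_site,
    distance_raw = sites$distance_to_large_forest_m,
    distance_std = as.numeric(dStd),
    area_raw = sites$area_ha, area_std = as.numeric(aStd),
    stringsAsFactors = FALSE)
  rownames(siteCov) <- NULL
  new("DetectionHistory", focalSpecies = focalSpecies, visits = visitsOut,
      siteCovariates = siteCov, siteYears = siteYears,
      years = as.integer(years), observers = observers,
      transforms = transforms)
}

#' Summary of a detection history (dataset-variant properties)
#'
#' One summary row per dataset variant: number of sites with observations,
#' mean visits per site, mean list length, number of observers, and the
#' counts of detection and non-detection records of the focal species.
#'
#' @param history a [DetectionHistory-class].
#' @return one-row data.frame.
#' @export
historySummary <- function(history) {
  v <- history@visits
  nSites <- length(unique(v$site_id))
  data.frame(
    n_sites = nSites,
    # mean visits per surveyed site-year
    mean_visits_per_site = nrow(v) / length(unique(paste(v$site_id, v$year))),
    mean_list_length = mean(v$list_length_raw),
    n_observers = length(history@observers),
    n_detections = sum(v$y),
    n_nondetections = sum(v$y == 0L))
}

#' Serialize / read back a detection history
#'
#' Writes the visit-level table
#' (\code{site_id,year,visit_index,observer_id,y,list_length_raw,habitat_of_observation})
#' and the site-covariate table as comma-separated text. \code{readHistory}
#' reconstructs the [DetectionHistory-class] losslessly (standardized
#' covariates are recomputed from the raw values by the same deterministic
#' transform).
#'
#' @param history a [DetectionHistory-class].
#' @param visitsPath,sitesPath output (input) file paths.
#' @param focalSpecies,years for \code{readHistory}: the focal species name
#'   and ordered seasons of the serialized history.
#' @return \code{readHistory} returns the reconstructed
#'   [DetectionHistory-class]; \code{writeHistory} returns the paths,
#'   invisibly.
#' @export
writeHistory <- function(history, visitsPath, sitesPath) {
  v <- history@visits[, c("site_id", "year", "visit_index", "observer_id",
                          "y", "list_length_raw", "habitat_of_observation")]
  write.csv(v, visitsPath, row.names = FALSE, quote = FALSE)
  s <- history@siteCovariates[, c("site_id", "habitat_of_site",
                                  "distance_raw", "area_raw")]
  write.csv(s, sitesPath, row.names = FALSE, quote = FALSE)
  invisible(c(visitsPath, sitesPath))
}

#' @rdname writeHistory
#' @export
readHistory <- function(visitsPath, sitesPath, focalSpecies, years) {
  v <- read.csv(visitsPath, stringsAsFactors = FALSE,
                colClasses = c(site_id = "character",
                               observer_id = "character"))
  s <- read.csv(sitesPath, stringsAsFactors = FALSE,
                colClasses = c(site_id = "character"))
  s <- s[order(s$site_id), , drop = FALSE]
  years <- as.integer(years)
  v <- v[order(v$site_id, v$year, v$visit_index), , drop = FALSE]
  siteYears <- data.frame(
    site_id = rep(s$site_id, each = length(years)),
    year = rep(years, times = nrow(s)), stringsAsFactors = FALSE)
  siteYears$unit <- seq_len(nrow(siteYears))
  v$unit <- siteYears$unit[match(paste(v$site_id, v$year, sep = "\r"),
                                 paste(siteYears$site_id, siteYears$year,
                                       sep = "\r"))]
  observers <- sort(unique(v$observer_id))
  v$observer <- match(v$observer_id, observers)
  llStd <- standardizeCovariate(as.numeric(v$list_length_raw))
  dStd <- standardizeCovariate(s$distance_raw)
  aStd <- standardizeCovariate(s$area_raw)
  visitsOut <- data.frame(
    site_id = v$site_id, year = v$year, visit_index = v$visit_index,
    observer_id = v$observer_id, observer = v$observer, y = as.integer(v$y),
    list_length_raw = as.integer(v$list_length_raw),
    list_length_std = as.numeric(llStd),
    habitat_of_observation = v$habitat_of_observation,
    unit = v$unit, stringsAsFactors = FALSE)
  rownames(visitsOut) <- NULL
  siteCov <- data.frame(
    site_id = s$site_id, habitat_of_site = s$habitat_of_site,
    distance_raw = s$distance_raw, distance_std = as.numeric(dStd),
    area_raw = s$area_raw, area_std = as.numeric(aStd),
    stringsAsFactors = FALSE)
  rownames(siteCov) <- NULL
  new("DetectionHistory", focalSpecies = focalSpecies, visits = visitsOut,
      siteCovariates = siteCov, siteYears = siteYears, years = years,
      observers = observers,
      transforms = list(
        list_length = c(center = attr(llStd, "center"),
                        scale = attr(llStd, "scale")),
        distance = c(center = attr(dStd, "center"),
                     scale = attr(dStd, "scale")),
        area = c(center = attr(aStd, "center"),
                 scale = attr(aStd, "scale"))))
}
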