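#' ChecklistDataset: validated opportunistic sighting records plus sites
#'
#' Container for a working checklist dataset: one row of \code{records} per
#' sighting (site, date, observer, species, group, count, optional in-forest
#' flag), one row of \code{sites} per spatial unit, and the ordered calendar
#' years that define the closure seasons.
#'
#' @slot records data.frame with columns \code{site_id}, \code{date} (Date),
#'   \code{observer_id}, \code{species}, \code{group}, \code{count},
#'   \code{in_forest} (logical, may be NA).
#' @slot sites data.frame with columns \code{site_id}, \code{site_type}
#'   (\code{"forest"} or \code{"non_natural"}), \code{has_forest_patch},
#'   \code{area_ha}, \code{distance_to_large_forest_m},
#'   \code{habitat_of_site} (derived: forest iff a forest site or a
#'   non-natural site with a forest patch).
#' @slot years integer vector of ordered calendar years.
#' @exportClass ChecklistDataset
setClass("ChecklistDataset",
  representation(records = "data.frame", sites = "data.frame",
                 years = "integer"))

setValidity("ChecklistDataset", function(object) {
  msg <- character()
  rec <- object@records
  st <- object@sites
  need_r <- c("site_id", "date", "observer_id", "species", "group", "count")
  need_s <- c("site_id", "site_type", "has_forest_patch", "area_ha",
              "distance_to_large_forest_m", "habitat_of_site")
  if (!all(need_r %in% names(rec)))
    msg <- c(msg, paste("records lacks columns:",
                        paste(setdiff(need_r, names(rec)), collapse = ", ")))
  if (!all(need_s %in% names(st)))
    msg <- c(msg, paste("sites lacks columns:",
                        paste(setdiff(need_s, names(st)), collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(st$site_id))
    msg <- c(msg, "duplicated site_id in site table")
  if (nrow(rec)) {
    bad <- setdiff(unique(rec$site_id), st$site_id)
    if (length(bad))
      msg <- c(msg, paste("records refer to unknown sites:",
                          paste(head(bad, 5), collapse = ", ")))
    if (!all(rec$group %in% .GROUPS))
      msg <- c(msg, paste("unknown group label(s):",
                          paste(unique(setdiff(rec$group, .GROUPS)),
                                collapse = ", ")))
    if (any(rec$count < 1 | rec$count != round(rec$count)))
      msg <- c(msg, "count must be a positive integer")
    ry <- as.integer(format(rec$date, "%Y"))
    if (!all(ry %in% object@years))
      msg <- c(msg, "record dates outside the dataset years")
  }
  if (any(st$area_ha <= 0)) msg <- c(msg, "site area must be > 0")
  if (any(st$distance_to_large_forest_m < 0))
    msg <- c(msg, "distance to large forest must be >= 0")
  derived <- ifelse(st$site_type == "forest" | st$has_forest_patch,
                    "forest", "non_forest")
  if (!identical(as.character(st$habitat_of_site), derived))
    msg <- c(msg, "habitat_of_site inconsistent with site_type/has_forest_patch")
  if (length(msg)) msg else TRUE
})

#' DetectionHistory: per-species ragged detection array with covariates
#'
#' Detection/non-detection data for one focal species: one row of
#' \code{visits} per checklist (unique site x date x observer), grouped into
#' site-year units (calendar-year closure), plus standardized site- and
#' visit-level covariates and a dense observer index.
#'
#' @slot focalSpecies character scalar.
#' @slot visits data.frame with columns \code{site_id}, \code{year},
#'   \code{visit_index}, \code{observer_id}, \code{observer} (dense integer
#'   index), \code{y} (0/1), \code{list_length_raw}, \code{list_length_std},
#'   \code{habitat_of_observation}, \code{unit} (site-year index).
#' @slot siteCovariates data.frame with per-site \code{habitat_of_site},
#'   raw and standardized \code{distance} and \code{area}.
#' @slot siteYears data.frame enumerating the site-year units (rows define
#'   the unit index used by the model code).
#' @slot years integer vector of seasons.
#' @slot observers character vector: observer id per dense index.
#' @slot transforms named list of \code{c(center, scale)} pairs recorded at
#'   standardization time (\code{list_length}, \code{distance}, \code{area}).
#' @exportClass DetectionHistory
setClass("DetectionHistory",
  representation(focalSpecies = "character", visits = "data.frame",
                 siteCovariates = "data.frame", siteYears = "data.frame",
                 years = "integer", observers = "character",
                 transforms = "list"))

setValidity("DetectionHistory", function(object) {
  msg <- character()
  v <- object@visits
  if (!all(v$y %in% c(0L, 1L))) msg <- c(msg, "y must be 0 or 1")
  if (nrow(v)) {
    if (any(v$unit < 1 | v$unit > nrow(object@siteYears)))
      msg <- c(msg, "visit unit index out of range")
    if (any(v$observer < 1 | v$observer > length(object@observers)))
      msg <- c(msg, "observer index out of range")
    if (!all(v$habitat_of_observation %in% c("forest", "non_forest")))
      msg <- c(msg, "habitat_of_observation must be forest/non_forest")
    if (any(v$list_length_raw < 1))
      msg <- c(msg, "list_length must be >= 1")
    if (nrow(v) >= 2 && sd(v$list_length_std) > 0) {
      if (abs(mean(v$list_length_std)) > 1e-8 ||
          abs(sd(v$list_length_std) - 1) > 1e-8)
        msg <- c(msg, "standardized list length must have mean 0, sd 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' OccuModelSpec: one cell of the candidate model grid
#'
#' Which occupancy and detection covariates are included. Both submodels
#' always contain an intercept; \code{"observer"} enters the detection
#' submodel as a random effect, all other terms are fixed effects.
#'
#' @slot id character label.
#' @slot occupancyTerms subset of \code{year}, \code{habitat_of_site},
#'   \code{distance_to_large_forest}, \code{site_size}.
#' @slot detectionTerms subset of \code{list_length},
#'   \code{habitat_of_observation}, \code{observer}.
#' @exportClass OccuModelSpec
setClass("OccuModelSpec",
  representation(id = "character", occupancyTerms = "character",
                 detectionTerms = "character"))

setValidity("OccuModelSpec", function(object) {
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  bad <- setdiff(object@occupancyTerms, .OCC_TERMS)
  if (length(bad))
    msg <- c(msg, paste("unknown occupancy term(s):", paste(bad, collapse = ", ")))
  bad <- setdiff(object@detectionTerms, .DET_TERMS)
  if (length(bad))
    msg <- c(msg, paste("unknown detection term(s):", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' OccuPriors: prior hyperparameters of the occupancy model
#'
#' Normal priors (logit scale) on the fixed effects of both submodels and an
#' inverse-gamma prior on the observer random-effect variance.
#'
#' @slot betaMean,betaVar normal prior on occupancy fixed effects.
#' @slot alphaMean,alphaVar normal prior on detection fixed effects.
#' @slot sigmaSqObsShape,sigmaSqObsScale inverse-gamma prior on the observer
#'   random-effect variance.
#' @exportClass OccuPriors
setClass("OccuPriors",
  representation(betaMean = "numeric", betaVar = "numeric",
                 alphaMean = "numeric", alphaVar = "numeric",
                 sigmaSqObsShape = "numeric", sigmaSqObsScale = "numeric"))

setValidity("OccuPriors", function(object) {
  msg <- character()
  if (object@betaVar <= 0 || object@alphaVar <= 0)
    msg <- c(msg, "prior variances must be > 0")
  if (object@sigmaSqObsShape <= 0 || object@sigmaSqObsScale <= 0)
    msg <- c(msg, "inverse-gamma shape/scale must be > 0")
  if (length(msg)) msg else TRUE
})

#' OccuFit: posterior sample of a fitted occupancy model
#'
#' Retained MCMC draws of the occupancy coefficients, detection
#' coefficients, observer random effects and their variance, the latent
#' occupancy states, and the per-site-year marginal log-likelihood at each
#' retained draw. Rows of the draw matrices align across slots; \code{chain}
#' records the chain of each draw.
#'
#' @slot spec the fitted [OccuModelSpec-class].
#' @slot history the [DetectionHistory-class] the model was fitted to.
#' @slot beta draws x occupancy-coefficients matrix.
#' @slot alpha draws x detection-coefficients matrix.
#' @slot observerEffects draws x observers matrix (0 columns when the spec
#'   has no observer term).
#' @slot sigmaSqObs numeric vector of variance draws (length 0 when absent).
#' @slot z integer draws x site-years matrix of latent occupancy states.
#' @slot pointwiseLogLik draws x site-years matrix of marginal
#'   log-likelihood contributions (0 for site-years without visits).
#' @slot chain integer chain id per draw.
#' @slot settings list: chains, iterations, burnIn, thin, seed, priors.
#' @exportClass OccuFit
setClass("OccuFit",
  representation(spec = "OccuModelSpec", history = "DetectionHistory",
                 beta = "matrix", alpha = "matrix",
                 observerEffects = "matrix", sigmaSqObs = "numeric",
                 z = "matrix", pointwiseLogLik = "matrix",
                 chain = "integer", settings = "list"))

setValidity("OccuFit", function(object) {
  msg <- character()
  n <- nrow(object@beta)
  if (nrow(object@alpha) != n || nrow(object@z) != n ||
      nrow(object@pointwiseLogLik) != n || length(object@chain) != n)
    msg <- c(msg, "draw counts differ across slots")
  if (!all(object@z %in% c(0L, 1L)))
    msg <- c(msg, "latent z draws must be 0/1")
  if (length(msg)) msg else TRUE
})
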