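#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @rdname accessors
#' @export
setGeneric("studyYears", function(x) standardGeneric("studyYears"))

#' @rdname accessors
#' @export
setGeneric("visitTable", function(x) standardGeneric("visitTable"))

#' @rdname accessors
#' @export
setGeneric("focalSpecies", function(x) standardGeneric("focalSpecies"))

#' @rdname accessors
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' Per-year summary of a checklist dataset
#'
#' Computes, per calendar year, the number of sites with observations, the
#' total number of presence records, the mean number of visits per surveyed
#' site and the mean list length (distinct species per visit) — the annual
#' field-effort summary of a working dataset.
#'
#' @param x a [ChecklistDataset-class].
#' @return data.frame with columns \code{year}, \code{n_sites},
#'   \code{n_records}, \code{mean_visits_per_site}, \code{mean_list_length}.
#' @export
setGeneric("datasetSummary", function(x) standardGeneric("datasetSummary"))

#' Accessors for checklistOccupancy objects
#'
#' \code{records} and \code{siteTable} return the record and site tables of
#' a [ChecklistDataset-class]; \code{studyYears} its seasons.
#' \code{visitTable}, \code{focalSpecies} and \code{nDraws} access a
#' [DetectionHistory-class] or [OccuFit-class].
#'
#' @param x the object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("records", "ChecklistDataset", function(x) x@records)

#' @rdname accessors
setMethod("siteTable", "ChecklistDataset", function(x) x@sites)

#' @rdname accessors
setMethod("studyYears", "ChecklistDataset", function(x) x@years)

#' @rdname accessors
setMethod("studyYears", "DetectionHistory", function(x) x@years)

#' @rdname accessors
setMethod("visitTable", "DetectionHistory", function(x) x@visits)

#' @rdname accessors
setMethod("focalSpecies", "DetectionHistory", function(x) x@focalSpecies)

#' @rdname accessors
setMethod("nDraws", "OccuFit", function(x) nrow(x@beta))

setMethod("show", "ChecklistDataset", function(object) {
  cat("ChecklistDataset:", nrow(object@records), "records,",
      nrow(object@sites), "sites,",
      length(unique(object@records$species)), "species, years",
      paste(range(object@years), collapse = "-"), "\n")
})

setMethod("show", "DetectionHistory", function(object) {
  v <- object@visits
  cat("DetectionHistory for", sQuote(object@focalSpecies), "\n",
      nrow(v), "visits at", length(unique(v$site_id)), "sites,",
      length(object@years), "seasons,",
      length(object@observers), "observers\n",
      "detections:", sum(v$y), " non-detections:", sum(v$y == 0), "\n")
})

setMethod("show", "OccuModelSpec", function(object) {
  cat("OccuModelSpec", sQuote(object@id), "\n",
      "occupancy: ~", paste(c("1", object@occupancyTerms), collapse = " + "),
      "\n detection: ~",
      paste(c("1", object@detectionTerms), collapse = " + "), "\n")
})

setMethod("show", "OccuFit", function(object) {
  cat("OccuFit:", sQuote(object@spec@id), "for",
      sQuote(object@history@focalSpecies), "\n",
      nrow(object@beta), "retained draws over",
      length(unique(object@chain)), "chains; seed",
      object@settings$seed, "\n")
})
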