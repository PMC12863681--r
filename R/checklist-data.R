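#' Read sighting records from a delimited text file
#'
#' Parses a records file with header
#' \code{site_id,date,observer_id,species,group,count} (an optional logical
#' \code{in_forest} column records whether the observation was made in a
#' forested part of the site). Rows with an unparseable date or a
#' non-positive/non-integer count are rejected; the rejected line numbers
#' and reasons form the validation report. An unknown species-group label is
#' a hard error, as is a missing required column.
#'
#' @param path path to the records file.
#' @param sep field delimiter (default comma).
#' @param reportPath optional path; when given, the validation report is
#'   written there as plain text.
#' @return data.frame of valid records with a \code{"validation"} attribute
#'   (character vector, one entry per rejected row).
#' @export
readRecords <- function(path, sep = ",", reportPath = NULL) {
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  stringsAsFactors = FALSE)
  required <- c("site_id", "date", "observer_id", "species", "group", "count")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("records file lacks required column(s): ",
         paste(missing, collapse = ", "))
  badgrp <- setdiff(unique(raw$group), .GROUPS)
  if (length(badgrp))
    stop("unknown species group label(s): ", paste(badgrp, collapse = ", "),
         " (expected one of ", paste(.GROUPS, collapse = ", "), ")")

  date <- as.Date(raw$date, format = "%Y-%m-%d")
  count <- suppressWarnings(as.numeric(raw$count))
  ok_date <- !is.na(date)
  ok_count <- !is.na(count) & count >= 1 & count == round(count)
  report <- character()
  # +1 for the header line, so numbers refer to lines in the file
  if (any(!ok_date))
    report <- c(report, paste0("line ", which(!ok_date) + 1L,
                               ": unparseable date '",
                               raw$date[!ok_date], "'"))
  if (any(!ok_count))
    report <- c(report, paste0("line ", which(!ok_count) + 1L,
                               ": invalid count '", raw$count[!ok_count], "'"))
  keep <- ok_date & ok_count
  out <- data.frame(site_id = raw$site_id[keep], date = date[keep],
                    observer_id = raw$observer_id[keep],
                    species = raw$species[keep], group = raw$group[keep],
                    count = as.integer(count[keep]),
                    stringsAsFactors = FALSE)
  out$in_forest <- if ("in_forest" %in% names(raw)) {
    as.logical(raw$in_forest[keep])
  } else rep(NA, nrow(out))
  if (!is.null(reportPath))
    writeLines(if (length(report)) report else "all rows valid", reportPath)
  attr(out, "validation") <- report
  out
}

#' Read the site attribute table
#'
#' Parses a sites file with header
#' \code{site_id,site_type,has_forest_patch,area_ha,distance_to_large_forest_m}
#' and derives \code{habitat_of_site}: forest iff the site is a forest site
#' or a non-natural site with a forest patch.
#'
#' @param path path to the site table.
#' @param sep field delimiter.
#' @return data.frame of sites including the derived \code{habitat_of_site}.
#' @export
readSites <- function(path, sep = ",") {
  if (!file.exists(path)) stop("sites file not found: ", path)
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  required <- c("site_id", "site_type", "has_forest_patch", "area_ha",
                "distance_to_large_forest_m")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("sites file lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (!all(raw$site_type %in% c("forest", "non_natural")))
    stop("site_type must be 'forest' or 'non_natural'")
  raw$has_forest_patch <- as.logical(raw$has_forest_patch)
  raw$habitat_of_site <- ifelse(
    raw$site_type == "forest" | raw$has_forest_patch, "forest", "non_forest")
  raw
}

#' Construct a ChecklistDataset
#'
#' Bundles validated records and sites into a [ChecklistDataset-class]. The
#' closure seasons default to the calendar years spanned by the records.
#'
#' @param records data.frame as returned by [readRecords()].
#' @param sites data.frame as returned by [readSites()].
#' @param years optional integer vector of seasons (defaults to the years
#'   present in the records).
#' @return a validated [ChecklistDataset-class].
#' @export
ChecklistDataset <- function(records, sites, years = NULL) {
  if (!"in_forest" %in% names(records)) records$in_forest <- NA
  if (!"habitat_of_site" %in% names(sites))
    sites$habitat_of_site <- ifelse(
      sites$site_type == "forest" | sites$has_forest_patch,
      "forest", "non_forest")
  if (is.null(years)) {
    years <- sort(unique(as.integer(format(records$date, "%Y"))))
  }
  new("ChecklistDataset", records = records, sites = sites,
      years = as.integer(years))
}

# list length of each (site, date, observer) among a record table
.visitListLengths <- function(records) {
  key <- paste(records$site_id, records$date, records$observer_id, sep = "\r")
  ll <- tapply(records$species, key, function(s) length(unique(s)))
  as.integer(ll[key])
}

#' Deduplicate sighting records
#'
#' Collapses records of the same species on the same date and site collected
#' by different observers (these may refer to the same sighting) down to a
#' single record. The retained record is that of the observer with the
#' longest species list at that site and date; remaining ties go to the
#' lexicographically smallest observer id. Idempotent.
#'
#' @param x a [ChecklistDataset-class] or a records data.frame.
#' @return the same type of object, deduplicated.
#' @export
deduplicateRecords <- function(x) {
  if (is(x, "ChecklistDataset")) {
    out <- x
    out@records <- deduplicateRecords(x@records)
    validObject(out)
    return(out)
  }
  rec <- x
  if (!nrow(rec)) return(rec)
  ll <- .visitListLengths(rec)
  ord <- order(rec$site_id, rec$date, rec$species, -ll, rec$observer_id)
  rec <- rec[ord, , drop = FALSE]
  key <- paste(rec$site_id, rec$date, rec$species, sep = "\r")
  out <- rec[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select study species by presence-record thresholds
#'
#' Returns the species with at least \code{minPerYear} deduplicated presence
#' records in every season of the dataset and strictly more than
#' \code{minTotal} records in total — the inclusion rule that defines which
#' species carry enough data for occupancy modelling.
#'
#' @param dataset a deduplicated [ChecklistDataset-class].
#' @param minPerYear minimum records per year (default 5).
#' @param minTotal total records must exceed this (default 150).
#' @return sorted character vector of qualifying species.
#' @export
filterStudySpecies <- function(dataset, minPerYear = 5, minTotal = 150) {
  rec <- dataset@records
  if (!nrow(rec)) return(character())
  yr <- factor(as.integer(format(rec$date, "%Y")), levels = dataset@years)
  tab <- table(rec$species, yr)
  perYear <- apply(tab, 1, min)
  total <- rowSums(tab)
  sort(rownames(tab)[perYear >= minPerYear & total > minTotal])
}

#' Drop poorly surveyed sites
#'
#' \code{remove_sites_1year} drops sites whose records span exactly one
#' calendar year; \code{remove_sites_2024} drops sites all of whose records
#' fall in the final season. Dropped sites are removed from both the records
#' and the site table used for fitting; \code{none} returns the dataset
#' unchanged. Sites without any records are untouched by either filter.
#'
#' @param dataset a deduplicated [ChecklistDataset-class].
#' @param filter one of \code{"none"}, \code{"remove_sites_1year"},
#'   \code{"remove_sites_2024"}.
#' @return the filtered [ChecklistDataset-class].
#' @export
applySiteFilter <- function(dataset,
                            filter = c("none", "remove_sites_1year",
                                       "remove_sites_2024")) {
  filter <- match.arg(filter)
  if (filter == "none") return(dataset)
  rec <- dataset@records
  yr <- as.integer(format(rec$date, "%Y"))
  span <- tapply(yr, rec$site_id, function(y) length(unique(y)))
  lastOnly <- tapply(yr, rec$site_id,
                     function(y) all(y == max(dataset@years)))
  drop <- if (filter == "remove_sites_1year") {
    names(span)[span == 1L]
  } else {
    names(lastOnly)[lastOnly]
  }
  out <- dataset
  out@records <- rec[!rec$site_id %in% drop, , drop = FALSE]
  out@sites <- dataset@sites[!dataset@sites$site_id %in% drop, , drop = FALSE]
  rownames(out@records) <- NULL
  rownames(out@sites) <- NULL
  validObject(out)
  out
}

#' @rdname datasetSummary
setMethod("datasetSummary", "ChecklistDataset", function(x) {
  rec <- x@records
  yr <- as.integer(format(rec$date, "%Y"))
  out <- lapply(x@years, function(y) {
    r <- rec[yr == y, , drop = FALSE]
    if (!nrow(r))
      return(data.frame(year = y, n_sites = 0L, n_records = 0L,
                        mean_visits_per_site = NA_real_,
                        mean_list_length = NA_real_))
    vkey <- unique(paste(r$site_id, r$date, r$observer_id, sep = "\r"))
    nv <- length(vkey)
    ll <- tapply(r$species,
                 paste(r$site_id, r$date, r$observer_id, sep = "\r"),
                 function(s) length(unique(s)))
    data.frame(year = y, n_sites = length(unique(r$site_id)),
               n_records = nrow(r),
               mean_visits_per_site = nv / length(unique(r$site_id)),
               mean_list_length = mean(ll))
  })
  do.call(rbind, out)
})
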