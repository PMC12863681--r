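#' Configuration of an end-to-end occupancy study
#'
#' One object describing a full study: the input source (a generator
#' scenario or a records/sites file pair — exactly one), the dataset
#' variants to prepare (non-detection schemes and site filters), the focal
#' species (explicit list or automatic thresholds), the candidate model
#' grid, and the sampler settings. All randomness of the study flows from
#' the single root seed.
#'
#' @param scenario name from [scenarioLibrary()] or an
#'   \code{"occuSimConfig"}; mutually exclusive with file input.
#' @param recordsPath,sitesPath input files (see [readRecords()],
#'   [readSites()]).
#' @param species character vector of focal species, or NULL to apply the
#'   inclusion thresholds.
#' @param minPerYear,minTotal inclusion thresholds when \code{species} is
#'   NULL.
#' @param schemes subset of the non-detection schemes; \code{"standard"} is
#'   always included.
#' @param siteFilters subset of the site filters; \code{"none"} is always
#'   included.
#' @param grid list of [OccuModelSpec-class]; defaults to
#'   [defaultModelGrid()].
#' @param sitePopulation passed to [assembleHistory()].
#' @param chains,iterations,burnIn,thin sampler settings.
#' @param seed root seed.
#' @return validated list of class \code{"occuStudyConfig"}.
#' @export
studyConfig <- function(scenario = NULL, recordsPath = NULL,
                        sitesPath = NULL, species = NULL, minPerYear = 5,
                        minTotal = 150, schemes = "standard",
                        siteFilters = "none", grid = NULL,
                        sitePopulation = "observed", chains = 3,
                        iterations = 60000, burnIn = 50000, thin = 10,
                        seed = 1) {
  fromFiles <- !is.null(recordsPath) || !is.null(sitesPath)
  if (is.null(scenario) == !fromFiles)
    stop("exactly one input source: a scenario or a records/sites file pair")
  if (fromFiles && (is.null(recordsPath) || is.null(sitesPath)))
    stop("file input needs both recordsPath and sitesPath")
  schemes <- union("standard", match.arg(schemes, .SCHEMES,
                                         several.ok = TRUE))
  siteFilters <- union("none", match.arg(siteFilters, .SITE_FILTERS,
                                         several.ok = TRUE))
  if (chains < 1 || iterations <= burnIn || thin < 1 || burnIn < 0)
    stop("sampler settings must be positive with iterations > burnIn")
  cfg <- list(scenario = scenario, recordsPath = recordsPath,
              sitesPath = sitesPath, species = species,
              minPerYear = minPerYear, minTotal = minTotal,
              schemes = schemes, siteFilters = siteFilters,
              grid = if (is.null(grid)) defaultModelGrid() else grid,
              sitePopulation = sitePopulation, chains = chains,
              iterations = iterations, burnIn = burnIn, thin = thin,
              seed = seed)
  class(cfg) <- "occuStudyConfig"
  cfg
}

.configHash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(cfg, f)
  unname(tools::md5sum(f))
}

#' Run a full occupancy study
#'
#' Reproduces the study design end-to-end: ingest (or simulate) and
#' deduplicate the records, prepare every requested dataset variant
#' (non-detection schemes and site filters), fit the candidate grid per
#' species and variant, select top models by WAIC, diagnose convergence,
#' and emit occupancy series and paired cross-variant comparison tables. A
#' manifest records the root seed, the config hash and any per-stage
#' failures; partial results are preserved. Rerunning with the same config
#' reproduces the bundle exactly.
#'
#' @param config an \code{"occuStudyConfig"} from [studyConfig()].
#' @param outDir optional directory: writes \code{waic_ladders.csv},
#'   \code{fit_reports.csv}, \code{occupancy_series.csv},
#'   \code{comparisons.csv} and \code{manifest.txt}.
#' @return list with \code{manifest}, \code{species}, \code{variants},
#'   \code{ladders}, \code{reports}, \code{occupancySeries},
#'   \code{comparisons}, \code{summaries}.
#' @export
runStudy <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "occuStudyConfig"))
  cfg <- config
  if (!is.null(cfg$scenario)) {
    simCfg <- if (inherits(cfg$scenario, "occuSimConfig")) cfg$scenario
    else scenarioLibrary()[[cfg$scenario]]
    if (is.null(simCfg)) stop("unknown scenario ", sQuote(cfg$scenario))
    dataset <- simulateChecklists(simCfg)$dataset
  } else {
    records <- readRecords(cfg$recordsPath)
    sites <- readSites(cfg$sitesPath)
    dataset <- ChecklistDataset(records, sites)
  }
  dataset <- deduplicateRecords(dataset)
  species <- if (is.null(cfg$species))
    filterStudySpecies(dataset, cfg$minPerYear, cfg$minTotal)
  else cfg$species
  if (!length(species)) stop("no species meet the inclusion thresholds")
  grpMap <- with(records(dataset),
                 setNames(group, species)[!duplicated(species)])

  variants <- rbind(
    data.frame(label = "standard", scheme = "standard",
               site_filter = "none", stringsAsFactors = FALSE),
    if (length(setdiff(cfg$schemes, "standard")))
      data.frame(label = setdiff(cfg$schemes, "standard"),
                 scheme = setdiff(cfg$schemes, "standard"),
                 site_filter = "none", stringsAsFactors = FALSE),
    if (length(setdiff(cfg$siteFilters, "none")))
      data.frame(label = setdiff(cfg$siteFilters, "none"),
                 scheme = "standard",
                 site_filter = setdiff(cfg$siteFilters, "none"),
                 stringsAsFactors = FALSE))

  ladders <- reports <- occSeries <- list()
  summaries <- list()
  failures <- character()
  for (vi in seq_len(nrow(variants))) {
    ds <- applySiteFilter(dataset, variants$site_filter[vi])
    visits <- buildVisits(ds)
    for (sp in species) {
      lab <- paste(sp, variants$label[vi], sep = "|")
      res <- tryCatch({
        vv <- restrictForScheme(visits, ds, variants$scheme[vi],
                                grpMap[[sp]])
        hist <- assembleHistory(vv, sp, ds,
                                sitePopulation = cfg$sitePopulation)
        sel <- selectTopModel(cfg$grid, hist, chains = cfg$chains,
                              iterations = cfg$iterations,
                              burnIn = cfg$burnIn, thin = cfg$thin,
                              seed = cfg$seed)
        rep <- fitReport(sel$fit)
        occ <- finiteSampleOccupancy(sel$fit)
        occ$species <- sp
        occ$dataset <- variants$label[vi]
        list(ladder = cbind(species = sp, dataset = variants$label[vi],
                            sel$ladder),
             report = rep, occ = occ, summary = historySummary(hist))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, paste0(lab, ": ", conditionMessage(res)))
        next
      }
      ladders[[lab]] <- res$ladder
      reports[[lab]] <- res$report
      occSeries[[lab]] <- res$occ
      summaries[[lab]] <- cbind(species = sp,
                                dataset = variants$label[vi],
                                res$summary)
    }
  }

  occAll <- if (length(occSeries)) do.call(rbind, occSeries) else NULL
  if (!is.null(occAll)) rownames(occAll) <- NULL
  comparisons <- NULL
  if (nrow(variants) > 1 && length(species) >= 3) {
    meanBy <- function(metric, lab) {
      vapply(species, function(sp) {
        r <- reports[[paste(sp, lab, sep = "|")]]
        if (is.null(r)) return(NA_real_)
        if (metric == "occupancy") unname(r$mean_psi["mean"])
        else unname(r$detection_baseline["mean"])
      }, numeric(1))
    }
    rows <- list()
    for (lab in variants$label[-1]) {
      for (metric in c("occupancy", "detection")) {
        a <- meanBy(metric, "standard")
        b <- meanBy(metric, lab)
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) >= 3) {
          cmp <- compareDatasets(a[ok], b[ok])
          rows[[paste(lab, metric)]] <- data.frame(
            dataset = lab, metric = metric, t = cmp$t, p_t = cmp$p_t,
            r = cmp$r, p_r = cmp$p_r, n = cmp$n,
            stringsAsFactors = FALSE)
        }
      }
    }
    comparisons <- do.call(rbind, rows)
    if (!is.null(comparisons)) rownames(comparisons) <- NULL
  }

  manifest <- c(
    paste0("package: checklistOccupancy ",
           as.character(utils::packageVersion("checklistOccupancy"))),
    paste0("seed: ", cfg$seed),
    paste0("config_hash: ", .configHash(cfg)),
    paste0("species: ", paste(species, collapse = ", ")),
    paste0("variants: ", paste(variants$label, collapse = ", ")),
    paste0("failures: ", if (length(failures))
      paste(failures, collapse = "; ") else "none"))

  bindRows <- function(x) if (length(x))
    do.call(rbind, c(x, make.row.names = FALSE)) else NULL
  bundle <- list(manifest = manifest, species = species,
                 variants = variants, ladders = bindRows(ladders),
                 reports = reports, occupancySeries = occAll,
                 comparisons = comparisons,
                 summaries = bindRows(summaries))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(bundle$ladders, file.path(outDir, "waic_ladders.csv"),
              row.names = FALSE)
    coefTab <- do.call(rbind, lapply(names(reports), function(lab) {
      cbind(label = lab, reports[[lab]]$coefficients)
    }))
    write.csv(coefTab, file.path(outDir, "fit_reports.csv"),
              row.names = FALSE)
    write.csv(bundle$occupancySeries,
              file.path(outDir, "occupancy_series.csv"),
              row.names = FALSE)
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(outDir, "comparisons.csv"),
                row.names = FALSE)
    writeLines(manifest, file.path(outDir, "manifest.txt"))
  }
  bundle
}
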