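test_that("readRecords parses valid files and rejects malformed rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,date,observer_id,species,group,count",
               "A,2020-03-01,o1,sp1,bird,1",
               "A,2020-03-02,o1,sp2,mammal,2",
               "B,2020-04-01,o2,sp1,bird,1"), f)
  rec <- readRecords(f)
  expect_equal(nrow(rec), 3L)
  expect_s3_class(rec$date, "Date")
  expect_length(attr(rec, "validation"), 0L)

  # header-only file -> empty collection
  writeLines("site_id,date,observer_id,species,group,count", f)
  expect_equal(nrow(readRecords(f)), 0L)

  # malformed date and count are rejected with line numbers
  writeLines(c("site_id,date,observer_id,species,group,count",
               "A,2020-03-01,o1,sp1,bird,1",
               "A,not-a-date,o1,sp2,mammal,1",
               "B,2020-04-01,o2,sp1,bird,0"), f)
  rep <- withr::local_tempfile()
  rec <- readRecords(f, reportPath = rep)
  expect_equal(nrow(rec), 1L)
  val <- attr(rec, "validation")
  expect_length(val, 2L)
  expect_match(val[1], "line 3")
  expect_match(val[2], "line 4")
  expect_true(file.exists(rep))
})

test_that("readRecords hard errors name the offending column or group", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,date,observer_id,species,count",
               "A,2020-03-01,o1,sp1,1"), f)
  expect_error(readRecords(f), "group")
  writeLines(c("site_id,date,observer_id,species,group,count",
               "A,2020-03-01,o1,sp1,fungus,1"), f)
  expect_error(readRecords(f), "fungus")
})

test_that("readSites derives habitat_of_site from type and patch flag", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,site_type,has_forest_patch,area_ha,distance_to_large_forest_m",
               "A,forest,FALSE,120,0",
               "B,non_natural,TRUE,30,800",
               "C,non_natural,FALSE,25,1500"), f)
  s <- readSites(f)
  expect_equal(s$habitat_of_site, c("forest", "forest", "non_forest"))
  writeLines(c("site_id,site_type,has_forest_patch,area_ha,distance_to_large_forest_m",
               "A,meadow,FALSE,120,0"), f)
  expect_error(readSites(f), "site_type")
})

test_that("deduplication keeps one record per species-date-site with the documented tie-break", {
  rec <- tinyRecords()
  # A/2020-03-01: o1 reported sp1+sp2 (list length 2), o2 only sp1
  out <- deduplicateRecords(rec)
  expect_equal(nrow(out), 5L)
  kept <- out[out$site_id == "A" & out$species == "sp1", ]
  expect_equal(kept$observer_id, "o1")  # longer list wins

  # pure tie on list length: lexicographically smallest observer wins
  tie <- data.frame(site_id = "A", date = as.Date("2020-03-01"),
                    observer_id = c("oB", "oA"), species = "sp1",
                    group = "bird", count = c(5L, 2L),
                    stringsAsFactors = FALSE)
  keptTie <- deduplicateRecords(tie)
  expect_equal(keptTie$observer_id, "oA")
  expect_equal(keptTie$count, 2L)  # all fields of the retained record

  # different dates are different sightings
  two <- tie
  two$date <- as.Date(c("2020-03-01", "2020-03-02"))
  expect_equal(nrow(deduplicateRecords(two)), 2L)

  # idempotence and empty input
  expect_identical(deduplicateRecords(out), out)
  expect_equal(nrow(deduplicateRecords(rec[0, ])), 0L)
})

test_that("study-species filter applies both thresholds over deduplicated records", {
  years <- 2020:2024
  mk <- function(sp, perYear) {
    do.call(rbind, lapply(seq_along(years), function(t) {
      n <- perYear[t]
      if (n == 0) return(NULL)
      data.frame(site_id = "A", date = as.Date(sprintf("%d-01-01", years[t])) +
                   seq_len(n) - 1,
                 observer_id = "o1", species = sp, group = "bird",
                 count = 1L, stringsAsFactors = FALSE)
    }))
  }
  rec <- rbind(mk("meets_both", c(31, 30, 30, 30, 30)),     # total 151 > 150
               mk("low_total", c(5, 5, 5, 5, 5)),           # total 25
               mk("one_bad_year", c(100, 100, 100, 100, 4)),
               mk("exactly_150", c(30, 30, 30, 30, 30)))    # total 150, not >150
  ds <- ChecklistDataset(rec, tinySites("A"), years)
  expect_equal(filterStudySpecies(ds), "meets_both")
  # zero thresholds return every species with at least one record
  expect_setequal(filterStudySpecies(ds, 0, 0),
                  unique(rec$species))
})

test_that("site filters drop the specified sites from records and site table", {
  rec <- data.frame(
    site_id = c("A", "A", "B", "C"),
    date = as.Date(c("2021-05-01", "2024-06-01", "2021-03-01",
                     "2024-02-01")),
    observer_id = "o1", species = "sp1", group = "bird", count = 1L,
    stringsAsFactors = FALSE)
  ds <- ChecklistDataset(rec, tinySites(c("A", "B", "C", "D")), 2020:2024)

  expect_identical(applySiteFilter(ds, "none"), ds)

  one <- applySiteFilter(ds, "remove_sites_1year")
  expect_setequal(unique(one@records$site_id), "A")   # B and C span one year
  expect_setequal(one@sites$site_id, c("A", "D"))     # unsurveyed D untouched

  last <- applySiteFilter(ds, "remove_sites_2024")
  expect_setequal(unique(last@records$site_id), c("A", "B"))  # A spans 2021+2024
  expect_false("C" %in% last@sites$site_id)

  # filters never add; record counts non-increasing
  expect_lte(nrow(one@records), nrow(ds@records))
  expect_lte(nrow(last@records), nrow(ds@records))
})

test_that("dataset summary reports per-year effort in the expected format", {
  ds <- tinyDataset()
  s <- datasetSummary(ds)
  expect_named(s, c("year", "n_sites", "n_records",
                    "mean_visits_per_site", "mean_list_length"))
  expect_equal(s$year, 2020:2021)
  r2020 <- s[s$year == 2020, ]
  expect_equal(r2020$n_sites, 3L)
  expect_equal(r2020$n_records, 5L)
  # 2020 visits: A(o1), A(o2), B(o1), C(o3) over 3 sites
  expect_equal(r2020$mean_visits_per_site, 4 / 3)
  # list lengths 2, 1, 1, 1
  expect_equal(r2020$mean_list_length, 1.25)
})

test_that("dataset validity catches inconsistent inputs", {
  rec <- tinyRecords()
  sites <- tinySites()
  expect_error(ChecklistDataset(rec, sites[1:2, ], 2020:2021),
               "unknown sites")
  bad <- rec
  bad$count[1] <- 0L
  expect_error(ChecklistDataset(bad, sites, 2020:2021), "count")
})
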