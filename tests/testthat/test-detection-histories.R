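test_that("visits are unique site-date-observer checklists with list lengths", {
  ds <- tinyDataset()
  v <- buildVisits(ds)
  # A/2020-03-01 has two observers -> two distinct visits
  expect_equal(nrow(v), 5L)
  a1 <- v[v$site_id == "A" & v$observer_id == "o1" &
            v$date == as.Date("2020-03-01"), ]
  expect_equal(a1$list_length, 2L)
  expect_setequal(a1$species[[1]], c("sp1", "sp2"))
  # default habitat of observation follows the site type
  expect_equal(unique(v$habitat_of_observation[v$site_id == "A"]), "forest")
  expect_equal(unique(v$habitat_of_observation[v$site_id == "B"]),
               "non_forest")
  expect_equal(mean(v$list_length), (2 + 1 + 1 + 1 + 1) / 5)
})

test_that("record-level in_forest flags override the default and are sanity-checked", {
  rec <- tinyRecords()
  rec$in_forest <- c(NA, NA, NA, TRUE, FALSE, FALSE)
  ds <- ChecklistDataset(rec, tinySites(), 2020:2021)
  # B is non_natural without patch: forest observation there is inconsistent
  expect_warning(v <- buildVisits(ds), "coerced")
  expect_equal(v$habitat_of_observation[v$site_id == "B" & v$year == 2020],
               "non_forest")
})

test_that("non-detection schemes restrict visits exactly as documented", {
  cfg <- smallConfig(seed = 31, nObservers = 25,
                     observerSpecialization = list(
                       list(groups = c("bird", "mammal", "reptile",
                                       "plant", "insect"), weight = 0.4),
                       list(groups = "plant", weight = 0.3),
                       list(groups = c("bird", "mammal"), weight = 0.3)))
  sim <- simulateChecklists(cfg)
  ds <- deduplicateRecords(sim$dataset)
  v <- buildVisits(ds)

  expect_identical(restrictForScheme(v, ds, "standard", "reptile"), v)
  expect_error(restrictForScheme(v, ds, "nondet3grp", "plant"),
               "birds, mammals and reptiles")

  v3 <- restrictForScheme(v, ds, "nondet3grp", "reptile")
  # plant/insect species removed everywhere; empty visits vanish
  expect_true(all(vapply(v3$species, function(s)
    !any(grepl("^(plant|insect)", s)), logical(1))))
  expect_true(all(v3$list_length >= 1))
  expect_lte(nrow(v3), nrow(v))

  v1g <- restrictForScheme(v, ds, "nondet3grp_obs1grp", "reptile")
  rec <- records(ds)
  reptileObs <- unique(rec$observer_id[rec$group == "reptile"])
  expect_true(all(v1g$observer_id %in% reptileObs))

  v3g <- restrictForScheme(v, ds, "nondet3grp_obs3grp", "reptile")
  threeGrpObs <- names(which(tapply(rec$group, rec$observer_id, function(g)
    all(c("bird", "mammal", "reptile") %in% g))))
  expect_true(all(v3g$observer_id %in% threeGrpObs))
  # monotone visit removal across scheme strictness
  expect_lte(nrow(v1g), nrow(v3))
  expect_lte(nrow(v3g), nrow(v1g))
})

test_that("scheme restriction only removes visits, never flips surviving detections", {
  out <- simHistory(smallConfig(seed = 32))
  ds <- out$dataset
  focal <- out$truth$config$focalSpecies
  v <- buildVisits(ds)
  key <- function(h) with(visitTable(h),
                          paste(site_id, year, observer_id, visit_index))
  hStd <- assembleHistory(v, focal, ds)
  detStd <- with(visitTable(hStd), paste(site_id, year, observer_id))[
    visitTable(hStd)$y == 1]
  nonDet <- Inf
  for (sch in c("nondet3grp", "nondet3grp_obs1grp", "nondet3grp_obs3grp")) {
    vr <- restrictForScheme(v, ds, sch, out$truth$config$focalGroup)
    h <- assembleHistory(vr, focal, ds)
    det <- with(visitTable(h), paste(site_id, year, observer_id))[
      visitTable(h)$y == 1]
    expect_true(all(det %in% detStd))
    nnd <- sum(visitTable(h)$y == 0)
    expect_lte(nnd, min(nonDet, sum(visitTable(hStd)$y == 0)))
    nonDet <- nnd
  }
  # standard-scheme restriction is the identity on assembled histories
  expect_identical(
    assembleHistory(restrictForScheme(v, ds, "standard", "reptile"),
                    focal, ds),
    hStd)
})

test_that("standardization is exact, idempotent and errors on constants", {
  z <- standardizeCovariate(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_equal(attr(z, "center"), 2)
  expect_equal(attr(z, "scale"), 1)
  again <- standardizeCovariate(as.numeric(z))
  expect_equal(as.numeric(again), as.numeric(z), tolerance = 1e-12)
  expect_error(standardizeCovariate(c(5, 5, 5)), "constant")
  expect_error(standardizeCovariate(3), "at least 2")
})

test_that("assembled histories have correct y, units, indices and transforms", {
  out <- simHistory(smallConfig(seed = 33))
  h <- out$history
  v <- visitTable(h)
  # y marks exactly the visits whose checklist contains the focal species
  rec <- records(out$dataset)
  focalKey <- unique(with(rec[rec$species == h@focalSpecies, ],
                          paste(site_id, format(date, "%Y"), observer_id)))
  expect_setequal(with(v[v$y == 1, ], paste(site_id, year, observer_id)),
                  focalKey)
  # unit grid covers every fitted site x year even without visits
  expect_equal(nrow(h@siteYears),
               length(unique(v$site_id)) * length(h@years))
  expect_true(length(setdiff(h@siteYears$unit, v$unit)) > 0)
  # dense observer indices round-trip to ids
  expect_identical(h@observers[v$observer], v$observer_id)
  # standardized columns carry their transforms
  expect_equal(mean(v$list_length_std), 0, tolerance = 1e-10)
  expect_equal(sd(v$list_length_std), 1, tolerance = 1e-10)
  expect_equal(v$list_length_raw,
               as.integer(round(v$list_length_std *
                                  h@transforms$list_length["scale"] +
                                  h@transforms$list_length["center"])))
  expect_error(assembleHistory(buildVisits(out$dataset), "no_such_species",
                               out$dataset), "absent")
})

test_that("history serialization round-trips losslessly", {
  out <- simHistory(smallConfig(seed = 34, nSites = 40))
  h <- out$history
  vf <- withr::local_tempfile(fileext = ".csv")
  sf <- withr::local_tempfile(fileext = ".csv")
  writeHistory(h, vf, sf)
  h2 <- readHistory(vf, sf, focalSpecies(h), studyYears(h))
  expect_equal(h2, h)
})
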