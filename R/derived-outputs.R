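#' Per-draw annual finite-sample occupancy
#'
#' For each retained draw and season, the realized proportion of occupied
#' sites: the latent states summed over the sites of the fitted statistical
#' population and divided by the number of sites (constant across years).
#'
#' @param fit an [OccuFit-class].
#' @return draws x years matrix of occupancy proportions.
#' @export
annualOccupancyDraws <- function(fit) {
  sy <- fit@history@siteYears
  years <- fit@history@years
  out <- sapply(years, function(y)
    rowMeans(fit@z[, sy$year == y, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- years
  out
}

#' Annual finite-sample occupancy series
#'
#' Posterior mean and sd (the reported "se") of the finite-sample occupancy
#' per season, obtained by summing the latent z over sites within each year.
#'
#' @param fit an [OccuFit-class].
#' @return data.frame with columns \code{year}, \code{occupancy_mean},
#'   \code{occupancy_sd}.
#' @export
finiteSampleOccupancy <- function(fit) {
  if (!nrow(fit@z)) stop("fit contains no draws")
  occ <- annualOccupancyDraws(fit)
  data.frame(year = fit@history@years,
             occupancy_mean = colMeans(occ),
             occupancy_sd = apply(occ, 2, sd),
             row.names = NULL)
}

#' Baseline detection probability
#'
#' The back-transformed detection intercept: detection probability of a
#' single visit by an average observer (random effect 0) with a species
#' list of mean length outside forest habitat, i.e. all detection
#' covariates at their baseline. Returns the posterior mean and sd.
#'
#' @param fit an [OccuFit-class].
#' @return named numeric vector \code{c(mean, sd)}.
#' @export
detectionAtBaseline <- function(fit) {
  p <- plogis(.clip(fit@alpha[, 1]))
  c(mean = mean(p), sd = sd(p))
}

#' Posterior response curve of a covariate
#'
#' Posterior mean and equal-tailed 95% band of the occupancy or detection
#' probability over a natural-scale grid of one covariate, all other
#' covariates held at their baseline (first season, non-forest, mean
#' distance/area/list length, average observer).
#'
#' @param fit an [OccuFit-class].
#' @param covariate a covariate of the fitted spec (e.g.
#'   \code{"list_length"}, \code{"distance_to_large_forest"}).
#' @param grid numeric (or character, for habitat terms) vector of
#'   natural-scale covariate values.
#' @return data.frame with columns \code{value}, \code{mean}, \code{lower},
#'   \code{upper}.
#' @export
responseCurve <- function(fit, covariate, grid) {
  tr <- fit@history@transforms
  occTerms <- fit@spec@occupancyTerms
  detTerms <- setdiff(fit@spec@detectionTerms, "observer")
  if (covariate %in% occTerms) submodel <- "occupancy"
  else if (covariate %in% detTerms) submodel <- "detection"
  else stop("covariate ", sQuote(covariate), " not in the fitted spec")
  baseline <- list(
    year = fit@history@years[1], habitat_of_site = "non_forest",
    distance_to_large_forest = unname(tr$distance["center"]),
    site_size = unname(tr$area["center"]),
    list_length = unname(tr$list_length["center"]),
    habitat_of_observation = "non_forest")
  terms <- if (submodel == "occupancy") occTerms else detTerms
  newdata <- as.data.frame(baseline[terms], optional = TRUE)
  newdata <- newdata[rep(1, length(grid)), , drop = FALSE]
  names(newdata) <- terms
  newdata[[covariate]] <- grid
  pr <- predictLinear(fit, newdata, submodel)
  data.frame(value = grid, mean = colMeans(pr),
             lower = apply(pr, 2, quantile, 0.025),
             upper = apply(pr, 2, quantile, 0.975), row.names = NULL)
}

#' Paired comparison of per-species estimates between two dataset variants
#'
#' Two-sided paired Student t-test on the differences (b - a) and Pearson
#' correlation between the paired values, as used to compare mean detection
#' or occupancy across species between a standard and an alternative
#' dataset. With zero variance of the differences the t statistic is not
#' assessable and reported as NA.
#'
#' @param estimatesA,estimatesB equal-length numeric vectors, one value per
#'   species (n >= 3).
#' @return list with \code{t}, \code{p_t}, \code{n}, \code{r}, \code{p_r}.
#' @export
compareDatasets <- function(estimatesA, estimatesB) {
  if (length(estimatesA) != length(estimatesB))
    stop("paired vectors differ in length")
  n <- length(estimatesA)
  if (n < 3L) stop("need at least 3 pairs")
  d <- estimatesB - estimatesA
  tt <- if (sd(d) == 0) {
    # identical vectors: no difference at all (t = 0); a constant non-zero
    # shift has zero-variance differences and is not assessable
    if (all(d == 0)) list(statistic = 0, p.value = 1)
    else list(statistic = NA_real_, p.value = NA_real_)
  } else t.test(estimatesB, estimatesA, paired = TRUE)
  ct <- tryCatch(cor.test(estimatesA, estimatesB),
                 error = function(e) list(estimate = NA_real_,
                                          p.value = NA_real_))
  list(t = unname(tt$statistic), p_t = tt$p.value, n = n,
       r = unname(ct$estimate), p_r = ct$p.value)
}
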