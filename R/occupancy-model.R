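#' Define an occupancy model specification
#'
#' One cell of the candidate grid: which covariates enter the occupancy and
#' detection submodels. Both submodels always contain an intercept; year
#' enters occupancy as categorical fixed effects (reference = first season);
#' \code{"observer"} enters detection as a zero-mean random effect. The
#' detection submodel carries no year effects.
#'
#' @param id character label.
#' @param occupancyTerms subset of \code{"year"}, \code{"habitat_of_site"},
#'   \code{"distance_to_large_forest"}, \code{"site_size"}.
#' @param detectionTerms subset of \code{"list_length"},
#'   \code{"habitat_of_observation"}, \code{"observer"}.
#' @return an [OccuModelSpec-class].
#' @export
occuModelSpec <- function(id, occupancyTerms = character(),
                          detectionTerms = character()) {
  new("OccuModelSpec", id = as.character(id),
      occupancyTerms = as.character(occupancyTerms),
      detectionTerms = as.character(detectionTerms))
}

#' Prior hyperparameters for the occupancy model
#'
#' Defaults follow the conventional weakly informative choice for Bayesian
#' logistic occupancy models: Normal(0, 2.72) on all fixed effects (logit
#' scale) and inverse-Gamma(0.1, 0.1) on the observer random-effect
#' variance.
#'
#' @param betaMean,betaVar normal prior on occupancy fixed effects.
#' @param alphaMean,alphaVar normal prior on detection fixed effects.
#' @param sigmaSqObsShape,sigmaSqObsScale inverse-gamma prior on the
#'   observer-effect variance.
#' @return an [OccuPriors-class].
#' @export
occuPriors <- function(betaMean = 0, betaVar = 2.72, alphaMean = 0,
                       alphaVar = 2.72, sigmaSqObsShape = 0.1,
                       sigmaSqObsScale = 0.1) {
  new("OccuPriors", betaMean = betaMean, betaVar = betaVar,
      alphaMean = alphaMean, alphaVar = alphaVar,
      sigmaSqObsShape = sigmaSqObsShape, sigmaSqObsScale = sigmaSqObsScale)
}

#' Design matrices of a model spec on a detection history
#'
#' Expands an [OccuModelSpec-class] into the occupancy design matrix X (one
#' row per site-year unit) and the detection design matrix W (one row per
#' visit), both on the standardized covariate scale, plus the visit-level
#' observer index (NULL when the spec has no observer term). Coefficient
#' vectors passed to [marginalLogLik()] follow the column order of these
#' matrices.
#'
#' @param spec an [OccuModelSpec-class].
#' @param history a [DetectionHistory-class].
#' @return list with elements \code{X}, \code{W}, \code{observerIndex}.
#' @export
designMatrices <- function(spec, history) {
  sy <- history@siteYears
  sc <- history@siteCovariates
  v <- history@visits
  X <- matrix(1, nrow(sy), 1, dimnames = list(NULL, "(Intercept)"))
  if ("year" %in% spec@occupancyTerms && length(history@years) > 1L) {
    yf <- factor(sy$year, levels = history@years)
    dummies <- stats::model.matrix(~yf)[, -1, drop = FALSE]
    colnames(dummies) <- paste0("year", history@years[-1])
    X <- cbind(X, dummies)
  }
  idx <- match(sy$site_id, sc$site_id)
  if ("habitat_of_site" %in% spec@occupancyTerms)
    X <- cbind(X, habitat_of_site =
                 as.numeric(sc$habitat_of_site[idx] == "forest"))
  if ("distance_to_large_forest" %in% spec@occupancyTerms)
    X <- cbind(X, distance_to_large_forest = sc$distance_std[idx])
  if ("site_size" %in% spec@occupancyTerms)
    X <- cbind(X, site_size = sc$area_std[idx])

  W <- matrix(1, nrow(v), 1, dimnames = list(NULL, "(Intercept)"))
  if ("list_length" %in% spec@detectionTerms)
    W <- cbind(W, list_length = v$list_length_std)
  if ("habitat_of_observation" %in% spec@detectionTerms)
    W <- cbind(W, habitat_of_observation =
                 as.numeric(v$habitat_of_observation == "forest"))
  obsIdx <- if ("observer" %in% spec@detectionTerms) v$observer else NULL
  list(X = X, W = W, observerIndex = obsIdx)
}

.clip <- function(x) pmin(pmax(x, -.LOGIT_CLIP), .LOGIT_CLIP)

#' Marginal per-site-year log-likelihood
#'
#' The occupancy likelihood with the latent state integrated out. For a
#' site-year with at least one detection the contribution is
#' \eqn{\log\psi + \sum_j [y \log p + (1-y)\log(1-p)]}; with an all-zero
#' history it is \eqn{\log(\psi \prod_j (1-p_j) + 1 - \psi)}; a site-year
#' without visits contributes 0. The total log-likelihood is the sum over
#' units.
#'
#' @param spec an [OccuModelSpec-class].
#' @param params list with \code{beta} (occupancy coefficients in
#'   [designMatrices()] column order), \code{alpha} (detection
#'   coefficients), and optionally \code{observerEffects} (one value per
#'   dense observer index; defaults to 0).
#' @param history a [DetectionHistory-class].
#' @return numeric vector, one value per site-year unit.
#' @export
marginalLogLik <- function(spec, params, history) {
  d <- designMatrices(spec, history)
  beta <- params$beta
  alpha <- params$alpha
  if (length(beta) != ncol(d$X))
    stop("beta has length ", length(beta), ", expected ", ncol(d$X))
  if (length(alpha) != ncol(d$W))
    stop("alpha has length ", length(alpha), ", expected ", ncol(d$W))
  if (!all(is.finite(d$X)) || !all(is.finite(d$W)))
    stop("non-finite covariate in design")
  eta <- rep(0, length(history@observers))
  if (!is.null(params$observerEffects) && !is.null(d$observerIndex))
    eta <- params$observerEffects
  occLp <- .clip(drop(d$X %*% beta))
  detLp <- drop(d$W %*% alpha)
  if (!is.null(d$observerIndex)) detLp <- detLp + eta[d$observerIndex]
  detLp <- .clip(detLp)
  v <- history@visits
  lpsi <- -log1p(exp(-occLp))
  l1mpsi <- -log1p(exp(occLp))
  logp <- -log1p(exp(-detLp))
  log1mp <- -log1p(exp(detLp))

  U <- nrow(history@siteYears)
  uf <- factor(v$unit, levels = seq_len(U))
  condSum <- vapply(split(ifelse(v$y == 1L, logp, log1mp), uf), sum,
                    numeric(1))
  logq <- vapply(split(log1mp, uf), sum, numeric(1))
  nVisits <- tabulate(v$unit, nbins = U)
  detected <- tabulate(v$unit[v$y == 1L], nbins = U) > 0

  out <- numeric(U)
  out[detected] <- lpsi[detected] + condSum[detected]
  idx <- !detected & nVisits > 0
  a <- lpsi[idx] + logq[idx]
  b <- l1mpsi[idx]
  m <- pmax(a, b)
  out[idx] <- m + log(exp(a - m) + exp(b - m))
  out
}

#' Fit the occupancy model by Gibbs sampling
#'
#' Samples the joint posterior of the occupancy coefficients, detection
#' coefficients, observer random effects and their variance, and the latent
#' occupancy states, using Polya-Gamma data augmentation for both logistic
#' submodels, conditional Bernoulli updates for the latent state at
#' undetected site-years, and a conjugate inverse-gamma update for the
#' observer-effect variance. The latent state is sampled (not marginalized)
#' so finite-sample occupancy is available. Per-site-year marginal
#' log-likelihoods are stored at every retained draw. A fixed seed gives
#' bit-identical draws.
#'
#' @param spec an [OccuModelSpec-class].
#' @param history a [DetectionHistory-class] with at least one detection and
#'   one non-detection.
#' @param priors an [OccuPriors-class].
#' @param chains number of (sequential) chains.
#' @param iterations iterations per chain.
#' @param burnIn discarded initial iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed for all randomness of the fit.
#' @return an [OccuFit-class] with \code{chains * (iterations - burnIn) /
#'   thin} retained draws.
#' @export
sampleOccupancy <- function(spec, history, priors = occuPriors(),
                            chains = 3, iterations = 60000,
                            burnIn = 50000, thin = 10, seed = 1) {
  stopifnot(is(spec, "OccuModelSpec"), is(history, "DetectionHistory"))
  if (thin < 1 || burnIn < 0 || iterations <= burnIn)
    stop("need iterations > burnIn, burnIn >= 0 and thin >= 1")
  v <- history@visits
  if (all(v$y == 1L))
    stop("every visit detects the species: no non-detections; ",
         "the species fails the inclusion criteria for occupancy modelling")
  if (all(v$y == 0L))
    stop("the species is never detected; ",
         "it fails the inclusion criteria for occupancy modelling")
  d <- designMatrices(spec, history)
  ord <- order(v$unit, v$visit_index)
  U <- nrow(history@siteYears)
  nVis <- tabulate(v$unit, nbins = U)
  visStart <- cumsum(c(0L, nVis[-U]))  # 0-based, contiguous by unit
  hasObs <- !is.null(d$observerIndex)
  nObserver <- if (hasObs) length(history@observers) else 0L

  perChain <- (iterations - burnIn) %/% thin
  set.seed(seed)
  res <- vector("list", chains)
  for (ch in seq_len(chains)) {
    res[[ch]] <- .occu_gibbs_cpp(
      d$X, d$W[ord, , drop = FALSE], as.integer(visStart),
      as.integer(nVis), as.integer(v$y[ord]),
      as.integer(if (hasObs) d$observerIndex[ord] - 1L else
        rep(-1L, nrow(v))),
      as.integer(nObserver), as.integer(iterations), as.integer(burnIn),
      as.integer(thin), priors@betaVar, priors@alphaVar,
      priors@sigmaSqObsShape, priors@sigmaSqObsScale, .LOGIT_CLIP)
  }
  bind <- function(name) do.call(rbind, lapply(res, `[[`, name))
  beta <- bind("beta"); colnames(beta) <- colnames(d$X)
  alpha <- bind("alpha"); colnames(alpha) <- colnames(d$W)
  eta <- bind("eta")
  if (hasObs) colnames(eta) <- history@observers
  zmat <- bind("z")
  storage.mode(zmat) <- "integer"
  fit <- new("OccuFit", spec = spec, history = history, beta = beta,
             alpha = alpha, observerEffects = eta,
             sigmaSqObs = if (hasObs) as.numeric(unlist(
               lapply(res, `[[`, "sigma_sq_obs"))) else numeric(0),
             z = zmat, pointwiseLogLik = bind("loglik"),
             chain = rep(seq_len(chains), each = perChain),
             settings = list(chains = chains, iterations = iterations,
                             burnIn = burnIn, thin = thin, seed = seed,
                             priors = priors))
  validObject(fit)
  fit
}

#' Posterior predicted probabilities at new covariate values
#'
#' Inverse-logit of the linear predictor at each retained draw, with the
#' observer random effect set to 0 (the "average observer"). Covariates are
#' supplied on the natural scale; the transforms recorded at
#' standardization time are applied internally.
#'
#' @param fit an [OccuFit-class].
#' @param newdata data.frame of covariate values on the natural scale. For
#'   \code{submodel = "occupancy"}: \code{year}, \code{habitat_of_site}
#'   (\code{"forest"}/\code{"non_forest"}), \code{distance_to_large_forest}
#'   (m), \code{site_size} (ha) — exactly the terms of the fitted spec. For
#'   \code{"detection"}: \code{list_length}, \code{habitat_of_observation}.
#' @param submodel \code{"occupancy"} or \code{"detection"}.
#' @return draws x rows matrix of probabilities.
#' @export
predictLinear <- function(fit, newdata, submodel = c("occupancy",
                                                     "detection")) {
  submodel <- match.arg(submodel)
  spec <- fit@spec
  tr <- fit@history@transforms
  n <- nrow(newdata)
  if (submodel == "occupancy") {
    terms <- spec@occupancyTerms
    extra <- setdiff(names(newdata), c("year", "habitat_of_site",
                                       "distance_to_large_forest",
                                       "site_size"))
    if (length(extra)) stop("unknown covariate(s): ",
                            paste(extra, collapse = ", "))
    miss <- setdiff(terms, names(newdata))
    if (length(miss)) stop("newdata lacks fitted covariate(s): ",
                           paste(miss, collapse = ", "))
    off <- setdiff(names(newdata), terms)
    if (length(off)) stop("covariate(s) absent from the fitted spec: ",
                          paste(off, collapse = ", "))
    M <- matrix(1, n, 1)
    if ("year" %in% terms && length(fit@history@years) > 1L) {
      yf <- factor(newdata$year, levels = fit@history@years)
      if (anyNA(yf)) stop("year outside the fitted seasons")
      M <- cbind(M, stats::model.matrix(~yf)[, -1, drop = FALSE])
    }
    if ("habitat_of_site" %in% terms)
      M <- cbind(M, as.numeric(newdata$habitat_of_site == "forest"))
    if ("distance_to_large_forest" %in% terms)
      M <- cbind(M, (newdata$distance_to_large_forest -
                       tr$distance["center"]) / tr$distance["scale"])
    if ("site_size" %in% terms)
      M <- cbind(M, (newdata$site_size - tr$area["center"]) /
                   tr$area["scale"])
    draws <- fit@beta
  } else {
    terms <- setdiff(spec@detectionTerms, "observer")
    extra <- setdiff(names(newdata), c("list_length",
                                       "habitat_of_observation"))
    if (length(extra)) stop("unknown covariate(s): ",
                            paste(extra, collapse = ", "))
    miss <- setdiff(terms, names(newdata))
    if (length(miss)) stop("newdata lacks fitted covariate(s): ",
                           paste(miss, collapse = ", "))
    off <- setdiff(names(newdata), terms)
    if (length(off)) stop("covariate(s) absent from the fitted spec: ",
                          paste(off, collapse = ", "))
    M <- matrix(1, n, 1)
    if ("list_length" %in% terms)
      M <- cbind(M, (newdata$list_length - tr$list_length["center"]) /
                   tr$list_length["scale"])
    if ("habitat_of_observation" %in% terms)
      M <- cbind(M, as.numeric(newdata$habitat_of_observation == "forest"))
    draws <- fit@alpha
  }
  if (ncol(M) != ncol(draws))
    stop("design/coefficient dimension mismatch")
  plogis(.clip(draws %*% t(M)))
}
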