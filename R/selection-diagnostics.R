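#' Widely Applicable Information Criterion
#'
#' WAIC from pointwise posterior log-likelihoods:
#' \eqn{-2\sum_u[\mathrm{lppd}_u - p_u]} with
#' \eqn{\mathrm{lppd}_u = \log \frac{1}{D}\sum_d e^{\ell_{ud}}} (computed
#' with log-sum-exp stabilization) and penalty
#' \eqn{p_u = \mathrm{Var}_d(\ell_{ud})}. Lower is better. For an
#' [OccuFit-class] the units are the site-years with at least one visit.
#'
#' @param x draws x units matrix of log-likelihoods, or an [OccuFit-class].
#' @return list with \code{waic}, \code{lppd}, \code{penalty}.
#' @export
waic <- function(x) {
  if (is(x, "OccuFit")) {
    nVis <- tabulate(x@history@visits$unit, nbins = nrow(x@history@siteYears))
    x <- x@pointwiseLogLik[, nVis > 0, drop = FALSE]
  }
  if (nrow(x) < 2L) stop("need at least 2 draws")
  if (!all(is.finite(x))) stop("non-finite log-likelihood")
  m <- apply(x, 2, max)
  lppd <- sum(m + log(colMeans(exp(sweep(x, 2, m)))))
  penalty <- sum(apply(x, 2, var))
  list(waic = -2 * (lppd - penalty), lppd = lppd, penalty = penalty)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic Rhat from between- and within-chain variances. When every chain
#' has zero within-chain variance the statistic is not assessable and
#' \code{NA} is returned (a frozen sampler is not evidence of convergence).
#'
#' @param x numeric vector of draws (one parameter) or a draws x parameters
#'   matrix.
#' @param chain integer chain id per draw; at least 2 chains of equal
#'   length >= 2.
#' @return Rhat value(s), one per parameter.
#' @export
gelmanRhat <- function(x, chain) {
  if (is.matrix(x))
    return(apply(x, 2, gelmanRhat, chain = chain))
  groups <- split(x, chain)
  if (length(groups) < 2L) stop("need at least 2 chains")
  n <- lengths(groups)
  if (length(unique(n)) != 1L) stop("chains must have equal length")
  n <- n[[1]]
  if (n < 2L) stop("chains must have length >= 2")
  W <- mean(vapply(groups, var, numeric(1)))
  B <- n * var(vapply(groups, mean, numeric(1)))
  if (W == 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Max Rhat over the monitored parameters of a fit
#'
#' Monitors all occupancy and detection fixed effects plus the observer
#' random-effect variance (when present). \code{NA} components are not
#' assessable and propagate.
#'
#' @param fit an [OccuFit-class] with >= 2 chains.
#' @return named numeric vector of Rhat values.
#' @export
fitRhat <- function(fit) {
  draws <- cbind(fit@beta,
                 setNames(as.data.frame(fit@alpha),
                          paste0("det_", colnames(fit@alpha))))
  draws <- as.matrix(draws)
  if (length(fit@sigmaSqObs))
    draws <- cbind(draws, sigma_sq_obs = fit@sigmaSqObs)
  gelmanRhat(draws, fit@chain)
}

#' Is a coefficient "significant" under the 95% credible-interval rule?
#'
#' TRUE iff the equal-tailed 95% interval (2.5th to 97.5th percentile of
#' the posterior draws) excludes 0. The posterior sd of the draws is the
#' quantity reported as the coefficient's standard error.
#'
#' @param coefDraws numeric vector of posterior draws (>= 2).
#' @return logical.
#' @export
isSignificant <- function(coefDraws) {
  if (length(coefDraws) < 2L) stop("need at least 2 draws")
  q <- quantile(coefDraws, c(0.025, 0.975), names = FALSE)
  q[1] > 0 || q[2] < 0
}

#' Posterior predictive Bayesian p-value
#'
#' For each retained draw, replicate detections are simulated from the
#' fitted model at that draw conditional on its latent occupancy states
#' (y_rep ~ Bernoulli(z * p), the convention of standard occupancy
#' software), observed and replicate detections are aggregated into groups
#' — data
#' grouped across sites (total detections per site, over all seasons and
#' visits) or across replicates (total detections per within-site-year
#' visit rank) — and compared with the expected counts implied by the
#' draw's psi * p structure through the Freeman-Tukey or Chi-square
#' discrepancy. The p-value is the proportion of draws whose replicate
#' discrepancy is at least the observed one (ties count toward the upper
#' tail); values near 0.5 indicate a good fit. Because replicates condition
#' on the latent states, the check is primarily sensitive to detection-side
#' misfit (e.g. unmodeled between-site variation in detection); occupancy
#' misfit is partially absorbed by the latent states, a known property of
#' this class of checks.
#'
#' @param fit an [OccuFit-class].
#' @param statistic \code{"freeman_tukey"} or \code{"chi_square"}.
#' @param grouping \code{"sites"} or \code{"replicates"}.
#' @param seed seed for the replicate simulations.
#' @param stabilizer small constant added to Chi-square denominators.
#' @return the Bayesian p-value (scalar in [0, 1]).
#' @export
bayesP <- function(fit, statistic = c("freeman_tukey", "chi_square"),
                   grouping = c("sites", "replicates"), seed = 1,
                   stabilizer = 1e-4) {
  statistic <- match.arg(statistic)
  grouping <- match.arg(grouping)
  d <- designMatrices(fit@spec, fit@history)
  v <- fit@history@visits
  D <- nrow(fit@beta)
  V <- nrow(v)
  grp <- if (grouping == "sites") v$site_id else v$visit_index
  grp <- factor(grp)
  obsCount <- vapply(split(v$y, grp), sum, numeric(1))

  discrepancy <- function(counts, expected) {
    if (statistic == "freeman_tukey") {
      colSums((sqrt(counts) - sqrt(expected))^2)
    } else {
      colSums((counts - expected)^2 / (expected + stabilizer))
    }
  }

  set.seed(seed)
  Tobs <- Trep <- numeric(D)
  chunk <- max(1L, floor(2e6 / V))
  starts <- seq(1L, D, by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, D)
    nd <- length(rows)
    detLp <- fit@alpha[rows, , drop = FALSE] %*% t(d$W)
    if (!is.null(d$observerIndex))
      detLp <- detLp + fit@observerEffects[rows, d$observerIndex,
                                           drop = FALSE]
    p <- plogis(.clip(detLp))                       # nd x V
    psiU <- plogis(.clip(fit@beta[rows, , drop = FALSE] %*% t(d$X)))
    psi <- psiU[, v$unit, drop = FALSE]             # nd x V
    e <- psi * p
    zdraw <- fit@z[rows, , drop = FALSE]
    yrep <- matrix(rbinom(nd * V, 1L,
                          zdraw[, v$unit, drop = FALSE] * p), nd)
    eg <- rowsum(t(e), grp)                          # groups x nd
    yg <- rowsum(t(yrep), grp)
    Tobs[rows] <- discrepancy(matrix(obsCount, nrow(eg), nd), eg)
    Trep[rows] <- discrepancy(yg, eg)
  }
  mean(Trep >= Tobs)
}

#' All four posterior predictive p-values of a fit
#'
#' Freeman-Tukey and Chi-square statistics, each grouped by sites and by
#' replicates.
#'
#' @param fit an [OccuFit-class].
#' @param seed seed for the replicate simulations.
#' @return named numeric vector of length 4.
#' @export
bayesPAll <- function(fit, seed = 1) {
  c(ft_sites = bayesP(fit, "freeman_tukey", "sites", seed = seed),
    ft_replicates = bayesP(fit, "freeman_tukey", "replicates", seed = seed),
    chisq_sites = bayesP(fit, "chi_square", "sites", seed = seed),
    chisq_replicates = bayesP(fit, "chi_square", "replicates", seed = seed))
}

#' The packaged 18-model candidate grid
#'
#' Model 1 is the most comprehensive model (all occupancy and detection
#' terms); the remainder omit one or several covariates: all single-term
#' deletions of either submodel, intercept-only variants, single-covariate
#' occupancy submodels with full detection, and reduced detection submodels
#' retaining list length (with and without the observer effect). The exact
#' grid is a reconstruction from the models actually named in published
#' applications of this design, and is user-overridable wherever a grid is
#' accepted.
#'
#' @return list of 18 [OccuModelSpec-class] objects.
#' @export
defaultModelGrid <- function() {
  occFull <- .OCC_TERMS
  detFull <- .DET_TERMS
  specs <- list(
    occuModelSpec("1", occFull, detFull),
    occuModelSpec("2", setdiff(occFull, "year"), detFull),
    occuModelSpec("3", setdiff(occFull, "habitat_of_site"), detFull),
    occuModelSpec("4", setdiff(occFull, "distance_to_large_forest"),
                  detFull),
    occuModelSpec("5", setdiff(occFull, "site_size"), detFull),
    occuModelSpec("6", occFull, setdiff(detFull, "list_length")),
    occuModelSpec("7", occFull, setdiff(detFull, "habitat_of_observation")),
    occuModelSpec("8", occFull, setdiff(detFull, "observer")),
    occuModelSpec("9", character(), detFull),
    occuModelSpec("10", "year", detFull),
    occuModelSpec("11", "habitat_of_site", detFull),
    occuModelSpec("12", "distance_to_large_forest", detFull),
    occuModelSpec("13", "site_size", detFull),
    occuModelSpec("14", "site_size", c("list_length", "observer")),
    occuModelSpec("15", occFull, c("list_length", "observer")),
    occuModelSpec("16", occFull, "list_length"),
    occuModelSpec("17", character(), character()),
    occuModelSpec("18", occFull, character()))
  specs
}

#' Fit a candidate grid and select the WAIC-minimizing model
#'
#' Fits every spec of the grid to the same detection history with the same
#' seed policy, ranks them by WAIC (lower is better, ties broken toward the
#' spec with fewer terms), flags non-converged fits (max Rhat >= 1.1) but
#' keeps them in the ranking, and returns the winning fit together with the
#' complete WAIC ladder.
#'
#' @param grid list of [OccuModelSpec-class] (e.g. [defaultModelGrid()]).
#' @param history a [DetectionHistory-class].
#' @param priors an [OccuPriors-class].
#' @param chains,iterations,burnIn,thin,seed sampler settings, shared by
#'   every fit.
#' @param rhatThreshold convergence threshold (default 1.1).
#' @return list with \code{fit} (the winning [OccuFit-class]),
#'   \code{ladder} (data.frame: spec_id, waic, lppd, penalty, converged,
#'   max_rhat, n_terms) and \code{topSpec}.
#' @export
selectTopModel <- function(grid, history, priors = occuPriors(),
                           chains = 3, iterations = 60000, burnIn = 50000,
                           thin = 10, seed = 1, rhatThreshold = 1.1) {
  if (!length(grid)) stop("empty model grid")
  rows <- vector("list", length(grid))
  fits <- vector("list", length(grid))
  errs <- character()
  for (i in seq_along(grid)) {
    spec <- grid[[i]]
    fit <- tryCatch(
      sampleOccupancy(spec, history, priors, chains, iterations, burnIn,
                      thin, seed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errs <- c(errs, paste0(spec@id, ": ", conditionMessage(fit)))
      next
    }
    w <- waic(fit)
    mr <- suppressWarnings(max(fitRhat(fit)))
    rows[[i]] <- data.frame(
      spec_id = spec@id, waic = w$waic, lppd = w$lppd,
      penalty = w$penalty,
      converged = is.finite(mr) && mr < rhatThreshold, max_rhat = mr,
      n_terms = length(spec@occupancyTerms) + length(spec@detectionTerms),
      stringsAsFactors = FALSE)
    fits[[i]] <- fit
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep))
    stop("all fits failed:\n", paste(errs, collapse = "\n"))
  ladder <- do.call(rbind, rows[keep])
  fits <- fits[keep]
  ord <- order(ladder$waic, ladder$n_terms)
  ladder <- ladder[ord, , drop = FALSE]
  rownames(ladder) <- NULL
  list(fit = fits[[ord[1]]], ladder = ladder,
       topSpec = ladder$spec_id[1], failures = errs)
}

#' Structured report of one fitted model
#'
#' Posterior summaries in the layout of published occupancy tables: the
#' back-transformed detection intercept (mean detection probability of a
#' single visit by an average observer with a mean-length list outside
#' forest), coefficients on the logit scale with posterior sd ("standard
#' error") and the 95% credible-interval significance flag, the WAIC, the
#' convergence diagnostic, and (optionally) the four Bayesian p-values.
#'
#' @param fit an [OccuFit-class].
#' @param ppc logical: compute the four posterior predictive p-values?
#' @param ppcSeed seed for the replicate simulations.
#' @return list with elements \code{spec_id}, \code{coefficients}
#'   (data.frame), \code{detection_baseline}, \code{mean_psi},
#'   \code{waic}, \code{max_rhat}, \code{converged}, \code{bayes_p}.
#' @export
fitReport <- function(fit, ppc = FALSE, ppcSeed = 1) {
  summarize <- function(draws, submodel) {
    data.frame(
      submodel = submodel, term = colnames(draws),
      mean = colMeans(draws), sd = apply(draws, 2, sd),
      lower = apply(draws, 2, quantile, 0.025),
      upper = apply(draws, 2, quantile, 0.975),
      significant = apply(draws, 2, isSignificant),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  coefs <- rbind(summarize(fit@beta, "occupancy"),
                 summarize(fit@alpha, "detection"))
  if (length(fit@sigmaSqObs))
    coefs <- rbind(coefs, data.frame(
      submodel = "detection", term = "sigma_sq_obs",
      mean = mean(fit@sigmaSqObs), sd = sd(fit@sigmaSqObs),
      lower = quantile(fit@sigmaSqObs, 0.025),
      upper = quantile(fit@sigmaSqObs, 0.975),
      significant = NA, stringsAsFactors = FALSE, row.names = NULL))
  mr <- suppressWarnings(max(fitRhat(fit)))
  occ <- finiteSampleOccupancy(fit)
  list(spec_id = fit@spec@id,
       coefficients = coefs,
       detection_baseline = detectionAtBaseline(fit),
       mean_psi = c(mean = mean(occ$occupancy_mean),
                    se = mean(occ$occupancy_sd)),
       waic = waic(fit)$waic,
       max_rhat = mr,
       converged = is.finite(mr) && mr < 1.1,
       bayes_p = if (ppc) bayesPAll(fit, seed = ppcSeed) else NULL)
}

#' Serialize / read back a posterior sample
#'
#' \code{writeFit} writes the retained draws as a draw-by-parameter
#' comma-separated table (chain, draw, coefficients, observer effects,
#' variance, latent states, pointwise log-likelihoods) preceded by a
#' metadata block of \code{#}-prefixed lines (spec id and terms, seed and
#' chain layout). \code{readFit} reconstructs the [OccuFit-class] given the
#' detection history; the round trip is lossless (doubles are written with
#' 17 significant digits).
#'
#' @param fit an [OccuFit-class].
#' @param path file path.
#' @param history for \code{readFit}: the [DetectionHistory-class] the fit
#'   belongs to.
#' @return \code{readFit} returns the [OccuFit-class]; \code{writeFit} the
#'   path, invisibly.
#' @export
writeFit <- function(fit, path) {
  meta <- c(
    paste0("# spec_id: ", fit@spec@id),
    paste0("# occupancy_terms: ",
           paste(fit@spec@occupancyTerms, collapse = "|")),
    paste0("# detection_terms: ",
           paste(fit@spec@detectionTerms, collapse = "|")),
    paste0("# chains: ", fit@settings$chains),
    paste0("# iterations: ", fit@settings$iterations),
    paste0("# burnIn: ", fit@settings$burnIn),
    paste0("# thin: ", fit@settings$thin),
    paste0("# seed: ", fit@settings$seed))
  tab <- cbind(chain = fit@chain, draw = seq_along(fit@chain),
               fit@beta,
               `colnames<-`(fit@alpha, paste0("det.",
                                              colnames(fit@alpha))),
               if (ncol(fit@observerEffects))
                 `colnames<-`(fit@observerEffects,
                              paste0("eta.",
                                     seq_len(ncol(fit@observerEffects)))),
               if (length(fit@sigmaSqObs)) cbind(sigma_sq_obs =
                                                   fit@sigmaSqObs),
               `colnames<-`(fit@z, paste0("z.", seq_len(ncol(fit@z)))),
               `colnames<-`(fit@pointwiseLogLik,
                            paste0("ll.",
                                   seq_len(ncol(fit@pointwiseLogLik)))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines(paste(colnames(tab), collapse = ","), con)
  body <- apply(tab, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeFit
#' @export
readFit <- function(path, history) {
  lines <- readLines(path)
  metaLines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in metaLines) {
    kv <- sub("^# ", "", ml)
    key <- sub(":.*", "", kv)
    meta[[key]] <- sub("^[^:]*: ?", "", kv)
  }
  splitTerms <- function(s) if (nzchar(s)) strsplit(s, "|",
                                                   fixed = TRUE)[[1]]
    else character()
  spec <- occuModelSpec(meta$spec_id, splitTerms(meta$occupancy_terms),
                        splitTerms(meta$detection_terms))
  tab <- read.csv(textConnection(lines[!grepl("^#", lines)]),
                  check.names = FALSE)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix), names(tab))
    m <- as.matrix(tab[, cols, drop = FALSE])
    colnames(m) <- sub(paste0("^", prefix), "", colnames(m))
    m
  }
  zmat <- pick("z\\."); storage.mode(zmat) <- "integer"
  dimnames(zmat) <- NULL
  ll <- pick("ll\\."); dimnames(ll) <- NULL
  eta <- pick("eta\\.")
  if (ncol(eta)) colnames(eta) <- history@observers
  betaCols <- setdiff(names(tab),
                      c("chain", "draw", "sigma_sq_obs",
                        grep("^(det|eta|z|ll)\\.", names(tab),
                             value = TRUE)))
  beta <- as.matrix(tab[, betaCols, drop = FALSE])
  new("OccuFit", spec = spec, history = history, beta = beta,
      alpha = pick("det\\."), observerEffects = eta,
      sigmaSqObs = if ("sigma_sq_obs" %in% names(tab))
        tab$sigma_sq_obs else numeric(0),
      z = zmat, pointwiseLogLik = ll, chain = as.integer(tab$chain),
      settings = list(chains = as.integer(meta$chains),
                      iterations = as.integer(meta$iterations),
                      burnIn = as.integer(meta$burnIn),
                      thin = as.integer(meta$thin),
                      seed = as.integer(meta$seed),
                      priors = occuPriors()))
}
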