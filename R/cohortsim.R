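#' Cohort simulation parameters
#'
#' Defines the generative model of a synthetic contusion cohort: marginal
#' covariate distributions patterned on the baseline table of a two-centre
#' tICH cohort, a logistic sign-assignment model confounded by baseline
#' volume, mean arterial pressure, frontal location, subarachnoid and
#' subdural hemorrhage, and a logistic expansion-outcome model with a strong
#' sign effect.
#'
#' The two intercepts are calibrated (Monte Carlo, n = 2e6) so that the
#' marginal sign prevalence is ~43.9% and the expansion incidence ~63.7%
#' under the default coefficients; they are frozen constants, not fitted at
#' run time.  The sign requires three or more hematomas by definition, so
#' sign assignment is gated on the simulated `multiple_hematomas` indicator.
#'
#' @param nPatients cohort size.
#' @param signModel named list: `intercept` plus log-odds coefficients on
#'   `volume` (per mL), `map` (per mmHg), `frontal`, `sah`, `sdh`.
#' @param outcomeModel named list: `intercept`, `sign` (the true conditional
#'   log odds ratio of interest, default log 12, which puts the crude
#'   marginal odds ratio near 12 under the default confounding), plus
#'   coefficients on
#'   `volume`, `map`, `frontal`, `sah`, `sdh`, `multiple`, `timeToCT`.
#' @param pMultiple probability of three or more hematomas.
#' @param covariates named list of marginal distribution settings; see
#'   defaults.
#' @return list of class `CohortParams`
#' @export
cohortParams <- function(nPatients = 482L,
                         signModel = list(intercept = -4.7702,
                                          volume = 0.08, map = 0.028,
                                          frontal = 1.2, sah = 1.2,
                                          sdh = 1.3),
                         outcomeModel = list(intercept = -1.3934,
                                             sign = log(12),
                                             volume = 0.04, map = 0.012,
                                             frontal = 0.25, sah = 0.25,
                                             sdh = 0.25, multiple = 0,
                                             timeToCT = -0.3),
                         pMultiple = 0.58,
                         covariates = list(
                           maleP = 0.75, ageMean = 51, ageSD = 17.5,
                           hypertensionP = 0.13, diabetesP = 0.06,
                           mapMean = 102, mapSD = 14, coagulopathyP = 0.165,
                           gcsP = c(mild = 0.50, moderate = 0.22,
                                    severe = 0.28),
                           locationP = c(frontal = 0.49, temporal = 0.42,
                                         parietal = 0.033, occipital = 0.029,
                                         deep = 0.031),
                           ivhP = 0.083, sahP = 0.83, sdhP = 0.77,
                           timeToCTRange = c(0.5, 6),
                           timeToFollowupRange = c(6, 48),
                           volumeMeanML = 9.1, volumeSDML = 9.8,
                           volumeMinML = 2)) {
  stopifnot(nPatients >= 1L, pMultiple > 0, pMultiple < 1)
  probs <- c(covariates$maleP, covariates$hypertensionP,
             covariates$diabetesP, covariates$coagulopathyP,
             covariates$ivhP, covariates$sahP, covariates$sdhP)
  if (any(probs < 0 | probs > 1))
    stop("covariate probabilities must lie in [0, 1]")
  structure(list(nPatients = as.integer(nPatients), signModel = signModel,
                 outcomeModel = outcomeModel, pMultiple = pMultiple,
                 covariates = covariates),
            class = c("CohortParams", "list"))
}

#' Baseline covariates used in the propensity model
#'
#' The "nonparsimonious" covariate set: every baseline characteristic of the
#' cohort table enters the sign propensity model.
#'
#' @return character vector of column names
#' @export
baselineCovariates <- function() {
  c("male", "age", "hypertension", "diabetes", "map", "coagulopathy",
    "gcs", "location", "ivh", "sah", "sdh", "time_to_ct",
    "time_to_followup", "baseline_volume")
}

# lognormal parameters matched to a target mean/SD (before truncation)
lognormalFromMoments <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

rtruncated <- function(n, draw, ok) {
  x <- draw(n)
  bad <- !ok(x)
  while (any(bad)) {
    x[bad] <- draw(sum(bad))
    bad <- !ok(x)
  }
  x
}

#' Simulate a patient-level cohort
#'
#' Covariates are drawn from the marginals in `params`, the sign from the
#' confounded logistic model (gated on three or more hematomas), and the
#' expansion outcome from the logistic outcome model.  The true generative
#' probabilities are stored per row for parameter-recovery checks.
#'
#' @param params a [cohortParams()] list.
#' @param seed integer seed; the same `(params, seed)` reproduces the cohort
#'   row for row.
#' @return data.frame of class `CohortTable`: one row per patient with all
#'   covariates, `n_hematomas`, `multiple_hematomas`, `sign`, `expanded`,
#'   `true_propensity` and `true_outcome_probability`.
#' @examples
#' head(generateCohort(cohortParams(nPatients = 100), seed = 1))
#' @export
generateCohort <- function(params = cohortParams(), seed = 1L) {
  stopifnot(inherits(params, "CohortParams"))
  cv <- params$covariates
  n <- params$nPatients
  withSeed(seed, {
    male <- stats::rbinom(n, 1L, cv$maleP)
    age <- rtruncated(n, function(m) stats::rnorm(m, cv$ageMean, cv$ageSD),
                      function(x) x >= 18)
    hypertension <- stats::rbinom(n, 1L, cv$hypertensionP)
    diabetes <- stats::rbinom(n, 1L, cv$diabetesP)
    map <- stats::rnorm(n, cv$mapMean, cv$mapSD)
    coagulopathy <- stats::rbinom(n, 1L, cv$coagulopathyP)
    gcs <- factor(sample(names(cv$gcsP), n, replace = TRUE,
                         prob = cv$gcsP / sum(cv$gcsP)),
                  levels = c("mild", "moderate", "severe"))
    location <- factor(sample(names(cv$locationP), n, replace = TRUE,
                              prob = cv$locationP / sum(cv$locationP)),
                       levels = c("frontal", "temporal", "parietal",
                                  "occipital", "deep"))
    ivh <- stats::rbinom(n, 1L, cv$ivhP)
    sah <- stats::rbinom(n, 1L, cv$sahP)
    sdh <- stats::rbinom(n, 1L, cv$sdhP)
    time_to_ct <- stats::runif(n, cv$timeToCTRange[1], cv$timeToCTRange[2])
    time_to_followup <- stats::runif(n, cv$timeToFollowupRange[1],
                                     cv$timeToFollowupRange[2])
    lp_ <- lognormalFromMoments(cv$volumeMeanML, cv$volumeSDML)
    baseline_volume <- rtruncated(
      n, function(m) stats::rlnorm(m, lp_$meanlog, lp_$sdlog),
      function(x) x >= cv$volumeMinML)

    multiple <- stats::rbinom(n, 1L, params$pMultiple)
    n_hematomas <- ifelse(multiple == 1L,
                          3L + stats::rpois(n, 1.0),
                          sample(1:2, n, replace = TRUE,
                                 prob = c(0.55, 0.45)))

    sm <- params$signModel
    frontal <- as.integer(location == "frontal")
    lpSign <- sm$intercept + sm$volume * baseline_volume + sm$map * map +
      sm$frontal * frontal + sm$sah * sah + sm$sdh * sdh
    if (any(!is.finite(lpSign)))
      stop("non-finite linear predictor in the sign model")
    pSign <- multiple * stats::plogis(lpSign)
    sign <- stats::rbinom(n, 1L, pSign)

    om <- params$outcomeModel
    lpOut <- om$intercept + om$sign * sign + om$volume * baseline_volume +
      om$map * map + om$frontal * frontal + om$sah * sah + om$sdh * sdh +
      om$multiple * multiple + om$timeToCT * time_to_ct
    if (any(!is.finite(lpOut)))
      stop("non-finite linear predictor in the outcome model")
    pOut <- stats::plogis(lpOut)
    expanded <- stats::rbinom(n, 1L, pOut)

    out <- data.frame(id = seq_len(n), male = male, age = age,
                      hypertension = hypertension, diabetes = diabetes,
                      map = map, coagulopathy = coagulopathy, gcs = gcs,
                      location = location, ivh = ivh, sah = sah, sdh = sdh,
                      time_to_ct = time_to_ct,
                      time_to_followup = time_to_followup,
                      baseline_volume = baseline_volume,
                      n_hematomas = as.integer(n_hematomas),
                      multiple_hematomas = as.integer(multiple),
                      sign = sign, expanded = expanded,
                      true_propensity = pSign,
                      true_outcome_probability = pOut)
    class(out) <- c("CohortTable", "data.frame")
    out
  })
}

#' Apply the study eligibility filters
#'
#' Removes patients whose baseline CT came more than 6 h after trauma, whose
#' follow-up CT came more than 48 h after, or whose baseline hematoma volume
#' is below 2 mL (too small for reliable volumetry).  Exclusion counts per
#' criterion (applied in that order) are attached as the `"eligibility"`
#' attribute.
#'
#' @param table a `CohortTable` (or any data.frame with `time_to_ct`,
#'   `time_to_followup` and `baseline_volume` columns).
#' @return the filtered table, with an `eligibility` attribute
#' @export
applyEligibility <- function(table) {
  need <- c("time_to_ct", "time_to_followup", "baseline_volume")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L)
    stop("missing columns: ", paste(miss, collapse = ", "))
  crit <- list(baseline_ct_over_6h = quote(time_to_ct > 6),
               followup_ct_over_48h = quote(time_to_followup > 48),
               baseline_volume_under_2ml = quote(baseline_volume < 2))
  out <- table
  log_ <- data.frame(criterion = names(crit),
                     excluded = 0L, remaining = 0L)
  for (k in seq_along(crit)) {
    bad <- eval(crit[[k]], envir = out)
    log_$excluded[k] <- sum(bad)
    out <- out[!bad, , drop = FALSE]
    log_$remaining[k] <- nrow(out)
  }
  rownames(out) <- NULL
  attr(out, "eligibility") <- log_
  out
}

#' Write a cohort as CSV with a JSON parameter sidecar
#'
#' @param table a `CohortTable`.
#' @param path CSV path; a `.json` sidecar with the generating parameters is
#'   written next to it when `params` is supplied.
#' @param params optional [cohortParams()] used to generate the table.
#' @return `path`, invisibly.
#' @export
writeCohort <- function(table, path, params = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(params))
    jsonlite::write_json(unclass(params), sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort CSV written by [writeCohort()]
#'
#' @param path CSV path.
#' @return a `CohortTable` data.frame
#' @export
readCohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("gcs" %in% names(out))
    out$gcs <- factor(out$gcs, levels = c("mild", "moderate", "severe"))
  if ("location" %in% names(out))
    out$location <- factor(out$location,
                           levels = c("frontal", "temporal", "parietal",
                                      "occipital", "deep"))
  class(out) <- c("CohortTable", "data.frame")
  out
}
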