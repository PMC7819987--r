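#' Maximum-likelihood logistic regression by IRLS
#'
#' Newton-Raphson on the Bernoulli log-likelihood (equivalently iteratively
#' reweighted least squares).  The Wald covariance is the inverse observed
#' information at the solution.  Complete separation, which has no finite
#' maximiser, is reported as an error rather than returning runaway
#' coefficients; so is a rank-deficient design.
#'
#' @param x design matrix (include a column of ones for an intercept).
#' @param y binary outcome vector (0/1).
#' @param tolerance convergence threshold on the score (gradient) norm.
#' @param maxIter maximum Newton iterations.
#' @return a [LogisticFit-class]
#' @examples
#' x <- cbind(1, c(rep(1, 50), rep(0, 50)))
#' y <- c(rep(1, 44), rep(0, 6), rep(1, 22), rep(0, 28))
#' coef(fitLogistic(x, y))  # closed form: log(22/28), log((44*28)/(6*22))
#' @export
fitLogistic <- function(x, y, tolerance = 1e-8, maxIter = 50L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (nrow(x) != length(y)) stop("design and outcome sizes differ")
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  p <- ncol(x)
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(x, y - mu))
    if (sqrt(sum(score^2)) < tolerance * max(1, length(y))) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(x, x * w)
    step <- tryCatch(solve(info, score),
                     error = function(e) stop(
                       "information matrix is singular (separation?)"))
    # dampen absurd steps so divergence is detected, not propagated
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    if (max(abs(beta)) > 30)
      stop("complete separation: no finite maximum-likelihood estimate")
    if (iter >= maxIter) break
  }
  eta <- drop(x %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  vc <- solve(crossprod(x, x * w))
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(p))
  names(beta) <- nm
  dimnames(vc) <- list(nm, nm)
  new("LogisticFit", coefficients = beta, vcov = vc, logLik = ll,
      converged = converged, nIter = iter, fitted = mu)
}

#' @describeIn fitLogistic coefficient vector
#' @param object a LogisticFit
#' @export
setMethod("coef", "LogisticFit", function(object) object@coefficients)

#' @describeIn fitLogistic Wald covariance matrix
#' @export
setMethod("vcov", "LogisticFit", function(object) object@vcov)

setMethod("show", "LogisticFit", function(object) {
  cat(sprintf("LogisticFit: %d coefficient(s), logLik %.3f, %s in %d iter\n",
              length(object@coefficients), object@logLik,
              if (object@converged) "converged" else "NOT converged",
              object@nIter))
  se <- sqrt(diag(object@vcov))
  print(data.frame(estimate = object@coefficients, se = se,
                   z = object@coefficients / se), digits = 4)
})

# Design matrix (with intercept) from a cohort table and covariate names;
# factors expand to treatment dummies against their first level
# (GCS: mild; location: frontal).
buildDesign <- function(cohort, covariates, extra = NULL) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss) > 0L)
    stop("missing covariate columns: ", paste(miss, collapse = ", "))
  fm <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  x <- stats::model.matrix(fm, data = cohort)
  colnames(x)[1] <- "(Intercept)"
  if (!is.null(extra)) x <- cbind(x, extra)
  x
}

#' Estimate the sign propensity score
#'
#' Nonparsimonious logistic model: the sign indicator regressed on every
#' baseline covariate.  The fitted probabilities are the propensity scores;
#' by the logistic score equation their mean equals the observed sign
#' prevalence.
#'
#' @param cohort a `CohortTable`.
#' @param covariates covariate column names; default [baselineCovariates()].
#' @param exposure exposure column (default `"sign"`).
#' @return list with `scores` (numeric in (0,1)) and `fit`
#'   (a [LogisticFit-class])
#' @export
estimatePropensity <- function(cohort, covariates = baselineCovariates(),
                               exposure = "sign") {
  if (!exposure %in% names(cohort))
    stop("missing exposure column: ", exposure)
  x <- buildDesign(cohort, covariates)
  fit <- fitLogistic(x, cohort[[exposure]])
  list(scores = fit@fitted, fit = fit)
}

#' Exposure odds ratio under a chosen adjustment scheme
#'
#' Logistic regression of the outcome on the exposure plus an adjustment
#' set: none (crude), sex and age, the full individual-confounder set, or
#' the fitted propensity score as a single extra covariate.  The reported
#' odds ratio is `exp` of the exposure coefficient with a Wald confidence
#' interval.
#'
#' @param cohort a `CohortTable`.
#' @param exposure,outcome column names (defaults `"sign"`, `"expanded"`).
#' @param adjustment one of `"none"`, `"sex_age"`, `"individual_confounders"`,
#'   `"ps_covariate"`.
#' @param confounders covariate set for `"individual_confounders"` and the
#'   propensity model; default [baselineCovariates()].
#' @param ps optional precomputed propensity scores for `"ps_covariate"`.
#' @param level confidence level.
#' @return one effect row (data.frame): method, oddsRatio, ciLow, ciHigh,
#'   pValue, nUsed
#' @export
adjustedOR <- function(cohort, exposure = "sign", outcome = "expanded",
                       adjustment = c("none", "sex_age",
                                      "individual_confounders",
                                      "ps_covariate"),
                       confounders = baselineCovariates(), ps = NULL,
                       level = 0.95) {
  adjustment <- match.arg(adjustment)
  if (!outcome %in% names(cohort)) stop("missing outcome column: ", outcome)
  if (!exposure %in% names(cohort)) stop("missing exposure column: ", exposure)
  adjSet <- switch(adjustment,
                   none = character(0),
                   sex_age = c("male", "age"),
                   individual_confounders = setdiff(confounders, exposure),
                   ps_covariate = character(0))
  extra <- NULL
  if (adjustment == "ps_covariate") {
    if (is.null(ps))
      ps <- estimatePropensity(cohort, confounders, exposure)$scores
    extra <- cbind(ps = ps)
  }
  x <- cbind(buildDesign(cohort,
                         covariates = c(exposure, adjSet)), extra)
  fit <- fitLogistic(x, cohort[[outcome]])
  b <- coef(fit)[[exposure]]
  se <- sqrt(vcov(fit)[exposure, exposure])
  z <- stats::qnorm(1 - (1 - level) / 2)
  effectRow(method = switch(adjustment, none = "crude",
                            sex_age = "adjusted_sex_age",
                            individual_confounders = "adjusted_confounders",
                            ps_covariate = "ps_adjusted"),
            oddsRatio = exp(b), ciLow = exp(b - z * se),
            ciHigh = exp(b + z * se),
            pValue = 2 * stats::pnorm(-abs(b / se)), nUsed = nrow(cohort))
}
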