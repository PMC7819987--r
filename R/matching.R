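#' 1:1 greedy propensity-score matching with a caliper
#'
#' Treated subjects are visited in a seeded random order; each takes the
#' nearest still-unused control whose score lies within the caliper
#' (distance ties go to the lower control id so the result is fully
#' deterministic).  Matching is without replacement; treated subjects with
#' no admissible control are recorded as unmatched.  The default caliper,
#' 0.05, is 5 percentage points on the probability scale of the propensity
#' score.
#'
#' @param scores propensity scores for all subjects.
#' @param treated logical (or 0/1) exposure flags, same length.
#' @param caliper maximum admissible absolute score difference (> 0).
#' @param seed seed for the processing order (ignored when `order` given).
#' @param order optional explicit processing order: a permutation of the
#'   treated ids.
#' @param ids subject identifiers; default `seq_along(scores)`.
#' @return a [MatchedCohort-class]
#' @examples
#' m <- greedyMatch(c(0.30, 0.60, 0.31, 0.58, 0.90),
#'                  c(TRUE, TRUE, FALSE, FALSE, FALSE), caliper = 0.05,
#'                  seed = 1)
#' matchedPairs(m)
#' @export
greedyMatch <- function(scores, treated, caliper = 0.05, seed = 1L,
                        order = NULL, ids = seq_along(scores)) {
  stopifnot(length(scores) == length(treated), caliper > 0)
  treated <- as.logical(treated)
  if (!any(treated) || all(treated))
    stop("matching needs at least one subject in each arm")
  tid <- ids[treated]
  if (is.null(order)) {
    order <- withSeed(seed, sample(tid))
  } else {
    if (!setequal(order, tid) || length(order) != length(tid))
      stop("order must be a permutation of the treated ids")
    seed <- NA_real_
  }
  cid <- ids[!treated]
  cps <- scores[!treated]
  tps <- scores[match(order, ids)]
  used <- rep(FALSE, length(cid))
  pt <- character(0)
  pairsT <- vector(mode(ids), 0); pairsC <- vector(mode(ids), 0)
  pairsD <- numeric(0)
  for (k in seq_along(order)) {
    d <- abs(cps - tps[k])
    d[used] <- Inf
    j <- which.min(d)                     # ties: lowest index wins
    if (length(j) == 1L && is.finite(d[j]) && d[j] <= caliper) {
      used[j] <- TRUE
      pairsT <- c(pairsT, order[k])
      pairsC <- c(pairsC, cid[j])
      pairsD <- c(pairsD, d[j])
    } else {
      pt <- c(pt, as.character(order[k]))
    }
  }
  pairs <- data.frame(treated = pairsT, control = pairsC,
                      psDistance = pairsD)
  unmatched <- if (is.numeric(ids)) as.numeric(pt) else pt
  new("MatchedCohort", pairs = pairs, unmatchedTreated = unmatched,
      caliper = caliper, seed = as.numeric(seed))
}

#' @rdname matchedPairs
setMethod("matchedPairs", "MatchedCohort", function(object) object@pairs)

#' @rdname unmatchedTreated
setMethod("unmatchedTreated", "MatchedCohort",
          function(object) object@unmatchedTreated)

setMethod("show", "MatchedCohort", function(object) {
  cat(sprintf(
    "MatchedCohort: %d pair(s), %d unmatched treated, caliper %.3g\n",
    nrow(object@pairs), length(object@unmatchedTreated), object@caliper))
  if (nrow(object@pairs) > 0L)
    cat(sprintf("  score distances: median %.4f, max %.4f\n",
                stats::median(object@pairs$psDistance),
                max(object@pairs$psDistance)))
})

#' Standardized difference between two groups (percent)
#'
#' Scale-free imbalance measure: `100 |m1 - m0| / sqrt((s1^2 + s0^2) / 2)`.
#' For binary covariates the group variances are `p(1-p)`.  Values below 10%
#' conventionally indicate adequate balance.
#'
#' @param values covariate values.
#' @param group logical (or 0/1) group flags.
#' @param type `"auto"` detects binary 0/1 input; otherwise `"continuous"`
#'   or `"binary"`.
#' @return absolute standardized difference, in percent
#' @examples
#' standardizedDifference(c(rnorm(50, 12, 4), rnorm(50, 10, 4)),
#'                        rep(c(TRUE, FALSE), each = 50))
#' @export
standardizedDifference <- function(values, group,
                                   type = c("auto", "continuous", "binary")) {
  type <- match.arg(type)
  group <- as.logical(group)
  if (!any(group) || all(group)) stop("both groups must be non-empty")
  v1 <- values[group]; v0 <- values[!group]
  if (type == "auto")
    type <- if (all(values %in% c(0, 1))) "binary" else "continuous"
  if (type == "binary") {
    if (!all(values %in% c(0, 1))) stop("binary type requires 0/1 values")
    p1 <- mean(v1); p0 <- mean(v0)
    s2 <- (p1 * (1 - p1) + p0 * (1 - p0)) / 2
    num <- abs(p1 - p0)
  } else {
    s2 <- (stats::var(v1) + stats::var(v0)) / 2
    num <- abs(mean(v1) - mean(v0))
  }
  if (s2 <= 0) {
    if (num == 0) return(0)
    stop("zero pooled variance with unequal means: difference undefined")
  }
  100 * num / sqrt(s2)
}

# expand a covariate set to the numeric columns actually balanced: factors
# become one indicator per level
expandBalanceColumns <- function(cohort, covariates) {
  out <- list()
  for (cv in covariates) {
    x <- cohort[[cv]]
    if (is.factor(x) || is.character(x)) {
      lvls <- if (is.factor(x)) levels(x) else sort(unique(x))
      for (lv in lvls)
        out[[paste0(cv, ":", lv)]] <- as.numeric(x == lv)
    } else {
      out[[cv]] <- as.numeric(x)
    }
  }
  out
}

#' Covariate balance before and after matching
#'
#' Standardized differences for every baseline covariate (factor levels as
#' indicators), in the full cohort and in the matched sample — the data
#' behind a Love plot.
#'
#' @param cohort a `CohortTable` with an id column.
#' @param matched a [MatchedCohort-class] whose ids refer to `cohort$id`.
#' @param covariates covariate names; default [baselineCovariates()].
#' @param exposure exposure column (default `"sign"`).
#' @return data.frame with columns `covariate`, `smdBefore`, `smdAfter`
#' @export
balanceReport <- function(cohort, matched, covariates = baselineCovariates(),
                          exposure = "sign") {
  pr <- matchedPairs(matched)
  sel <- c(match(pr$treated, cohort$id), match(pr$control, cohort$id))
  if (any(is.na(sel))) stop("matched ids not found in cohort")
  sub <- cohort[sel, , drop = FALSE]
  colsAll <- expandBalanceColumns(cohort, covariates)
  colsSub <- expandBalanceColumns(sub, covariates)
  data.frame(
    covariate = names(colsAll),
    smdBefore = vapply(names(colsAll), function(nm)
      standardizedDifference(colsAll[[nm]], cohort[[exposure]]), numeric(1)),
    smdAfter = vapply(names(colsAll), function(nm)
      standardizedDifference(colsSub[[nm]], sub[[exposure]]), numeric(1)),
    row.names = NULL)
}
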