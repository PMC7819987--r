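#' Odds ratio from a 2x2 table
#'
#' `OR = ad / (bc)` with a log-scale Wald confidence interval.  When any
#' cell is zero the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied and flagged; when both cells of a margin are zero the odds ratio
#' is undefined and an error is raised.
#'
#' @param a,b,c,d non-negative integer cells: exposed with / without the
#'   event (`a`, `b`), unexposed with / without (`c`, `d`).
#' @param level confidence level.
#' @param method label carried into the result row.
#' @return one effect row (data.frame) with a `corrected` flag
#' @examples
#' oddsRatio2x2(44, 6, 22, 28)  # OR 9.33, 95% CI roughly (3.4, 25.9)
#' @export
oddsRatio2x2 <- function(a, b, c, d, level = 0.95, method = "crude") {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop("odds ratio undefined: a table margin is empty")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  lor <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - level) / 2)
  effectRow(method = method, oddsRatio = exp(lor),
            ciLow = exp(lor - z * se), ciHigh = exp(lor + z * se),
            pValue = 2 * stats::pnorm(-abs(lor / se)),
            nUsed = sum(c(a, b, c, d)), corrected = corrected)
}

#' Conditional odds ratio and McNemar test for 1:1 matched pairs
#'
#' For 1:1 matched binary outcomes the pair-stratified conditional
#' maximum-likelihood odds ratio reduces to the ratio of discordant pair
#' counts, `n10 / n01` (treated-event/control-no-event over the converse).
#' The Wald interval uses `sqrt(1/n10 + 1/n01)` on the log scale, and the
#' McNemar chi-square is `(n10 - n01)^2 / (n10 + n01)` on 1 df (no
#' continuity correction).  Concordant pairs carry no information about the
#' within-pair effect.
#'
#' @param treatedOutcome binary outcomes of the treated member of each pair.
#' @param controlOutcome binary outcomes of the matched controls.
#' @param level confidence level.
#' @return list with `effect` (an effect row, method
#'   `"matched_conditional"`) and `mcnemar`
#'   (`statistic`, `pValue`, `n10`, `n01`)
#' @examples
#' t <- rep(c(1, 1, 0, 0), c(30, 30, 8, 12))
#' c <- rep(c(1, 0, 1, 0), c(30, 30, 8, 12))
#' matchedConditionalOR(t, c)$effect$oddsRatio  # 30/8 = 3.75
#' @export
matchedConditionalOR <- function(treatedOutcome, controlOutcome,
                                 level = 0.95) {
  stopifnot(length(treatedOutcome) == length(controlOutcome))
  t_ <- as.numeric(treatedOutcome); c_ <- as.numeric(controlOutcome)
  if (!all(c(t_, c_) %in% c(0, 1))) stop("outcomes must be binary 0/1")
  n10 <- sum(t_ == 1 & c_ == 0)
  n01 <- sum(t_ == 0 & c_ == 1)
  if (n10 + n01 == 0)
    stop("no discordant pairs: the conditional odds ratio is undefined")
  corrected <- n10 == 0 || n01 == 0
  a10 <- n10 + if (corrected) 0.5 else 0
  a01 <- n01 + if (corrected) 0.5 else 0
  lor <- log(a10 / a01)
  se <- sqrt(1 / a10 + 1 / a01)
  z <- stats::qnorm(1 - (1 - level) / 2)
  chi2 <- (n10 - n01)^2 / (n10 + n01)
  list(effect = effectRow(method = "matched_conditional",
                          oddsRatio = a10 / a01,
                          ciLow = exp(lor - z * se),
                          ciHigh = exp(lor + z * se),
                          pValue = 2 * stats::pnorm(-abs(lor / se)),
                          nUsed = length(t_), corrected = corrected),
       mcnemar = list(statistic = chi2,
                      pValue = stats::pchisq(chi2, df = 1,
                                             lower.tail = FALSE),
                      n10 = n10, n01 = n01))
}

#' Subgroup odds ratios and interaction tests
#'
#' For each binary stratification factor, the exposure-outcome odds ratio is
#' computed per level from the 2x2 table, and the interaction p-value from a
#' Wald test on the exposure-by-factor product term in an unconditional
#' logistic model.  A factor that is constant in the sample (or a level with
#' an empty table margin) is flagged, not fatal.
#'
#' @param cohort data.frame (typically the matched sample).
#' @param factors named list: each element a logical/0-1 vector aligned with
#'   `cohort`, or a column name.
#' @param exposure,outcome column names.
#' @param level confidence level.
#' @return list with `estimates` (per-level effect rows with `factor` and
#'   `levelLabel` columns) and `interactions` (one row per factor:
#'   `factor`, `pInteraction`, `note`)
#' @export
subgroupInteraction <- function(cohort, factors, exposure = "sign",
                                outcome = "expanded", level = 0.95) {
  est <- list(); inter <- list()
  for (nm in names(factors)) {
    f <- factors[[nm]]
    if (is.character(f) && length(f) == 1L) f <- cohort[[f]]
    f <- as.numeric(f)
    note <- ""
    if (length(unique(f)) < 2L) {
      inter[[nm]] <- data.frame(factor = nm, pInteraction = NA_real_,
                                note = "factor constant in sample")
      next
    }
    for (lv in c(0, 1)) {
      sub <- cohort[f == lv, , drop = FALSE]
      tab <- table(factor(sub[[exposure]], levels = c(1, 0)),
                   factor(sub[[outcome]], levels = c(1, 0)))
      row <- tryCatch(
        oddsRatio2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                     level = level, method = "subgroup"),
        error = function(e) effectRow("subgroup", NA, NA, NA, NA,
                                      nrow(sub), note = conditionMessage(e)))
      row$factor <- nm
      row$levelLabel <- sprintf("%s=%d", nm, lv)
      est[[paste(nm, lv)]] <- row
    }
    x <- cbind(`(Intercept)` = 1, exposure = cohort[[exposure]],
               factor = f, interaction = cohort[[exposure]] * f)
    pI <- tryCatch({
      fit <- fitLogistic(x, cohort[[outcome]])
      b <- coef(fit)[["interaction"]]
      se <- sqrt(vcov(fit)["interaction", "interaction"])
      2 * stats::pnorm(-abs(b / se))
    }, error = function(e) {
      note <<- conditionMessage(e)
      NA_real_
    })
    inter[[nm]] <- data.frame(factor = nm, pInteraction = pI, note = note)
  }
  estimates <- if (length(est) > 0L)
    do.call(rbind, c(est, list(make.row.names = FALSE))) else
      data.frame()
  interactions <- if (length(inter) > 0L)
    do.call(rbind, c(inter, list(make.row.names = FALSE))) else
      data.frame()
  list(estimates = estimates, interactions = interactions)
}
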