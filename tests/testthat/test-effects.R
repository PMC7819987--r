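test_that("2x2 odds ratios match the log-scale Wald closed form", {
  eff <- oddsRatio2x2(44, 6, 22, 28)
  expect_equal(eff$oddsRatio, (44 * 28) / (6 * 22))
  se <- sqrt(1 / 44 + 1 / 6 + 1 / 22 + 1 / 28)
  expect_equal(eff$ciLow, exp(log(eff$oddsRatio) - qnorm(0.975) * se))
  expect_equal(eff$ciHigh, exp(log(eff$oddsRatio) + qnorm(0.975) * se))
  expect_equal(round(eff$ciLow, 2), 3.37)
  expect_equal(round(eff$ciHigh, 2), 25.87)
  expect_false(eff$corrected)

  expect_equal(oddsRatio2x2(10, 10, 10, 10)$oddsRatio, 1)

  corr <- oddsRatio2x2(5, 0, 5, 5)
  expect_true(corr$corrected)
  expect_equal(corr$oddsRatio, (5.5 * 5.5) / (0.5 * 5.5))

  expect_error(oddsRatio2x2(0, 0, 5, 5), "margin")
  expect_error(oddsRatio2x2(-1, 2, 3, 4), "non-negative")
})

test_that("the matched conditional estimator is the discordant-pair ratio", {
  t_ <- rep(c(1, 1, 0, 0), c(30, 30, 8, 12))
  c_ <- rep(c(1, 0, 1, 0), c(30, 30, 8, 12))
  res <- matchedConditionalOR(t_, c_)
  expect_equal(res$effect$oddsRatio, 30 / 8)
  expect_equal(res$mcnemar$statistic, (30 - 8)^2 / 38)
  expect_equal(res$mcnemar$statistic, 484 / 38)
  # cross-check against the stock McNemar test without continuity correction
  ref <- stats::mcnemar.test(table(t_, c_), correct = FALSE)
  expect_equal(res$mcnemar$statistic, unname(ref$statistic))
  expect_equal(res$mcnemar$pValue, unname(ref$p.value))

  # symmetric discordance: odds ratio one, zero statistic
  sym <- matchedConditionalOR(rep(c(1, 0), 25), rep(c(0, 1), 25))
  expect_equal(sym$effect$oddsRatio, 1)
  expect_equal(sym$mcnemar$statistic, 0)

  expect_error(matchedConditionalOR(c(1, 0), c(1, 0)), "discordant")
})

test_that("matched pairs recover a within-pair odds ratio of 10", {
  # pair-level random intercepts; within every pair the odds ratio is 10
  set.seed(1601)
  ors <- replicate(200, {
    alpha <- rnorm(1000, 0, 1)
    t_ <- rbinom(1000, 1, plogis(alpha + log(10)))
    c_ <- rbinom(1000, 1, plogis(alpha))
    matchedConditionalOR(t_, c_)$effect$oddsRatio
  })
  expect_lt(abs(median(ors) - 10) / 10, 0.2)
})

test_that("the null conditional odds ratio is covered at nominal rate", {
  set.seed(1602)
  covered <- replicate(200, {
    alpha <- rnorm(1000, 0, 1)
    t_ <- rbinom(1000, 1, plogis(alpha))
    c_ <- rbinom(1000, 1, plogis(alpha))
    eff <- matchedConditionalOR(t_, c_)$effect
    eff$ciLow <= 1 && 1 <= eff$ciHigh
  })
  expect_gte(mean(covered), 0.93)
})

test_that("an empty adjustment set reduces to the crude 2x2 odds ratio", {
  co <- generateCohort(cohortParams(nPatients = 2000), seed = 41)
  crude <- adjustedOR(co, adjustment = "none")
  tab <- table(sign = co$sign, expanded = co$expanded)
  ref <- oddsRatio2x2(tab["1", "1"], tab["1", "0"],
                      tab["0", "1"], tab["0", "0"])
  expect_equal(crude$oddsRatio, ref$oddsRatio, tolerance = 1e-6)
  expect_equal(crude$ciLow, ref$ciLow, tolerance = 1e-4)
})

test_that("adjustment pulls the estimate toward the generating effect", {
  # confounding inflates the crude estimate; covariate adjustment removes
  # most of the bias (median over replicates)
  truth <- cohortParams()$outcomeModel$sign
  biases <- t(vapply(1:30, function(r) {
    co <- generateCohort(cohortParams(nPatients = 4000), seed = 1700 + r)
    crude <- log(adjustedOR(co, adjustment = "none")$oddsRatio)
    adj <- log(adjustedOR(co,
                          adjustment = "individual_confounders")$oddsRatio)
    c(crude = abs(crude - truth), adjusted = abs(adj - truth))
  }, numeric(2)))
  expect_lt(median(biases[, "adjusted"]), median(biases[, "crude"]))
})

test_that("null-effect confidence intervals reach nominal coverage", {
  params <- cohortParams(nPatients = 10000)
  params$outcomeModel$sign <- 0
  covered <- vapply(1:100, function(r) {
    co <- generateCohort(params, seed = 1800 + r)
    eff <- adjustedOR(co, adjustment = "individual_confounders")
    eff$ciLow <= 1 && 1 <= eff$ciHigh
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("subgroup estimates bracket stratum-specific generating effects", {
  # two strata with designed odds ratios 9.5 and 6.25
  set.seed(1901)
  n <- 40000
  f <- rbinom(n, 1, 0.5)
  x <- rbinom(n, 1, 0.5)
  lp <- -0.8 + x * (log(6.25) + f * (log(9.5) - log(6.25)))
  y <- rbinom(n, 1, plogis(lp))
  d <- data.frame(sign = x, expanded = y, stratum = f)
  res <- subgroupInteraction(d, factors = list(stratum = "stratum"))
  est <- res$estimates
  or0 <- est$oddsRatio[est$levelLabel == "stratum=0"]
  or1 <- est$oddsRatio[est$levelLabel == "stratum=1"]
  expect_equal(or0, 6.25, tolerance = 0.2)
  expect_equal(or1, 9.5, tolerance = 0.2)
  expect_lt(res$interactions$pInteraction, 0.5)
})

test_that("interaction p-values are calibrated under the null", {
  set.seed(1902)
  pvals <- replicate(200, {
    n <- 600
    f <- rbinom(n, 1, 0.5)
    x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x + 0.3 * f))
    d <- data.frame(sign = x, expanded = y, stratum = f)
    subgroupInteraction(d,
                        factors = list(stratum = "stratum"))$interactions$pInteraction
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a constant stratification factor is flagged, not fatal", {
  d <- data.frame(sign = rbinom(50, 1, 0.5), expanded = rbinom(50, 1, 0.5),
                  stratum = rep(1, 50))
  res <- subgroupInteraction(d, factors = list(stratum = "stratum"))
  expect_true(is.na(res$interactions$pInteraction))
  expect_match(res$interactions$note, "constant")
})
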