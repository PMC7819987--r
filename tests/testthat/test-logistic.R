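test_that("the IRLS fit reproduces the closed-form 2x2 logit", {
  # cells: exposed 44/6 events/non-events, unexposed 22/28
  x <- cbind(intercept = 1, exposure = rep(c(1, 0), c(50, 50)))
  y <- c(rep(1, 44), rep(0, 6), rep(1, 22), rep(0, 28))
  fit <- fitLogistic(x, y)
  expect_true(fit@converged)
  expect_equal(unname(coef(fit)["exposure"]), log((44 * 28) / (6 * 22)),
               tolerance = 1e-6)
  expect_equal(unname(coef(fit)["intercept"]), log(22 / 28),
               tolerance = 1e-6)
  # Wald covariance is symmetric positive definite
  expect_equal(vcov(fit), t(vcov(fit)))
  expect_true(all(eigen(vcov(fit), symmetric = TRUE)$values > 0))
})

test_that("IRLS agrees with the closed form on random 2x2 tables", {
  set.seed(1401)
  for (r in 1:25) {
    cells <- rpois(4, 12) + 1
    x <- cbind(1, rep(c(1, 0), c(cells[1] + cells[2], cells[3] + cells[4])))
    y <- rep(c(1, 0, 1, 0), cells)
    fit <- fitLogistic(x, y)
    expect_equal(unname(coef(fit)[2]),
                 log((cells[1] * cells[4]) / (cells[2] * cells[3])),
                 tolerance = 1e-6)
  }
})

test_that("IRLS matches glm on a multivariable problem", {
  set.seed(1402)
  n <- 400
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 1.1 * x2))
  fit <- fitLogistic(cbind(1, x1, x2), y)
  ref <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(fit)))),
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  expect_equal(fit@logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("an outcome independent of a symmetric covariate gives slope zero", {
  x <- cbind(1, rep(c(1, 0), each = 40))
  y <- rep(c(1, 0, 1, 0), c(20, 20, 20, 20))
  fit <- fitLogistic(x, y)
  expect_equal(unname(coef(fit)[2]), 0, tolerance = 1e-8)
})

test_that("separation and rank deficiency raise explicit errors", {
  x <- cbind(1, c(rep(0, 10), rep(1, 10)))
  y <- c(rep(0, 10), rep(1, 10))            # perfectly separated
  expect_error(fitLogistic(x, y), "separation")
  x2 <- cbind(1, 1:20, 2 * (1:20))          # collinear
  expect_error(fitLogistic(x2, rep(c(0, 1), 10)), "rank deficient")
  expect_error(fitLogistic(cbind(1, 1:5), c(0, 1, 2, 1, 0)), "binary")
})

test_that("propensity scores average to the sign prevalence", {
  co <- mediumCohort()
  ps <- estimatePropensity(co)
  expect_equal(mean(ps$scores), mean(co$sign), tolerance = 1e-6)
  expect_true(all(ps$scores > 0 & ps$scores < 1))
  # confounded cohort: the score discriminates sign carriers
  expect_gt(rocAuc(ps$scores, co$sign)$auc, 0.6)
})

test_that("propensity slopes vanish when covariates are independent of the sign", {
  set.seed(1403)
  n <- 5000
  co <- data.frame(id = 1:n, male = rbinom(n, 1, 0.5), age = rnorm(n, 50, 10),
                   sign = rbinom(n, 1, 0.45))
  ps <- estimatePropensity(co, covariates = c("male", "age"))
  slopes <- coef(ps$fit)[-1]
  se <- sqrt(diag(vcov(ps$fit)))[-1]
  expect_true(all(abs(slopes / se) < 4))
  expect_equal(unname(stats::sd(ps$scores)), 0, tolerance = 0.02)
})
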