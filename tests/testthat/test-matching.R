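test_that("greedy matching solves the textbook toy instances", {
  # nearest admissible controls are taken regardless of processing order
  m <- greedyMatch(c(0.30, 0.60, 0.31, 0.58, 0.90),
                   c(TRUE, TRUE, FALSE, FALSE, FALSE), caliper = 0.05,
                   seed = 1)
  pr <- matchedPairs(m)
  expect_equal(nrow(pr), 2L)
  expect_setequal(paste(pr$treated, pr$control), c("1 3", "2 4"))

  # distance beyond the caliper: no pair
  m2 <- greedyMatch(c(0.90, 0.80), c(TRUE, FALSE), caliper = 0.05, seed = 1)
  expect_equal(nrow(matchedPairs(m2)), 0L)
  expect_equal(length(unmatchedTreated(m2)), 1L)

  # without replacement: one control can serve only one treated
  m3 <- greedyMatch(c(0.50, 0.50, 0.50), c(TRUE, TRUE, FALSE),
                    caliper = 0.05, seed = 1)
  expect_equal(nrow(matchedPairs(m3)), 1L)
  expect_equal(length(unmatchedTreated(m3)), 1L)
})

test_that("greedy matching agrees with an exhaustive oracle on small instances", {
  # oracle: literal greedy walk for an explicit treated order
  oracle <- function(scores, treated, caliper, ord) {
    cid <- which(!treated)
    used <- logical(length(cid))
    pairs <- NULL
    for (t in ord) {
      d <- abs(scores[cid] - scores[t]); d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= caliper) {
        used[j] <- TRUE
        pairs <- rbind(pairs, c(t, cid[j]))
      }
    }
    pairs
  }
  allPerms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in allPerms(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  set.seed(1501)
  for (r in 1:30) {
    nT <- sample(1:3, 1); nC <- sample(1:3, 1)
    scores <- round(runif(nT + nC), 3)
    treated <- rep(c(TRUE, FALSE), c(nT, nC))
    for (o in allPerms(which(treated))) {   # every processing order
      m <- greedyMatch(scores, treated, caliper = 0.1, order = o)
      ref <- oracle(scores, treated, 0.1, o)
      pr <- matchedPairs(m)
      if (is.null(ref)) {
        expect_equal(nrow(pr), 0L)
      } else {
        expect_equal(unname(as.matrix(pr[, 1:2])), unname(ref))
      }
    }
  }
})

test_that("matching never violates the caliper or reuses a subject", {
  set.seed(1502)
  for (r in 1:20) {
    n <- 80
    scores <- runif(n)
    treated <- runif(n) < 0.4
    if (!any(treated) || all(treated)) next
    m <- greedyMatch(scores, treated, caliper = 0.03, seed = r)
    pr <- matchedPairs(m)
    expect_true(all(pr$psDistance <= 0.03))
    expect_false(anyDuplicated(pr$treated) > 0)
    expect_false(anyDuplicated(pr$control) > 0)
    expect_true(all(pr$control %in% which(!treated)))
    expect_equal(nrow(pr) + length(unmatchedTreated(m)), sum(treated))
    # deterministic under the same seed
    m2 <- greedyMatch(scores, treated, caliper = 0.03, seed = r)
    expect_identical(matchedPairs(m2), pr)
  }
})

test_that("standardized differences reproduce hand-computed values", {
  g <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(standardizedDifference(rep(c(1, 2), 50), g), 0)
  # means 12 vs 10, both SD 4 -> 100 * 2 / 4 = 50%
  x <- c(scale(rnorm(50)) * 4 + 12, scale(rnorm(50)) * 4 + 10)
  expect_equal(standardizedDifference(x, g), 50, tolerance = 1e-6)
  # proportions 0.5 vs 0.3 -> 41.7%
  xb <- c(rep(1, 25), rep(0, 25), rep(1, 15), rep(0, 35))
  expect_equal(standardizedDifference(xb, g), 100 * 0.2 / sqrt(0.23),
               tolerance = 1e-6)
  # degenerate: zero variance with unequal means is undefined
  expect_error(standardizedDifference(rep(c(1, 2), each = 50), g),
               "zero pooled variance")
  expect_equal(standardizedDifference(rep(5, 100), g), 0)
})

test_that("matching restores covariate balance on confounded cohorts", {
  co <- mediumCohort()[1:2000, ]
  ps <- estimatePropensity(co)
  m <- greedyMatch(ps$scores, co$sign == 1, caliper = 0.05, seed = 9,
                   ids = co$id)
  b <- balanceReport(co, m)
  expect_gt(max(b$smdBefore), 10)
  expect_lt(max(b$smdAfter), 10)
})
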