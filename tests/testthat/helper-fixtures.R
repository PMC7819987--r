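# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# small phantom suite (2 per scenario) reused across imaging tests
smallSuite <- function() {
  if (is.null(.fixtures$suite))
    .fixtures$suite <- generatePhantomSuite(nPerScenario = 2, seed = 301)
  .fixtures$suite
}

# default confounded cohort reused across statistics tests
mediumCohort <- function() {
  if (is.null(.fixtures$cohort))
    .fixtures$cohort <- generateCohort(cohortParams(nPatients = 5000),
                                       seed = 302)
  .fixtures$cohort
}

# full-size suite (10 per scenario) for the acceptance checks
acceptanceSuite <- function() {
  if (is.null(.fixtures$bigSuite))
    .fixtures$bigSuite <- generatePhantomSuite(nPerScenario = 10, seed = 501)
  .fixtures$bigSuite
}

# segmentation + evidence for one scenario drawn from the shared suite
detectOn <- function(ph) {
  seg <- segmentHematomas(ph$volume)
  list(seg = seg, ev = detectFuzzySign(ph$volume, seg))
}
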