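test_that("phantom generation is deterministic under a fixed seed", {
  spec <- scenarioSpec("positive", seed = 41)
  a <- generatePhantom(spec, seed = 42)
  b <- generatePhantom(spec, seed = 42)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  expect_identical(a$truth@blobLabels, b$truth@blobLabels)
  c_ <- generatePhantom(spec, seed = 43)
  expect_false(identical(voxelData(a$volume), voxelData(c_$volume)))

  s1 <- generatePhantomSuite(nPerScenario = 1, seed = 7)
  s2 <- generatePhantomSuite(nPerScenario = 1, seed = 7)
  expect_length(s1, 6L)
  expect_setequal(vapply(s1, `[[`, "", "scenario"), phantomScenarios())
  expect_identical(lapply(s1, function(p) voxelData(p$volume)),
                   lapply(s2, function(p) voxelData(p$volume)))
})

test_that("ground truth is internally consistent for every phantom", {
  for (ph in smallSuite()) {
    tr <- ph$truth
    expect_identical(tr@expectedSign, unname(all(tr@expectedCriteria)),
                     info = ph$scenario)
    # corridors never intrude into a clot
    expect_false(any(tr@bridgeLabels > 0L & tr@blobLabels > 0L),
                 info = ph$scenario)
    # every positive phantom satisfies all three criteria by construction
    if (ph$scenario == "positive")
      expect_true(all(tr@expectedCriteria))
  }
})

test_that("rasterised blob volumes track the analytic ellipsoid volumes", {
  for (ph in smallSuite()) {
    tr <- ph$truth
    voxML <- prod(voxelSpacing(ph$volume)) / 1000
    for (i in seq_along(tr@blobVolumesML)) {
      if (tr@blobVolumesML[i] < 2) next
      rast <- sum(tr@blobLabels == i) * voxML
      expect_lt(abs(rast - tr@blobVolumesML[i]) / tr@blobVolumesML[i], 0.05)
    }
  }
})

test_that("invalid phantom geometry is rejected", {
  # blob poking outside the field of view
  spec <- phantomSpec("single_blob",
                      blobs = list(list(center = c(2, 32, 40),
                                        radii = c(8, 8, 12), hu = 65)))
  expect_error(generatePhantom(spec, seed = 1), "outside")
  # overlapping blobs in a scenario that requires disjoint ones
  spec2 <- phantomSpec("two_blobs",
                       blobs = list(
                         list(center = c(30, 32, 40), radii = c(8, 8, 12),
                              hu = 65),
                         list(center = c(34, 32, 40), radii = c(8, 8, 12),
                              hu = 65)),
                       bridges = list(list(pair = c(1L, 2L), radius = 2.5,
                                           hu = 45)))
  expect_error(generatePhantom(spec2, seed = 1), "overlap")
  # density regime violations are caught at construction
  expect_error(phantomSpec("single_blob",
                           blobs = list(list(center = c(32, 32, 40),
                                             radii = c(8, 8, 12),
                                             hu = 120))),
               "50, 90")
  expect_error(generatePhantomSuite(nPerScenario = 0, seed = 1))
})

test_that("scenario labels must match the geometry they claim", {
  # a 'positive' spec with only two blobs is inconsistent
  spec <- phantomSpec("positive",
                      blobs = list(
                        list(center = c(25, 32, 40), radii = c(6, 6, 12),
                             hu = 65),
                        list(center = c(40, 32, 40), radii = c(6, 6, 12),
                             hu = 65)),
                      bridges = list(list(pair = c(1L, 2L), radius = 2.5,
                                          hu = 44)))
  expect_error(generatePhantom(spec, seed = 1), "requires 3 blobs")
})
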