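test_that("a single sphere segments to its analytic volume", {
  # 10 mm radius sphere at 70 HU: (4/3) pi (1 cm)^3 = 4.19 mL
  spec <- phantomSpec("single_blob",
                      blobs = list(list(center = c(32, 32, 40),
                                        radii = c(10, 10, 10), hu = 70)),
                      noiseSD = 0.5)
  ph <- generatePhantom(spec, seed = 9)
  cmp <- hematomaComponents(segmentHematomas(ph$volume))
  expect_equal(nrow(cmp), 1L)
  expect_equal(cmp$volumeML, 4 / 3 * pi, tolerance = 0.05)
  expect_gte(cmp$meanHU, 50)
})

test_that("a uniform parenchyma volume yields no components", {
  vol <- CTVolume(array(33, dim = c(32, 32, 8)))
  seg <- segmentHematomas(vol)
  expect_equal(nrow(hematomaComponents(seg)), 0L)
  expect_equal(totalHematomaVolume(seg), 0)
})

test_that("components come back sorted, filtered and volume-accurate", {
  for (ph in smallSuite()) {
    seg <- segmentHematomas(ph$volume)
    cmp <- hematomaComponents(seg)
    expect_equal(nrow(cmp), length(ph$truth@blobVolumesML),
                 info = ph$scenario)
    expect_false(is.unsorted(rev(cmp$volumeML)), info = ph$scenario)
    expect_true(all(cmp$volumeML >= 0.1), info = ph$scenario)
    expect_true(all(cmp$meanHU >= 50), info = ph$scenario)
    tv <- sort(ph$truth@blobVolumesML, decreasing = TRUE)
    sv <- sort(cmp$volumeML, decreasing = TRUE)
    keep <- tv >= 2
    expect_true(all(abs(sv[keep] - tv[keep]) / tv[keep] < 0.05),
                info = ph$scenario)
    # total volume matches the summed analytic truth
    expect_equal(totalHematomaVolume(seg), sum(tv), tolerance = 0.05)
  }
})

test_that("segmentation volume error shrinks as the grid is refined", {
  sphereErr <- function(f) {
    sp <- c(0.5, 0.5, 5) * f
    shape <- as.integer(round(c(64 / sp[1], 64 / sp[2], 80 / sp[3])))
    spec <- phantomSpec("single_blob",
                        blobs = list(list(center = c(32, 32, 40),
                                          radii = c(13, 13, 13), hu = 70)),
                        shape = shape, spacing = sp, noiseSD = 0.5)
    ph <- generatePhantom(spec, seed = 5)
    cmp <- hematomaComponents(segmentHematomas(ph$volume))
    abs(cmp$volumeML[1] - ph$truth@blobVolumesML[1]) /
      ph$truth@blobVolumesML[1]
  }
  errs <- vapply(c(2, 1, 0.5), sphereErr, numeric(1))
  expect_false(is.unsorted(rev(errs)))   # coarse >= default >= fine
  expect_lt(errs[3], 0.01)
})

test_that("the minimum component size suppresses small islands", {
  spec <- phantomSpec("two_blobs",
                      blobs = list(
                        list(center = c(20, 32, 40), radii = c(8, 8, 12),
                             hu = 65),
                        list(center = c(44, 32, 40), radii = c(1.2, 1.2, 5.2),
                             hu = 65)),
                      bridges = list(), noiseSD = 0.5)
  # second blob ~0.03 mL, below the 0.1 mL floor
  ph <- generatePhantom(spec, seed = 3)
  cmp <- hematomaComponents(segmentHematomas(ph$volume))
  expect_equal(nrow(cmp), 1L)
  cmp2 <- hematomaComponents(
    segmentHematomas(ph$volume, segmentationConfig(minComponentML = 0.01)))
  expect_equal(nrow(cmp2), 2L)
})

test_that("segmentation config validates its invariants", {
  expect_error(segmentationConfig(clotThresholdHU = 35), "exceed")
  expect_error(segmentationConfig(minComponentML = 0), "positive")
  expect_error(segmentationConfig(connectivity = 4), "connectivity")
})
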