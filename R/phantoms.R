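#' Scenario labels understood by the phantom generator
#'
#' Six designed geometries: one that satisfies all three criteria of the
#' multihematoma fuzzy sign, and five negatives each engineered to fail a
#' specific criterion (or the component count) while keeping everything else
#' valid.
#'
#' @return character vector of scenario labels
#' @export
phantomScenarios <- function() {
  c("positive", "two_blobs", "far_apart", "low_contrast_bridge",
    "parenchyma_gap", "single_blob")
}

# designed criterion pattern (c1, c2, c3) per scenario; when c1 fails there
# is no adjacency cluster to evaluate, so c2/c3 are FALSE by convention.
scenarioCriteria <- function(scenario) {
  switch(scenario,
         positive            = c(c1 = TRUE,  c2 = TRUE,  c3 = TRUE),
         two_blobs           = c(c1 = FALSE, c2 = FALSE, c3 = FALSE),
         far_apart           = c(c1 = FALSE, c2 = FALSE, c3 = FALSE),
         low_contrast_bridge = c(c1 = TRUE,  c2 = TRUE,  c3 = FALSE),
         parenchyma_gap      = c(c1 = TRUE,  c2 = FALSE, c3 = TRUE),
         single_blob         = c(c1 = FALSE, c2 = FALSE, c3 = FALSE),
         stop(sprintf("unknown scenario '%s'", scenario)))
}

#' Construct a PhantomSpec
#'
#' Low-level constructor; most users will call [scenarioSpec()] (randomised
#' geometry within a scenario's constraints) or [generatePhantomSuite()].
#'
#' @param scenario one of [phantomScenarios()].
#' @param blobs list of `list(center =, radii =, hu =)` ellipsoids (mm / HU).
#' @param bridges list of `list(pair =, radius =, hu =)` corridors.
#' @param shape grid size (voxels).
#' @param spacing voxel size (mm).
#' @param backgroundHU mean parenchyma density; 33 HU sits in the gray/white
#'   band.
#' @param noiseSD additive Gaussian noise (HU).
#' @return a [PhantomSpec-class]
#' @export
phantomSpec <- function(scenario, blobs, bridges = list(),
                        shape = c(128L, 128L, 16L),
                        spacing = c(0.5, 0.5, 5),
                        backgroundHU = 33, noiseSD = 2) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      backgroundHU = backgroundHU, noiseSD = noiseSD,
      blobs = blobs, bridges = bridges, scenario = scenario)
}

# In-plane radius of an axis-aligned ellipsoid along unit direction u
# (z-component ignored; blobs share a z-centre so adjacency is in-plane).
ellipseRadiusAlong <- function(radii, u) {
  1 / sqrt((u[1] / radii[1])^2 + (u[2] / radii[2])^2)
}

# Centre-line surface gap between two blobs (mm).
blobGap <- function(a, b) {
  v <- b$center - a$center
  d <- sqrt(sum(v^2))
  u <- v / d
  ta <- 1 / sqrt(sum((u / a$radii)^2))
  tb <- 1 / sqrt(sum((u / b$radii)^2))
  d - ta - tb
}

# Place three circles-in-plane with prescribed pairwise centre distances,
# randomly rotated and jittered about the volume centre; retries the pose
# until every blob sits inside the field of view.
placeTriangle <- function(d12, d13, d23, rIn, fovXY, margin) {
  x3 <- (d12^2 + d13^2 - d23^2) / (2 * d12)
  y3 <- sqrt(max(d13^2 - x3^2, 0))
  pts <- rbind(c(0, 0), c(d12, 0), c(x3, y3))
  ctr <- colMeans(pts)
  for (try in 1:64) {
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    jit <- stats::runif(2, -3, 3)
    cand <- sweep(pts, 2L, ctr) %*% R
    cand <- sweep(cand, 2L, fovXY / 2 + jit, "+")
    lo <- cand - rIn
    hi <- cand + rIn
    if (all(lo > margin) && all(hi[, 1] < fovXY[1] - margin) &&
        all(hi[, 2] < fovXY[2] - margin))
      return(cand)
  }
  stop("could not place blobs inside the field of view")
}

#' Draw a randomised PhantomSpec for a scenario
#'
#' Geometry and densities are sampled within each scenario's designed
#' constraints: clot 50-90 HU, corridors 40-50 HU, criterion margins of at
#' least ~2 HU / several mm so that the expected detector call is
#' unambiguous under the default noise level.  Axial semi-axes stay at two
#' or more slice thicknesses so that voxelised blob volumes track the
#' analytic ellipsoid volumes despite the 5 mm slices.
#'
#' @param scenario one of [phantomScenarios()].
#' @param seed integer; fixes all random draws.
#' @param shape,spacing grid geometry, as in [phantomSpec()].
#' @return a [PhantomSpec-class]
#' @export
scenarioSpec <- function(scenario, seed, shape = c(128L, 128L, 16L),
                         spacing = c(0.5, 0.5, 5)) {
  scenario <- match.arg(scenario, phantomScenarios())
  fov <- shape * spacing
  withSeed(seed, {
    zc <- fov[3] / 2 + stats::runif(1, -2.5, 2.5)
    mkBlob <- function(xy, rIn, rz, hu)
      list(center = c(xy[1], xy[2], zc), radii = c(rIn, rIn, rz), hu = hu)

    if (scenario == "single_blob") {
      r <- stats::runif(1, 6, 9); rz <- stats::runif(1, 11, 14)
      xy <- fov[1:2] / 2 + stats::runif(2, -4, 4)
      blobs <- list(mkBlob(xy, r, rz, stats::runif(1, 62, 72)))
      return(phantomSpec(scenario, blobs, list(), shape, spacing))
    }

    if (scenario == "two_blobs") {
      r1 <- stats::runif(1, 7, 9);  rz1 <- stats::runif(1, 12, 14)
      r2 <- stats::runif(1, 5, 7);  rz2 <- stats::runif(1, 11, 13)
      gap <- stats::runif(1, 3, 5.5)
      bridgeHU <- stats::runif(1, 42.5, 46.5)
      hu <- bridgeHU + stats::runif(1, 22, 26)
      th <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(th), sin(th))
      c1 <- fov[1:2] / 2 - u * (r1 + gap / 2) + stats::runif(2, -2, 2)
      c2 <- c1 + u * (r1 + r2 + gap)
      blobs <- list(mkBlob(c1, r1, rz1, hu),
                    mkBlob(c2, r2, rz2, hu + stats::runif(1, -0.5, 0.5)))
      bridges <- list(list(pair = c(1L, 2L), radius = 2.5, hu = bridgeHU))
      return(phantomSpec(scenario, blobs, bridges, shape, spacing))
    }

    # three-blob scenarios -------------------------------------------------
    if (scenario == "far_apart") {
      rIn <- stats::runif(3, 4, 5.5)
      rz <- stats::runif(3, 11, 12.5)
      dMax <- 2 * max(rz, rIn)
      gaps <- dMax * stats::runif(3, 1.10, 1.22)
      hu <- stats::runif(1, 62, 72) + stats::runif(3, -0.5, 0.5)
      bridgeHU <- NULL
    } else {
      rIn <- c(stats::runif(1, 8, 10), stats::runif(2, 5, 7))
      rz <- c(stats::runif(1, 12, 15), stats::runif(2, 11, 13))
      gaps <- stats::runif(3, 3, 5.5)
      if (scenario == "low_contrast_bridge") {
        bridgeHU <- stats::runif(1, 43.5, 47)
        base <- bridgeHU + stats::runif(1, 13.5, 17)
      } else if (scenario == "positive") {
        bridgeHU <- stats::runif(1, 42.5, 46.5)
        base <- bridgeHU + stats::runif(1, 22.5, 26)
      } else { # parenchyma_gap
        bridgeHU <- NULL
        base <- stats::runif(1, 62, 72)
      }
      hu <- base + stats::runif(3, -0.5, 0.5)
    }
    d12 <- rIn[1] + rIn[2] + gaps[1]
    d13 <- rIn[1] + rIn[3] + gaps[2]
    d23 <- rIn[2] + rIn[3] + gaps[3]
    xy <- placeTriangle(d12, d13, d23, rIn, fov[1:2], margin = 1)
    blobs <- lapply(1:3, function(i) mkBlob(xy[i, ], rIn[i], rz[i], hu[i]))
    bridges <- list()
    if (!is.null(bridgeHU)) {
      bridges <- lapply(list(c(1L, 2L), c(1L, 3L), c(2L, 3L)), function(p)
        list(pair = p, radius = 2.5, hu = bridgeHU))
    }
    phantomSpec(scenario, blobs, bridges, shape, spacing)
  })
}

# Linear voxel indices inside an axis-aligned ellipsoid.
rasterizeEllipsoid <- function(shape, spacing, center, radii) {
  ax <- lapply(1:3, function(k) {
    x <- (seq_len(shape[k]) - 0.5) * spacing[k]
    which(abs(x - center[k]) <= radii[k])
  })
  if (any(lengths(ax) == 0L)) return(integer(0))
  grid <- expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]])
  xs <- (grid$i - 0.5) * spacing[1]
  ys <- (grid$j - 0.5) * spacing[2]
  zs <- (grid$k - 0.5) * spacing[3]
  inside <- ((xs - center[1]) / radii[1])^2 +
    ((ys - center[2]) / radii[2])^2 +
    ((zs - center[3]) / radii[3])^2 < 1
  (grid$i + shape[1] * (grid$j - 1L) +
      shape[1] * shape[2] * (grid$k - 1L))[inside]
}

# Consistency audit: the scenario label must match the geometry/densities
# actually present in the spec (count, adjacency regime, corridor regime).
checkScenarioConsistency <- function(spec) {
  sc <- spec@scenario
  nb <- length(spec@blobs)
  expectN <- c(positive = 3L, two_blobs = 2L, far_apart = 3L,
               low_contrast_bridge = 3L, parenchyma_gap = 3L,
               single_blob = 1L)[[sc]]
  if (nb != expectN)
    stop(sprintf("scenario '%s' requires %d blobs, got %d", sc, expectN, nb))
  if (nb < 2L) return(invisible(TRUE))
  gaps <- utils::combn(nb, 2L, function(p)
    blobGap(spec@blobs[[p[1]]], spec@blobs[[p[2]]]))
  if (any(gaps <= 0))
    stop("blobs overlap: scenario requires disjoint blobs")
  dMax <- 2 * max(vapply(spec@blobs, function(b) max(b$radii), numeric(1)))
  if (sc == "far_apart" && any(gaps <= dMax))
    stop("far_apart scenario requires every gap to exceed the largest diameter")
  if (sc %in% c("positive", "low_contrast_bridge", "parenchyma_gap") &&
      any(gaps >= dMax))
    stop("adjacent-blob scenario requires gaps below the largest diameter")
  if (length(spec@bridges) > 0L) {
    bhu <- vapply(spec@bridges, function(b) b$hu, numeric(1))
    clot <- min(vapply(spec@blobs, function(b) b$hu, numeric(1)))
    if (any(bhu <= 40 | bhu >= 50))
      stop("bridge corridors must sit in the 40-50 HU blood-density band")
    if (sc == "positive" && clot - max(bhu) < 20)
      stop("positive scenario requires >= 20 HU clot-corridor contrast")
    if (sc == "low_contrast_bridge" && clot - min(bhu) >= 20)
      stop("low_contrast_bridge requires < 20 HU clot-corridor contrast")
  }
  invisible(TRUE)
}

#' Generate a synthetic CT phantom with voxel-exact ground truth
#'
#' Rasterises the spec onto the voxel grid (a voxel belongs to a region when
#' its centre does), paints blob and corridor mean densities over the
#' parenchymal background, and adds i.i.d. Gaussian noise.  The same
#' `(spec, seed)` always yields an identical volume.
#'
#' @param spec a [PhantomSpec-class], e.g. from [scenarioSpec()].
#' @param seed integer seed for the noise field.
#' @return list with elements `volume` (a [CTVolume-class]) and `truth`
#'   (a [PhantomTruth-class]).
#' @examples
#' ph <- generatePhantom(scenarioSpec("positive", seed = 1), seed = 1)
#' ph$truth@expectedSign
#' @export
generatePhantom <- function(spec, seed) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  checkScenarioConsistency(spec)
  shape <- spec@shape; spacing <- spec@spacing
  fov <- shape * spacing
  for (b in spec@blobs) {
    if (any(b$center - b$radii < 0) || any(b$center + b$radii > fov))
      stop("blob extends outside the volume bounds")
  }
  blobLabels <- array(0L, dim = shape)
  for (i in seq_along(spec@blobs)) {
    lin <- rasterizeEllipsoid(shape, spacing, spec@blobs[[i]]$center,
                              spec@blobs[[i]]$radii)
    if (any(blobLabels[lin] != 0L))
      stop("blobs overlap: scenario requires disjoint blobs")
    blobLabels[lin] <- i
  }
  # Corridors model liquid blood filling the cleft between two clots: voxels
  # within `radius` (in-plane) of the centre chord, extruded axially over the
  # pair's shared z-span, minus the blobs themselves.  The axial extrusion
  # matters with 5 mm slices: the narrowest voxel gap between two blobs can
  # sit one slice away from the blob centres, and the fuzzy signal must be
  # present there too.
  bridgeLabels <- array(0L, dim = shape)
  for (i in seq_along(spec@bridges)) {
    br <- spec@bridges[[i]]
    a <- spec@blobs[[br$pair[1]]]; b <- spec@blobs[[br$pair[2]]]
    v <- b$center - a$center
    u <- v / sqrt(sum(v^2))
    p <- a$center + u / sqrt(sum((u / a$radii)^2))
    q <- b$center - u / sqrt(sum((u / b$radii)^2))
    zSpan <- c(max(a$center[3] - 0.7 * a$radii[3],
                   b$center[3] - 0.7 * b$radii[3]),
               min(a$center[3] + 0.7 * a$radii[3],
                   b$center[3] + 0.7 * b$radii[3]))
    lo <- c(pmax(pmin(p, q)[1:2] - br$radius - spacing[1:2], 0), zSpan[1])
    hi <- c(pmin(pmax(p, q)[1:2] + br$radius + spacing[1:2], fov[1:2]),
            zSpan[2])
    ax <- lapply(1:3, function(k) {
      x <- (seq_len(shape[k]) - 0.5) * spacing[k]
      which(x >= lo[k] & x <= hi[k])
    })
    if (any(lengths(ax) == 0L)) next
    grid <- expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]])
    pts <- cbind((grid$i - 0.5) * spacing[1],
                 (grid$j - 0.5) * spacing[2],
                 0)
    lin <- grid$i + shape[1] * (grid$j - 1L) +
      shape[1] * shape[2] * (grid$k - 1L)
    p2 <- c(p[1:2], 0); q2 <- c(q[1:2], 0)
    sel <- distToSegment(pts, p2, q2) <= br$radius
    lin <- lin[sel]
    lin <- lin[blobLabels[lin] == 0L]          # corridors never enter a blob
    lin <- lin[bridgeLabels[lin] == 0L]
    bridgeLabels[lin] <- i
  }
  mean_field <- array(spec@backgroundHU, dim = shape)
  for (i in seq_along(spec@blobs))
    mean_field[blobLabels == i] <- spec@blobs[[i]]$hu
  for (i in seq_along(spec@bridges))
    mean_field[bridgeLabels == i] <- spec@bridges[[i]]$hu
  vox <- withSeed(seed,
    mean_field + stats::rnorm(length(mean_field), 0, spec@noiseSD))
  vox <- pmin(pmax(vox, -1024), 3071)
  dim(vox) <- shape
  crit <- scenarioCriteria(spec@scenario)
  truth <- new("PhantomTruth",
               blobLabels = blobLabels, bridgeLabels = bridgeLabels,
               blobVolumesML = vapply(spec@blobs, function(b)
                 4 / 3 * pi * prod(b$radii) / 1000, numeric(1)),
               expectedSign = unname(all(crit)), expectedCriteria = crit,
               scenario = spec@scenario)
  list(volume = CTVolume(vox, spacing = spacing), truth = truth)
}

#' Generate a full phantom suite across all scenarios
#'
#' @param nPerScenario phantoms per scenario label (>= 1).
#' @param seed master seed; all geometry and noise derive from it
#'   deterministically.
#' @param shape,spacing grid geometry.
#' @return list of `list(volume, truth, scenario, seed)`, of length
#'   `6 * nPerScenario`.
#' @export
generatePhantomSuite <- function(nPerScenario = 1L, seed = 1L,
                                 shape = c(128L, 128L, 16L),
                                 spacing = c(0.5, 0.5, 5)) {
  stopifnot(nPerScenario >= 1L)
  out <- list()
  k <- 0L
  for (sc in phantomScenarios()) {
    for (j in seq_len(nPerScenario)) {
      k <- k + 1L
      sub <- (as.numeric(seed) + 7919 * k) %% 2147483629
      spec <- scenarioSpec(sc, seed = sub, shape = shape, spacing = spacing)
      ph <- generatePhantom(spec, seed = sub + 1)
      out[[k]] <- list(volume = ph$volume, truth = ph$truth,
                       scenario = sc, seed = sub)
    }
  }
  out
}

#' @rdname labelMap
setMethod("labelMap", "PhantomTruth", function(object) object@blobLabels)

#' @rdname signCriteria
setMethod("signCriteria", "PhantomTruth",
          function(object) object@expectedCriteria)

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: scenario '%s', %d blob(s), expected sign %s\n",
              object@scenario, length(object@blobVolumesML),
              object@expectedSign))
  cat(sprintf("  criteria c1=%s c2=%s c3=%s; analytic volumes %s mL\n",
              object@expectedCriteria[1], object@expectedCriteria[2],
              object@expectedCriteria[3],
              paste(sprintf("%.2f", object@blobVolumesML), collapse = ", ")))
})
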