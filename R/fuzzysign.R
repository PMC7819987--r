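#' Detect the multihematoma fuzzy sign
#'
#' Applies the three-criteria rule to a segmented scan:
#'
#' * **c1 (multiplicity / adjacency)** — three or more hematomas form an
#'   adjacency cluster, where two hematomas are adjacent when their nearest
#'   surface-to-surface separation does not exceed `d_max`, the largest
#'   (Feret) diameter of the cluster's largest hematoma.
#' * **c2 (blood-density corridor)** — for every adjacent pair in the
#'   cluster, the corridor between the two surfaces has a mean density above
#'   the gray/white parenchyma band but below the clot threshold: the gap is
#'   "fuzzy" liquid blood, not brain tissue.
#' * **c3 (contrast)** — the mean clot density of each adjacent pair exceeds
#'   its corridor mean by at least 20 HU.
#'
#' The sign is called positive only when all three criteria hold.  When no
#' cluster of three or more exists, c2 and c3 are reported `FALSE` alongside
#' c1 (there is no corridor to assess).
#'
#' @param vol the [CTVolume-class] the segmentation was computed from.
#' @param seg a [HematomaSegmentation-class] from [segmentHematomas()].
#' @param cfg the [segmentationConfig()]; defaults to the one stored in
#'   `seg`.
#' @param corridorRadiusVoxels in-plane radius of the sampling corridor
#'   around the nearest-surface segment, in voxels (default 2).
#' @return a [SignEvidence-class]
#' @examples
#' ph <- generatePhantom(scenarioSpec("positive", seed = 3), seed = 3)
#' ev <- detectFuzzySign(ph$volume, segmentHematomas(ph$volume))
#' signCall(ev)
#' @export
detectFuzzySign <- function(vol, seg, cfg = NULL, corridorRadiusVoxels = 2) {
  stopifnot(is(vol, "CTVolume"), is(seg, "HematomaSegmentation"))
  if (!identical(dim(vol@voxels), dim(seg@labels)))
    stop("segmentation was not derived from this volume (dimension mismatch)")
  if (is.null(cfg)) cfg <- seg@config
  cmp <- seg@components
  n <- nrow(cmp)
  emptyPairs <- data.frame(idA = integer(0), idB = integer(0),
                           separationMM = numeric(0),
                           bridgeMeanHU = numeric(0), clotMeanHU = numeric(0),
                           clotMinusBridgeHU = numeric(0))
  if (n < 3L) {
    return(new("SignEvidence", nComponents = as.integer(n),
               involvedIds = integer(0),
               separationMM = matrix(numeric(0), 0L, 0L),
               dMaxMM = if (n > 0L) cmp$feretMM[1] else NA_real_,
               pairs = emptyPairs,
               c1 = FALSE, c2 = FALSE, c3 = FALSE, sign = FALSE))
  }

  bnd <- lapply(cmp$id, function(id) {
    lin <- boundaryVoxels(seg@labels, id)
    voxelCentersMM(lin, dim(seg@labels), seg@spacing)
  })
  sepMM <- matrix(0, n, n, dimnames = list(cmp$id, cmp$id))
  closest <- vector("list", n * n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ns <- nearestSurfacePair(bnd[[i]], bnd[[j]])
      sepMM[i, j] <- sepMM[j, i] <- ns$distance
      closest[[(i - 1L) * n + j]] <- ns
    }
  }

  # adjacency graph with d_max from the overall largest component, then the
  # chosen cluster re-screened against its own largest member's diameter
  clusterFrom <- function(dMax) {
    adj <- sepMM <= dMax & !diag(TRUE, n)
    comp <- rep(0L, n); cur <- 0L
    for (s in seq_len(n)) {
      if (comp[s] > 0L) next
      cur <- cur + 1L
      queue <- s; comp[s] <- cur
      while (length(queue) > 0L) {
        v <- queue[[1]]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
    sizes <- tabulate(comp)
    if (max(sizes) < 3L) return(integer(0))
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # tie: take the cluster holding the largest component (lowest id wins)
      first <- vapply(best, function(cl) min(which(comp == cl)), integer(1))
      best <- best[which.min(first)]
    }
    which(comp == best)
  }

  members <- clusterFrom(cmp$feretMM[1])
  dMax <- cmp$feretMM[1]
  if (length(members) >= 3L) {
    dMax <- cmp$feretMM[min(members)]          # cluster's largest component
    sub <- clusterFrom(dMax)
    members <- intersect(sub, members)
  }
  c1 <- length(members) >= 3L

  pairs <- emptyPairs
  c2 <- FALSE; c3 <- FALSE
  if (c1) {
    edges <- utils::combn(sort(members), 2L)
    rows <- list()
    for (e in seq_len(ncol(edges))) {
      i <- edges[1, e]; j <- edges[2, e]
      if (sepMM[i, j] > dMax) next             # not adjacent within cluster
      ns <- closest[[(min(i, j) - 1L) * n + max(i, j)]]
      bridgeMean <- corridorMeanHU(vol, seg, ns$pointA, ns$pointB,
                                   corridorRadiusVoxels)
      clotMean <- mean(c(cmp$meanHU[i], cmp$meanHU[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        idA = i, idB = j, separationMM = sepMM[i, j],
        bridgeMeanHU = bridgeMean, clotMeanHU = clotMean,
        clotMinusBridgeHU = clotMean - bridgeMean)
    }
    pairs <- do.call(rbind, rows)
    bandHigh <- cfg$parenchymaBandHU[["high"]]
    ok <- !is.na(pairs$bridgeMeanHU)
    c2 <- all(ok) && all(pairs$bridgeMeanHU > bandHigh &
                           pairs$bridgeMeanHU < cfg$clotThresholdHU)
    c3 <- all(ok) && all(pairs$clotMinusBridgeHU >= 20)
  }

  new("SignEvidence", nComponents = as.integer(n),
      involvedIds = as.integer(sort(members)),
      separationMM = sepMM, dMaxMM = dMax, pairs = pairs,
      c1 = c1, c2 = c2, c3 = c3, sign = c1 && c2 && c3)
}

# Mean HU over the corridor: voxels within `radiusVoxels` in-plane voxel
# widths of the segment joining the two nearest surface points, excluding
# every segmented component voxel.  NA when the corridor holds no voxel.
corridorMeanHU <- function(vol, seg, p, q, radiusVoxels = 2) {
  spacing <- seg@spacing
  radius <- radiusVoxels * min(spacing[1:2])
  shape <- dim(seg@labels)
  lo <- pmax(pmin(p, q) - radius - spacing, 0)
  hi <- pmin(pmax(p, q) + radius + spacing, shape * spacing)
  ax <- lapply(1:3, function(k) {
    x <- (seq_len(shape[k]) - 0.5) * spacing[k]
    which(x >= lo[k] & x <= hi[k])
  })
  if (any(lengths(ax) == 0L)) return(NA_real_)
  grid <- expand.grid(i = ax[[1]], j = ax[[2]], k = ax[[3]])
  pts <- cbind((grid$i - 0.5) * spacing[1],
               (grid$j - 0.5) * spacing[2],
               (grid$k - 0.5) * spacing[3])
  lin <- grid$i + shape[1] * (grid$j - 1L) + shape[1] * shape[2] * (grid$k - 1L)
  sel <- distToSegment(pts, p, q) <= radius & seg@labels[lin] == 0L
  if (!any(sel)) return(NA_real_)
  mean(vol@voxels[lin[sel]])
}

#' @rdname signCall
setMethod("signCall", "SignEvidence", function(object) object@sign)

#' @rdname signCriteria
setMethod("signCriteria", "SignEvidence", function(object)
  c(c1 = object@c1, c2 = object@c2, c3 = object@c3))

setMethod("show", "SignEvidence", function(object) {
  cat(sprintf(
    "SignEvidence: %d component(s); c1=%s c2=%s c3=%s -> sign %s\n",
    object@nComponents, object@c1, object@c2, object@c3, object@sign))
  if (nrow(object@pairs) > 0L) {
    cat(sprintf("  cluster {%s}, d_max %.1f mm\n",
                paste(object@involvedIds, collapse = ","), object@dMaxMM))
    print(object@pairs, digits = 4)
  }
})

#' Write a SignEvidence record as JSON
#'
#' @param evidence a [SignEvidence-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignEvidence <- function(evidence, path) {
  out <- list(nComponents = evidence@nComponents,
              involvedIds = evidence@involvedIds,
              dMaxMM = evidence@dMaxMM,
              separationMM = evidence@separationMM,
              pairs = evidence@pairs,
              c1 = evidence@c1, c2 = evidence@c2, c3 = evidence@c3,
              sign = evidence@sign)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
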