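# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Neighbourhood offsets for 6/18/26-connectivity on a 3-D grid.
connectivityOffsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1L,
                 "18" = ord >= 1L & ord <= 2L,
                 "26" = ord >= 1L)
  off[keep, , drop = FALSE]
}

# Label connected components of a logical 3-D mask.  Vectorised frontier
# BFS on linear indices: the grid is padded with one empty voxel on every
# face so neighbour offsets never wrap across rows/slices, and each sweep
# advances the whole frontier one shell, so total work is linear in the
# mask size times the neighbourhood size.
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  off <- connectivityOffsets(as.integer(connectivity))
  pd <- d + 2L
  padded <- array(FALSE, dim = pd)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  remaining <- as.logical(padded)
  loff <- as.integer(off[, 1] + pd[1] * off[, 2] + pd[1] * pd[2] * off[, 3])
  plabels <- integer(prod(pd))
  seeds <- which(remaining)
  nextLabel <- 0L
  for (s in seeds) {
    if (!remaining[s]) next
    nextLabel <- nextLabel + 1L
    frontier <- s
    plabels[s] <- nextLabel
    remaining[s] <- FALSE
    while (length(frontier) > 0L) {
      cand <- as.vector(outer(loff, frontier, "+"))
      cand <- unique(cand[remaining[cand]])
      if (length(cand) == 0L) break
      plabels[cand] <- nextLabel
      remaining[cand] <- FALSE
      frontier <- cand
    }
  }
  array(plabels, dim = pd)[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
}

# Physical (mm) coordinates of voxel centres for linear indices.
voxelCentersMM <- function(lin, dims, spacing, origin = c(0, 0, 0)) {
  ijk <- arrayInd(lin, dims)
  sweep(sweep(ijk - 0.5, 2L, spacing, "*"), 2L, origin, "+")
}

# Boundary voxels of one label: any 6-neighbour outside the label (or the
# grid).  Returns linear indices.
boundaryVoxels <- function(labels, id) {
  d <- dim(labels)
  lin <- which(labels == id)
  ijk <- arrayInd(lin, d)
  inner <- rep(TRUE, length(lin))
  for (ax in 1:3) {
    for (ds in c(-1L, 1L)) {
      nb <- ijk
      nb[, ax] <- nb[, ax] + ds
      inside <- nb[, ax] >= 1L & nb[, ax] <= d[ax]
      nbLin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      same <- inside
      same[inside] <- labels[nbLin[inside]] == id
      inner <- inner & same
    }
  }
  lin[!inner]
}

# Max pairwise distance between rows of a coordinate matrix (mm), chunked
# to bound memory.
feretDiameter <- function(coords) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  best <- 0
  step <- 1024L
  for (i0 in seq(1L, n, by = step)) {
    i1 <- min(i0 + step - 1L, n)
    blk <- coords[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(coords^2), "+") -
      2 * tcrossprod(blk, coords)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

# Minimum distance between two coordinate sets; returns the distance and the
# closest pair of points.
nearestSurfacePair <- function(a, b) {
  best <- Inf; bi <- 1L; bj <- 1L
  step <- 1024L
  nb2 <- rowSums(b^2)
  for (i0 in seq(1L, nrow(a), by = step)) {
    i1 <- min(i0 + step - 1L, nrow(a))
    blk <- a[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), nb2, "+") - 2 * tcrossprod(blk, b)
    m <- which.min(d2)
    if (d2[m] < best) {
      best <- d2[m]
      bi <- i0 + (m - 1L) %% nrow(blk)
      bj <- 1L + (m - 1L) %/% nrow(blk)
    }
  }
  list(distance = sqrt(max(best, 0)),
       pointA = a[bi, ], pointB = b[bj, ])
}

# Distance from points (rows of x) to the segment p->q.
distToSegment <- function(x, p, q) {
  v <- q - p
  len2 <- sum(v^2)
  if (len2 == 0) {
    return(sqrt(rowSums(sweep(x, 2L, p)^2)))
  }
  t <- pmin(pmax(as.vector(sweep(x, 2L, p) %*% v) / len2, 0), 1)
  proj <- cbind(p[1] + t * v[1], p[2] + t * v[2], p[3] + t * v[3])
  sqrt(rowSums((x - proj)^2))
}

# One effect-estimate row in the shape shared by all estimators.
effectRow <- function(method, oddsRatio, ciLow, ciHigh, pValue, nUsed,
                      corrected = FALSE, note = "") {
  data.frame(method = method, oddsRatio = oddsRatio, ciLow = ciLow,
             ciHigh = ciHigh, pValue = pValue, nUsed = as.integer(nUsed),
             corrected = corrected, note = note,
             stringsAsFactors = FALSE)
}
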