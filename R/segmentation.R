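#' Segmentation configuration
#'
#' Parameters of the fixed-threshold hematoma segmentation and of the sign
#' detector's density bands.  The 50 HU clot threshold is the conventional
#' lower bound of acute clotted blood; the 20-40 HU band brackets normal
#' gray/white parenchyma, so a corridor whose mean falls inside it is tissue,
#' not blood.
#'
#' @param clotThresholdHU voxels at or above this are clot (default 50).
#' @param parenchymaBandHU `c(low, high)` gray/white band (default 20-40).
#' @param minComponentML discard components below this volume; suppresses
#'   noise speckles (default 0.1 mL).
#' @param connectivity 6, 18 or 26 neighbourhood (default 26).
#' @return a named list of class `segmentationConfig`
#' @export
segmentationConfig <- function(clotThresholdHU = 50,
                               parenchymaBandHU = c(low = 20, high = 40),
                               minComponentML = 0.1,
                               connectivity = 26L) {
  if (clotThresholdHU <= parenchymaBandHU[[2]])
    stop("clot threshold must exceed the top of the parenchyma band")
  if (minComponentML <= 0)
    stop("minComponentML must be positive")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  structure(list(clotThresholdHU = clotThresholdHU,
                 parenchymaBandHU = c(low = parenchymaBandHU[[1]],
                                      high = parenchymaBandHU[[2]]),
                 minComponentML = minComponentML,
                 connectivity = as.integer(connectivity)),
            class = c("segmentationConfig", "list"))
}

#' Segment hyperdense hematomas by fixed HU threshold
#'
#' Voxels with HU at or above the clot threshold are grouped into maximal
#' connected components; components smaller than `minComponentML` are
#' discarded.  Volumes are voxel counts times the voxel volume.  Components
#' are returned sorted by descending volume (ties broken by higher mean HU,
#' then lower label).
#'
#' @param vol a [CTVolume-class].
#' @param cfg a [segmentationConfig()].
#' @return a [HematomaSegmentation-class]; zero components is a valid result
#'   (empty table), not an error.
#' @examples
#' ph <- generatePhantom(scenarioSpec("single_blob", seed = 2), seed = 2)
#' seg <- segmentHematomas(ph$volume)
#' hematomaComponents(seg)$volumeML
#' @export
segmentHematomas <- function(vol, cfg = segmentationConfig()) {
  stopifnot(is(vol, "CTVolume"))
  validObject(vol)
  mask <- vol@voxels >= cfg$clotThresholdHU
  raw <- labelComponents(mask, cfg$connectivity)
  voxML <- prod(vol@spacing) / 1000
  ids <- sort(unique(raw[raw > 0L]))
  if (length(ids) == 0L) {
    return(new("HematomaSegmentation", labels = raw,
               components = emptyComponentTable(),
               spacing = vol@spacing, config = unclass(cfg)))
  }
  counts <- tabulate(raw[raw > 0L], nbins = max(ids))
  keep <- ids[counts[ids] * voxML >= cfg$minComponentML]
  if (length(keep) == 0L) {
    return(new("HematomaSegmentation", labels = array(0L, dim(raw)),
               components = emptyComponentTable(),
               spacing = vol@spacing, config = unclass(cfg)))
  }
  stats_ <- lapply(keep, function(id) {
    lin <- which(raw == id)
    xyz <- voxelCentersMM(lin, dim(raw), vol@spacing, vol@origin)
    bnd <- boundaryVoxels(raw, id)
    bxyz <- voxelCentersMM(bnd, dim(raw), vol@spacing, vol@origin)
    data.frame(rawId = id, nVoxels = length(lin),
               volumeML = length(lin) * voxML,
               meanHU = mean(vol@voxels[lin]),
               centroidX = mean(xyz[, 1]), centroidY = mean(xyz[, 2]),
               centroidZ = mean(xyz[, 3]),
               feretMM = feretDiameter(bxyz))
  })
  cmp <- do.call(rbind, stats_)
  ord <- order(-cmp$volumeML, -cmp$meanHU, cmp$rawId)
  cmp <- cmp[ord, , drop = FALSE]
  cmp$id <- seq_len(nrow(cmp))
  rownames(cmp) <- NULL
  # relabel the map so label k is component id k (volume rank order)
  labels <- array(0L, dim(raw))
  for (k in seq_len(nrow(cmp)))
    labels[raw == cmp$rawId[k]] <- k
  cmp$rawId <- NULL
  cmp <- cmp[, c("id", "nVoxels", "volumeML", "meanHU",
                 "centroidX", "centroidY", "centroidZ", "feretMM")]
  new("HematomaSegmentation", labels = labels, components = cmp,
      spacing = vol@spacing, config = unclass(cfg))
}

emptyComponentTable <- function() {
  data.frame(id = integer(0), nVoxels = integer(0), volumeML = numeric(0),
             meanHU = numeric(0), centroidX = numeric(0),
             centroidY = numeric(0), centroidZ = numeric(0),
             feretMM = numeric(0))
}

#' @rdname hematomaComponents
setMethod("hematomaComponents", "HematomaSegmentation",
          function(object) object@components)

#' @rdname labelMap
setMethod("labelMap", "HematomaSegmentation", function(object) object@labels)

#' @rdname voxelSpacing
setMethod("voxelSpacing", "HematomaSegmentation",
          function(object) object@spacing)

setMethod("show", "HematomaSegmentation", function(object) {
  cat(sprintf("HematomaSegmentation: %d component(s) at threshold %.0f HU\n",
              nrow(object@components), object@config$clotThresholdHU))
  if (nrow(object@components) > 0L)
    print(utils::head(object@components, 10L), digits = 4)
})

#' Total hematoma volume of one scan
#'
#' When multiple hematomas are present in the contusion region the total
#' volume is the relevant quantity; an empty segmentation totals 0 mL.
#'
#' @param seg a [HematomaSegmentation-class] or the component data.frame.
#' @return total volume in mL
#' @export
totalHematomaVolume <- function(seg) {
  cmp <- if (is(seg, "HematomaSegmentation")) seg@components else seg
  if (nrow(cmp) == 0L) return(0)
  sum(cmp$volumeML)
}
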