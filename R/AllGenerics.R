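#' @include AllClasses.R
NULL

#' Access the voxel array of a CTVolume
#' @param object a [CTVolume-class]
#' @return 3-D numeric array of HU values
#' @export
setGeneric("voxelData", function(object) standardGeneric("voxelData"))

#' Access the voxel spacing (mm)
#' @param object a [CTVolume-class] or [HematomaSegmentation-class]
#' @return numeric length-3
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))

#' Access the physical origin (mm)
#' @param object a [CTVolume-class]
#' @return numeric length-3
#' @export
setGeneric("voxelOrigin", function(object) standardGeneric("voxelOrigin"))

#' Component morphometry table of a segmentation
#' @param object a [HematomaSegmentation-class]
#' @return data.frame, one row per connected component, sorted by
#'   descending volume
#' @export
setGeneric("hematomaComponents",
           function(object) standardGeneric("hematomaComponents"))

#' Integer label volume of a segmentation or phantom truth
#' @param object a [HematomaSegmentation-class] or [PhantomTruth-class]
#' @return integer array (0 = background)
#' @export
setGeneric("labelMap", function(object) standardGeneric("labelMap"))

#' Final boolean call of a SignEvidence record
#' @param object a [SignEvidence-class]
#' @return logical scalar
#' @export
setGeneric("signCall", function(object) standardGeneric("signCall"))

#' The three criteria of a sign call
#' @param object a [SignEvidence-class] or [PhantomTruth-class]
#' @return named logical triple (c1, c2, c3)
#' @export
setGeneric("signCriteria", function(object) standardGeneric("signCriteria"))

#' Matched pairs of a MatchedCohort
#' @param object a [MatchedCohort-class]
#' @return data.frame with treated, control and psDistance columns
#' @export
setGeneric("matchedPairs", function(object) standardGeneric("matchedPairs"))

#' Treated subjects left unmatched
#' @param object a [MatchedCohort-class]
#' @return vector of ids
#' @export
setGeneric("unmatchedTreated",
           function(object) standardGeneric("unmatchedTreated"))

#' Effect table of a StudyReport
#' @param object a [StudyReport-class]
#' @return data.frame, one row per adjustment scheme
#' @export
setGeneric("effectTable", function(object) standardGeneric("effectTable"))

#' Balance table of a StudyReport
#' @param object a [StudyReport-class]
#' @return data.frame of standardized differences before/after matching
#' @export
setGeneric("balanceTable", function(object) standardGeneric("balanceTable"))
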