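#' @import methods
NULL

#' CTVolume: a 3-D grid of Hounsfield units
#'
#' The unit of image analysis: a dense 3-D array of CT attenuation values in
#' Hounsfield units (HU) together with the physical voxel spacing and origin.
#' Spacing is anisotropic by default (0.5 x 0.5 x 5 mm) to mirror routine
#' 5 mm axial head CT reconstructions.
#'
#' @slot voxels 3-D numeric array of HU values.
#' @slot spacing numeric length-3, positive voxel edge lengths in mm (x, y, z).
#' @slot origin numeric length-3, physical position (mm) of the first voxel
#'   corner.
#'
#' @seealso [CTVolume()], [readCTVolume()], [segmentHematomas()]
#' @exportClass CTVolume
setClass("CTVolume",
         representation(voxels = "array", spacing = "numeric",
                        origin = "numeric"))

setValidity("CTVolume", function(object) {
  d <- dim(object@voxels)
  if (length(d) != 3L)
    return("voxels must be a 3-D array")
  if (any(d < c(16L, 16L, 4L)))
    return("volume too small: shape must be at least 16 x 16 x 4")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be three strictly positive values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be three finite values (mm)")
  rng <- range(object@voxels)
  if (!all(is.finite(rng)))
    return("voxel values must be finite")
  if (rng[1] < -1024 || rng[2] > 3071)
    return("HU values must lie in [-1024, 3071]")
  TRUE
})

#' PhantomSpec: geometry and density plan for a synthetic CT phantom
#'
#' Describes a contusion-like phantom: ellipsoidal hyperdense blobs (acute
#' clot, 50-90 HU) on a noisy parenchymal background (~33 HU), optionally
#' joined by cylindrical "fuzzy" corridors of intermediate blood density.
#'
#' @slot shape integer length-3 grid size.
#' @slot spacing numeric length-3 voxel size (mm).
#' @slot backgroundHU mean parenchyma attenuation (HU).
#' @slot noiseSD standard deviation of additive Gaussian noise (HU).
#' @slot blobs list of lists with elements `center` (mm), `radii` (mm,
#'   semi-axes), `hu` (mean attenuation).
#' @slot bridges list of lists with elements `pair` (two blob indices),
#'   `radius` (corridor radius, mm), `hu` (mean attenuation).
#' @slot scenario one of the labels returned by [phantomScenarios()].
#'
#' @exportClass PhantomSpec
setClass("PhantomSpec",
         representation(shape = "integer", spacing = "numeric",
                        backgroundHU = "numeric", noiseSD = "numeric",
                        blobs = "list", bridges = "list",
                        scenario = "character"))

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < c(16L, 16L, 4L)))
    return("shape must be three integers, at least 16 x 16 x 4")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three strictly positive values (mm)")
  if (!object@scenario %in% phantomScenarios())
    return(sprintf("unknown scenario '%s'", object@scenario))
  if (length(object@blobs) == 0L)
    return("at least one blob is required")
  hu <- vapply(object@blobs, function(b) b$hu, numeric(1))
  if (any(hu < 50 | hu > 90))
    return("blob mean HU must lie in [50, 90] (acute clot range)")
  for (b in object@blobs) {
    if (length(b$center) != 3L || length(b$radii) != 3L || any(b$radii <= 0))
      return("each blob needs center (3 mm coords) and positive radii (3 mm)")
  }
  for (br in object@bridges) {
    if (length(br$pair) != 2L || any(br$pair < 1L) ||
        any(br$pair > length(object@blobs)) || br$pair[1] == br$pair[2])
      return("bridge pair must index two distinct blobs")
    if (br$radius <= 0)
      return("bridge radius must be positive")
    if (br$hu >= min(hu))
      return("bridge mean HU must be below the dimmest blob")
  }
  TRUE
})

#' PhantomTruth: voxel-exact ground truth for a generated phantom
#'
#' @slot blobLabels integer array; voxel value k marks blob k, 0 background.
#' @slot bridgeLabels integer array; voxel value k marks corridor k.
#' @slot blobVolumesML analytic ellipsoid volumes, (4/3) pi r1 r2 r3, in mL.
#' @slot expectedSign logical, the designed detector call.
#' @slot expectedCriteria named logical (c1, c2, c3); `expectedSign` is their
#'   conjunction.
#' @slot scenario scenario label.
#'
#' @exportClass PhantomTruth
setClass("PhantomTruth",
         representation(blobLabels = "array", bridgeLabels = "array",
                        blobVolumesML = "numeric", expectedSign = "logical",
                        expectedCriteria = "logical", scenario = "character"))

setValidity("PhantomTruth", function(object) {
  if (length(object@expectedCriteria) != 3L ||
      !identical(names(object@expectedCriteria), c("c1", "c2", "c3")))
    return("expectedCriteria must be a named logical triple (c1, c2, c3)")
  if (!identical(object@expectedSign, unname(all(object@expectedCriteria))))
    return("expectedSign must equal c1 & c2 & c3")
  if (any(object@blobVolumesML <= 0))
    return("analytic blob volumes must be positive")
  if (any(object@bridgeLabels > 0L & object@blobLabels > 0L))
    return("no bridge voxel may lie inside a blob mask")
  TRUE
})

#' HematomaSegmentation: labeled hyperdense components of one scan
#'
#' Result of threshold segmentation: a label volume plus one row of
#' morphometry per connected component (sorted by descending volume).
#'
#' @slot labels integer array, 0 = background, k = component id k.
#' @slot components data.frame with columns `id`, `nVoxels`, `volumeML`,
#'   `meanHU`, `centroidX/Y/Z` (mm) and `feretMM` (largest boundary-to-
#'   boundary distance).
#' @slot spacing voxel spacing (mm) of the source volume.
#' @slot config the [segmentationConfig()] used.
#'
#' @exportClass HematomaSegmentation
setClass("HematomaSegmentation",
         representation(labels = "array", components = "data.frame",
                        spacing = "numeric", config = "list"))

setValidity("HematomaSegmentation", function(object) {
  cmp <- object@components
  need <- c("id", "nVoxels", "volumeML", "meanHU",
            "centroidX", "centroidY", "centroidZ", "feretMM")
  if (!all(need %in% names(cmp)))
    return("components is missing morphometry columns")
  if (nrow(cmp) > 0L) {
    if (is.unsorted(rev(cmp$volumeML)))
      return("components must be sorted by descending volume")
    if (any(cmp$feretMM <= 0))
      return("Feret diameters must be positive")
  }
  TRUE
})

#' SignEvidence: audit record of the multihematoma fuzzy sign call
#'
#' Stores everything the three-criteria decision rests on: the adjacency
#' cluster, the pairwise nearest-surface separations, the reference diameter
#' d_max, and per-pair corridor densities.
#'
#' @slot nComponents number of segmented hematomas.
#' @slot involvedIds component ids forming the adjacency cluster (empty when
#'   no cluster of three or more exists).
#' @slot separationMM matrix of pairwise nearest-surface distances (mm).
#' @slot dMaxMM Feret diameter of the cluster's largest component (mm);
#'   the adjacency threshold.
#' @slot pairs data.frame of evaluated adjacent pairs: `idA`, `idB`,
#'   `separationMM`, `bridgeMeanHU`, `clotMeanHU`, `clotMinusBridgeHU`.
#' @slot c1,c2,c3 the three criteria: multiplicity/adjacency, blood-density
#'   corridor, >= 20 HU contrast.
#' @slot sign the final call, `c1 & c2 & c3`.
#'
#' @exportClass SignEvidence
setClass("SignEvidence",
         representation(nComponents = "integer", involvedIds = "integer",
                        separationMM = "matrix", dMaxMM = "numeric",
                        pairs = "data.frame",
                        c1 = "logical", c2 = "logical", c3 = "logical",
                        sign = "logical"))

setValidity("SignEvidence", function(object) {
  if (!identical(object@sign, object@c1 && object@c2 && object@c3))
    return("sign must equal c1 & c2 & c3")
  if (object@nComponents < 3L && object@c1)
    return("c1 cannot hold with fewer than three components")
  TRUE
})

#' LogisticFit: maximum-likelihood logistic regression result
#'
#' Fitted by iteratively reweighted least squares (Newton-Raphson on the
#' log-likelihood); the covariance slot is the inverse observed information
#' (Wald covariance).
#'
#' @slot coefficients named coefficient vector (including intercept if the
#'   design carries one).
#' @slot vcov Wald covariance matrix.
#' @slot logLik maximised log-likelihood.
#' @slot converged logical.
#' @slot nIter number of Newton iterations used.
#' @slot fitted fitted success probabilities.
#'
#' @exportClass LogisticFit
setClass("LogisticFit",
         representation(coefficients = "numeric", vcov = "matrix",
                        logLik = "numeric", converged = "logical",
                        nIter = "integer", fitted = "numeric"))

#' MatchedCohort: 1:1 greedy caliper matching result
#'
#' @slot pairs data.frame with columns `treated`, `control` (ids) and
#'   `psDistance` (absolute propensity-score difference).
#' @slot unmatchedTreated ids of treated subjects with no admissible control.
#' @slot caliper maximum admissible score distance.
#' @slot seed seed that fixed the greedy processing order (NA when an
#'   explicit order was supplied).
#'
#' @exportClass MatchedCohort
setClass("MatchedCohort",
         representation(pairs = "data.frame", unmatchedTreated = "vector",
                        caliper = "numeric", seed = "numeric"))

setValidity("MatchedCohort", function(object) {
  p <- object@pairs
  if (!all(c("treated", "control", "psDistance") %in% names(p)))
    return("pairs needs treated, control and psDistance columns")
  if (anyDuplicated(p$treated) || anyDuplicated(p$control))
    return("matching must be 1:1 without replacement")
  if (nrow(p) > 0L && any(p$psDistance > object@caliper + 1e-12))
    return("a pair exceeds the caliper")
  TRUE
})

#' StudyReport: full output of the matched-cohort study replica
#'
#' Analogues of the study's published displays: the selection flowchart, the
#' baseline/balance table, the effect table across adjustment schemes, the
#' sensitivity analysis restricted to patients with three or more hematomas,
#' subgroup/interaction results, and the ROC comparison of candidate
#' predictors.
#'
#' @slot eligibility data.frame of per-criterion exclusion counts.
#' @slot balance data.frame of standardized differences before/after
#'   matching.
#' @slot effects data.frame, one row per adjustment scheme.
#' @slot sensitivity data.frame, effect rows restricted to multiple
#'   (>= 3) hematomas.
#' @slot subgroups data.frame of per-level odds ratios.
#' @slot interactions data.frame of interaction Wald p-values.
#' @slot roc data.frame of AUCs with DeLong confidence intervals.
#' @slot matching list: number of pairs, unmatched treated, caliper,
#'   McNemar test.
#' @slot cohortSummary list of headline proportions (sign prevalence,
#'   expansion incidence, matched-group expansion proportions).
#'
#' @exportClass StudyReport
setClass("StudyReport",
         representation(eligibility = "data.frame", balance = "data.frame",
                        effects = "data.frame", sensitivity = "data.frame",
                        subgroups = "data.frame", interactions = "data.frame",
                        roc = "data.frame", matching = "list",
                        cohortSummary = "list"))
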