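#' @import methods
NULL

## Integer labels used inside the phantom label volume.
## 0 = outside, 1 = brain shell (non-specific background), 2..5 = wells.
.compartmentLabels <- c(CA_R = 2L, CA_L = 3L, PU_R = 4L, PU_L = 5L)
.shellLabel <- 1L

#' Digital striatal phantom geometry
#'
#' A voxelized label volume describing the four striatal wells (right/left
#' caudate and putamen) embedded in an ellipsoidal brain-shell compartment,
#' together with the voxel geometry and the nominal (design) volume of each
#' well.  Labels: 0 outside, 1 shell, 2 CA right, 3 CA left, 4 PU right,
#' 5 PU left.  Voxel indices are 1-based; world coordinates are mm from the
#' volume corner.
#'
#' @slot labelVolume 3-D integer array of compartment labels.
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot nominalVolumes named numeric, design volume in mL per well
#'   (names \code{CA_R}, \code{CA_L}, \code{PU_R}, \code{PU_L}).
#' @slot compartmentSpec data.frame recording the analytic shape parameters
#'   (shape, center, dimensions, fitted scale) used to voxelize each well.
#'
#' @exportClass PhantomGeometry
setClass("PhantomGeometry",
  representation(
    labelVolume = "array",
    voxelSize = "numeric",
    nominalVolumes = "numeric",
    compartmentSpec = "data.frame"
  )
)

setValidity("PhantomGeometry", function(object) {
  msg <- character()
  lv <- object@labelVolume
  if (length(dim(lv)) != 3L)
    msg <- c(msg, "labelVolume must be a 3-D array")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive mm lengths")
  if (!all(names(.compartmentLabels) %in% names(object@nominalVolumes)))
    msg <- c(msg, "nominalVolumes must name CA_R, CA_L, PU_R, PU_L")
  if (any(!(unique(as.integer(lv)) %in% 0:5)))
    msg <- c(msg, "labels must lie in 0..5")
  if (length(msg) == 0L) {
    ach <- .achievedVolumes(lv, object@voxelSize)
    nom <- object@nominalVolumes[names(.compartmentLabels)]
    if (any(is.na(ach)) || any(abs(ach - nom) / nom > 0.02))
      msg <- c(msg, "achieved well volumes deviate > 2% from nominal")
  }
  if (length(msg)) msg else TRUE
})

.achievedVolumes <- function(labelVolume, voxelSize) {
  voxML <- prod(voxelSize) / 1000
  counts <- tabulate(as.integer(labelVolume) + 1L, nbins = 6L)
  v <- counts[.compartmentLabels + 1L] * voxML
  names(v) <- names(.compartmentLabels)
  v
}

#' Ground-truth fill record for one simulated acquisition
#'
#' Stores the achieved (post-jitter) activity concentrations that play the
#' role of the aliquot measurements in a physical phantom experiment: the
#' truth every quantification method is judged against.
#'
#' @slot nominalRatio specific:non-specific design ratio (dimensionless).
#' @slot achievedConcSpecific named numeric, achieved concentration
#'   (counts/mL, arbitrary scale) per well.
#' @slot achievedConcNonspecific shell concentration (same scale).
#' @slot achievedBpi volume-weighted achieved ratio minus one.
#' @slot achievedSbr volume-weighted achieved ratio (= achievedBpi + 1).
#' @slot activityLevel one of \code{"high"} (ratios 10--8),
#'   \code{"intermediary"} (7--5), \code{"low"} (4--2).
#' @slot jitterCv lognormal fill-jitter coefficient of variation used.
#' @slot seed integer seed used for the jitter draws.
#'
#' @exportClass FillRecord
setClass("FillRecord",
  representation(
    nominalRatio = "numeric",
    achievedConcSpecific = "numeric",
    achievedConcNonspecific = "numeric",
    achievedBpi = "numeric",
    achievedSbr = "numeric",
    activityLevel = "character",
    jitterCv = "numeric",
    seed = "integer"
  )
)

setValidity("FillRecord", function(object) {
  msg <- character()
  if (abs(object@achievedSbr - (object@achievedBpi + 1)) > 1e-9)
    msg <- c(msg, "achievedSbr must equal achievedBpi + 1")
  if (!object@activityLevel %in% c("high", "intermediary", "low"))
    msg <- c(msg, "activityLevel must be high/intermediary/low")
  if (object@activityLevel != .activityLevel(object@nominalRatio))
    msg <- c(msg, "activityLevel inconsistent with nominalRatio")
  if (length(msg)) msg else TRUE
})

.activityLevel <- function(ratio) {
  if (ratio >= 8) "high" else if (ratio >= 5) "intermediary" else "low"
}

#' Acquisition simulation settings
#'
#' @slot psfFwhm system resolution surrogate, Gaussian FWHM in mm.
#' @slot expectedTotalCounts expected total counts in the volume before
#'   Poisson sampling.
#' @slot postFilterFwhm Gaussian post-reconstruction filter FWHM in mm.
#' @slot matrixSize integer(3) voxel grid dimensions.
#' @slot voxelSize numeric(3) voxel edge lengths in mm.
#' @slot seed integer seed for the Poisson noise draw.
#' @slot noiseless logical; skip the Poisson step (expectation image).
#'
#' @exportClass AcquisitionConfig
setClass("AcquisitionConfig",
  representation(
    psfFwhm = "numeric",
    expectedTotalCounts = "numeric",
    postFilterFwhm = "numeric",
    matrixSize = "integer",
    voxelSize = "numeric",
    seed = "integer",
    noiseless = "logical"
  )
)

setValidity("AcquisitionConfig", function(object) {
  msg <- character()
  if (object@psfFwhm < 0) msg <- c(msg, "psfFwhm must be >= 0")
  if (object@postFilterFwhm < 0) msg <- c(msg, "postFilterFwhm must be >= 0")
  if (object@expectedTotalCounts <= 0)
    msg <- c(msg, "expectedTotalCounts must be > 0")
  if (length(object@matrixSize) != 3L || any(object@matrixSize < 8L))
    msg <- c(msg, "matrixSize must be three dimensions >= 8")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive mm lengths")
  if (length(msg)) msg else TRUE
})

#' One simulated SPECT acquisition
#'
#' @slot countsVolume 3-D non-negative array of (post-filtered, hence
#'   real-valued) counts.
#' @slot fill the \linkS4class{FillRecord} ground truth.
#' @slot config the \linkS4class{AcquisitionConfig} used.
#' @slot id acquisition identifier.
#'
#' @exportClass Acquisition
setClass("Acquisition",
  representation(
    countsVolume = "array",
    fill = "FillRecord",
    config = "AcquisitionConfig",
    id = "character"
  )
)

setValidity("Acquisition", function(object) {
  cv <- object@countsVolume
  if (length(dim(cv)) != 3L) return("countsVolume must be 3-D")
  if (any(!is.finite(cv)) || any(cv < 0))
    return("countsVolume must be finite and non-negative")
  TRUE
})

#' Summed transaxial composite image (CI-2D)
#'
#' @slot image 2-D matrix of summed counts.
#' @slot sliceIndices 1-based axial indices of the summed slices.
#' @slot pixelSize numeric(2) in-plane pixel size in mm.
#' @slot sliceThickness axial slice thickness in mm.
#'
#' @exportClass Composite2D
setClass("Composite2D",
  representation(
    image = "matrix",
    sliceIndices = "integer",
    pixelSize = "numeric",
    sliceThickness = "numeric"
  )
)

setValidity("Composite2D", function(object) {
  msg <- character()
  if (length(object@sliceIndices) < 1L)
    msg <- c(msg, "at least one slice must be summed")
  if (length(object@pixelSize) != 2L || any(object@pixelSize <= 0))
    msg <- c(msg, "pixelSize must be two positive mm lengths")
  if (object@sliceThickness <= 0)
    msg <- c(msg, "sliceThickness must be > 0")
  if (length(msg)) msg else TRUE
})

#' Structural volume-of-interest set
#'
#' Masks for the four wells plus a posterior-shell reference region, as a
#' structural segmentation would supply them.  \code{exact} masks equal the
#' phantom labels; \code{mri_like}/\code{ct_like} add a seeded boundary
#' perturbation (volume error up to 4.1\%) and one shared rigid shift of at
#' most one voxel per axis, emulating segmentation plus co-registration
#' error.
#'
#' @slot masks named list of 3-D logical arrays
#'   (\code{CA_R}, \code{CA_L}, \code{PU_R}, \code{PU_L}, \code{reference}).
#' @slot volumes named numeric, mask volumes in mL.
#' @slot provenance \code{"exact"}, \code{"mri_like"} or \code{"ct_like"}.
#' @slot seed integer perturbation seed.
#'
#' @exportClass VoiSet
setClass("VoiSet",
  representation(
    masks = "list",
    volumes = "numeric",
    provenance = "character",
    seed = "integer"
  )
)

setValidity("VoiSet", function(object) {
  msg <- character()
  need <- c(names(.compartmentLabels), "reference")
  if (!all(need %in% names(object@masks)))
    msg <- c(msg, "masks must name CA_R, CA_L, PU_R, PU_L, reference")
  if (!object@provenance %in% c("exact", "mri_like", "ct_like"))
    msg <- c(msg, "provenance must be exact/mri_like/ct_like")
  if (length(msg) == 0L) {
    tot <- Reduce(`+`, lapply(object@masks[need], function(m) m * 1L))
    if (max(tot) > 1L) msg <- c(msg, "region masks must be pairwise disjoint")
    if (any(vapply(object@masks[need], sum, 0) == 0))
      msg <- c(msg, "all region masks must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Geometric transfer matrix model
#'
#' Matrix of regional cross-contamination fractions: entry (i, j) is the
#' mean, over voxels of region i, of the PSF-blurred indicator of region j.
#' Inverting it recovers partial-volume-corrected regional concentrations.
#'
#' @slot omega square numeric matrix of transfer coefficients.
#' @slot regionOrder character, region names in matrix order.
#' @slot psfFwhm mm FWHM of the Gaussian kernel used.
#' @slot conditionNumber 2-norm condition number of \code{omega}.
#'
#' @exportClass GtmModel
setClass("GtmModel",
  representation(
    omega = "matrix",
    regionOrder = "character",
    psfFwhm = "numeric",
    conditionNumber = "numeric"
  )
)

setValidity("GtmModel", function(object) {
  om <- object@omega
  msg <- character()
  if (nrow(om) != ncol(om)) msg <- c(msg, "omega must be square")
  if (length(object@regionOrder) != nrow(om))
    msg <- c(msg, "regionOrder length must match omega")
  if (any(om < -1e-9) || any(om > 1 + 1e-6))
    msg <- c(msg, "omega entries must lie in [0, 1]")
  if (any(rowSums(om) > 1 + 1e-6))
    msg <- c(msg, "omega row sums must not exceed 1")
  if (length(msg)) msg else TRUE
})

#' Full study configuration
#'
#' @slot design data.frame with columns \code{ratio}, \code{replicates}.
#' @slot acquisition an \linkS4class{AcquisitionConfig}.
#' @slot jitterCv lognormal fill-jitter CV.
#' @slot masterSeed integer master seed for the whole study.
#' @slot methods character, methods to run.
#' @slot sbrTruth \code{"bpi"} or \code{"sbr"}: truth axis for TwoBox SBR.
#' @slot outputDir output directory for \code{runStudy}.
#' @slot writeVolumes logical, write per-acquisition NIfTI volumes.
#'
#' @exportClass StudyConfig
setClass("StudyConfig",
  representation(
    design = "data.frame",
    acquisition = "AcquisitionConfig",
    jitterCv = "numeric",
    masterSeed = "integer",
    methods = "character",
    sbrTruth = "character",
    outputDir = "character",
    writeVolumes = "logical"
  )
)

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (!all(c("ratio", "replicates") %in% names(object@design)))
    msg <- c(msg, "design needs columns ratio, replicates")
  if (nrow(object@design) == 0L) msg <- c(msg, "design must be non-empty")
  if (!object@sbrTruth %in% c("bpi", "sbr"))
    msg <- c(msg, "sbrTruth must be 'bpi' or 'sbr'")
  if (object@jitterCv < 0 || object@jitterCv >= 0.5)
    msg <- c(msg, "jitterCv must lie in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PhantomGeometry", function(object) {
  ach <- .achievedVolumes(object@labelVolume, object@voxelSize)
  cat("PhantomGeometry:", paste(dim(object@labelVolume), collapse = " x "),
      "voxels @", paste(signif(object@voxelSize, 4), collapse = " x "), "mm\n")
  cat("  wells (achieved mL):",
      paste(sprintf("%s=%.2f", names(ach), ach), collapse = ", "), "\n")
  cat("  shell voxels:", sum(object@labelVolume == .shellLabel), "\n")
})

setMethod("show", "Acquisition", function(object) {
  cat("Acquisition", object@id, "- ratio",
      object@fill@nominalRatio, sprintf("(%s)", object@fill@activityLevel),
      "\n  total counts:", round(sum(object@countsVolume)),
      "| achieved BPI:", signif(object@fill@achievedBpi, 4), "\n")
})

setMethod("show", "Composite2D", function(object) {
  cat("Composite2D:", nrow(object@image), "x", ncol(object@image),
      "pixels, n_slices =", length(object@sliceIndices),
      sprintf("(%.1f mm effective thickness)\n",
              length(object@sliceIndices) * object@sliceThickness))
})

setMethod("show", "GtmModel", function(object) {
  cat("GtmModel over", length(object@regionOrder), "regions, PSF FWHM",
      object@psfFwhm, "mm, condition number",
      signif(object@conditionNumber, 4), "\n")
  print(round(object@omega, 4))
})

setMethod("show", "VoiSet", function(object) {
  cat("VoiSet (", object@provenance, "): ",
      paste(sprintf("%s=%.2f mL", names(object@volumes), object@volumes),
            collapse = ", "), "\n", sep = "")
})
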