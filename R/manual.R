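#' Anatomical-projection ROIs for the manual method
#'
#' Deterministic emulation of an operator tracing the wells on the top-5
#' slice composite: each well's ROI is the in-plane projection (logical OR
#' across the selected slices) of its label, and the striatal ROI of each
#' side is the union of that side's caudate and putamen ROIs.  Such ROIs
#' capture in-boundary counts but none of the PSF spill-out, which is the
#' mechanism behind the manual method's partial-volume underestimation.
#'
#' @param geometry a \linkS4class{PhantomGeometry}.
#' @param composite a \linkS4class{Composite2D} built from an acquisition of
#'   the same geometry.
#' @return Named list of logical ROI matrices (\code{CA_R}, \code{CA_L},
#'   \code{PU_R}, \code{PU_L}, \code{ST_R}, \code{ST_L}), each with an
#'   \code{area} attribute in mm^2.
#' @export
deriveManualRois <- function(geometry, composite) {
  lab <- labelVolume(geometry)
  sel <- sliceIndices(composite)
  pxArea <- .pixelAreaMm2(composite)
  rois <- lapply(names(.compartmentLabels), function(w) {
    m <- .projectMask(lab == .compartmentLabels[[w]], sel)
    if (!any(m))
      stop("well ", w, " lies outside the selected slices")
    m
  })
  names(rois) <- names(.compartmentLabels)
  rois$ST_R <- rois$CA_R | rois$PU_R
  rois$ST_L <- rois$CA_L | rois$PU_L
  for (nm in names(rois)) attr(rois[[nm]], "area") <- sum(rois[[nm]]) * pxArea
  rois
}

#' Low-count reference ROI for the manual method
#'
#' Reference region on the composite emulating typical posterior
#' (occipital-like) placement: shell-projection pixels restricted to the
#' posterior third of the shell projection, at least \code{marginMm}
#' (Euclidean, in-plane) from every striatal ROI pixel, and at least
#' \code{edgeMarginMm} interior to the shell-projection boundary (an
#' operator places the reference inside uniform background, clear of the
#' blurred brain edge where the apparent level falls off).
#'
#' @param composite a \linkS4class{Composite2D}.
#' @param geometry a \linkS4class{PhantomGeometry}.
#' @param marginMm exclusion distance from the striatal ROIs, mm.
#' @param edgeMarginMm interior clearance from the shell-projection edge, mm.
#' @param minPixels minimum acceptable reference size.
#' @return Logical reference mask with an \code{area} attribute (mm^2).
#' @export
referenceRoiLowcount <- function(composite, geometry, marginMm = 20,
                                 edgeMarginMm = 12, minPixels = 50L) {
  lab <- labelVolume(geometry)
  sel <- sliceIndices(composite)
  shellProj <- .projectMask(lab == .shellLabel, sel)
  striatProj <- .projectMask(striatalMask(geometry), sel)

  near <- .withinDistance(striatProj, marginMm, composite@pixelSize)
  nearEdge <- .withinDistance(!shellProj, edgeMarginMm, composite@pixelSize)
  ref <- shellProj & !striatProj & !near & !nearEdge

  ## posterior third of the shell projection (low y = posterior)
  yIdx <- col(shellProj)[shellProj]
  yCut <- min(yIdx) + (max(yIdx) - min(yIdx)) / 3
  ref <- ref & (col(ref) <= yCut)

  if (sum(ref) < minPixels)
    stop("fewer than ", minPixels, " qualifying reference pixels")
  attr(ref, "area") <- sum(ref) * .pixelAreaMm2(composite)
  ref
}

#' Binding potential index from ROI mean counts
#'
#' \code{BPI = (C_s - C_ns) / C_ns} from mean counts per pixel in the
#' specific and reference ROIs.
#'
#' @param meanSpecific mean counts per pixel in the specific ROI.
#' @param meanNonspecific mean counts per pixel in the reference ROI.
#' @return BPI (dimensionless).
#' @export
computeBpi <- function(meanSpecific, meanNonspecific) {
  if (!is.finite(meanNonspecific) || meanNonspecific <= 0)
    stop("invalid reference: mean non-specific counts must be > 0")
  (meanSpecific - meanNonspecific) / meanNonspecific
}

#' Manual-method quantification of one acquisition
#'
#' Builds the top-\code{k} composite, derives anatomical-projection ROIs and
#' the low-count reference, and reports pooled-count BPI for the caudate
#' (both sides), putamen (both sides) and striatum (all four wells).
#'
#' @param acquisition an \linkS4class{Acquisition}.
#' @param geometry the matching \linkS4class{PhantomGeometry}.
#' @param k number of composite slices.
#' @return data.frame of \code{QuantResult} rows.
#' @export
quantifyManual <- function(acquisition, geometry, k = 5L) {
  comp <- compositeTopK(acquisition, striatalMask(geometry), k = k)
  rois <- deriveManualRois(geometry, comp)
  ref <- referenceRoiLowcount(comp, geometry)
  img <- compositeImage(comp)
  meanRef <- mean(img[ref])

  pooledMean <- function(members) {
    m <- Reduce(`|`, rois[members])
    mean(img[m])
  }
  groups <- list(CA = c("CA_R", "CA_L"), PU = c("PU_R", "PU_L"),
                 ST = c("CA_R", "CA_L", "PU_R", "PU_L"))
  vols <- nominalVolumes(geometry)
  fill <- fillRecord(acquisition)
  do.call(rbind, lapply(names(groups), function(g) {
    .quantRow(acquisition, method = "manual", compartment = g,
              indexType = "BPI",
              value = computeBpi(pooledMean(groups[[g]]), meanRef),
              truthBpi = achievedBpi(fill, g, vols))
  }))
}

## One row of the study results table.
.quantRow <- function(acquisition, method, compartment, indexType, value,
                      truthBpi) {
  fill <- fillRecord(acquisition)
  data.frame(
    acquisition_id = acquisition@id,
    method = method,
    compartment = compartment,
    index_type = indexType,
    value = value,
    truth_bpi = truthBpi,
    truth_sbr = truthBpi + 1,
    nominal_ratio = fill@nominalRatio,
    activity_level = fill@activityLevel,
    stringsAsFactors = FALSE
  )
}
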