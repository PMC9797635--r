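## Pixel-center world coordinates (mm) of a composite image.
.compositeCoords <- function(composite) {
  d <- dim(composite@image)
  list(x = (seq_len(d[1]) - 0.5) * composite@pixelSize[1],
       y = (seq_len(d[2]) - 0.5) * composite@pixelSize[2])
}

## Count-weighted striatal centroid per side, and the midline, in mm.
.sideCentroids <- function(composite, geometry) {
  proj <- .projectMask(striatalMask(geometry), sliceIndices(composite))
  co <- .compositeCoords(composite)
  mid <- dim(composite@image)[1] * composite@pixelSize[1] / 2
  w <- composite@image * proj
  X <- matrix(co$x, nrow = length(co$x), ncol = length(co$y))
  Y <- matrix(co$y, nrow = length(co$x), ncol = length(co$y), byrow = TRUE)
  cen <- function(sideMask) {
    ws <- w * sideMask
    c(x = sum(X * ws) / sum(ws), y = sum(Y * ws) / sum(ws))
  }
  list(R = cen(X > mid), L = cen(X <= mid), mid = mid)
}

## Symmetrize per-side centers about the midline (to within one pixel).
.symmetrizeCenters <- function(centroids) {
  off <- (abs(centroids$R[["x"]] - centroids$mid) +
          abs(centroids$L[["x"]] - centroids$mid)) / 2
  yc <- (centroids$R[["y"]] + centroids$L[["y"]]) / 2
  list(R = c(x = centroids$mid + off, y = yc),
       L = c(x = centroids$mid - off, y = yc))
}

.templateMask <- function(composite, center, boxMm, shape = c("trapezoid",
                          "rectangle"), side = c("R", "L"), topRatio = 0.7) {
  shape <- match.arg(shape)
  side <- match.arg(side)
  co <- .compositeCoords(composite)
  halfX <- boxMm[2] / 2   # medio-lateral half-extent
  halfY <- boxMm[1] / 2   # anterior-posterior half-extent
  if (center[["x"]] - halfX < 0 || center[["x"]] + halfX > max(co$x) + 0.5 ||
      center[["y"]] - halfY < 0 || center[["y"]] + halfY > max(co$y) + 0.5)
    stop("template leaves the composite image bounds")
  dx <- matrix(co$x - center[["x"]], length(co$x), length(co$y))
  dy <- matrix(co$y - center[["y"]], length(co$x), length(co$y), byrow = TRUE)
  if (shape == "rectangle") {
    mask <- abs(dx) <= halfX & abs(dy) <= halfY
  } else {
    ## isosceles trapezoid: parallel sides run anterior-posterior, the wider
    ## side (full boxMm[1]) lies lateral, the medial side is topRatio of it
    lat <- if (side == "R") dx else -dx
    halfYAt <- halfY * (topRatio + (1 - topRatio) * (lat + halfX) /
                          (2 * halfX))
    mask <- abs(dx) <= halfX & abs(dy) <= halfYAt
  }
  attr(mask, "area") <- sum(mask) * .pixelAreaMm2(composite)
  attr(mask, "volume") <- sum(mask) * .pixelVolumeMl(composite)
  attr(mask, "center") <- center
  mask
}

#' Place the TwoBox trapezoidal striatal templates
#'
#' Two isosceles trapezoids (parallel sides oriented anterior-posterior,
#' wider side lateral, bounding box 44.8 x 38.4 mm) centered on the
#' per-side striatal count centroids, symmetrized about the midline.
#'
#' @param composite a \linkS4class{Composite2D}.
#' @param centers list with elements \code{R} and \code{L}, each a named
#'   numeric \code{c(x=, y=)} center in mm.
#' @param boxMm bounding box, c(anterior-posterior, medio-lateral) mm.
#' @param topRatio medial/lateral parallel-side length ratio.
#' @return list of two logical template masks (\code{R}, \code{L}) with
#'   \code{area} (mm^2) and \code{volume} (mL) attributes.
#' @export
placeStriatalTemplates <- function(composite, centers,
                                   boxMm = c(44.8, 38.4), topRatio = 0.7) {
  tplR <- .templateMask(composite, centers$R, boxMm, "trapezoid", "R",
                        topRatio)
  tplL <- .templateMask(composite, centers$L, boxMm, "trapezoid", "L",
                        topRatio)
  if (any(tplR & tplL)) stop("striatal templates overlap")
  list(R = tplR, L = tplL)
}

#' Semi-automated TwoBox reference region
#'
#' Reference pipeline on the composite: (1) zero the two striatal template
#' regions (intrinsic binary mask); (2) smooth the remainder with a 3 x 3
#' uniform mean filter applied three times; (3) keep pixels at or above
#' 50\% of the smoothed remainder's maximum, minus any template overlap.
#' The non-specific level is measured on the original (unsmoothed)
#' composite over that mask, so smoothing defines geometry only.
#'
#' Striatal counts spilling over the template borders form a bright ring
#' around the zeroed regions whose intensity scales with the fill contrast;
#' were the ring allowed to set the threshold level, the reference would
#' become contrast-dependent.  Pixels within \code{spillMarginMm} of the
#' templates (about one system PSF width) are therefore excluded from both
#' the threshold maximum and the final mask, keeping the reference inside
#' genuinely non-specific background.
#'
#' @param composite a \linkS4class{Composite2D}.
#' @param templates list of the two striatal template masks.
#' @param threshold fraction of the smoothed maximum (default 0.5).
#' @param spillMarginMm exclusion margin around the templates, mm.
#' @return list with \code{mask}, \code{meanCounts} (counts/pixel) and
#'   \code{concentration} (counts/mL of represented volume).
#' @export
twoboxReference <- function(composite, templates, threshold = 0.5,
                            spillMarginMm = 11) {
  img <- compositeImage(composite)
  tpl <- templates$R | templates$L
  excl <- if (spillMarginMm > 0)
    .withinDistance(tpl, spillMarginMm, composite@pixelSize) else tpl
  rem <- img
  rem[excl] <- 0
  sm <- rem
  for (i in 1:3) sm <- .meanFilter3x3(sm)
  mask <- sm >= threshold * max(sm)
  mask <- mask & !excl
  if (!any(mask)) stop("empty TwoBox reference mask")
  meanCounts <- mean(img[mask])
  list(mask = mask, meanCounts = meanCounts,
       concentration = meanCounts / .pixelVolumeMl(composite))
}

#' TwoBox specific binding ratio
#'
#' \code{SBR = (1 / V_ST) * (Ct_ROI / c_ns - V_ROI)}: total template counts
#' are converted to the volume of background-equivalent activity and the
#' known striatal volume is used as the weighting factor.  Under exact
#' capture of the specific counts this returns the achieved concentration
#' ratio minus one.
#'
#' @param totalCountsRoi total counts inside the striatal template.
#' @param cNs non-specific concentration, counts/mL.
#' @param vSt known striatal compartment volume, mL.
#' @param vRoi template volume (area x composite thickness), mL.
#' @return SBR (dimensionless).
#' @export
twoboxSbr <- function(totalCountsRoi, cNs, vSt, vRoi) {
  if (!is.finite(cNs) || cNs <= 0) stop("c_ns must be > 0")
  if (vSt <= 0) stop("V_ST must be > 0")
  if (vRoi < vSt) stop("template volume smaller than the target volume")
  (totalCountsRoi / cNs - vRoi) / vSt
}

#' TwoBox quantification of one acquisition
#'
#' All-striatal-slice composite, trapezoidal templates on the symmetrized
#' per-side striatal centroids, mask/smooth/threshold reference, and per-
#' side SBR pooled into a volume-weighted striatal value.
#'
#' @inheritParams quantifyManual
#' @param thresholdFraction slice-selection threshold for the composite.
#' @return data.frame of \code{QuantResult} rows.
#' @export
quantifyTwoBox <- function(acquisition, geometry, thresholdFraction = 0.05) {
  comp <- compositeAllStriatal(acquisition, striatalMask(geometry),
                               thresholdFraction)
  centers <- .symmetrizeCenters(.sideCentroids(comp, geometry))
  tpl <- placeStriatalTemplates(comp, centers)
  ref <- twoboxReference(comp, tpl)
  img <- compositeImage(comp)
  vols <- nominalVolumes(geometry)
  vSt <- c(R = sum(vols[c("CA_R", "PU_R")]), L = sum(vols[c("CA_L", "PU_L")]))
  sbr <- vapply(c("R", "L"), function(s) {
    twoboxSbr(sum(img[tpl[[s]]]), ref$concentration, vSt[[s]],
              attr(tpl[[s]], "volume"))
  }, 0)
  pooled <- sum(sbr * vSt) / sum(vSt)
  fill <- fillRecord(acquisition)
  .quantRow(acquisition, method = "twobox", compartment = "ST",
            indexType = "SBR", value = pooled,
            truthBpi = achievedBpi(fill, "ST", vols))
}

#' ThreeBox striatal and reference rectangles
#'
#' Per side, one rectangle (default 44.8 x 38.4 mm) centered on the
#' striatal count centroid to delimit the maximum count density, and a
#' reference rectangle of identical area placed immediately posterior
#' (adjacent, non-overlapping).
#'
#' @inheritParams placeStriatalTemplates
#' @return list with \code{striatal} and \code{reference}, each a list of
#'   the \code{R}/\code{L} logical masks.
#' @export
threeboxRois <- function(composite, centers, boxMm = c(44.8, 38.4)) {
  mk <- function(center, side) {
    st <- .templateMask(composite, center, boxMm, "rectangle", side)
    refCenter <- c(x = center[["x"]], y = center[["y"]] - boxMm[1])
    rf <- .templateMask(composite, refCenter, boxMm, "rectangle", side)
    list(striatal = st, reference = rf)
  }
  r <- mk(centers$R, "R")
  l <- mk(centers$L, "L")
  list(striatal = list(R = r$striatal, L = l$striatal),
       reference = list(R = r$reference, L = l$reference))
}

#' ThreeBox total binding potential index
#'
#' \code{TBPI = (1 / V_ST) * (Ct_ROI - c_ns * V_ns) / (c_ns * V_ns)}, the
#' excess counts in the striatal rectangle relative to the background
#' counts predicted from the posterior reference rectangle, weighted by the
#' known striatal volume.  Note the printed index has units of 1/mL; it is
#' conventionally reported multiplied by 100 ("TBPI \%").
#'
#' @param totalCountsRoi total counts inside the striatal rectangle.
#' @param cNs non-specific concentration, counts/mL.
#' @param vNs reference-predicted background volume
#'   (rectangle area x composite thickness), mL.
#' @param vSt known striatal compartment volume, mL.
#' @return TBPI (1/mL; multiply by 100 for the percentage form).
#' @export
threeboxTbpi <- function(totalCountsRoi, cNs, vNs, vSt) {
  if (!is.finite(cNs) || cNs <= 0 || vNs <= 0 || cNs * vNs <= 0)
    stop("background term c_ns * V_ns must be > 0")
  if (vSt <= 0) stop("V_ST must be > 0")
  ((totalCountsRoi - cNs * vNs) / (cNs * vNs)) / vSt
}

#' ThreeBox quantification of one acquisition
#'
#' All-striatal-slice composite, per-side rectangles with posterior
#' same-area reference rectangles, per-side TBPI pooled volume-weighted and
#' reported as a percentage.
#'
#' @inheritParams quantifyTwoBox
#' @return data.frame of \code{QuantResult} rows.
#' @export
quantifyThreeBox <- function(acquisition, geometry, thresholdFraction = 0.05) {
  comp <- compositeAllStriatal(acquisition, striatalMask(geometry),
                               thresholdFraction)
  centers <- .symmetrizeCenters(.sideCentroids(comp, geometry))
  rois <- threeboxRois(comp, centers)
  img <- compositeImage(comp)
  pxVol <- .pixelVolumeMl(comp)
  vols <- nominalVolumes(geometry)
  vSt <- c(R = sum(vols[c("CA_R", "PU_R")]), L = sum(vols[c("CA_L", "PU_L")]))
  tbpi <- vapply(c("R", "L"), function(s) {
    cNs <- mean(img[rois$reference[[s]]]) / pxVol
    vNs <- sum(rois$reference[[s]]) * pxVol
    threeboxTbpi(sum(img[rois$striatal[[s]]]), cNs, vNs, vSt[[s]])
  }, 0)
  pooled <- 100 * sum(tbpi * vSt) / sum(vSt)
  fill <- fillRecord(acquisition)
  .quantRow(acquisition, method = "threebox", compartment = "ST",
            indexType = "TBPI", value = pooled,
            truthBpi = achievedBpi(fill, "ST", vols))
}
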