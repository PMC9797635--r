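## Per-slice counts restricted to a 3-D mask.
.sliceCountsInMask <- function(counts, mask) {
  d <- dim(counts)
  colSums(matrix(counts * mask, nrow = d[1] * d[2], ncol = d[3]))
}

.makeComposite <- function(acquisition, sel) {
  counts <- countsVolume(acquisition)
  img <- rowSums(counts[, , sel, drop = FALSE], dims = 2L)
  vox <- voxelSize(acquisitionConfigOf(acquisition))
  methods::new("Composite2D", image = img, sliceIndices = as.integer(sel),
               pixelSize = vox[1:2], sliceThickness = vox[3])
}

#' Composite image from the k highest-count striatal slices
#'
#' Ranks axial slices by their counts inside the striatal mask and sums the
#' top \code{k} (ties broken toward the lower slice index).  This is the
#' composite the manual ROI method is drawn on (default k = 5).
#'
#' @param acquisition an \linkS4class{Acquisition}.
#' @param mask 3-D logical striatal mask (e.g. \code{\link{striatalMask}}).
#' @param k number of slices to sum.
#' @return A \linkS4class{Composite2D}.
#' @export
compositeTopK <- function(acquisition, mask, k = 5L) {
  if (!any(mask)) stop("striatal mask is empty")
  sc <- .sliceCountsInMask(countsVolume(acquisition), mask)
  k <- as.integer(k)
  if (k < 1L || k > length(sc)) stop("k must lie in 1..number of slices")
  sel <- sort(order(-sc, seq_along(sc))[seq_len(k)])
  .makeComposite(acquisition, sel)
}

#' Composite image from all striatal slices
#'
#' Sums every axial slice whose striatal-mask counts exceed
#' \code{thresholdFraction} of the maximum per-slice striatal counts --
#' the operational stand-in for an expert selecting "all cross-sections of
#' the striatum".  This is the composite used by the TwoBox and ThreeBox
#' template methods.
#'
#' @inheritParams compositeTopK
#' @param thresholdFraction fraction of the per-slice maximum (in (0, 1)).
#' @return A \linkS4class{Composite2D}.
#' @export
compositeAllStriatal <- function(acquisition, mask, thresholdFraction = 0.05) {
  if (!any(mask)) stop("striatal mask is empty")
  if (thresholdFraction <= 0 || thresholdFraction >= 1)
    stop("thresholdFraction must lie in (0, 1)")
  sc <- .sliceCountsInMask(countsVolume(acquisition), mask)
  if (max(sc) <= 0) stop("no striatal counts in any slice")
  sel <- which(sc > thresholdFraction * max(sc))
  if (length(sel) == 0L) stop("no slice passes the striatal threshold")
  .makeComposite(acquisition, sel)
}

## In-plane projection (logical OR across the composite's slices) of a
## 3-D mask.
.projectMask <- function(mask3d, sel) {
  rowSums(mask3d[, , sel, drop = FALSE], dims = 2L) > 0
}

## Pixel area (mm^2) and represented per-pixel volume (mL) of a composite.
.pixelAreaMm2 <- function(composite) prod(composite@pixelSize)
.effectiveThicknessMm <- function(composite)
  length(composite@sliceIndices) * composite@sliceThickness
.pixelVolumeMl <- function(composite)
  .pixelAreaMm2(composite) * .effectiveThicknessMm(composite) / 1000
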