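#' Build a structural VOI set
#'
#' Produces the volume-of-interest masks a structural (MRI- or CT-based)
#' segmentation would supply: the four wells plus a posterior-shell
#' reference VOI at least \code{marginMm} from every well.  With
#' \code{provenance = "exact"} the masks equal the phantom labels; with
#' \code{"mri_like"}/\code{"ct_like"} each well receives a seeded random
#' boundary perturbation (volume error up to \code{maxVolumeError}) and the
#' whole set one shared rigid integer shift of at most one voxel per axis,
#' emulating segmentation error plus a known co-registration error.
#'
#' @param geometry a \linkS4class{PhantomGeometry}.
#' @param provenance \code{"exact"}, \code{"mri_like"} or \code{"ct_like"}.
#' @param perturbationSeed integer seed for the perturbation draws.
#' @param marginMm reference VOI clearance from the wells, mm.
#' @param maxVolumeError largest fractional volume perturbation (default
#'   0.041, the reported structural segmentation error bound).
#' @return A \linkS4class{VoiSet}.
#' @export
makeVoiSet <- function(geometry, provenance = c("exact", "mri_like",
                       "ct_like"), perturbationSeed = 1L, marginMm = 20,
                       maxVolumeError = 0.041) {
  provenance <- match.arg(provenance)
  lab <- labelVolume(geometry)
  vox <- voxelSize(geometry)
  voxML <- prod(vox) / 1000

  masks <- lapply(names(.compartmentLabels), function(w)
    lab == .compartmentLabels[[w]])
  names(masks) <- names(.compartmentLabels)

  ## posterior-shell reference VOI
  shell <- lab == .shellLabel
  near <- .withinDistance(striatalMask(geometry), marginMm, vox)
  yIdx <- which(shell, arr.ind = TRUE)[, 2]
  yCut <- min(yIdx) + (max(yIdx) - min(yIdx)) / 3
  ref <- shell & !near
  ref <- ref & (slice.index(ref, 2) <= yCut)
  if (!any(ref)) stop("empty reference VOI")
  masks$reference <- ref

  if (provenance != "exact") {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    ## distinct perturbations for the two structural modalities
    set.seed(as.integer(perturbationSeed) +
               if (provenance == "ct_like") 104729L else 0L)
    shift <- sample(-1:1, 3, replace = TRUE)
    occupied <- Reduce(`|`, masks[names(.compartmentLabels)])
    for (w in names(.compartmentLabels)) {
      masks[[w]] <- .perturbBoundary(masks[[w]], occupied,
                                     stats::runif(1, -maxVolumeError,
                                                  maxVolumeError))
      occupied <- occupied | masks[[w]]
    }
    masks <- lapply(masks, .shiftMask, shift = shift)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    ## shifting can re-introduce contact between abutting masks
    tot <- Reduce(`+`, lapply(masks[names(.compartmentLabels)],
                              function(m) m * 1L))
    if (max(tot) > 1L)
      stop("perturbation made region masks overlap; use another seed")
    if (any(vapply(masks, sum, 0) == 0))
      stop("perturbation emptied a region")
  }

  vols <- vapply(masks, function(m) sum(m) * voxML, 0)
  methods::new("VoiSet", masks = masks, volumes = vols,
               provenance = provenance,
               seed = as.integer(perturbationSeed))
}

## Random boundary add/remove reaching a target fractional volume change,
## restricted so grown voxels never enter other regions.
.perturbBoundary <- function(mask, occupied, deltaFraction) {
  n <- round(abs(deltaFraction) * sum(mask))
  if (n == 0) return(mask)
  d <- dim(mask)
  neighborOr <- function(m) {
    out <- array(FALSE, d)
    for (ax in 1:3) for (s in c(-1L, 1L)) out <- out | .shiftMask(m, {
      sh <- c(0L, 0L, 0L); sh[ax] <- s; sh
    })
    out
  }
  if (deltaFraction > 0) {
    cand <- which(neighborOr(mask) & !occupied)
  } else {
    inner <- mask & neighborOr(!mask)
    cand <- which(inner)
  }
  if (length(cand) < n) stop("perturbation exceeds available boundary voxels")
  pick <- sample(cand, n)
  mask[pick] <- deltaFraction > 0
  if (!any(mask)) stop("perturbation emptied a region")
  mask
}

## Integer-voxel translation (zero-filled borders).
.shiftMask <- function(mask, shift) {
  if (all(shift == 0L)) return(mask)
  d <- dim(mask)
  out <- array(FALSE, d)
  src <- tgt <- vector("list", 3)
  for (ax in 1:3) {
    s <- shift[ax]
    src[[ax]] <- max(1, 1 - s):min(d[ax], d[ax] - s)
    tgt[[ax]] <- max(1, 1 + s):min(d[ax], d[ax] + s)
  }
  out[tgt[[1]], tgt[[2]], tgt[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

#' Compute the geometric transfer matrix
#'
#' Entry (i, j) is the mean, over the voxels of region i, of the Gaussian-
#' blurred indicator of region j.  By default a background region (the
#' brain-shell remainder not covered by any VOI) is appended so the linear
#' model tiles the whole activity support; without it, shell activity
#' outside the reference VOI is unmodeled and biases the correction.
#'
#' @param voiSet a \linkS4class{VoiSet}.
#' @param psfFwhm Gaussian kernel FWHM in mm; a vector is applied as a
#'   sequence of convolutions.  For images produced by
#'   \code{\link{simulateSpect}} pass \code{c(psfFwhm, postFilterFwhm)} so
#'   the model kernel equals the simulation's total discrete blur.
#' @param geometry the \linkS4class{PhantomGeometry} (supplies voxel size
#'   and the shell support for the background region).
#' @param includeBackground append the shell-remainder background region.
#' @return A \linkS4class{GtmModel}.
#' @export
computeGtm <- function(voiSet, psfFwhm, geometry, includeBackground = TRUE) {
  if (any(psfFwhm < 0)) stop("psfFwhm must be >= 0")
  vox <- voxelSize(geometry)
  masks <- voiMasks(voiSet)
  if (includeBackground) {
    bg <- labelVolume(geometry) >= .shellLabel
    for (m in masks) bg <- bg & !m
    if (!any(bg)) stop("background region is empty")
    masks$background <- bg
  }
  regions <- names(masks)
  n <- length(regions)
  blurred <- lapply(masks, function(m) {
    b <- m * 1
    for (f in psfFwhm) b <- gaussianSmooth3d(b, f, vox)
    b
  })
  omega <- matrix(0, n, n, dimnames = list(regions, regions))
  for (i in seq_len(n)) {
    mi <- masks[[i]]
    for (j in seq_len(n)) omega[i, j] <- mean(blurred[[j]][mi])
  }
  kappa <- kappa(omega, exact = TRUE)
  if (kappa > 1e8)
    stop("GTM is numerically singular (condition number > 1e8)")
  methods::new("GtmModel", omega = omega, regionOrder = regions,
               psfFwhm = psfFwhm, conditionNumber = kappa)
}

#' Invert the GTM to recover regional concentrations
#'
#' Solves \code{omega \%*\% t = m} for the true regional concentrations
#' \code{t} given observed regional mean counts \code{m} (least-squares via
#' QR, which tolerates mild ill-conditioning).
#'
#' @param observedMeans numeric vector of observed regional means, in the
#'   order of \code{regionOrder(model)}.
#' @param model a \linkS4class{GtmModel}.
#' @return Named numeric vector of corrected concentrations.
#' @export
gtmCorrect <- function(observedMeans, model) {
  om <- gtmOmega(model)
  if (length(observedMeans) != nrow(om))
    stop("observedMeans length must match the GTM region order")
  t <- qr.solve(om, observedMeans)
  names(t) <- regionOrder(model)
  t
}

#' Partial-volume-corrected BPI per compartment
#'
#' \code{BPI = (t_region - t_ref) / t_ref} from GTM-corrected regional
#' concentrations; caudate, putamen and striatal values pool the per-well
#' concentrations volume-weighted before forming the ratio.
#'
#' @param corrected named corrected concentrations (from
#'   \code{\link{gtmCorrect}}).
#' @param volumes named well volumes in mL (pooling weights).
#' @param referenceName name of the reference region entry.
#' @return Named numeric BPI for CA_R, CA_L, PU_R, PU_L, CA, PU, ST.
#' @export
voiBpi <- function(corrected, volumes, referenceName = "reference") {
  tRef <- corrected[[referenceName]]
  if (!is.finite(tRef) || tRef <= 0)
    stop("corrected reference concentration must be > 0")
  wells <- names(.compartmentLabels)
  out <- (corrected[wells] - tRef) / tRef
  pool <- function(members)
    sum(corrected[members] * volumes[members]) / sum(volumes[members])
  out <- c(out,
           CA = pool(c("CA_R", "CA_L")) / tRef - 1,
           PU = pool(c("PU_R", "PU_L")) / tRef - 1,
           ST = pool(wells) / tRef - 1)
  out
}

#' Observed regional mean counts
#'
#' @param acquisition an \linkS4class{Acquisition}.
#' @param masks named list of 3-D logical masks.
#' @return Named numeric mean counts per voxel.
#' @export
regionMeans <- function(acquisition, masks) {
  counts <- countsVolume(acquisition)
  vapply(masks, function(m) mean(counts[m]), 0)
}

#' Structural-VOI quantification of one acquisition
#'
#' Regional means over the VOI masks, GTM partial-volume correction (with
#' shell-remainder background by default), and corrected BPI per
#' compartment.  The GTM kernel defaults to the acquisition's own blur
#' sequence (system PSF followed by the post-filter).
#'
#' @inheritParams quantifyManual
#' @param voiSet a \linkS4class{VoiSet}.
#' @param gtm optional precomputed \linkS4class{GtmModel} (recommended when
#'   quantifying many acquisitions of one geometry).
#' @param gtmFwhm kernel FWHM override, mm.
#' @param includeBackground see \code{\link{computeGtm}}.
#' @param method result label (defaults to the VOI provenance).
#' @return data.frame of \code{QuantResult} rows.
#' @export
quantifyVoi <- function(acquisition, geometry, voiSet, gtm = NULL,
                        gtmFwhm = NULL, includeBackground = TRUE,
                        method = NULL) {
  cfg <- acquisitionConfigOf(acquisition)
  if (is.null(gtmFwhm))
    gtmFwhm <- c(cfg@psfFwhm, cfg@postFilterFwhm)
  if (is.null(gtm))
    gtm <- computeGtm(voiSet, gtmFwhm, geometry, includeBackground)
  if (is.null(method))
    method <- switch(voiSet@provenance, exact = "voi_exact",
                     mri_like = "voi_mri_like", ct_like = "voi_ct_like")
  masks <- voiMasks(voiSet)
  if ("background" %in% regionOrder(gtm)) {
    bg <- labelVolume(geometry) >= .shellLabel
    for (m in masks) bg <- bg & !m
    masks$background <- bg
  }
  m <- regionMeans(acquisition, masks[regionOrder(gtm)])
  corrected <- gtmCorrect(m, gtm)
  bpi <- voiBpi(corrected, voiVolumes(voiSet))
  vols <- nominalVolumes(geometry)
  fill <- fillRecord(acquisition)
  do.call(rbind, lapply(c("CA", "PU", "ST"), function(g) {
    .quantRow(acquisition, method = method, compartment = g,
              indexType = "BPI", value = bpi[[g]],
              truthBpi = achievedBpi(fill, g, vols))
  }))
}
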