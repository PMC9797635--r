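#' Acquisition simulation settings
#'
#' Constructor for \linkS4class{AcquisitionConfig}.  The defaults describe
#' the surrogate acquisition chain: an 11 mm FWHM stationary Gaussian system
#' PSF (typical of an LEHR collimator at a 20 cm rotation radius), Poisson
#' counting noise scaled to 3e6 expected total counts, and a 6 mm FWHM
#' Gaussian post-filter, on a 128 x 128 matrix of 2.13 mm pixels.
#'
#' @param psfFwhm system PSF FWHM in mm.
#' @param expectedTotalCounts expected total counts per acquisition.
#' @param postFilterFwhm post-filter FWHM in mm.
#' @param matrixSize integer(3) grid dimensions.
#' @param voxelSize voxel edge length in mm (scalar or numeric(3)).
#' @param seed integer Poisson seed (set per acquisition by
#'   \code{\link{generateStudy}}).
#' @param noiseless skip the Poisson step and keep the expectation image.
#' @return An \linkS4class{AcquisitionConfig}.
#' @export
acquisitionConfig <- function(psfFwhm = 11, expectedTotalCounts = 3e6,
                              postFilterFwhm = 6,
                              matrixSize = c(128L, 128L, 80L),
                              voxelSize = 2.13, seed = 1L,
                              noiseless = FALSE) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  methods::new("AcquisitionConfig",
    psfFwhm = psfFwhm,
    expectedTotalCounts = expectedTotalCounts,
    postFilterFwhm = postFilterFwhm,
    matrixSize = as.integer(matrixSize),
    voxelSize = voxelSize,
    seed = as.integer(seed),
    noiseless = noiseless)
}

#' Simulate one SPECT acquisition
#'
#' Surrogate for the acquisition/reconstruction chain: the activity map is
#' convolved with a count-preserving Gaussian system PSF, rescaled so the
#' expected image sums to \code{expectedTotalCounts}, sampled voxel-wise
#' from independent Poisson distributions (unless \code{noiseless}), and
#' finally smoothed with a count-preserving Gaussian post-filter.  Counts
#' are real-valued after post-filtering.
#'
#' @param activity 3-D non-negative concentration array (as from
#'   \code{\link{fillActivities}}).
#' @param config an \linkS4class{AcquisitionConfig}.
#' @param fill the matching \linkS4class{FillRecord} ground truth.
#' @param id acquisition identifier.
#' @return An \linkS4class{Acquisition}.
#' @export
simulateSpect <- function(activity, config, fill, id = "acq") {
  if (any(!is.finite(activity)))
    stop("activity map contains non-finite values")
  if (any(activity < 0))
    stop("activity map must be non-negative")
  if (!identical(dim(activity), as.integer(config@matrixSize)))
    stop("activity dimensions do not match config matrixSize")

  expected <- gaussianSmooth3d(activity, config@psfFwhm, config@voxelSize)
  s <- sum(expected)
  if (s <= 0) stop("activity map has zero total activity")
  expected <- expected * (config@expectedTotalCounts / s)

  if (config@noiseless) {
    counts <- expected
  } else {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(config@seed)
    counts <- array(stats::rpois(length(expected), lambda = expected),
                    dim(expected))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  counts <- gaussianSmooth3d(counts, config@postFilterFwhm, config@voxelSize)
  counts[counts < 0] <- 0

  methods::new("Acquisition", countsVolume = counts, fill = fill,
               config = config, id = id)
}

#' Default 23-acquisition ratio design
#'
#' Nine specific:non-specific ratios 10:1 down to 2:1 with replicate counts
#' (3, 2, 3, 3, 2, 3, 3, 2, 2), totalling 23 acquisitions: 8 at the high
#' activity level (10--8), 8 intermediary (7--5) and 7 low (4--2).
#'
#' @return data.frame with columns \code{ratio} and \code{replicates}.
#' @export
defaultStudyDesign <- function() {
  data.frame(ratio = c(10, 9, 8, 7, 6, 5, 4, 3, 2),
             replicates = c(3L, 2L, 3L, 3L, 2L, 3L, 3L, 2L, 2L))
}

#' Simulate a full phantom study
#'
#' Fills and images the phantom once per replicate of every design ratio.
#' Each acquisition receives its own fill-jitter seed and Poisson seed,
#' both derived deterministically from \code{masterSeed}, and retains its
#' achieved ground truth.
#'
#' @param geometry a \linkS4class{PhantomGeometry}.
#' @param design data.frame with columns \code{ratio}, \code{replicates}
#'   (default \code{\link{defaultStudyDesign}}).
#' @param config an \linkS4class{AcquisitionConfig} template.
#' @param jitterCv lognormal fill-jitter CV.
#' @param masterSeed integer master seed.
#' @return Named list of \linkS4class{Acquisition} objects.
#' @export
generateStudy <- function(geometry, design = defaultStudyDesign(),
                          config = acquisitionConfig(),
                          jitterCv = 0.1, masterSeed = 1L) {
  if (nrow(design) == 0L) stop("empty study design")
  if (any(design$replicates < 1L)) stop("replicates must be >= 1")
  ratios <- rep(design$ratio, design$replicates)
  n <- length(ratios)
  seeds <- .deriveSeeds(masterSeed, 2L * n)

  acqs <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("acq%02d", i)
    filled <- fillActivities(geometry, ratios[i], jitterCv = jitterCv,
                             seed = seeds[2L * i - 1L])
    cfg <- config
    cfg@seed <- as.integer(seeds[2L * i])
    acqs[[i]] <- simulateSpect(filled$activity, cfg, filled$fill, id = id)
  }
  names(acqs) <- vapply(acqs, function(a) a@id, "")
  acqs
}
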