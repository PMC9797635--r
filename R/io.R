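#' Write an acquisition as NIfTI plus JSON sidecar
#'
#' The counts volume goes to \code{<prefix>.nii.gz} (the affine carries the
#' voxel size) and the ground-truth fill record plus simulation settings to
#' \code{<prefix>.json}.
#'
#' @param acquisition an \linkS4class{Acquisition}.
#' @param prefix output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
writeAcquisition <- function(acquisition, prefix) {
  vox <- voxelSize(acquisitionConfigOf(acquisition))
  img <- RNifti::asNifti(countsVolume(acquisition))
  RNifti::pixdim(img) <- vox
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  fill <- fillRecord(acquisition)
  cfg <- acquisitionConfigOf(acquisition)
  side <- list(
    id = acquisition@id,
    fill = list(
      nominal_ratio = fill@nominalRatio,
      achieved_conc_specific = as.list(fill@achievedConcSpecific),
      achieved_conc_nonspecific = fill@achievedConcNonspecific,
      achieved_bpi = fill@achievedBpi,
      achieved_sbr = fill@achievedSbr,
      activity_level = fill@activityLevel,
      jitter_cv = fill@jitterCv,
      seed = fill@seed
    ),
    config = list(
      psf_fwhm = cfg@psfFwhm,
      expected_total_counts = cfg@expectedTotalCounts,
      post_filter_fwhm = cfg@postFilterFwhm,
      matrix_size = cfg@matrixSize,
      voxel_size = cfg@voxelSize,
      seed = cfg@seed,
      noiseless = cfg@noiseless
    )
  )
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read an acquisition written by \code{writeAcquisition}
#'
#' @param prefix path prefix used when writing.
#' @return An \linkS4class{Acquisition}.
#' @export
readAcquisition <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  conc <- unlist(side$fill$achieved_conc_specific)
  fill <- methods::new("FillRecord",
    nominalRatio = side$fill$nominal_ratio,
    achievedConcSpecific = conc,
    achievedConcNonspecific = side$fill$achieved_conc_nonspecific,
    achievedBpi = side$fill$achieved_bpi,
    achievedSbr = side$fill$achieved_sbr,
    activityLevel = side$fill$activity_level,
    jitterCv = side$fill$jitter_cv,
    seed = as.integer(side$fill$seed))
  cfg <- acquisitionConfig(
    psfFwhm = side$config$psf_fwhm,
    expectedTotalCounts = side$config$expected_total_counts,
    postFilterFwhm = side$config$post_filter_fwhm,
    matrixSize = side$config$matrix_size,
    voxelSize = side$config$voxel_size,
    seed = side$config$seed,
    noiseless = side$config$noiseless)
  counts <- array(as.numeric(img), dim = dim(img))
  methods::new("Acquisition", countsVolume = counts, fill = fill,
               config = cfg, id = side$id)
}

#' Write a phantom geometry as a NIfTI label volume
#'
#' @param geometry a \linkS4class{PhantomGeometry}.
#' @param path output file (\code{.nii} or \code{.nii.gz}).
#' @return The path, invisibly.
#' @export
writePhantom <- function(geometry, path) {
  img <- RNifti::asNifti(labelVolume(geometry) * 1L)
  RNifti::pixdim(img) <- voxelSize(geometry)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a composite image as single-slice NIfTI plus JSON sidecar
#'
#' @param composite a \linkS4class{Composite2D}.
#' @param prefix output path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
writeComposite <- function(composite, prefix) {
  d <- dim(compositeImage(composite))
  arr <- array(compositeImage(composite), c(d, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(composite@pixelSize,
                           .effectiveThicknessMm(composite))
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  jsonlite::write_json(list(slice_indices = sliceIndices(composite),
                            n_slices = nSlices(composite),
                            slice_thickness = composite@sliceThickness),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
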