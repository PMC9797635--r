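#' Accessor generics
#'
#' Standard accessors for the phantom/acquisition containers.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("labelVolume", function(x) standardGeneric("labelVolume"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("nominalVolumes", function(x) standardGeneric("nominalVolumes"))

#' @rdname accessors
#' @export
setGeneric("achievedVolumes", function(x) standardGeneric("achievedVolumes"))

#' @rdname accessors
#' @export
setGeneric("countsVolume", function(x) standardGeneric("countsVolume"))

#' @rdname accessors
#' @export
setGeneric("fillRecord", function(x) standardGeneric("fillRecord"))

#' @rdname accessors
#' @export
setGeneric("acquisitionConfigOf", function(x) standardGeneric("acquisitionConfigOf"))

#' @rdname accessors
#' @export
setGeneric("compositeImage", function(x) standardGeneric("compositeImage"))

#' @rdname accessors
#' @export
setGeneric("sliceIndices", function(x) standardGeneric("sliceIndices"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("voiMasks", function(x) standardGeneric("voiMasks"))

#' @rdname accessors
#' @export
setGeneric("voiVolumes", function(x) standardGeneric("voiVolumes"))

#' @rdname accessors
#' @export
setGeneric("gtmOmega", function(x) standardGeneric("gtmOmega"))

#' @rdname accessors
#' @export
setGeneric("regionOrder", function(x) standardGeneric("regionOrder"))

#' @rdname accessors
setMethod("labelVolume", "PhantomGeometry", function(x) x@labelVolume)

#' @rdname accessors
setMethod("voxelSize", "PhantomGeometry", function(x) x@voxelSize)

#' @rdname accessors
setMethod("voxelSize", "AcquisitionConfig", function(x) x@voxelSize)

#' @rdname accessors
setMethod("nominalVolumes", "PhantomGeometry", function(x)
  x@nominalVolumes[names(.compartmentLabels)])

#' @rdname accessors
setMethod("achievedVolumes", "PhantomGeometry", function(x)
  .achievedVolumes(x@labelVolume, x@voxelSize))

#' @rdname accessors
setMethod("countsVolume", "Acquisition", function(x) x@countsVolume)

#' @rdname accessors
setMethod("fillRecord", "Acquisition", function(x) x@fill)

#' @rdname accessors
setMethod("acquisitionConfigOf", "Acquisition", function(x) x@config)

#' @rdname accessors
setMethod("compositeImage", "Composite2D", function(x) x@image)

#' @rdname accessors
setMethod("sliceIndices", "Composite2D", function(x) x@sliceIndices)

#' @rdname accessors
setMethod("nSlices", "Composite2D", function(x) length(x@sliceIndices))

#' @rdname accessors
setMethod("voiMasks", "VoiSet", function(x) x@masks)

#' @rdname accessors
setMethod("voiVolumes", "VoiSet", function(x) x@volumes)

#' @rdname accessors
setMethod("gtmOmega", "GtmModel", function(x) x@omega)

#' @rdname accessors
setMethod("regionOrder", "GtmModel", function(x) x@regionOrder)
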