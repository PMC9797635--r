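.allMethods <- c("manual", "twobox", "threebox", "voi_mri_like",
                 "voi_ct_like")

#' Quantify a set of acquisitions with the selected methods
#'
#' Runs the chosen quantification methods on every acquisition of a study.
#' The structural VOI sets and their geometric transfer matrices are built
#' once (the geometry is shared by all acquisitions) and reused.
#'
#' @param acquisitions list of \linkS4class{Acquisition} objects sharing
#'   one geometry.
#' @param geometry the \linkS4class{PhantomGeometry}.
#' @param methods subset of \code{manual}, \code{twobox}, \code{threebox},
#'   \code{voi_mri_like}, \code{voi_ct_like}, \code{voi_exact}.
#' @param voiSeed perturbation seed for the structural VOI sets.
#' @param gtmFwhm GTM kernel FWHM override, mm (default: effective total
#'   blur of the first acquisition).
#' @param includeBackground see \code{\link{computeGtm}}.
#' @return data.frame of QuantResult rows, one per
#'   (acquisition, method, compartment).
#' @export
quantifyStudy <- function(acquisitions, geometry, methods = .allMethods,
                          voiSeed = 1L, gtmFwhm = NULL,
                          includeBackground = TRUE) {
  stopifnot(length(acquisitions) > 0)
  known <- c(.allMethods, "voi_exact")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  cfg <- acquisitionConfigOf(acquisitions[[1]])
  if (is.null(gtmFwhm))
    gtmFwhm <- c(cfg@psfFwhm, cfg@postFilterFwhm)

  voiJobs <- list()
  for (m in intersect(methods, c("voi_exact", "voi_mri_like",
                                 "voi_ct_like"))) {
    prov <- sub("^voi_", "", m)
    prov <- if (prov == "exact") "exact" else prov
    vs <- makeVoiSet(geometry, provenance = prov,
                     perturbationSeed = voiSeed)
    gtm <- computeGtm(vs, gtmFwhm, geometry, includeBackground)
    voiJobs[[m]] <- list(voiSet = vs, gtm = gtm)
  }

  rows <- lapply(acquisitions, function(acq) {
    out <- list()
    if ("manual" %in% methods) out$manual <- quantifyManual(acq, geometry)
    if ("twobox" %in% methods) out$twobox <- quantifyTwoBox(acq, geometry)
    if ("threebox" %in% methods)
      out$threebox <- quantifyThreeBox(acq, geometry)
    for (m in names(voiJobs)) {
      out[[m]] <- quantifyVoi(acq, geometry, voiJobs[[m]]$voiSet,
                              gtm = voiJobs[[m]]$gtm, method = m)
    }
    do.call(rbind, out)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Study configuration
#'
#' Constructor for \linkS4class{StudyConfig}; every argument has the
#' default study value, so \code{studyConfig()} describes the standard
#' 23-acquisition design.
#'
#' @param design ratio/replicate table.
#' @param acquisition an \linkS4class{AcquisitionConfig}.
#' @param jitterCv fill-jitter CV.
#' @param masterSeed master seed.
#' @param methods methods to run.
#' @param sbrTruth truth pairing for SBR (see \code{\link{evaluateStudy}}).
#' @param outputDir output directory.
#' @param writeVolumes write per-acquisition NIfTI volumes.
#' @return A \linkS4class{StudyConfig}.
#' @export
studyConfig <- function(design = defaultStudyDesign(),
                        acquisition = acquisitionConfig(),
                        jitterCv = 0.1, masterSeed = 1L,
                        methods = .allMethods, sbrTruth = "bpi",
                        outputDir = "datquant-study",
                        writeVolumes = TRUE) {
  methods::new("StudyConfig", design = design, acquisition = acquisition,
               jitterCv = jitterCv, masterSeed = as.integer(masterSeed),
               methods = methods, sbrTruth = sbrTruth,
               outputDir = outputDir, writeVolumes = writeVolumes)
}

#' Read a study configuration from YAML
#'
#' Recognized keys (all optional): \code{design} (list of
#' \code{\{ratio, replicates\}}), \code{psf_fwhm}, \code{post_filter_fwhm},
#' \code{expected_total_counts}, \code{matrix_size}, \code{voxel_size},
#' \code{jitter_cv}, \code{master_seed}, \code{methods}, \code{sbr_truth},
#' \code{output_dir}, \code{write_volumes}.
#'
#' @param path YAML file path.
#' @return A \linkS4class{StudyConfig}.
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  design <- if (is.null(y$design)) defaultStudyDesign() else
    do.call(rbind, lapply(y$design, function(d)
      data.frame(ratio = d$ratio, replicates = as.integer(d$replicates))))
  acq <- acquisitionConfig(
    psfFwhm = y$psf_fwhm %||% 11,
    expectedTotalCounts = y$expected_total_counts %||% 3e6,
    postFilterFwhm = y$post_filter_fwhm %||% 6,
    matrixSize = unlist(y$matrix_size) %||% c(128L, 128L, 80L),
    voxelSize = unlist(y$voxel_size) %||% 2.13)
  studyConfig(design = design, acquisition = acq,
              jitterCv = y$jitter_cv %||% 0.1,
              masterSeed = y$master_seed %||% 1L,
              methods = unlist(y$methods) %||% .allMethods,
              sbrTruth = y$sbr_truth %||% "bpi",
              outputDir = y$output_dir %||% "datquant-study",
              writeVolumes = isTRUE(y$write_volumes %||% TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a complete phantom study end to end
#'
#' Builds the phantom, simulates the designed acquisitions, quantifies them
#' with every requested method and writes the results table
#' (\code{results.csv}), the agreement report (\code{report.csv},
#' \code{report.json}) and, optionally, per-acquisition NIfTI volumes with
#' JSON ground-truth sidecars into the output directory.
#'
#' @param config a \linkS4class{StudyConfig}.
#' @param geometry optional pre-built \linkS4class{PhantomGeometry}
#'   (default: standard phantom at the config's voxel/matrix geometry).
#' @param quiet suppress progress messages.
#' @return list with \code{geometry}, \code{acquisitions}, \code{results},
#'   \code{report} (invisibly).
#' @export
runStudy <- function(config = studyConfig(), geometry = NULL,
                     quiet = FALSE) {
  methods::validObject(config)
  say <- function(...) if (!quiet) message(...)
  t0 <- Sys.time()
  if (is.null(geometry))
    geometry <- buildPhantom(voxelSize = config@acquisition@voxelSize,
                             matrixSize = config@acquisition@matrixSize)
  dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config@outputDir))
    stop("cannot create output directory: ", config@outputDir)

  say("Simulating ", sum(config@design$replicates), " acquisitions ",
      "(master seed ", config@masterSeed, ") ...")
  acqs <- generateStudy(geometry, design = config@design,
                        config = config@acquisition,
                        jitterCv = config@jitterCv,
                        masterSeed = config@masterSeed)
  if (config@writeVolumes) {
    for (acq in acqs)
      writeAcquisition(acq, file.path(config@outputDir, acq@id))
  }

  say("Quantifying with: ", paste(config@methods, collapse = ", "), " ...")
  results <- quantifyStudy(acqs, geometry, methods = config@methods,
                           voiSeed = config@masterSeed)
  utils::write.csv(results, file.path(config@outputDir, "results.csv"),
                   row.names = FALSE)

  report <- evaluateStudy(results, sbrTruth = config@sbrTruth)
  utils::write.csv(report, file.path(config@outputDir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(config@outputDir, "report.json"),
                       dataframe = "rows", digits = NA, auto_unbox = TRUE)
  say(sprintf("Done in %.1f s; outputs in %s",
              as.numeric(difftime(Sys.time(), t0, units = "secs")),
              config@outputDir))
  invisible(list(geometry = geometry, acquisitions = acqs,
                 results = results, report = report))
}

#' Test-scale and full-scale fixtures
#'
#' \code{tiny}: a 48^3 grid of 4 mm voxels with linearly 1.44x scaled wells
#' (volumes about 3x nominal so each well still spans enough voxels), for
#' fast unit tests.  \code{default}: the standard phantom geometry.
#'
#' @param size \code{"tiny"} or \code{"default"}.
#' @param ratio fill ratio of the returned acquisition.
#' @param seed seed for fill jitter and noise.
#' @param noiseless skip the Poisson step.
#' @param jitterCv fill-jitter CV.
#' @return list with \code{geometry}, \code{config}, \code{acquisition}.
#' @export
makeFixture <- function(size = c("tiny", "default"), ratio = 10,
                        seed = 1L, noiseless = FALSE, jitterCv = 0.1) {
  size <- match.arg(size)
  if (size == "tiny") {
    geometry <- buildPhantom(
      voxelSize = 4,
      matrixSize = c(48L, 48L, 48L),
      shellSemiAxes = c(60, 70, 45),
      nominalVolumes = c(CA_R = 14.1, CA_L = 13.8, PU_R = 16.2,
                         PU_L = 18.0),
      compartments = defaultCompartments(scale = 1.44))
    config <- acquisitionConfig(matrixSize = c(48L, 48L, 48L),
                                voxelSize = 4,
                                expectedTotalCounts = 1e6,
                                seed = seed, noiseless = noiseless)
  } else {
    geometry <- buildPhantom()
    config <- acquisitionConfig(seed = seed, noiseless = noiseless)
  }
  seeds <- .deriveSeeds(seed, 2L)
  filled <- fillActivities(geometry, ratio, jitterCv = jitterCv,
                           seed = seeds[1])
  config@seed <- as.integer(seeds[2])
  acq <- simulateSpect(filled$activity, config, filled$fill, id = "fixture")
  list(geometry = geometry, config = config, acquisition = acq)
}
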