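#' Default analytic well shapes of the digital striatal phantom
#'
#' The right/left caudate is modeled as an axially oriented capsule
#' (cylinder with hemispherical caps, the caudate-head-like well) and the
#' right/left putamen as a lens-shaped ellipsoid lateral and slightly
#' posterior to it.  All positions are mm offsets from the striatal center
#' (the grid center); linear dimensions are rescaled per well during
#' voxelization so each achieved volume matches its nominal volume.
#'
#' @param scale global linear scale factor applied to every dimension and
#'   center offset (used by the coarse test fixture).
#' @return data.frame with one row per well: shape, center, dimensions.
#' @export
defaultCompartments <- function(scale = 1) {
  spec <- data.frame(
    name = c("CA_R", "CA_L", "PU_R", "PU_L"),
    shape = c("capsule", "capsule", "ellipsoid", "ellipsoid"),
    cx = c(15, -15, 29, -29),
    cy = c(6, 6, -2, -2),
    cz = c(0, 0, 0, 0),
    d1 = c(6.5, 6.5, 4.95, 4.95), # capsule radius / ellipsoid x semi-axis
    d2 = c(21, 21, 13, 13),       # capsule half-length / y semi-axis
    d3 = c(NA, NA, 21, 21),       # ellipsoid z semi-axis
    stringsAsFactors = FALSE
  )
  spec[c("cx", "cy", "cz", "d1", "d2", "d3")] <-
    spec[c("cx", "cy", "cz", "d1", "d2", "d3")] * scale
  spec
}

## Minimal linear scale s at which a voxel offset enters the shape ("gauge"
## of the star-shaped well): selecting the N voxels of smallest gauge
## voxelizes the shape at the exact scale that achieves N voxels.
.shapeGauge <- function(dx, dy, dz, row) {
  if (row$shape == "ellipsoid") {
    sqrt((dx / row$d1)^2 + (dy / row$d2)^2 + (dz / row$d3)^2)
  } else if (row$shape == "capsule") {
    r0 <- row$d1
    h0 <- row$d2
    if (h0 <= r0) stop("capsule half-length must exceed its radius")
    c0 <- h0 - r0
    rho <- sqrt(dx^2 + dy^2)
    az <- abs(dz)
    gCyl <- rho / r0
    A <- c0^2 - r0^2
    disc <- pmax(az^2 * c0^2 - A * (rho^2 + az^2), 0)
    gCap <- if (abs(A) < 1e-9) sqrt(rho^2 + az^2) / r0
            else (az * c0 - sqrt(disc)) / A
    ifelse(az * r0 <= rho * c0, gCyl, gCap)
  } else {
    stop("unknown shape: ", row$shape)
  }
}

#' Build the digital striatal phantom
#'
#' Voxelizes four striatal wells inside an ellipsoidal brain shell.  For
#' each well the analytic shape is isotropically rescaled so that the
#' achieved voxelized volume matches the nominal volume to within half a
#' voxel (selection of the N nearest-gauge voxels), which keeps the
#' achieved/nominal deviation below 2\% at any sensible resolution.
#'
#' @param voxelSize voxel edge length in mm (scalar, isotropic) or
#'   numeric(3).
#' @param nominalVolumes named numeric, target well volumes in mL
#'   (defaults: CA 4.7/4.6, PU 5.4/6.0 right/left).
#' @param matrixSize integer(3) grid dimensions (default 128 x 128 x 80).
#' @param shellSemiAxes numeric(3) brain-shell ellipsoid semi-axes in mm.
#' @param compartments shape table as from \code{\link{defaultCompartments}}.
#' @return A \linkS4class{PhantomGeometry}.
#' @examples
#' geom <- buildPhantom(voxelSize = 4, matrixSize = c(48L, 48L, 48L),
#'                      shellSemiAxes = c(60, 70, 45),
#'                      nominalVolumes = c(CA_R = 14.1, CA_L = 13.8,
#'                                         PU_R = 16.2, PU_L = 18.0),
#'                      compartments = defaultCompartments(scale = 1.44))
#' achievedVolumes(geom)
#' @export
buildPhantom <- function(voxelSize = 2.13,
                         nominalVolumes = c(CA_R = 4.7, CA_L = 4.6,
                                            PU_R = 5.4, PU_L = 6.0),
                         matrixSize = c(128L, 128L, 80L),
                         shellSemiAxes = c(65, 80, 50),
                         compartments = defaultCompartments()) {
  if (length(voxelSize) == 1L) voxelSize <- rep(voxelSize, 3L)
  stopifnot(all(voxelSize > 0), length(matrixSize) == 3L)
  if (any(nominalVolumes <= 0))
    stop("all nominal well volumes must be > 0")
  if (!all(names(.compartmentLabels) %in% names(nominalVolumes)))
    stop("nominalVolumes must name CA_R, CA_L, PU_R, PU_L")
  matrixSize <- as.integer(matrixSize)
  voxML <- prod(voxelSize) / 1000

  ## voxel-center world coordinates relative to the grid center (mm)
  ctr <- matrixSize * voxelSize / 2
  xs <- (seq_len(matrixSize[1]) - 0.5) * voxelSize[1] - ctr[1]
  ys <- (seq_len(matrixSize[2]) - 0.5) * voxelSize[2] - ctr[2]
  zs <- (seq_len(matrixSize[3]) - 0.5) * voxelSize[3] - ctr[3]
  X <- array(xs, matrixSize)
  Y <- array(rep(ys, each = matrixSize[1]), matrixSize)
  Z <- array(rep(zs, each = matrixSize[1] * matrixSize[2]), matrixSize)

  shell <- (X / shellSemiAxes[1])^2 + (Y / shellSemiAxes[2])^2 +
    (Z / shellSemiAxes[3])^2 <= 1
  label <- array(0L, matrixSize)
  label[shell] <- .shellLabel

  fitted <- numeric(nrow(compartments))
  for (i in seq_len(nrow(compartments))) {
    row <- compartments[i, ]
    nominal <- nominalVolumes[[row$name]]
    n <- round(nominal / voxML)
    if (n < 1)
      stop("well ", row$name, " smaller than one voxel: unresolvable geometry")
    if (abs(n * voxML - nominal) / nominal > 0.02)
      stop("voxel size too coarse to resolve well ", row$name,
           " within 2% of its nominal volume")
    g <- .shapeGauge(X - row$cx, Y - row$cy, Z - row$cz, row)
    sel <- order(g)[seq_len(n)]
    fitted[i] <- g[sel[n]]
    if (any(label[sel] == 0L))
      stop("well ", row$name, " protrudes outside the brain shell")
    if (any(label[sel] > .shellLabel))
      stop("wells overlap at this voxel size: ", row$name)
    label[sel] <- .compartmentLabels[[row$name]]
  }
  compartments$fittedScale <- fitted

  methods::new("PhantomGeometry",
    labelVolume = label,
    voxelSize = voxelSize,
    nominalVolumes = nominalVolumes[names(.compartmentLabels)],
    compartmentSpec = compartments)
}

#' Logical mask of the striatal wells
#'
#' @param geometry a \linkS4class{PhantomGeometry}.
#' @return 3-D logical array, TRUE inside any of the four wells.
#' @export
striatalMask <- function(geometry) {
  labelVolume(geometry) >= min(.compartmentLabels)
}

#' Fill the phantom at a prescribed specific:non-specific ratio
#'
#' Assigns the shell a non-specific concentration and each well the
#' concentration \code{cNs * nominalRatio} times an independent lognormal
#' jitter factor (mean 1, coefficient of variation \code{jitterCv}) -- the
#' synthetic analogue of the aliquot-measured achieved fills of a physical
#' phantom experiment.  The achieved (post-jitter) values are recorded as
#' ground truth.
#'
#' @param geometry a \linkS4class{PhantomGeometry}.
#' @param nominalRatio design specific:non-specific ratio (>= 1).
#' @param jitterCv lognormal jitter CV in [0, 0.5); 0 disables jitter.
#' @param seed integer seed for the jitter draws.
#' @param cNs non-specific (shell) concentration, arbitrary counts/mL.
#' @return list with \code{activity} (3-D concentration array) and
#'   \code{fill} (a \linkS4class{FillRecord}).
#' @export
fillActivities <- function(geometry, nominalRatio, jitterCv = 0.1,
                           seed = 1L, cNs = 1) {
  if (nominalRatio < 1)
    stop("nominalRatio must be >= 1 (specific below background not in design)")
  if (jitterCv < 0 || jitterCv >= 0.5)
    stop("jitterCv must lie in [0, 0.5)")
  stopifnot(cNs > 0)
  seed <- as.integer(seed)

  wells <- names(.compartmentLabels)
  if (jitterCv > 0) {
    sdlog <- sqrt(log(1 + jitterCv^2))
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    jit <- stats::rlnorm(length(wells), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  } else {
    jit <- rep(1, length(wells))
  }
  conc <- cNs * nominalRatio * jit
  names(conc) <- wells

  lab <- labelVolume(geometry)
  activity <- array(0, dim(lab))
  activity[lab == .shellLabel] <- cNs
  for (w in wells) activity[lab == .compartmentLabels[[w]]] <- conc[[w]]

  vols <- nominalVolumes(geometry)
  achievedRatio <- sum(conc * vols) / sum(vols) / cNs
  fill <- methods::new("FillRecord",
    nominalRatio = nominalRatio,
    achievedConcSpecific = conc,
    achievedConcNonspecific = cNs,
    achievedBpi = achievedRatio - 1,
    achievedSbr = achievedRatio,
    activityLevel = .activityLevel(nominalRatio),
    jitterCv = jitterCv,
    seed = seed)
  list(activity = activity, fill = fill)
}

#' Achieved ground-truth BPI for a compartment
#'
#' Volume-weighted achieved concentration ratio minus one, pooled over the
#' wells that make up the requested compartment.
#'
#' @param fill a \linkS4class{FillRecord}.
#' @param compartment one of \code{"CA"}, \code{"PU"}, \code{"ST"},
#'   \code{"CA_R"}, \code{"CA_L"}, \code{"PU_R"}, \code{"PU_L"},
#'   \code{"ST_R"}, \code{"ST_L"}.
#' @param volumes named numeric well volumes (mL) used as pooling weights.
#' @return achieved BPI (dimensionless).
#' @export
achievedBpi <- function(fill, compartment, volumes) {
  members <- switch(compartment,
    CA = c("CA_R", "CA_L"), PU = c("PU_R", "PU_L"),
    ST = c("CA_R", "CA_L", "PU_R", "PU_L"),
    ST_R = c("CA_R", "PU_R"), ST_L = c("CA_L", "PU_L"),
    compartment)
  if (!all(members %in% names(fill@achievedConcSpecific)))
    stop("unknown compartment: ", compartment)
  w <- volumes[members]
  conc <- sum(fill@achievedConcSpecific[members] * w) / sum(w)
  conc / fill@achievedConcNonspecific - 1
}
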