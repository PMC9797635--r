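## Separable Gaussian smoothing and distance-based morphology on regular
## grids.  Kernels are bin-integrated and normalized to unit sum, so total
## counts are conserved up to truncation at the volume borders (the phantom
## is padded so that support stays well clear of them).

.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## Discrete 1-D Gaussian, integrated over voxel-width bins, unit sum.
.gaussKernel1d <- function(sigmaVox) {
  half <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  off <- (-half):half
  k <- stats::pnorm(off + 0.5, sd = sigmaVox) -
    stats::pnorm(off - 0.5, sd = sigmaVox)
  k / sum(k)
}

## Banded n x n convolution matrix for a 1-D kernel (truncated at borders).
.gaussBandMatrix <- function(n, sigmaVox) {
  k <- .gaussKernel1d(sigmaVox)
  half <- (length(k) - 1L) %/% 2L
  dif <- outer(seq_len(n), seq_len(n), `-`)
  K <- matrix(0, n, n)
  sel <- abs(dif) <= half
  K[sel] <- k[dif[sel] + half + 1L]
  K
}

## Apply a convolution matrix along one axis of a 3-D array.
.convolveAxis <- function(vol, axis, K) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  v <- K %*% matrix(v, nrow = d[axis])
  dim(v) <- d[perm]
  aperm(v, order(perm))
}

#' Separable 3-D Gaussian smoothing
#'
#' Count-preserving (unit-sum kernel) Gaussian convolution, specified by its
#' full width at half maximum in mm.  A FWHM of zero returns the input
#' unchanged (delta kernel).
#'
#' @param vol 3-D numeric array.
#' @param fwhm Gaussian FWHM in mm (single value, isotropic in space).
#' @param voxelSize numeric(3), voxel edge lengths in mm.
#' @return Array of the same dimension.
#' @export
gaussianSmooth3d <- function(vol, fwhm, voxelSize) {
  stopifnot(length(dim(vol)) == 3L, fwhm >= 0, length(voxelSize) == 3L)
  if (fwhm == 0) return(vol)
  sigma <- .fwhmToSigma(fwhm)
  for (ax in 1:3) {
    sVox <- sigma / voxelSize[ax]
    if (sVox < 1e-6) next
    vol <- .convolveAxis(vol, ax, .gaussBandMatrix(dim(vol)[ax], sVox))
  }
  vol
}

## 3x3 uniform mean filter on a matrix (zero-padded borders).
.meanFilter3x3 <- function(img) {
  d <- dim(img)
  out <- matrix(0, d[1], d[2])
  for (dx in -1:1) {
    for (dy in -1:1) {
      sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
      tx <- max(1, 1 - dx):min(d[1], d[1] - dx)
      sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
      ty <- max(1, 1 - dy):min(d[2], d[2] - dy)
      out[tx, ty] <- out[tx, ty] + img[sx, sy]
    }
  }
  out / 9
}

## Euclidean dilation: TRUE for grid points within `dist` mm of the mask.
## FFT-based convolution with a ball indicator; works for 2-D and 3-D masks.
.withinDistance <- function(mask, dist, spacing) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(length(spacing) == nd)
  r <- pmin(ceiling(dist / spacing), d %/% 2 - 1L)
  offs <- lapply(seq_len(nd), function(a) ((-r[a]):r[a]) * spacing[a])
  sq <- lapply(offs, function(o) o^2)
  if (nd == 2L) {
    ker <- outer(sq[[1]], sq[[2]], `+`) <= dist^2
  } else {
    ker <- outer(outer(sq[[1]], sq[[2]], `+`), sq[[3]], `+`) <= dist^2
  }
  K <- array(0, d)
  idx <- lapply(seq_len(nd), function(a) (((-r[a]):r[a]) %% d[a]) + 1L)
  if (nd == 2L) K[idx[[1]], idx[[2]]] <- ker * 1
  else K[idx[[1]], idx[[2]], idx[[3]]] <- ker * 1
  conv <- Re(stats::fft(stats::fft(mask * 1) * stats::fft(K), inverse = TRUE)) /
    prod(d)
  conv > 0.5
}

## Derive a vector of independent sub-seeds from one master seed.
.deriveSeeds <- function(masterSeed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(masterSeed))
  sample.int(.Machine$integer.max - 1L, n)
}
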