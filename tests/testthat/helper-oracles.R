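## Small synthetic geometry with two abutting 20 mm slabs (CA_R / CA_L) and
## three well-separated cubes; used to check omega against a brute-force
## convolution oracle.
.slabGeometry <- function() {
  d <- c(24L, 24L, 24L)
  lab <- array(1L, d)
  slab1 <- array(FALSE, d); slab1[7:18, 7:18, 3:12] <- TRUE
  slab2 <- array(FALSE, d); slab2[7:18, 7:18, 13:22] <- TRUE
  cube1 <- array(FALSE, d); cube1[2:4, 2:4, 2:4] <- TRUE
  cube2 <- array(FALSE, d); cube2[21:23, 2:4, 2:4] <- TRUE
  cube3 <- array(FALSE, d); cube3[2:4, 21:23, 21:23] <- TRUE
  lab[slab1] <- 2L; lab[slab2] <- 3L; lab[cube1] <- 4L; lab[cube2] <- 5L
  voxML <- 8 / 1000
  geom <- methods::new("PhantomGeometry", labelVolume = lab,
                       voxelSize = rep(2, 3),
                       nominalVolumes = c(CA_R = sum(slab1), CA_L = sum(slab2),
                                          PU_R = sum(cube1),
                                          PU_L = sum(cube2)) * voxML,
                       compartmentSpec = data.frame())
  vs <- methods::new("VoiSet",
                     masks = list(CA_R = slab1, CA_L = slab2, PU_R = cube1,
                                  PU_L = cube2, reference = cube3),
                     volumes = c(CA_R = sum(slab1), CA_L = sum(slab2),
                                 PU_R = sum(cube1), PU_L = sum(cube2),
                                 reference = sum(cube3)) * voxML,
                     provenance = "exact", seed = 0L)
  list(geometry = geom, voiSet = vs)
}

## Independent convolution oracle: direct shifted-copy accumulation with an
## explicit 3-D kernel (same bin-integrated taps, no separable machinery).
.bruteBlur <- function(vol, fwhm, vox) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  taps <- lapply(1:3, function(ax) {
    s <- sigma / vox[ax]
    h <- max(1L, as.integer(ceiling(4 * s)))
    off <- (-h):h
    k <- pnorm(off + 0.5, sd = s) - pnorm(off - 0.5, sd = s)
    k / sum(k)
  })
  h <- (lengths(taps) - 1L) %/% 2L
  d <- dim(vol)
  shift1 <- function(v, sh) {
    out <- array(0, d)
    src <- tgt <- vector("list", 3)
    for (ax in 1:3) {
      src[[ax]] <- max(1, 1 - sh[ax]):min(d[ax], d[ax] - sh[ax])
      tgt[[ax]] <- max(1, 1 + sh[ax]):min(d[ax], d[ax] + sh[ax])
    }
    out[tgt[[1]], tgt[[2]], tgt[[3]]] <- v[src[[1]], src[[2]], src[[3]]]
    out
  }
  out <- array(0, d)
  for (i in seq_along(taps[[1]])) {
    for (j in seq_along(taps[[2]])) {
      for (l in seq_along(taps[[3]])) {
        w <- taps[[1]][i] * taps[[2]][j] * taps[[3]][l]
        out <- out + w * shift1(vol, c(i - 1L - h[1], j - 1L - h[2],
                                       l - 1L - h[3]))
      }
    }
  }
  out
}

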