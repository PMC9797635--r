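test_that("voxelized well volumes match nominal volumes within 2%", {
  geom <- defaultGeom()
  ach <- achievedVolumes(geom)
  nom <- nominalVolumes(geom)
  expect_equal(names(ach), c("CA_R", "CA_L", "PU_R", "PU_L"))
  expect_true(all(abs(ach - nom) / nom < 0.02))
  ## labels are a partition by construction; wells must sit inside the shell
  lab <- labelVolume(geom)
  expect_true(all(lab %in% 0:5))
  ## every well voxel has shell or well neighbors, never outside-phantom air
  expect_true(all(lab[DATquant:::.withinDistance(striatalMask(geom), 2.2,
                                                 voxelSize(geom))] >= 1))
})

test_that("re-voxelization at doubled voxel size keeps volumes on target", {
  coarse <- buildPhantom(voxelSize = 4.26)
  ach <- achievedVolumes(coarse)
  nom <- nominalVolumes(coarse)
  expect_true(all(abs(ach - nom) / nom < 0.02))
})

test_that("degenerate well volumes are rejected", {
  expect_error(buildPhantom(nominalVolumes = c(CA_R = 0, CA_L = 4.6,
                                               PU_R = 5.4, PU_L = 6.0)),
               "> 0")
  ## smaller than one voxel at this resolution
  expect_error(buildPhantom(nominalVolumes = c(CA_R = 0.005, CA_L = 4.6,
                                               PU_R = 5.4, PU_L = 6.0)),
               "unresolvable|2%")
})

test_that("overlapping wells are rejected", {
  comp <- defaultCompartments()
  comp$cx <- c(15, -15, 17, -17)   # putamen pushed onto the caudate
  expect_error(buildPhantom(compartments = comp), "overlap")
})

test_that("jitter-free fills give exact achieved indices and levels", {
  geom <- tinyNoiseless()$geometry
  f <- fillActivities(geom, 10, jitterCv = 0, seed = 1)
  expect_equal(f$fill@achievedBpi, 9)
  expect_equal(f$fill@achievedSbr, 10)
  expect_identical(f$fill@activityLevel, "high")
  expect_identical(fillActivities(geom, 2, jitterCv = 0)$fill@activityLevel,
                   "low")
  expect_identical(fillActivities(geom, 7, jitterCv = 0)$fill@activityLevel,
                   "intermediary")
  expect_error(fillActivities(geom, 0.5), ">= 1")
  ## shell at cNs, outside at zero
  expect_equal(unique(f$activity[labelVolume(geom) == 1]), 1)
  expect_equal(unique(f$activity[labelVolume(geom) == 0]), 0)
})

test_that("lognormal fill jitter has the prescribed mean and CV", {
  geom <- tinyNoiseless()$geometry
  ratios <- vapply(1:1000, function(s)
    fillActivities(geom, 10, jitterCv = 0.1, seed = s)$fill@achievedSbr, 0)
  expect_lt(abs(mean(ratios) / 10 - 1), 0.03)
  ## pooled over 4 wells the volume-weighted ratio has CV ~ cv/2
  conc1 <- vapply(1:1000, function(s)
    fillActivities(geom, 10, jitterCv = 0.1,
                   seed = s)$fill@achievedConcSpecific[["CA_R"]], 0)
  expect_gt(sd(conc1) / mean(conc1), 0.07)
  expect_lt(sd(conc1) / mean(conc1), 0.13)
})

test_that("simulation preserves counts and is deterministic", {
  fx <- tinyNoiseless()
  geom <- fx$geometry
  f <- fillActivities(geom, 10, jitterCv = 0, seed = 1)

  ## delta-kernel identity: no blur, no noise -> proportional to activity
  cfg0 <- acquisitionConfig(psfFwhm = 0, postFilterFwhm = 0,
                            matrixSize = dim(f$activity), voxelSize = 4,
                            noiseless = TRUE)
  acq0 <- simulateSpect(f$activity, cfg0, f$fill)
  ratio <- countsVolume(acq0)[f$activity > 0] / f$activity[f$activity > 0]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)

  ## normalization contract: expected image sums to the requested total
  expect_lt(abs(sum(countsVolume(acq0)) / cfg0@expectedTotalCounts - 1),
            0.001)
  acqB <- simulateSpect(f$activity, fx$config, f$fill)
  expect_lt(abs(sum(countsVolume(acqB)) /
                  fx$config@expectedTotalCounts - 1), 0.001)

  ## determinism: same seed, bit-identical counts
  cfg <- acquisitionConfig(matrixSize = dim(f$activity), voxelSize = 4,
                           seed = 42L)
  expect_identical(countsVolume(simulateSpect(f$activity, cfg, f$fill)),
                   countsVolume(simulateSpect(f$activity, cfg, f$fill)))
  expect_error(simulateSpect(f$activity * NA, cfg, f$fill), "non-finite")
})

test_that("counting noise is Poisson-like before post-filtering", {
  geom <- tinyNoiseless()$geometry
  f <- fillActivities(geom, 5, jitterCv = 0, seed = 1)
  mask <- striatalMask(geom)
  sums <- vapply(1:100, function(s) {
    cfg <- acquisitionConfig(psfFwhm = 11, postFilterFwhm = 0,
                             matrixSize = dim(f$activity), voxelSize = 4,
                             expectedTotalCounts = 2e5, seed = s)
    sum(countsVolume(simulateSpect(f$activity, cfg, f$fill))[mask])
  }, 0)
  vm <- var(sums) / mean(sums)
  expect_gt(vm, 0.8)
  expect_lt(vm, 1.2)
})

test_that("specific counts increase monotonically with the fill ratio", {
  fx <- tinyNoiseless()
  geom <- fx$geometry
  mask <- striatalMask(geom)
  cfg <- acquisitionConfig(matrixSize = dim(labelVolume(geom)),
                           voxelSize = 4, noiseless = TRUE)
  m <- vapply(2:10, function(r) {
    f <- fillActivities(geom, r, jitterCv = 0, seed = 1)
    mean(countsVolume(simulateSpect(f$activity, cfg, f$fill))[mask])
  }, 0)
  expect_true(all(diff(m) > 0))
})

test_that("the default study design yields 23 acquisitions in 8/8/7 levels", {
  des <- defaultStudyDesign()
  expect_equal(sum(des$replicates), 23L)
  geom <- tinyNoiseless()$geometry
  cfg <- acquisitionConfig(matrixSize = dim(labelVolume(geom)),
                           voxelSize = 4, expectedTotalCounts = 1e5)
  acqs <- generateStudy(geom, config = cfg, masterSeed = 3L)
  lv <- table(vapply(acqs, function(a) fillRecord(a)@activityLevel, ""))
  expect_equal(as.vector(lv[c("high", "intermediary", "low")]),
               c(8L, 8L, 7L))

  ## determinism contract: identical ground truth for the same master seed
  acqs2 <- generateStudy(geom, config = cfg, masterSeed = 3L)
  expect_identical(lapply(acqs, function(a) fillRecord(a)@achievedConcSpecific),
                   lapply(acqs2, function(a) fillRecord(a)@achievedConcSpecific))
  expect_identical(countsVolume(acqs[[5]]), countsVolume(acqs2[[5]]))

  single <- generateStudy(geom, design = data.frame(ratio = 10,
                                                    replicates = 1L),
                          config = cfg, masterSeed = 1L)
  expect_length(single, 1L)
  expect_identical(fillRecord(single[[1]])@activityLevel, "high")
  expect_error(generateStudy(geom, design = data.frame(ratio = numeric(),
                                                       replicates = integer()),
                             config = cfg), "empty")
})
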