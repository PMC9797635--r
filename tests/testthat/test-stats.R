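test_that("Lin's CCC reproduces hand-computed values", {
  expect_equal(linCcc(1:10, 1:10)$ccc, 1)
  ## x=(1,2,3), y=(2,3,4): population moments give 2*(2/3)/(2/3+2/3+1)=4/7
  expect_equal(linCcc(c(1, 2, 3), c(2, 3, 4))$ccc, 4 / 7,
               tolerance = 1e-12)
  ## a location shift is penalized relative to Pearson
  x <- c(1, 2, 4, 6, 9)
  y <- 2 + 1.5 * x
  expect_lt(linCcc(x, y)$ccc, pearsonR(x, y)$r)
  expect_error(linCcc(rep(1, 5), 1:5), "variance")
  expect_error(linCcc(1:2, 1:2), "n >= 3")
  ## CI brackets the estimate
  cc <- linCcc(x, y + rnorm(5, sd = 0.01))
  expect_true(cc$lo <= cc$ccc && cc$ccc <= cc$hi)
  ## sample-moment variant differs at small n but agrees at scale
  expect_false(isTRUE(all.equal(linCcc(x, y)$ccc,
                                linCcc(x, y, type = "sample")$ccc)))
})

test_that("CCC never exceeds |r| and scale bias drives it below r", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(12, mean = 5)
    y <- runif(1, 0.2, 2) * x + rnorm(12, sd = 0.3) + runif(1, -2, 2)
    cc <- linCcc(x, y)$ccc
    r <- pearsonR(x, y)$r
    expect_lte(abs(cc), abs(r) + 1e-12)
  }
  x <- seq(1, 9, length.out = 12)
  expect_lt(linCcc(x, 0.4 * x)$ccc, pearsonR(x, 0.4 * x)$r)
})

test_that("Pearson correlation matches its defining formula", {
  expect_equal(pearsonR(1:5, 2 * (1:5))$r, 1)
  expect_equal(pearsonR(1:5, -(1:5))$r, -1)
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 5)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y)$r, oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 4), 0.9827)
  expect_error(pearsonR(rep(2, 4), 1:4), "variance")
})

test_that("least squares matches the normal-equations oracle to 1e-9", {
  f <- olsFit(1:6, 2 * (1:6))
  expect_equal(f$slope$est, 2)
  expect_equal(f$intercept$est, 0, tolerance = 1e-12)
  expect_equal(f$slope$se, 0, tolerance = 1e-12)

  set.seed(17)
  x <- rnorm(50); y <- 1.3 * x - 0.4 + rnorm(50, sd = 0.5)
  f <- olsFit(x, y)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_lt(abs(f$intercept$est - beta[1]), 1e-9)
  expect_lt(abs(f$slope$est - beta[2]), 1e-9)

  ## affine equivariance: adding a constant moves only the intercept
  f2 <- olsFit(x, y + 3)
  expect_equal(f2$slope$est, f$slope$est, tolerance = 1e-12)
  expect_equal(f2$intercept$est, f$intercept$est + 3, tolerance = 1e-12)
  expect_error(olsFit(rep(1, 5), 1:5), "degenerate")
})

## Synthetic results table shaped like the default study output.
.fakeResults <- function(measure) {
  des <- defaultStudyDesign()
  ratios <- rep(des$ratio, des$replicates)
  rows <- list()
  for (m in c("manual", "voi_mri_like", "voi_ct_like")) {
    for (comp in c("CA", "PU", "ST")) {
      rows[[paste(m, comp)]] <- data.frame(
        acquisition_id = sprintf("acq%02d", seq_along(ratios)),
        method = m, compartment = comp, index_type = "BPI",
        value = measure(ratios - 1), truth_bpi = ratios - 1,
        truth_sbr = ratios, nominal_ratio = ratios,
        activity_level = vapply(ratios, DATquant:::.activityLevel, ""))
    }
  }
  rows$twobox <- data.frame(
    acquisition_id = sprintf("acq%02d", seq_along(ratios)),
    method = "twobox", compartment = "ST", index_type = "SBR",
    value = measure(ratios - 1), truth_bpi = ratios - 1,
    truth_sbr = ratios, nominal_ratio = ratios,
    activity_level = vapply(ratios, DATquant:::.activityLevel, ""))
  rows$threebox <- data.frame(
    acquisition_id = sprintf("acq%02d", seq_along(ratios)),
    method = "threebox", compartment = "ST", index_type = "TBPI",
    value = measure(ratios - 1), truth_bpi = ratios - 1,
    truth_sbr = ratios, nominal_ratio = ratios,
    activity_level = vapply(ratios, DATquant:::.activityLevel, ""))
  do.call(rbind, rows)
}

test_that("a perfect method scores CCC 1, slope 1, intercept 0 everywhere", {
  rep <- suppressWarnings(evaluateStudy(.fakeResults(identity)))
  expect_equal(nrow(rep), 11L)   # 3 methods x 3 compartments + 2 x ST
  expect_true(all(abs(rep$ccc_high - 1) < 1e-9))
  expect_true(all(abs(rep$ccc_low - 1) < 1e-9))
  expect_true(all(abs(rep$slope - 1) < 1e-12))
  expect_true(all(abs(rep$intercept) < 1e-12))
  expect_true(all(abs(rep$cod - 1) < 1e-12))
  ## cod equals r^2 by construction
  expect_true(all(abs(rep$cod - rep$pearson_r^2) < 1e-12))
})

test_that("pure scale bias keeps r at 1 but collapses per-level CCC", {
  rep <- suppressWarnings(evaluateStudy(.fakeResults(function(t) 0.4 * t)))
  expect_true(all(abs(rep$slope - 0.4) < 1e-12))
  expect_true(all(abs(rep$pearson_r - 1) < 1e-9))
  ## closed form within one level: ccc = 2*0.4*s2 / (s2 + 0.16 s2 + (0.6 m)^2)
  des <- defaultStudyDesign()
  ratios <- rep(des$ratio, des$replicates)
  t <- ratios[ratios >= 8] - 1
  s2 <- mean(t^2) - mean(t)^2
  closed <- 2 * 0.4 * s2 / (s2 + 0.16 * s2 + (0.6 * mean(t))^2)
  expect_equal(rep$ccc_high[1], closed, tolerance = 1e-12)
  expect_true(all(rep$ccc_high < 0.15))
  ## restricted-range CCC below the pooled-range equivalent
  pooledCcc <- linCcc(ratios - 1, 0.4 * (ratios - 1))$ccc
  expect_gt(pooledCcc, max(rep$ccc_high))
})

test_that("levels with fewer than three points yield NA, not an error", {
  res <- .fakeResults(identity)
  res <- res[res$activity_level != "low" |
               res$acquisition_id %in% c("acq18", "acq19"), ]
  rep <- suppressWarnings(evaluateStudy(res))
  expect_true(all(is.na(rep$ccc_low)))
  expect_false(any(is.na(rep$ccc_high)))
})

test_that("SBR truth pairing switches between ratio and ratio minus one", {
  res <- .fakeResults(identity)
  repB <- suppressWarnings(evaluateStudy(res, sbrTruth = "bpi"))
  repS <- suppressWarnings(evaluateStudy(res, sbrTruth = "sbr"))
  tb <- function(r) r[r$method == "twobox", ]
  expect_equal(tb(repB)$intercept, 0, tolerance = 1e-12)
  expect_equal(tb(repS)$intercept, -1, tolerance = 1e-12)
  expect_equal(tb(repB)$slope, tb(repS)$slope, tolerance = 1e-12)
})
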