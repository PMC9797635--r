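#' Lin's concordance correlation coefficient
#'
#' \code{CCC = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)} with
#' population (1/n) moments -- the original definition -- or sample
#' (1/(n-1)) moments via \code{type}.  The 95\% confidence interval uses
#' the asymptotic variance of the Fisher z-transformed coefficient.
#'
#' @param x truth vector.
#' @param y measurement vector.
#' @param type moment convention, \code{"population"} or \code{"sample"}.
#' @param level confidence level.
#' @return list with \code{ccc}, \code{lo}, \code{hi}, \code{n}.
#' @export
linCcc <- function(x, y, type = c("population", "sample"), level = 0.95) {
  type <- match.arg(type)
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  mx <- mean(x); my <- mean(y)
  sxy <- mean(x * y) - mx * my
  sx2 <- mean(x^2) - mx^2
  sy2 <- mean(y^2) - my^2
  if (sx2 <= 0 || sy2 <= 0) stop("zero variance in x or y")
  if (type == "sample") {
    f <- n / (n - 1)
    sxy <- sxy * f; sx2 <- sx2 * f; sy2 <- sy2 * f
  }
  ccc <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  r <- sxy / sqrt(sx2 * sy2)
  u <- (mx - my) / sqrt(sqrt(sx2) * sqrt(sy2))
  z <- atanh(min(max(ccc, -1 + 1e-12), 1 - 1e-12))
  sz2 <- ((1 - r^2) * ccc^2 / ((1 - ccc^2) * r^2) +
          2 * ccc^3 * (1 - ccc) * u^2 / (r * (1 - ccc^2)^2) -
          ccc^4 * u^4 / (2 * r^2 * (1 - ccc^2)^2)) / (n - 2)
  q <- stats::qnorm(1 - (1 - level) / 2)
  half <- q * sqrt(max(sz2, 0))
  list(ccc = ccc, lo = tanh(z - half), hi = tanh(z + half), n = n)
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearsonR <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Ordinary least squares y on x with confidence intervals
#'
#' Slope and intercept with standard errors and t-based confidence
#' intervals (n - 2 degrees of freedom).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param level confidence level.
#' @return list with \code{slope}, \code{intercept}, each a list of
#'   \code{est}, \code{se}, \code{lo}, \code{hi}; plus \code{r2}, \code{n}.
#' @export
olsFit <- function(x, y, level = 0.95) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  if (stats::sd(x) == 0) stop("degenerate predictor: all x equal")
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = level)
  pack <- function(row) list(est = unname(cf[row, 1]),
                             se = unname(cf[row, 2]),
                             lo = unname(ci[row, 1]),
                             hi = unname(ci[row, 2]))
  list(slope = pack("x"), intercept = pack("(Intercept)"),
       r2 = summary(fit)$r.squared, n = n)
}

#' Evaluate a study: agreement report per method and compartment
#'
#' For every (method, compartment) pair in the results table, computes
#' Lin's CCC (with 95\% CI) within each activity level, the pooled OLS
#' regression of measured index on achieved truth, Pearson's r and the
#' coefficient of determination.  The truth axis is the achieved BPI
#' (ratio - 1) for BPI- and TBPI-type indices; for the TwoBox SBR it is
#' the achieved BPI by default (\code{sbrTruth = "bpi"}, the scale the
#' TwoBox expression returns under exact capture) or the achieved ratio
#' (\code{sbrTruth = "sbr"}).
#'
#' @param results data.frame of QuantResult rows (from the quantify
#'   functions).
#' @param sbrTruth truth pairing for SBR-type indices.
#' @param cccType moment convention passed to \code{\link{linCcc}}.
#' @return data.frame with one row per (method, compartment): per-level
#'   CCCs with CIs, slope/intercept with SE and CI, \code{pearson_r},
#'   \code{cod} and \code{n}.
#' @export
evaluateStudy <- function(results, sbrTruth = c("bpi", "sbr"),
                          cccType = "population") {
  sbrTruth <- match.arg(sbrTruth)
  stopifnot(all(c("method", "compartment", "index_type", "value",
                  "truth_bpi", "truth_sbr", "activity_level") %in%
                  names(results)))
  results$truth <- ifelse(results$index_type == "SBR" & sbrTruth == "sbr",
                          results$truth_sbr, results$truth_bpi)
  keys <- unique(results[c("method", "compartment", "index_type")])
  levels <- c("high", "intermediary", "low")

  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- results[results$method == keys$method[i] &
                     results$compartment == keys$compartment[i], ]
    out <- data.frame(method = keys$method[i],
                      compartment = keys$compartment[i],
                      index_type = keys$index_type[i],
                      n = nrow(sub), stringsAsFactors = FALSE)
    for (lv in levels) {
      sl <- sub[sub$activity_level == lv, ]
      cc <- if (nrow(sl) >= 3)
        tryCatch(linCcc(sl$truth, sl$value, type = cccType),
                 error = function(e) NULL) else NULL
      out[[paste0("ccc_", lv)]] <- if (is.null(cc)) NA_real_ else cc$ccc
      out[[paste0("ccc_", lv, "_lo")]] <- if (is.null(cc)) NA_real_ else cc$lo
      out[[paste0("ccc_", lv, "_hi")]] <- if (is.null(cc)) NA_real_ else cc$hi
    }
    fit <- if (nrow(sub) >= 3 && stats::sd(sub$truth) > 0)
      olsFit(sub$truth, sub$value) else NULL
    pr <- if (!is.null(fit)) pearsonR(sub$truth, sub$value) else NULL
    out$slope <- if (is.null(fit)) NA_real_ else fit$slope$est
    out$slope_se <- if (is.null(fit)) NA_real_ else fit$slope$se
    out$slope_lo <- if (is.null(fit)) NA_real_ else fit$slope$lo
    out$slope_hi <- if (is.null(fit)) NA_real_ else fit$slope$hi
    out$intercept <- if (is.null(fit)) NA_real_ else fit$intercept$est
    out$intercept_se <- if (is.null(fit)) NA_real_ else fit$intercept$se
    out$intercept_lo <- if (is.null(fit)) NA_real_ else fit$intercept$lo
    out$intercept_hi <- if (is.null(fit)) NA_real_ else fit$intercept$hi
    out$pearson_r <- if (is.null(pr)) NA_real_ else pr$r
    out$pearson_p <- if (is.null(pr)) NA_real_ else pr$p
    out$cod <- if (is.null(pr)) NA_real_ else pr$r^2
    out
  })
  do.call(rbind, rows)
}

#' Pretty-print an agreement report
#'
#' Text table mirroring the usual layout: per-level CCC, regression
#' coefficients with CIs, Pearson's r and the coefficient of
#' determination.
#'
#' @param report data.frame from \code{\link{evaluateStudy}}.
#' @return The report, invisibly.
#' @export
printAgreementReport <- function(report) {
  fmt <- function(v) ifelse(is.na(v), "   -  ", sprintf("%6.3f", v))
  cat(sprintf("%-14s %-4s %-5s %7s %7s %7s %22s %22s %7s %7s\n",
              "method", "comp", "index", "CCC.hi", "CCC.int", "CCC.low",
              "intercept (CI)", "slope (CI)", "r", "rho2"))
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    cat(sprintf("%-14s %-4s %-5s %7s %7s %7s %7.3f (%6.3f;%6.3f) %7.3f (%5.3f;%5.3f) %7.3f %7.3f\n",
                r$method, r$compartment, r$index_type,
                fmt(r$ccc_high), fmt(r$ccc_intermediary), fmt(r$ccc_low),
                r$intercept, r$intercept_lo, r$intercept_hi,
                r$slope, r$slope_lo, r$slope_hi, r$pearson_r, r$cod))
  }
  invisible(report)
}
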