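# Method-comparison statistics: Bland-Altman mean difference with 95%
# limits of agreement, two-way random-effects absolute-agreement ICC, and
# method ranking.  Sign convention throughout: a - b = method - reference,
# so a positive mean difference means overestimation.

#' Bland-Altman analysis of paired measurements
#'
#' Differences d = a - b; the report carries mean(d) and the limits-of-
#' agreement halfwidth 1.96 x SD(d) (sample SD, n - 1), i.e. the
#' "mean +/- halfwidth" convention.
#'
#' @param a,b numeric vectors of paired measurements (method, reference).
#' @param method optional label stored in the report.
#' @param icc also compute the ICC (see \code{\link{iccAbsoluteAgreement}})?
#'   ICC is set to NA if its ANOVA decomposition is degenerate.
#' @return An \linkS4class{AgreementReport}.
#' @examples
#' blandAltman(c(10, 20, 30), c(12, 19, 33))
#' @export
blandAltman <- function(a, b, method = "", icc = FALSE) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  if (length(a) < 2L) stop("Bland-Altman requires >= 2 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing pairs are not allowed")
  d <- a - b
  iccv <- NA_real_
  if (icc) iccv <- tryCatch(iccAbsoluteAgreement(a, b), error = function(e) NA_real_)
  new("AgreementReport", method = method, meanDifference = mean(d),
      loaHalfwidth = 1.96 * stats::sd(d), icc = iccv, nPairs = length(d))
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' Single-measure absolute-agreement ICC (Shrout-Fleiss ICC(2,1)) from the
#' mean-squares decomposition of the units x raters table:
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' with MSR/MSC/MSE the row (unit), column (rater) and residual mean squares.
#'
#' @param a,b paired measurements by the two raters/methods, or \code{a} may
#'   be an n x k matrix (units x raters) with \code{b} missing.
#' @return The ICC estimate (single numeric; can be slightly negative).
#' @export
iccAbsoluteAgreement <- function(a, b = NULL) {
  Y <- if (is.null(b)) as.matrix(a) else cbind(a, b)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L || k < 2L) stop("need >= 2 units and >= 2 raters")
  if (anyNA(Y)) stop("missing values are not allowed")
  grand <- mean(Y)
  SST <- sum((Y - grand)^2)
  if (SST == 0) stop("ICC undefined: zero total variance")
  rowm <- rowMeans(Y); colm <- colMeans(Y)
  SSR <- k * sum((rowm - grand)^2)
  SSC <- n * sum((colm - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

#' Full agreement report: Bland-Altman plus ICC
#'
#' @inheritParams blandAltman
#' @return An \linkS4class{AgreementReport} with the ICC slot filled.
#' @export
agreementReport <- function(a, b, method = "") {
  blandAltman(a, b, method = method, icc = TRUE)
}

#' Concordance of per-slice SI thresholds against the manual standard
#'
#' Bland-Altman and ICC applied to the per-slice threshold values
#' (unit = slice); only LGE-positive slices should be supplied.  Sign
#' convention: method - manual.
#'
#' @param manualThresholds per-slice thresholds chosen by the manual sweep.
#' @param methodThresholds per-slice thresholds of the semi-automated method.
#' @param method optional label.
#' @return An \linkS4class{AgreementReport}.
#' @export
sliceThresholdConcordance <- function(manualThresholds, methodThresholds,
                                      method = "") {
  agreementReport(methodThresholds, manualThresholds, method = method)
}

#' Rank methods by absolute mean difference
#'
#' Sorts per-method agreement reports by |mean difference| (ties broken by
#' higher ICC) and returns a tidy table.  Positive mean difference =
#' overestimation relative to the common reference.
#'
#' @param reports list of \linkS4class{AgreementReport}, one per method,
#'   all against the same reference; names are used when a report carries
#'   no method label.
#' @return data.frame with columns method, mean_difference, loa_halfwidth,
#'   loa_lower, loa_upper, icc, n, sorted best-first.
#' @export
rankMethods <- function(reports) {
  tab <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    lab <- if (length(r@method) && nzchar(r@method[1])) r@method[1]
           else names(reports)[i]
    data.frame(method = lab,
               mean_difference = r@meanDifference,
               loa_halfwidth = r@loaHalfwidth,
               loa_lower = r@meanDifference - r@loaHalfwidth,
               loa_upper = r@meanDifference + r@loaHalfwidth,
               icc = r@icc,
               n = r@nPairs,
               stringsAsFactors = FALSE)
  }))
  ord <- order(abs(tab$mean_difference), -replace(tab$icc, is.na(tab$icc), -Inf))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Bland-Altman plot
#'
#' Classic layout: pair means on x, differences on y, horizontal lines at
#' the mean difference and at the 95% limits of agreement.
#'
#' @inheritParams blandAltman
#' @param main plot title.
#' @param xlab,ylab axis labels.
#' @return Invisibly, the \linkS4class{AgreementReport}.
#' @export
blandAltmanPlot <- function(a, b, method = "", main = NULL,
                            xlab = "Mean of pair", ylab = "Difference (a - b)") {
  rep <- blandAltman(a, b, method = method)
  if (is.null(main))
    main <- sprintf("%s: %.2f +/- %.2f", if (nzchar(method)) method else "Bland-Altman",
                    rep@meanDifference, rep@loaHalfwidth)
  plot((a + b) / 2, a - b, pch = 19, cex = 0.7, main = main,
       xlab = xlab, ylab = ylab)
  abline(h = rep@meanDifference, lty = 1)
  abline(h = rep@meanDifference + c(-1, 1) * rep@loaHalfwidth, lty = 2)
  invisible(rep)
}

#' Simulate paired ratings with a known population ICC
#'
#' Draws from the two-way model y_ij = u_i + d_j + e_ij with unit effects
#' u ~ N(0, icc), fixed rater offsets d = (-c, +c) and residual noise, the
#' variance shares chosen so the population absolute-agreement ICC equals
#' \code{icc}.  Used for parameter-recovery checks of
#' \code{\link{iccAbsoluteAgreement}}.
#'
#' @param nUnits number of units (rows).
#' @param icc target population ICC in [0, 1).
#' @param raterShare share of the non-unit variance assigned to the rater
#'   offset (the rest is residual noise).
#' @param seed integer seed.
#' @return nUnits x 2 matrix of paired ratings.
#' @export
simulateIccPairs <- function(nUnits, icc, raterShare = 0.3, seed = 1L) {
  stopifnot(icc >= 0, icc < 1)
  sigmaU <- sqrt(icc)
  sigmaR <- sqrt(raterShare * (1 - icc))
  sigmaE <- sqrt((1 - raterShare) * (1 - icc))
  withr::with_seed(as.integer(seed), {
    u <- stats::rnorm(nUnits, 0, sigmaU)
    delta <- c(-1, 1) * sigmaR / sqrt(2)   # fixed offsets with variance sigmaR^2
    e <- matrix(stats::rnorm(nUnits * 2, 0, sigmaE), nUnits, 2)
    cbind(u + delta[1] + e[, 1], u + delta[2] + e[, 2])
  })
}
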