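#' Dominant fold wavelength of a folded profile
#'
#' Wavelength of the strongest Fourier component of the linearly detrended
#' top-surface profile.  Used as the default local-window width for outcome
#' classification.
#'
#' @param profile two-column matrix (x, height), evenly spaced in x.
#' @return wavelength (mm)
#' @export
estimateFoldWavelength <- function(profile) {
  x <- profile[, 1]; h <- profile[, 2]
  r <- stats::lm.fit(cbind(1, x), h)$residuals
  n <- length(r)
  spec <- Mod(fft(r))[2:floor(n / 2)]
  k <- which.max(spec)
  (max(x) - min(x)) / k
}

#' Classify the centre of a folded profile as gyrus, sulcus or bank
#'
#' Operationalises the visual trichotomy "top of a gyrus / wall of a gyrus /
#' sulcus": the profile is linearly detrended within a local window around
#' the centre and the centre point's height percentile among the window
#' samples decides the label — at least \code{thresholds[2]} (default 75)
#' means gyrus, at most \code{thresholds[1]} (default 25) sulcus, anything
#' between a bank.  Detrending makes the rule invariant to adding a constant
#' or a linear trend.
#'
#' @param profile two-column matrix (x, height) covering
#'   [center - window/2, center + window/2].
#' @param center x-coordinate to classify (mm); defaults to the profile
#'   midpoint.
#' @param window full window width (mm); defaults to the whole profile (the
#'   centre's standing among all surface heights), which is robust when a
#'   dome or dip apex sits a few millimetres off the query point.  Pass
#'   \code{estimateFoldWavelength(profile)} for a strictly local one-
#'   wavelength window.
#' @param thresholds percentile thresholds c(sulcus, gyrus).
#' @param minAmplitude minimum detrended fold amplitude (mm) for the
#'   profile to count as folded; below it the classification errors with
#'   "no instability".
#' @return a \linkS4class{FoldOutcome}
#' @examples
#' x <- seq(0, 100, by = 0.5)
#' prof <- cbind(x, cos(2 * pi * x / 10))
#' outcomeLabel(classifyCenter(prof, center = 50, window = 10))  # crest
#' @export
classifyCenter <- function(profile, center = NULL, window = NULL,
                           thresholds = c(25, 75), minAmplitude = 0.2) {
  x <- profile[, 1]; h <- profile[, 2]
  if (is.null(center)) center <- (min(x) + max(x)) / 2
  if (is.null(window)) window <- max(x) - min(x)
  r <- stats::lm.fit(cbind(1, x), h)$residuals
  if (max(r) - min(r) < minAmplitude)
    stop("no instability: fold amplitude below threshold")
  window <- min(window, max(x) - min(x))
  inWin <- abs(x - center) <= window / 2 + 1e-9
  if (min(x) - 1e-9 > center - window / 2 ||
      max(x) + 1e-9 < center + window / 2)
    stop("profile does not cover the classification window")
  xw <- x[inWin]; hw <- h[inWin]
  # detrend within the window
  rw <- stats::lm.fit(cbind(1, xw), hw)$residuals
  ic <- which.min(abs(xw - center))
  pct <- 100 * mean(rw <= rw[ic])
  slope <- if (length(rw) > 2) {
    i2 <- max(2, min(ic, length(rw) - 1))
    (rw[i2 + 1] - rw[i2 - 1]) / (xw[i2 + 1] - xw[i2 - 1])
  } else 0
  label <- if (pct >= thresholds[2]) "gyrus"
           else if (pct <= thresholds[1]) "sulcus" else "bank"
  new("FoldOutcome", label = label, percentile = pct, localSlope = slope,
      window = window, center = center)
}

#' Tabulate fold outcomes across seeded batches
#'
#' Counts per label and mode, with the exact binomial 95\% confidence
#' interval on the gyrus proportion per mode.
#'
#' @param outcomes list of \linkS4class{FoldOutcome} objects (or character
#'   labels).
#' @param modes character vector of mode labels, recycled to the outcomes.
#' @return an \linkS4class{OutcomeTable}
#' @examples
#' tabulateOutcomes(rep(list("gyrus"), 10), "fast_patch")
#' @export
tabulateOutcomes <- function(outcomes, modes = "all") {
  if (!length(outcomes)) stop("no outcomes to tabulate")
  labels <- vapply(outcomes, function(o)
    if (is.character(o)) o else outcomeLabel(o), "")
  modes <- rep(modes, length.out = length(labels))
  lv <- c("gyrus", "sulcus", "bank")
  counts <- table(factor(labels, levels = lv), factor(modes))
  counts <- matrix(counts, nrow = 3,
                   dimnames = list(lv, colnames(counts)))
  nRuns <- colSums(counts)
  ci <- vapply(seq_len(ncol(counts)), function(j)
    as.numeric(stats::binom.test(counts["gyrus", j], nRuns[j])$conf.int),
    numeric(2))
  dimnames(ci) <- list(c("lower", "upper"), colnames(counts))
  new("OutcomeTable", counts = counts, nRuns = as.integer(nRuns),
      gyrusCI = ci)
}
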