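## Twenty time-domain sEMG features per interval.
##
## Conventions (documented because the literature varies):
##  * VAR and SSI are computed on the raw samples (the signal is zero-mean
##    after band-pass conditioning); STD is the usual mean-subtracted sample
##    standard deviation (ddof 1).
##  * KURT and SKEW use population central moments (m4/m2^2 and m3/m2^1.5),
##    not bias-corrected estimators.
##  * IAV is the trapezoidal integral of |x| at unit sample spacing and so
##    differs from the rectangular IEMG sum by (|x_1| + |x_N|)/2.

.FEATURE_NAMES <- c("iemg", "mav", "mmav1", "mmav2", "ssi", "var", "rms",
                    "std", "wl", "dasdv", "aac", "log_det", "iav", "vorder",
                    "zc", "ssc", "wamp", "myop", "kurt", "skew")

.AMPLITUDE_FEATURES <- c("iemg", "mav", "mmav1", "mmav2", "ssi", "var",
                         "rms", "std", "wl", "dasdv", "aac", "log_det",
                         "iav", "vorder")
.SHAPE_FEATURES <- c("zc", "ssc", "wamp", "myop", "kurt", "skew")
## features that can legitimately go negative (sign-crossing statistics)
.SIGNED_FEATURES <- c("skew")

#' Names of the twenty time-domain features
#'
#' @param which `"all"` (default), `"amplitude"` (the fourteen
#'   amplitude/energy features, non-negative by construction) or `"shape"`
#'   (threshold counts and distribution-shape features).
#' @return Character vector of feature names in canonical order.
#' @examples
#' featureNames()
#' @export
featureNames <- function(which = c("all", "amplitude", "shape")) {
  switch(match.arg(which),
         all = .FEATURE_NAMES,
         amplitude = .AMPLITUDE_FEATURES,
         shape = .SHAPE_FEATURES)
}

#' Extract the twenty time-domain features from one interval
#'
#' Definitions for a segment `x` of length `N` (thresholds from `th`):
#' IEMG = sum(|x|); MAV = IEMG/N; MMAV1/MMAV2 = weighted MAV with window
#' weights (0.5 outside the middle half for MMAV1; linear 4i/N ramps for
#' MMAV2); SSI = sum(x^2); VAR = SSI/(N-1); RMS = sqrt(SSI/N); STD = sample
#' SD; WL = sum(|diff(x)|); DASDV = sqrt(sum(diff(x)^2)/(N-1)); AAC = WL/N;
#' LOG = exp(mean(log(|x| + 1e-12))); IAV = trapezoidal integral of |x|;
#' VORDER = mean(|x|^v)^(1/v); ZC, SSC, WAMP = threshold crossing/slope/step
#' counts; MYOP = fraction of samples with |x| above threshold; KURT, SKEW =
#' population moment ratios. Zero-variance segments yield NaN KURT/SKEW with
#' a warning.
#'
#' @param x numeric vector of at least 4 samples (uV), or an
#'   [IntervalSegment-class].
#' @param th a [ThresholdSpec-class].
#' @return Named numeric vector of the 20 features (see [featureNames()]).
#' @examples
#' extractFeatures(c(1, -1, 1, -1), ThresholdSpec(0, 0, 0, 0, 3))
#' @export
setGeneric("extractFeatures",
           function(x, th = ThresholdSpec()) standardGeneric("extractFeatures"))

#' @rdname extractFeatures
setMethod("extractFeatures", "numeric", function(x, th = ThresholdSpec()) {
  stopifnot(is(th, "ThresholdSpec"))
  n <- length(x)
  if (n < 4L) stop("segment must have at least 4 samples")
  if (anyNA(x)) stop("segment contains missing samples")

  ax <- abs(x)
  dx <- diff(x)
  i <- seq_len(n)

  iemg <- sum(ax)
  mav <- iemg / n
  mid <- i >= 0.25 * n & i <= 0.75 * n
  w1 <- ifelse(mid, 1, 0.5)
  mmav1 <- sum(w1 * ax) / n
  w2 <- ifelse(mid, 1, ifelse(i < 0.25 * n, 4 * i / n, 4 * (n - i) / n))
  mmav2 <- sum(w2 * ax) / n
  ssi <- sum(x^2)
  varr <- ssi / (n - 1)
  rms <- sqrt(ssi / n)
  stdv <- stats::sd(x)
  wl <- sum(abs(dx))
  dasdv <- sqrt(sum(dx^2) / (n - 1))
  aac <- wl / n
  log_det <- exp(mean(log(ax + 1e-12)))
  iav <- iemg - (ax[1] + ax[n]) / 2
  v <- th@vorder_v
  vorder <- mean(ax^v)^(1 / v)
  zc <- sum(x[-n] * x[-1] < 0 & abs(dx) >= th@zc_thresh)
  ## slope product must be strictly positive: a flat run is not a slope
  ## sign change even at threshold 0
  xm <- x[2:(n - 1)]
  sscp <- (xm - x[1:(n - 2)]) * (xm - x[3:n])
  ssc <- sum(sscp >= th@ssc_thresh & sscp > 0)
  wamp <- sum(abs(dx) >= th@wamp_thresh)
  myop <- mean(ax >= th@myop_thresh)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) {
    warning("zero-variance segment: kurtosis and skewness are undefined")
    kurt <- NaN; skew <- NaN
  } else {
    kurt <- mean(xc^4) / m2^2
    skew <- mean(xc^3) / m2^1.5
  }

  c(iemg = iemg, mav = mav, mmav1 = mmav1, mmav2 = mmav2, ssi = ssi,
    var = varr, rms = rms, std = stdv, wl = wl, dasdv = dasdv, aac = aac,
    log_det = log_det, iav = iav, vorder = vorder, zc = zc, ssc = ssc,
    wamp = wamp, myop = myop, kurt = kurt, skew = skew)
})

#' @rdname extractFeatures
setMethod("extractFeatures", "IntervalSegment",
          function(x, th = ThresholdSpec()) {
  extractFeatures(x@samples, th = th)
})

#' Per-interval feature table for one recording run
#'
#' Segments the (already conditioned) recording, extracts the twenty
#' features per interval, and returns one row per segment. By default only
#' the channels relevant to the protocol's movement are analysed.
#'
#' @param rec a conditioned [EmgRecording-class].
#' @param protocol the [ProtocolSpec-class] of the run.
#' @param th a [ThresholdSpec-class].
#' @param channels data.frame of channels to analyse (subset of the
#'   recording's montage); default [relevantChannels()] for the movement.
#' @param ... passed to [segmentIntervals()] (`lead_in_s`, `trim_s`).
#' @return data.frame with columns `side`, `region`, `condition`, `trial`,
#'   `movement`, `intensity` and the 20 feature columns.
#' @export
extractFeatureTable <- function(rec, protocol, th = ThresholdSpec(),
                                channels = relevantChannels(
                                  protocol@movement, channelLabels(rec)),
                                ...) {
  stopifnot(is(rec, "EmgRecording"))
  key_rec <- paste(rec@channels$side, rec@channels$region)
  idx <- match(paste(channels$side, channels$region), key_rec)
  if (anyNA(idx)) stop("requested channels are absent from the recording")
  sub <- EmgRecording(rec@samples[, idx, drop = FALSE], rec@fs_hz,
                      channels = rec@channels[idx, , drop = FALSE])
  segs <- segmentIntervals(sub, protocol, ...)
  feat <- t(vapply(segs, function(s) extractFeatures(s@samples, th = th),
                   numeric(length(.FEATURE_NAMES))))
  meta <- data.frame(
    side = vapply(segs, slot, character(1), "side"),
    region = vapply(segs, slot, character(1), "region"),
    condition = vapply(segs, slot, character(1), "condition"),
    trial = vapply(segs, slot, integer(1), "trial_index"),
    movement = protocol@movement,
    intensity = protocol@intensity,
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feat))
}

#' Aggregate per-trial features to per-(side, condition) means
#'
#' The severity analysis works on one value per subject, side and
#' condition: the arithmetic mean over the run's trials; the across-trial
#' standard deviation is reported alongside as the dispersion.
#'
#' @param feature_table a per-trial table from [extractFeatureTable()].
#' @return Long data.frame: `side`, `region`, `condition`, `movement`,
#'   `intensity`, `feature`, `mean`, `sd`.
#' @export
aggregateTrials <- function(feature_table) {
  if (nrow(feature_table) == 0L) stop("empty feature table")
  keys <- c("side", "region", "condition", "movement", "intensity")
  present <- intersect(.FEATURE_NAMES, names(feature_table))
  groups <- split(feature_table, feature_table[keys], drop = TRUE)
  rows <- lapply(groups, function(g) {
    data.frame(g[1L, keys, drop = FALSE],
               feature = present,
               mean = vapply(present, function(f) mean(g[[f]]), numeric(1)),
               sd = vapply(present, function(f) stats::sd(g[[f]]), numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Melt a wide per-trial feature table to long format
#'
#' @param feature_table a table from [extractFeatureTable()], optionally
#'   with extra id columns (e.g. `subject_id`).
#' @return Long data.frame with `feature` and `value` columns replacing the
#'   20 feature columns.
#' @export
featureTableLong <- function(feature_table) {
  present <- intersect(.FEATURE_NAMES, names(feature_table))
  ids <- setdiff(names(feature_table), present)
  dt <- data.table::as.data.table(feature_table)
  long <- data.table::melt(dt, id.vars = ids, measure.vars = present,
                           variable.name = "feature", value.name = "value",
                           variable.factor = FALSE)
  data.table::setDF(long)
  long
}
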