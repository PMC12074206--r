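#' @import methods
NULL

.MOVEMENTS <- c("smile", "eyes", "forehead")
.INTENSITIES <- c("strong", "light")
.SIDES <- c("left", "right")
.REGIONS <- c("forehead", "eye", "mouth")
.CONDITIONS <- c("MOVE", "REST")

## region of the face each instructed movement recruits
.MOVEMENT_REGION <- c(smile = "mouth", eyes = "eye", forehead = "forehead")

#' ProtocolSpec: the MOVE/REST trial structure of one recording run
#'
#' One run consists of `n_trials` repetitions of a MOVE interval followed by a
#' REST interval (or REST first when `rest_first = TRUE`), sampled at `fs_hz`.
#' The default protocol is 20 trials of 3 s MOVE + 4 s REST at 2000 Hz, i.e.
#' 140 s and 280,000 samples per run.
#'
#' @slot n_trials integer, number of MOVE+REST repetitions (>= 1).
#' @slot move_s numeric, MOVE interval duration in seconds (> 0).
#' @slot rest_s numeric, REST interval duration in seconds (> 0).
#' @slot fs_hz numeric, sampling rate in Hz (> 0).
#' @slot movement character, one of `"smile"`, `"eyes"`, `"forehead"`.
#' @slot intensity character, `"strong"` or `"light"`.
#' @slot rest_first logical, whether each trial starts with REST.
#' @export
setClass("ProtocolSpec",
  representation(
    n_trials = "integer",
    move_s = "numeric",
    rest_s = "numeric",
    fs_hz = "numeric",
    movement = "character",
    intensity = "character",
    rest_first = "logical"
  )
)

setValidity("ProtocolSpec", function(object) {
  msg <- character()
  if (length(object@n_trials) != 1L || is.na(object@n_trials) ||
      object@n_trials < 1L)
    msg <- c(msg, "n_trials must be a single integer >= 1")
  if (length(object@move_s) != 1L || !is.finite(object@move_s) ||
      object@move_s <= 0)
    msg <- c(msg, "move_s must be a single positive number")
  if (length(object@rest_s) != 1L || !is.finite(object@rest_s) ||
      object@rest_s <= 0)
    msg <- c(msg, "rest_s must be a single positive number")
  if (length(object@fs_hz) != 1L || !is.finite(object@fs_hz) ||
      object@fs_hz <= 0)
    msg <- c(msg, "fs_hz must be a single positive number")
  if (!identical(length(object@movement), 1L) ||
      !object@movement %in% .MOVEMENTS)
    msg <- c(msg, sprintf("movement must be one of: %s",
                          paste(.MOVEMENTS, collapse = ", ")))
  if (!identical(length(object@intensity), 1L) ||
      !object@intensity %in% .INTENSITIES)
    msg <- c(msg, sprintf("intensity must be one of: %s",
                          paste(.INTENSITIES, collapse = ", ")))
  if (length(object@rest_first) != 1L || is.na(object@rest_first))
    msg <- c(msg, "rest_first must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a ProtocolSpec
#'
#' @param n_trials number of MOVE+REST repetitions.
#' @param move_s MOVE duration (s).
#' @param rest_s REST duration (s).
#' @param fs_hz sampling rate (Hz).
#' @param movement instructed movement: `"smile"`, `"eyes"` or `"forehead"`.
#' @param intensity instructed strength: `"strong"` or `"light"`.
#' @param rest_first logical; start each trial with REST instead of MOVE.
#' @return A [ProtocolSpec-class] object.
#' @examples
#' p <- ProtocolSpec()
#' protocolSamples(p)  # 280000
#' @export
ProtocolSpec <- function(n_trials = 20L, move_s = 3, rest_s = 4,
                         fs_hz = 2000, movement = "smile",
                         intensity = "strong", rest_first = FALSE) {
  new("ProtocolSpec",
      n_trials = as.integer(n_trials), move_s = as.numeric(move_s),
      rest_s = as.numeric(rest_s), fs_hz = as.numeric(fs_hz),
      movement = as.character(movement), intensity = as.character(intensity),
      rest_first = as.logical(rest_first))
}

#' SubjectProfile: synthetic-subject parameters
#'
#' Describes one synthetic subject: clinical House-Brackmann grade, which
#' facial side is lesioned, and the physical parameters of the signal model
#' (lesioned-side amplitude attenuation, baseline noise, mains interference,
#' healthy-side burst amplitude).
#'
#' @slot subject_id character scalar.
#' @slot hb_grade integer 1..6 (I = normal, VI = complete paralysis).
#' @slot lesioned_side `"left"`, `"right"`, or `"none"` (healthy control).
#' @slot attenuation numeric in \[0, 1\]; lesioned-side amplitude multiplier.
#' @slot baseline_noise_sd numeric > 0; baseline noise SD (uV).
#' @slot mains_amplitude numeric >= 0; 50 Hz mains amplitude (uV).
#' @slot burst_amplitude numeric > 0; healthy-side MOVE modulation depth (uV).
#' @slot fars logical; synkinetic reinnervation flag (reserved, generation of
#'   synkinetic activity is not implemented).
#' @slot seed integer; per-subject random stream seed.
#' @export
setClass("SubjectProfile",
  representation(
    subject_id = "character",
    hb_grade = "integer",
    lesioned_side = "character",
    attenuation = "numeric",
    baseline_noise_sd = "numeric",
    mains_amplitude = "numeric",
    burst_amplitude = "numeric",
    fars = "logical",
    seed = "integer"
  )
)

setValidity("SubjectProfile", function(object) {
  msg <- character()
  if (length(object@subject_id) != 1L || is.na(object@subject_id) ||
      !nzchar(object@subject_id))
    msg <- c(msg, "subject_id must be a non-empty string")
  if (length(object@hb_grade) != 1L || is.na(object@hb_grade) ||
      !object@hb_grade %in% 1:6)
    msg <- c(msg, "hb_grade must be an integer in 1..6")
  if (!object@lesioned_side %in% c(.SIDES, "none"))
    msg <- c(msg, "lesioned_side must be 'left', 'right' or 'none'")
  if (length(object@hb_grade) == 1L && !is.na(object@hb_grade) &&
      object@hb_grade > 1L && identical(object@lesioned_side, "none"))
    msg <- c(msg, "a subject with hb_grade > 1 must have a lesioned side")
  if (!is.finite(object@attenuation) || object@attenuation < 0 ||
      object@attenuation > 1)
    msg <- c(msg, "attenuation must lie in [0, 1]")
  if (!is.finite(object@baseline_noise_sd) || object@baseline_noise_sd <= 0)
    msg <- c(msg, "baseline_noise_sd must be > 0")
  if (!is.finite(object@mains_amplitude) || object@mains_amplitude < 0)
    msg <- c(msg, "mains_amplitude must be >= 0")
  if (!is.finite(object@burst_amplitude) || object@burst_amplitude <= 0)
    msg <- c(msg, "burst_amplitude must be > 0")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectProfile
#'
#' When `attenuation` is not given it is derived from the HB grade with
#' [attenuationForGrade()], so grade I subjects are fully symmetric.
#'
#' @param subject_id subject identifier string.
#' @param hb_grade House-Brackmann grade, integer 1..6.
#' @param lesioned_side `"left"`, `"right"`, or `"none"` (grade I only).
#' @param attenuation lesioned-side amplitude multiplier in \[0, 1\].
#' @param baseline_noise_sd baseline (instrumentation + resting muscle tone)
#'   noise SD in uV.
#' @param mains_amplitude 50 Hz mains interference amplitude in uV.
#' @param burst_amplitude healthy-side MOVE burst amplitude (SD of the
#'   modulated EMG process) in uV.
#' @param fars synkinetic reinnervation flag (reserved; must be FALSE for
#'   signal generation).
#' @param seed integer seed for the subject's random streams.
#' @return A [SubjectProfile-class] object.
#' @examples
#' SubjectProfile("S001", hb_grade = 3, lesioned_side = "left")
#' @export
SubjectProfile <- function(subject_id, hb_grade = 1L,
                           lesioned_side = c("none", "left", "right"),
                           attenuation = attenuationForGrade(hb_grade),
                           baseline_noise_sd = 2, mains_amplitude = 10,
                           burst_amplitude = 50, fars = FALSE, seed = 1L) {
  lesioned_side <- match.arg(lesioned_side)
  new("SubjectProfile",
      subject_id = as.character(subject_id),
      hb_grade = as.integer(hb_grade),
      lesioned_side = lesioned_side,
      attenuation = as.numeric(attenuation),
      baseline_noise_sd = as.numeric(baseline_noise_sd),
      mains_amplitude = as.numeric(mains_amplitude),
      burst_amplitude = as.numeric(burst_amplitude),
      fars = as.logical(fars),
      seed = as.integer(seed))
}

#' EmgRecording: a multichannel surface-EMG signal
#'
#' Holds the signal matrix (rows = samples, columns = channels, units uV),
#' the sampling rate, and per-channel facial side/region labels. The default
#' montage has six bipolar channels: forehead, eye and mouth regions on each
#' facial side.
#'
#' @slot samples numeric matrix, `n_samples x n_channels`, in uV.
#' @slot fs_hz numeric sampling rate (Hz).
#' @slot channels data.frame with columns `side` and `region`, one row per
#'   channel.
#' @export
setClass("EmgRecording",
  representation(
    samples = "matrix",
    fs_hz = "numeric",
    channels = "data.frame"
  )
)

setValidity("EmgRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@samples))
    msg <- c(msg, "samples must be a numeric matrix")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain missing values")
  if (length(object@fs_hz) != 1L || !is.finite(object@fs_hz) ||
      object@fs_hz <= 0)
    msg <- c(msg, "fs_hz must be a single positive number")
  ch <- object@channels
  if (!all(c("side", "region") %in% names(ch))) {
    msg <- c(msg, "channels must have columns 'side' and 'region'")
  } else {
    if (nrow(ch) != ncol(object@samples))
      msg <- c(msg, "one channels row is required per samples column")
    if (!all(ch$side %in% .SIDES))
      msg <- c(msg, "channel side must be 'left' or 'right'")
    if (!all(ch$region %in% .REGIONS))
      msg <- c(msg, "channel region must be 'forehead', 'eye' or 'mouth'")
    if (anyDuplicated(paste(ch$side, ch$region)))
      msg <- c(msg, "each (side, region) pair may appear at most once")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EmgRecording
#'
#' @param samples numeric matrix of signal values (uV), samples in rows.
#' @param fs_hz sampling rate in Hz.
#' @param channels data.frame with `side` and `region` columns, one row per
#'   column of `samples`; defaults to [defaultMontage()].
#' @return An [EmgRecording-class] object.
#' @export
EmgRecording <- function(samples, fs_hz, channels = defaultMontage()) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  colnames(samples) <- paste(channels$side, channels$region, sep = "_")
  new("EmgRecording", samples = samples, fs_hz = as.numeric(fs_hz),
      channels = as.data.frame(channels))
}

#' The default six-channel bipolar montage
#'
#' Three bipolar channels per facial side, covering the forehead, eye and
#' mouth regions.
#'
#' @return A data.frame with columns `side` and `region` (6 rows).
#' @export
defaultMontage <- function() {
  data.frame(side = rep(.SIDES, each = 3L),
             region = rep(.REGIONS, times = 2L),
             stringsAsFactors = FALSE)
}

#' FilterSpec: a Butterworth band specification
#'
#' @slot kind `"bandpass"` or `"bandstop"`.
#' @slot order integer Butterworth prototype order.
#' @slot low_hz lower band edge (Hz).
#' @slot high_hz upper band edge (Hz).
#' @export
setClass("FilterSpec",
  representation(
    kind = "character",
    order = "integer",
    low_hz = "numeric",
    high_hz = "numeric"
  )
)

setValidity("FilterSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("bandpass", "bandstop"))
    msg <- c(msg, "kind must be 'bandpass' or 'bandstop'")
  if (length(object@order) != 1L || is.na(object@order) || object@order < 1L)
    msg <- c(msg, "order must be a positive integer")
  if (!is.finite(object@low_hz) || !is.finite(object@high_hz) ||
      object@low_hz <= 0 || object@high_hz <= object@low_hz)
    msg <- c(msg, "band edges must satisfy 0 < low_hz < high_hz")
  if (length(msg)) msg else TRUE
})

#' Construct a FilterSpec
#'
#' @param kind `"bandpass"` or `"bandstop"`.
#' @param order Butterworth prototype order (default 4).
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2` at design time.
#' @return A [FilterSpec-class] object.
#' @examples
#' FilterSpec("bandpass", 4, 10, 250)
#' FilterSpec("bandstop", 4, 48.5, 51.5)
#' @export
FilterSpec <- function(kind = c("bandpass", "bandstop"), order = 4L,
                       low_hz, high_hz) {
  kind <- match.arg(kind)
  new("FilterSpec", kind = kind, order = as.integer(order),
      low_hz = as.numeric(low_hz), high_hz = as.numeric(high_hz))
}

#' IntervalSegment: one MOVE or REST window of one channel
#'
#' @slot samples numeric vector of signal values (uV).
#' @slot condition `"MOVE"` or `"REST"`.
#' @slot trial_index integer >= 1.
#' @slot side,region channel labels.
#' @slot movement,intensity the protocol run labels.
#' @export
setClass("IntervalSegment",
  representation(
    samples = "numeric",
    condition = "character",
    trial_index = "integer",
    side = "character",
    region = "character",
    movement = "character",
    intensity = "character"
  )
)

setValidity("IntervalSegment", function(object) {
  msg <- character()
  if (!object@condition %in% .CONDITIONS)
    msg <- c(msg, "condition must be 'MOVE' or 'REST'")
  if (length(object@trial_index) != 1L || is.na(object@trial_index) ||
      object@trial_index < 1L)
    msg <- c(msg, "trial_index must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' ThresholdSpec: thresholds for count-type features
#'
#' Zero crossing (ZC), slope sign change (SSC) and Willison amplitude (WAMP)
#' counts, and the myopulse percentage rate (MYOP), require noise-rejection
#' thresholds; the v-order statistic requires its order `v`. Defaults follow
#' common myoelectric practice and are fully configurable.
#'
#' @slot zc_thresh uV; minimum step across a zero crossing (default 5).
#' @slot ssc_thresh uV^2; minimum slope-product at a slope sign change
#'   (default 5).
#' @slot wamp_thresh uV; minimum absolute sample-to-sample step (default 10).
#' @slot myop_thresh uV; absolute amplitude above which a sample counts as a
#'   myopulse (default 16).
#' @slot vorder_v order of the v-order statistic (default 3; 2 would
#'   duplicate RMS).
#' @export
setClass("ThresholdSpec",
  representation(
    zc_thresh = "numeric",
    ssc_thresh = "numeric",
    wamp_thresh = "numeric",
    myop_thresh = "numeric",
    vorder_v = "numeric"
  )
)

setValidity("ThresholdSpec", function(object) {
  vals <- c(object@zc_thresh, object@ssc_thresh, object@wamp_thresh,
            object@myop_thresh, object@vorder_v)
  msg <- character()
  if (length(vals) != 5L || !all(is.finite(vals)))
    msg <- c(msg, "all thresholds must be single finite numbers")
  else {
    if (any(vals[1:4] < 0))
      msg <- c(msg, "thresholds must be >= 0")
    if (object@vorder_v <= 0)
      msg <- c(msg, "vorder_v must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ThresholdSpec
#'
#' @param zc_thresh,ssc_thresh,wamp_thresh,myop_thresh,vorder_v see
#'   [ThresholdSpec-class].
#' @return A [ThresholdSpec-class] object.
#' @export
ThresholdSpec <- function(zc_thresh = 5, ssc_thresh = 5, wamp_thresh = 10,
                          myop_thresh = 16, vorder_v = 3) {
  new("ThresholdSpec", zc_thresh = as.numeric(zc_thresh),
      ssc_thresh = as.numeric(ssc_thresh),
      wamp_thresh = as.numeric(wamp_thresh),
      myop_thresh = as.numeric(myop_thresh),
      vorder_v = as.numeric(vorder_v))
}
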