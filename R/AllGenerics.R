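#' Accessors for EMG objects
#'
#' `emgData()` returns the signal matrix, `samplingRate()` the sampling rate
#' in Hz, `channelLabels()` the per-channel side/region table, `nSamples()`
#' and `nChannels()` the matrix dimensions, and `recordingDuration()` the
#' duration in seconds.
#'
#' @param x an [EmgRecording-class] (or, for `samplingRate`, a
#'   [ProtocolSpec-class]).
#' @return See each accessor's description.
#' @name emg-accessors
#' @aliases emgData samplingRate channelLabels nSamples nChannels
#'   recordingDuration
#' @examples
#' rec <- EmgRecording(matrix(0, 100, 6), fs_hz = 2000)
#' nSamples(rec); nChannels(rec); samplingRate(rec)
NULL

#' @rdname emg-accessors
#' @export
setGeneric("emgData", function(x) standardGeneric("emgData"))

#' @rdname emg-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname emg-accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname emg-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname emg-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname emg-accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname emg-accessors
setMethod("emgData", "EmgRecording", function(x) x@samples)

#' @rdname emg-accessors
setMethod("samplingRate", "EmgRecording", function(x) x@fs_hz)

#' @rdname emg-accessors
setMethod("samplingRate", "ProtocolSpec", function(x) x@fs_hz)

#' @rdname emg-accessors
setMethod("channelLabels", "EmgRecording", function(x) x@channels)

#' @rdname emg-accessors
setMethod("nSamples", "EmgRecording", function(x) nrow(x@samples))

#' @rdname emg-accessors
setMethod("nChannels", "EmgRecording", function(x) ncol(x@samples))

#' @rdname emg-accessors
setMethod("recordingDuration", "EmgRecording",
          function(x) nrow(x@samples) / x@fs_hz)

#' Total number of samples a protocol run spans
#'
#' @param protocol a [ProtocolSpec-class].
#' @return `round(n_trials * (move_s + rest_s) * fs_hz)`.
#' @export
protocolSamples <- function(protocol) {
  stopifnot(is(protocol, "ProtocolSpec"))
  as.integer(round(protocol@n_trials *
                     (protocol@move_s + protocol@rest_s) * protocol@fs_hz))
}

#' Samples in one interval segment
#'
#' @param seg an [IntervalSegment-class].
#' @return Numeric vector of the segment's samples (uV).
#' @export
segmentData <- function(seg) {
  stopifnot(is(seg, "IntervalSegment"))
  seg@samples
}

#' Condition label of one interval segment
#'
#' @param seg an [IntervalSegment-class].
#' @return `"MOVE"` or `"REST"`.
#' @export
segmentCondition <- function(seg) {
  stopifnot(is(seg, "IntervalSegment"))
  seg@condition
}

setMethod("show", "ProtocolSpec", function(object) {
  cat(sprintf(
    "ProtocolSpec: %d trials of %g s MOVE + %g s REST @ %g Hz\n",
    object@n_trials, object@move_s, object@rest_s, object@fs_hz))
  cat(sprintf("  movement: %s (%s)%s; %d samples per run\n",
              object@movement, object@intensity,
              if (object@rest_first) ", REST first" else "",
              protocolSamples(object)))
})

setMethod("show", "SubjectProfile", function(object) {
  cat(sprintf("SubjectProfile '%s': HB %s, lesioned side %s\n",
              object@subject_id, as.roman(object@hb_grade),
              object@lesioned_side))
  cat(sprintf(
    "  attenuation %.2f | burst %.3g uV | baseline sd %.3g uV | mains %.3g uV | seed %d\n",
    object@attenuation, object@burst_amplitude, object@baseline_noise_sd,
    object@mains_amplitude, object@seed))
})

setMethod("show", "EmgRecording", function(object) {
  cat(sprintf("EmgRecording: %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(object@samples), ncol(object@samples), object@fs_hz,
              nrow(object@samples) / object@fs_hz))
  cat("  channels:", paste(colnames(object@samples), collapse = ", "), "\n")
})

setMethod("show", "FilterSpec", function(object) {
  cat(sprintf("FilterSpec: order-%d Butterworth %s, %g-%g Hz\n",
              object@order, object@kind, object@low_hz, object@high_hz))
})

setMethod("show", "IntervalSegment", function(object) {
  cat(sprintf("IntervalSegment: %s trial %d, %s %s (%s, %s), %d samples\n",
              object@condition, object@trial_index, object@side,
              object@region, object@movement, object@intensity,
              length(object@samples)))
})
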