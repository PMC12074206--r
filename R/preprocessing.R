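## Signal conditioning and protocol-clock segmentation.
##
## Conditioning applies a 4th-order Butterworth band-pass (10-250 Hz) and a
## 4th-order Butterworth band-stop (48.5-51.5 Hz, mains) per channel,
## zero-phase (forward-backward), so MOVE onsets are not delayed; the
## effective amplitude response is the squared single-pass response.

#' Design a Butterworth filter for a given sampling rate
#'
#' @param spec a [FilterSpec-class].
#' @param fs_hz sampling rate the filter will run at (Hz). Band edges must
#'   lie strictly below the Nyquist frequency.
#' @return An object of class `emgFilter`: a list with the `signal::butter`
#'   coefficients (`b`, `a`), the spec and the design rate.
#' @examples
#' bp <- designButterworth(FilterSpec("bandpass", 4, 10, 250), 2000)
#' filterGain(bp, 100)   # ~1 in mid-band
#' @export
designButterworth <- function(spec, fs_hz) {
  stopifnot(is(spec, "FilterSpec"))
  validObject(spec)
  if (spec@high_hz >= fs_hz / 2)
    stop(sprintf("band edge %g Hz is at or above Nyquist (%g Hz)",
                 spec@high_hz, fs_hz / 2))
  type <- if (spec@kind == "bandpass") "pass" else "stop"
  flt <- signal::butter(spec@order,
                        c(spec@low_hz, spec@high_hz) / (fs_hz / 2),
                        type = type)
  structure(list(b = flt$b, a = flt$a, spec = spec, fs_hz = fs_hz),
            class = "emgFilter")
}

#' Single-pass magnitude response of a designed filter
#'
#' Evaluates |H(e^(i 2 pi f / fs))| directly from the coefficients. The
#' zero-phase conditioning in [applyConditioning()] has the square of this
#' response.
#'
#' @param filt an `emgFilter` from [designButterworth()].
#' @param f_hz frequencies (Hz) at which to evaluate the gain.
#' @return Numeric vector of magnitude gains.
#' @export
filterGain <- function(filt, f_hz) {
  stopifnot(inherits(filt, "emgFilter"))
  vapply(f_hz, function(f) {
    z <- exp(-1i * 2 * pi * f / filt$fs_hz)
    zp <- z^(seq_along(filt$b) - 1)
    abs(sum(filt$b * zp) / sum(filt$a * z^(seq_along(filt$a) - 1)))
  }, numeric(1))
}

#' Condition a recording (band-pass + mains band-stop, zero-phase)
#'
#' Applies both filters per channel with forward-backward filtering
#' (`signal::filtfilt`), preserving length and phase.
#'
#' @param rec an [EmgRecording-class].
#' @param bandpass,bandstop [FilterSpec-class] objects; defaults are the
#'   10-250 Hz band-pass and 48.5-51.5 Hz band-stop, both order 4.
#' @return A conditioned [EmgRecording-class] of identical dimensions.
#' @export
applyConditioning <- function(rec,
                              bandpass = FilterSpec("bandpass", 4, 10, 250),
                              bandstop = FilterSpec("bandstop", 4, 48.5, 51.5)) {
  stopifnot(is(rec, "EmgRecording"))
  if (nSamples(rec) == 0L) stop("recording is empty")
  bp <- designButterworth(bandpass, rec@fs_hz)
  bs <- designButterworth(bandstop, rec@fs_hz)
  m <- rec@samples
  for (j in seq_len(ncol(m))) {
    x <- signal::filtfilt(signal::Arma(b = bp$b, a = bp$a), m[, j])
    m[, j] <- signal::filtfilt(signal::Arma(b = bs$b, a = bs$a), x)
  }
  EmgRecording(m, fs_hz = rec@fs_hz, channels = rec@channels)
}

#' Segment a recording into MOVE and REST intervals by the protocol clock
#'
#' Segmentation is purely protocol-driven (no onset detection): starting at
#' sample 0 (plus an optional lead-in pad), each trial contributes one MOVE
#' window of `round(move_s * fs)` samples and one REST window of
#' `round(rest_s * fs)` samples, in protocol order. Intervals are half-open
#' and non-overlapping, and together cover the protocol span exactly.
#'
#' @param rec an [EmgRecording-class] (typically conditioned).
#' @param protocol the [ProtocolSpec-class] the run followed.
#' @param lead_in_s seconds to skip before the first trial (default 0).
#' @param trim_s seconds trimmed from both ends of every interval before the
#'   samples are extracted (default 0; a guard band for sensitivity
#'   analyses).
#' @return A list of [IntervalSegment-class], ordered channel-major then
#'   trial, with `2 * n_trials` segments per channel.
#' @export
segmentIntervals <- function(rec, protocol, lead_in_s = 0, trim_s = 0) {
  stopifnot(is(rec, "EmgRecording"), is(protocol, "ProtocolSpec"))
  fs <- protocol@fs_hz
  if (abs(fs - rec@fs_hz) > 1e-9)
    stop(sprintf("sampling-rate mismatch: recording %g Hz, protocol %g Hz",
                 rec@fs_hz, fs))
  move_n <- as.integer(round(protocol@move_s * fs))
  rest_n <- as.integer(round(protocol@rest_s * fs))
  lead_n <- as.integer(round(lead_in_s * fs))
  trim_n <- as.integer(round(trim_s * fs))
  need <- lead_n + protocol@n_trials * (move_n + rest_n)
  if (nSamples(rec) < need)
    stop(sprintf("recording too short for protocol: %d samples present, %d required (%d missing)",
                 nSamples(rec), need, need - nSamples(rec)))

  first <- if (protocol@rest_first) "REST" else "MOVE"
  second <- setdiff(.CONDITIONS, first)
  len <- c(MOVE = move_n, REST = rest_n)

  out <- vector("list", nChannels(rec) * protocol@n_trials * 2L)
  k <- 0L
  for (ch in seq_len(nChannels(rec))) {
    pos <- lead_n                               # 0-based cursor
    for (tr in seq_len(protocol@n_trials)) {
      for (cond in c(first, second)) {
        n_c <- len[[cond]]
        idx <- (pos + 1L + trim_n):(pos + n_c - trim_n)
        k <- k + 1L
        out[[k]] <- new("IntervalSegment",
          samples = rec@samples[idx, ch],
          condition = cond, trial_index = tr,
          side = rec@channels$side[ch], region = rec@channels$region[ch],
          movement = protocol@movement, intensity = protocol@intensity)
        pos <- pos + n_c
      }
    }
  }
  out
}

#' Channels relevant to an instructed movement
#'
#' Analysis restricts each movement to the electrodes over the recruited
#' region: smiling to the mouth channels, eye closure to the eye channels,
#' forehead raising to the forehead channels — both facial sides.
#'
#' @param movement `"smile"`, `"eyes"` or `"forehead"`.
#' @param montage channel table (data.frame with `side`, `region`), default
#'   [defaultMontage()].
#' @return The montage rows (with their original row indices in
#'   `attr(, "index")`) whose region matches the movement.
#' @examples
#' relevantChannels("smile")
#' @export
relevantChannels <- function(movement, montage = defaultMontage()) {
  movement <- match.arg(movement, .MOVEMENTS)
  if (nrow(montage) == 0L) stop("montage is empty")
  region <- .MOVEMENT_REGION[[movement]]
  idx <- which(montage$region == region)
  if (length(idx) == 0L)
    stop(sprintf("montage has no '%s' channels for movement '%s'",
                 region, movement))
  out <- montage[idx, , drop = FALSE]
  attr(out, "index") <- idx
  out
}
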