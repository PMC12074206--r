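# Small in-code fixtures shared across test files.

smallProtocol <- function(n_trials = 3L, move_s = 0.5, rest_s = 0.5,
                          fs_hz = 1000, ...) {
  ProtocolSpec(n_trials = n_trials, move_s = move_s, rest_s = rest_s,
               fs_hz = fs_hz, ...)
}

zeroThresholds <- function() ThresholdSpec(0, 0, 0, 0, 3)

sineRecording <- function(f_hz, amp = 100, fs = 2000, dur_s = 10,
                          n_channels = 6) {
  t <- (seq_len(fs * dur_s) - 1) / fs
  EmgRecording(matrix(rep(amp * sin(2 * pi * f_hz * t), n_channels),
                      ncol = n_channels), fs_hz = fs)
}

centralRMS <- function(x, frac = 0.8) {
  n <- length(x)
  lo <- floor(n * (1 - frac) / 2) + 1
  hi <- n - floor(n * (1 - frac) / 2)
  sqrt(mean(x[lo:hi]^2))
}
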