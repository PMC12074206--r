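test_that("Butterworth designs have the specified band behaviour", {
  bp <- designButterworth(FilterSpec("bandpass", 4, 10, 250), 2000)
  expect_equal(filterGain(bp, 100), 1, tolerance = 0.01)
  expect_equal(filterGain(bp, 0), 0, tolerance = 1e-10)
  # -3 dB at the band edges, within 1% design tolerance
  expect_equal(filterGain(bp, c(10, 250)), rep(1 / sqrt(2), 2),
               tolerance = 0.01)
  bs <- designButterworth(FilterSpec("bandstop", 4, 48.5, 51.5), 2000)
  expect_lt(filterGain(bs, 50), 0.01)
  expect_gt(filterGain(bs, 100), 0.99)
  expect_error(designButterworth(FilterSpec("bandpass", 4, 10, 1000), 2000),
               "Nyquist")
  expect_error(FilterSpec("bandpass", 4, 250, 10), "low_hz")
})

test_that("conditioning notches mains, passes the EMG band, kills DC", {
  r50 <- applyConditioning(sineRecording(50))
  expect_lt(centralRMS(emgData(r50)[, 1]), 5)
  r100 <- applyConditioning(sineRecording(100))
  expect_equal(centralRMS(emgData(r100)[, 1]), 100 / sqrt(2),
               tolerance = 0.02)
  dc <- applyConditioning(EmgRecording(matrix(50, 20000, 6), 2000))
  expect_lt(centralRMS(emgData(dc)[, 1], frac = 0.5), 1e-3)
  # length preserved; mean ~ 0 over whole periods after transient exclusion
  expect_equal(nSamples(r100), 20000)
  xm <- emgData(r100)[2001:18000, 1]
  expect_lt(abs(mean(xm)), 1e-6 * sd(xm))
})

test_that("conditioning is idempotent at 50 Hz: a second pass is inert", {
  # mains-contaminated noise; 50 Hz power via Hann-windowed Goertzel so
  # spectral leakage does not mask the notch floor
  set.seed(5)
  t <- (0:11999) / 2000
  m <- matrix(rnorm(12000 * 6, sd = 5), ncol = 6) + 50 * sin(2 * pi * 50 * t)
  rec <- EmgRecording(m, 2000)
  once <- applyConditioning(rec)
  again <- applyConditioning(once)
  p50 <- function(x) {
    n <- length(x)
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    k <- 2 * pi * 50 * (seq_len(n) - 1) / 2000
    (sum(w * x * cos(k))^2 + sum(w * x * sin(k))^2) / sum(w^2)
  }
  cen <- 1201:10800
  raw <- p50(emgData(rec)[cen, 1])
  p1 <- p50(emgData(once)[cen, 1])
  p2 <- p50(emgData(again)[cen, 1])
  expect_lt(p1, raw * 1e-5)
  expect_lt(abs(p2 - p1), raw * 1e-6)
})

test_that("conditioning is zero-phase: a burst's energy centroid stays put", {
  fs <- 2000
  t <- (0:9999) / fs
  pulse <- exp(-((t - 2.5)^2) / (2 * 0.05^2)) * sin(2 * pi * 80 * t) * 100
  rec <- EmgRecording(matrix(rep(pulse, 6), ncol = 6), fs)
  cond <- applyConditioning(rec)
  centroid <- function(x) sum(seq_along(x) * x^2) / sum(x^2)
  expect_equal(centroid(emgData(cond)[, 1]), centroid(pulse), tolerance = 1)
})

test_that("segmentation partitions the protocol span exactly", {
  pr <- smallProtocol(n_trials = 3L, move_s = 0.5, rest_s = 0.7, fs_hz = 500)
  n <- protocolSamples(pr)
  rec <- EmgRecording(matrix(seq_len(n * 6), nrow = n), 500)
  segs <- segmentIntervals(rec, pr)
  expect_length(segs, 6 * 3 * 2)
  per_ch <- split(segs, vapply(segs, function(s) paste(s@side, s@region),
                               character(1)))
  for (chsegs in per_ch) {
    expect_equal(sum(vapply(chsegs, function(s) s@condition == "MOVE",
                            logical(1))), 3)
    recon <- unlist(lapply(chsegs, segmentData))
    col <- chsegs[[1]]
    orig <- emgData(rec)[, paste(col@side, col@region, sep = "_")]
    expect_identical(recon, unname(orig))  # exact coverage, no overlap
  }
  # MOVE/REST lengths
  lens <- vapply(segs, function(s) length(s@samples), integer(1))
  conds <- vapply(segs, segmentCondition, character(1))
  expect_true(all(lens[conds == "MOVE"] == 250))
  expect_true(all(lens[conds == "REST"] == 350))
})

test_that("segmentation honours ordering, rest_first, and length checks", {
  pr <- smallProtocol(n_trials = 1L, move_s = 0.5, rest_s = 0.5, fs_hz = 500)
  rec <- EmgRecording(matrix(0, protocolSamples(pr), 6), 500)
  segs <- segmentIntervals(rec, pr)
  expect_equal(vapply(segs[1:2], segmentCondition, character(1)),
               c("MOVE", "REST"))
  prR <- smallProtocol(n_trials = 1L, move_s = 0.5, rest_s = 0.5,
                       fs_hz = 500, rest_first = TRUE)
  expect_equal(segmentCondition(segmentIntervals(rec, prR)[[1]]), "REST")
  short <- EmgRecording(matrix(0, protocolSamples(pr) - 10, 6), 500)
  expect_error(segmentIntervals(short, pr), "10 missing")
  wrong_fs <- EmgRecording(matrix(0, protocolSamples(pr), 6), 1000)
  expect_error(segmentIntervals(wrong_fs, pr), "mismatch")
})

test_that("movement-relevant channel selection follows the region map", {
  sm <- relevantChannels("smile")
  expect_setequal(paste(sm$side, sm$region),
                  c("left mouth", "right mouth"))
  fh <- relevantChannels("forehead")
  expect_setequal(paste(fh$side, fh$region),
                  c("left forehead", "right forehead"))
  ey <- relevantChannels("eyes")
  expect_setequal(ey$region, "eye")
  no_eye <- defaultMontage()[defaultMontage()$region != "eye", ]
  expect_error(relevantChannels("eyes", no_eye), "no 'eye' channels")
})
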