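test_that("grade-to-attenuation map is the documented strictly decreasing map", {
  expect_equal(attenuationForGrade(1), 1.00)
  expect_equal(attenuationForGrade(6), 0.05)
  expect_equal(attenuationForGrade(3), 0.55)
  a <- attenuationForGrade(1:6)
  expect_true(all(diff(a) < 0))
  expect_error(attenuationForGrade(0), "1..6")
  expect_error(attenuationForGrade(7), "1..6")
  # custom maps must stay strictly decreasing
  expect_error(attenuationForGrade(2, map = c(1, 1, 0.5, 0.4, 0.3, 0.2)),
               "decreasing")
})

test_that("profiles validate their clinical invariants", {
  expect_error(SubjectProfile("S1", hb_grade = 3, lesioned_side = "none"),
               "lesioned side")
  expect_error(SubjectProfile("S1", hb_grade = 7), "1..6")
  p <- SubjectProfile("S1", hb_grade = 1)
  expect_equal(p@attenuation, 1.0)
  expect_error(generateRecording(
    SubjectProfile("S1", hb_grade = 2, lesioned_side = "left", fars = TRUE),
    smallProtocol()), "not implemented")
})

test_that("generation is deterministic and shielded from the global RNG", {
  prof <- SubjectProfile("S1", hb_grade = 3, lesioned_side = "left",
                         seed = 101)
  pr <- smallProtocol()
  set.seed(1); r1 <- generateRecording(prof, pr)
  set.seed(999); r2 <- generateRecording(prof, pr)
  expect_identical(emgData(r1), emgData(r2))
  # global stream is restored
  set.seed(42); before <- rnorm(3)
  set.seed(42); invisible(generateRecording(prof, pr)); after <- rnorm(3)
  expect_identical(before, after)
  # different seed, different samples
  prof2 <- SubjectProfile("S1", hb_grade = 3, lesioned_side = "left",
                          seed = 102)
  expect_false(identical(emgData(r1), emgData(generateRecording(prof2, pr))))
})

test_that("shared noise streams give exactly symmetric healthy sides", {
  prof <- SubjectProfile("C1", hb_grade = 1, lesioned_side = "none",
                         seed = 7)
  rec <- generateRecording(prof, smallProtocol(), shared_noise = TRUE)
  m <- emgData(rec)
  for (reg in c("forehead", "eye", "mouth"))
    expect_identical(m[, paste0("left_", reg)], m[, paste0("right_", reg)])
})

test_that("the envelope is confined to MOVE on movement-relevant channels", {
  # noise-free limit: REST must be exactly zero, MOVE non-zero, and
  # non-relevant regions silent throughout
  prof <- SubjectProfile("S1", hb_grade = 1, lesioned_side = "none",
                         baseline_noise_sd = 1e-9, mains_amplitude = 0,
                         seed = 3)
  pr <- smallProtocol(n_trials = 2L, move_s = 1, rest_s = 1, fs_hz = 500,
                      movement = "smile")
  rec <- generateRecording(prof, pr)
  m <- emgData(rec)
  move1 <- 1:500; rest1 <- 501:1000
  expect_gt(sd(m[move1, "left_mouth"]), 1)
  expect_lt(max(abs(m[rest1, "left_mouth"])), 1e-6)
  expect_lt(max(abs(m[, "left_forehead"])), 1e-6)
  # rest_first flips the layout
  rec2 <- generateRecording(prof, smallProtocol(n_trials = 2L, move_s = 1,
                                                rest_s = 1, fs_hz = 500,
                                                rest_first = TRUE))
  expect_lt(max(abs(emgData(rec2)[move1, "left_mouth"])), 1e-6)
})

test_that("doubling the burst amplitude doubles healthy MOVE RMS", {
  pr <- smallProtocol(n_trials = 4L, move_s = 1, rest_s = 0.5, fs_hz = 500)
  mk <- function(amp) {
    prof <- SubjectProfile("S1", hb_grade = 1, lesioned_side = "none",
                           burst_amplitude = amp, baseline_noise_sd = 1e-9,
                           mains_amplitude = 0, seed = 88)
    emgData(generateRecording(prof, pr))[, "left_mouth"]
  }
  x1 <- mk(25); x2 <- mk(50)
  expect_equal(sqrt(mean(x2^2)) / sqrt(mean(x1^2)), 2, tolerance = 1e-6)
})

test_that("light intensity halves the burst amplitude", {
  prof <- SubjectProfile("S1", hb_grade = 1, lesioned_side = "none",
                         baseline_noise_sd = 1e-9, mains_amplitude = 0,
                         seed = 4)
  strong <- generateRecording(prof, smallProtocol(intensity = "strong"))
  light <- generateRecording(prof, smallProtocol(intensity = "light"))
  rms <- function(r) sqrt(mean(emgData(r)[, "left_mouth"]^2))
  expect_equal(rms(strong) / rms(light), 2, tolerance = 1e-6)
})

test_that("REST amplitude is grade-independent while MOVE attenuates", {
  pr <- smallProtocol(n_trials = 4L, move_s = 1, rest_s = 1, fs_hz = 500)
  rest_idx <- as.vector(sapply(0:3, function(k) k * 1000 + 501:1000))
  move_idx <- as.vector(sapply(0:3, function(k) k * 1000 + 1:500))
  mk <- function(grade, side) {
    prof <- SubjectProfile("S1", hb_grade = grade, lesioned_side = side,
                           mains_amplitude = 0, seed = 55)
    emgData(generateRecording(prof, pr))[, "left_mouth"]
  }
  healthy <- mk(1, "none"); severe <- mk(6, "left")
  expect_identical(healthy[rest_idx], severe[rest_idx])
  expect_gt(sd(healthy[move_idx]), 5 * sd(severe[move_idx]))
})

test_that("cohort generation is deterministic with the documented layout", {
  pr <- list(smallProtocol())
  coh <- generateCohort(2, groups = 0:4, protocols = pr, master_seed = 31)
  expect_length(coh$profiles, 10)
  expect_equal(nrow(coh$manifest), 10)
  expect_equal(sum(coh$manifest$hb_group == 0), 2)
  expect_true(all(coh$manifest$lesioned_side[coh$manifest$hb_group == 0] ==
                    "none"))
  expect_true(all(coh$manifest$lesioned_side[coh$manifest$hb_group > 0] %in%
                    c("left", "right")))
  # HB II+III group cycles grades 2 and 3
  expect_setequal(coh$manifest$hb_grade[coh$manifest$hb_group == 2], c(2, 3))
  # controls are grade I with attenuation 1
  expect_equal(coh$profiles[[1]]@attenuation, 1.0)
  # bit-identical rerun
  coh2 <- generateCohort(2, groups = 0:4, protocols = pr, master_seed = 31)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(emgData(coh$recordings[[1]][[1]]),
                   emgData(coh2$recordings[[1]][[1]]))
  expect_error(generateCohort(2, groups = integer()), "at least one")
  expect_error(generateCohort(0, groups = 0:1), "n_per_group")
})

test_that("hb group coding follows the five-level ordinal scheme", {
  expect_equal(hbGroupCode(1, is_control = TRUE), 0L)
  expect_equal(hbGroupCode(1, is_control = FALSE), 1L)
  expect_equal(hbGroupCode(c(2, 3, 4, 5, 6)), c(2L, 2L, 3L, 3L, 4L))
  expect_length(hbGroupLabels(), 5)
})
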