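## Synthetic bilateral facial sEMG generator.
##
## Signal model, per channel:
##   x(t) = e(t) * g * b(t) + n(t) + m * sin(2*pi*50*t + phi)
## where b(t) is zero-mean unit-variance Gaussian noise band-shaped to
## 20-250 Hz, e(t) the MOVE/REST envelope (burst amplitude during MOVE with
## 100 ms linear ramps, 0 during REST), g the lesioned-side attenuation for
## movement-relevant channels (1 otherwise), n(t) white baseline noise and
## m the 50 Hz mains amplitude. The envelope is applied only to channels of
## the region the instructed movement recruits.

#' Lesioned-side amplitude attenuation for a House-Brackmann grade
#'
#' Maps the clinical ordinal grade onto the amplitude multiplier applied to
#' lesioned-side channels of the movement-relevant region during MOVE. The
#' default map is strictly decreasing from 1.0 (grade I, no palsy) to 0.05
#' (grade VI, residual noise floor only); no published amplitude-vs-grade
#' relation exists, so the map is a configurable modelling choice.
#'
#' @param hb_grade integer vector with values in 1..6.
#' @param map numeric length-6 vector, the attenuation for grades 1..6.
#' @return Numeric vector of attenuations in \[0, 1\].
#' @examples
#' attenuationForGrade(1:6)
#' @export
attenuationForGrade <- function(hb_grade,
                                map = c(1.00, 0.80, 0.55, 0.35, 0.20, 0.05)) {
  if (length(map) != 6L || any(!is.finite(map)) ||
      any(map < 0) || any(map > 1) || any(diff(map) >= 0))
    stop("'map' must be 6 strictly decreasing values in [0, 1]")
  g <- as.integer(hb_grade)
  if (length(g) == 0L || anyNA(g) || any(g < 1L | g > 6L))
    stop("hb_grade must be in 1..6")
  map[g]
}

## deterministic per-channel sub-seed; kept below 2^31 - 1. The stream
## depends on the movement but not the intensity, so a strong and a light
## run of one movement differ exactly by the halved burst amplitude.
.channelSeed <- function(seed, movement, stream_id) {
  run_off <- match(movement, .MOVEMENTS) - 1L
  as.integer((as.numeric(seed) * 48271 + run_off * 7907 +
                stream_id * 104729) %% 2147483647)
}

## MOVE/REST envelope in [0, 1]; linear ramps of ramp_s at MOVE on/offsets
.moveRestEnvelope <- function(protocol, ramp_s = 0.1) {
  fs <- protocol@fs_hz
  move_n <- as.integer(round(protocol@move_s * fs))
  rest_n <- as.integer(round(protocol@rest_s * fs))
  ramp_n <- min(as.integer(round(ramp_s * fs)), move_n %/% 2L)
  move <- rep(1, move_n)
  if (ramp_n > 0L) {
    ramp <- seq_len(ramp_n) / ramp_n
    move[seq_len(ramp_n)] <- ramp
    move[move_n - ramp_n + seq_len(ramp_n)] <- rev(ramp)
  }
  trial <- if (protocol@rest_first) c(rep(0, rest_n), move)
           else c(move, rep(0, rest_n))
  rep(trial, protocol@n_trials)
}

#' Generate one bilateral sEMG recording
#'
#' Simulates the six-channel bipolar montage for one protocol run. The
#' MOVE/REST envelope modulates band-limited (20-250 Hz) Gaussian EMG
#' activity on the channels of the movement-relevant region only; the
#' lesioned-side channel of that region is scaled by the profile's
#' attenuation. All channels additionally carry white baseline noise and a
#' 50 Hz mains component. The `"light"` intensity halves the burst
#' amplitude. Generation is a pure function of (profile, protocol,
#' arguments): the global RNG state is saved and restored.
#'
#' @param profile a [SubjectProfile-class].
#' @param protocol a [ProtocolSpec-class].
#' @param shared_noise logical; if TRUE the left and right channels of each
#'   region share one noise stream (and mains phase), producing exactly
#'   symmetric sides when `attenuation = 1`. Default FALSE: independent
#'   streams per channel.
#' @param ramp_s envelope on/off ramp duration in seconds (default 0.1).
#' @param montage channel table, defaults to [defaultMontage()].
#' @return An [EmgRecording-class].
#' @examples
#' prof <- SubjectProfile("S001", hb_grade = 3, lesioned_side = "left",
#'                        seed = 42)
#' rec <- generateRecording(prof, ProtocolSpec(n_trials = 2L))
#' rec
#' @export
generateRecording <- function(profile, protocol, shared_noise = FALSE,
                              ramp_s = 0.1, montage = defaultMontage()) {
  stopifnot(is(profile, "SubjectProfile"), is(protocol, "ProtocolSpec"))
  validObject(profile); validObject(protocol)
  if (profile@fars)
    stop("synkinetic (FARS) activity generation is not implemented")

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })

  n <- protocolSamples(protocol)
  fs <- protocol@fs_hz
  env <- .moveRestEnvelope(protocol, ramp_s = ramp_s)
  tt <- (seq_len(n) - 1) / fs
  rel_region <- .MOVEMENT_REGION[[protocol@movement]]
  amp <- profile@burst_amplitude *
    if (protocol@intensity == "light") 0.5 else 1

  ## burst band 20-250 Hz, clipped below Nyquist for low-rate protocols
  band_hi <- min(250, 0.45 * fs)
  bf <- signal::butter(4, c(20, band_hi) / (fs / 2), type = "pass")
  region_idx <- match(montage$region, .REGIONS)

  samples <- matrix(0, nrow = n, ncol = nrow(montage))
  for (i in seq_len(nrow(montage))) {
    side <- montage$side[i]; region <- montage$region[i]
    stream_id <- if (shared_noise) region_idx[i] else i
    set.seed(.channelSeed(profile@seed, protocol@movement, stream_id))
    b <- as.numeric(signal::filter(bf, stats::rnorm(n)))
    b <- b / stats::sd(b)
    phi <- stats::runif(1, 0, 2 * pi)
    noise <- stats::rnorm(n, 0, profile@baseline_noise_sd)
    x <- noise + profile@mains_amplitude * sin(2 * pi * 50 * tt + phi)
    if (region == rel_region) {
      g <- if (side == profile@lesioned_side) profile@attenuation else 1
      x <- x + env * (amp * g) * b
    }
    samples[, i] <- x
  }
  EmgRecording(samples, fs_hz = fs, channels = montage)
}

#' Ordinal House-Brackmann group coding
#'
#' The five-level ordinal grouping used for all severity statistics:
#' 0 = HB I healthy controls, 1 = HB I patients, 2 = HB II+III,
#' 3 = HB IV+V, 4 = HB VI. The raw six-level grade is kept alongside in all
#' metadata tables.
#'
#' @param hb_grade integer vector in 1..6.
#' @param is_control logical vector; TRUE for healthy controls (only
#'   meaningful for grade I).
#' @return Integer vector of group codes 0..4.
#' @examples
#' hbGroupCode(c(1, 1, 3, 5, 6), is_control = c(TRUE, FALSE, FALSE, FALSE, FALSE))
#' @export
hbGroupCode <- function(hb_grade, is_control = FALSE) {
  g <- as.integer(hb_grade)
  if (anyNA(g) || any(g < 1L | g > 6L)) stop("hb_grade must be in 1..6")
  is_control <- rep_len(as.logical(is_control), length(g))
  code <- integer(length(g))
  code[g == 1L] <- ifelse(is_control[g == 1L], 0L, 1L)
  code[g %in% 2:3] <- 2L
  code[g %in% 4:5] <- 3L
  code[g == 6L] <- 4L
  code
}

#' @rdname hbGroupCode
#' @return `hbGroupLabels()`: the five group labels in code order.
#' @export
hbGroupLabels <- function() {
  c("HB I controls", "HB I patients", "HB II+III", "HB IV+V", "HB VI")
}

## representative raw grades cycled within each ordinal group
.GROUP_GRADES <- list(`0` = 1L, `1` = 1L, `2` = c(2L, 3L),
                      `3` = c(4L, 5L), `4` = 6L)

#' Generate a severity-graded synthetic cohort
#'
#' Builds subject profiles for each requested House-Brackmann group and
#' (optionally) their recordings for a set of protocol runs. Per-subject
#' burst amplitude and baseline noise are jittered log-normally around the
#' defaults to emulate inter-subject variability in absolute sEMG amplitude;
#' within a group the raw grades of the group (e.g. II and III) are cycled.
#' Everything is deterministic given `master_seed`.
#'
#' @param n_per_group integer >= 1, subjects per group.
#' @param groups integer vector of ordinal group codes 0..4 (see
#'   [hbGroupCode()]).
#' @param protocols list of [ProtocolSpec-class] runs each subject performs.
#' @param master_seed integer master seed.
#' @param burst_amplitude,baseline_noise_sd,mains_amplitude cohort-level
#'   default signal parameters (uV) around which subjects are jittered.
#' @param burst_jitter_sdlog,noise_jitter_sdlog log-normal jitter SDs for the
#'   per-subject burst amplitude and baseline noise.
#' @param return_recordings logical; if FALSE only profiles and the manifest
#'   are returned (recordings for large cohorts are better generated
#'   on the fly from the profiles).
#' @return A list with `profiles` (list of [SubjectProfile-class]),
#'   `manifest` (data.frame: subject_id, hb_grade, hb_group, is_control,
#'   lesioned_side), and, when requested, `recordings` (per subject, a list
#'   of [EmgRecording-class] per protocol).
#' @examples
#' coh <- generateCohort(1, groups = c(0, 4),
#'                       protocols = list(ProtocolSpec(n_trials = 1L)),
#'                       master_seed = 7)
#' coh$manifest
#' @export
generateCohort <- function(n_per_group, groups = 0:4,
                           protocols = list(ProtocolSpec()),
                           master_seed = 1L,
                           burst_amplitude = 50, baseline_noise_sd = 2,
                           mains_amplitude = 10,
                           burst_jitter_sdlog = 0.3,
                           noise_jitter_sdlog = 0.2,
                           return_recordings = TRUE) {
  if (length(groups) == 0L) stop("at least one HB group is required")
  groups <- as.integer(groups)
  if (anyNA(groups) || any(groups < 0L | groups > 4L))
    stop("groups must be ordinal codes in 0..4")
  if (n_per_group < 1L) stop("n_per_group must be >= 1")
  stopifnot(all(vapply(protocols, is, logical(1), "ProtocolSpec")))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(master_seed))

  profiles <- list()
  rows <- list()
  k <- 0L
  for (grp in groups) {
    grades <- .GROUP_GRADES[[as.character(grp)]]
    for (j in seq_len(n_per_group)) {
      k <- k + 1L
      id <- sprintf("S%03d", k)
      grade <- grades[((j - 1L) %% length(grades)) + 1L]
      is_control <- grp == 0L
      side <- if (is_control) "none" else sample(.SIDES, 1L)
      burst <- burst_amplitude * exp(stats::rnorm(1, 0, burst_jitter_sdlog))
      noise <- baseline_noise_sd * exp(stats::rnorm(1, 0, noise_jitter_sdlog))
      seed <- sample.int(2147483646L, 1L)
      profiles[[id]] <- SubjectProfile(
        id, hb_grade = grade, lesioned_side = side,
        burst_amplitude = burst, baseline_noise_sd = noise,
        mains_amplitude = mains_amplitude, seed = seed)
      rows[[id]] <- data.frame(
        subject_id = id, hb_grade = grade, hb_group = grp,
        is_control = is_control, lesioned_side = side,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL

  out <- list(profiles = profiles, manifest = manifest)
  if (return_recordings) {
    out$recordings <- lapply(profiles, function(p)
      lapply(protocols, function(pr) generateRecording(p, pr)))
  }
  out
}
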